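#!/usr/bin/env Rscript
# Stage 1 -- synthetic study populations.
#
# Builds six populations in two "regions" whose demographic histories mimic
# the regional shapes of human mtDNA skyline profiles: region A populations
# share a ten-fold expansion starting 40 ka (rapid ancient growth), region B
# populations an older, milder expansion from a larger base. For each
# population a coalescent genealogy of 100 sequences is drawn, a partitioned
# whole-mtDNA alignment (~16.5 kb) simulated, and 85 sequences subsampled --
# the same equalised sample size used across real populations. SNP allele
# counts for the Fst stage are simulated under a Balding-Nichols model.
#
# Outputs under results/simulated/: per-population NEXUS alignments with
# charsets, true genealogies (newick, years), the true demographies (JSON),
# and a shared SNP counts table.

suppressPackageStartupMessages(library(mtskyline))

seed <- 20260926L
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

demogs <- list(
  A1 = demography(c(0, 40000), c(10000, 1000)),
  A2 = demography(c(0, 40000), c(12000, 1200)),
  A3 = demography(c(0, 35000), c(9000, 1100)),
  B1 = demography(c(0, 15000, 60000), c(30000, 26000, 8000)),
  B2 = demography(c(0, 18000, 60000), c(34000, 28000, 9000)),
  B3 = demography(c(0, 16000, 55000), c(28000, 25000, 8500))
)
regions <- c(A1 = "A", A2 = "A", A3 = "A", B1 = "B", B2 = "B", B3 = "B")
scheme <- partition_scheme()

for (p in names(demogs)) {
  tr <- sample_coalescent_tree(100, demogs[[p]], seed = derive_seed(seed, p, "tree"),
                               labels = sprintf("%s_%03d", p, 1:100))
  aln <- simulate_alignment(tr, scheme, seed = derive_seed(seed, p, "seq"))
  aln <- subsample_alignment(aln, 85, seed = derive_seed(seed, p, "sub"))
  write_alignment(aln, file.path(out, paste0(p, ".nex")), format = "nexus",
                  seed = seed)
  ape::write.tree(tr, file.path(out, paste0(p, "_true.nwk")))
  write_demography_json(demogs[[p]], file.path(out, paste0(p, "_demography.json")))
  seg <- sum(vapply(names(aln), function(nm)
    sum(apply(aln[[nm]], 2, function(col) length(unique(col)) > 1)), 0))
  cat(sprintf("%s: root %6.0f yr BP, %d segregating sites in 85 x %d bp\n",
              p, max(ape::branching.times(tr)), seg, sum(vapply(aln, ncol, 0L))))
}

counts <- simulate_snp_counts(0.08, n_loci = 4000, samples_per_pop = 170,
                              n_pops = length(demogs),
                              pop_labels = names(demogs),
                              region_map = regions, F_within = 0.015,
                              seed = derive_seed(seed, "snp"))
write_snp_counts(counts, file.path(out, "snp_counts.tsv"), seed = seed)
writeLines(jsonlite::toJSON(as.list(regions), auto_unbox = TRUE),
           file.path(out, "regions.json"))
cat("SNP counts:", 4000, "loci x", length(demogs), "populations written\n")
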