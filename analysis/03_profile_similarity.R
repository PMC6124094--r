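#!/usr/bin/env Rscript
# Stage 3 -- profile similarity and its clustering.
#
# Reads the demographic profiles of stage 2, computes the pairwise lambda
# statistic (sum of absolute log-size differences at 21 evenly spaced time
# points over the shorter of each pair of histories), and clusters the
# matrix with neighbour joining. If regional structure is recovered, the
# within-region lambda values should be small relative to between-region
# values and the NJ tree should separate the regions.
#
# Outputs under results/similarity/: lambda.tsv (+ PHYLIP copy) and
# nj_lambda.nwk.

suppressPackageStartupMessages(library(mtskyline))

seed <- 20260926L
prof_dir <- "results/skyline/profiles"
out <- "results/similarity"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

files <- list.files(prof_dir, pattern = "\\.tsv$", full.names = TRUE)
profiles <- lapply(files, read_profile)
names(profiles) <- sub("\\.tsv$", "", basename(files))

lam <- lambda_matrix(profiles)
write_matrix_tsv(lam, file.path(out, "lambda.tsv"), seed = seed, phylip = TRUE)

regions <- unlist(jsonlite::read_json("results/simulated/regions.json"))
within <- between <- c()
for (i in rownames(lam)) for (j in colnames(lam)) {
  if (i >= j) next
  if (regions[i] == regions[j]) within <- c(within, lam[i, j])
  else between <- c(between, lam[i, j])
}
cat(sprintf("lambda within regions : mean %5.1f (n=%d)\n", mean(within), length(within)))
cat(sprintf("lambda between regions: mean %5.1f (n=%d)\n", mean(between), length(between)))

tr <- nj_tree(lam)
ape::write.tree(tr, file.path(out, "nj_lambda.nwk"))
cat("NJ tree of profile similarity:", ape::write.tree(tr), "\n")
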