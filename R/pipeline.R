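# End-to-end pipeline: simulate -> skyline -> profiles -> lambda -> Fst ->
# NJ trees -> association, with per-stage seeds and an ESS gate.

#' Pipeline configuration
#'
#' Describes an end-to-end synthetic run: one demography per population,
#' sampling and subsampling sizes, the partition scheme, skyline MCMC
#' settings, SNP-simulation settings for Fst, and an optional region map for
#' the association stage. All randomness derives from the single `seed` via
#' [derive_seed()] substreams named by population and stage.
#'
#' @param populations Named list of [demography()] objects.
#' @param seed Top-level integer seed (mandatory: reproducibility is the
#'   contract).
#' @param n_tips Sequences simulated per population before subsampling.
#' @param n_subsample Sequences retained per population (default 85, an
#'   equalised sample size across populations).
#' @param scheme A [partition_scheme()].
#' @param tree_source `"clock"` rebuilds the genealogy from the simulated
#'   alignment with [build_clock_tree()] (the full data path);
#'   `"true"` conditions the MCMC on the simulated genealogy itself
#'   (isolates the demographic model).
#' @param skyline A [skyline_config()].
#' @param snp List with `F`, `n_loci`, `samples_per_pop` for
#'   [simulate_snp_counts()].
#' @param regions Optional named character vector population -> region.
#' @param profile_points Grid size of extracted profiles.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(populations, seed,
                            n_tips = 100, n_subsample = 85,
                            scheme = partition_scheme(),
                            tree_source = c("clock", "true"),
                            skyline = skyline_config(),
                            snp = list(F = 0.1, n_loci = 5000,
                                       samples_per_pop = 100),
                            regions = NULL, profile_points = 100) {
  if (missing(seed)) stop("'seed' is mandatory for a reproducible run")
  stopifnot(is.list(populations), length(populations) >= 2,
            all(vapply(populations, inherits, TRUE, "demography")),
            !is.null(names(populations)), !anyDuplicated(names(populations)),
            n_subsample <= n_tips)
  tree_source <- match.arg(tree_source)
  if (!is.null(regions)) {
    miss <- setdiff(names(populations), names(regions))
    if (length(miss))
      stop("populations absent from the region map: ",
           paste(miss, collapse = ", "))
  }
  structure(list(populations = populations, seed = as.integer(seed),
                 n_tips = n_tips, n_subsample = n_subsample, scheme = scheme,
                 tree_source = tree_source, skyline = skyline, snp = snp,
                 regions = regions, profile_points = profile_points),
            class = "pipeline_config")
}

#' Run the full demographic-history pipeline on synthetic populations
#'
#' Per population: simulate a genealogy and alignment from its demography,
#' subsample to the target size, obtain the analysis genealogy (clock tree
#' or truth), run replicate skyline MCMC chains, apply the ESS convergence
#' gate (populations failing it are flagged, never dropped), combine the
#' chains after burn-in and extract the demographic profile. Across
#' populations: the pairwise lambda matrix, simulated SNP counts and the
#' Hudson Fst matrix, neighbour-joining trees of both, and the
#' lambda-vs-Fst Mantel association. Fully deterministic given the config
#' seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, profiles, matrices, trees,
#'   counts and a JSON report are written there.
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `"pipeline_result"`: `profiles`, `posteriors`,
#'   `lambda`, `fst`, `trees` (NJ trees as newick strings), `association`,
#'   `diagnostics` (per population: ESS table, gate flag, acceptance rates,
#'   HPD of the number of change points), and the config seed.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  pops <- names(config$populations)
  seed <- config$seed
  sk <- config$skyline

  profiles <- list()
  posteriors <- list()
  diagnostics <- list()
  for (p in pops) {
    say("population ", p, ": simulate")
    d <- config$populations[[p]]
    tr_true <- sample_coalescent_tree(config$n_tips, d, g = sk$g, f = sk$f,
                                      seed = derive_seed(seed, p, "tree"),
                                      labels = sprintf("%s_%03d", p,
                                                       seq_len(config$n_tips)))
    tree <- tr_true
    if (config$tree_source == "clock") {
      aln <- simulate_alignment(tr_true, config$scheme,
                                seed = derive_seed(seed, p, "seq"))
      aln <- subsample_alignment(aln, config$n_subsample,
                                 seed = derive_seed(seed, p, "subsample"))
      tree <- build_clock_tree(aln, config$scheme)
    } else if (config$n_subsample < config$n_tips) {
      keep <- local({
        set.seed(derive_seed(seed, p, "subsample"))
        sample(tr_true$tip.label, config$n_subsample)
      })
      tree <- ape::keep.tip(tr_true, keep)
    }

    say("population ", p, ": ", sk$n_runs, " skyline run(s)")
    runs <- lapply(seq_len(sk$n_runs), function(r) {
      t0 <- Sys.time()
      run <- skyline_mcmc(tree, sk, seed = derive_seed(seed, p, "mcmc", r))
      attr(run, "runtime_s") <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      run
    })
    comb <- combine_traces(runs, sk$burn_in_fraction)

    ess_tab <- c(loglik = ess(comb$samples$loglik),
                 logprior = suppressWarnings(ess(comb$samples$logprior)),
                 n_changes = suppressWarnings(ess(comb$samples$n_changes)),
                 ne0 = ess(comb$traj[, 1]))
    gate <- all(ess_tab >= sk$ess_threshold)
    if (!gate) say("population ", p, ": ESS gate FAILED (flagged, kept)")
    hpd_k <- hpd_interval(comb$samples$n_changes, 0.95)

    profiles[[p]] <- extract_profile(comb, config$profile_points)
    posteriors[[p]] <- comb
    diagnostics[[p]] <- list(
      ess = as.list(ess_tab), ess_pass = gate,
      acceptance = as.list(comb$acceptance),
      hpd_n_changes = hpd_k,
      runtime_s = vapply(runs, attr, 0, "runtime_s"),
      root_age = max(comb$grid_times))
  }

  say("lambda matrix")
  lam <- lambda_matrix(profiles)

  say("SNP counts and Fst matrix")
  counts <- simulate_snp_counts(config$snp$F, config$snp$n_loci,
                                config$snp$samples_per_pop,
                                n_pops = length(pops), pop_labels = pops,
                                seed = derive_seed(seed, "snp"))
  fst <- fst_matrix(counts)

  say("NJ trees and association")
  trees <- list(lambda = ape::write.tree(nj_tree(lam)),
                fst = ape::write.tree(nj_tree(fst)))
  assoc <- profile_fst_association(lam, fst, n_permutations = 999,
                                   regions = config$regions,
                                   seed = derive_seed(seed, "mantel"))

  res <- structure(list(profiles = profiles, posteriors = posteriors,
                        lambda = lam, fst = fst, trees = trees,
                        association = assoc, diagnostics = diagnostics,
                        seed = seed),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir, counts = counts)
  res
}

#' Write a pipeline result to disk
#'
#' Profiles, lambda and Fst matrices, NJ trees, SNP counts and a JSON report
#' of all diagnostics land under `out_dir`, every table headed by a
#' provenance comment with the producing seed.
#'
#' @param res A `"pipeline_result"`.
#' @param out_dir Output directory (created if needed).
#' @param counts Optional SNP counts table to include.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(res, out_dir, counts = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "profiles"), showWarnings = FALSE)
  for (p in names(res$profiles))
    write_profile(res$profiles[[p]],
                  file.path(out_dir, "profiles", paste0(p, ".tsv")),
                  seed = res$seed)
  write_matrix_tsv(res$lambda, file.path(out_dir, "lambda.tsv"),
                   seed = res$seed, phylip = TRUE)
  write_matrix_tsv(res$fst, file.path(out_dir, "fst.tsv"),
                   seed = res$seed, phylip = TRUE)
  writeLines(res$trees$lambda, file.path(out_dir, "nj_lambda.nwk"))
  writeLines(res$trees$fst, file.path(out_dir, "nj_fst.nwk"))
  if (!is.null(counts))
    write_snp_counts(counts, file.path(out_dir, "snp_counts.tsv"),
                     seed = res$seed)
  report <- list(
    version = as.character(utils::packageVersion("mtskyline")),
    seed = res$seed,
    diagnostics = res$diagnostics,
    association = list(correlation = res$association$correlation,
                       mantel_p = res$association$mantel_p))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(out_dir)
}
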