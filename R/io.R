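# File formats: FASTA/NEXUS alignments, newick trees, TSV tables.
#
# Tabular outputs carry a "# mtskyline <version> seed=<seed>" header comment
# so any result file declares its producing version and seed; readers skip
# comment lines. FASTA has no comment syntax, so alignments record
# provenance in the NEXUS variant only.

.provenance_line <- function(seed = NA) {
  ver <- as.character(utils::packageVersion("mtskyline"))
  sprintf("# mtskyline %s seed=%s", ver, ifelse(is.na(seed), "NA", seed))
}

.write_tsv <- function(df, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_line(seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write an alignment to FASTA (one file per partition) or NEXUS
#'
#' FASTA mode writes `<prefix>_<partition>.fasta` per partition. NEXUS mode
#' writes a single file with the partitions concatenated and a `sets` block
#' of `charset` lines naming each partition, the layout Bayesian phylogenetic
#' tools expect.
#'
#' @param aln An `"mt_alignment"`.
#' @param path Output file (NEXUS) or prefix (FASTA).
#' @param format `"fasta"` or `"nexus"`.
#' @param seed Seed recorded in the NEXUS provenance comment.
#' @return The path(s) written, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "nexus"), seed = NA) {
  stopifnot(inherits(aln, "mt_alignment"))
  format <- match.arg(format)
  if (format == "fasta") {
    out <- character(0)
    for (nm in names(aln)) {
      p <- paste0(path, "_", nm, ".fasta")
      ape::write.FASTA(ape::as.DNAbin(aln[[nm]]), p)
      out <- c(out, p)
    }
    return(invisible(out))
  }
  full <- do.call(cbind, aln)
  lens <- vapply(aln, ncol, 0L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines(sprintf("[%s]", sub("^# ", "", .provenance_line(seed))), con)
  writeLines("BEGIN DATA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(full), ncol(full)), con)
  writeLines("  FORMAT DATATYPE=DNA MISSING=? GAP=-;", con)
  writeLines("  MATRIX", con)
  for (i in seq_len(nrow(full)))
    writeLines(sprintf("    %s  %s", rownames(full)[i],
                       paste(full[i, ], collapse = "")), con)
  writeLines("  ;", con)
  writeLines("END;", con)
  writeLines("BEGIN SETS;", con)
  for (k in seq_along(lens))
    writeLines(sprintf("  CHARSET %s = %d-%d;", names(aln)[k], starts[k], ends[k]), con)
  writeLines("END;", con)
  invisible(path)
}

#' Read an alignment from FASTA files or a NEXUS file with charsets
#'
#' FASTA mode takes a named character vector of per-partition files. NEXUS
#' mode reads the sequence matrix and, when a `sets` block with `charset`
#' lines is present, recovers the partition boundaries; without one the
#' alignment is returned as a single partition.
#'
#' @param path NEXUS file, or named character vector of FASTA files (names =
#'   partition names).
#' @param format `"fasta"` or `"nexus"`.
#' @return An `"mt_alignment"` (no scheme attribute; pair it with a
#'   [partition_scheme()] whose site counts match, e.g. for
#'   [build_clock_tree()]).
#' @export
read_alignment <- function(path, format = c("fasta", "nexus")) {
  format <- match.arg(format)
  if (format == "fasta") {
    if (is.null(names(path)) || any(!nzchar(names(path))))
      stop("FASTA mode needs a named vector of files (names = partitions)")
    parts <- lapply(path, function(p) {
      x <- ape::read.FASTA(p)
      if (anyDuplicated(names(x))) stop("duplicate sequence ids in ", p)
      lens <- lengths(x)
      if (length(unique(lens)) != 1)
        stop("ragged alignment in ", p, ": record '",
             names(x)[which(lens != lens[1])[1]], "' has ",
             lens[lens != lens[1]][1], " sites, expected ", lens[1])
      m <- toupper(as.character(as.matrix(x)))
      bad <- !(m %in% c("A", "C", "G", "T", "-", "N", "?"))
      if (any(bad)) stop("illegal character '", m[bad][1], "' in ", p)
      m
    })
    return(structure(parts, class = "mt_alignment"))
  }
  lines <- readLines(path)
  seqs <- ape::read.nexus.data(path)
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids in ", path)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1)
    stop("ragged alignment in ", path, ": record '",
         names(seqs)[which(lens != lens[1])[1]], "'")
  full <- toupper(do.call(rbind, seqs))
  rownames(full) <- names(seqs)
  bad <- !(full %in% c("A", "C", "G", "T", "-", "N", "?"))
  if (any(bad)) stop("illegal character '", full[bad][1], "' in ", path)

  cs <- regmatches(lines,
                   regexpr("charset\\s+[^=;]+=\\s*[0-9]+\\s*-\\s*[0-9]+",
                           lines, ignore.case = TRUE))
  if (!length(cs)) {
    return(structure(list(all = full), class = "mt_alignment"))
  }
  parts <- list()
  for (s in cs) {
    nm <- sub("(?i)charset\\s+([^=;\\s]+).*", "\\1", s, perl = TRUE)
    rng <- as.integer(strsplit(sub(".*=\\s*", "", s), "\\s*-\\s*")[[1]])
    parts[[nm]] <- full[, rng[1]:rng[2], drop = FALSE]
  }
  structure(parts, class = "mt_alignment")
}

#' Write / read a demographic profile as TSV
#'
#' Columns `time`, `median`, `lower`, `upper`; a provenance comment line
#' leads the file.
#'
#' @param profile A `"demographic_profile"`.
#' @param path File path.
#' @param seed Seed recorded in the header comment.
#' @return `write_profile`: the path, invisibly. `read_profile`: the
#'   profile.
#' @export
write_profile <- function(profile, path, seed = NA) {
  stopifnot(inherits(profile, "demographic_profile"))
  .write_tsv(as.data.frame(profile), path, seed = seed)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- .read_tsv(path)
  demographic_profile(df$time, df$median, df$lower, df$upper)
}

#' Write / read a labelled square matrix (lambda or Fst) as TSV
#'
#' Square layout with a `label` first column and one column per population;
#' `phylip = TRUE` additionally writes a PHYLIP-style distance matrix for
#' external tree builders.
#'
#' @param m Symmetric labelled matrix.
#' @param path File path.
#' @param seed Seed recorded in the header comment.
#' @param phylip Also write `<path>.phylip`.
#' @return `write_matrix_tsv`: the path, invisibly. `read_matrix_tsv`: the
#'   matrix.
#' @export
write_matrix_tsv <- function(m, path, seed = NA, phylip = FALSE) {
  m <- as.matrix(m)
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  .write_tsv(df, path, seed = seed)
  if (phylip) {
    con <- file(paste0(path, ".phylip"), "w")
    writeLines(sprintf("%5d", nrow(m)), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(formatC(rownames(m)[i], width = -10),
                       paste(sprintf("%.6f", m[i, ]), collapse = " ")), con)
    close(con)
  }
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$label
  colnames(m) <- df$label
  m
}

#' Write SNP allele counts as TSV
#'
#' @param counts Counts data frame (`locus`, `pop`, `derived_count`,
#'   `total`).
#' @param path File path.
#' @param seed Seed recorded in the header comment.
#' @return The path, invisibly.
#' @export
write_snp_counts <- function(counts, path, seed = NA) {
  .write_tsv(counts[, c("locus", "pop", "derived_count", "total")], path,
             seed = seed)
}

#' @rdname write_snp_counts
#' @export
read_snp_counts <- function(path) .read_tsv(path)

#' Read / write a demography as JSON (list of [time, Ne] knots)
#'
#' @param d A [demography()].
#' @param path File path.
#' @return `write_demography_json`: the path, invisibly;
#'   `read_demography_json`: a [demography()].
#' @export
write_demography_json <- function(d, path) {
  stopifnot(inherits(d, "demography"))
  jsonlite::write_json(list(knots = Map(c, d$times, d$sizes)), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_demography_json
#' @export
read_demography_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- x$knots
  if (is.list(k)) k <- do.call(rbind, k)
  demography(k[, 1], k[, 2])
}

#' Derive a reproducible child seed from a top-level seed
#'
#' All randomness in multi-stage runs flows from one top-level seed through
#' named substreams, so adding a population or stage does not perturb the
#' draws of existing ones. A small deterministic string hash keeps the
#' result a valid 31-bit R seed.
#'
#' @param seed Integer top-level seed.
#' @param ... Stage / population labels (coerced to character).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}
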