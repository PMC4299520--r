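# Distance matrix assembly and serialization (PHYLIP square, NEXUS
# distances block). Matrices are plain symmetric numeric matrices with
# genome ids as dimnames plus `method` and `provenance` attributes;
# undefined corrections are NA entries.

.as_estimate_df <- function(estimates) {
  if (inherits(estimates, "raw_estimate")) estimates <- list(estimates)
  do.call(rbind, lapply(estimates, function(e) {
    stopifnot(inherits(e, "raw_estimate"))
    data.frame(genome_a = e$genome_a, genome_b = e$genome_b,
               replicate = e$replicate, k_fail = e$k_fail, n = e$n,
               seed = e$seed, stringsAsFactors = FALSE)
  }))
}

#' Assemble distance matrices from raw estimates
#'
#' In `"pooled"` mode, failure and draw counts are summed across replicates
#' per genome pair before correcting (100 replicates of 100000 draws pool to
#' 10 million); correcting the summed counts is not the same as averaging
#' per-replicate corrections. In `"per_replicate"` mode one matrix per
#' replicate index is returned, the inputs for replicate ("bootstrap")
#' trees.
#'
#' @param estimates List of `raw_estimate` objects covering all unordered
#'   pairs of the taxon set (for each replicate in `per_replicate` mode).
#' @param correction `"raw"`, `"jc"`, `"tajima"`, or `"logcorr"`.
#' @param combine `"pooled"` or `"per_replicate"`.
#' @param m Circular arrangement constant for the corrections; defaults to
#'   the `m` recorded in the estimates.
#' @return A distance matrix (pooled) or a list of matrices indexed by
#'   replicate. Undefined corrections are NA.
#' @export
assemble_matrix <- function(estimates,
                            correction = c("raw", "jc", "tajima", "logcorr"),
                            combine = c("pooled", "per_replicate"), m = NULL) {
  correction <- match.arg(correction)
  combine <- match.arg(combine)
  df <- .as_estimate_df(estimates)
  if (is.null(m)) m <- estimates[[1L]]$m %||% 60L
  taxa <- sort(unique(c(df$genome_a, df$genome_b)))
  build <- function(sub, tag) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    agg_k <- tapply(sub$k_fail, key(sub$genome_a, sub$genome_b), sum)
    agg_n <- tapply(sub$n, key(sub$genome_a, sub$genome_b), sum)
    M <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
    missing <- character(0)
    for (i in seq_along(taxa)[-1L]) {
      for (j in seq_len(i - 1L)) {
        kk <- key(taxa[i], taxa[j])
        if (is.na(agg_n[kk])) {
          missing <- c(missing, paste(taxa[j], taxa[i], sep = "-"))
          next
        }
        v <- .correct_counts(agg_k[[kk]], agg_n[[kk]], correction, m)
        M[i, j] <- M[j, i] <- v
      }
    }
    if (length(missing)) {
      stop("assembly error (", tag, "): missing pairs ",
           paste(missing, collapse = ", "))
    }
    attr(M, "method") <- correction
    attr(M, "provenance") <- list(m = m, combine = combine, tag = tag,
                                  total_n = sum(sub$n))
    M
  }
  if (combine == "pooled") return(build(df, "pooled"))
  reps <- sort(unique(df$replicate))
  out <- lapply(reps, function(r) build(df[df$replicate == r, , drop = FALSE],
                                        paste0("replicate_", r)))
  names(out) <- reps
  out
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param m Square distance matrix with taxon dimnames.
#' @param path Output path.
#' @param na String used for undefined entries (default `"-1"`; PHYLIP has
#'   no NA convention).
#' @return `path`, invisibly.
#' @export
write_phylip_matrix <- function(m, path, na = "-1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    vals <- ifelse(is.na(m[i, ]), na, sprintf("%.8f", m[i, ]))
    writeLines(paste(formatC(rownames(m)[i], width = -10), paste(vals, collapse = "  ")), con)
  }
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' @param path File path (first line: taxon count; then one row per taxon:
#'   name followed by the full row of distances).
#' @return Symmetric numeric matrix with taxon dimnames.
#' @export
read_phylip_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) < n + 1L) stop("malformed PHYLIP matrix")
  taxa <- character(n)
  M <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    taxa[i] <- parts[1L]
    row <- as.numeric(parts[-1L])
    if (length(row) != n) stop("malformed PHYLIP row for taxon ", parts[1L])
    M[i, ] <- row
  }
  dimnames(M) <- list(taxa, taxa)
  M[M < 0] <- NA_real_
  M
}

#' Write a NEXUS distances block
#'
#' Emits a PAUP-compatible NEXUS file with a taxa block and a distances
#' block (`triangle=both`).
#'
#' @param m Square distance matrix with taxon dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nexus_distances <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  taxa <- rownames(m)
  writeLines(c("#NEXUS", "", "begin taxa;",
               sprintf("  dimensions ntax=%d;", length(taxa)),
               paste0("  taxlabels ", paste(taxa, collapse = " "), ";"),
               "end;", "", "begin distances;",
               sprintf("  dimensions ntax=%d;", length(taxa)),
               "  format triangle=both diagonal labels missing=?;",
               "  matrix"), con)
  for (i in seq_along(taxa)) {
    vals <- ifelse(is.na(m[i, ]), "?", sprintf("%.8f", m[i, ]))
    writeLines(paste0("    ", formatC(taxa[i], width = -12),
                      paste(vals, collapse = " ")), con)
  }
  writeLines(c("  ;", "end;"), con)
  invisible(path)
}

#' Write per-pair distance estimates as TSV
#'
#' One row per (pair, replicate): counts, raw distance, and the three
#' corrections.
#'
#' @param estimates List of `raw_estimate`.
#' @param path Output path.
#' @param m Arrangement constant for the corrections.
#' @return `path`, invisibly.
#' @export
write_distance_table <- function(estimates, path, m = NULL) {
  df <- .as_estimate_df(estimates)
  if (is.null(m)) m <- estimates[[1L]]$m %||% 60L
  df$D <- df$k_fail / df$n
  df$D_jc <- .jc_value(df$D, m)
  df$D_tajima <- vapply(seq_len(nrow(df)),
                        function(i) .tajima_value(df$k_fail[i], df$n[i], m),
                        numeric(1))
  df$D_log <- .log_value(df$D)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
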