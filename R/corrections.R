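# Divergence corrections for the raw distributed gene order distance.
# Random rearrangement saturates the raw distance at (m-1)/m, where m is the
# number of circular arrangement classes of the k drawn orthologs (60 for
# six, 12 for five). The corrections map the saturating raw frequency to an
# additive divergence, in direct analogy with nucleotide distance
# corrections for multiple hits.

.jc_value <- function(D, m) {
  a <- (m - 1) / m
  out <- rep(NA_real_, length(D))
  ok <- D >= 0 & D < a
  out[ok] <- -a * log(1 - D[ok] / a)
  out
}

.log_value <- function(D) {
  out <- rep(NA_real_, length(D))
  ok <- D >= 0 & D < 1
  out[ok] <- -log(1 - D[ok])
  out
}

.tajima_value <- function(k_fail, n, m, rel_tol = 1e-12) {
  if (k_fail > n) stop("k_fail exceeds n")
  if (k_fail < 0 || n < 1) stop("invalid counts")
  if (k_fail == 0) return(0)
  ratio <- m / (m - 1)
  t <- k_fail / n
  s <- t
  i <- 1
  while (i < k_fail) {
    t <- t * ((k_fail - i) / (n - i)) * (i / (i + 1)) * ratio
    s <- s + t
    i <- i + 1
    if (t < rel_tol * s) break
  }
  s
}

.corrected <- function(method, value, m = NA_integer_) {
  structure(list(method = method, value = value, m = m,
                 defined = is.finite(value)),
            class = "corrected_distance")
}

#' @export
print.corrected_distance <- function(x, ...) {
  cat(sprintf("corrected_distance [%s%s]: %s\n", x$method,
              if (is.na(x$m)) "" else paste0(", m=", x$m),
              if (all(x$defined)) format(x$value) else "undefined"))
  invisible(x)
}

#' Adapted Jukes-Cantor correction for gene order distance
#'
#' Computes `-((m-1)/m) * ln(1 - (m/(m-1)) * D)`, the gene order analogue of
#' the Jukes-Cantor nucleotide correction: with m equally likely circular
#' arrangements in the saturated limit, the raw distance D converges to
#' (m-1)/m, and this logarithm maps it back to an additive divergence. For
#' six orthologs (m = 60) the formula is `-(59/60) ln(1 - (60/59) D)` and it
#' is undefined for D >= 59/60.
#'
#' @param D Raw distance in `[0, 1]`.
#' @param m Circular arrangement constant (default 60, the six-gene value).
#' @return A `corrected_distance`; `$value` is `NA` with `$defined = FALSE`
#'   when `D >= (m-1)/m`.
#' @export
jc_correction <- function(D, m = 60L) {
  if (any(D < 0)) stop("D must be non-negative")
  .corrected("jc", .jc_value(D, m), as.integer(m))
}

#' Tajima series correction for gene order distance
#'
#' The falling-factorial (unbiased moment) series analogue of
#' [jc_correction()]:
#' `sum_{i=1..k} k^(i) / (i * ((m-1)/m)^(i-1) * n^(i))` with
#' `k^(i) = k!/(k-i)!` and `n^(i) = n!/(n-i)!`, where k is the number of
#' failed draws and n the number of draws. Unlike the logarithm it is finite
#' for every k <= n, which matters for genome pairs at or beyond the random
#' expectation. Terms are accumulated by recurrence and truncated when the
#' relative term falls below `rel_tol` (or at i = k).
#'
#' @param k_fail Number of draws failing the order test.
#' @param n Number of valid draws.
#' @param m Circular arrangement constant (default 60).
#' @param rel_tol Relative truncation tolerance (default 1e-12).
#' @return A `corrected_distance` (always defined).
#' @export
tajima_correction <- function(k_fail, n, m = 60L, rel_tol = 1e-12) {
  .corrected("tajima", .tajima_value(k_fail, n, m, rel_tol), as.integer(m))
}

#' Simple logarithmic correction D' = -ln(1 - D)
#'
#' The common saturation transform, computationally much lighter than the
#' series and functionally close to the five-gene distance corrected with
#' the six-gene constant.
#'
#' @param D Raw distance in `[0, 1)`.
#' @return A `corrected_distance`; undefined for D >= 1.
#' @export
log_correction <- function(D) {
  if (any(D < 0)) stop("D must be non-negative")
  .corrected("logcorr", .log_value(D))
}

#' Domain boundary of the adapted Jukes-Cantor correction
#'
#' The supremum of raw distances with a finite correction: `(m-1)/m`, the
#' saturation expectation for randomly ordered genomes.
#'
#' @param m Circular arrangement constant.
#' @return `(m-1)/m`.
#' @export
jc_domain_sup <- function(m = 60L) (m - 1) / m

# numeric correction dispatcher used by matrix assembly
.correct_counts <- function(k_fail, n, method, m) {
  switch(method,
         raw = k_fail / n,
         jc = .jc_value(k_fail / n, m),
         tajima = .tajima_value(k_fail, n, m),
         logcorr = .log_value(k_fail / n),
         stop("unknown correction method: ", method))
}
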