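# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' Mixes a base seed with an arbitrary set of string keys (genome pair,
#' replicate index, pipeline stage) into a positive 32-bit integer, so that
#' every source of randomness in a run flows deterministically from one
#' user-supplied seed and is independent of execution order.
#'
#' @param seed Integer base seed.
#' @param ... Character or numeric keys naming the substream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  keys <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                       character(1)), collapse = "\r")
  h <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (ch in utf8ToInt(keys)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

# evaluate expr under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# all permutations of 1..k as a k! x k integer matrix (k small)
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(k)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], k, after = pos - 1L)
    }
  }
  out
}

# canonical label for a circular order up to rotation + reflection:
# lexicographically smallest rotation of the sequence or its reverse
circular_canonical <- function(p) {
  k <- length(p)
  best <- NULL
  for (q in list(p, rev(p))) {
    for (s in seq_len(k)) {
      rot <- q[((seq_len(k) + s - 2L) %% k) + 1L]
      key <- paste(rot, collapse = ".")
      if (is.null(best) || key < best) best <- key
    }
  }
  best
}

#' Count circular arrangement classes
#'
#' Exhaustively enumerates all `k!` linear orders of `k` labels and counts
#' the distinct classes under rotation and reflection of the circle. For
#' `k = 6` this is 60; for `k = 5` it is 12. The reciprocal of this count is
#' the chance that two randomly ordered genomes agree on the circular order
#' of `k` shared orthologs, which is why it appears as the constant `m` in
#' the saturation corrections.
#'
#' @param k Number of labels (2..7; enumeration is exhaustive).
#' @return Integer number of equivalence classes.
#' @export
circular_order_classes <- function(k) {
  stopifnot(k >= 2L, k <= 7L)
  perms <- permutations_of(as.integer(k))
  keys <- apply(perms, 1L, circular_canonical)
  length(unique(keys))
}
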