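# Distributed gene order distance: Monte Carlo sampler, exact enumerator,
# and the primitive order/spacing tests they share. The estimator repeatedly
# draws k well-separated ortholog pairs and asks whether they lie in the
# same circular order in both genomes; the raw distance D is the fraction of
# draws for which they do not.

# row-wise ranks of a B x k matrix of distinct values (k small)
.row_ranks <- function(p) {
  k <- ncol(p)
  r <- matrix(1L, nrow(p), k)
  for (j in seq_len(k)) {
    for (l in seq_len(k)) {
      if (l != j) r[, j] <- r[, j] + (p[, l] < p[, j])
    }
  }
  r
}

# vectorized order test: pa, pb are B x k position matrices for the same k
# orthologs, column-aligned. Circular case: pass iff the permutation
# relating the two orders is a rotation or a reflected rotation (dihedral),
# i.e. all cyclic rank differences equal 1 or all equal k-1. Linear case:
# pass iff the relating permutation is the identity or the full reversal.
.order_pass <- function(pa, pb, circular = TRUE) {
  B <- nrow(pa)
  k <- ncol(pa)
  ra <- .row_ranks(pa)
  rb <- .row_ranks(pb)
  sigma <- matrix(0L, B, k)
  sigma[cbind(rep(seq_len(B), k), as.vector(ra))] <- as.vector(rb)
  if (circular) {
    d <- (sigma[, c(seq_len(k)[-1L], 1L), drop = FALSE] - sigma) %% k
    (rowSums(d == 1L) == k) | (rowSums(d == (k - 1L)) == k)
  } else {
    fwd <- matrix(seq_len(k), B, k, byrow = TRUE)
    (rowSums(sigma == fwd) == k) | (rowSums(sigma == fwd[, k:1, drop = FALSE]) == k)
  }
}

# vectorized spacing test on a B x k position matrix
.spacing_ok <- function(pos, L, min_gap, circular = TRUE) {
  k <- ncol(pos)
  ok <- rep(TRUE, nrow(pos))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      d <- abs(pos[, i] - pos[, j])
      if (circular) d <- pmin(d, L - d)
      ok <- ok & (d >= min_gap)
    }
  }
  ok
}

#' Test whether k orthologs are in the same circular order in two genomes
#'
#' The two position vectors index the same k orthologs in the same pairing
#' order, on circles of length `len_a` and `len_b`. The test passes iff the
#' cyclic sequence of the orthologs around genome B equals the sequence
#' around genome A up to rotation and reflection: a genome has no intrinsic
#' starting point or reading direction, and gene strand is ignored. For six
#' orthologs exactly 12 of the 720 linear permutations pass, so two
#' randomly ordered genomes agree with probability 1/60.
#'
#' @param positions_a,positions_b Integer positions (0-based ranks) of the
#'   orthologs in each genome.
#' @param len_a,len_b Replicon lengths (gene counts).
#' @param circular_a,circular_b Replicon circularity; if either is linear
#'   the test degrades to linear order (identity or reversal, no wrap).
#' @return `TRUE` if the circular orders agree.
#' @export
circular_order_equal <- function(positions_a, len_a, positions_b, len_b,
                                 circular_a = TRUE, circular_b = TRUE) {
  k <- length(positions_a)
  if (length(positions_b) != k) stop("ortholog count mismatch between genomes")
  if (k < 2L) stop("need at least two orthologs")
  if (anyDuplicated(positions_a) || anyDuplicated(positions_b)) {
    stop("duplicate positions")
  }
  if (any(positions_a < 0L | positions_a >= len_a) ||
      any(positions_b < 0L | positions_b >= len_b)) {
    stop("positions out of range")
  }
  .order_pass(matrix(as.integer(positions_a), 1L),
              matrix(as.integer(positions_b), 1L),
              circular = circular_a && circular_b)[1L]
}

#' Test the minimum-separation constraint for a set of positions
#'
#' Orthologs drawn for the order test must be at least `min_gap` genes away
#' from each other along the genome, which limits draws of co-operonic
#' genes. Separation is circular index distance: `min(|i-j|, L-|i-j|)`.
#'
#' @param positions Distinct integer positions on a circle of length `L`.
#' @param L Replicon length (gene count).
#' @param min_gap Minimum separation (default 5).
#' @param circular Use circular distance (default) or linear.
#' @return `TRUE` iff every pair of positions is separated by at least
#'   `min_gap`.
#' @export
spacing_valid <- function(positions, L, min_gap = 5L, circular = TRUE) {
  if (anyDuplicated(positions)) stop("duplicate positions")
  if (length(positions) < 2L) return(TRUE)
  .spacing_ok(matrix(as.integer(positions), 1L), L, min_gap, circular)[1L]
}

#' Sampler configuration for the distributed gene order distance
#'
#' @param k_genes Orthologs per draw, 5 or 6.
#' @param min_gap Minimum circular index separation between drawn orthologs,
#'   enforced in both genomes (default 5).
#' @param n_iter Valid draws per replicate (default 100000).
#' @param n_replicates Replicate samplings per genome pair (default 100).
#' @param seed Base seed; every (pair, replicate) stream is derived from it.
#' @param replicon_mode `"largest"` restricts each genome to its largest
#'   replicon before sampling; `"per-replicon"` draws a replicon pair with
#'   probability proportional to its count of co-resident shared orthologs,
#'   then draws all k orthologs from that pair.
#' @param m_constant `"auto"` uses the number of circular arrangement
#'   classes `(k_genes - 1)!/2` (60 for six genes, 12 for five); an integer
#'   fixes it (e.g. 60 for five-gene runs corrected with the six-gene
#'   equations).
#' @return An object of class `sampler_config` with the resolved arrangement
#'   constant in `$m`.
#' @export
sampler_config <- function(k_genes = 6L, min_gap = 5L, n_iter = 100000L,
                           n_replicates = 100L, seed = 1L,
                           replicon_mode = c("largest", "per-replicon"),
                           m_constant = "auto") {
  k_genes <- as.integer(k_genes)
  if (!k_genes %in% c(5L, 6L)) stop("k_genes must be 5 or 6")
  stopifnot(min_gap >= 1L, n_iter >= 1L, n_replicates >= 1L)
  replicon_mode <- match.arg(replicon_mode)
  if (identical(m_constant, "auto")) {
    m <- as.integer(factorial(k_genes - 1L) / 2L)
  } else if (is.character(m_constant) && grepl("^fixed:", m_constant)) {
    m <- as.integer(sub("^fixed:", "", m_constant))
  } else {
    m <- as.integer(m_constant)
  }
  if (is.na(m) || m < 2L) stop("invalid m_constant")
  structure(list(k_genes = k_genes, min_gap = as.integer(min_gap),
                 n_iter = as.integer(n_iter),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), replicon_mode = replicon_mode,
                 m_constant = m_constant, m = m),
            class = "sampler_config")
}

# shared ortholog position table for a genome pair under a config.
# Returns a data frame with one row per usable ortholog pair and an attached
# group table (one row per replicon pair).
.shared_loci <- function(a, b, orthomap, cfg) {
  if (!setequal(c(orthomap$genome_a, orthomap$genome_b),
                c(a$genome_id, b$genome_id))) {
    stop("ortholog map does not cover genomes ", a$genome_id, ", ", b$genome_id)
  }
  pairs <- orthomap$pairs
  if (orthomap$genome_a != a$genome_id) {
    pairs <- data.frame(gene_a = pairs$gene_b, gene_b = pairs$gene_a,
                        stringsAsFactors = FALSE)
  }
  if (cfg$replicon_mode == "largest") {
    a <- restrict_to_replicon(a, "largest")
    b <- restrict_to_replicon(b, "largest")
  }
  locus_table <- function(g) {
    do.call(rbind, lapply(g$replicons, function(r) {
      data.frame(gene_id = r$loci$gene_id, rep = r$replicon_id,
                 pos = r$loci$index, L = nrow(r$loci), circ = r$circular,
                 stringsAsFactors = FALSE)
    }))
  }
  ta <- locus_table(a)
  tb <- locus_table(b)
  ta <- ta[!ta$gene_id %in% a$excluded_genes, , drop = FALSE]
  tb <- tb[!tb$gene_id %in% b$excluded_genes, , drop = FALSE]
  ia <- match(pairs$gene_a, ta$gene_id)
  ib <- match(pairs$gene_b, tb$gene_id)
  keep <- !is.na(ia) & !is.na(ib)
  sh <- data.frame(gene_a = pairs$gene_a[keep], gene_b = pairs$gene_b[keep],
                   pos_a = ta$pos[ia[keep]], pos_b = tb$pos[ib[keep]],
                   rep_a = ta$rep[ia[keep]], rep_b = tb$rep[ib[keep]],
                   La = ta$L[ia[keep]], Lb = tb$L[ib[keep]],
                   circ_a = ta$circ[ia[keep]], circ_b = tb$circ[ib[keep]],
                   stringsAsFactors = FALSE)
  grp <- paste(sh$rep_a, sh$rep_b, sep = "\r")
  sh$group <- match(grp, sort(unique(grp)))
  sh[order(sh$group, sh$pos_a), , drop = FALSE]
}

# draw B rows of k distinct pool indices each
.draw_rows <- function(pool, B, k) {
  n <- length(pool)
  m <- matrix(0L, B, k)
  for (i in seq_len(B)) m[i, ] <- pool[sample.int(n, k)]
  m
}

#' Monte Carlo estimate of the raw distributed gene order distance
#'
#' Performs `cfg$n_iter` valid draws of `cfg$k_genes` shared orthologs
#' (uniformly, without replacement). A draw violating the minimum-separation
#' rule in either genome is discarded and redrawn; it does not count toward
#' n. The raw distance D is the fraction of valid draws whose circular order
#' test fails. Deterministic given the config seed, genome pair, and
#' replicate index.
#'
#' @param a,b [genome_record()]s.
#' @param orthomap An [ortholog_map()] between them.
#' @param cfg A [sampler_config()].
#' @param replicate_index Replicate number (names the RNG substream).
#' @param audit_file Optional path; when given, one TSV line per counted
#'   draw is appended (gene ids, positions, pass/fail) to support
#'   composition audits of the sampled sets.
#' @return An object of class `raw_estimate` with fields `k_fail`, `n`,
#'   `D = k_fail/n`, `seed`, `replicate`.
#' @export
sample_raw_distance <- function(a, b, orthomap, cfg, replicate_index = 1L,
                                audit_file = NULL) {
  sh <- .shared_loci(a, b, orthomap, cfg)
  k <- cfg$k_genes
  if (nrow(sh) < k) {
    stop("estimation error: only ", nrow(sh), " shared orthologs; need ", k)
  }
  groups <- split(seq_len(nrow(sh)), sh$group)
  gsize <- lengths(groups)
  ginfo <- lapply(groups, function(ix) {
    r <- sh[ix[1L], ]
    list(rows = ix, La = r$La, Lb = r$Lb, circ = r$circ_a && r$circ_b)
  })
  w <- ifelse(gsize >= k, gsize, 0L)
  if (sum(w) == 0L) stop("estimation error: no replicon pair shares ", k, " orthologs")
  stream_seed <- derive_seed(cfg$seed, a$genome_id, b$genome_id,
                             "replicate", replicate_index)
  audit_con <- NULL
  if (!is.null(audit_file)) {
    audit_con <- file(audit_file, open = "a")
    on.exit(close(audit_con), add = TRUE)
  }
  res <- with_seed(stream_seed, {
    n_valid <- 0L
    k_fail <- 0L
    attempts <- 0L
    n_ok_total <- 0L
    while (n_valid < cfg$n_iter) {
      need <- cfg$n_iter - n_valid
      B <- min(max(2L * need, 2000L), 100000L)
      gidx <- if (length(ginfo) == 1L) rep(1L, B) else
        sample.int(length(ginfo), B, replace = TRUE, prob = w)
      for (g in seq_along(ginfo)) {
        Bg <- sum(gidx == g)
        if (Bg == 0L || n_valid >= cfg$n_iter) next
        gi <- ginfo[[g]]
        rows <- .draw_rows(gi$rows, Bg, k)
        pa <- matrix(sh$pos_a[rows], Bg, k)
        pb <- matrix(sh$pos_b[rows], Bg, k)
        ok <- .spacing_ok(pa, gi$La, cfg$min_gap, sh$circ_a[gi$rows[1L]]) &
              .spacing_ok(pb, gi$Lb, cfg$min_gap, sh$circ_b[gi$rows[1L]])
        attempts <- attempts + Bg
        n_ok_total <- n_ok_total + sum(ok)
        if (attempts >= 10000L && n_ok_total / attempts < 0.001) {
          stop("unsatisfiable spacing: rejection rate > 99.9% over ",
               attempts, " attempts")
        }
        vr <- which(ok)
        if (!length(vr)) next
        take <- min(length(vr), cfg$n_iter - n_valid)
        vr <- vr[seq_len(take)]
        pass <- .order_pass(pa[vr, , drop = FALSE], pb[vr, , drop = FALSE],
                            circular = gi$circ)
        n_valid <- n_valid + take
        k_fail <- k_fail + sum(!pass)
        if (!is.null(audit_con)) {
          lines <- paste(
            apply(matrix(sh$gene_a[rows[vr, , drop = FALSE]], take, k), 1L,
                  paste, collapse = ","),
            apply(pa[vr, , drop = FALSE], 1L, paste, collapse = ","),
            apply(pb[vr, , drop = FALSE], 1L, paste, collapse = ","),
            ifelse(pass, "pass", "fail"), sep = "\t")
          writeLines(lines, audit_con)
        }
      }
    }
    list(k_fail = k_fail, n = n_valid)
  })
  structure(list(genome_a = a$genome_id, genome_b = b$genome_id,
                 k_fail = res$k_fail, n = res$n, D = res$k_fail / res$n,
                 seed = stream_seed, replicate = as.integer(replicate_index),
                 k_genes = k, m = cfg$m),
            class = "raw_estimate")
}

#' @export
print.raw_estimate <- function(x, ...) {
  cat(sprintf("raw_estimate %s-%s: D = %d/%d = %.5f (replicate %d)\n",
              x$genome_a, x$genome_b, x$k_fail, x$n, x$D, x$replicate))
  invisible(x)
}

#' Run all replicates for one genome pair
#'
#' @inheritParams sample_raw_distance
#' @return List of `raw_estimate`, one per replicate.
#' @export
sample_raw_distance_replicates <- function(a, b, orthomap, cfg) {
  lapply(seq_len(cfg$n_replicates), function(r) {
    sample_raw_distance(a, b, orthomap, cfg, replicate_index = r)
  })
}

#' Exact expectation of the raw distance by exhaustive enumeration
#'
#' Enumerates every spacing-valid k-subset of the shared orthologs and
#' returns the exact fraction failing the circular order test: the quantity
#' the Monte Carlo sampler estimates. Intended as a test oracle on small
#' genomes; refuses when the subset count exceeds `budget`.
#'
#' @inheritParams sample_raw_distance
#' @param budget Maximum number of k-subsets to enumerate (default 1e7).
#' @return The exact raw distance, with attributes `n_valid` (spacing-valid
#'   subsets) and `n_fail`.
#' @export
exact_raw_distance <- function(a, b, orthomap, cfg, budget = 1e7) {
  sh <- .shared_loci(a, b, orthomap, cfg)
  k <- cfg$k_genes
  if (nrow(sh) < k) stop("estimation error: fewer than ", k, " shared orthologs")
  if (length(unique(sh$group)) != 1L) {
    stop("exact oracle supports a single replicon pair only")
  }
  n <- nrow(sh)
  if (choose(n, k) > budget) {
    stop("combinatorial budget exceeded: choose(", n, ", ", k, ") subsets")
  }
  subsets <- utils::combn(n, k)
  circ <- sh$circ_a[1L] && sh$circ_b[1L]
  n_valid <- 0
  n_fail <- 0
  step <- 100000L
  for (from in seq(1L, ncol(subsets), by = step)) {
    cols <- from:min(from + step - 1L, ncol(subsets))
    rows <- t(subsets[, cols, drop = FALSE])
    pa <- matrix(sh$pos_a[rows], length(cols), k)
    pb <- matrix(sh$pos_b[rows], length(cols), k)
    ok <- .spacing_ok(pa, sh$La[1L], cfg$min_gap, sh$circ_a[1L]) &
          .spacing_ok(pb, sh$Lb[1L], cfg$min_gap, sh$circ_b[1L])
    if (!any(ok)) next
    pass <- .order_pass(pa[ok, , drop = FALSE], pb[ok, , drop = FALSE], circ)
    n_valid <- n_valid + sum(ok)
    n_fail <- n_fail + sum(!pass)
  }
  if (n_valid == 0) stop("unsatisfiable spacing: no valid subset exists")
  structure(n_fail / n_valid, n_valid = n_valid, n_fail = n_fail)
}
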