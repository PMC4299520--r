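#' Ortholog gene content distance
#'
#' Gene content similarity S is the number of ortholog pairs shared by two
#' genomes divided by the gene count of the smaller genome, computed
#' genome-wide (all replicons) after exclusion masks. The distance is
#' `-ln(S)` (default) or `1 - S`.
#'
#' @param a,b [genome_record()]s.
#' @param orthomap An [ortholog_map()] between them.
#' @param mode `"neglog"` or `"one_minus"`.
#' @return An object of class `content_distance` with fields `S`, `value`,
#'   `mode`, `n_pairs`.
#' @export
gene_content_distance <- function(a, b, orthomap, mode = c("neglog", "one_minus")) {
  mode <- match.arg(mode)
  ga <- genome_genes(a, apply_exclusions = TRUE)
  gb <- genome_genes(b, apply_exclusions = TRUE)
  pairs <- orthomap$pairs
  if (orthomap$genome_a != a$genome_id) {
    pairs <- data.frame(gene_a = pairs$gene_b, gene_b = pairs$gene_a,
                        stringsAsFactors = FALSE)
  }
  npairs <- sum(pairs$gene_a %in% ga & pairs$gene_b %in% gb)
  if (npairs == 0L) stop("zero shared orthologs: content distance is infinite")
  S <- npairs / min(length(ga), length(gb))
  value <- if (mode == "neglog") -log(S) else 1 - S
  structure(list(S = S, value = value, mode = mode, n_pairs = npairs),
            class = "content_distance")
}

#' @export
print.content_distance <- function(x, ...) {
  cat(sprintf("content_distance: S = %.4f, %s = %.4f (%d pairs)\n",
              x$S, if (x$mode == "neglog") "-ln(S)" else "1-S", x$value, x$n_pairs))
  invisible(x)
}

#' Correlate two distance matrices over their shared genome pairs
#'
#' Ordinary least squares of `y` on `x` over the lower-triangle pairs common
#' to both matrices (undefined entries excluded pairwise), optionally
#' restricted to pairs where `x` is below a threshold; used to compare gene
#' order distances against rRNA or protein sequence distances.
#'
#' @param x,y Square symmetric distance matrices with genome ids as
#'   dimnames (e.g. from [assemble_matrix()] or [read_phylip_matrix()]).
#' @param subset_max_x Optional threshold: keep only pairs with `x < `
#'   threshold.
#' @return List with `r_squared`, `slope`, `intercept`, `n_pairs`.
#' @export
correlate_matrices <- function(x, y, subset_max_x = NULL) {
  taxa <- intersect(rownames(x), rownames(y))
  if (length(taxa) < 3L) stop("need at least 3 shared taxa")
  xv <- x[taxa, taxa][lower.tri(x[taxa, taxa])]
  yv <- y[taxa, taxa][lower.tri(y[taxa, taxa])]
  keep <- is.finite(xv) & is.finite(yv)
  if (!is.null(subset_max_x)) keep <- keep & xv < subset_max_x
  xv <- xv[keep]
  yv <- yv[keep]
  if (length(xv) < 3L) stop("fewer than 3 usable pairs")
  fit <- stats::lm(yv ~ xv)
  list(r_squared = stats::cor(xv, yv)^2,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       n_pairs = length(xv))
}
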