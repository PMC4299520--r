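# Agreement subtrees: the largest taxon subsets on which every tree in a
# collection, after pruning, has the identical topology. Multi-tree maximum
# agreement is NP-hard, so the package ships an exhaustive small-instance
# search plus a greedy conflict-pruning heuristic for larger inputs.

# do all trees agree (identical topology) when restricted to `taxa`?
.all_agree <- function(trees, taxa) {
  if (length(taxa) < 4L) return(TRUE)
  ref <- bipartition_keys(.restrict_tree(trees[[1L]], taxa))
  for (t in trees[-1L]) {
    k <- bipartition_keys(.restrict_tree(t, taxa))
    if (length(k) != length(ref) || !setequal(k, ref)) return(FALSE)
  }
  TRUE
}

#' Exact maximum agreement subtrees (small instances)
#'
#' Exhaustive top-down search over taxon subsets, largest first, returning
#' all maximum-cardinality subsets on which every input tree restricts to
#' the same topology, together with that common restricted tree.
#'
#' @param trees List of `phylo` trees (>= 2) sharing a common taxon set.
#' @param max_taxa Refuse instances larger than this (default 20).
#' @return A list with one element per maximum agreement set:
#'   `list(taxa = <character>, tree = <phylo>)`.
#' @export
agreement_subtree_exact <- function(trees, max_taxa = 20L) {
  stopifnot(length(trees) >= 2L)
  common <- Reduce(intersect, lapply(trees, function(t) t$tip.label))
  if (length(common) > max_taxa) {
    stop("taxon set too large for exact search (", length(common), " > ",
         max_taxa, "); use agreement_subtree_heuristic")
  }
  common <- sort(common)
  for (size in seq(length(common), 3L)) {
    subsets <- utils::combn(common, size, simplify = FALSE)
    hits <- Filter(function(s) .all_agree(trees, s), subsets)
    if (length(hits)) {
      return(lapply(hits, function(s) {
        list(taxa = s, tree = .restrict_tree(trees[[1L]], s))
      }))
    }
  }
  list()
}

# total pairwise RF over all tree pairs restricted to `taxa`
.total_conflict <- function(trees, taxa) {
  if (length(taxa) < 4L) return(0L)
  keysets <- lapply(trees, function(t) bipartition_keys(.restrict_tree(t, taxa)))
  tot <- 0L
  for (i in seq_along(keysets)[-1L]) {
    for (j in seq_len(i - 1L)) {
      tot <- tot + length(setdiff(keysets[[i]], keysets[[j]])) +
        length(setdiff(keysets[[j]], keysets[[i]]))
    }
  }
  tot
}

#' Greedy agreement subtree heuristic
#'
#' Repeatedly removes the taxon whose deletion most reduces the total
#' pairwise Robinson-Foulds conflict across all trees (lexicographic
#' tie-break), until every restricted pair agrees. Always terminates (three
#' taxa always agree); the returned set is an agreement set but not
#' necessarily a maximum one.
#'
#' @param trees List of `phylo` trees (>= 2) with >= 4 shared taxa.
#' @return `list(taxa = <character>, tree = <phylo>)`.
#' @export
agreement_subtree_heuristic <- function(trees) {
  stopifnot(length(trees) >= 2L)
  taxa <- sort(Reduce(intersect, lapply(trees, function(t) t$tip.label)))
  if (length(taxa) < 4L) stop("need at least 4 shared taxa")
  current <- .total_conflict(trees, taxa)
  while (current > 0L && length(taxa) > 3L) {
    reductions <- vapply(taxa, function(tx) {
      current - .total_conflict(trees, setdiff(taxa, tx))
    }, numeric(1))
    best <- taxa[reductions == max(reductions)][1L]  # taxa sorted: lexicographic tie-break
    taxa <- setdiff(taxa, best)
    current <- .total_conflict(trees, taxa)
  }
  list(taxa = taxa, tree = .restrict_tree(trees[[1L]], taxa))
}

#' Write agreement subtree results
#'
#' @param results Output of [agreement_subtree_exact()] (list of sets) or a
#'   single [agreement_subtree_heuristic()] result.
#' @param newick_path Path for the Newick trees (one per line).
#' @param taxa_path Path for a TSV listing (set index, taxon).
#' @return Invisibly, the two paths.
#' @export
write_agreement <- function(results, newick_path, taxa_path) {
  if (!is.null(results$taxa)) results <- list(results)
  trees <- lapply(results, `[[`, "tree")
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, newick_path)
  tab <- do.call(rbind, lapply(seq_along(results), function(i) {
    data.frame(set = i, taxon = results[[i]]$taxa, stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, taxa_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(newick_path, taxa_path))
}
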