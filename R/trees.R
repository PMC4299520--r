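# Tree construction and comparison on `ape::phylo` objects: neighbor
# joining, midpoint rooting, bipartition-based Robinson-Foulds distance,
# and replicate support counting.

#' Neighbor joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration via [ape::nj()]. Negative branch-length
#' estimates (a known NJ artifact) are clamped to zero with the deficit
#' transferred to the sibling branch so leaf-to-leaf distances are
#' approximately preserved.
#'
#' @param m Square symmetric distance matrix with taxon dimnames; undefined
#'   (NA) entries are an error - impute or prune first.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(m) {
  if (nrow(m) < 3L) stop("need at least 3 taxa for NJ")
  if (anyNA(m)) {
    bad <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
    stop("undefined entries in distance matrix: ",
         paste(rownames(m)[bad[, 1L]], colnames(m)[bad[, 2L]],
               sep = "-", collapse = ", "),
         "; impute or prune before NJ")
  }
  tr <- ape::nj(m)
  for (pass in 1:5) {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    for (e in neg) {
      deficit <- tr$edge.length[e]
      tr$edge.length[e] <- 0
      sib <- which(tr$edge[, 1L] == tr$edge[e, 1L])
      sib <- setdiff(sib, e)
      if (length(sib)) {
        tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + deficit
      }
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path.
#'
#' @param tree An unrooted `phylo` with branch lengths.
#' @return A rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length) || all(tree$edge.length == 0)) {
    stop("midpoint undefined: all branch lengths are zero")
  }
  if (length(tree$tip.label) == 2L) {
    tot <- sum(tree$edge.length)
    tree$edge.length <- rep(tot / 2, length(tree$edge.length))
    return(tree)
  }
  phangorn::midpoint(tree)
}

#' Canonical bipartition keys of a tree
#'
#' Each non-trivial internal edge of an unrooted tree splits the leaves in
#' two; the key is the sorted label list of the side containing the overall
#' lexicographically smallest label. Two trees on the same leaf set are
#' topologically identical iff their key sets are equal.
#'
#' @param tree A `phylo`.
#' @return Character vector of bipartition keys (possibly empty).
#' @export
bipartition_keys <- function(tree) {
  labs <- tree$tip.label
  if (length(labs) < 4L) return(character(0))
  tree <- ape::unroot(tree)
  pp <- ape::prop.part(tree)
  anchor <- min(labs)
  keys <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (length(side) < 2L || length(side) > length(labs) - 2L) next
    if (!anchor %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

# restrict a tree to a taxon subset (ape::keep.tip keeps branch lengths)
.restrict_tree <- function(tree, taxa) {
  ape::keep.tip(tree, intersect(tree$tip.label, taxa))
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of non-trivial bipartitions after restricting
#' both trees to their shared leaf set (mode `"shared_taxa"`) or requiring
#' identical leaf sets (mode `"strict"`).
#'
#' @param t1,t2 `phylo` trees.
#' @param restrict `"shared_taxa"` or `"strict"`.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2, restrict = c("shared_taxa", "strict")) {
  restrict <- match.arg(restrict)
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (restrict == "strict" && !setequal(t1$tip.label, t2$tip.label)) {
    stop("strict mode requires identical label sets")
  }
  if (length(shared) < 4L) stop("RF undefined: fewer than 4 shared taxa")
  b1 <- bipartition_keys(.restrict_tree(t1, shared))
  b2 <- bipartition_keys(.restrict_tree(t2, shared))
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# TRUE when two trees agree on shared taxa (vacuously when < 4 shared)
.congruent <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L) return(TRUE)
  rf_distance(t1, t2) == 0L
}

#' Annotate a reference tree with replicate support counts
#'
#' Each internal edge of the reference is labeled with the number of
#' replicate trees containing the same bipartition, the support convention
#' for replicate Monte Carlo distance matrices: the reference tree comes
#' from the pooled distances and each replicate matrix contributes one tree.
#'
#' @param reference A `phylo` tree.
#' @param replicate_trees List of `phylo` trees on (a superset of) the
#'   reference taxa.
#' @return The reference with `node.label` set to support counts (root and
#'   trivial nodes get the replicate count).
#' @export
support_from_replicates <- function(reference, replicate_trees) {
  taxa <- reference$tip.label
  repsets <- lapply(replicate_trees, function(t) {
    if (!all(taxa %in% t$tip.label)) {
      stop("replicate tree missing reference taxa: ",
           paste(setdiff(taxa, t$tip.label), collapse = ", "))
    }
    bipartition_keys(.restrict_tree(t, taxa))
  })
  nrep <- length(replicate_trees)
  ref <- ape::unroot(reference)
  labs <- ref$tip.label
  anchor <- min(labs)
  pp <- ape::prop.part(ref)
  counts <- integer(length(pp))
  for (i in seq_along(pp)) {
    side <- labs[pp[[i]]]
    if (length(side) < 2L || length(side) > length(labs) - 2L) {
      counts[i] <- nrep
      next
    }
    if (!anchor %in% side) side <- setdiff(labs, side)
    key <- paste(sort(side), collapse = "|")
    counts[i] <- sum(vapply(repsets, function(ks) key %in% ks, logical(1)))
  }
  ref$node.label <- as.character(counts)
  ref
}
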