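# Hierarchical ranked-pair tree building: shorter distances are known with
# more confidence than longer ones, so trees are grown from a ranked list of
# pairwise distances, keeping only mutually congruent trees, then extended
# by single-taxon addition.

#' Ranked list of pairwise distances
#'
#' Lower-triangle pairs of a distance matrix, ascending by distance with
#' ties broken lexicographically by pair label. Undefined entries are ranked
#' last and flagged.
#'
#' @param m Square distance matrix with taxon dimnames.
#' @return A `ranked_pair_list` data frame with columns `rank`, `genome_a`,
#'   `genome_b`, `distance`, `defined`.
#' @export
build_ranked_list <- function(m) {
  taxa <- rownames(m)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  a <- pmin(taxa[idx[, 1L]], taxa[idx[, 2L]])
  b <- pmax(taxa[idx[, 1L]], taxa[idx[, 2L]])
  d <- m[idx]
  def <- is.finite(d)
  ord <- order(!def, ifelse(def, d, Inf), a, b)
  out <- data.frame(rank = seq_along(ord), genome_a = a[ord], genome_b = b[ord],
                    distance = d[ord], defined = def[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_pair_list", "data.frame")
  out
}

.ledger_entry <- function(formation_rank, last_rank, tree) {
  list(formation_rank = formation_rank, last_rank = last_rank,
       taxa = sort(tree$tip.label), tree = tree)
}

# try to merge `entry` with every congruent ledger entry; a merge is kept
# only if NJ on the union reproduces both original topologies and stays
# congruent with the rest of the ledger
.combine_pass <- function(ledger, entry, m, rank) {
  repeat {
    merged <- FALSE
    for (i in seq_along(ledger)) {
      other <- ledger[[i]]
      union_taxa <- sort(union(entry$taxa, other$taxa))
      if (length(union_taxa) == length(entry$taxa) ||
          anyNA(m[union_taxa, union_taxa])) next
      cand <- nj_tree(m[union_taxa, union_taxa])
      ok <- .congruent(.restrict_tree(cand, entry$taxa), entry$tree) &&
            .congruent(.restrict_tree(cand, other$taxa), other$tree)
      if (ok) {
        rest <- ledger[-i]
        ok <- all(vapply(rest, function(e) .congruent(cand, e$tree), logical(1)))
      }
      if (ok) {
        entry <- .ledger_entry(min(entry$formation_rank, other$formation_rank),
                               rank, cand)
        ledger <- ledger[-i]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  list(ledger = ledger, entry = entry)
}

#' Grow congruent trees down a ranked pair list
#'
#' Walks the ranked list maintaining a graph of included pairs. Whenever the
#' newly added pair completes a clique of four or more taxa (all pairwise
#' distances included), an NJ tree is built on that clique. A new tree is
#' rejected if it is incongruent (restricted RF > 0 on >= 4 shared taxa)
#' with any retained tree; otherwise it is retained, absorbing retained
#' trees fully contained in it, and pairwise combination with the other
#' retained trees is attempted (the union tree is kept only when its
#' restrictions reproduce both original topologies). Undefined distances
#' never enter the graph.
#'
#' @param ranked A [build_ranked_list()] result.
#' @param m The distance matrix the list was built from.
#' @return A `tree_ledger`: list of entries with `formation_rank`,
#'   `last_rank`, `taxa`, `tree`.
#' @export
grow_trees <- function(ranked, m) {
  taxa <- sort(rownames(m))
  A <- matrix(FALSE, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  ledger <- list()
  for (r in seq_len(nrow(ranked))) {
    if (!ranked$defined[r]) next
    u <- ranked$genome_a[r]
    v <- ranked$genome_b[r]
    A[u, v] <- A[v, u] <- TRUE
    common <- taxa[A[u, ] & A[v, ]]
    if (length(common) < 2L) next
    verts <- c(u, v, common)
    g <- igraph::graph_from_adjacency_matrix(A[verts, verts], mode = "undirected")
    cls <- igraph::max_cliques(g, min = 4L)
    cls <- Filter(function(cl) all(c(u, v) %in% names(cl)), cls)
    if (!length(cls)) next
    clique_sets <- lapply(cls, function(cl) sort(names(cl)))
    clique_sets <- clique_sets[order(vapply(clique_sets, paste, character(1),
                                            collapse = "|"))]
    for (cs in clique_sets) {
      cand <- nj_tree(m[cs, cs])
      if (!all(vapply(ledger, function(e) .congruent(cand, e$tree), logical(1)))) next
      contained <- vapply(ledger, function(e) all(e$taxa %in% cs), logical(1))
      formation <- if (any(contained)) {
        min(r, vapply(ledger[contained], `[[`, numeric(1), "formation_rank"))
      } else r
      ledger <- ledger[!contained]
      entry <- .ledger_entry(formation, r, cand)
      res <- .combine_pass(ledger, entry, m, r)
      ledger <- c(res$ledger, list(res$entry))
    }
  }
  structure(ledger, class = "tree_ledger")
}

#' @export
print.tree_ledger <- function(x, ...) {
  cat("tree_ledger:", length(x), "retained tree(s)\n")
  for (e in x) {
    cat(sprintf("  %d taxa (formed at rank %d, last pair rank %d)\n",
                length(e$taxa), e$formation_rank, e$last_rank))
  }
  invisible(x)
}

#' Largest tree in a ledger
#' @param ledger A `tree_ledger`.
#' @return The entry with the most taxa (ties: smallest formation rank).
#' @export
largest_ledger_tree <- function(ledger) {
  if (!length(ledger)) stop("empty ledger")
  sizes <- vapply(ledger, function(e) length(e$taxa), integer(1))
  forms <- vapply(ledger, function(e) e$formation_rank, numeric(1))
  ledger[[order(-sizes, forms)[1L]]]
}

#' Second-round single-taxon addition
#'
#' Candidate taxa are visited in order of their best (smallest-rank)
#' distance to any current tree member; each candidate is added by
#' rebuilding NJ on the union and accepted only if the restriction to the
#' prior taxa leaves the topology unchanged. The pass repeats until no
#' candidate is accepted.
#'
#' @param tree A `phylo` with >= 4 taxa (e.g. from [largest_ledger_tree()]).
#' @param m Distance matrix covering candidates and tree taxa.
#' @param ranked The corresponding [build_ranked_list()].
#' @return The extended `phylo` tree.
#' @export
add_single_taxa <- function(tree, m, ranked) {
  stopifnot(length(tree$tip.label) >= 4L)
  repeat {
    members <- tree$tip.label
    cands <- setdiff(rownames(m), members)
    cands <- cands[vapply(cands, function(cd) !anyNA(m[cd, members]), logical(1))]
    if (!length(cands)) return(tree)
    touches <- (ranked$genome_a %in% cands & ranked$genome_b %in% members) |
               (ranked$genome_b %in% cands & ranked$genome_a %in% members)
    sub <- ranked[touches & ranked$defined, , drop = FALSE]
    cd_of <- ifelse(sub$genome_a %in% cands, sub$genome_a, sub$genome_b)
    best <- tapply(sub$rank, cd_of, min)
    cands <- cands[order(best[cands], cands)]
    cands <- cands[!is.na(best[cands])]
    accepted <- FALSE
    for (cd in cands) {
      un <- sort(c(members, cd))
      cand_tree <- nj_tree(m[un, un])
      if (rf_distance(.restrict_tree(cand_tree, members), tree) == 0L) {
        tree <- cand_tree
        accepted <- TRUE
        break
      }
    }
    if (!accepted) return(tree)
  }
}

#' Write a tree ledger as TSV
#'
#' One row per retained tree: formation rank, last pair rank, taxon list,
#' Newick string.
#'
#' @param ledger A `tree_ledger`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_ledger <- function(ledger, path) {
  tab <- do.call(rbind, lapply(ledger, function(e) {
    data.frame(formation_rank = e$formation_rank, last_rank = e$last_rank,
               n_taxa = length(e$taxa), taxa = paste(e$taxa, collapse = ","),
               newick = ape::write.tree(e$tree), stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) {
    tab <- data.frame(formation_rank = numeric(0), last_rank = numeric(0),
                      n_taxa = integer(0), taxa = character(0),
                      newick = character(0))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
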