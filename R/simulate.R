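# Synthetic-data generator: circular genomes evolving by inversions and
# transpositions, shuffled-order saturation controls, and additive matrices
# for tree-algorithm oracles. Events preserve gene content exactly; gene
# gain/loss, duplication, and horizontal transfer are deliberately not
# modeled.

#' Rearrangement model
#'
#' @param inversion_weight,transposition_weight Non-negative relative
#'   weights of the two event types (not both zero). The default is
#'   inversion-only: inversions are the dominant rearrangement between
#'   closely related prokaryotes.
#' @param segment_dist Segment length distribution: `"geometric"` with
#'   parameter `geom_p` (default; most fixed rearrangements are local) or
#'   `"uniform"` on 1..floor(L/2), the regime of occasional genome-half
#'   inversions, which randomizes order within a few dozen events.
#' @param geom_p Geometric parameter (mean segment length ~ 1/p).
#' @param events_per_branch `"poisson"` (counts drawn as
#'   Poisson(rate x branch length)) or a fixed non-negative integer.
#' @param rate Events per unit branch length for the Poisson option.
#' @return An object of class `rearrangement_model`.
#' @export
rearrangement_model <- function(inversion_weight = 1, transposition_weight = 0,
                                segment_dist = c("geometric", "uniform"),
                                geom_p = 0.05, events_per_branch = "poisson",
                                rate = 1) {
  segment_dist <- match.arg(segment_dist)
  stopifnot(inversion_weight >= 0, transposition_weight >= 0)
  if (inversion_weight + transposition_weight == 0) {
    stop("event weights must not both be zero")
  }
  structure(list(inversion_weight = inversion_weight,
                 transposition_weight = transposition_weight,
                 segment_dist = segment_dist, geom_p = geom_p,
                 events_per_branch = events_per_branch, rate = rate),
            class = "rearrangement_model")
}

#' Generate a random circular genome
#'
#' One circular replicon with genes `g0..g{n-1}` in index order and random
#' strands. Simulated descendants keep these gene ids, so orthology between
#' them is the identity map.
#'
#' @param n_genes Number of genes.
#' @param genome_id Genome id.
#' @param seed Integer seed.
#' @return A [genome_record()].
#' @export
random_genome <- function(n_genes, genome_id, seed = 1L) {
  stopifnot(n_genes >= 1L)
  with_seed(derive_seed(seed, "random_genome", genome_id), {
    ids <- paste0("g", seq_len(n_genes) - 1L)
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    genome_record(genome_id, replicon("chr", ids, strands, circular = TRUE))
  })
}

#' Independently shuffle the gene order of a genome
#'
#' The saturation control: a uniformly random circular order shares the
#' arrangement of k sampled orthologs with any other order only by chance.
#'
#' @param genome A [genome_record()].
#' @param seed Integer seed.
#' @param genome_id Optional new genome id (default: keep).
#' @return A [genome_record()] with each replicon's order permuted.
#' @export
shuffle_gene_order <- function(genome, seed = 1L, genome_id = NULL) {
  gid <- genome_id %||% genome$genome_id
  with_seed(derive_seed(seed, "shuffle", gid), {
    reps <- lapply(genome$replicons, function(r) {
      p <- sample.int(nrow(r$loci))
      replicon(r$replicon_id, r$loci$gene_id[p], r$loci$strand[p], r$circular)
    })
    genome_record(gid, unname(reps),
                  intersect(genome$excluded_genes, genome_genes(genome)))
  })
}

.flip <- function(strand) c("+" = "-", "-" = "+", "?" = "?")[strand]

.sample_seg_len <- function(model, L) {
  if (model$segment_dist == "uniform") {
    sample.int(max(1L, L %/% 2L), 1L)
  } else {
    min(L - 1L, 1L + stats::rgeom(1L, model$geom_p))
  }
}

# apply one event to an (ids, strands) order; circular indexing
.one_event <- function(ids, strands, model) {
  L <- length(ids)
  type <- sample(c("inv", "trans"), 1L,
                 prob = c(model$inversion_weight, model$transposition_weight))
  len <- .sample_seg_len(model, L)
  start <- sample.int(L, 1L) - 1L
  idx <- ((start + seq_len(len) - 1L) %% L) + 1L
  if (type == "inv") {
    ids[idx] <- rev(ids[idx])
    strands[idx] <- .flip(rev(strands[idx]))
  } else {
    if (len >= L) len <- L - 1L
    idx <- ((start + seq_len(len) - 1L) %% L) + 1L
    seg_ids <- ids[idx]
    seg_str <- strands[idx]
    rem_ids <- ids[-idx]
    rem_str <- strands[-idx]
    at <- sample.int(length(rem_ids) + 1L, 1L) - 1L
    ids <- append(rem_ids, seg_ids, after = at)
    strands <- append(rem_str, seg_str, after = at)
  }
  list(ids = ids, strands = strands)
}

#' Apply rearrangement events to a genome
#'
#' Inversions reverse a contiguous circular segment (flipping strands);
#' transpositions excise a segment and reinsert it elsewhere. The gene set
#' is unchanged. Single-replicon genomes only.
#'
#' @param genome A [genome_record()] with one replicon.
#' @param model A [rearrangement_model()].
#' @param n_events Number of events (>= 0).
#' @param seed Integer seed.
#' @return The rearranged [genome_record()].
#' @export
apply_events <- function(genome, model, n_events, seed = 1L) {
  stopifnot(n_events >= 0L, length(genome$replicons) == 1L)
  r <- genome$replicons[[1L]]
  with_seed(derive_seed(seed, "events", genome$genome_id, n_events), {
    ids <- r$loci$gene_id
    strands <- r$loci$strand
    for (e in seq_len(n_events)) {
      res <- .one_event(ids, strands, model)
      ids <- res$ids
      strands <- res$strands
    }
    stopifnot(setequal(ids, r$loci$gene_id))  # content conservation
    genome_record(genome$genome_id,
                  replicon(r$replicon_id, ids, strands, r$circular),
                  genome$excluded_genes)
  })
}

#' Evolve genomes along a tree by rearrangement
#'
#' Descends the tree from the root genome, applying per-branch event counts
#' (Poisson(rate x length) or fixed per the model); tips become genomes
#' named by the tip labels. Orthology between any two leaves is the
#' identity on gene ids.
#'
#' @param tree A `phylo` with non-negative branch lengths.
#' @param root_genome A single-replicon [genome_record()].
#' @param model A [rearrangement_model()].
#' @param seed Integer seed.
#' @return `list(genomes = <named list of genome_record>, true_tree = tree)`.
#' @export
evolve_along_tree <- function(tree, root_genome, model, seed = 1L) {
  stopifnot(all(tree$edge.length >= 0))
  tree <- stats::reorder(tree, "cladewise")  # parents precede descendants
  ntip <- length(tree$tip.label)
  node_genomes <- vector("list", ntip + tree$Nnode)
  node_genomes[[ntip + 1L]] <- root_genome
  genomes <- list()
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    bl <- tree$edge.length[e]
    n_events <- if (identical(model$events_per_branch, "poisson")) {
      with_seed(derive_seed(seed, "branch_count", e),
                stats::rpois(1L, model$rate * bl))
    } else as.integer(model$events_per_branch)
    gparent <- node_genomes[[parent]]
    child_id <- if (child <= ntip) tree$tip.label[child] else paste0("node", child)
    gp <- genome_record(child_id, unname(gparent$replicons), gparent$excluded_genes)
    gchild <- apply_events(gp, model, n_events, seed = derive_seed(seed, "branch", e))
    node_genomes[[child]] <- gchild
    if (child <= ntip) genomes[[child_id]] <- gchild
  }
  list(genomes = genomes, true_tree = tree)
}

#' Additive leaf-to-leaf distance matrix of a tree
#'
#' Path-length distances between all leaf pairs; the oracle input on which
#' neighbor joining provably recovers the generating topology.
#'
#' @param tree A `phylo` with branch lengths.
#' @return Symmetric matrix with taxa sorted alphabetically.
#' @export
additive_matrix <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  taxa <- sort(rownames(m))
  m[taxa, taxa]
}
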