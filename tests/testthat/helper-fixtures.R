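# Fixture builders and independent oracles used across the suite.

# small genome with the given gene order on one circular replicon
toy_genome <- function(id, order, circular = TRUE) {
  genome_record(id, replicon("chr", order, circular = circular))
}

# independent scalar order test: generate all rotations of the A-ordered
# gene sequence and of its reverse, and ask whether the B-ordered sequence
# is among them (set membership, no rank arithmetic)
oracle_order_equal <- function(pos_a, pos_b, circular = TRUE) {
  k <- length(pos_a)
  seq_a <- order(pos_a)        # orthologs by A position
  seq_b <- order(pos_b)
  images <- list()
  cands <- if (circular) {
    c(lapply(seq_len(k) - 1L, function(s) seq_a[((seq_len(k) + s - 1L) %% k) + 1L]),
      lapply(seq_len(k) - 1L, function(s) rev(seq_a)[((seq_len(k) + s - 1L) %% k) + 1L]))
  } else {
    list(seq_a, rev(seq_a))
  }
  any(vapply(cands, function(im) all(im == seq_b), logical(1)))
}

# brute-force reciprocal best hits by direct double scan
oracle_rbh <- function(hits_ab, hits_ba) {
  best_of <- function(h, q) {
    rows <- h[h$qseqid == q, , drop = FALSE]
    if (nrow(rows) == 0L) return(NA_character_)
    agg <- tapply(rows$bitscore, rows$sseqid, max)
    top <- names(agg)[agg == max(agg)]
    if (length(top) == 1L) top else NA_character_
  }
  pairs <- character(0)
  for (a in unique(hits_ab$qseqid)) {
    b <- best_of(hits_ab, a)
    if (is.na(b)) next
    back <- best_of(hits_ba, b)
    if (!is.na(back) && back == a) pairs <- c(pairs, paste(a, b, sep = "\r"))
  }
  sort(pairs)
}

# random BLAST-like hit tables between two id spaces
random_hit_tables <- function(seed, na = 6, nb = 6) {
  set.seed(seed)
  ids_a <- paste0("a", seq_len(na))
  ids_b <- paste0("b", seq_len(nb))
  mk <- function(qs, ss) {
    n <- sample(8:20, 1)
    data.frame(qseqid = sample(qs, n, replace = TRUE),
               sseqid = sample(ss, n, replace = TRUE),
               bitscore = sample(50:80, n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  list(ab = mk(ids_a, ids_b), ba = mk(ids_b, ids_a))
}

# copy a genome under a new id (same order; identity orthology)
clone_genome <- function(genome, id) {
  genome_record(id, unname(genome$replicons), genome$excluded_genes)
}

# randomly regraft `n_moves` leaves of a tree (topology perturbation)
regraft_leaves <- function(tree, n_moves, seed) {
  set.seed(seed)
  for (i in seq_len(n_moves)) {
    leaf <- sample(tree$tip.label, 1)
    pruned <- ape::drop.tip(tree, leaf)
    at <- sample(length(pruned$tip.label), 1)
    tree <- phangorn::add.tips(pruned, leaf, where = at)
  }
  tree
}

# the frozen rogue-taxon fixture: 6 clean taxa on a symmetric tree plus a
# seventh whose distances pull opposite ends of the tree together
rogue_fixture <- function() {
  clean <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);")
  m <- additive_matrix(clean)
  taxa <- rownames(m)
  m2 <- rbind(cbind(m, R = 0), R = 0)
  m2["R", taxa] <- m2[taxa, "R"] <- c(A = 0.05, B = 20, C = 20, D = 20, E = 20, F = 0.05)
  list(clean = clean, matrix = m2)
}
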