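make_estimate <- function(a, b, k_fail, n, replicate = 1L) {
  structure(list(genome_a = a, genome_b = b, k_fail = as.integer(k_fail),
                 n = as.integer(n), D = k_fail / n, seed = 0L,
                 replicate = as.integer(replicate), k_genes = 6L, m = 60L),
            class = "raw_estimate")
}

test_that("matrix assembly pools counts before correcting", {
  taxa <- c("A", "B", "C")
  zero <- list(make_estimate("A", "B", 0, 100), make_estimate("A", "C", 0, 100),
               make_estimate("B", "C", 0, 100))
  m0 <- assemble_matrix(zero, "raw", "pooled")
  expect_true(all(m0 == 0))
  expect_equal(dim(m0), c(3L, 3L))
  expect_equal(rownames(m0), taxa)

  # two replicates: pooled n is the sum and the correction is applied to the
  # summed counts, not averaged across replicates
  ests <- list(make_estimate("A", "B", 1, 10, 1), make_estimate("A", "B", 9, 10, 2),
               make_estimate("A", "C", 0, 10, 1), make_estimate("A", "C", 0, 10, 2),
               make_estimate("B", "C", 0, 10, 1), make_estimate("B", "C", 0, 10, 2))
  pooled <- assemble_matrix(ests, "jc", "pooled")
  expect_equal(pooled["A", "B"], jc_correction(0.5)$value)
  mean_of_corr <- mean(c(jc_correction(0.1)$value, jc_correction(0.9)$value))
  expect_false(isTRUE(all.equal(pooled["A", "B"], mean_of_corr)))
  expect_equal(attr(pooled, "provenance")$total_n, 60L)

  per <- assemble_matrix(ests, "jc", "per_replicate")
  expect_length(per, 2L)
  expect_equal(per[["1"]]["A", "B"], jc_correction(0.1)$value)
  expect_equal(per[["2"]]["A", "B"], jc_correction(0.9)$value)

  expect_error(assemble_matrix(ests[-(1:2)], "raw", "pooled"), "missing pairs.*A-B")
})

test_that("100 replicates of 100000 draws pool to 10 million", {
  ests <- unlist(lapply(1:100, function(r) {
    list(make_estimate("A", "B", 98000, 100000, r),
         make_estimate("A", "C", 0, 100000, r),
         make_estimate("B", "C", 0, 100000, r))
  }), recursive = FALSE)
  m <- assemble_matrix(ests, "tajima", "pooled")
  expect_equal(attr(m, "provenance")$total_n, 3e7)
  expect_equal(m["A", "B"],
               tajima_correction(9800000, 10000000, m = 60)$value)
})

test_that("NJ recovers the additive quartet with its branch lengths", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  m <- additive_matrix(tr)
  expect_equal(m["A", "B"], 3)
  expect_equal(m["A", "C"], 5)
  expect_equal(m["B", "D"], 7)
  nj <- nj_tree(m)
  expect_equal(rf_distance(nj, tr), 0L)
  expect_equal(additive_matrix(nj), m, tolerance = 1e-9)
})

test_that("three taxa resolve by the three-point formulas", {
  m <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(m)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 2, 3))
})

test_that("NJ is consistent on additive matrices from random trees", {
  for (s in 1:30) {
    set.seed(s)
    tr <- ape::rtree(sample(5:20, 1))
    expect_equal(rf_distance(nj_tree(additive_matrix(tr)), tr), 0L,
                 info = paste("seed", s))
  }
})

test_that("NJ refuses undefined entries with an informative message", {
  m <- additive_matrix(ape::rtree(5))
  m[1, 2] <- m[2, 1] <- NA
  expect_error(nj_tree(m), "undefined entries")
  expect_error(nj_tree(m[1:2, 1:2]), "at least 3")
})

test_that("RF distance counts bipartition differences and matches phangorn", {
  set.seed(3)
  t1 <- ape::rtree(8)
  expect_equal(rf_distance(t1, t1), 0L)
  q1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  q2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(rf_distance(q1, q2), 2L)
  # 5-taxon pair against exhaustive bipartition listing by hand:
  # t5a has splits AB|CDE and ABC|DE; t5b has AC|BDE and ABC|DE -> symdiff 2
  t5a <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,E:1):1);")
  t5b <- ape::read.tree(text = "(((A:1,C:1):1,B:1):1,(D:1,E:1):1);")
  expect_equal(rf_distance(t5a, t5b), 2L)
  # independent cross-check on random pairs
  for (s in 1:15) {
    set.seed(s)
    a <- ape::rtree(10)
    b <- ape::rtree(10)
    expect_equal(rf_distance(a, b),
                 as.integer(phangorn::RF.dist(ape::unroot(a), ape::unroot(b))),
                 info = paste("seed", s))
  }
  expect_error(rf_distance(ape::rtree(3), ape::rtree(3)), "fewer than 4")
  t10 <- ape::rtree(10); t9 <- ape::drop.tip(t10, "t1")
  expect_error(rf_distance(t10, t9, restrict = "strict"), "identical label sets")
  expect_equal(rf_distance(t10, t9), 0L)  # shared-taxa restriction
})

test_that("RF is a metric on random triples", {
  for (s in 1:10) {
    set.seed(s)
    trs <- replicate(3, ape::rtree(8), simplify = FALSE)
    d12 <- rf_distance(trs[[1]], trs[[2]])
    d13 <- rf_distance(trs[[1]], trs[[3]])
    d23 <- rf_distance(trs[[2]], trs[[3]])
    expect_true(d12 <= d13 + d23 && d13 <= d12 + d23 && d23 <= d12 + d13)
    expect_equal(d12, rf_distance(trs[[2]], trs[[1]]))
  }
})

test_that("midpoint rooting splits the longest leaf-to-leaf path", {
  two <- ape::read.tree(text = "(A:1,B:3);")
  expect_equal(midpoint_root(two)$edge.length, c(2, 2))
  # symmetric quartet: root lands on the central edge
  q <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  r <- midpoint_root(ape::unroot(q))
  kids <- ape::prop.part(r)
  clades <- lapply(kids, function(cl) sort(r$tip.label[cl]))
  expect_true(any(vapply(clades, identical, logical(1), c("A", "B"))) ||
              any(vapply(clades, identical, logical(1), c("C", "D"))))
  # caterpillar: longest path A-E of length 10; midpoint inside an internal edge
  cat5 <- ape::read.tree(text = "((((A:4,B:1):1,C:1):2,D:1):2,E:1);")
  mr <- midpoint_root(ape::unroot(cat5))
  dm <- ape::cophenetic.phylo(mr)
  expect_equal(unname(dm["A", "E"]), 10)
  zero <- ape::rtree(4)
  zero$edge.length[] <- 0
  expect_error(midpoint_root(zero), "midpoint undefined")
})

test_that("replicate support counts bipartition occurrences", {
  set.seed(5)
  ref <- ape::rtree(8)
  reps <- replicate(10, ref, simplify = FALSE)
  sup <- support_from_replicates(ref, reps)
  expect_true(all(as.integer(sup$node.label) == 10L))
  # construct 7-of-10 support for every reference split
  set.seed(6)
  other <- ape::rtree(8)
  while (rf_distance(other, ref) == 0) other <- ape::rtree(8)
  mixed <- c(replicate(7, ref, simplify = FALSE),
             replicate(3, other, simplify = FALSE))
  supm <- support_from_replicates(ref, mixed)
  labs <- as.integer(supm$node.label)
  shared_splits <- length(intersect(bipartition_keys(ref), bipartition_keys(other)))
  expect_equal(sum(labs == 7L), length(bipartition_keys(ref)) - shared_splits)
  # a bipartition absent from every replicate gets zero
  alltrees <- replicate(5, other, simplify = FALSE)
  if (!length(intersect(bipartition_keys(ref), bipartition_keys(other)))) {
    sup0 <- support_from_replicates(ref, alltrees)
    expect_true(all(as.integer(sup0$node.label)[-1] == 0L))
  }
})

test_that("Newick round-trip preserves topology, lengths, and support", {
  set.seed(9)
  ref <- ape::rtree(10)
  sup <- support_from_replicates(ref, replicate(4, ref, simplify = FALSE))
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(sup, path)
  back <- ape::read.tree(path)
  expect_equal(rf_distance(back, sup), 0L)
  expect_equal(sort(back$edge.length), sort(sup$edge.length), tolerance = 1e-9)
  expect_setequal(back$node.label, sup$node.label)
})

test_that("PHYLIP and NEXUS serialization", {
  m <- additive_matrix(ape::rtree(6))
  p <- withr::local_tempfile(fileext = ".phy")
  write_phylip_matrix(m, p)
  back <- read_phylip_matrix(p)
  expect_equal(back[rownames(m), colnames(m)], m, tolerance = 1e-7)
  nx <- withr::local_tempfile(fileext = ".nex")
  write_nexus_distances(m, nx)
  lines <- readLines(nx)
  expect_equal(lines[1], "#NEXUS")
  expect_true(any(grepl("begin distances;", lines)))
  expect_true(any(grepl("ntax=6", lines)))
})
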