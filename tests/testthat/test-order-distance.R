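test_that("the circular order test is invariant to rotation and reflection only", {
  # six consecutive orthologs A..F; swapping the genome-B positions of the
  # third and fifth (C and E) breaks the shared order
  expect_false(circular_order_equal(0:5, 6, c(0, 1, 4, 3, 2, 5), 6))
  # identity
  expect_true(circular_order_equal(c(0, 5, 10, 15, 20, 25), 30,
                                   c(0, 5, 10, 15, 20, 25), 30))
  # every rotation and every reflected rotation passes
  for (s in 0:5) {
    expect_true(circular_order_equal(0:5, 6, (0:5 + s) %% 6, 6))
    expect_true(circular_order_equal(0:5, 6, rev((0:5 + s) %% 6), 6))
  }
  # errors
  expect_error(circular_order_equal(c(0, 0, 2), 5, 0:2, 5), "duplicate")
  expect_error(circular_order_equal(0:5, 6, 0:4, 6), "mismatch")
})

test_that("the order test agrees with an independent membership oracle", {
  set.seed(42)
  for (rep in 1:200) {
    k <- sample(c(5L, 6L), 1)
    La <- sample(k:20, 1)
    Lb <- sample(k:20, 1)
    pa <- sample(La, k) - 1L
    pb <- sample(Lb, k) - 1L
    expect_equal(circular_order_equal(pa, La, pb, Lb),
                 oracle_order_equal(pa, pb),
                 info = sprintf("rep %d", rep))
  }
})

test_that("exactly 60 circular classes of six labels; 12 of 720 orders pass", {
  expect_equal(circular_order_classes(6), 60L)
  expect_equal(circular_order_classes(5), 12L)
  perms <- geneorderdist:::permutations_of(6L)
  pass <- apply(perms, 1, function(p) {
    pos_b <- integer(6)
    pos_b[p] <- 0:5   # ortholog i sits at circular position giving order p
    circular_order_equal(0:5, 6, pos_b, 6)
  })
  expect_equal(sum(pass), 12L)
  # five labels: 2k = 10 of 120 pass, hence 12 classes
  perms5 <- geneorderdist:::permutations_of(5L)
  pass5 <- apply(perms5, 1, function(p) {
    pos_b <- integer(5); pos_b[p] <- 0:4
    circular_order_equal(0:4, 5, pos_b, 5)
  })
  expect_equal(sum(pass5), 10L)
})

test_that("spacing constraint uses circular index separation", {
  expect_true(spacing_valid(c(0, 5, 10, 15), 20, 5))
  expect_false(spacing_valid(c(0, 4, 10, 15), 20, 5))
  expect_true(spacing_valid(c(0, 6), 12, 5))   # circular distance is 6
  expect_false(spacing_valid(c(0, 18), 20, 5)) # wraps to distance 2
  expect_true(spacing_valid(c(0, 18), 20, 5, circular = FALSE))
  expect_error(spacing_valid(c(1, 1), 10, 2), "duplicate")
})

test_that("sampler config resolves the arrangement constant", {
  expect_equal(sampler_config(k_genes = 6)$m, 60L)
  expect_equal(sampler_config(k_genes = 5)$m, 12L)
  expect_equal(sampler_config(k_genes = 5, m_constant = "fixed:60")$m, 60L)
  expect_equal(sampler_config(k_genes = 5, m_constant = 60)$m, 60L)
  expect_error(sampler_config(k_genes = 4), "5 or 6")
})

test_that("identical gene order gives raw distance zero; same seed is bit-identical", {
  a <- random_genome(150, "A", seed = 5)
  b <- clone_genome(a, "B")
  cfg <- sampler_config(n_iter = 1500, seed = 11)
  est <- sample_raw_distance(a, b, identity_ortholog_map(a, b), cfg)
  expect_equal(est$D, 0)
  expect_equal(est$n, 1500L)
  est2 <- sample_raw_distance(a, b, identity_ortholog_map(a, b), cfg)
  expect_identical(est, est2)
  # different replicate -> different stream (almost surely different draws,
  # same expectation; here both must still be D = 0 but seeds differ)
  est3 <- sample_raw_distance(a, b, identity_ortholog_map(a, b), cfg,
                              replicate_index = 2L)
  expect_false(identical(est$seed, est3$seed))
})

test_that("sampler errors on too few orthologs and unsatisfiable spacing", {
  a <- toy_genome("A", paste0("g", 1:5))
  b <- clone_genome(a, "B")
  cfg <- sampler_config(n_iter = 100, seed = 1)
  expect_error(sample_raw_distance(a, b, identity_ortholog_map(a, b), cfg),
               "shared orthologs")
  # 20 genes cannot hold 6 positions pairwise >= 5 apart on a circle
  a2 <- random_genome(20, "A2", seed = 1)
  b2 <- clone_genome(a2, "B2")
  expect_error(sample_raw_distance(a2, b2, identity_ortholog_map(a2, b2), cfg),
               "unsatisfiable")
  expect_error(exact_raw_distance(a2, b2, identity_ortholog_map(a2, b2), cfg),
               "unsatisfiable")
})

test_that("exact enumerator: identity is zero and budget is enforced", {
  a <- random_genome(25, "A", seed = 3)
  b <- clone_genome(a, "B")
  cfg <- sampler_config(min_gap = 1, n_iter = 10, seed = 1)
  expect_equal(as.numeric(exact_raw_distance(a, b, identity_ortholog_map(a, b), cfg)), 0)
  big <- random_genome(80, "C", seed = 4)
  big2 <- clone_genome(big, "D")
  expect_error(exact_raw_distance(big, big2, identity_ortholog_map(big, big2),
                                  cfg, budget = 1e5),
               "budget")
})

test_that("independently shuffled 30-gene orders enumerate close to 59/60", {
  a <- random_genome(30, "A", seed = 21)
  b <- shuffle_gene_order(clone_genome(a, "B"), seed = 22)
  cfg <- sampler_config(min_gap = 1, n_iter = 10, seed = 1)
  ex <- as.numeric(exact_raw_distance(a, b, identity_ortholog_map(a, b), cfg))
  expect_lt(abs(ex - 59 / 60), 0.01)
})

test_that("Monte Carlo estimate matches the exact oracle within 3 SE (3 seeds)", {
  base <- random_genome(30, "A", seed = 2)
  div <- apply_events(clone_genome(base, "B"),
                      rearrangement_model(segment_dist = "uniform"),
                      n_events = 1, seed = 9)
  cfg0 <- sampler_config(min_gap = 2, n_iter = 10, seed = 1)
  ex <- as.numeric(exact_raw_distance(base, div, identity_ortholog_map(base, div), cfg0))
  expect_gt(ex, 0)
  for (s in 1:3) {
    cfg <- sampler_config(min_gap = 2, n_iter = 40000, seed = s)
    mc <- sample_raw_distance(base, div, identity_ortholog_map(base, div), cfg)
    se <- sqrt(ex * (1 - ex) / mc$n)
    expect_lt(abs(mc$D - ex), 3 * se)
  }
})

test_that("per-replicon mode samples within co-resident replicon pairs", {
  ra1 <- replicon("c1", paste0("a", 1:40))
  ra2 <- replicon("c2", paste0("b", 1:40))
  a <- genome_record("A", list(ra1, ra2))
  b <- genome_record("B", list(replicon("c1", paste0("a", 1:40)),
                               replicon("c2", paste0("b", 1:40))))
  cfg <- sampler_config(n_iter = 500, seed = 3, replicon_mode = "per-replicon",
                        min_gap = 2)
  est <- sample_raw_distance(a, b, identity_ortholog_map(a, b), cfg)
  expect_equal(est$D, 0)  # both replicons order-identical
  # largest mode ignores the second replicon entirely
  cfgL <- sampler_config(n_iter = 500, seed = 3, min_gap = 2)
  estL <- sample_raw_distance(a, b, identity_ortholog_map(a, b), cfgL)
  expect_equal(estL$D, 0)
})

test_that("audit log records one line per counted draw", {
  a <- random_genome(60, "A", seed = 8)
  b <- shuffle_gene_order(clone_genome(a, "B"), seed = 9)
  cfg <- sampler_config(n_iter = 200, seed = 4, min_gap = 2)
  log <- withr::local_tempfile(fileext = ".tsv")
  est <- sample_raw_distance(a, b, identity_ortholog_map(a, b), cfg,
                             audit_file = log)
  lines <- readLines(log)
  expect_length(lines, 200L)
  verdicts <- vapply(strsplit(lines, "\t"), `[[`, character(1), 4L)
  expect_equal(sum(verdicts == "fail"), est$k_fail)
})
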