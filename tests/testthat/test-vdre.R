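test_that("rank transformation follows the within-gene, average-tie convention", {
  m <- make_expr(list(g1 = c(3.2, 1.1, 5.0)))
  expect_equal(unname(rank_profiles(m)[1, ]), c(2, 1, 3))

  expect_message(r <- rank_profiles(make_expr(list(g1 = rep(2, 4)))), "constant")
  expect_equal(unname(r[1, ]), rep(2.5, 4))

  # row sums equal E(E+1)/2 on random rows, checked against a sort oracle
  set.seed(5)
  for (e in c(3L, 7L, 20L)) {
    m <- make_expr(list(g1 = rnorm(e), g2 = sample(rnorm(e))))
    r <- rank_profiles(m)
    expect_equal(unname(rowSums(r)), rep(e * (e + 1) / 2, 2))
    expect_equal(unname(r[1, order(m[1, ])]), as.numeric(seq_len(e)))
  }
})

test_that("rank distance is Euclidean, symmetric and metric", {
  expect_equal(rank_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rank_distance(c(1, 2, 3), c(3, 2, 1)), sqrt(8))
  expect_error(rank_distance(1:3, 1:4), "equal length")
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(5); z <- rnorm(5)
    expect_equal(rank_distance(x, y), rank_distance(y, x))
    expect_lte(rank_distance(x, z),
               rank_distance(x, y) + rank_distance(y, z) + 1e-12)
  }
})

test_that("F score matches exhaustive pair enumeration", {
  # identical profiles in both groups: every distance zero, F = 0
  r <- rank_profiles(make_expr(list(g1 = c(1, 2, 3), g2 = c(10, 20, 30),
                                    g3 = c(0.1, 0.5, 0.9), g4 = c(5, 6, 7))))
  gr <- make_grouping(list(A = c("g1", "g2"), T = c("g3", "g4")))
  expect_equal(vdre_score(gr, r)$F, 0)

  # within-group identical, constant between-group distance d: F = -d
  m <- make_expr(list(g1 = c(1, 2, 3), g2 = c(1, 2, 3),
                      g3 = c(3, 2, 1), g4 = c(3, 2, 1)))
  r <- rank_profiles(m)
  res <- vdre_score(gr, r)
  expect_equal(res$F, -sqrt(8))
  expect_equal(c(res$N, res$M), c(2L, 4L))

  # three groups of two, random profiles: exhaustive pair oracle
  genes <- sprintf("g%d", 1:6)
  r <- make_ranks(genes, n_cond = 8L, seed = 31L)
  groups <- list(A = genes[1:2], C = genes[3:4], T = genes[5:6])
  gr3 <- make_grouping(groups)
  oracle <- brute_force_F(r, groups)
  res3 <- vdre_score(gr3, r)
  expect_equal(res3$F, oracle$F)
  expect_equal(c(res3$N, res3$M), c(oracle$N, oracle$M))
  expect_equal(c(oracle$N, oracle$M), c(3L, 12L))
})

test_that("singleton groups are excluded from both distance sums", {
  genes <- sprintf("g%d", 1:5)
  r <- make_ranks(genes, seed = 13L)
  with_singleton <- make_grouping(list(A = genes[1:2], T = genes[3:4],
                                       C = genes[5]))
  without <- make_grouping(list(A = genes[1:2], T = genes[3:4]))
  expect_equal(vdre_score(with_singleton, r), vdre_score(without, r))
})

test_that("permutation p is degenerate-safe, seeded, and matches enumeration", {
  # all profiles identical: every permuted F equals the observed 0, p = 1
  m <- make_expr(list(g1 = 1:4, g2 = 1:4, g3 = 1:4, g4 = 1:4))
  gr <- make_grouping(list(A = c("g1", "g2"), T = c("g3", "g4")))
  res <- vdre_permutation_test(gr, rank_profiles(m), 200, seed = 1)
  expect_equal(res$p_value, 1)

  # seeded reproducibility
  r <- make_ranks(sprintf("g%d", 1:4), seed = 77L)
  a <- vdre_permutation_test(gr, r, 500, seed = 42)
  b <- vdre_permutation_test(gr, r, 500, seed = 42)
  expect_identical(a$p_value, b$p_value)

  # Monte-Carlo p agrees with exhaustive label enumeration within 3 SE
  groups <- list(A = c("g1", "g2"), T = c("g3", "g4"))
  p_exact <- exact_vdre_p(r, groups)
  mc <- vdre_permutation_test(make_grouping(groups), r, 10000, seed = 3)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(mc$p_value - p_exact), 3 * se + 2 / 10001)

  expect_error(vdre_permutation_test(gr, r, 0), "n_permutations")
  expect_error(vdre_permutation_test(make_grouping(list(A = "g1", T = "g2")), r),
               "not testable")
})

test_that("Storey q-values match a brute-force computation of the formula", {
  expect_equal(as.numeric(estimate_fdr(rep(1, 5))), rep(1, 5))

  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.31, 0.61, 0.72, 0.99)
  q <- estimate_fdr(p)
  expect_equal(as.numeric(q), brute_force_storey(p))
  # monotone in p, within [0, 1]
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= 0 & q <= 1))

  # uniform null: pi0 estimate close to 1
  set.seed(11)
  qq <- estimate_fdr(runif(500))
  expect_gte(attr(qq, "pi0"), 0.8)
  expect_lte(attr(qq, "pi0"), 1)

  expect_error(estimate_fdr(numeric(0)), "no p-values")
  expect_error(estimate_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("min comparison count takes the lower of N and M", {
  genes <- sprintf("g%d", 1:24)
  expect_equal(min_comparison_count(
    make_grouping(list(A = genes[1:2], T = genes[3:4]))), 2L)
  expect_equal(min_comparison_count(
    make_grouping(list(A = genes[1:3], T = genes[4:6]))), 6L)
  expect_equal(min_comparison_count(
    make_grouping(list(A = genes[1:2], T = genes[3:22]))), 40L)
})

test_that("vdre_scan reports every testable position with q-values", {
  scn <- generate_scenario(scenario_config(n_tfs = 2L, motif_length = 7L,
                                           regime = "reversal", seed = 21L))
  res <- vdre_scan(scn$sites, scn$expression, n_permutations = 300, seed = 4)
  expect_true(all(c("tf_id", "position", "F", "N", "M", "p_value", "q_value")
                  %in% names(res)))
  # the focal position is the only variable one per synthetic TF
  expect_equal(nrow(res), 2L)
  truth <- unique(scn$truth[, c("tf_id", "position")])
  expect_identical(res$position[order(res$tf_id)],
                   truth$position[order(truth$tf_id)])
  expect_true(all(res$p_value < 0.05))  # strong planted reversals
  # identical re-run: seeded determinism of the whole scan
  res2 <- vdre_scan(scn$sites, scn$expression, n_permutations = 300, seed = 4)
  expect_identical(res, res2)
})

test_that("genes sharing one simple regulatory input have closer profiles", {
  # each TF's targets respond together to that TF's conditions; random pairs
  # mix regulons perturbed in different conditions
  scn <- generate_scenario(scenario_config(n_tfs = 4L, motif_length = 8L,
                                           regime = "affinity_scaling",
                                           effect_size = 4,
                                           secondary_fraction = 0, seed = 19L))
  cmp <- distance_class_comparison(scn$sites, scn$expression,
                                   class_pair = c("one_primary", "random"),
                                   n_random = 400L, seed = 2L)
  expect_lt(cmp$means[["one_primary"]], cmp$means[["random"]])
  expect_lt(cmp$p_value, 0.01)
  expect_lt(cmp$t_statistic, 0)
})
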