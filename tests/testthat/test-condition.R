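# Shared fixture: a grouping with two variant groups of two genes whose
# expression is constructed directly.
cs_fixture <- function(rows, cond_ids = NULL) {
  m <- make_expr(rows, cond_ids)
  gr <- make_grouping(list(A = c("a1", "a2"), T = c("t1", "t2")))
  list(expr = m, ranks = rank_profiles(m), grouping = gr)
}

test_that("experiment ordering is standardized, deterministic and antisymmetric", {
  set.seed(8)
  fx <- cs_fixture(list(a1 = rnorm(6), a2 = rnorm(6),
                        t1 = rnorm(6), t2 = rnorm(6)))
  ord_at <- order_experiments(fx$grouping, fx$expr, c("A", "T"))
  ord_ta <- order_experiments(fx$grouping, fx$expr, c("T", "A"))
  expect_equal(ord_at$table$statistic, -ord_ta$table$statistic)
  expect_identical(ord_at$ordering, rev(ord_ta$ordering))
  expect_setequal(ord_at$experiment_rank, seq_len(6))

  # all-equal target means: statistics 0, ordering falls back to lexical ids
  fx0 <- cs_fixture(list(a1 = c(1, 2, 3), a2 = c(3, 2, 1),
                         t1 = c(1, 2, 3), t2 = c(3, 2, 1)),
                    cond_ids = c("cB", "cA", "cC"))
  ord0 <- suppressWarnings(order_experiments(fx0$grouping, fx0$expr, c("A", "T")))
  expect_equal(ord0$table$statistic, rep(0, 3))
  expect_identical(ord0$ordering, c("cA", "cB", "cC"))

  # zero pooled spread in one condition: statistic forced to 0 with warning
  fxz <- cs_fixture(list(a1 = c(5, 1), a2 = c(5, 2),
                         t1 = c(5, 3), t2 = c(5, 4)))
  expect_warning(ordz <- order_experiments(fxz$grouping, fxz$expr, c("A", "T")),
                 "zero pooled")
  expect_equal(ordz$table$statistic[1], 0)
})

test_that("clustering score matches hand enumeration and its decomposition", {
  md <- data.frame(condition_id = c("c1", "c2", "c3", "c4"),
                   experiment_type = c("X", "X", "Y", "Y"))
  ord <- structure(list(variant_pair = c("A", "T"),
                        experiment_rank = c(c1 = 1L, c2 = 2L, c3 = 3L, c4 = 4L),
                        ordering = c("c1", "c2", "c3", "c4")),
                   class = "experiment_ordering")
  cs <- clustering_score(ord, md)
  expect_equal(cs$C_W, 1)
  expect_equal(cs$C_Q, 2)
  expect_equal(cs$S, 1)
  expect_equal(c(cs$A, cs$B), c(2L, 4L))

  # interleaved types score lower than separated ones
  md_i <- data.frame(condition_id = c("c1", "c2", "c3", "c4"),
                     experiment_type = c("X", "Y", "X", "Y"))
  cs_i <- clustering_score(ord, md_i)
  oracle <- brute_force_S(ord$experiment_rank, md_i$experiment_type)
  expect_equal(cs_i$S, oracle$S)
  expect_lt(cs_i$S, cs$S)

  # A*C_W + B*C_Q recovers the total pairwise rank distance (random cases)
  set.seed(3)
  for (i in 1:10) {
    e <- sample(4:9, 1)
    r <- sample(e)
    names(r) <- sprintf("c%d", seq_len(e))
    types <- sample(c("u", "v", "w"), e, replace = TRUE)
    if (length(unique(types)) < 2L || !any(duplicated(types))) next
    md_r <- data.frame(condition_id = names(r), experiment_type = types)
    ord_r <- structure(list(variant_pair = c("A", "T"), experiment_rank = r,
                            ordering = names(sort(r))),
                       class = "experiment_ordering")
    cs_r <- clustering_score(ord_r, md_r)
    total <- sum(abs(outer(r, r, "-"))[upper.tri(diag(e))])
    expect_equal(cs_r$A * cs_r$C_W + cs_r$B * cs_r$C_Q, total)
  }

  expect_error(clustering_score(ord, data.frame(condition_id = md$condition_id,
                                                experiment_type = "X")),
               ">= 2 experiment types")
})

test_that("clustering permutation p matches exhaustive label enumeration", {
  ord <- structure(list(variant_pair = c("A", "T"),
                        experiment_rank = stats::setNames(1:6, sprintf("c%d", 1:6)),
                        ordering = sprintf("c%d", 1:6)),
                   class = "experiment_ordering")
  cases <- list(c("X", "X", "X", "Y", "Y", "Y"),   # separated: strongest
                c("X", "Y", "X", "Y", "X", "Y"),   # interleaved: weakest
                c("X", "X", "Y", "X", "Y", "Y"))
  for (types in cases) {
    md <- data.frame(condition_id = sprintf("c%d", 1:6),
                     experiment_type = types)
    p_exact <- exact_clustering_p(ord$experiment_rank, types)
    res <- clustering_permutation_test(ord, md, 4000, seed = 6)
    se <- sqrt(p_exact * (1 - p_exact) / 4000)
    expect_lt(abs(res$p_value - p_exact), 3 * se + 2 / 4001)
  }
  # weakest possible clustering: every permuted arrangement >= observed, p -> 1
  md_w <- data.frame(condition_id = sprintf("c%d", 1:6),
                     experiment_type = cases[[2L]])
  expect_gt(clustering_permutation_test(ord, md_w, 500, seed = 1)$p_value, 0.9)
})

test_that("rank reversal statistic is signed Spearman correlation", {
  # perfect reversal across 3 conditions
  fx <- cs_fixture(list(a1 = c(1, 2, 3), a2 = c(1, 2, 3),
                        t1 = c(3, 2, 1), t2 = c(3, 2, 1)))
  rev <- reversal_rank_test(fx$grouping, fx$ranks, c("A", "T"))
  expect_equal(rev$statistic, -1)

  # identical mean-rank vectors: correlation +1, never a reversal
  fx2 <- cs_fixture(list(a1 = c(1, 2, 3), a2 = c(1, 2, 3),
                         t1 = c(1, 2, 3), t2 = c(1, 2, 3)))
  rev2 <- reversal_rank_test(fx2$grouping, fx2$ranks, c("A", "T"))
  expect_equal(rev2$statistic, 1)
  expect_false(rev2$significant_reversal)

  # constant mean-rank vector: undefined correlation, non-significant
  fx3 <- cs_fixture(list(a1 = c(1, 2, 3), a2 = c(3, 2, 1),
                         t1 = c(1, 2, 3), t2 = c(1, 2, 3)))
  rev3 <- reversal_rank_test(fx3$grouping, fx3$ranks, c("A", "T"))
  expect_true(is.na(rev3$statistic))
  expect_equal(rev3$p_value, 1)
})

test_that("reversal regime is flagged, affinity scaling is not", {
  base <- function(regime, seed) {
    scn <- generate_scenario(scenario_config(
      n_tfs = 1L, motif_length = 8L, nucleotides_per_position = 2L,
      regime = regime, effect_size = 4, noise_sd = 0.5, seed = seed))
    gr <- build_variant_groupings(scn$sites, "TF01", scn$truth$position[1])
    vp <- unique(scn$truth$nucleotide)
    reversal_rank_test(gr, rank_profiles(scn$expression), vp)
  }
  rev <- base("reversal", 101L)
  expect_true(rev$significant_reversal)
  aff <- base("affinity_scaling", 101L)
  expect_false(aff$significant_reversal)
})

test_that("slope test recovers signs and the normal-equations estimate", {
  e <- 5L
  # group A means fall linearly along the ordering, group T means rise
  fx <- cs_fixture(list(a1 = c(10, 8, 6, 4, 2), a2 = c(9, 7, 5, 3, 1),
                        t1 = c(1, 3, 5, 7, 9), t2 = c(2, 4, 6, 8, 10)))
  ord <- order_experiments(fx$grouping, fx$expr, c("A", "T"))
  st <- slope_sign_test(fx$grouping, fx$ranks, ord, c("A", "T"))
  expect_lt(st$slope_a, 0)
  expect_gt(st$slope_b, 0)
  expect_true(st$passes)

  # slope equals closed-form least squares on the ordered group means
  ya <- colMeans(fx$ranks[c("a1", "a2"), ])[ord$ordering]
  expect_equal(st$slope_a, normal_eq_slope(seq_len(e), ya))

  # flat groups: near-zero slopes, no pass
  fx0 <- cs_fixture(list(a1 = c(1, 2, 3, 4, 5), a2 = c(5, 4, 3, 2, 1),
                         t1 = c(1, 2, 3, 4, 5), t2 = c(5, 4, 3, 2, 1)))
  ord0 <- suppressWarnings(order_experiments(fx0$grouping, fx0$expr, c("A", "T")))
  st0 <- slope_sign_test(fx0$grouping, fx0$ranks, ord0, c("A", "T"))
  expect_false(st0$passes)

  fx2 <- cs_fixture(list(a1 = c(1, 2), a2 = c(2, 1),
                         t1 = c(1, 2), t2 = c(2, 1)))
  ord2 <- order_experiments(fx2$grouping, fx2$expr, c("A", "T"))
  expect_error(slope_sign_test(fx2$grouping, fx2$ranks, ord2, c("A", "T")),
               "fewer than 3")
})
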