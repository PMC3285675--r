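test_that("scenario generation is deterministic under the master seed", {
  cfg <- scenario_config(n_tfs = 2L, regime = "null", seed = 5L)
  a <- generate_scenario(cfg)
  b <- generate_scenario(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$sites, b$sites)
  expect_identical(a$go_map, b$go_map)
  c2 <- generate_scenario(scenario_config(n_tfs = 2L, regime = "null", seed = 6L))
  expect_false(identical(a$expression, c2$expression))
})

test_that("noise-free null scenarios give identical ranked profiles", {
  scn <- generate_scenario(scenario_config(n_tfs = 1L, regime = "null",
                                           noise_sd = 0, seed = 2L))
  r <- rank_profiles(scn$expression)
  # expression differs between genes only by the baseline shift, which the
  # within-gene ranking removes entirely
  for (i in 2:nrow(r)) expect_equal(unname(r[i, ]), unname(r[1, ]))
})

test_that("reversal regime inverts group mean ordering across types at zero noise", {
  scn <- generate_scenario(scenario_config(n_tfs = 1L, motif_length = 8L,
                                           regime = "reversal", noise_sd = 0,
                                           condition_effect_sd = 0, seed = 3L))
  vp <- unique(scn$truth$nucleotide)[1:2]
  gr <- build_variant_groupings(scn$sites, "TF01", scn$truth$position[1])
  type_of <- scn$metadata$experiment_type
  type_means <- function(nuc) {
    m <- colMeans(scn$expression[gr$groups[[nuc]], , drop = FALSE])
    tapply(m, type_of, mean)
  }
  ord_a <- order(type_means(vp[1]))
  ord_b <- order(type_means(vp[2]))
  # the effect types are exactly swapped; the null types tie at the baseline,
  # so compare the rank positions of the two perturbed types
  expect_identical(ord_a[1], ord_b[length(ord_b)])
  expect_identical(ord_b[1], ord_a[length(ord_a)])
  # and the planted effect vectors have negative rank correlation
  eff <- scn$truth[scn$truth$nucleotide %in% vp, ]
  e1 <- eff$effect[eff$nucleotide == vp[1]]
  e2 <- eff$effect[eff$nucleotide == vp[2]]
  expect_lt(cor(e1, e2, method = "spearman"), 0)
})

test_that("synthetic sites respect posterior classes and motif structure", {
  scn <- generate_scenario(scenario_config(n_tfs = 3L, motif_length = c(6L, 10L, 16L),
                                           secondary_fraction = 0.5, seed = 9L))
  prim <- scn$sites[scn$sites$site_class == "primary", ]
  sec <- scn$sites[scn$sites$site_class == "secondary", ]
  expect_true(all(prim$posterior >= 0.7))
  expect_true(all(sec$posterior > 0.2 & sec$posterior < 0.7))
  expect_gt(nrow(sec), 0L)
  # each target gene has exactly one primary site: the single-primary filter
  # keeps every annotated target
  expect_equal(as.integer(table(prim$gene_id)), rep(1L, nrow(prim)))
  for (tf in unique(prim$tf_id)) {
    lens <- nchar(scn$sites$site_sequence[scn$sites$tf_id == tf])
    expect_equal(length(unique(lens)), 1L)
  }
})

test_that("detection power is non-decreasing in the planted effect size", {
  power_at <- function(effect) {
    hits <- 0L
    for (s in 1:20) {
      scn <- generate_scenario(scenario_config(
        n_tfs = 1L, motif_length = 8L, nucleotides_per_position = 2L,
        regime = "reversal", effect_size = effect, seed = 1000L + s))
      gr <- build_variant_groupings(scn$sites, "TF01", scn$truth$position[1])
      p <- vdre_permutation_test(gr, rank_profiles(scn$expression), 300,
                                 seed = s)$p_value
      if (p < 0.05) hits <- hits + 1L
    }
    hits / 20
  }
  pw <- vapply(c(0, 1, 3), power_at, numeric(1L))
  expect_true(all(diff(pw) >= 0))
  expect_gt(pw[3], 0.9)
})

test_that("invalid configurations are rejected", {
  expect_error(scenario_config(motif_length = 5L), "6\\.\\.16")
  expect_error(scenario_config(regime = "reversal", genes_per_group = 1L),
               ">= 2 genes")
  expect_error(scenario_config(regime = "reversal", n_experiment_types = 1L),
               "experiment types")
  expect_error(scenario_config(nucleotides_per_position = 5L))
})

test_that("scenario tables round-trip through the writers", {
  scn <- generate_scenario(scenario_config(n_tfs = 1L, seed = 4L))
  dir <- withr::local_tempdir()
  paths <- write_scenario(scn, dir)
  expect_true(all(file.exists(paths)))
  expr <- read_expression_matrix(paths[["expression"]])
  expect_equal(expr, scn$expression, tolerance = 1e-8)
  sites <- read_binding_sites(paths[["sites"]])
  expect_equal(as.character(sites$site_class), as.character(scn$sites$site_class))
  md <- read_condition_metadata(paths[["conditions"]], colnames(expr))
  expect_identical(md, scn$metadata)
  go <- read_go_map(paths[["go"]])
  expect_identical(go[sort(names(go))],
                   lapply(scn$go_map, unname)[sort(names(scn$go_map))])
})
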