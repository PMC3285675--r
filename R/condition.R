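#' Order experiments by the standardized difference between two variants
#'
#' For one pair of nucleotide variants at a functional motif position, each
#' condition receives the statistic
#' `(mean_a(c) - mean_b(c)) / pooled_sd(c)`, where the means are over the two
#' variants' target-gene expression values in condition `c` and `pooled_sd`
#' is the standard deviation of the two target sets' values pooled in that
#' condition. Experiments are then sorted by this statistic in decreasing
#' order (ties broken by condition id) so that conditions where variant `a`
#' dominates sit at one end and conditions where variant `b` dominates at the
#' other.
#'
#' @param grouping A [build_variant_groupings()] result.
#' @param expression Gene-by-condition expression matrix.
#' @param variant_pair Character vector of two nucleotides, e.g. `c("A","T")`.
#' @param normalize `"sd"` (default) divides by the pooled standard deviation;
#'   `"var"` by the pooled variance.
#' @return Object of class `experiment_ordering`: list with `variant_pair`,
#'   `table` (data.frame: `condition_id`, `statistic`, `experiment_rank`),
#'   `ordering` (condition ids sorted, rank 1 first) and `experiment_rank`
#'   (named integer vector).
#' @export
order_experiments <- function(grouping, expression, variant_pair,
                              normalize = c("sd", "var")) {
  normalize <- match.arg(normalize)
  stopifnot(length(variant_pair) == 2L)
  ga <- grouping$groups[[variant_pair[1L]]]
  gb <- grouping$groups[[variant_pair[2L]]]
  if (is.null(ga) || is.null(gb) || length(ga) < 2L || length(gb) < 2L) {
    stop("both variants need >= 2 target genes with expression data")
  }
  a_mat <- expression[ga, , drop = FALSE]
  b_mat <- expression[gb, , drop = FALSE]
  diff_mean <- colMeans(a_mat) - colMeans(b_mat)
  pooled <- vapply(seq_len(ncol(expression)), function(j) {
    stats::sd(c(a_mat[, j], b_mat[, j]))
  }, numeric(1L))
  if (normalize == "var") pooled <- pooled^2
  statistic <- ifelse(pooled > 0, diff_mean / pooled, 0)
  if (any(pooled == 0)) {
    warning(sum(pooled == 0), " condition(s) with zero pooled spread; statistic set to 0")
  }
  cond <- colnames(expression)
  ord <- order(-statistic, cond)
  experiment_rank <- integer(length(cond))
  experiment_rank[ord] <- seq_along(cond)
  names(experiment_rank) <- cond
  structure(list(variant_pair = variant_pair,
                 table = data.frame(condition_id = cond,
                                    statistic = statistic,
                                    experiment_rank = experiment_rank,
                                    stringsAsFactors = FALSE),
                 ordering = cond[ord],
                 experiment_rank = experiment_rank),
            class = "experiment_ordering")
}

#' Experiment-type clustering score for an ordering
#'
#' Measures whether experiments of the same type sit close together in the
#' variant-driven ordering. With experiment ranks 1..E, the distance between
#' two experiments is `|rank_i - rank_j|`; `C_W` is the mean distance over
#' same-type pairs (A of them), `C_Q` the mean over different-type pairs (B of
#' them), and the score is `S = C_Q - C_W`. Larger S means stronger clustering
#' of like experiments.
#'
#' @param ordering An [order_experiments()] result.
#' @param metadata Condition metadata data.frame (`condition_id`,
#'   `experiment_type`) covering every ordered condition.
#' @return List with `S`, `C_W`, `C_Q`, `A`, `B`.
#' @export
clustering_score <- function(ordering, metadata) {
  r <- ordering$experiment_rank
  types <- metadata$experiment_type[match(names(r), metadata$condition_id)]
  if (anyNA(types)) stop("conditions without experiment-type metadata")
  clustering_score_ranks(r, types)
}

clustering_score_ranks <- function(r, types) {
  if (length(unique(types)) < 2L) {
    stop("need >= 2 experiment types for a within/between contrast")
  }
  dm <- abs(outer(r, r, "-"))
  same <- outer(types, types, "==")
  ut <- upper.tri(dm)
  a <- sum(same & ut)
  b <- sum(!same & ut)
  if (a == 0L) stop("no same-type pair; clustering score undefined")
  c_w <- sum(dm[same & ut]) / a
  c_q <- sum(dm[!same & ut]) / b
  list(S = c_q - c_w, C_W = c_w, C_Q = c_q, A = as.integer(a), B = as.integer(b))
}

#' Permutation test for experiment-type clustering
#'
#' Keeps the variant-driven experiment ordering fixed and permutes the
#' assignment of experiment-type labels to conditions; the one-sided p-value
#' is `(1 + #{S_perm >= S_obs}) / (1 + n)` (right tail: stronger clustering
#' than expected by chance).
#'
#' @inheritParams clustering_score
#' @param n_permutations Number of label permutations (default 10000).
#' @param seed Optional integer seed.
#' @return Object of class `clustering_result`: list with `S`, `C_W`, `C_Q`,
#'   `A`, `B`, `p_value`, `n_permutations`, `seed`, `variant_pair`.
#' @export
clustering_permutation_test <- function(ordering, metadata,
                                        n_permutations = 10000L, seed = NULL) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  r <- ordering$experiment_rank
  types <- metadata$experiment_type[match(names(r), metadata$condition_id)]
  if (anyNA(types)) stop("conditions without experiment-type metadata")
  obs <- clustering_score_ranks(r, types)
  # S = C_Q - C_W with A, B fixed under label permutation; only the within-
  # type distance sum varies, so precompute the distance matrix once.
  dm <- abs(outer(r, r, "-"))
  total <- sum(dm[upper.tri(dm)])
  n_cond <- length(r)
  idx_by_type <- split(seq_len(n_cond), types)
  idx_by_type <- idx_by_type[lengths(idx_by_type) > 1L]
  if (!is.null(seed)) set.seed(seed)
  n_ge <- 0L
  for (bb in seq_len(n_permutations)) {
    perm <- sample.int(n_cond)
    w_sum <- 0
    for (idx in idx_by_type) {
      pg <- perm[idx]
      w_sum <- w_sum + sum(dm[pg, pg]) / 2
    }
    s_perm <- (total - w_sum) / obs$B - w_sum / obs$A
    if (s_perm >= obs$S) n_ge <- n_ge + 1L
  }
  structure(c(obs,
              list(p_value = (1 + n_ge) / (1 + n_permutations),
                   n_permutations = as.integer(n_permutations),
                   seed = seed,
                   variant_pair = ordering$variant_pair)),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("Experiment-type clustering (%s vs %s): S = %.4f (C_Q = %.3f, C_W = %.3f) | p = %.4g\n",
              x$variant_pair[1L], x$variant_pair[2L], x$S, x$C_Q, x$C_W, x$p_value))
  invisible(x)
}

#' Rank-reversal test between two variants
#'
#' Tests whether the relative ranking of expression across conditions is
#' inverted between the target genes of two nucleotide variants, the
#' signature of cofactor-mediated (allosteric) rather than pure-affinity
#' regulation. Per condition, each variant's mean within-gene rank is
#' computed; the statistic is the Spearman correlation between the two
#' mean-rank vectors across conditions, and a significant reversal is a
#' negative correlation with a one-sided p below 0.05.
#'
#' @param grouping A [build_variant_groupings()] result.
#' @param ranks Ranked profile matrix from [rank_profiles()].
#' @param variant_pair Two nucleotides.
#' @return List with `statistic` (Spearman rho), `p_value` (one-sided, left
#'   tail), `significant_reversal`. A constant mean-rank vector leaves the
#'   correlation undefined and is reported as non-significant (`statistic`
#'   NA, `p_value` 1).
#' @export
reversal_rank_test <- function(grouping, ranks, variant_pair) {
  stopifnot(length(variant_pair) == 2L)
  ga <- grouping$groups[[variant_pair[1L]]]
  gb <- grouping$groups[[variant_pair[2L]]]
  if (is.null(ga) || is.null(gb) || length(ga) < 2L || length(gb) < 2L) {
    stop("both variants need >= 2 target genes")
  }
  ma <- colMeans(ranks[ga, , drop = FALSE])
  mb <- colMeans(ranks[gb, , drop = FALSE])
  if (stats::sd(ma) == 0 || stats::sd(mb) == 0) {
    return(list(statistic = NA_real_, p_value = 1,
                significant_reversal = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(ma, mb, method = "spearman",
                                         alternative = "less", exact = FALSE))
  list(statistic = unname(ct$estimate), p_value = ct$p.value,
       significant_reversal = unname(ct$estimate) < 0 && ct$p.value < 0.05)
}

#' Slope-sign test along the variant-driven experiment ordering
#'
#' With experiments ordered by the standardized between-variant difference,
#' fits a least-squares line through each variant's per-condition mean rank
#' against the experiment rank 1..E. Opposite regulation shows up as slopes
#' of opposite sign: one variant's targets fall along the ordering while the
#' other's rise. Slope significance is a two-sided t-test on the regression
#' coefficient.
#'
#' @param grouping A [build_variant_groupings()] result.
#' @param ranks Ranked profile matrix from [rank_profiles()].
#' @param ordering An [order_experiments()] result for the same pair.
#' @param variant_pair Two nucleotides (must match `ordering$variant_pair`).
#' @param alpha Significance level for each slope (default 0.05).
#' @return List with `slope_a`, `p_a`, `slope_b`, `p_b`, `passes` (slopes of
#'   opposite sign, both significant).
#' @export
slope_sign_test <- function(grouping, ranks, ordering, variant_pair,
                            alpha = 0.05) {
  stopifnot(length(variant_pair) == 2L)
  if (!identical(as.character(variant_pair), as.character(ordering$variant_pair))) {
    stop("variant_pair does not match the supplied ordering")
  }
  e <- length(ordering$experiment_rank)
  if (e < 3L) stop("slope test undefined for fewer than 3 conditions")
  x <- seq_len(e)
  fit_one <- function(genes) {
    m <- colMeans(ranks[genes, , drop = FALSE])
    y <- m[ordering$ordering]              # means along the ordering
    fit <- stats::lm(y ~ x)
    sm <- suppressWarnings(summary(fit))
    co <- stats::coef(sm)
    p <- if (nrow(co) >= 2L && !is.na(co[2L, 4L])) co[2L, 4L] else 1
    list(slope = unname(stats::coef(fit)[2L]), p = p)
  }
  ga <- grouping$groups[[variant_pair[1L]]]
  gb <- grouping$groups[[variant_pair[2L]]]
  if (is.null(ga) || is.null(gb) || length(ga) < 2L || length(gb) < 2L) {
    stop("both variants need >= 2 target genes")
  }
  fa <- fit_one(ga)
  fb <- fit_one(gb)
  list(slope_a = fa$slope, p_a = fa$p, slope_b = fb$slope, p_b = fb$p,
       passes = (fa$slope * fb$slope < 0) && fa$p < alpha && fb$p < alpha)
}

#' Full condition-specificity characterization of one variant pair
#'
#' Convenience wrapper running [order_experiments()],
#' [clustering_permutation_test()], [reversal_rank_test()] and
#' [slope_sign_test()] for one pair of variants at a functional position, and
#' reporting whether the pair passes both allostery tests (significant rank
#' reversal and opposite significant slopes).
#'
#' @param grouping A [build_variant_groupings()] result.
#' @param expression Gene-by-condition expression matrix.
#' @param metadata Condition metadata.
#' @param variant_pair Two nucleotides.
#' @param ranks Optional precomputed [rank_profiles()] matrix.
#' @param n_permutations Clustering permutations (default 10000).
#' @param seed Optional integer seed.
#' @return List with `ordering`, `clustering`, `reversal`, `slopes`,
#'   `passes_both`.
#' @export
characterize_variant_pair <- function(grouping, expression, metadata,
                                      variant_pair, ranks = NULL,
                                      n_permutations = 10000L, seed = NULL) {
  if (is.null(ranks)) ranks <- rank_profiles(expression)
  ordering <- order_experiments(grouping, expression, variant_pair)
  clustering <- clustering_permutation_test(ordering, metadata,
                                            n_permutations, seed)
  reversal <- reversal_rank_test(grouping, ranks, variant_pair)
  slopes <- slope_sign_test(grouping, ranks, ordering, variant_pair)
  list(ordering = ordering, clustering = clustering, reversal = reversal,
       slopes = slopes,
       passes_both = reversal$significant_reversal && slopes$passes)
}
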