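#' Rank-transform expression profiles within genes
#'
#' Replaces each gene's expression values by their ranks across conditions
#' (rank 1 = lowest expression; ties receive the average rank), so that genes
#' become comparable on a common scale and any strictly monotone
#' transformation of a gene's measurements leaves its profile unchanged.
#'
#' @param mat Numeric gene-by-condition matrix with dimnames (at least 2
#'   conditions).
#' @return Matrix of the same shape holding within-row ranks. Every row sums
#'   to E(E+1)/2 where E is the number of conditions.
#' @export
rank_profiles <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2L)
  constant <- apply(mat, 1L, function(x) max(x) == min(x))
  if (any(constant)) {
    message(sum(constant), " constant expression row(s); all ranks set to (E+1)/2")
  }
  r <- t(apply(mat, 1L, rank, ties.method = "average"))
  dimnames(r) <- dimnames(mat)
  r
}

#' Euclidean distance between two ranked profiles
#'
#' @param g1,g2 Numeric rank vectors of equal length.
#' @return The Euclidean distance (zero iff identical).
#' @export
rank_distance <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("rank vectors must have equal length")
  sqrt(sum((g1 - g2)^2))
}

# Pairwise distance matrix among a set of genes, rows taken from the ranked
# profile matrix.
pair_distances <- function(ranks, genes) {
  as.matrix(stats::dist(ranks[genes, , drop = FALSE]))
}

# F from a precomputed distance matrix and an integer group-label vector.
# Labels <= 0 mark genes excluded from both sums (singleton groups).
f_from_labels <- function(dm, labels) {
  total <- sum(dm[labels > 0L, labels > 0L]) / 2
  w_sum <- 0
  n_within <- 0L
  n_genes <- 0L
  for (g in unique(labels[labels > 0L])) {
    idx <- which(labels == g)
    w_sum <- w_sum + sum(dm[idx, idx]) / 2
    n_within <- n_within + choose(length(idx), 2L)
    n_genes <- n_genes + length(idx)
  }
  m_between <- choose(n_genes, 2L) - n_within
  list(F = w_sum / n_within - (total - w_sum) / m_between,
       N = as.integer(n_within), M = as.integer(m_between))
}

# Integer labels for the qualifying (size >= 2) groups of a grouping, in the
# order of grouping$eligible_genes restricted to qualifying genes.
grouping_labels <- function(grouping) {
  qg <- qualifying_groups(grouping)
  qg <- qg[order(names(qg))]   # canonical order: results invariant to relabeling
  if (length(qg) < 2L) {
    stop("grouping is not testable (need >= 2 nucleotide groups with >= 2 genes); skip it")
  }
  genes <- unlist(qg, use.names = FALSE)
  labels <- rep(seq_along(qg), vapply(qg, length, integer(1L)))
  list(genes = genes, labels = labels, nucleotides = names(qg))
}

#' VDRE functionality score for one motif position
#'
#' The variant distance of ranked experiments (VDRE) compares expression
#' profile distances within and between nucleotide groups. With `D_W` the
#' pairwise ranked-profile distances between targets carrying the same
#' nucleotide and `D_B` those between targets carrying different nucleotides,
#' the score is `F = sum(D_W)/N - sum(D_B)/M`, all variants of the position
#' considered simultaneously. A strongly negative F means genes sharing a
#' variant have more similar condition-dependent expression than genes with
#' different variants.
#'
#' Only nucleotide groups with at least two genes enter either sum; genes in
#' singleton groups are excluded from both (see the package vignette for the
#' alternative reading).
#'
#' @param grouping A testable [build_variant_groupings()] result.
#' @param ranks Ranked profile matrix from [rank_profiles()].
#' @return List with elements `F`, `N` (within-pair count) and `M`
#'   (between-pair count).
#' @export
vdre_score <- function(grouping, ranks) {
  gl <- grouping_labels(grouping)
  missing <- setdiff(gl$genes, rownames(ranks))
  if (length(missing)) stop("genes missing from rank matrix: ",
                            paste(missing, collapse = ", "))
  dm <- pair_distances(ranks, gl$genes)
  f_from_labels(dm, gl$labels)
}

#' Permutation test for the VDRE score
#'
#' Permutes the assignment of target genes to nucleotide groups (group sizes
#' preserved) and compares the observed F with the permuted null
#' distribution. The test is one-sided in the negative-F direction: functional
#' positions have smaller within- than between-variant distances. The p-value
#' uses the bias-avoiding estimator `(1 + #{F_perm <= F_obs}) / (1 + n)` and
#' can therefore never be exactly zero.
#'
#' @inheritParams vdre_score
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Optional integer seed making the result reproducible.
#' @return Object of class `vdre_result`: list with `tf_id`, `motif_position`,
#'   `group_sizes`, `F`, `N`, `M`, `p_value`, `n_permutations`, `seed`
#'   (`q_value` is filled in later by a scan across positions).
#' @export
vdre_permutation_test <- function(grouping, ranks, n_permutations = 1000L,
                                  seed = NULL) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  gl <- grouping_labels(grouping)
  dm <- pair_distances(ranks, gl$genes)
  obs <- f_from_labels(dm, gl$labels)
  # under label permutation N, M and the total distance sum are invariant;
  # only the within-group sum varies, so permute gene indices against fixed
  # per-group slots
  total <- sum(dm) / 2
  n_genes <- length(gl$labels)
  idx_by_group <- split(seq_len(n_genes), gl$labels)
  if (!is.null(seed)) set.seed(seed)
  n_le <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n_genes)
    w_sum <- 0
    for (idx in idx_by_group) {
      pg <- perm[idx]
      w_sum <- w_sum + sum(dm[pg, pg]) / 2
    }
    f_perm <- w_sum / obs$N - (total - w_sum) / obs$M
    if (f_perm <= obs$F) n_le <- n_le + 1L
  }
  structure(list(tf_id = grouping$tf_id,
                 motif_position = grouping$motif_position,
                 group_sizes = grouping$group_sizes,
                 F = obs$F, N = obs$N, M = obs$M,
                 p_value = (1 + n_le) / (1 + n_permutations),
                 q_value = NA_real_,
                 n_permutations = as.integer(n_permutations),
                 seed = seed),
            class = "vdre_result")
}

#' @export
print.vdre_result <- function(x, ...) {
  cat(sprintf("VDRE: TF %s position %d | F = %.4f (N = %d, M = %d) | p = %.4g\n",
              x$tf_id, x$motif_position, x$F, x$N, x$M, x$p_value))
  invisible(x)
}

#' Storey q-values with fixed lambda
#'
#' Estimates the null proportion as
#' `pi0 = min(1, #(p > lambda) / (m (1 - lambda)))` and converts p-values to
#' q-values by `q(i) = min_(j >= i) pi0 * m * p(j) / j` over the sorted
#' p-values. Q-values are monotone in p and lie in `[0, 1]`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param lambda Tuning parameter in (0, 1) for the pi0 estimate (default 0.5).
#' @return Numeric vector of q-values in the original order, with the
#'   estimated null proportion attached as attribute `"pi0"`.
#' @export
estimate_fdr <- function(p_values, lambda = 0.5) {
  if (length(p_values) == 0L) stop("no p-values supplied")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie in (0, 1)")
  m <- length(p_values)
  pi0 <- min(1, sum(p_values > lambda) / (m * (1 - lambda)))
  ord <- order(p_values)
  q <- pi0 * m * p_values[ord] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  attr(out, "pi0") <- pi0
  out
}

#' Expected number of true positives among discoveries
#'
#' At a false discovery rate `fdr`, a set of `n_discoveries` rejections is
#' expected to contain `n_discoveries * (1 - fdr)` true positives.
#'
#' @param n_discoveries Number of rejected hypotheses.
#' @param fdr False discovery rate of the rejection set.
#' @return Expected count of true positives (not rounded).
#' @export
expected_true_positives <- function(n_discoveries, fdr) {
  stopifnot(n_discoveries >= 0, fdr >= 0, fdr <= 1)
  n_discoveries * (1 - fdr)
}

#' Minimum of within- and between-variant comparison counts
#'
#' A diagnostic of the information available to the permutation test at one
#' position: the lower of the number of within-group pairs N and between-group
#' pairs M.
#'
#' @param grouping A testable [build_variant_groupings()] result.
#' @return Integer `min(N, M)`.
#' @export
min_comparison_count <- function(grouping) {
  gl <- grouping_labels(grouping)
  sizes <- tabulate(gl$labels)
  n_within <- sum(choose(sizes, 2L))
  m_between <- choose(sum(sizes), 2L) - n_within
  as.integer(min(n_within, m_between))
}

#' Scan all TFs and motif positions for functional variants
#'
#' Builds the variant grouping for every (TF, motif position) pair, runs the
#' VDRE permutation test on each testable one, and estimates q-values across
#' the whole scan.
#'
#' @param sites Classified binding site data.frame.
#' @param expression Gene-by-condition expression matrix.
#' @param tf_ids TFs to scan (default: all with primary sites).
#' @param n_permutations Permutations per position (default 1000).
#' @param seed Integer seed; position-level seeds are derived from it so the
#'   scan is reproducible and order-independent.
#' @param gene_filter,scope Passed to [build_variant_groupings()].
#' @param fdr_lambda Lambda for [estimate_fdr()].
#' @return data.frame with one row per testable position: `tf_id`, `position`,
#'   `group_sizes`, `F`, `N`, `M`, `min_comparisons`, `p_value`, `q_value`.
#' @export
vdre_scan <- function(sites, expression, tf_ids = NULL,
                      n_permutations = 1000L, seed = 1L,
                      gene_filter = c("single_primary", "any_primary"),
                      scope = c("all_tfs", "same_tf"), fdr_lambda = 0.5) {
  gene_filter <- match.arg(gene_filter)
  scope <- match.arg(scope)
  ranks <- rank_profiles(expression)
  prim <- sites[sites$site_class == "primary", , drop = FALSE]
  if (is.null(tf_ids)) tf_ids <- sort(unique(prim$tf_id))
  rows <- list()
  k <- 0L
  for (tf in tf_ids) {
    tf_sites <- prim[prim$tf_id == tf, , drop = FALSE]
    if (nrow(tf_sites) == 0L) next
    motif_len <- nchar(tf_sites$site_sequence[1L])
    for (pos in seq_len(motif_len)) {
      grouping <- withCallingHandlers(
        build_variant_groupings(sites, tf, pos, gene_filter,
                                expression_genes = rownames(expression),
                                scope = scope),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!grouping$testable) next
      k <- k + 1L
      res <- vdre_permutation_test(grouping, ranks, n_permutations,
                                   seed = derive_seed(seed, tf, pos))
      rows[[k]] <- data.frame(tf_id = tf, position = pos,
                              group_sizes = format_group_sizes(grouping),
                              F = res$F, N = res$N, M = res$M,
                              min_comparisons = min(res$N, res$M),
                              p_value = res$p_value,
                              stringsAsFactors = FALSE)
    }
  }
  out <- if (k == 0L) {
    data.frame(tf_id = character(0L), position = integer(0L),
               group_sizes = character(0L), F = numeric(0L),
               N = integer(0L), M = integer(0L),
               min_comparisons = integer(0L), p_value = numeric(0L))
  } else {
    do.call(rbind, rows)
  }
  out$q_value <- if (nrow(out)) estimate_fdr(out$p_value, fdr_lambda) else numeric(0L)
  out
}

# Deterministic 31-bit sub-seed from a master seed and a string/int context,
# so each position (or pipeline stage) gets an independent reproducible stream.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Compare ranked-profile distances between binding-site sharing classes
#'
#' Computes pairwise ranked-profile distances for gene pairs that share a
#' binding site of a given class, and contrasts two classes with a Welch two
#' sample t-test. Classes:
#' \describe{
#'   \item{one_primary}{both genes have exactly one primary site genome-wide
#'     and those sites belong to the same TF;}
#'   \item{multi_primary}{the genes share a primary site for the same TF but
#'     at least one of them carries additional primary sites;}
#'   \item{secondary}{the genes share a secondary site for the same TF;}
#'   \item{random}{random gene pairs, drawn with the given seed.}
#' }
#'
#' @param sites Classified binding site data.frame.
#' @param expression Gene-by-condition expression matrix.
#' @param class_pair Character vector of two class names to contrast.
#' @param n_random Number of random pairs drawn for the `random` class.
#' @param seed Integer seed for the random pairs.
#' @param max_pairs_per_tf Cap on pairs sampled per TF and class to bound cost.
#' @return List with `means` (named mean distance per requested class),
#'   `t_statistic`, `p_value`, `df`, and `distances` (list of the raw distance
#'   vectors). Degenerate variance is reported via `note` instead of an error.
#' @export
distance_class_comparison <- function(sites, expression,
                                      class_pair = c("one_primary", "random"),
                                      n_random = 1000L, seed = 1L,
                                      max_pairs_per_tf = 500L) {
  stopifnot(length(class_pair) == 2L)
  valid <- c("one_primary", "multi_primary", "secondary", "random")
  if (!all(class_pair %in% valid)) {
    stop("classes must be among: ", paste(valid, collapse = ", "))
  }
  ranks <- rank_profiles(expression)
  genes <- rownames(ranks)
  prim <- sites[sites$site_class == "primary" & sites$gene_id %in% genes, , drop = FALSE]
  n_primary <- table(prim$gene_id)
  set.seed(derive_seed(seed, "distance-classes"))

  pair_dists_for <- function(members, keep_pair) {
    out <- numeric(0L)
    for (tf in names(members)) {
      g <- unique(members[[tf]])
      if (length(g) < 2L) next
      pairs <- utils::combn(g, 2L)
      keep <- apply(pairs, 2L, keep_pair)
      pairs <- pairs[, keep, drop = FALSE]
      if (ncol(pairs) == 0L) next
      if (ncol(pairs) > max_pairs_per_tf) {
        pairs <- pairs[, sample.int(ncol(pairs), max_pairs_per_tf), drop = FALSE]
      }
      dm <- pair_distances(ranks, g)
      out <- c(out, dm[cbind(pairs[1L, ], pairs[2L, ])])
    }
    out
  }

  get_class <- function(cls) {
    switch(cls,
      one_primary = {
        singles <- names(n_primary)[n_primary == 1L]
        pair_dists_for(split(prim$gene_id[prim$gene_id %in% singles],
                             prim$tf_id[prim$gene_id %in% singles]),
                       function(p) TRUE)
      },
      multi_primary = {
        multi <- names(n_primary)[n_primary > 1L]
        pair_dists_for(split(prim$gene_id, prim$tf_id),
                       function(p) any(p %in% multi))
      },
      secondary = {
        sec <- sites[sites$site_class == "secondary" & sites$gene_id %in% genes, , drop = FALSE]
        pair_dists_for(split(sec$gene_id, sec$tf_id), function(p) TRUE)
      },
      random = {
        i <- sample.int(length(genes), n_random, replace = TRUE)
        j <- sample.int(length(genes), n_random, replace = TRUE)
        keep <- i != j
        vapply(which(keep), function(k) {
          rank_distance(ranks[i[k], ], ranks[j[k], ])
        }, numeric(1L))
      })
  }

  distances <- lapply(stats::setNames(class_pair, class_pair), get_class)
  if (any(lengths(distances) < 2L)) {
    stop("need at least 2 pair distances per class; got ",
         paste(lengths(distances), collapse = ", "))
  }
  means <- vapply(distances, mean, numeric(1L))
  tt <- tryCatch(stats::t.test(distances[[1L]], distances[[2L]], var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) {
    return(list(means = means, t_statistic = NA_real_, p_value = NA_real_,
                df = NA_real_, distances = distances,
                note = "degenerate variance; Welch statistic undefined"))
  }
  list(means = means, t_statistic = unname(tt$statistic),
       p_value = tt$p.value, df = unname(tt$parameter), distances = distances)
}
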