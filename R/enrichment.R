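#' Permutation-based GO process enrichment per variant group
#'
#' For each nucleotide group at a variant position and each GO biological
#' process annotated on at least one eligible target gene, counts the
#' annotated genes in the group and compares the count to a null built by
#' shuffling the gene-to-group assignment (group sizes fixed, annotations
#' staying with their genes). The p-value is one-sided for enrichment:
#' `(1 + #{null >= observed}) / (1 + n)`.
#'
#' @param grouping A [build_variant_groupings()] result.
#' @param go_map Named list gene id -> character vector of process ids; genes
#'   absent from the map are unannotated.
#' @param n_permutations Number of assignment shuffles (default 10000).
#' @param seed Optional integer seed.
#' @return data.frame with columns `nucleotide`, `go_process_id`,
#'   `group_size`, `observed_count`, `p_value`, `n_permutations`. Empty (with
#'   a warning) when no eligible gene is annotated.
#' @export
go_enrichment <- function(grouping, go_map, n_permutations = 10000L,
                          seed = NULL) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  genes <- unlist(grouping$groups, use.names = FALSE)
  nucs <- rep(names(grouping$groups),
              vapply(grouping$groups, length, integer(1L)))
  processes <- sort(unique(unlist(go_map[intersect(genes, names(go_map))],
                                  use.names = FALSE)))
  if (length(processes) == 0L) {
    warning("no eligible target gene carries a GO annotation")
    return(data.frame(nucleotide = character(0L), go_process_id = character(0L),
                      group_size = integer(0L), observed_count = integer(0L),
                      p_value = numeric(0L), n_permutations = integer(0L)))
  }
  # genes x processes indicator
  ann <- vapply(processes, function(p) {
    vapply(genes, function(g) p %in% go_map[[g]], logical(1L))
  }, logical(length(genes)))
  ann <- matrix(ann, nrow = length(genes),
                dimnames = list(genes, processes))
  group_levels <- names(grouping$groups)
  observed <- rowsum(ann + 0, nucs)[group_levels, , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  n_ge <- matrix(0L, nrow = length(group_levels), ncol = length(processes),
                 dimnames = dimnames(observed))
  for (b in seq_len(n_permutations)) {
    perm_counts <- rowsum(ann + 0, sample(nucs))[group_levels, , drop = FALSE]
    n_ge <- n_ge + (perm_counts >= observed)
  }
  p <- (1 + n_ge) / (1 + n_permutations)
  sizes <- grouping$group_sizes[group_levels]
  data.frame(nucleotide = rep(group_levels, times = length(processes)),
             go_process_id = rep(processes, each = length(group_levels)),
             group_size = rep(unname(sizes), times = length(processes)),
             observed_count = as.integer(observed),
             p_value = as.numeric(p),
             n_permutations = as.integer(n_permutations),
             stringsAsFactors = FALSE)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value under the probability-ordering definition (the sum of
#' hypergeometric probabilities of all tables with the same margins that are
#' as or less probable than the observed one). A zero row or column margin
#' gives p = 1.
#'
#' @param table 2x2 matrix of non-negative counts, or the four counts
#'   `c(a, b, c, d)` filled by row.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, nrow = 2L, byrow = TRUE)
  stopifnot(identical(dim(table), c(2L, 2L)))
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  stats::fisher.test(table)$p.value
}

#' Screen a variant position for confounding secondary binding sites
#'
#' A functional variant call could be explained by a lower-quality binding
#' site of another TF that happens to co-occur with one nucleotide group. For
#' every (nucleotide group, other TF with at least one secondary site among
#' the position's target genes), this screen tallies targets by group
#' membership and presence of a coincident secondary site into a 2x2 table
#' and applies [fisher_exact_2x2()]. "Coincident" means any secondary site of
#' that TF annotated to the same target gene.
#'
#' @param grouping A [build_variant_groupings()] result.
#' @param sites Classified binding site data.frame (secondary sites are drawn
#'   from here).
#' @param alpha Flagging level (default 0.01).
#' @return data.frame with columns `nucleotide`, `other_tf`, `a`, `b`, `c`,
#'   `d` (a = in group & has site, b = in group & lacks site, c/d the
#'   complement group), `p_value`, `flagged`; attribute `any_flagged` records
#'   the position-level exclusion criterion. Empty when no secondary sites
#'   touch the targets.
#' @export
cooccurrence_screen <- function(grouping, sites, alpha = 0.01) {
  targets <- grouping$eligible_genes
  sec <- sites[sites$site_class == "secondary" &
                 sites$gene_id %in% targets &
                 sites$tf_id != grouping$tf_id, , drop = FALSE]
  empty <- data.frame(nucleotide = character(0L), other_tf = character(0L),
                      a = integer(0L), b = integer(0L), c = integer(0L),
                      d = integer(0L), p_value = numeric(0L),
                      flagged = logical(0L))
  attr(empty, "any_flagged") <- FALSE
  if (nrow(sec) == 0L) return(empty)
  carriers <- split(sec$gene_id, sec$tf_id)
  rows <- list()
  k <- 0L
  for (nuc in names(grouping$groups)) {
    in_group <- targets %in% grouping$groups[[nuc]]
    for (tf in names(carriers)) {
      has_site <- targets %in% carriers[[tf]]
      a <- sum(in_group & has_site)
      b <- sum(in_group & !has_site)
      cc <- sum(!in_group & has_site)
      d <- sum(!in_group & !has_site)
      p <- fisher_exact_2x2(matrix(c(a, b, cc, d), 2L, byrow = TRUE))
      k <- k + 1L
      rows[[k]] <- data.frame(nucleotide = nuc, other_tf = tf,
                              a = a, b = b, c = cc, d = d,
                              p_value = p, flagged = p < alpha,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "any_flagged") <- any(out$flagged)
  out
}
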