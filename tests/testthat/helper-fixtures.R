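# In-code fixtures shared across test files.

# Site table from compact triples.
make_sites <- function(...) {
  rows <- list(...)
  df <- data.frame(tf_id = vapply(rows, `[[`, character(1L), 1L),
                   gene_id = vapply(rows, `[[`, character(1L), 2L),
                   site_sequence = vapply(rows, `[[`, character(1L), 3L),
                   posterior = vapply(rows, function(r) as.numeric(r[[4L]]),
                                      numeric(1L)),
                   stringsAsFactors = FALSE)
  classify_binding_sites(df)
}

# A deterministic rank-profile matrix for a set of genes (values arbitrary
# but fixed by the gene index and a seed).
make_ranks <- function(genes, n_cond = 6L, seed = 42L) {
  set.seed(seed)
  m <- matrix(rnorm(length(genes) * n_cond), length(genes),
              dimnames = list(genes, sprintf("c%02d", seq_len(n_cond))))
  rank_profiles(m)
}

# Minimal grouping object without going through site tables.
make_grouping <- function(groups, tf_id = "TFX", position = 1L) {
  sizes <- vapply(groups, length, integer(1L))
  structure(list(tf_id = tf_id, motif_position = as.integer(position),
                 groups = groups, group_sizes = sizes,
                 testable = sum(sizes >= 2L) >= 2L,
                 eligible_genes = sort(unlist(groups, use.names = FALSE)),
                 gene_filter = "single_primary"),
            class = "variant_grouping")
}

# Expression matrix whose rows are explicit vectors.
make_expr <- function(rows, cond_ids = NULL) {
  m <- do.call(rbind, rows)
  if (is.null(cond_ids)) cond_ids <- sprintf("c%02d", seq_len(ncol(m)))
  dimnames(m) <- list(names(rows), cond_ids)
  m
}
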