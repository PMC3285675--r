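#' Run the full BSMV analysis pipeline
#'
#' Orchestrates the stages in the order of the analysis: (optionally)
#' generate synthetic inputs, scan all TF motif positions with the VDRE
#' permutation test, and characterize the significant positions
#' (condition-specificity clustering, rank reversal and slope-sign tests, GO
#' enrichment, secondary-site co-occurrence screen). All stage outputs are
#' written as TSV files plus a machine-readable JSON manifest; fixed seeds
#' make re-runs byte-identical (floats formatted to 6 significant digits).
#'
#' @param config List with either `scenario` (a [scenario_config()]) or
#'   `inputs` (named paths `expression`, `conditions`, `sites`, optionally
#'   `go`), plus optional overrides: `n_perm_vdre` (1000), `n_perm_clustering`
#'   (10000), `n_perm_go` (10000), `p_max` (0.05), `q_max` (NULL, set to gate
#'   on FDR instead of raw p), `alpha_cooccurrence` (0.01), `gene_filter`
#'   (`"single_primary"`), `seed` (1).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the stage data.frames and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  defaults <- list(n_perm_vdre = 1000L, n_perm_clustering = 10000L,
                   n_perm_go = 10000L, p_max = 0.05, q_max = NULL,
                   alpha_cooccurrence = 0.01, gene_filter = "single_primary",
                   seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$scenario)) {
    scenario <- generate_scenario(config$scenario)
    input_dir <- file.path(out_dir, "inputs")
    input_paths <- write_scenario(scenario, input_dir)
    expression <- scenario$expression
    metadata <- scenario$metadata
    sites <- scenario$sites
    go_map <- scenario$go_map
  } else {
    if (is.null(config$inputs)) stop("config needs either $scenario or $inputs")
    input_paths <- unlist(config$inputs)
    for (p in input_paths) {
      if (!file.exists(p)) stop("pipeline input file not found: ", p)
    }
    expression <- read_expression_matrix(config$inputs$expression)
    metadata <- read_condition_metadata(config$inputs$conditions,
                                        colnames(expression))
    sites <- read_binding_sites(config$inputs$sites)
    if (nrow(sites) == 0L) stop("empty binding-site file: ", config$inputs$sites)
    go_map <- if (!is.null(config$inputs$go)) read_go_map(config$inputs$go) else NULL
  }
  validate_condition_metadata(metadata, colnames(expression))
  ranks <- rank_profiles(expression)

  # --- stage 1: VDRE scan -------------------------------------------------
  vdre <- vdre_scan(sites, expression,
                    n_permutations = config$n_perm_vdre,
                    seed = derive_seed(config$seed, "vdre"),
                    gene_filter = config$gene_filter)
  write_stage_tsv(vdre, file.path(out_dir, "vdre.tsv"))
  significant <- if (!is.null(config$q_max)) {
    vdre[vdre$p_value < config$p_max & vdre$q_value <= config$q_max, , drop = FALSE]
  } else {
    vdre[vdre$p_value < config$p_max, , drop = FALSE]
  }

  # --- stage 2: condition specificity, reversal, slopes -------------------
  cs_rows <- list(); go_rows <- list(); co_rows <- list()
  k <- 0L
  for (i in seq_len(nrow(significant))) {
    tf <- significant$tf_id[i]
    pos <- significant$position[i]
    grouping <- withCallingHandlers(
      build_variant_groupings(sites, tf, pos, config$gene_filter,
                              expression_genes = rownames(expression)),
      warning = function(w) invokeRestart("muffleWarning"))
    qg <- qualifying_groups(grouping)
    pairs <- utils::combn(names(qg), 2L)
    for (j in seq_len(ncol(pairs))) {
      vp <- pairs[, j]
      ch <- characterize_variant_pair(
        grouping, expression, metadata, vp, ranks = ranks,
        n_permutations = config$n_perm_clustering,
        seed = derive_seed(config$seed, "cs", tf, pos, vp[1L], vp[2L]))
      k <- k + 1L
      cs_rows[[k]] <- data.frame(
        tf_id = tf, position = pos,
        variant_a = vp[1L], variant_b = vp[2L],
        S = ch$clustering$S, C_W = ch$clustering$C_W, C_Q = ch$clustering$C_Q,
        A = ch$clustering$A, B = ch$clustering$B,
        clustering_p = ch$clustering$p_value,
        reversal_rho = ch$reversal$statistic,
        reversal_p = ch$reversal$p_value,
        slope_a = ch$slopes$slope_a, slope_p_a = ch$slopes$p_a,
        slope_b = ch$slopes$slope_b, slope_p_b = ch$slopes$p_b,
        passes_both = ch$passes_both, stringsAsFactors = FALSE)
    }
    if (!is.null(go_map)) {
      enr <- withCallingHandlers(
        go_enrichment(grouping, go_map, config$n_perm_go,
                      seed = derive_seed(config$seed, "go", tf, pos)),
        warning = function(w) invokeRestart("muffleWarning"))
      if (nrow(enr)) {
        go_rows[[length(go_rows) + 1L]] <-
          cbind(data.frame(tf_id = tf, position = pos), enr)
      }
    }
    co <- cooccurrence_screen(grouping, sites, config$alpha_cooccurrence)
    if (nrow(co)) {
      co_rows[[length(co_rows) + 1L]] <-
        cbind(data.frame(tf_id = tf, position = pos), co)
    }
  }
  cond_spec <- rbind_or_empty(cs_rows, c("tf_id", "position", "variant_a",
                                         "variant_b", "S", "C_W", "C_Q", "A", "B",
                                         "clustering_p", "reversal_rho", "reversal_p",
                                         "slope_a", "slope_p_a", "slope_b",
                                         "slope_p_b", "passes_both"))
  go_out <- rbind_or_empty(go_rows, c("tf_id", "position", "nucleotide",
                                      "go_process_id", "group_size",
                                      "observed_count", "p_value",
                                      "n_permutations"))
  co_out <- rbind_or_empty(co_rows, c("tf_id", "position", "nucleotide",
                                      "other_tf", "a", "b", "c", "d",
                                      "p_value", "flagged"))
  write_stage_tsv(cond_spec, file.path(out_dir, "condition_specificity.tsv"))
  write_stage_tsv(go_out, file.path(out_dir, "go_enrichment.tsv"))
  write_stage_tsv(co_out, file.path(out_dir, "cooccurrence.tsv"))

  # --- stage 3: summary + manifest ----------------------------------------
  summary <- summarize_results(vdre, p_max = config$p_max, q_max = config$q_max)
  write_stage_tsv(summary, file.path(out_dir, "summary.tsv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("bsmv")),
    seed = config$seed,
    stage_seeds = list(vdre = derive_seed(config$seed, "vdre")),
    parameters = config[c("n_perm_vdre", "n_perm_clustering", "n_perm_go",
                          "p_max", "q_max", "alpha_cooccurrence", "gene_filter")],
    input_digests = as.list(tools::md5sum(unname(input_paths))),
    row_counts = list(vdre = nrow(vdre), significant = nrow(significant),
                      condition_specificity = nrow(cond_spec),
                      go_enrichment = nrow(go_out),
                      cooccurrence = nrow(co_out)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(vdre = vdre, significant = significant,
                 condition_specificity = cond_spec, go_enrichment = go_out,
                 cooccurrence = co_out, summary = summary, manifest = manifest))
}

rbind_or_empty <- function(rows, col_names) {
  if (length(rows)) return(do.call(rbind, rows))
  df <- as.data.frame(stats::setNames(rep(list(logical(0L)), length(col_names)),
                                      col_names))
  df
}

# TSV writer with fixed float formatting (6 significant digits) so pipeline
# outputs are byte-stable across runs.
write_stage_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6L)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize a VDRE scan per TF
#'
#' Counts, per TF and overall, the motif positions considered and the
#' positions called functional, with percentages — and likewise at the motif
#' level (a TF counts as having functional variants when any of its positions
#' is significant).
#'
#' @param vdre A [vdre_scan()] data.frame (or a results directory containing
#'   `vdre.tsv`).
#' @param p_max Raw p-value gate (default 0.05).
#' @param q_max Optional q-value gate applied in addition.
#' @return data.frame with one row per TF plus a `TOTAL` row: `tf_id`,
#'   `n_positions`, `n_functional`, `pct_functional`.
#' @export
summarize_results <- function(vdre, p_max = 0.05, q_max = NULL) {
  if (is.character(vdre)) {
    path <- file.path(vdre, "vdre.tsv")
    if (!file.exists(path)) stop("no vdre.tsv under ", vdre)
    vdre <- utils::read.delim(path, sep = "\t", header = TRUE)
  }
  need <- c("tf_id", "position", "p_value", "q_value")
  if (!all(need %in% names(vdre))) {
    stop("summary needs columns: ", paste(need, collapse = ", "))
  }
  hit <- vdre$p_value < p_max
  if (!is.null(q_max)) hit <- hit & vdre$q_value <= q_max
  tfs <- sort(unique(vdre$tf_id))
  rows <- lapply(tfs, function(tf) {
    sel <- vdre$tf_id == tf
    data.frame(tf_id = tf, n_positions = sum(sel),
               n_functional = sum(hit & sel),
               pct_functional = 100 * sum(hit & sel) / sum(sel),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(tf_id = "TOTAL", n_positions = nrow(vdre),
                        n_functional = sum(hit),
                        pct_functional = if (nrow(vdre)) 100 * sum(hit) / nrow(vdre) else 0))
}
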