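#' Configure a synthetic BSMV scenario
#'
#' Describes a simulated study: a set of TFs, each with one focal variable
#' motif position whose nucleotide groups of target genes may carry a planted
#' BSMV-by-condition-class interaction. Expression is generated as
#' `baseline(gene) + condition_effect(condition) +
#' interaction(nucleotide(gene), experiment_type(condition)) +
#' Gaussian(0, noise_sd)` on a log-like scale. Because all downstream
#' statistics use within-gene ranks, per-gene baselines cancel and the noise
#' family affects power, not validity.
#'
#' Regimes per TF (each TF responds to its own pair of experiment types,
#' rotated across TFs, so different regulons are perturbed under different
#' conditions):
#' \describe{
#'   \item{null}{no interaction anywhere;}
#'   \item{affinity_scaling}{the first two nucleotide groups respond in the
#'     same direction to the TF's first experiment type, with different
#'     magnitudes (effect_size and 0.3 * effect_size);}
#'   \item{reversal}{the first nucleotide group gets `+effect_size` in the
#'     TF's first experiment type and `-effect_size` in its second; the
#'     second group the mirror image (effect vectors with rank correlation
#'     -1); remaining groups are untouched.}
#' }
#'
#' @param n_tfs Number of TFs (default 4).
#' @param motif_length Motif length(s) in bp, each in 6..16, recycled over
#'   TFs; `NULL` (default) samples lengths uniformly from 6..16.
#' @param n_conditions Number of conditions (default 24).
#' @param n_experiment_types Number of experiment-type classes; conditions are
#'   split as evenly as possible (default 4).
#' @param nucleotides_per_position Number of nucleotide groups at each focal
#'   position, 2..4 (default 3).
#' @param genes_per_group Target genes per nucleotide group (default 5).
#' @param regime Per-TF regime, recycled: `"null"`, `"affinity_scaling"` or
#'   `"reversal"` (default `"null"`).
#' @param effect_size Interaction magnitude in expression units (default 3).
#' @param noise_sd Gaussian noise standard deviation (default 1).
#' @param baseline_sd Per-gene baseline standard deviation (default 2).
#' @param condition_effect_sd Shared per-condition effect sd (default 1).
#' @param secondary_fraction Probability that a target gene receives one
#'   secondary site of a random other TF (default 0.1).
#' @param go_background_rate Probability that a gene gets one random
#'   background GO process (default 0.3).
#' @param go_signal Optional named character vector nucleotide -> GO process
#'   id: every gene in that nucleotide group is annotated with the process.
#' @param seed Master integer seed; component sub-streams are derived from it.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(n_tfs = 4L, motif_length = NULL,
                            n_conditions = 24L, n_experiment_types = 4L,
                            nucleotides_per_position = 3L,
                            genes_per_group = 5L,
                            regime = "null", effect_size = 3,
                            noise_sd = 1, baseline_sd = 2,
                            condition_effect_sd = 1,
                            secondary_fraction = 0.1,
                            go_background_rate = 0.3,
                            go_signal = NULL, seed = 1L) {
  stopifnot(n_tfs >= 1L, n_conditions >= 2L, n_experiment_types >= 1L,
            n_experiment_types <= n_conditions,
            nucleotides_per_position >= 2L, nucleotides_per_position <= 4L,
            genes_per_group >= 1L, noise_sd >= 0, baseline_sd >= 0,
            condition_effect_sd >= 0, effect_size >= 0,
            secondary_fraction >= 0, secondary_fraction <= 1)
  regime <- rep_len(match.arg(regime, c("null", "affinity_scaling", "reversal"),
                              several.ok = TRUE), n_tfs)
  if (!is.null(motif_length)) {
    motif_length <- rep_len(as.integer(motif_length), n_tfs)
    if (any(motif_length < 6L | motif_length > 16L)) {
      stop("motif lengths must lie in 6..16")
    }
  }
  if (any(regime != "null") && genes_per_group < 2L) {
    stop("planted regimes need >= 2 genes per nucleotide group")
  }
  if (any(regime == "reversal") && n_experiment_types < 2L) {
    stop("reversal regime needs >= 2 experiment types")
  }
  structure(as.list(environment()), class = "scenario_config")
}

#' Generate a synthetic scenario with known ground truth
#'
#' Produces an expression matrix, condition metadata, classified binding site
#' annotations, a GO map, and a truth table describing every planted effect,
#' all reproducible from `config$seed`.
#'
#' @param config A [scenario_config()].
#' @return List of class `bsmv_scenario` with elements `expression` (matrix),
#'   `metadata`, `sites`, `go_map`, `truth` (data.frame: `tf_id`, `position`,
#'   `regime`, `nucleotide`, `experiment_type`, `effect`) and `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  nucs <- c("A", "C", "G", "T")

  # conditions & types
  type_sizes <- rep(config$n_conditions %/% config$n_experiment_types,
                    config$n_experiment_types)
  rem <- config$n_conditions - sum(type_sizes)
  if (rem > 0L) type_sizes[seq_len(rem)] <- type_sizes[seq_len(rem)] + 1L
  types <- sprintf("type%02d", seq_len(config$n_experiment_types))
  metadata <- data.frame(
    condition_id = sprintf("cond%03d", seq_len(config$n_conditions)),
    experiment_type = rep(types, times = type_sizes),
    stringsAsFactors = FALSE)

  # motifs, focal positions, target genes, primary sites
  set.seed(derive_seed(config$seed, "motifs"))
  tf_ids <- sprintf("TF%02d", seq_len(config$n_tfs))
  motif_len <- if (is.null(config$motif_length)) {
    sample(6:16, config$n_tfs, replace = TRUE)
  } else config$motif_length
  focal_pos <- vapply(motif_len, function(l) sample.int(l, 1L), integer(1L))
  consensus <- vapply(motif_len, function(l) {
    paste(sample(nucs, l, replace = TRUE), collapse = "")
  }, character(1L))

  site_rows <- list()
  truth_rows <- list()
  gene_group <- list()    # per TF: named chr vector gene -> nucleotide
  for (i in seq_len(config$n_tfs)) {
    group_nucs <- sample(nucs, config$nucleotides_per_position)
    genes <- character(0L)
    assign <- character(0L)
    for (nuc in group_nucs) {
      g <- sprintf("%s_%s_g%02d", tf_ids[i], nuc, seq_len(config$genes_per_group))
      genes <- c(genes, g)
      assign <- c(assign, rep(nuc, length(g)))
    }
    names(assign) <- genes
    gene_group[[tf_ids[i]]] <- assign
    seqs <- vapply(assign, function(nuc) {
      s <- consensus[i]
      substr(s, focal_pos[i], focal_pos[i]) <- nuc
      s
    }, character(1L))
    site_rows[[i]] <- data.frame(tf_id = tf_ids[i], gene_id = genes,
                                 site_sequence = unname(seqs),
                                 posterior = stats::runif(length(genes), 0.7, 1),
                                 stringsAsFactors = FALSE)
    # planted interaction: nucleotide x experiment type
    eff <- matrix(0, nrow = length(group_nucs), ncol = config$n_experiment_types,
                  dimnames = list(group_nucs, types))
    # each TF responds to its own pair of experiment types (rotated across
    # TFs) so that different TFs' regulons are perturbed in different
    # conditions, as with real condition-specific regulators
    t1 <- (i - 1L) %% config$n_experiment_types + 1L
    t2 <- i %% config$n_experiment_types + 1L
    if (config$regime[i] == "affinity_scaling") {
      eff[1L, t1] <- config$effect_size
      eff[2L, t1] <- 0.3 * config$effect_size
    } else if (config$regime[i] == "reversal") {
      eff[1L, t1] <- config$effect_size
      eff[1L, t2] <- -config$effect_size
      eff[2L, t1] <- -config$effect_size
      eff[2L, t2] <- config$effect_size
    }
    truth_rows[[i]] <- data.frame(
      tf_id = tf_ids[i], position = focal_pos[i], regime = config$regime[i],
      nucleotide = rep(group_nucs, each = config$n_experiment_types),
      experiment_type = rep(types, times = length(group_nucs)),
      effect = as.numeric(t(eff)), stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_rows)

  # secondary sites sprinkled uniformly (null for the co-occurrence screen)
  set.seed(derive_seed(config$seed, "secondary"))
  if (config$secondary_fraction > 0 && config$n_tfs > 1L) {
    hit <- stats::runif(nrow(sites)) < config$secondary_fraction
    if (any(hit)) {
      idx <- which(hit)
      other <- vapply(sites$tf_id[idx], function(tf) {
        sample(setdiff(tf_ids, tf), 1L)
      }, character(1L))
      oi <- match(other, tf_ids)
      sec_seq <- vapply(oi, function(j) {
        s <- consensus[j]
        substr(s, focal_pos[j], focal_pos[j]) <- sample(nucs, 1L)
        s
      }, character(1L))
      sites <- rbind(sites, data.frame(
        tf_id = other, gene_id = sites$gene_id[idx], site_sequence = sec_seq,
        posterior = stats::runif(length(idx), 0.2 + 1e-6, 0.7 - 1e-6),
        stringsAsFactors = FALSE))
    }
  }
  sites <- classify_binding_sites(sites)

  # GO annotations
  set.seed(derive_seed(config$seed, "go"))
  all_genes <- unlist(lapply(gene_group, names), use.names = FALSE)
  pool <- sprintf("GO:BP%02d", 1:10)
  go_map <- list()
  bg <- stats::runif(length(all_genes)) < config$go_background_rate
  bg_proc <- sample(pool, length(all_genes), replace = TRUE)
  for (k in which(bg)) go_map[[all_genes[k]]] <- bg_proc[k]
  if (!is.null(config$go_signal)) {
    for (tf in tf_ids) {
      assign <- gene_group[[tf]]
      for (nuc in names(config$go_signal)) {
        for (g in names(assign)[assign == nuc]) {
          go_map[[g]] <- unique(c(go_map[[g]], config$go_signal[[nuc]]))
        }
      }
    }
  }

  # expression
  set.seed(derive_seed(config$seed, "expression"))
  n_genes <- length(all_genes)
  baseline <- stats::rnorm(n_genes, 6, config$baseline_sd)
  cond_eff <- stats::rnorm(config$n_conditions, 0, config$condition_effect_sd)
  truth <- do.call(rbind, truth_rows)
  expr <- matrix(baseline, n_genes, config$n_conditions) +
    matrix(cond_eff, n_genes, config$n_conditions, byrow = TRUE)
  dimnames(expr) <- list(all_genes, metadata$condition_id)
  type_of <- stats::setNames(metadata$experiment_type, metadata$condition_id)
  for (tf in tf_ids) {
    assign <- gene_group[[tf]]
    tf_truth <- truth[truth$tf_id == tf, , drop = FALSE]
    for (g in names(assign)) {
      e <- tf_truth[tf_truth$nucleotide == assign[[g]], , drop = FALSE]
      eff_by_type <- stats::setNames(e$effect, e$experiment_type)
      expr[g, ] <- expr[g, ] + eff_by_type[type_of[colnames(expr)]]
    }
  }
  if (config$noise_sd > 0) {
    expr <- expr + matrix(stats::rnorm(length(expr), 0, config$noise_sd),
                          nrow = n_genes)
  }

  structure(list(expression = expr, metadata = metadata, sites = sites,
                 go_map = go_map, truth = truth, config = config),
            class = "bsmv_scenario")
}

#' @export
print.bsmv_scenario <- function(x, ...) {
  cat("Synthetic BSMV scenario:", nrow(x$expression), "genes x",
      ncol(x$expression), "conditions;", x$config$n_tfs, "TF(s);",
      "regimes:", paste(unique(x$config$regime), collapse = ","), "\n")
  invisible(x)
}

#' Bundled reversal demo scenario
#'
#' One TF whose focal position carries a strong sign-reversing
#' BSMV-by-condition interaction (effect three times the noise sd), three
#' nucleotide groups of five genes, 24 conditions in four experiment types,
#' and a GO process planted on the first reversal group. This is the
#' positive-control scenario used throughout the test suite.
#'
#' @param seed Integer seed.
#' @param go_process Process id planted on the first nucleotide group.
#' @return A [generate_scenario()] result.
#' @export
reversal_scenario <- function(seed = 1L, go_process = "GO:PLANTED") {
  cfg <- scenario_config(n_tfs = 1L, motif_length = 8L, regime = "reversal",
                         seed = seed)
  scn <- generate_scenario(cfg)
  # attach the planted GO signal to the first reversal nucleotide
  planted_nuc <- unique(scn$truth$nucleotide)[1L]
  cfg2 <- scenario_config(n_tfs = 1L, motif_length = 8L, regime = "reversal",
                          go_signal = stats::setNames(go_process, planted_nuc),
                          seed = seed)
  generate_scenario(cfg2)
}

#' Plant secondary-site co-occurrence for one nucleotide group
#'
#' Adds secondary binding sites (posterior uniform in (0.2, 0.7)) of a
#' confounder TF to the target genes carrying a given nucleotide at the focal
#' position of `tf_id`, at the given per-gene rate. Serves as the positive
#' control for [cooccurrence_screen()].
#'
#' @param sites Classified binding site data.frame.
#' @param tf_id Focal TF.
#' @param motif_position 1-based focal position.
#' @param nucleotide The nucleotide group to confound.
#' @param confounder_tf TF id whose secondary sites are planted (need not have
#'   other annotations).
#' @param rate Per-gene probability of receiving a planted site, in `[0, 1]`.
#' @param motif_length Motif length used for the confounder's site sequences
#'   (default 8).
#' @param seed Optional integer seed.
#' @return The site table with planted secondary sites appended (reclassified).
#' @export
plant_cooccurrence <- function(sites, tf_id, motif_position, nucleotide,
                               confounder_tf, rate, motif_length = 8L,
                               seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  prim <- sites[sites$tf_id == tf_id & sites$site_class == "primary", , drop = FALSE]
  nuc <- substr(prim$site_sequence, motif_position, motif_position)
  targets <- unique(prim$gene_id[nuc == nucleotide])
  hit <- targets[stats::runif(length(targets)) < rate]
  if (length(hit) == 0L) return(sites)
  planted <- data.frame(
    tf_id = confounder_tf, gene_id = hit,
    site_sequence = vapply(hit, function(g) {
      paste(sample(c("A", "C", "G", "T"), motif_length, replace = TRUE),
            collapse = "")
    }, character(1L)),
    posterior = stats::runif(length(hit), 0.2 + 1e-6, 0.7 - 1e-6),
    stringsAsFactors = FALSE)
  classify_binding_sites(rbind(sites[, c("tf_id", "gene_id", "site_sequence",
                                         "posterior")], planted))
}

#' Write a scenario's input tables to a directory
#'
#' Writes `expression.tsv`, `conditions.tsv`, `sites.tsv`, `go.tsv` and
#' `truth.tsv` in the package's external formats.
#'
#' @param scenario A [generate_scenario()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             conditions = file.path(dir, "conditions.tsv"),
             sites = file.path(dir, "sites.tsv"),
             go = file.path(dir, "go.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression_matrix(scenario$expression, paths[["expression"]])
  write_condition_metadata(scenario$metadata, paths[["conditions"]])
  write_binding_sites(scenario$sites, paths[["sites"]])
  write_go_map(scenario$go_map, paths[["go"]])
  utils::write.table(scenario$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
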