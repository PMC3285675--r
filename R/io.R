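#' Read a gene-by-condition expression matrix
#'
#' Reads a tab-delimited expression table whose first row holds condition
#' identifiers and whose first column holds gene identifiers. Values are
#' assumed to be normalized, log-scale expression measurements; the platform
#' is irrelevant because all downstream statistics operate on within-gene
#' ranks.
#'
#' @param path Path to a UTF-8, tab-delimited file. The header line is
#'   `gene_id<TAB>cond1<TAB>cond2...`; each subsequent line is one gene.
#' @return A numeric matrix with gene identifiers as rownames and condition
#'   identifiers as colnames.
#' @details Malformed rows (wrong field count), non-numeric cells, duplicate
#'   gene or condition identifiers, and non-finite values are rejected with
#'   an error naming the offending line.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("expression matrix file must contain a header and at least one gene row: ", path)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_cond <- length(header) - 1L
  if (n_cond < 1L) stop("header must name at least one condition (line 1)")
  cond_ids <- header[-1L]
  if (anyDuplicated(cond_ids)) stop("duplicate condition ids in header (line 1)")
  widths <- lengths(fields[-1L])
  bad <- which(widths != n_cond + 1L)
  if (length(bad)) {
    stop(sprintf("line %d has %d fields, expected %d", bad[1L] + 1L,
                 widths[bad[1L]], n_cond + 1L))
  }
  gene_ids <- vapply(fields[-1L], `[[`, character(1L), 1L)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[anyDuplicated(gene_ids)][1L])
  }
  values <- matrix(NA_real_, nrow = length(gene_ids), ncol = n_cond,
                   dimnames = list(gene_ids, cond_ids))
  for (i in seq_along(gene_ids)) {
    v <- suppressWarnings(as.numeric(fields[[i + 1L]][-1L]))
    if (anyNA(v)) stop(sprintf("non-numeric expression value on line %d", i + 1L))
    values[i, ] <- v
  }
  if (!all(is.finite(values))) stop("expression values must be finite")
  values
}

#' Write an expression matrix to tab-delimited text
#'
#' Inverse of [read_expression_matrix()]; the round trip preserves gene and
#' condition identifiers exactly and values to the stated precision.
#'
#' @param mat Numeric matrix with gene rownames and condition colnames.
#' @param path Output file path.
#' @param digits Significant digits used when formatting values.
#' @export
write_expression_matrix <- function(mat, path, digits = 10L) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  header <- paste(c("gene_id", colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], formatC(mat[i, ], digits = digits, format = "g")),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read condition metadata
#'
#' @param path Two-column tab-delimited file `condition_id<TAB>experiment_type`
#'   with a header line.
#' @param condition_ids Optional character vector of condition identifiers that
#'   must each be covered exactly once (typically the colnames of the
#'   expression matrix).
#' @return A data.frame with columns `condition_id` and `experiment_type`.
#' @export
read_condition_metadata <- function(path, condition_ids = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (!all(c("condition_id", "experiment_type") %in% names(df))) {
    stop("condition metadata needs columns condition_id and experiment_type")
  }
  df <- df[, c("condition_id", "experiment_type")]
  if (anyDuplicated(df$condition_id)) {
    stop("duplicate condition_id in metadata: ",
         df$condition_id[anyDuplicated(df$condition_id)][1L])
  }
  validate_condition_metadata(df, condition_ids)
  df
}

validate_condition_metadata <- function(metadata, condition_ids = NULL) {
  stopifnot(is.data.frame(metadata),
            all(c("condition_id", "experiment_type") %in% names(metadata)))
  if (!is.null(condition_ids)) {
    missing <- setdiff(condition_ids, metadata$condition_id)
    if (length(missing)) {
      stop("conditions without metadata: ", paste(missing, collapse = ", "))
    }
  }
  if (length(unique(metadata$experiment_type)) < 1L) stop("need at least one experiment type")
  invisible(metadata)
}

#' Write condition metadata
#' @param metadata data.frame with `condition_id`, `experiment_type`.
#' @param path Output path.
#' @export
write_condition_metadata <- function(metadata, path) {
  utils::write.table(metadata[, c("condition_id", "experiment_type")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify binding sites by posterior probability
#'
#' Assigns each annotated site to the primary class (posterior >=
#' `primary_threshold`), the secondary class (`secondary_floor` < posterior <
#' `primary_threshold`) or discard (posterior <= `secondary_floor`). Discarded
#' sites are retained in the table so that counts stay auditable.
#'
#' @param sites data.frame with columns `tf_id`, `gene_id`, `site_sequence`,
#'   `posterior`.
#' @param primary_threshold Posterior at or above which a site is primary
#'   (default 0.7).
#' @param secondary_floor Posterior at or below which a site is discarded
#'   (default 0.2; the secondary class is the open interval between the two).
#' @return The input data.frame with a `site_class` factor column added.
#' @export
classify_binding_sites <- function(sites, primary_threshold = 0.7,
                                   secondary_floor = 0.2) {
  required <- c("tf_id", "gene_id", "site_sequence", "posterior")
  if (!all(required %in% names(sites))) {
    stop("binding sites need columns: ", paste(required, collapse = ", "))
  }
  post <- sites$posterior
  if (!is.numeric(post) || any(!is.finite(post)) || any(post < 0 | post > 1)) {
    stop("posterior probabilities must lie in [0, 1]")
  }
  if (any(grepl("[^ACGT]", sites$site_sequence))) {
    stop("site sequences must contain only A, C, G, T")
  }
  len_by_tf <- tapply(nchar(sites$site_sequence), sites$tf_id,
                      function(x) length(unique(x)))
  if (any(len_by_tf > 1L)) {
    stop("all sites of one TF must share the motif length; offending TF: ",
         names(len_by_tf)[which(len_by_tf > 1L)[1L]])
  }
  cls <- ifelse(post >= primary_threshold, "primary",
                ifelse(post > secondary_floor, "secondary", "discard"))
  sites$site_class <- factor(cls, levels = c("primary", "secondary", "discard"))
  sites
}

#' Read binding site annotations
#'
#' Reads a SwissRegulon-style annotation table of predicted binding sites and
#' classifies each site as primary, secondary or discard by its posterior
#' probability (see [classify_binding_sites()]).
#'
#' @inheritParams classify_binding_sites
#' @param path Tab-delimited file with header columns `tf_id`, `gene_id`,
#'   `site_sequence`, `posterior`.
#' @return data.frame of sites with a `site_class` column.
#' @export
read_binding_sites <- function(path, primary_threshold = 0.7,
                               secondary_floor = 0.2) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = c(tf_id = "character",
                                         gene_id = "character",
                                         site_sequence = "character",
                                         posterior = "numeric"))
  classify_binding_sites(df, primary_threshold, secondary_floor)
}

#' Write binding site annotations
#' @param sites Classified site data.frame.
#' @param path Output path.
#' @export
write_binding_sites <- function(sites, path) {
  utils::write.table(sites[, c("tf_id", "gene_id", "site_sequence", "posterior")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-GO-process map
#'
#' @param path Two-column tab-delimited file `gene_id<TAB>go_process_id`, one
#'   pair per line, with a header. Genes absent from the map are treated as
#'   unannotated, never as errors.
#' @return Named list mapping gene id to a character vector of process ids.
#' @export
read_go_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (!all(c("gene_id", "go_process_id") %in% names(df))) {
    stop("GO map needs columns gene_id and go_process_id")
  }
  split(df$go_process_id, df$gene_id)
}

#' Write a gene-to-GO-process map
#' @param go_map Named list gene id -> character vector of process ids.
#' @param path Output path.
#' @export
write_go_map <- function(go_map, path) {
  df <- data.frame(gene_id = rep(names(go_map), lengths(go_map)),
                   go_process_id = unlist(go_map, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select target genes with a single primary binding site
#'
#' Returns genes used as a proxy for simple regulatory control: genes whose
#' total number of primary binding sites equals exactly one, where that one
#' site belongs to `tf_id`. By default "single primary" is counted genome-wide
#' across all annotated TFs; `scope = "same_tf"` restricts the count to sites
#' of the focal TF.
#'
#' @param sites Classified binding site data.frame.
#' @param tf_id Focal transcription factor identifier.
#' @param scope `"all_tfs"` (default) or `"same_tf"`.
#' @return Character vector of gene ids (possibly empty, with a warning when
#'   `tf_id` has no primary sites at all).
#' @export
select_single_primary_targets <- function(sites, tf_id,
                                          scope = c("all_tfs", "same_tf")) {
  scope <- match.arg(scope)
  stopifnot("site_class" %in% names(sites))
  prim <- sites[sites$site_class == "primary", , drop = FALSE]
  focal <- prim[prim$tf_id == tf_id, , drop = FALSE]
  if (nrow(focal) == 0L) {
    warning("no primary binding sites annotated for TF '", tf_id, "'")
    return(character(0L))
  }
  counted <- if (scope == "all_tfs") prim else focal
  n_primary <- table(counted$gene_id)
  singles <- names(n_primary)[n_primary == 1L]
  sort(unique(focal$gene_id[focal$gene_id %in% singles]))
}

#' Group a TF's target genes by the nucleotide at one motif position
#'
#' For one transcription factor and one 1-based motif position, partitions the
#' eligible target genes into nucleotide groups according to the base their
#' binding site carries at that position. The grouping is flagged testable
#' when at least two nucleotide groups contain at least two genes each; groups
#' below the two-gene minimum are retained for reporting but excluded from
#' testing.
#'
#' @param sites Classified binding site data.frame.
#' @param tf_id Focal TF identifier.
#' @param motif_position 1-based position within the TF's motif.
#' @param gene_filter `"single_primary"` (default; genes with exactly one
#'   primary site genome-wide, see [select_single_primary_targets()]) or
#'   `"any_primary"` (any gene with a primary site for the TF).
#' @param expression_genes Optional character vector of genes present in the
#'   expression matrix; annotated genes missing from it are dropped with a
#'   warning.
#' @param scope Passed to [select_single_primary_targets()].
#' @return An object of class `variant_grouping`: list with elements `tf_id`,
#'   `motif_position`, `groups` (named list nucleotide -> gene ids),
#'   `group_sizes`, `testable`, `eligible_genes`, `gene_filter`.
#' @export
build_variant_groupings <- function(sites, tf_id, motif_position,
                                    gene_filter = c("single_primary", "any_primary"),
                                    expression_genes = NULL,
                                    scope = c("all_tfs", "same_tf")) {
  gene_filter <- match.arg(gene_filter)
  scope <- match.arg(scope)
  stopifnot("site_class" %in% names(sites))
  focal <- sites[sites$tf_id == tf_id & sites$site_class == "primary", , drop = FALSE]
  if (nrow(focal) == 0L) stop("no primary sites for TF '", tf_id, "'")
  motif_len <- nchar(focal$site_sequence[1L])
  if (motif_position < 1L || motif_position > motif_len) {
    stop(sprintf("motif_position %d out of range 1..%d for TF '%s'",
                 motif_position, motif_len, tf_id))
  }
  genes <- if (gene_filter == "single_primary") {
    select_single_primary_targets(sites, tf_id, scope)
  } else {
    sort(unique(focal$gene_id))
  }
  if (!is.null(expression_genes)) {
    absent <- setdiff(genes, expression_genes)
    if (length(absent)) {
      warning(length(absent), " annotated target gene(s) absent from the ",
              "expression matrix were dropped for TF '", tf_id, "'")
      genes <- setdiff(genes, absent)
    }
  }
  focal <- focal[focal$gene_id %in% genes, , drop = FALSE]
  nuc <- substr(focal$site_sequence, motif_position, motif_position)
  # a gene with several primary sites for the TF (any_primary mode) must carry
  # a consistent base at the focal position to be assignable
  nuc_by_gene <- tapply(nuc, focal$gene_id, function(x) unique(x))
  conflicted <- names(nuc_by_gene)[lengths(nuc_by_gene) > 1L]
  if (length(conflicted)) {
    warning(length(conflicted), " gene(s) with conflicting bases at position ",
            motif_position, " dropped for TF '", tf_id, "'")
    nuc_by_gene <- nuc_by_gene[lengths(nuc_by_gene) == 1L]
  }
  assignment <- vapply(nuc_by_gene, `[[`, character(1L), 1L)
  groups <- split(names(assignment), assignment)
  groups <- lapply(groups, sort)
  sizes <- vapply(groups, length, integer(1L))
  structure(list(tf_id = tf_id,
                 motif_position = as.integer(motif_position),
                 groups = groups,
                 group_sizes = sizes,
                 testable = sum(sizes >= 2L) >= 2L,
                 eligible_genes = sort(unlist(groups, use.names = FALSE)),
                 gene_filter = gene_filter),
            class = "variant_grouping")
}

#' @export
print.variant_grouping <- function(x, ...) {
  cat("Variant grouping: TF", x$tf_id, "position", x$motif_position, "\n")
  cat("  groups:", paste(sprintf("%s:%d", names(x$group_sizes), x$group_sizes),
                         collapse = ", "), "\n")
  cat("  gene filter:", x$gene_filter,
      "| testable:", x$testable, "\n")
  invisible(x)
}

qualifying_groups <- function(grouping, min_size = 2L) {
  grouping$groups[vapply(grouping$groups, length, integer(1L)) >= min_size]
}

format_group_sizes <- function(grouping) {
  paste(sprintf("%s:%d", names(grouping$group_sizes), grouping$group_sizes),
        collapse = ",")
}
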