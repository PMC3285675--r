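#' Genomic background nucleotide frequencies
#'
#' Constructs a validated background frequency vector over A, C, G, T.
#' Frequencies are renormalized to sum exactly to one (published background
#' compositions are often rounded and sum slightly off one; the yeast
#' intergenic default printed to three decimals sums to 0.999, and only the
#' renormalized entropy reproduces the published 1.96-bit maximum).
#'
#' @param f_A,f_C,f_G,f_T Background frequencies; the defaults are the yeast
#'   genomic composition used for motif information content.
#' @return Named numeric vector of class `background_frequencies`, summing to 1.
#' @export
background_frequencies <- function(f_A = 0.307, f_C = 0.188, f_G = 0.188,
                                   f_T = 0.316) {
  f <- c(A = f_A, C = f_C, G = f_G, T = f_T)
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1)) {
    stop("background frequencies must lie in (0, 1)")
  }
  s <- sum(f)
  if (abs(s - 1) > 0.05) stop("background frequencies must sum to ~1; got ", s)
  structure(f / s, class = "background_frequencies")
}

#' Shannon entropy of a probability vector, in bits
#'
#' @param p Numeric probability vector (must sum to 1 within 1e-6); zero
#'   entries contribute zero (`0 log 0 = 0`).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(p) {
  if (any(!is.finite(p)) || any(p < 0)) stop("probabilities must be finite and >= 0")
  if (abs(sum(p) - 1) > 1e-6) stop("probabilities must sum to 1; got ", sum(p))
  p <- p / sum(p)
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Information content of a motif position
#'
#' Schneider-style information with a non-uniform background:
#' `R = H(background) - H(position)`, both Shannon entropies in bits. The
#' maximum, attained by a fully conserved position, equals the background
#' entropy (1.96 bits under the default yeast composition) regardless of
#' which base is conserved. Negative values (position more entropic than the
#' background) are reported, not clamped.
#'
#' @param pos Numeric frequency vector over A, C, G, T for the position.
#' @param bg [background_frequencies()] object (default: yeast composition).
#' @return Information content in bits.
#' @export
information_content <- function(pos, bg = background_frequencies()) {
  if (length(pos) != 4L) stop("position frequencies must have 4 entries (A, C, G, T)")
  shannon_entropy(unclass(bg)) - shannon_entropy(pos)
}

#' Classify a motif position by information content
#'
#' Positions with at most `threshold_bits` of information (default 1 bit) are
#' "highly_variable"; positions above it are "variable".
#'
#' @inheritParams information_content
#' @param threshold_bits Cut in bits (default 1).
#' @return `"highly_variable"` or `"variable"`.
#' @export
classify_position_variability <- function(pos, bg = background_frequencies(),
                                          threshold_bits = 1) {
  r <- information_content(pos, bg)
  if (r <= threshold_bits) "highly_variable" else "variable"
}

#' Read a position frequency matrix
#'
#' @param path Tab-delimited file with header `position  A  C  G  T`, one row
#'   per motif position; frequencies per row must sum to 1 within 1e-6.
#' @return Numeric matrix (positions x 4) with columns A, C, G, T.
#' @export
read_pwm <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "")
  need <- c("position", "A", "C", "G", "T")
  if (!all(need %in% names(df))) stop("PWM needs columns: ", paste(need, collapse = ", "))
  m <- as.matrix(df[, c("A", "C", "G", "T")])
  rownames(m) <- df$position
  bad <- abs(rowSums(m) - 1) > 1e-6
  if (any(bad)) stop("PWM rows must sum to 1; offending position: ",
                     rownames(m)[which(bad)[1L]])
  m
}

#' Per-position information content of a PWM
#'
#' @param pwm Positions x 4 frequency matrix (columns A, C, G, T).
#' @inheritParams information_content
#' @return data.frame with `position`, `information_bits`, `variability`.
#' @export
pwm_information <- function(pwm, bg = background_frequencies()) {
  bits <- apply(pwm, 1L, information_content, bg = bg)
  data.frame(position = seq_len(nrow(pwm)),
             information_bits = as.numeric(bits),
             variability = ifelse(bits <= 1, "highly_variable", "variable"),
             stringsAsFactors = FALSE)
}

#' Wilson score interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param conf Confidence level (default 0.95, i.e. z = 1.959964).
#' @return List with `estimate`, `lower`, `upper`, `conf`.
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(estimate = p, lower = max(0, center - half),
       upper = min(1, center + half), conf = conf)
}

check_alignment_columns <- function(cols) {
  if (length(cols) == 0L) stop("no alignment columns supplied")
  if (any(nchar(cols) < 2L)) stop("every column needs >= 2 species")
  if (any(grepl("[^ACGT]", cols))) stop("columns must contain only A, C, G, T")
  invisible(cols)
}

#' Proportion of invariant alignment columns with a Wilson interval
#'
#' A column (one site position across aligned species, gaps already excluded)
#' is invariant when all species share one nucleotide.
#'
#' @param cols Character vector of alignment columns, one string per column
#'   (e.g. `"AATA"` = four species).
#' @param conf Confidence level for the Wilson interval (default 0.95).
#' @return List with `proportion`, `n_columns`, `n_invariant`, `ci`
#'   (a [wilson_interval()]).
#' @export
invariant_proportion <- function(cols, conf = 0.95) {
  check_alignment_columns(cols)
  inv <- vapply(strsplit(cols, ""), function(x) length(unique(x)) == 1L,
                logical(1L))
  k <- sum(inv)
  n <- length(cols)
  list(proportion = k / n, n_columns = n, n_invariant = k,
       ci = wilson_interval(k, n, conf))
}

#' Mean number of distinct nucleotides per alignment column
#'
#' @inheritParams invariant_proportion
#' @return Mean count of distinct bases per column, in `[1, 4]`.
#' @export
mean_alleles_per_position <- function(cols) {
  check_alignment_columns(cols)
  mean(vapply(strsplit(cols, ""), function(x) length(unique(x)), integer(1L)))
}

#' Read alignment columns grouped by site class
#'
#' @param path Tab-delimited file with header `site_class<TAB>bases`, one
#'   column per line (`bases` = the per-species nucleotides as one string).
#' @return data.frame with `site_class` and `bases`.
#' @export
read_alignment_columns <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (!all(c("site_class", "bases") %in% names(df))) {
    stop("alignment columns need columns site_class and bases")
  }
  df
}

#' Diversity summary per site class
#'
#' Per-class invariant proportion (with Wilson 95% interval) and mean
#' distinct nucleotides per position, the shape used to compare binding-site
#' positions against codon positions, introns and intergenic sites.
#'
#' @param columns data.frame from [read_alignment_columns()] (or with the same
#'   columns).
#' @param conf Confidence level (default 0.95).
#' @return data.frame with one row per site class: `site_class`, `n_columns`,
#'   `invariant_pct`, `ci_lower_pct`, `ci_upper_pct`, `mean_nucleotides`.
#' @export
alignment_diversity_summary <- function(columns, conf = 0.95) {
  stopifnot(all(c("site_class", "bases") %in% names(columns)))
  classes <- unique(columns$site_class)
  rows <- lapply(classes, function(cl) {
    cols <- columns$bases[columns$site_class == cl]
    ip <- invariant_proportion(cols, conf)
    data.frame(site_class = cl, n_columns = ip$n_columns,
               invariant_pct = 100 * ip$proportion,
               ci_lower_pct = 100 * ip$ci$lower,
               ci_upper_pct = 100 * ip$ci$upper,
               mean_nucleotides = mean_alleles_per_position(cols),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
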