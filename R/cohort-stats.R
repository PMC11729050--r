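#' Two-sided Student-t confidence interval from summary statistics
#'
#' `mean +/- t(1-(1-level)/2, n-1) * sd/sqrt(n)`, the interval convention
#' used for per-lineage altered-arm summaries.
#'
#' @param mean Sample mean.
#' @param sd Sample standard deviation (>= 0).
#' @param n Sample size (>= 2).
#' @param level Confidence level, default 0.95.
#' @return A `summary_interval` list with raw `lower`/`upper` and the
#'   2-decimal reporting values `lower_2dp`/`upper_2dp`.
#' @examples
#' t_confidence_interval(14.1, 13.04, 10)  # (4.77, 23.43)
#' @export
t_confidence_interval <- function(mean, sd, n, level = 0.95) {
  if (n < 2) stop("n must be >= 2")
  if (sd < 0) stop("sd must be >= 0")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * sd / sqrt(n)
  structure(list(mean = mean, sd = sd, n = as.integer(n), level = level,
                 lower = mean - half, upper = mean + half,
                 lower_2dp = round(mean - half, 2),
                 upper_2dp = round(mean + half, 2)),
            class = "summary_interval")
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson statistic with df = (r-1)(c-1) and upper-tail
#' asymptotic p. Expected counts below 5 trigger a warning (not an error);
#' an all-zero row or column is an error.
#'
#' @param counts Non-negative integer matrix of counts.
#' @param row_labels,col_labels Optional dimension labels.
#' @return List with `statistic`, `df`, `p_value` and the `expected` matrix.
#' @export
chi_square_independence <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("counts must be non-negative with a positive total")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("chi-square undefined: table has an all-zero row or column")
  }
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5)) {
    warning("expected count(s) below 5; asymptotic p may be inaccurate")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value), expected = expected)
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Two-tailed test on the U statistic computed with midranks. When both
#' samples have at most 8 observations, the p-value is computed by exact
#' enumeration of all group assignments of the pooled values (a permutation
#' test, valid under ties); otherwise the normal approximation with tie
#' correction is used, without continuity correction.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return List with `U` (for `x`), `p_value` and `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(1, 2, 3))  # U = 4.5, p = 1
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); pooled <- c(x, y)
  r <- rank(pooled)
  u_from_r1 <- function(r1_sum) r1_sum - n1 * (n1 + 1) / 2
  U <- u_from_r1(sum(r[seq_len(n1)]))
  mu <- n1 * n2 / 2
  if (n1 <= 8 && n2 <= 8) {
    combs <- utils::combn(n1 + n2, n1)
    r_mat <- matrix(r[combs], nrow = n1)
    Us <- u_from_r1(colSums(r_mat))
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    N <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation with tie correction"
  }
  list(U = U, p_value = p, method = method)
}

#' Cohort summary: patterns by lineage, altered-arm intervals, percentages
#'
#' Cross-tabulates pattern against lineage, summarizes altered-arm counts
#' per lineage (mean, SD, two-sided t interval when n >= 2) and reports the
#' percentage of altered samples (Patterns 2-4) overall and per lineage,
#' at one decimal.
#'
#' @param results A data frame from [results_table()] (or a list of
#'   `sample_result` objects) with `sample_id`, `pattern`, `altered_arms`.
#' @param annotations A cohort annotation data frame (see
#'   [load_cohort_annotations()]) with one row per result.
#' @param level Confidence level for the intervals.
#' @return List with `pattern_by_lineage` (4 x lineage count matrix),
#'   `lineage_summary` (per-lineage n/mean/sd/lower/upper/percent_altered),
#'   `percent_altered` (overall, 1 decimal) and `n_samples`.
#' @export
pattern_lineage_summary <- function(results, annotations, level = 0.95) {
  if (!is.data.frame(results)) results <- results_table(results)
  unmatched <- setdiff(results$sample_id, annotations$sample_id)
  if (length(unmatched) > 0) {
    stop("no annotation for sample(s): ", paste(unmatched, collapse = ", "))
  }
  merged <- merge(results, annotations, by = "sample_id")
  merged$pattern <- factor(merged$pattern, levels = 1:4)
  lineages <- unique(annotations$lineage[annotations$sample_id %in% results$sample_id])
  merged$lineage <- factor(merged$lineage, levels = lineages)
  tab <- table(pattern = merged$pattern, lineage = merged$lineage)

  summaries <- lapply(split(merged, merged$lineage), function(d) {
    n <- nrow(d)
    m <- mean(d$altered_arms); s <- stats::sd(d$altered_arms)
    ci <- if (n >= 2) t_confidence_interval(m, s, n, level) else NULL
    data.frame(lineage = as.character(d$lineage[1]), n = n, mean = m,
               sd = if (n >= 2) s else NA_real_,
               lower = if (n >= 2) ci$lower else NA_real_,
               upper = if (n >= 2) ci$upper else NA_real_,
               percent_altered = round(100 * mean(d$pattern != "1"), 1),
               stringsAsFactors = FALSE)
  })
  lineage_summary <- do.call(rbind, summaries)
  rownames(lineage_summary) <- NULL

  list(pattern_by_lineage = unclass(tab),
       lineage_summary = lineage_summary,
       percent_altered = round(100 * mean(merged$pattern != "1"), 1),
       n_samples = nrow(merged))
}
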