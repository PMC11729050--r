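#' Count altered chromosome arms
#'
#' Counts arms whose mechanism is not `none`, excluding no-calls (41 arms
#' maximum). Male hemizygous X arms count only when their coverage tier
#' changed, which is the only way they acquire a non-`none` mechanism.
#'
#' @param calls An `arm_calls` data frame.
#' @param count_balanced_gain Should AABB (`balanced_gain`) arms count as
#'   alterations? Default `TRUE`.
#' @return Integer count in \[0, 41\].
#' @export
count_altered_arms <- function(calls, count_balanced_gain = TRUE) {
  if (anyDuplicated(calls$arm_id)) {
    stop("duplicate arm(s) in calls: ",
         paste(unique(calls$arm_id[duplicated(calls$arm_id)]), collapse = ", "))
  }
  altered <- !calls$no_call & calls$mechanism != "none"
  if (!count_balanced_gain) altered <- altered & calls$mechanism != "balanced_gain"
  sum(altered)
}

#' Classify a sample into one of the four chromosomal-alteration patterns
#'
#' Pattern 1: no alterations. Pattern 2: only losses or copy-neutral LOH.
#' Pattern 3: only gains (AABB counts on the gain side). Pattern 4: mixed
#' gains and losses. Also attaches the altered-arm count, the massive-loss
#' flags from [detect_massive_loss()], the genome-doubling inference from
#' [infer_genome_doubling()], a purity estimate (median of per-LOH-arm
#' estimates; absent without LOH arms) and an equal-weight ploidy estimate.
#'
#' @param calls An `arm_calls` data frame for one sample.
#' @param sample_id Sample identifier carried into the result (defaults to
#'   the calls' attribute, if set).
#' @param count_balanced_gain Passed to [count_altered_arms()].
#' @return A `sample_result` list with fields `sample_id`, `pattern`,
#'   `altered_arms`, `n_loss_tier`, `n_gain_tier`, `near_haploid`,
#'   `near_homozygous`, `loh_chromosome_fraction`, `doubling_inferred`,
#'   `purity_estimate`, `ploidy_estimate`, `ploidy_1dp`.
#' @export
classify_pattern <- function(calls, sample_id = NULL,
                             count_balanced_gain = TRUE) {
  if (is.null(sample_id)) sample_id <- attr(calls, "sample_id") %||% NA_character_
  usable <- !calls$no_call
  if (!any(usable)) stop("sample uninterpretable: all arms are no-calls")

  n_loss <- sum(usable & calls$mechanism %in% c("loss", "cn_loh"))
  n_gain <- sum(usable & calls$mechanism %in% c("gain", "balanced_gain"))
  altered <- count_altered_arms(calls, count_balanced_gain)

  pattern <- if (n_loss == 0 && n_gain == 0) 1L
    else if (n_loss > 0 && n_gain == 0) 2L
    else if (n_gain > 0 && n_loss == 0) 3L
    else 4L
  gains <- calls$mechanism[usable & calls$mechanism %in% c("gain", "balanced_gain")]
  if (pattern == 3L && length(gains) > 0 && all(gains == "balanced_gain")) {
    warning("only AABB (balanced gain) arms altered; pattern 3 assigned by convention")
  }

  massive <- detect_massive_loss(calls)
  doubling <- infer_genome_doubling(calls)

  # purity from LOH arms whose mirrored BAF is still measurable
  loh <- usable & !calls$hemizygous & !is.na(calls$median_mirrored_baf) &
    calls$median_mirrored_baf > 0.5 &
    ((calls$major == 1L & calls$minor == 0L) | (calls$major == 2L & calls$minor == 0L))
  purity <- if (any(loh)) {
    ests <- mapply(function(m, mech) {
      tryCatch(estimate_purity(m, mech), error = function(e) NA_real_)
    }, calls$median_mirrored_baf[loh],
       ifelse(calls$major[loh] == 1L, "loss", "cn_loh"))
    stats::median(ests, na.rm = TRUE)
  } else NA_real_

  ploidy <- ploidy_from_calls(calls)

  structure(list(
    sample_id = sample_id,
    pattern = pattern,
    altered_arms = altered,
    n_loss_tier = n_loss,
    n_gain_tier = n_gain,
    near_haploid = massive$near_haploid,
    near_homozygous = massive$near_homozygous,
    loh_chromosome_fraction = massive$loh_chromosome_fraction,
    doubling_inferred = doubling,
    purity_estimate = purity,
    ploidy_estimate = ploidy,
    ploidy_1dp = if (is.na(ploidy)) NA_real_ else round(ploidy, 1)
  ), class = "sample_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean total copy number over chromosomes, each chromosome the mean of its
# called arms; chromosomes with no usable call are dropped
ploidy_from_calls <- function(calls) {
  usable <- calls[!calls$no_call, ]
  if (nrow(usable) == 0) return(NA_real_)
  totals <- tapply(usable$major + usable$minor, usable$chrom, mean)
  mean(totals)
}

#' Detect massive chromosomal loss (near-haploid / near-homozygous genome)
#'
#' A chromosome is LOH'd when at least one of its scoreable arms carries an
#' LOH-tier state ((1,0) or (2,0)). The massive-loss flag is raised when 15
#' or more of the 22 autosomes are LOH'd; the genome is called near-haploid
#' when the LOH'd chromosomes are predominantly (>= 60%) single-copy (1,0),
#' and near-homozygous when predominantly copy-neutral (2,0), the doubled
#' descendant state.
#'
#' @param calls An `arm_calls` data frame.
#' @return List with `near_haploid`, `near_homozygous` and
#'   `loh_chromosome_fraction` (LOH'd autosomes / 22).
#' @export
detect_massive_loss <- function(calls) {
  auto <- calls[!calls$no_call & calls$chrom != "X", ]
  loh <- auto[(auto$major == 1L & auto$minor == 0L) |
              (auto$major == 2L & auto$minor == 0L), ]
  chroms <- unique(loh$chrom)
  frac <- length(chroms) / 22
  flag <- length(chroms) >= 15
  if (length(chroms) == 0) {
    return(list(near_haploid = FALSE, near_homozygous = FALSE,
                loh_chromosome_fraction = 0))
  }
  cn_type <- vapply(chroms, function(ch) {
    arms <- loh[loh$chrom == ch, ]
    mean(arms$major == 2L) >= 0.5
  }, logical(1))
  list(near_haploid = flag && mean(!cn_type) >= 0.6,
       near_homozygous = flag && mean(cn_type) >= 0.6,
       loh_chromosome_fraction = frac)
}

#' Infer endoreduplication / whole-genome doubling
#'
#' Doubling is inferred when either (a) ten or more arms are LOH-tier and
#' every remaining heterozygous arm carries the doubled-heterozygous state
#' AABB, or (b) at least 60% of the LOH'd chromosomes are copy-neutral
#' (coverage-neutral LOH is the post-doubling signature of a lost
#' chromosome).
#'
#' @param calls An `arm_calls` data frame.
#' @return Logical.
#' @export
infer_genome_doubling <- function(calls) {
  usable <- calls[!calls$no_call & !calls$hemizygous, ]
  loh <- usable[(usable$major == 1L & usable$minor == 0L) |
                (usable$major == 2L & usable$minor == 0L), ]
  het <- usable[usable$mechanism %in% c("none", "balanced_gain"), ]
  clause_a <- nrow(loh) >= 10 && nrow(het) >= 1 &&
    all(het$major == 2L & het$minor == 2L)
  loh_chroms <- unique(loh$chrom)
  clause_b <- if (length(loh_chroms) > 0) {
    cn_type <- vapply(loh_chroms, function(ch) {
      arms <- loh[loh$chrom == ch, ]
      mean(arms$major == 2L) >= 0.5
    }, logical(1))
    mean(cn_type) >= 0.6
  } else FALSE
  clause_a || clause_b
}

#' One-row data frame view of sample results
#'
#' @param results A list of `sample_result` objects (or a single one).
#' @return A data frame with one row per sample.
#' @export
results_table <- function(results) {
  if (inherits(results, "sample_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(sample_id = r$sample_id, pattern = r$pattern,
               altered_arms = r$altered_arms,
               n_loss_tier = r$n_loss_tier, n_gain_tier = r$n_gain_tier,
               near_haploid = r$near_haploid,
               near_homozygous = r$near_homozygous,
               doubling_inferred = r$doubling_inferred,
               purity_estimate = r$purity_estimate,
               ploidy_estimate = r$ploidy_estimate,
               stringsAsFactors = FALSE)
  }))
}
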