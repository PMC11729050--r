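#' Calling thresholds
#'
#' The decision thresholds of the arm caller. The LOH mirrored-BAF cut of
#' 0.75 mirrors the conventional 0.25/0.75 markings used when LOH is scored
#' on allele-frequency plots; the imbalance cut of 0.58 scores a single-copy
#' gain as an imbalance at purities of 0.4 and above; the coverage cuts
#' +0.13/-0.15 log2 detect single-copy events at purity >= 0.4 while
#' tolerating FFPE depth dispersion.
#'
#' @param imbalance_mbaf Mirrored-BAF cut between balanced and imbalance.
#' @param loh_mbaf Mirrored-BAF cut for full LOH.
#' @param gain_log2 Log2 coverage-ratio cut for gains.
#' @param loss_log2 Log2 coverage-ratio cut for losses (negative).
#' @param min_informative Minimum informative (heterozygous-band) loci for a
#'   confident allelic call.
#' @param het_deficit_fraction An arm whose observed het fraction falls below
#'   this multiple of the expected het fraction is scored LOH even when no
#'   loci remain in the heterozygous band (the high-purity LOH signature).
#' @return A `call_thresholds` list.
#' @export
call_thresholds <- function(imbalance_mbaf = 0.58, loh_mbaf = 0.75,
                            gain_log2 = 0.13, loss_log2 = -0.15,
                            min_informative = 8L,
                            het_deficit_fraction = 0.5) {
  if (!(0.5 < imbalance_mbaf && imbalance_mbaf < loh_mbaf && loh_mbaf <= 1)) {
    stop("need 0.5 < imbalance_mbaf < loh_mbaf <= 1")
  }
  if (!(loss_log2 < 0 && gain_log2 > 0)) stop("need loss_log2 < 0 < gain_log2")
  structure(list(imbalance_mbaf = imbalance_mbaf, loh_mbaf = loh_mbaf,
                 gain_log2 = gain_log2, loss_log2 = loss_log2,
                 min_informative = as.integer(min_informative),
                 het_deficit_fraction = het_deficit_fraction),
            class = "call_thresholds")
}

# minimum depth for a locus to enter the informative-band computation, and
# the open heterozygous-compatible BAF band
MIN_LOCUS_DEPTH <- 20L
HET_BAND <- c(0.05, 0.95)

#' Per-arm summary statistics
#'
#' Reduces the loci of one arm to the caller's summary statistics:
#' informative loci are those with depth >= 20 and BAF strictly inside
#' (0.05, 0.95) (the heterozygous-compatible band); the mirrored BAF
#' (`max(BAF, 1-BAF)`) median is computed over informative loci; hets that
#' migrated to BAF <= 0.05 / >= 0.95 under LOH are captured through the het
#' fraction, not the mirrored BAF. Coverage is the arm's median depth over
#' the sample's balanced-arm median depth, log2.
#'
#' @param observations Observations (`locus_id`, `depth`, `b_count`)
#'   restricted to one arm.
#' @param panel Panel rows for the same loci (supplies `pop_baf`).
#' @param balanced_depth Median depth of the sample's balanced arms.
#' @return A one-row `arm_stats` data frame.
#' @export
summarize_arm <- function(observations, panel, balanced_depth) {
  obs <- merge(observations, as.data.frame(panel), by = "locus_id", sort = FALSE)
  if (length(unique(obs$arm_id)) > 1) stop("observations span more than one arm")
  stats <- arm_stats_table(obs, balanced_depth)
  stats
}

# vectorized arm summaries for a merged locus table (panel columns + depth,
# b_count); one output row per arm present
arm_stats_table <- function(loci, balanced_depth) {
  loci$baf <- ifelse(loci$depth > 0, loci$b_count / loci$depth, NA_real_)
  loci$informative <- loci$depth >= MIN_LOCUS_DEPTH &
    !is.na(loci$baf) & loci$baf > HET_BAND[1] & loci$baf < HET_BAND[2]
  split_loci <- split(loci, loci$arm_id)
  rows <- lapply(split_loci, function(d) {
    nonzero <- d$depth > 0
    n_nonzero <- sum(nonzero)
    inf <- d$informative
    mbaf <- if (any(inf)) stats::median(pmax(d$baf[inf], 1 - d$baf[inf])) else NA_real_
    l2r <- if (n_nonzero > 0) {
      log2(stats::median(d$depth[nonzero]) / balanced_depth)
    } else NA_real_
    data.frame(
      chrom = d$chrom[1], arm = d$arm[1], arm_id = d$arm_id[1],
      n_loci = nrow(d),
      n_nonzero = n_nonzero,
      n_covered = sum(d$depth >= MIN_LOCUS_DEPTH),
      n_informative = sum(inf),
      het_fraction = if (n_nonzero > 0) sum(inf) / n_nonzero else NA_real_,
      expected_het = mean(2 * d$pop_baf * (1 - d$pop_baf)),
      median_mirrored_baf = mbaf,
      median_log2_ratio = l2r,
      stringsAsFactors = FALSE
    )
  })
  stats <- do.call(rbind, rows)
  stats <- stats[order(chrom_rank(stats$chrom), stats$arm), ]
  rownames(stats) <- NULL
  class(stats) <- c("arm_stats", "data.frame")
  stats
}

#' Classify one arm into a genotype state and mechanism
#'
#' Two-tier decision ladder. Allelic tier: *balanced* if the median mirrored
#' BAF is below the imbalance cut and the het fraction is intact; *LOH* if
#' the mirrored BAF reaches the LOH cut or the het band has emptied (het
#' deficit); *imbalance* otherwise. Coverage tier: loss / neutral / gain by
#' the log2 depth-ratio cuts. The joint state follows the tier pair (e.g.
#' LOH+loss is a hemizygous loss (1,0); LOH+neutral is copy-neutral LOH
#' (2,0); imbalance+gain a single-copy gain (2,1); balanced+gain AABB).
#' Incoherent tier pairs fall back to the nearest state in predicted
#' (BAF, log2) space and are flagged low-confidence. On the male X
#' (hemizygous baseline, no germline hets) only coverage changes are called.
#'
#' @param stats A one-row `arm_stats` data frame from [summarize_arm()].
#' @param thresholds A [call_thresholds()].
#' @param sex `"male"` or `"female"`.
#' @return A one-row `arm_calls` data frame.
#' @export
classify_arm <- function(stats, thresholds = call_thresholds(),
                         sex = c("female", "male")) {
  sex <- match.arg(sex)
  calls <- classify_stats_table(stats, thresholds, sex)
  calls
}

# vectorized classification over an arm_stats table
classify_stats_table <- function(stats, th, sex) {
  n <- nrow(stats)
  allelic <- character(n); coverage <- character(n)
  major <- integer(n); minor <- integer(n)
  mechanism <- character(n); low_conf <- logical(n); no_call <- logical(n)
  hemi <- sex == "male" & stats$chrom == "X"

  for (i in seq_len(n)) {
    s <- stats[i, ]
    if (hemi[i]) {
      # hemizygous baseline: one germline X copy, coverage evidence only
      if (is.na(s$median_log2_ratio) || s$n_nonzero == 0) {
        no_call[i] <- TRUE; major[i] <- 1L; minor[i] <- 0L
        mechanism[i] <- "none"; allelic[i] <- "hemizygous"; coverage[i] <- "no_call"
        next
      }
      adj <- s$median_log2_ratio + 1  # against the 1-copy baseline
      allelic[i] <- "hemizygous"
      if (adj >= th$gain_log2) {
        major[i] <- 2L; minor[i] <- 0L; mechanism[i] <- "gain"; coverage[i] <- "gain"
      } else if (adj <= th$loss_log2) {
        major[i] <- 0L; minor[i] <- 0L; mechanism[i] <- "loss"
        coverage[i] <- "loss"; low_conf[i] <- TRUE
      } else {
        major[i] <- 1L; minor[i] <- 0L; mechanism[i] <- "none"; coverage[i] <- "neutral"
      }
      next
    }

    het_deficit <- !is.na(s$het_fraction) &&
      s$het_fraction < th$het_deficit_fraction * s$expected_het
    if (s$n_informative < th$min_informative && s$n_covered < th$min_informative) {
      no_call[i] <- TRUE; low_conf[i] <- TRUE
      major[i] <- 1L; minor[i] <- 1L; mechanism[i] <- "none"
      allelic[i] <- "no_call"; coverage[i] <- "no_call"
      next
    }
    mbaf <- s$median_mirrored_baf
    allelic[i] <- if (!is.na(mbaf) && mbaf >= th$loh_mbaf) "loh"
      else if (het_deficit) "loh"
      else if (!is.na(mbaf) && mbaf < th$imbalance_mbaf) "balanced"
      else if (is.na(mbaf)) "balanced"  # thin but het-intact arm
      else "imbalance"
    if (is.na(mbaf) && allelic[i] == "balanced") low_conf[i] <- TRUE

    l2r <- s$median_log2_ratio
    coverage[i] <- if (is.na(l2r)) "neutral"
      else if (l2r <= th$loss_log2) "loss"
      else if (l2r >= th$gain_log2) "gain" else "neutral"

    key <- paste(allelic[i], coverage[i])
    st <- switch(key,
      "loh loss" = c(1L, 0L),
      "loh neutral" = c(2L, 0L),
      "imbalance gain" = c(2L, 1L),
      "imbalance loss" = { low_conf[i] <- TRUE; c(1L, 0L) },
      "balanced gain" = c(2L, 2L),
      "balanced neutral" = c(1L, 1L),
      { low_conf[i] <- TRUE
        nearest_state(ifelse(is.na(mbaf), 1, mbaf), ifelse(is.na(l2r), 0, l2r)) })
    major[i] <- st[1]; minor[i] <- st[2]
    mechanism[i] <- state_mechanism(major[i], minor[i])
  }

  calls <- data.frame(
    chrom = stats$chrom, arm = stats$arm, arm_id = stats$arm_id,
    n_informative = stats$n_informative,
    n_covered = stats$n_covered,
    het_fraction = stats$het_fraction,
    median_mirrored_baf = stats$median_mirrored_baf,
    median_log2_ratio = stats$median_log2_ratio,
    major = major, minor = minor,
    genotype_label = genotype_label(major, minor),
    mechanism = mechanism,
    allelic_tier = allelic,
    hemizygous = hemi,
    low_confidence = low_conf,
    no_call = no_call,
    stringsAsFactors = FALSE
  )
  class(calls) <- c("arm_calls", "data.frame")
  calls
}

# nearest state in predicted (mirrored BAF, log2 ratio) space over a purity
# grid; resolves incoherent tier pairs
nearest_state <- function(mbaf, l2r) {
  grid <- seq(0.05, 1, by = 0.01)
  best <- c(1L, 1L); best_d <- Inf
  for (j in seq_len(nrow(STATE_UNIVERSE))) {
    eb <- expected_baf(STATE_UNIVERSE$major[j], STATE_UNIVERSE$minor[j], grid)
    el <- expected_log2_ratio(STATE_UNIVERSE$major[j], STATE_UNIVERSE$minor[j], grid)
    d <- min((mbaf - eb)^2 + (l2r - el)^2)
    if (d < best_d) {
      best_d <- d
      best <- c(STATE_UNIVERSE$major[j], STATE_UNIVERSE$minor[j])
    }
  }
  best
}

#' Call all arms of one sample
#'
#' Assembles per-arm genotype calls for a whole sample with two-pass
#' self-normalized coverage: the first pass uses the genome-wide median
#' depth as the diploid baseline; arms whose allelic tier is balanced (the
#' heterozygous chromosomes, read the way a reviewer anchors copy-number
#' "height" to them) then define the final baseline, and all arms are
#' re-summarized and re-classified against it. Tumor-only data leaves the
#' diploid baseline ambiguous in fully altered genomes; when no arm is
#' allelically balanced the genome-wide median is kept.
#'
#' @param panel A `panel_design`.
#' @param observations Observations covering the panel (see
#'   [read_observations()]).
#' @param sex `"male"` or `"female"`.
#' @param thresholds A [call_thresholds()].
#' @return An `arm_calls` data frame with one row per scoreable arm (male X
#'   rows flagged `hemizygous`), ordered chromosome 1..22, X, p before q.
#' @export
call_sample <- function(panel, observations, sex = c("female", "male"),
                        thresholds = call_thresholds()) {
  sex <- match.arg(sex)
  loci <- merge(as.data.frame(panel), observations, by = "locus_id", sort = FALSE)
  if (nrow(loci) < nrow(panel)) stop("observations do not cover the panel")

  autosomal <- loci$chrom != "X" & loci$depth > 0
  if (!any(autosomal)) stop("sample uninterpretable: no covered autosomal loci")
  baseline1 <- stats::median(loci$depth[autosomal])

  stats1 <- arm_stats_table(loci, baseline1)
  calls1 <- classify_stats_table(stats1, thresholds, sex)

  balanced_arms <- calls1$arm_id[calls1$allelic_tier == "balanced" &
                                 !calls1$no_call & calls1$chrom != "X"]
  baseline2 <- if (length(balanced_arms) > 0) {
    in_bal <- loci$arm_id %in% balanced_arms & loci$depth > 0
    stats::median(loci$depth[in_bal])
  } else baseline1

  stats2 <- arm_stats_table(loci, baseline2)
  calls <- classify_stats_table(stats2, thresholds, sex)

  if (mean(calls$no_call) > 0.5) {
    stop("sample uninterpretable: more than half of the arms are no-calls")
  }
  attr(calls, "sex") <- sex
  attr(calls, "thresholds") <- thresholds
  attr(calls, "balanced_depth") <- baseline2
  calls
}
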