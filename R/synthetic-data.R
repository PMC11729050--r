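#' Simulation configuration
#'
#' @param mean_depth Mean read depth of a diploid locus (reads).
#' @param depth_dispersion Overdispersion of the gamma-Poisson depth model,
#'   parameterised as variance inflation: `Var(depth) = (1 + dispersion) * mean`.
#'   0 gives pure Poisson depths; the default 0.2 adds 20% extra variance to
#'   emulate FFPE library variability.
#' @param seed Integer RNG seed; every simulation is reproducible given the
#'   same spec, panel and config.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(mean_depth = 500L, depth_dispersion = 0.2,
                              seed = 1L) {
  if (mean_depth < 1) stop("mean_depth must be >= 1")
  if (depth_dispersion < 0) stop("depth_dispersion must be >= 0")
  structure(list(mean_depth = as.integer(mean_depth),
                 depth_dispersion = depth_dispersion,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default 1500-SNP panel
#'
#' Distributes 1500 loci over the 41 scoreable arms: every arm receives
#' `floor(1500/41)` = 36 loci and 24 arms (chosen reproducibly from `seed`)
#' receive one extra. All loci use a population B-allele frequency of 0.5,
#' the maximally informative value for tumor-only heterozygosity
#' expectations.
#'
#' @param seed Integer seed controlling which arms receive the extra locus.
#' @param n_loci Panel size (default 1500).
#' @return A `panel_design` data frame of `n_loci` loci.
#' @export
make_default_panel <- function(seed = 17L, n_loci = 1500L) {
  arms <- arm_universe()
  base <- n_loci %/% nrow(arms)
  extra <- n_loci %% nrow(arms)
  counts <- rep(base, nrow(arms))
  if (extra > 0) {
    counts[with_seed(seed, sample.int(nrow(arms), extra))] <-  base + 1L
  }
  idx <- rep(seq_len(nrow(arms)), counts)
  panel <- data.frame(
    locus_id = sprintf("snp%04d", seq_along(idx)),
    chrom = arms$chrom[idx],
    arm = arms$arm[idx],
    pop_baf = 0.5,
    arm_id = arms$arm_id[idx],
    stringsAsFactors = FALSE
  )
  class(panel) <- c("panel_design", "data.frame")
  panel
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Ground-truth tumor specification
#'
#' A `tumor_spec` fixes the simulation ground truth for one sample: its sex,
#' tumor purity, a genotype state for each of the 41 scoreable arms, and a
#' truth flag for whole-genome doubling. For male samples the X arms must be
#' hemizygous-consistent: (1,0) (the single germline X) or (2,0) (doubled X).
#'
#' @param sample_id Sample identifier.
#' @param sex `"male"` or `"female"`.
#' @param purity Tumor-cell fraction in (0, 1].
#' @param arm_states A data frame with columns `arm_id` (or `chrom` + `arm`),
#'   `major`, `minor`. Arms not listed default to (1,1) for autosomes and
#'   female X, and to (1,0) for male X.
#' @param doubling Truth flag: did endoreduplication/genome doubling occur?
#' @return A `tumor_spec` list.
#' @export
tumor_spec <- function(sample_id, sex = c("female", "male"), purity = 0.8,
                       arm_states = NULL, doubling = FALSE) {
  sex <- match.arg(sex)
  check_purity(purity)
  arms <- arm_universe()
  arms$major <- 1L
  arms$minor <- 1L
  if (sex == "male") {
    arms$minor[arms$chrom == "X"] <- 0L
  }
  if (!is.null(arm_states) && nrow(arm_states) > 0) {
    if (!"arm_id" %in% names(arm_states)) {
      arm_states$arm_id <- paste0(arm_states$chrom, arm_states$arm)
    }
    parse_arm_id(arm_states$arm_id)  # validates
    if (anyDuplicated(arm_states$arm_id)) stop("duplicate arm in arm_states")
    s <- genotype_state(arm_states$major, arm_states$minor)
    i <- match(arm_states$arm_id, arms$arm_id)
    arms$major[i] <- s$major
    arms$minor[i] <- s$minor
  }
  if (sex == "male") {
    x <- arms$chrom == "X"
    ok <- (arms$major[x] %in% c(1L, 2L)) & arms$minor[x] == 0L
    if (!all(ok)) stop("male X arm states must be (1,0) or (2,0)")
  }
  structure(list(sample_id = as.character(sample_id), sex = sex,
                 purity = purity, arm_states = arms,
                 doubling = isTRUE(doubling)),
            class = "tumor_spec")
}

#' Simulate panel observations for one tumor specimen
#'
#' Forward model, per locus: a germline genotype is drawn under
#' Hardy-Weinberg from the locus `pop_baf` (hemizygous on the male X); read
#' depth is drawn gamma-Poisson with mean `mean_depth` times the expected
#' relative coverage of the arm's state at the spec's purity; the B-allele
#' read count is binomial at the locus-level expected BAF. Germline
#' homozygous loci have expected BAF 0 or 1 regardless of the tumor state;
#' germline heterozygous loci follow [expected_baf()] with a random phase
#' (which parental haplotype carries B).
#'
#' @param spec A [tumor_spec()].
#' @param panel A `panel_design`.
#' @param config A [simulation_config()].
#' @return Observations: data frame `locus_id`, `depth`, `b_count` in panel
#'   order. Ground truth never leaks into this table; see [truth_table()].
#' @export
simulate_sample <- function(spec, panel, config = simulation_config()) {
  stopifnot(inherits(spec, "tumor_spec"))
  i <- match(panel$arm_id, spec$arm_states$arm_id)
  if (anyNA(i)) stop("spec arm_states incomplete for panel arm(s) ",
                     paste(unique(panel$arm_id[is.na(i)]), collapse = ", "))
  major <- spec$arm_states$major[i]
  minor <- spec$arm_states$minor[i]
  p <- spec$purity
  n <- nrow(panel)
  male_x <- spec$sex == "male" & panel$chrom == "X"
  normal_copies <- ifelse(male_x, 1, 2)
  rel_cov <- (p * (major + minor) + (1 - p) * normal_copies) / 2

  with_seed(config$seed, {
    # germline genotype: B-allele dose of the normal cells
    q <- panel$pop_baf
    u <- stats::runif(n)
    g <- ifelse(u < (1 - q)^2, 0L, ifelse(u < (1 - q)^2 + 2 * q * (1 - q), 1L, 2L))
    g[male_x] <- ifelse(stats::runif(sum(male_x)) < q[male_x], 2L, 0L)  # hemizygous: all-or-nothing

    mu <- config$mean_depth * rel_cov
    depth <- if (config$depth_dispersion > 0) {
      stats::rnbinom(n, size = mu / config$depth_dispersion, mu = mu)
    } else {
      stats::rpois(n, mu)
    }

    ebaf_het <- expected_baf(major, minor, p)
    phase_b_major <- stats::runif(n) < 0.5
    baf <- ifelse(g == 0L, 0, ifelse(g == 2L, 1,
                  ifelse(phase_b_major, ebaf_het, 1 - ebaf_het)))
    b_count <- stats::rbinom(n, depth, baf)
    data.frame(locus_id = panel$locus_id, depth = depth, b_count = b_count)
  })
}

#' Ground-truth table for a tumor specification
#'
#' @param spec A [tumor_spec()].
#' @return Data frame `sample_id`, `chrom`, `arm`, `major`, `minor` (one row
#'   per scoreable arm), the truth companion emitted alongside simulated
#'   observations.
#' @export
truth_table <- function(spec) {
  data.frame(sample_id = spec$sample_id,
             chrom = spec$arm_states$chrom,
             arm = spec$arm_states$arm,
             major = spec$arm_states$major,
             minor = spec$arm_states$minor)
}

#' Noise-free arm calls from ground truth
#'
#' Converts a [tumor_spec()] directly into the `arm_calls` the caller would
#' produce on noiseless expected-value data: summary statistics are the
#' closed-form expectations at the spec's purity, states and mechanisms are
#' the truth. Useful for testing sample-level synthesis independently of the
#' sequencing noise model.
#'
#' @param spec A [tumor_spec()].
#' @return An `arm_calls` data frame.
#' @export
truth_calls <- function(spec) {
  a <- spec$arm_states
  p <- spec$purity
  male_x <- spec$sex == "male" & a$chrom == "X"
  ebaf <- expected_baf(a$major, a$minor, p)
  el2r <- expected_log2_ratio(a$major, a$minor, p)
  el2r[male_x] <- log2((p * (a$major[male_x] + a$minor[male_x]) + (1 - p)) / 2)
  # saturated LOH empties the heterozygous band; the male X has no hets at all
  saturated <- ebaf >= 0.95 | male_x
  mech <- state_mechanism(a$major, a$minor)
  mech[male_x] <- ifelse(a$major[male_x] == 1L, "none", "gain")
  calls <- data.frame(
    chrom = a$chrom, arm = a$arm, arm_id = a$arm_id,
    n_informative = ifelse(saturated, 0L, 18L),
    n_covered = 37L,
    het_fraction = ifelse(saturated, 0, 0.5),
    median_mirrored_baf = ifelse(saturated, NA_real_, ebaf),
    median_log2_ratio = el2r,
    major = a$major, minor = a$minor,
    genotype_label = genotype_label(a$major, a$minor),
    mechanism = mech,
    hemizygous = male_x,
    low_confidence = FALSE,
    no_call = FALSE,
    stringsAsFactors = FALSE
  )
  class(calls) <- c("arm_calls", "data.frame")
  attr(calls, "sample_id") <- spec$sample_id
  attr(calls, "sex") <- spec$sex
  calls
}

#' Simulate a cohort with requested pattern composition
#'
#' Draws random tumor specifications whose true pattern labels match the
#' request: Pattern 1 samples are fully balanced; Pattern 2 samples carry
#' only losses/copy-neutral LOH; Pattern 3 only gains; Pattern 4 both.
#' Patterns 2-4 alter at least three arms (whole chromosomes are altered, as
#' arm-level events in these tumors are predominantly whole-chromosome).
#' Purity is drawn uniformly from 0.65-0.9, the high tumor-content range
#' typical of this tumor type.
#'
#' @param n_per_pattern Named vector/list, e.g. `c("1" = 16, "3" = 4)`;
#'   names must be among "1".."4".
#' @param config A [simulation_config()]; per-sample seeds are derived from
#'   `config$seed`.
#' @param panel Panel to simulate on (default [make_default_panel()]).
#' @param simulate If `FALSE`, skip read-count simulation and return specs
#'   only (fast path for truth-level cohort work).
#' @return A list with one element per sample: `spec`, `pattern` (true
#'   label) and `observations` (`NULL` when `simulate = FALSE`).
#' @export
simulate_cohort <- function(n_per_pattern, config = simulation_config(),
                            panel = make_default_panel(), simulate = TRUE) {
  patterns <- rep(as.integer(names(n_per_pattern)), unlist(n_per_pattern))
  if (length(patterns) == 0 || !all(patterns %in% 1:4)) {
    stop("n_per_pattern keys must be among 1..4")
  }
  out <- vector("list", length(patterns))
  for (k in seq_along(patterns)) {
    sample_seed <- config$seed + 7919L * k
    spec <- with_seed(sample_seed,
                      random_spec(sprintf("sim%03d", k), patterns[k]))
    obs <- if (simulate) {
      cfg <- config
      cfg$seed <- sample_seed + 1L
      simulate_sample(spec, panel, cfg)
    }
    out[[k]] <- list(spec = spec, pattern = patterns[k], observations = obs)
  }
  out
}

# draw one random spec with the requested true pattern
random_spec <- function(sample_id, pattern) {
  sex <- sample(c("female", "male"), 1)
  purity <- stats::runif(1, 0.65, 0.9)
  # candidate whole chromosomes; male alterations stay autosomal so the
  # hemizygous X keeps its (1,0) baseline
  chroms <- if (sex == "male") as.character(1:22) else c(as.character(1:22), "X")
  pick_states <- function(n_chrom, states) {
    repeat {  # acrocentric chromosomes carry one arm; guarantee >= 3 arms
      chosen <- sample(chroms, n_chrom)
      arms <- arm_universe()
      arms <- arms[arms$chrom %in% chosen, ]
      if (nrow(arms) >= 3) break
      n_chrom <- n_chrom + 1L
    }
    st <- states[sample.int(nrow(states), n_chrom, replace = TRUE), , drop = FALSE]
    i <- match(arms$chrom, chosen)
    data.frame(arm_id = arms$arm_id, major = st$major[i], minor = st$minor[i])
  }
  loss_states <- data.frame(major = c(1L, 2L), minor = c(0L, 0L))
  gain_states <- data.frame(major = c(2L, 2L, 2L), minor = c(1L, 1L, 2L))
  states <- switch(as.character(pattern),
    "1" = NULL,
    "2" = pick_states(sample(2:8, 1), loss_states),
    "3" = pick_states(sample(2:8, 1), gain_states),
    "4" = {
      k <- sample(2:5, 1); m <- sample(2:5, 1)
      picked <- sample(chroms, k + m)
      arms <- arm_universe()
      loss_arms <- arms[arms$chrom %in% picked[seq_len(k)], ]
      gain_arms <- arms[arms$chrom %in% picked[k + seq_len(m)], ]
      ls <- loss_states[sample.int(2, k, replace = TRUE), ]
      gs <- gain_states[sample.int(3, m, replace = TRUE), ]
      rbind(
        data.frame(arm_id = loss_arms$arm_id,
                   major = ls$major[match(loss_arms$chrom, picked[seq_len(k)])],
                   minor = ls$minor[match(loss_arms$chrom, picked[seq_len(k)])]),
        data.frame(arm_id = gain_arms$arm_id,
                   major = gs$major[match(gain_arms$chrom, picked[k + seq_len(m)])],
                   minor = gs$minor[match(gain_arms$chrom, picked[k + seq_len(m)])])
      )
    })
  tumor_spec(sample_id, sex = sex, purity = purity, arm_states = states)
}
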