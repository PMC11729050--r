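# shared fixtures for the test suite; everything is generated in code

# a one-row arm_stats table with sensible defaults, for classify_arm tests
make_stats <- function(mbaf, l2r, chrom = "1", arm = "p", n_informative = 18L,
                       n_covered = 37L, n_nonzero = 37L, het_fraction = 0.5,
                       expected_het = 0.5) {
  stats <- data.frame(
    chrom = chrom, arm = arm, arm_id = paste0(chrom, arm),
    n_loci = 37L, n_nonzero = n_nonzero, n_covered = n_covered,
    n_informative = n_informative, het_fraction = het_fraction,
    expected_het = expected_het,
    median_mirrored_baf = mbaf, median_log2_ratio = l2r,
    stringsAsFactors = FALSE
  )
  class(stats) <- c("arm_stats", "data.frame")
  stats
}

# expected-value stats for a state at a purity (noise-free oracle input)
state_stats <- function(major, minor, purity, chrom = "1", arm = "p") {
  eb <- expected_baf(major, minor, purity)
  saturated <- eb >= 0.95
  make_stats(
    mbaf = if (saturated) NA_real_ else eb,
    l2r = expected_log2_ratio(major, minor, purity),
    chrom = chrom, arm = arm,
    n_informative = if (saturated) 0L else 18L,
    het_fraction = if (saturated) 0 else 0.5
  )
}

# small shared panel so unit tests stay fast; acceptance uses the full 1500
test_panel <- function() make_default_panel(17)

# run simulate -> call for a spec, returning arm calls
simulate_and_call <- function(spec, depth = 1000, seed = 1,
                              panel = test_panel(),
                              thresholds = call_thresholds()) {
  obs <- simulate_sample(spec, panel,
                         simulation_config(mean_depth = depth, seed = seed))
  call_sample(panel, obs, sex = spec$sex, thresholds = thresholds)
}
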