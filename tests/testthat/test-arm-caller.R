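test_that("arm summaries report the heterozygous band and self-normalized coverage", {
  panel <- test_panel()
  spec <- tumor_spec("s", "female", 0.65,
                     arm_states = data.frame(arm_id = c("3p", "3q"),
                                             major = 1, minor = 0))
  obs <- simulate_sample(spec, panel, simulation_config(500, 0.2, 21))
  loci_ids <- panel$locus_id[panel$arm_id == "3p"]
  stats <- summarize_arm(obs[obs$locus_id %in% loci_ids, ],
                         panel[panel$arm_id == "3p", ],
                         balanced_depth = 500)
  expect_equal(stats$arm_id, "3p")
  expect_lt(abs(stats$median_mirrored_baf - expected_baf(1, 0, 0.65)), 0.02)
  expect_lt(abs(stats$median_log2_ratio - expected_log2_ratio(1, 0, 0.65)), 0.1)
  expect_gt(stats$n_informative, 8)
  expect_error(summarize_arm(obs, panel, 500), "one arm")
})

test_that("saturated LOH empties the informative band into the het fraction", {
  panel <- test_panel()
  spec <- tumor_spec("pure", "female", 1.0,
                     arm_states = data.frame(arm_id = c("5p", "5q"),
                                             major = 1, minor = 0))
  obs <- simulate_sample(spec, panel, simulation_config(500, 0.2, 22))
  ids <- panel$locus_id[panel$arm_id == "5q"]
  stats <- summarize_arm(obs[obs$locus_id %in% ids, ],
                         panel[panel$arm_id == "5q", ], 500)
  expect_equal(stats$n_informative, 0L)
  expect_lt(stats$het_fraction, 0.05)
  expect_true(is.na(stats$median_mirrored_baf))
})

test_that("the decision ladder maps tier pairs to the documented states", {
  th <- call_thresholds()
  cases <- list(
    #        mbaf  l2r    major minor mechanism
    list(0.80, -0.55, 1L, 0L, "loss"),          # LOH + loss
    list(0.80,  0.00, 2L, 0L, "cn_loh"),        # LOH + neutral coverage
    list(0.50,  0.00, 1L, 1L, "none"),          # balanced diploid
    list(0.62,  0.40, 2L, 1L, "gain"),          # imbalance + gain
    list(0.50,  0.85, 2L, 2L, "balanced_gain")  # balanced + strong gain
  )
  for (cs in cases) {
    call <- classify_arm(make_stats(cs[[1]], cs[[2]]), th, "female")
    expect_equal(call$major, cs[[3]], info = paste("mbaf", cs[[1]]))
    expect_equal(call$minor, cs[[4]], info = paste("mbaf", cs[[1]]))
    expect_equal(call$mechanism, cs[[5]])
  }
  # imbalance + loss resolves to (1,0) flagged low-confidence (subclonal loss)
  call <- classify_arm(make_stats(0.65, -0.30), th, "female")
  expect_equal(c(call$major, call$minor), c(1L, 0L))
  expect_true(call$low_confidence)
  # het deficit scores LOH even when the band is empty
  call <- classify_arm(make_stats(NA_real_, -0.7, n_informative = 0L,
                                  het_fraction = 0.02), th, "female")
  expect_equal(call$mechanism, "loss")
})

test_that("noise-free expected stats recover every state exactly (threshold consistency)", {
  th <- call_thresholds()
  states <- list(c(1, 1), c(1, 0), c(2, 0), c(2, 1), c(2, 2))
  for (st in states) {
    call <- classify_arm(state_stats(st[1], st[2], 0.8), th, "female")
    expect_equal(c(call$major, call$minor), as.integer(st),
                 info = paste("state", st[1], st[2]))
  }
})

test_that("LOH calls never revert to balanced as purity grows; dilution silences all", {
  th <- call_thresholds()
  for (st in list(c(1, 0), c(2, 0))) {
    called_loh <- FALSE
    for (p in seq(0.2, 1, by = 0.05)) {
      call <- classify_arm(state_stats(st[1], st[2], p), th, "female")
      is_loh <- call$mechanism %in% c("loss", "cn_loh")
      if (called_loh) expect_true(is_loh, info = paste(st[1], st[2], p))
      called_loh <- called_loh || is_loh
    }
    expect_true(called_loh)
  }
  # near-zero purity: every state is indistinguishable from diploid
  for (st in list(c(1, 0), c(2, 0), c(2, 1), c(2, 2))) {
    for (p in c(0.02, 0.05, 0.09)) {
      call <- classify_arm(state_stats(st[1], st[2], p), th, "female")
      expect_equal(call$mechanism, "none", info = paste(st[1], st[2], p))
    }
  }
})

test_that("male X arms are called on the hemizygous coverage baseline only", {
  th <- call_thresholds()
  # (1,0) at purity 0.8: rel coverage 0.5 of diploid, the male-X baseline
  base <- make_stats(NA_real_, -1, chrom = "X", arm = "p",
                     n_informative = 0L, het_fraction = 0)
  call <- classify_arm(base, th, "male")
  expect_true(call$hemizygous)
  expect_equal(call$mechanism, "none")
  expect_equal(c(call$major, call$minor), c(1L, 0L))
  # doubled X: coverage log2((1+p)) above the 1-copy baseline
  gained <- make_stats(NA_real_, log2(1.8) - 1, chrom = "X", arm = "q",
                       n_informative = 0L, het_fraction = 0)
  call <- classify_arm(gained, th, "male")
  expect_equal(call$mechanism, "gain")
  expect_equal(c(call$major, call$minor), c(2L, 0L))
})

test_that("thin arms become no-calls and a mostly-no-call sample errors", {
  th <- call_thresholds()
  thin <- make_stats(NA_real_, NA_real_, n_informative = 0L, n_covered = 2L,
                     n_nonzero = 3L, het_fraction = 0)
  expect_true(classify_arm(thin, th, "female")$no_call)

  panel <- test_panel()
  spec <- patient_fixture(51)
  obs <- simulate_sample(spec, panel, simulation_config(500, 0.2, 31))
  dropped <- obs
  dropped$depth[!(panel$arm_id %in% c("1p", "1q"))] <- 0L
  dropped$b_count <- pmin(dropped$b_count, dropped$depth)
  expect_error(call_sample(panel, dropped, "female", th), "uninterpretable")
})

test_that("whole-sample calling recovers the truth per arm across purities", {
  panel <- test_panel()
  arms <- arm_universe()
  autos <- arms$arm_id[arms$chrom != "X"]
  th <- call_thresholds()
  set.seed(88)
  for (p in c(0.6, 1.0)) {
    altered <- sample(autos, 16)
    st <- data.frame(arm_id = altered,
                     major = rep(c(2L, 1L, 2L, 2L), 4),
                     minor = rep(c(1L, 0L, 0L, 2L), 4))
    spec <- tumor_spec("rec", "female", p, arm_states = st)
    calls <- simulate_and_call(spec, depth = 500, seed = 100 + round(100 * p),
                               panel = panel, thresholds = th)
    merged <- merge(calls, spec$arm_states, by = "arm_id",
                    suffixes = c("_called", "_true"))
    agree <- merged$major_called == merged$major_true &
             merged$minor_called == merged$minor_true
    expect_gte(mean(agree), 40 / 41)
  }
})
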