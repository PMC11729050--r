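test_that("default panel covers every arm evenly and is deterministic", {
  panel <- make_default_panel(17)
  expect_equal(nrow(panel), 1500L)
  counts <- table(panel$arm_id)
  expect_equal(length(counts), 41L)
  expect_true(all(counts %in% c(36L, 37L)))
  expect_false("13p" %in% panel$arm_id)
  expect_identical(panel, make_default_panel(17))
  expect_false(identical(panel$arm_id, make_default_panel(99)$arm_id))
})

test_that("tumor specs validate arm completeness and male X consistency", {
  spec <- tumor_spec("s", "female", 0.8)
  expect_equal(nrow(spec$arm_states), 41L)
  expect_true(all(spec$arm_states$major == 1L & spec$arm_states$minor == 1L))
  m <- tumor_spec("s", "male", 0.8)
  expect_true(all(m$arm_states$minor[m$arm_states$chrom == "X"] == 0L))
  expect_error(
    tumor_spec("s", "male", 0.8,
               arm_states = data.frame(arm_id = "Xp", major = 1, minor = 1)),
    "male X")
  expect_error(
    tumor_spec("s", "female", 0.8,
               arm_states = data.frame(arm_id = "13p", major = 1, minor = 0)),
    "invalid")
})

test_that("simulation is deterministic given (spec, panel, config)", {
  panel <- test_panel()
  spec <- patient_fixture(22)
  cfg <- simulation_config(500, 0.2, 42)
  expect_identical(simulate_sample(spec, panel, cfg),
                   simulate_sample(spec, panel, cfg))
  other <- simulate_sample(spec, panel, simulation_config(500, 0.2, 43))
  expect_false(identical(simulate_sample(spec, panel, cfg), other))
  # observations carry no truth columns
  expect_named(other, c("locus_id", "depth", "b_count"))
})

test_that("a balanced pure sample simulates to BAF 0.5 and flat coverage", {
  panel <- test_panel()
  spec <- tumor_spec("flat", "female", 1.0)
  obs <- simulate_sample(spec, panel, simulation_config(500, 0.2, 7))
  loci <- merge(obs, as.data.frame(panel), by = "locus_id")
  baf <- loci$b_count / loci$depth
  het <- baf > 0.05 & baf < 0.95
  mirrored <- pmax(baf[het], 1 - baf[het])
  expect_lt(abs(mean(mirrored) - 0.51), 0.02)
  arm_med <- tapply(loci$depth, loci$arm_id, median)
  l2r <- log2(arm_med / median(loci$depth))
  expect_true(all(abs(l2r) < 0.05))
})

test_that("simulated het arms converge to the expected BAF at depth", {
  # law of large numbers: median mirrored BAF within 0.01 at depth 2000
  panel <- test_panel()
  spec <- tumor_spec("loh", "female", 0.65,
                     arm_states = data.frame(arm_id = c("1p", "1q"),
                                             major = 1, minor = 0))
  obs <- simulate_sample(spec, panel, simulation_config(2000, 0.2, 5))
  loci <- merge(obs, as.data.frame(panel), by = "locus_id")
  loci <- loci[loci$arm_id == "1p", ]
  baf <- loci$b_count / loci$depth
  het <- baf > 0.05 & baf < 0.95
  expect_gte(sum(het), 10)
  mbaf <- median(pmax(baf[het], 1 - baf[het]))
  expect_lt(abs(mbaf - expected_baf(1, 0, 0.65)), 0.01)
})

test_that("patient fixtures encode the captioned karyotypes", {
  f51 <- patient_fixture(51)
  expect_true(all(f51$arm_states$major == 1L & f51$arm_states$minor == 1L))

  f49 <- patient_fixture(49)
  expect_equal(f49$sex, "male")
  lost <- f49$arm_states$arm_id[f49$arm_states$minor == 0 &
                                f49$arm_states$major == 1 &
                                f49$arm_states$chrom != "X"]
  expect_setequal(lost, c("1p", "2p", "2q", "8p", "8q", "11p", "11q"))
  thirteen <- f49$arm_states[f49$arm_states$arm_id == "13q", ]
  expect_equal(c(thirteen$major, thirteen$minor), c(2L, 0L))

  f20 <- patient_fixture(20)
  gained <- unique(f20$arm_states$chrom[f20$arm_states$major == 2 &
                                        f20$arm_states$minor == 1])
  expect_setequal(gained, c("3", "7", "8", "9", "12", "19", "21", "22"))

  f22 <- patient_fixture(22)
  aabb <- unique(f22$arm_states$chrom[f22$arm_states$major == 2 &
                                      f22$arm_states$minor == 2])
  expect_setequal(aabb, c("5", "9"))

  f56 <- patient_fixture(56)
  expect_equal(f56$purity, 0.65)
  expect_true(f56$doubling)
  lost56 <- unique(f56$arm_states$chrom[f56$arm_states$minor == 0])
  expect_length(lost56, 16L)
  expect_true("X" %in% lost56)

  expect_error(patient_fixture(99), "unknown patient")
})

test_that("simulated cohorts honor the requested pattern composition", {
  cohort <- simulate_cohort(c("1" = 16, "3" = 4),
                            simulation_config(100, 0.2, 3), simulate = FALSE)
  expect_length(cohort, 20L)
  truth_patterns <- vapply(cohort, `[[`, 0L, "pattern")
  expect_equal(sum(truth_patterns == 1), 16L)
  specs <- lapply(cohort, `[[`, "spec")
  altered <- vapply(specs, function(s) {
    sum(!(s$arm_states$major == 1 &
          s$arm_states$minor == ifelse(s$sex == "male" &
                                       s$arm_states$chrom == "X", 0, 1)))
  }, 0L)
  expect_true(all(altered[truth_patterns == 1] == 0))
  expect_true(all(altered[truth_patterns == 3] >= 3))

  mixed <- simulate_cohort(c("4" = 6), simulation_config(100, 0.2, 9),
                           simulate = FALSE)
  for (s in mixed) {
    st <- s$spec$arm_states
    st <- st[!(s$spec$sex == "male" & st$chrom == "X"), ]
    total <- st$major + st$minor
    expect_true(any(total < 2 | (st$major == 2 & st$minor == 0)))  # loss side
    expect_true(any(total > 2))                                    # gain side
  }

  expect_error(simulate_cohort(c("5" = 1)), "1..4")
})
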