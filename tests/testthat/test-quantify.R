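test_that("isotope-dilution concentration is linear in area and anchored at the IS", {
  expect_equal(compute_concentration(0, 500, 2), 0)
  expect_equal(compute_concentration(500, 500, 2), 2)
  expect_equal(compute_concentration(1500, 500, 10), 30)
  # linearity
  expect_equal(compute_concentration(3 * 123, 456, 7),
               3 * compute_concentration(123, 456, 7))
  expect_error(compute_concentration(10, 0, 2),
               class = "hemoscreen_measurement_error")
  expect_error(compute_concentration(10, 500, -1),
               class = "hemoscreen_measurement_error")
})

test_that("chain ratio equals the ratio of the two concentrations", {
  expect_equal(compute_chain_ratio(200, 400, 800, 400, 0.1, 5), 0.005)
  # self-ratio with equal IS concentrations
  expect_equal(compute_chain_ratio(300, 450, 300, 450, 2, 2), 1)
  # agreement with the explicit concentration quotient, random positive inputs
  set.seed(11)
  for (i in 1:50) {
    a <- runif(4, 1, 1e5)
    cs <- runif(2, 0.05, 10)
    direct <- compute_chain_ratio(a[1], a[2], a[3], a[4], cs[1], cs[2])
    via_conc <- compute_concentration(a[1], a[2], cs[1]) /
      compute_concentration(a[3], a[4], cs[2])
    expect_equal(direct, via_conc, tolerance = 1e-12)
  }
  # scale invariance under common area scaling
  expect_equal(compute_chain_ratio(200 * 7, 400 * 7, 800 * 7, 400 * 7, 0.1, 5),
               compute_chain_ratio(200, 400, 800, 400, 0.1, 5))
  # zero denominator flags, not errors
  expect_true(is.na(compute_chain_ratio(200, 400, 0, 400, 0.1, 5)))
  expect_error(compute_chain_ratio(200, 400, 800, 400, NA, 5),
               class = "hemoscreen_config_error")
})

test_that("variant ratio uses IS-normalized areas without concentration terms", {
  expect_equal(compute_variant_ratio(0, 400, 600, 400), 0)
  expect_equal(compute_variant_ratio(400, 400, 400, 400), 1)
  expect_equal(compute_variant_ratio(300, 400, 600, 400), 0.5)
  expect_equal(compute_variant_ratio(300, 400, 600, 400, detected = FALSE), 0)
  expect_true(is.na(compute_variant_ratio(300, 400, 0, 400)))
})

test_that("detection requires signal-to-noise of at least 10", {
  expect_true(is_detected(100, 10))
  expect_false(is_detected(99, 10))
  expect_false(is_detected(0, 0))
  # without a noise estimate, the detection floor decides
  expect_true(is_detected(5, NA))
  expect_false(is_detected(0, NA))
  expect_false(is_detected(5, NA, floor = 10))
  expect_error(is_detected(-1, 5), class = "hemoscreen_measurement_error")
})

test_that("quantify_cohort emits the expected ratios for a flat sample", {
  prof <- quantify_cohort(core_sample())
  # all areas equal their IS areas, so every term cancels except the IS
  # concentrations
  expect_equal(prof$aT1_bT1, 2 / 5)
  expect_equal(prof$dT2_bT2, 0.2 / 5)
  expect_equal(prof$zT8_bT2, 0.1 / 5)
  expect_equal(prof$aT3_bT1, 10 / 5)
  expect_equal(prof$gT10_aT3, 0.5 / 10)
  expect_equal(prof$gT10_bT1, 0.5 / 5)
  expect_true(prof$evaluable)
  # emitted ratio columns are exactly the closed declared set
  expect_true(all(ratio_names() %in% names(prof)))
})

test_that("missing or undetected beta denominators make a sample non-evaluable", {
  no_bt2 <- dplyr::filter(core_sample(), peptide_id != "bT2")
  prof <- quantify_cohort(no_bt2)
  expect_false(prof$evaluable)
  expect_match(prof$reason, "bT2")

  dead_bt1 <- core_sample()
  dead_bt1$area[dead_bt1$peptide_id == "bT1"] <- 0
  prof2 <- quantify_cohort(dead_bt1)
  expect_false(prof2$evaluable)
  expect_match(prof2$reason, "bT1")
  # ratios with the dead denominator are absent, not infinite
  expect_true(is.na(prof2$aT1_bT1))
})

test_that("unknown peptides are skipped with a warning; duplicates error", {
  tbl <- dplyr::bind_rows(core_sample(),
                          tibble::tibble(sample_id = "s1", peptide_id = "mystery",
                                         area = 5, is_area = 5))
  expect_warning(prof <- quantify_cohort(tbl), "mystery")
  expect_equal(prof$aT1_bT1, 0.4)

  dup <- dplyr::bind_rows(core_sample(), core_sample()[1, ])
  expect_error(quantify_cohort(dup), class = "hemoscreen_input_error")
})

test_that("a detected mutant peptide yields its named variant ratio", {
  tbl <- dplyr::bind_rows(
    core_sample(),
    tibble::tibble(sample_id = "s1", peptide_id = "HbG_T3",
                   area = 1100, is_area = 500, noise = 1)
  )
  prof <- quantify_cohort(tbl)
  vr <- prof$variant_ratios[[1]]
  expect_true("Hb G-Coushatta" %in% names(vr))
  expect_equal(unname(vr["Hb G-Coushatta"]), (1100 * 500) / (500 * 500))

  # undetected mutant (S/N < 10) reports 0, so "> 0" cutoffs read as absent
  tbl$noise[tbl$peptide_id == "HbG_T3"] <- 1100
  prof0 <- quantify_cohort(tbl)
  expect_equal(unname(prof0$variant_ratios[[1]]["Hb G-Coushatta"]), 0)
})

test_that("quantification is pure and scale-invariant per sample", {
  set.seed(21)
  tbl <- core_sample(area = runif(7, 100, 5000), is_area = runif(7, 300, 700))
  p1 <- quantify_cohort(tbl)
  p2 <- quantify_cohort(tbl)
  expect_identical(p1, p2)
  scaled <- dplyr::mutate(tbl, area = area * 3.7, is_area = is_area * 3.7)
  p3 <- quantify_cohort(scaled)
  for (r in ratio_names()) expect_equal(p3[[r]], p1[[r]], tolerance = 1e-12)
})

test_that("registry and internal-standard defaults validate and match the assay design", {
  reg <- transition_registry()
  expect_true(all(reg$precursor_mz > 0))
  expect_true(all(reg$retention_time <= 2.6))
  # each IS pairs with exactly one analyte
  is_ids <- reg$peptide_id[reg$is_internal_standard]
  expect_setequal(is_ids, c("aT1", "aT3", "bT1", "bT2", "gT10", "dT2", "zT8"))
  is_cfg <- internal_standards()
  expect_equal(unname(is_cfg[c("aT1", "aT3", "bT1", "bT2", "gT10", "dT2", "zT8")]),
               c(2, 10, 5, 5, 0.5, 0.2, 0.1))
})
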