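test_that("default cutoff table carries the shipped screening thresholds", {
  cut <- default_cutoffs()
  expect_equal(cut$p_alpha_screen, 0.33)
  expect_equal(cut$p_beta_screen, 0.13)
  expect_equal(unname(cut$severity_bands[c("alpha0", "sea_deletion", "hbh")]),
               c(0.66, 0.87, 0.88))
  expect_equal(unname(cut$variant_thresholds["Hb S"]), 0)
  expect_equal(unname(cut$variant_thresholds["Hb G-Coushatta"]), 2.19)
  # un-rounded ROC decision points are available as a preset
  roc_cut <- default_cutoffs(preset = "roc")
  expect_equal(roc_cut$p_alpha_screen, 0.329)
  expect_equal(roc_cut$p_beta_screen, 0.126)
  # invariants on construction
  expect_error(new_cutoffs(0.5, 1.2), class = "hemoscreen_config_error")
  expect_error(new_cutoffs(0.5, 0.1, severity_bands = c(alpha0 = 0.4)),
               class = "hemoscreen_config_error")
})

test_that("classification reproduces the cutoff-table decision rules", {
  cut <- default_cutoffs()
  # high P(alpha), quiet P(beta): alpha-thalassemia with a severity band
  call <- classify_sample(0.90, 0.05, cutoffs = cut)
  expect_equal(call$category, "alpha_thalassemia")
  expect_equal(call$severity_band, "hbh_range") # highest band met at 0.90
  call_sea <- classify_sample(0.875, 0.05, cutoffs = cut)
  expect_equal(call_sea$severity_band, "sea_range")
  # both quiet, no variants: normal
  expect_equal(classify_sample(0.10, 0.02, c("Hb S" = 0), cut)$category,
               "normal")
  # both thresholds met: combined category
  expect_equal(classify_sample(0.40, 0.30, cutoffs = cut)$category,
               "alpha_and_beta_thalassemia")
  # variant above its threshold with quiet probabilities: abnormal Hb
  g <- classify_sample(0.05, 0.01, c("Hb G-Coushatta" = 2.20), cut)
  expect_equal(g$category, "abnormal_hb")
  expect_equal(g$variants_detected, "Hb G-Coushatta")
  # just under the Hb G threshold does not fire
  expect_equal(classify_sample(0.05, 0.01, c("Hb G-Coushatta" = 2.18), cut)$category,
               "normal")
  # "> 0" variants fire on any positive ratio, independent of thalassemia flags
  s <- classify_sample(0.90, 0.01, c("Hb S" = 0.8), cut)
  expect_equal(s$category, "alpha_thalassemia")
  expect_equal(s$variants_detected, "Hb S")
})

test_that("severity bands are monotone in P(alpha)", {
  cut <- default_cutoffs()
  bands <- c(NA, "alpha_plus_range", "alpha0_range", "sea_range", "hbh_range")
  grid <- seq(0.01, 0.99, by = 0.01)
  got <- vapply(grid, function(p) {
    b <- classify_sample(p, 0.01, cutoffs = cut)$severity_band
    match(ifelse(is.na(b), "NA", b), c("NA", bands[-1]))
  }, numeric(1))
  expect_true(all(diff(got) >= 0))
})

test_that("classification depends only on its inputs and behaves at cutoff extremes", {
  cut <- default_cutoffs()
  set.seed(43)
  for (i in 1:25) {
    pa <- runif(1); pb <- runif(1)
    vr <- setNames(runif(2, 0, 3), c("Hb S", "Hb E"))
    c1 <- classify_sample(pa, pb, vr, cut, sample_id = "x")
    c2 <- classify_sample(pa, pb, rev(vr), cut, sample_id = "x")
    expect_equal(c1$category, c2$category)
    expect_setequal(strsplit(c1$variants_detected, ";")[[1]],
                    strsplit(c2$variants_detected, ";")[[1]])
  }
  # near-zero thresholds: every sample screens positive
  lo <- new_cutoffs(1e-9, 1e-9)
  expect_equal(classify_sample(0.01, 0.01, cutoffs = lo)$category,
               "alpha_and_beta_thalassemia")
  # near-one thresholds: non-variant samples are normal
  hi <- new_cutoffs(1 - 1e-9, 1 - 1e-9)
  expect_equal(classify_sample(0.99, 0.99, cutoffs = hi)$category, "normal")
})

test_that("screen_cohort propagates non-evaluable samples and keeps stable order", {
  empty <- screen_cohort(quantify_cohort(core_sample())[0, ])
  expect_equal(nrow(empty$calls), 0)

  tbl <- dplyr::bind_rows(
    core_sample("s2"),
    dplyr::filter(core_sample("s1"), peptide_id != "bT2")
  )
  res <- screen_cohort(quantify_cohort(tbl))
  expect_equal(res$calls$sample_id, c("s1", "s2"))
  expect_equal(res$calls$category[1], "non_evaluable")
  expect_match(res$calls$reasons[1], "bT2")
  expect_false(res$calls$category[2] == "non_evaluable")
  # identical samples produce identical calls
  twin <- dplyr::mutate(core_sample("s3"), sample_id = "s3")
  res2 <- screen_cohort(quantify_cohort(dplyr::bind_rows(core_sample("s2"), twin)))
  expect_equal(res2$calls$category[1], res2$calls$category[2])
  expect_s3_class(autoplot(res2), "ggplot")
})

test_that("cutoff JSON round-trips", {
  cut <- default_cutoffs()
  path <- withr::local_tempfile(fileext = ".json")
  write_cutoffs(cut, path)
  back <- read_cutoffs(path)
  expect_equal(back$p_alpha_screen, cut$p_alpha_screen)
  expect_equal(back$severity_bands, cut$severity_bands)
  expect_equal(back$variant_thresholds, cut$variant_thresholds)
})
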