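test_that("the generator is reproducible from its seed and respects n = 0", {
  spec <- cohort_spec(c(normal = 5, sea_het = 3), seed = 101)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  c <- generate_cohort(cohort_spec(c(normal = 5, sea_het = 3), seed = 102))
  expect_false(identical(a, c))
  empty <- generate_cohort(cohort_spec(c(normal = 0), seed = 1))
  expect_equal(nrow(empty), 0)
  expect_error(cohort_spec(c(normal = 5)), class = "hemoscreen_config_error")
  expect_error(cohort_spec(c(nope = 5), seed = 1),
               class = "hemoscreen_config_error")
})

test_that("noise-free generation reproduces baseline x multiplier ratios exactly", {
  spec <- cohort_spec(c(normal = 1, sea_het = 1, beta0_het = 1),
                      cv = 0, is_cv = 0, seed = 3)
  prof <- quantify_cohort(generate_cohort(spec))
  normal <- prof[prof$genotype == "normal", ]
  expect_equal(normal$aT1_bT1, 4.5, tolerance = 1e-12)
  expect_equal(normal$aT3_bT1, 4.5, tolerance = 1e-12)
  expect_equal(normal$dT2_bT2, 0.04, tolerance = 1e-12)
  expect_equal(normal$zT8_bT2, 0.002, tolerance = 1e-12)
  expect_equal(normal$gT10_aT3, 0.8, tolerance = 1e-12)

  eff <- preset_effects()
  sea <- prof[prof$genotype == "aa/--SEA", ]
  m <- eff$sea_het$multipliers
  expect_equal(sea$aT1_bT1, 4.5 * m[["alpha"]] / m[["beta"]], tolerance = 1e-12)
  expect_equal(sea$zT8_bT2, 0.002 * m[["zeta"]] / m[["beta"]], tolerance = 1e-12)
  b0 <- prof[prof$genotype == "bN/bCodon17", ]
  mb <- eff$beta0_het$multipliers
  expect_equal(b0$dT2_bT2, 0.04 * mb[["delta"]] / mb[["beta"]], tolerance = 1e-12)
})

test_that("presets cover the genotype classes with physiologic directions", {
  eff <- preset_effects()
  expect_true(all(c("normal", "alpha_plus_het", "alpha_plus_homo", "sea_het",
                    "hbh", "beta_plus_het", "beta0_het", "alpha_beta_combined",
                    "hbs_het", "hbe_het", "hbd_het", "hbg_het") %in% names(eff)))
  expect_true(all(eff$normal$multipliers == 1))
  expect_length(eff$normal$variant_fractions, 0)
  # alpha deletions depress alpha and elevate zeta, increasingly with severity
  alphas <- vapply(eff[c("normal", "alpha_plus_het", "sea_het", "hbh")],
                   function(e) e$multipliers[["alpha"]], numeric(1))
  expect_true(all(diff(alphas) < 0))
  zetas <- vapply(eff[c("normal", "alpha_plus_het", "sea_het", "hbh")],
                  function(e) e$multipliers[["zeta"]], numeric(1))
  expect_true(all(diff(zetas) > 0))
  # Hb E carriers are mildly beta-thalassemic with a mutant fraction
  expect_lt(eff$hbe_het$multipliers[["beta"]], 1)
  expect_gt(eff$hbe_het$variant_fractions[["Hb E"]], 0)
})

test_that("beta0 preset drives dT2_bT2 above the normal distribution", {
  spec <- cohort_spec(c(normal = 60, beta0_het = 60), cv = 10, seed = 71)
  prof <- quantify_cohort(generate_cohort(spec))
  d_norm <- prof$dT2_bT2[prof$genotype == "normal"]
  d_b0 <- prof$dT2_bT2[prof$genotype != "normal"]
  expect_gt(min(d_b0), max(d_norm))
})

test_that("P(alpha) medians respect the severity band structure", {
  spec <- cohort_spec(c(normal = 200, sea_het = 200), cv = 10, seed = 73)
  prof <- predict_risk(quantify_cohort(generate_cohort(spec)),
                       default_model("alpha"))
  med_sea <- median(prof$p_alpha[prof$genotype == "aa/--SEA"])
  med_norm <- median(prof$p_alpha[prof$genotype == "normal"])
  expect_gt(med_sea, 0.87)
  expect_lt(med_norm, 0.33)
})

test_that("lowering the alpha multiplier never lowers mean P(alpha)", {
  mults <- c(1, 0.7, 0.5, 0.25)
  means <- vapply(mults, function(m) {
    custom <- list(dose = list(label = "dose",
                               multipliers = c(alpha = m, beta = 1, gamma = 1,
                                               delta = 1, zeta = 1),
                               variant_fractions = c()))
    spec <- cohort_spec(c(dose = 80), cv = 10, seed = 79,
                        custom_effects = custom)
    prof <- predict_risk(quantify_cohort(generate_cohort(spec)),
                         default_model("alpha"))
    mean(prof$p_alpha)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("variant carriers produce detectable mutant peptides, non-carriers do not", {
  spec <- cohort_spec(c(normal = 5, hbs_het = 5, hbg_het = 5), cv = 10, seed = 83)
  prof <- quantify_cohort(generate_cohort(spec))
  vr <- function(row, name) prof$variant_ratios[[row]][[name]]
  for (i in which(prof$genotype == "bN/bHbS")) {
    expect_gt(vr(i, "Hb S"), 0)
  }
  for (i in which(prof$genotype == "normal")) {
    expect_equal(vr(i, "Hb S"), 0)
    expect_equal(vr(i, "Hb G-Coushatta"), 0)
  }
  # Hb G carriers clear the 2.19 screening threshold
  for (i in which(prof$genotype == "bN/bHbG")) {
    expect_gte(vr(i, "Hb G-Coushatta"), 2.19)
  }
})

test_that("truth labels map genotype presets to disease groups", {
  spec <- cohort_spec(c(normal = 1, sea_het = 1, beta0_het = 1,
                        alpha_beta_combined = 1, hbd_het = 1), seed = 89)
  truth <- cohort_truth(generate_cohort(spec))
  got <- setNames(truth$group, truth$genotype)
  expect_equal(unname(got["normal"]), "normal")
  expect_equal(unname(got["aa/--SEA"]), "alpha_thalassemia")
  expect_equal(unname(got["bN/bCodon17"]), "beta_thalassemia")
  expect_equal(unname(got["aa/--SEA;bN/b-28"]), "alpha_and_beta_thalassemia")
  expect_equal(unname(got["bN/bHbD"]), "abnormal_hb")
})
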