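fx <- make_fixture("pravastatin_like")

test_that("a perfusion-limited tissue with zero blood flow is inert", {
  flows <- phys70$tissue_blood_flows_L_per_h
  flows$muscle <- flows$muscle + flows$rest_of_body  # keep cardiac closure
  flows$rest_of_body <- 0
  phys0 <- physiology_spec(70, phys70$tissue_volumes_L, flows)
  res <- local_sensitivity(fx$compound, phys0, fx$regimens$oral,
                           parameter = "Kp_rest_of_body",
                           output = "plasma_conc", window = c(0.5, 6),
                           time_step = 0.5, rel_tol = 1e-8, abs_tol = 1e-10)
  expect_true(all(abs(res$coefficients$coefficient) < 1e-6))
})

test_that("forward 1% coefficients match a 0.1% central-difference oracle", {
  # two parameters the plasma trace is strongly sensitive to
  for (par in c("CL_act_tot", "fu_p")) {
    fwd <- local_sensitivity(fx$compound, phys70, fx$regimens$oral_genotyped,
                             parameter = par, window = c(0.5, 8),
                             time_step = 0.5)
    ctr <- local_sensitivity(fx$compound, phys70, fx$regimens$oral_genotyped,
                             parameter = par, window = c(0.5, 8),
                             time_step = 0.5, perturbation = 0.001,
                             method = "central")
    flagged <- which(fwd$coefficients$flagged)
    expect_gt(length(flagged), 0)
    rel <- abs(fwd$coefficients$coefficient[flagged] /
                 ctr$coefficients$coefficient[flagged] - 1)
    expect_lt(max(rel), 0.01)
  }
})

test_that("normalized coefficients are dose-invariant (linear model)", {
  s1 <- local_sensitivity(fx$compound, phys70, dose_regimen("oral", 40),
                          parameter = "CL_bile", window = c(0.5, 8),
                          time_step = 1)
  s2 <- local_sensitivity(fx$compound, phys70, dose_regimen("oral", 80),
                          parameter = "CL_bile", window = c(0.5, 8),
                          time_step = 1)
  expect_equal(s1$coefficients$coefficient, s2$coefficients$coefficient,
               tolerance = 1e-6)
})

test_that("forward differences converge to the central oracle as the step shrinks", {
  ctr <- local_sensitivity(fx$compound, phys70, fx$regimens$oral_genotyped,
                           parameter = "CL_act_tot", output = "AUC_plasma",
                           window = c(0, 8), perturbation = 0.001,
                           method = "central")$coefficients$coefficient
  errs <- vapply(c(0.01, 0.005, 0.0025), function(h) {
    fwd <- local_sensitivity(fx$compound, phys70, fx$regimens$oral_genotyped,
                             parameter = "CL_act_tot", output = "AUC_plasma",
                             window = c(0, 8),
                             perturbation = h)$coefficients$coefficient
    abs(fwd - ctr)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))       # Richardson-style decrease
})

test_that("zero-valued parameters demand an absolute step", {
  cmp <- fx$compound
  cmp$CL_renal_L_per_h <- 0
  expect_error(local_sensitivity(cmp, phys70, fx$regimens$oral,
                                 parameter = "CL_renal",
                                 window = c(1, 4), time_step = 1),
               "absolute_step")
  res <- local_sensitivity(cmp, phys70, fx$regimens$oral,
                           parameter = "CL_renal", window = c(1, 4),
                           time_step = 1, absolute_step = 0.1)
  expect_true(all(is.finite(res$coefficients$coefficient)))
})

test_that("clearance-algebra sensitivities reproduce the analytic pattern", {
  sp <- fx$genotype
  # f = 0: no OATP1B1 contribution, all coefficients vanish
  tab0 <- invitro_ratio_sensitivity(sp, CL_act_tot = 90, f_grid = 0,
                                    target_ratio = "ratio_15")
  expect_true(all(tab0$coefficient == 0))

  # single-haplotype population: the *1b ratio never enters the weighting
  single <- genotype_spec(c(star1a = 1, star1b = 0, star15 = 0),
                          0.81, 0.35, 2, 1, f_OATP1B1 = 0.83)
  tab1 <- invitro_ratio_sensitivity(single, CL_act_tot = 90, f_grid = 0.83,
                                    target_ratio = "ratio_1b")
  expect_equal(tab1$coefficient[tab1$variant == "star1a"], 0,
               tolerance = 1e-12)

  # pravastatin preset at f = 0.83: only *15 is sensitive to the *15 ratio
  tab <- invitro_ratio_sensitivity(sp, CL_act_tot = 90, f_grid = 0.83,
                                   target_ratio = "ratio_15")
  s <- setNames(tab$coefficient, tab$variant)
  expect_gt(abs(s[["star15"]]), 0.1)
  expect_lt(abs(s[["star1a"]]), 0.1)
  expect_lt(abs(s[["star1b"]]), 0.1)
  expect_identical(tab$flagged, abs(tab$coefficient) >= 0.1)
})

test_that("coefficient magnitudes grow with the OATP1B1 fraction", {
  sp <- fx$genotype
  for (target in c("ratio_1b", "ratio_15")) {
    tab <- invitro_ratio_sensitivity(sp, CL_act_tot = 90,
                                     f_grid = seq(0.2, 1, 0.1),
                                     target_ratio = target)
    for (v in unique(tab$variant)) {
      s <- abs(tab$coefficient[tab$variant == v])
      expect_true(all(diff(s) > -1e-12))
    }
  }
})

test_that("the frequency-weighted OATP1B1 perturbation sums to zero", {
  # the population mean is held fixed, so frequency-weighted changes in the
  # per-variant OATP1B1 clearances cancel exactly
  sp <- fx$genotype
  f <- 0.7
  parts <- split_uptake(90, f)
  base <- variant_clearances(parts$CL_act_OATP1B1, sp,
                             parts$CL_act_other)
  sp2 <- sp
  sp2$activity_ratio_15 <- sp$activity_ratio_15 * 1.01
  pert <- variant_clearances(parts$CL_act_OATP1B1, sp2,
                             parts$CL_act_other)
  delta <- pert$CL_act_OATP1B1 - base$CL_act_OATP1B1
  expect_lt(abs(sum(sp$frequencies[names(delta)] * delta)), 1e-12 * 90)
})

test_that("ratio scenarios order the *15 profile and collapse at ratio 1", {
  grid <- seq(0, 24, 0.5)
  scen <- ratio_scenario_profiles(fx$compound, phys70, fx$genotype,
                                  fx$regimens$oral_genotyped,
                                  ratio_15_values = c(0.2, 0.5), grid)
  expect_gt(plasma_auc(scen[["0.2"]]$star15),
            plasma_auc(scen[["0.5"]]$star15))
  expect_length(attr(scen, "reweighting"), 2)

  # singleton set reproduces the direct per-genotype prediction
  one <- ratio_scenario_profiles(fx$compound, phys70, fx$genotype,
                                 fx$regimens$oral_genotyped,
                                 ratio_15_values = 0.35, grid)
  direct <- predict_genotype_profiles(fx$compound, phys70, fx$genotype,
                                      fx$regimens$oral_genotyped, grid)
  expect_identical(one[["0.35"]]$star15$plasma_ng_per_mL,
                   direct$star15$plasma_ng_per_mL)

  # ratio 1 with unit expression collapses *15 onto *1a
  sp1 <- fx$genotype
  sp1$expression_mult_15 <- 1
  coll <- ratio_scenario_profiles(fx$compound, phys70, sp1,
                                  fx$regimens$oral_genotyped,
                                  ratio_15_values = 1, grid)
  expect_identical(coll[["1"]]$star15$plasma_ng_per_mL,
                   coll[["1"]]$star1a$plasma_ng_per_mL)
})

test_that("degenerate sensitivity inputs raise errors", {
  expect_error(invitro_ratio_sensitivity(fx$genotype, 90,
                                         f_grid = numeric(0)),
               "empty")
  expect_error(invitro_ratio_sensitivity(fx$genotype, 90, f_grid = 1.2),
               "\\[0, 1\\]")
  expect_error(ratio_scenario_profiles(fx$compound, phys70, fx$genotype,
                                       fx$regimens$oral, -0.2,
                                       seq(0, 4, 1)),
               "> 0")
  expect_error(local_sensitivity(fx$compound, phys70, fx$regimens$oral,
                                 parameter = "CL_metabolic",
                                 window = c(0, 4)),
               "unknown parameter")
})
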