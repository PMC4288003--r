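prava_spec <- make_fixture("pravastatin_like")$genotype

test_that("split_uptake partitions the total exactly", {
  expect_equal(split_uptake(100, 0.83),
               list(CL_act_OATP1B1 = 83, CL_act_other = 17))
  expect_equal(split_uptake(7.3, 1), list(CL_act_OATP1B1 = 7.3,
                                          CL_act_other = 0))
  expect_equal(split_uptake(50, 0.5), list(CL_act_OATP1B1 = 25,
                                           CL_act_other = 25))
  expect_error(split_uptake(10, 1.2), "\\[0, 1\\]")
  expect_error(split_uptake(-1, 0.5), ">= 0")
})

test_that("two-stage pathway fractions multiply", {
  f <- oatp1b1_fraction_from_pathways(0.35, 0.77)
  expect_equal(f, 0.5005)
  expect_equal(round(100 * f), 50)      # printed as 50%
  expect_equal(oatp1b1_fraction_from_pathways(0, 1), 1)
  expect_equal(oatp1b1_fraction_from_pathways(1, 0.77), 0)
  expect_error(oatp1b1_fraction_from_pathways(-0.1, 0.5), "\\[0, 1\\]")
})

test_that("variant clearances reproduce the hand-computed weighting", {
  # ratios 0.81/0.35, expression 2/1, frequencies 0.56/0.26/0.18:
  # weight = 0.56 + 0.26*1.62 + 0.18*0.35 = 1.0442
  vs <- variant_clearances(83, prava_spec)
  w <- 0.56 + 0.26 * 1.62 + 0.18 * 0.35
  expect_equal(w, 1.0442)
  expect_equal(unname(vs$CL_act_OATP1B1[["star1a"]]), 83 / 1.0442)
  expect_equal(unname(vs$CL_act_OATP1B1[["star1b"]]), 1.62 * 83 / 1.0442)
  expect_equal(unname(vs$CL_act_OATP1B1[["star15"]]), 0.35 * 83 / 1.0442)
})

test_that("degenerate and identity populations behave", {
  ident <- genotype_spec(c(star1a = 0.2, star1b = 0.5, star15 = 0.3),
                         1, 1, 1, 1, f_OATP1B1 = 0.5)
  vs <- variant_clearances(42, ident)
  expect_true(all(vs$CL_act_OATP1B1 == 42))

  single <- genotype_spec(c(star1a = 1, star1b = 0, star15 = 0),
                          0.81, 0.35, 2, 1, f_OATP1B1 = 0.83)
  vs1 <- variant_clearances(83, single)
  expect_equal(unname(vs1$CL_act_OATP1B1[["star1a"]]), 83)
})

test_that("population-weighted mean of variant clearances is closed", {
  set.seed(101)
  for (i in 1:200) {
    sp <- random_genotype_spec()
    mean_cl <- runif(1, 0.1, 500)
    vs <- variant_clearances(mean_cl, sp)
    recon <- sum(sp$frequencies[names(vs$CL_act_OATP1B1)] *
                   vs$CL_act_OATP1B1)
    expect_lt(abs(recon / mean_cl - 1), 1e-12)
  }
})

test_that("genotyped totals add the shared non-OATP1B1 component", {
  vs <- variant_clearances(83, prava_spec, CL_act_other = 17)
  tot <- genotyped_total(vs)
  expect_equal(unname(tot - vs$CL_act_OATP1B1),
               rep(17, 3), ignore_attr = TRUE)

  vs0 <- variant_clearances(83, prava_spec, CL_act_other = 0)
  expect_equal(genotyped_total(vs0), vs0$CL_act_OATP1B1)

  # a c.521T>C-insensitive compound: *15 total equals *1a total exactly
  sp <- prava_spec
  sp$activity_ratio_15 <- 1
  sp$expression_mult_15 <- 1
  tot_f <- genotyped_total(variant_clearances(50, sp, CL_act_other = 11))
  expect_identical(tot_f[["star15"]], tot_f[["star1a"]])
})

test_that("ethnic scaling multiplies every active uptake entry", {
  vs <- variant_clearances(83, prava_spec, CL_act_other = 17)
  ja <- apply_ethnic_scaling(vs, 0.584)
  expect_equal(ja$CL_act_OATP1B1, 0.584 * vs$CL_act_OATP1B1)
  expect_equal(ja$CL_act_other, 0.584 * 17)
  expect_equal(ja$CL_act_tot, 0.584 * vs$CL_act_tot)
  expect_equal(apply_ethnic_scaling(vs, 1), vs)
  lo <- apply_ethnic_scaling(vs, 0.3)
  expect_equal(lo$CL_act_OATP1B1[["star1a"]],
               0.3 * vs$CL_act_OATP1B1[["star1a"]])
  expect_error(apply_ethnic_scaling(vs, 0), "> 0")
})

test_that("ethnic scaling commutes with the variant algebra", {
  set.seed(202)
  for (i in 1:25) {
    sp <- random_genotype_spec()
    mean_cl <- runif(1, 1, 100)
    other <- runif(1, 0, 50)
    a <- apply_ethnic_scaling(variant_clearances(mean_cl, sp, other), 0.584)
    b <- variant_clearances(0.584 * mean_cl, sp, 0.584 * other)
    expect_equal(a$CL_act_tot, b$CL_act_tot, tolerance = 1e-12)
  }
})

test_that("effective-ratio order carries over to total clearances", {
  sp <- prava_spec                 # effective ratios 1.62 > 1 > 0.35
  tot <- genotyped_total(genotype_clearances(
    make_fixture("pravastatin_like")$compound, sp))
  expect_gt(tot[["star1b"]], tot[["star1a"]])
  expect_gt(tot[["star1a"]], tot[["star15"]])
})

test_that("per-genotype profiles follow the clearance substitution", {
  fx <- make_fixture("fluvastatin_like")
  profs <- predict_genotype_profiles(fx$compound, phys70, fx$genotype,
                                     fx$regimens$oral_genotyped,
                                     seq(0, 24, 0.25))
  # ratio_15 = 1, mult_15 = 1: *15 and *1a pointwise identical
  expect_identical(profs$star15$plasma_ng_per_mL,
                   profs$star1a$plasma_ng_per_mL)

  fxp <- make_fixture("pravastatin_like")
  profs_p <- predict_genotype_profiles(fxp$compound, phys70, fxp$genotype,
                                       fxp$regimens$oral_genotyped,
                                       seq(0, 24, 0.25))
  expect_gt(plasma_auc(profs_p$star15), plasma_auc(profs_p$star1a))

  # a single-haplotype population reproduces the nongenotyped profile
  single <- genotype_spec(c(star1a = 1, star1b = 0, star15 = 0),
                          0.81, 0.35, 2, 1, f_OATP1B1 = 0.83)
  profs_s <- predict_genotype_profiles(fxp$compound, phys70, single,
                                       fxp$regimens$oral_genotyped,
                                       seq(0, 24, 0.25))
  base <- simulate_pbpk(fxp$compound, phys70, fxp$regimens$oral_genotyped,
                        seq(0, 24, 0.25))
  expect_equal(profs_s$star1a$plasma_ng_per_mL, base$plasma_ng_per_mL,
               tolerance = 1e-12)
})

test_that("c.521 labels map onto haplotype groups", {
  expect_identical(relabel_c521(c("c.521TT", "c.521CC")),
                   c("star1a", "star15"))
  expect_error(relabel_c521("c.521TC"), "c.521TC")
})
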