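#' Fixture compounds, genotype presets and default dosing regimens
#'
#' Returns a fully populated compound/genotype/regimen triple for one of
#' three statin-like fixtures.  The genotype constants (OATP1B1 fraction,
#' intrinsic activity ratios, expression multipliers, haplotype frequencies)
#' are the published in vitro and population values; the compound clearance
#' and partition magnitudes are documented implementation fixtures chosen to
#' give realistic profile shapes (pravastatin-like tmax about 1 h with
#' substantial renal clearance, rosuvastatin-like tmax about 3-4 h with
#' dominant biliary clearance, fluvastatin-like with a c.521T>C-insensitive
#' OATP1B1 activity), not reproductions of any fitted table.
#'
#' * `pravastatin_like`: f_OATP1B1 = 0.83, activity ratios 0.81 (*1b) and
#'   0.35 (*15), expression 2/1, frequencies 0.56/0.26/0.18; IV 9.9 mg,
#'   oral 19.2 mg (genotyped studies use 40 mg oral).
#' * `rosuvastatin_like`: f_OATP1B1 = (1 - 0.35) x 0.77 = 0.5005 (35% NTCP,
#'   77% of the remainder OATP1B1), ratios 0.82/0.15, expression 2/1;
#'   IV 8 mg, oral 40 mg (genotyped studies use 10 mg oral).
#' * `fluvastatin_like`: activity ratio and expression of *15 both 1, so the
#'   c.521T>C polymorphism leaves the hepatic clearance unchanged.
#'
#' @param name one of `"pravastatin_like"`, `"rosuvastatin_like"`,
#'   `"fluvastatin_like"`.
#' @return List with `compound` ([compound_spec()]), `genotype`
#'   ([genotype_spec()]), and `regimens` (list of [dose_regimen()]: `iv`,
#'   `oral`, and `oral_genotyped` where the genotyped study dose differs).
#' @export
make_fixture <- function(name = c("pravastatin_like", "rosuvastatin_like",
                                  "fluvastatin_like")) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("make_fixture: unknown fixture '", name[1],
         "'; choose one of pravastatin_like, rosuvastatin_like, ",
         "fluvastatin_like", call. = FALSE))
  euro_freq <- c(star1a = 0.56, star1b = 0.26, star15 = 0.18)
  # hydrophilic-acid pattern: low adipose, modest muscle, kidney-enriched
  kp_prava <- list(lung = 0.4, gut = 1.1, spleen = 0.7, kidney = 2,
                   rest_of_body = 1.5, muscle = 0.6, adipose = 0.15)
  # larger distribution volume pattern for the slow-absorbing fixture
  kp_rosu <- list(lung = 0.8, gut = 2, spleen = 1, kidney = 3,
                  rest_of_body = 3, muscle = 2.5, adipose = 0.4)
  kp_fluva <- list(lung = 0.4, gut = 1.1, spleen = 0.7, kidney = 2,
                   rest_of_body = 0.5, muscle = 0.4, adipose = 0.15)
  switch(name,
    pravastatin_like = list(
      compound = compound_spec(
        name = "pravastatin_like",
        fu_p = 0.5, RB_P = 0.55, fu_liver = 0.2,
        CL_renal_L_per_h = 22,
        CL_act_tot_L_per_h = 90,
        CL_bile_L_per_h = 30,
        CL_pass_liver_L_per_h = 4,
        pass_ratio_muscle = 2, pass_ratio_adipose = 1,
        ka_per_h = 0.5, FaFg = 0.46,
        Kp = kp_prava
      ),
      genotype = genotype_spec(
        frequencies = euro_freq,
        activity_ratio_1b = 0.81, activity_ratio_15 = 0.35,
        expression_mult_1b = 2, expression_mult_15 = 1,
        f_OATP1B1 = 0.83
      ),
      regimens = list(
        iv = dose_regimen("iv_infusion", dose_mg = 9.9,
                          infusion_duration_h = 0.5),
        oral = dose_regimen("oral", dose_mg = 19.2),
        oral_genotyped = dose_regimen("oral", dose_mg = 40)
      )
    ),
    rosuvastatin_like = list(
      compound = compound_spec(
        name = "rosuvastatin_like",
        fu_p = 0.12, RB_P = 0.69, fu_liver = 0.1,
        CL_renal_L_per_h = 10,
        CL_act_tot_L_per_h = 300,
        CL_bile_L_per_h = 120,
        CL_pass_liver_L_per_h = 12,
        pass_ratio_muscle = 2, pass_ratio_adipose = 1,
        ka_per_h = 0.12, FaFg = 0.5,
        Kp = kp_rosu
      ),
      genotype = genotype_spec(
        frequencies = euro_freq,
        activity_ratio_1b = 0.82, activity_ratio_15 = 0.15,
        expression_mult_1b = 2, expression_mult_15 = 1,
        f_OATP1B1 = oatp1b1_fraction_from_pathways(0.35, 0.77)
      ),
      regimens = list(
        iv = dose_regimen("iv_infusion", dose_mg = 8,
                          infusion_duration_h = 0.5),
        oral = dose_regimen("oral", dose_mg = 40),
        oral_genotyped = dose_regimen("oral", dose_mg = 10)
      )
    ),
    fluvastatin_like = list(
      compound = compound_spec(
        name = "fluvastatin_like",
        fu_p = 0.01, RB_P = 0.6, fu_liver = 0.02,
        CL_renal_L_per_h = 0.1,
        CL_act_tot_L_per_h = 4000,
        CL_bile_L_per_h = 900,
        CL_pass_liver_L_per_h = 150,
        pass_ratio_muscle = 2, pass_ratio_adipose = 1,
        ka_per_h = 2, FaFg = 0.9,
        Kp = kp_fluva
      ),
      genotype = genotype_spec(
        frequencies = euro_freq,
        activity_ratio_1b = 1, activity_ratio_15 = 1,
        expression_mult_1b = 2, expression_mult_15 = 1,
        f_OATP1B1 = 0.5
      ),
      regimens = list(
        iv = dose_regimen("iv_infusion", dose_mg = 2,
                          infusion_duration_h = 0.5),
        oral = dose_regimen("oral", dose_mg = 40),
        oral_genotyped = dose_regimen("oral", dose_mg = 40)
      )
    )
  )
}

#' Ethnic OATP1B1 activity scalar presets
#'
#' The published intrinsic OATP1B1 activity ratio of Japanese relative to
#' Caucasian populations is 0.584 (applied to all active uptake clearances);
#' an exploratory rosuvastatin value of 0.3 has also been discussed.
#'
#' @param population `"japanese"` or `"japanese_rosuvastatin_exploratory"`.
#' @return Numeric scalar.
#' @export
ethnic_scalar_preset <- function(population = c("japanese",
                                 "japanese_rosuvastatin_exploratory")) {
  population <- match.arg(population)
  switch(population,
         japanese = 0.584,
         japanese_rosuvastatin_exploratory = 0.3)
}

#' Lognormal observation-noise model
#'
#' Multiplicative lognormal noise with `sdlog = cv`, so log-residuals of
#' generated data against the true profile have mean about 0 and standard
#' deviation about `cv`.
#'
#' @param cv coefficient of variation (fraction, >= 0).
#' @param seed integer RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.2, seed = 1L) {
  if (!is.finite(cv) || cv < 0)
    stop("noise_model: cv must be >= 0", call. = FALSE)
  structure(list(kind = "lognormal_cv", cv = cv, seed = as.integer(seed)),
            class = "noise_model")
}

#' Concentration-time series container
#'
#' @param times_h observation times (h), strictly increasing.
#' @param conc_ng_per_mL concentrations (ng/mL), >= 0.
#' @param sd_ng_per_mL optional per-time standard deviations.
#' @param regimen the [dose_regimen()] that produced the profile.
#' @param label study/arm identifier.
#' @param n_subjects optional subject count backing a mean profile.
#' @return An object of class `conc_time_series`.
#' @export
conc_time_series <- function(times_h, conc_ng_per_mL, sd_ng_per_mL = NULL,
                             regimen, label = "", n_subjects = NULL) {
  times_h <- as.numeric(times_h)
  conc_ng_per_mL <- as.numeric(conc_ng_per_mL)
  if (length(times_h) != length(conc_ng_per_mL))
    stop("conc_time_series: times and concentrations differ in length",
         call. = FALSE)
  if (any(diff(times_h) <= 0))
    stop("conc_time_series: times must be strictly increasing", call. = FALSE)
  if (any(conc_ng_per_mL < 0))
    stop("conc_time_series: concentrations must be >= 0", call. = FALSE)
  if (!is.null(sd_ng_per_mL) && length(sd_ng_per_mL) != length(times_h))
    stop("conc_time_series: sd length mismatch", call. = FALSE)
  structure(list(times_h = times_h, conc_ng_per_mL = conc_ng_per_mL,
                 sd_ng_per_mL = sd_ng_per_mL, regimen = regimen,
                 label = label, n_subjects = n_subjects),
            class = "conc_time_series")
}

#' @export
print.conc_time_series <- function(x, ...) {
  cat("<conc_time_series> ", x$label, ": ", length(x$times_h), " points, ",
      x$regimen$route, " ", x$regimen$dose_mg, " mg\n", sep = "")
  invisible(x)
}

#' Generate a noisy synthetic concentration-time dataset
#'
#' Simulates the true profile, draws `n_replicates` multiplicative
#' lognormal-noised copies per time point (seeded), and returns the per-time
#' mean and standard deviation as a mean +/- SD profile, emulating a digitized
#' mean study profile.  With `cv = 0` the output equals the model prediction
#' with zero SD.
#'
#' @inheritParams simulate_pbpk
#' @param sampling_times_h observation times (h), all > the dose start (or
#'   within the infusion) so concentrations are positive.
#' @param noise a [noise_model()].
#' @param n_replicates number of noised replicate profiles averaged.
#' @param label study/arm identifier.
#' @return A [conc_time_series()].
#' @export
generate_dataset <- function(compound, physiology, regimen, sampling_times_h,
                             noise = noise_model(cv = 0.2),
                             n_replicates = 12, label = compound$name,
                             rel_tol = 1e-8, abs_tol = 1e-10) {
  grid <- sort(unique(c(regimen$start_time_h, sampling_times_h)))
  if (grid[1] > 0) grid <- c(0, grid)
  sim <- simulate_pbpk(compound, physiology, regimen, grid,
                       rel_tol = rel_tol, abs_tol = abs_tol)
  truth <- sim$plasma_ng_per_mL[match(sampling_times_h, sim$time_h)]
  if (noise$cv == 0) {
    return(conc_time_series(sampling_times_h, truth,
                            sd_ng_per_mL = rep(0, length(truth)),
                            regimen = regimen, label = label,
                            n_subjects = n_replicates))
  }
  reps <- with_preserved_seed(noise$seed, {
    matrix(truth, nrow = n_replicates, ncol = length(truth), byrow = TRUE) *
      matrix(rlnorm(n_replicates * length(truth), meanlog = 0,
                    sdlog = noise$cv),
             nrow = n_replicates)
  })
  conc_time_series(sampling_times_h, colMeans(reps),
                   sd_ng_per_mL = apply(reps, 2, sd),
                   regimen = regimen, label = label,
                   n_subjects = n_replicates)
}

#' Generate a genotype-stratified synthetic cohort
#'
#' Applies [predict_genotype_profiles()] and then per-group noising,
#' emulating genotype-stratified mean study profiles.
#'
#' @inheritParams generate_dataset
#' @param spec a [genotype_spec()].
#' @param n_per_group subjects per genotype group.
#' @return Named list (star1a, star1b, star15) of [conc_time_series()].
#' @export
generate_genotyped_cohort <- function(compound, physiology, spec, regimen,
                                      sampling_times_h,
                                      noise = noise_model(cv = 0.2),
                                      n_per_group = 8,
                                      rel_tol = 1e-8, abs_tol = 1e-10) {
  totals <- genotyped_total(genotype_clearances(compound, spec))
  out <- lapply(seq_along(VARIANTS), function(i) {
    v <- VARIANTS[i]
    cmp <- compound
    cmp$CL_act_tot_L_per_h <- totals[[v]]
    grp_noise <- noise
    grp_noise$seed <- noise$seed + i - 1L   # independent noise per group
    generate_dataset(cmp, physiology, regimen, sampling_times_h,
                     noise = grp_noise, n_replicates = n_per_group,
                     label = paste0(compound$name, "_", v),
                     rel_tol = rel_tol, abs_tol = abs_tol)
  })
  names(out) <- VARIANTS
  out
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
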