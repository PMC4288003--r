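SENSITIVITY_PARAMETERS <- c("fu_p", "RB_P", "fu_liver", "CL_renal",
                            "CL_act_tot", "CL_bile", "CL_pass_liver",
                            "ka", "FaFg",
                            "Kp_lung", "Kp_gut", "Kp_spleen", "Kp_kidney",
                            "Kp_rest_of_body", "Kp_muscle", "Kp_adipose")

sens_field <- function(parameter) {
  core <- c(fu_p = "fu_p", RB_P = "RB_P", fu_liver = "fu_liver",
            CL_renal = "CL_renal_L_per_h", CL_act_tot = "CL_act_tot_L_per_h",
            CL_bile = "CL_bile_L_per_h", CL_pass_liver = "CL_pass_liver_L_per_h",
            ka = "ka_per_h", FaFg = "FaFg")
  if (parameter %in% names(core))
    list(get = function(cmp) cmp[[core[[parameter]]]],
         set = function(cmp, v) { cmp[[core[[parameter]]]] <- v; cmp })
  else if (startsWith(parameter, "Kp_")) {
    tissue <- sub("^Kp_", "", parameter)
    if (!tissue %in% KP_TISSUES)
      stop("unknown Kp tissue: ", tissue, call. = FALSE)
    list(get = function(cmp) cmp$Kp[[tissue]],
         set = function(cmp, v) { cmp$Kp[[tissue]] <- v; cmp })
  } else
    stop("unknown parameter '", parameter, "'; choose one of ",
         paste(SENSITIVITY_PARAMETERS, collapse = ", "), call. = FALSE)
}

#' Local sensitivity of model outputs to a compound parameter
#'
#' Perturbs one compound-specific parameter by a relative step (default 1%),
#' re-simulates, and reports normalized sensitivity coefficients
#' `S(t) = [(y'(t) - y(t)) / y(t)] / step` — normalized to both the
#' parameter and the output, hence dimensionless.  For the `AUC_plasma`
#' output a single scalar is returned.  Output times where the unperturbed
#' output is zero yield `NA` coefficients (marked, not errors).
#' Coefficients with `|S|` at or above the flag threshold (default 0.3) are
#' flagged.
#'
#' @inheritParams simulate_pbpk
#' @param parameter one of fu_p, RB_P, fu_liver, CL_renal, CL_act_tot, CL_bile, CL_pass_liver, ka, FaFg, or Kp_<tissue>.
#' @param output `"plasma_conc"`, `"liver_conc"` or `"AUC_plasma"`.
#' @param window `c(t_start, t_end)` (h) over which the output is evaluated
#'   (e.g. up to 8 h for a pravastatin-like, 24 h for a rosuvastatin-like
#'   compound).
#' @param perturbation relative step (> 0, default 0.01).
#' @param method `"forward"` (default, matches the 1%-raise convention) or
#'   `"central"`.
#' @param time_step output grid spacing within the window (h).
#' @param flag_threshold |S| flagging threshold.
#' @param absolute_step optional absolute step to use when the nominal
#'   parameter value is zero (a relative step is undefined there).
#' @return An object of class `sensitivity_result`: `parameter`, `output`,
#'   `perturbation`, `coefficients` (data.frame `time_h`, `coefficient`,
#'   `flagged`, or a single scalar row with `time_h = NA` for AUC),
#'   `flag_threshold`.
#' @export
local_sensitivity <- function(compound, physiology, regimen, parameter,
                              output = c("plasma_conc", "liver_conc",
                                         "AUC_plasma"),
                              window = c(0, 24), perturbation = 0.01,
                              method = c("forward", "central"),
                              time_step = 0.1, flag_threshold = 0.3,
                              rel_tol = 1e-10, abs_tol = 1e-12,
                              absolute_step = NULL) {
  output <- match.arg(output)
  method <- match.arg(method)
  if (perturbation <= 0)
    stop("local_sensitivity: perturbation must be > 0", call. = FALSE)
  acc <- sens_field(parameter)
  p0 <- acc$get(compound)
  if (p0 == 0 && is.null(absolute_step))
    stop("local_sensitivity: parameter '", parameter, "' is zero; a ",
         "relative step is undefined - supply absolute_step to use an ",
         "absolute-step perturbation", call. = FALSE)

  grid <- seq(window[1], window[2], by = time_step)
  if (grid[length(grid)] < window[2]) grid <- c(grid, window[2])
  sim_grid <- sort(unique(c(0, regimen$start_time_h, grid)))

  run <- function(cmp) {
    sim <- simulate_pbpk(cmp, physiology, regimen, sim_grid,
                         rel_tol = rel_tol, abs_tol = abs_tol)
    if (output == "AUC_plasma")
      pk_metrics(sim, window[1], window[2], trace = "plasma")$AUC
    else {
      trace <- if (output == "plasma_conc") sim$plasma_ng_per_mL
               else sim$liver_ng_per_mL
      trace[match(grid, sim$time_h)]
    }
  }
  step_abs <- if (p0 == 0) absolute_step else perturbation * p0
  denom_rel <- if (p0 == 0) 1 else perturbation  # absolute mode: dS per unit

  y0 <- run(compound)
  if (method == "forward") {
    y_up <- run(acc$set(compound, p0 + step_abs))
    coef <- (y_up - y0) / y0 / denom_rel
  } else {
    y_up <- run(acc$set(compound, p0 + step_abs))
    y_dn <- run(acc$set(compound, p0 - step_abs))
    coef <- (y_up - y_dn) / y0 / (2 * denom_rel)
  }
  coef[!is.finite(coef)] <- NA_real_

  df <- if (output == "AUC_plasma")
    data.frame(time_h = NA_real_, coefficient = coef)
  else
    data.frame(time_h = grid, coefficient = coef)
  df$flagged <- !is.na(df$coefficient) &
    abs(df$coefficient) >= flag_threshold
  structure(list(parameter = parameter, output = output,
                 perturbation = perturbation, method = method,
                 coefficients = df, flag_threshold = flag_threshold),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> d", x$output, " / d", x$parameter,
      " (", x$method, ", step ", x$perturbation * 100, "%)\n", sep = "")
  co <- x$coefficients$coefficient
  if (nrow(x$coefficients) == 1)
    cat("  S =", signif(co, 4), "\n")
  else
    cat("  |S| max ", signif(max(abs(co), na.rm = TRUE), 4), "; ",
        sum(x$coefficients$flagged), " of ", nrow(x$coefficients),
        " times flagged\n", sep = "")
  invisible(x)
}

#' Sensitivity of genotyped clearances to the in vitro activity ratios
#'
#' Analytic-algebra counterpart of the model sensitivity analysis: for each
#' OATP1B1 fractional contribution on a grid, the intrinsic uptake activity
#' ratio of one variant (*1b or *15) is raised by 1% (expression multiplier
#' unperturbed), the per-variant total clearances are re-derived from the
#' fixed nongenotyped `CL_act_tot` and haplotype frequencies, and the
#' normalized coefficient
#' `S = (CL_act_tot_v' - CL_act_tot_v) / CL_act_tot_v / 0.01` is reported
#' per variant.  Coefficients with `|S| >=` the threshold (default 0.1) are
#' flagged.
#'
#' @param spec a [genotype_spec()] template (its `f_OATP1B1` is overridden
#'   by the grid).
#' @param CL_act_tot nongenotyped total active uptake clearance (L/h); held
#'   fixed, with both OATP1B1 and other components re-derived at each `f`.
#' @param f_grid fractional OATP1B1 contributions, each in `[0, 1]`
#'   (default 0.2 to 1 in steps of 0.1).
#' @param target_ratio `"ratio_1b"` or `"ratio_15"`.
#' @param rel_step relative perturbation (default 0.01).
#' @param flag_threshold |S| flagging threshold (default 0.1).
#' @return data.frame with columns `f`, `variant`, `coefficient`, `flagged`.
#' @note The perturbation targets the intrinsic activity ratio with the
#'   expression multiplier held fixed.  Because the effective per-variant
#'   ratio is the product of the two, a relative step on the intrinsic ratio
#'   and on the effective ratio induce the same relative change, so the two
#'   conventions coincide for this multiplicative perturbation.
#' @export
invitro_ratio_sensitivity <- function(spec, CL_act_tot = 1,
                                      f_grid = seq(0.2, 1, by = 0.1),
                                      target_ratio = c("ratio_1b", "ratio_15"),
                                      rel_step = 0.01, flag_threshold = 0.1) {
  target_ratio <- match.arg(target_ratio)
  validate_genotype_spec(spec)
  if (length(f_grid) == 0)
    stop("invitro_ratio_sensitivity: empty f grid", call. = FALSE)
  if (any(f_grid < 0 | f_grid > 1))
    stop("invitro_ratio_sensitivity: f values must be in [0, 1]",
         call. = FALSE)
  field <- if (target_ratio == "ratio_1b") "activity_ratio_1b"
           else "activity_ratio_15"
  totals_at <- function(sp, f) {
    parts <- split_uptake(CL_act_tot, f)
    genotyped_total(variant_clearances(parts$CL_act_OATP1B1, sp,
                                       CL_act_other = parts$CL_act_other))
  }
  rows <- lapply(f_grid, function(f) {
    base <- totals_at(spec, f)
    sp2 <- spec
    sp2[[field]] <- spec[[field]] * (1 + rel_step)
    pert <- totals_at(sp2, f)
    coef <- (pert - base) / base / rel_step
    data.frame(f = f, variant = VARIANTS, coefficient = unname(coef))
  })
  out <- do.call(rbind, rows)
  out$flagged <- abs(out$coefficient) >= flag_threshold
  out
}

#' Genotype profiles across in vitro *1a:*15 activity-ratio scenarios
#'
#' Regenerates the genotype clearances and simulates per-variant profiles
#' for each candidate *15 intrinsic activity ratio (e.g. the two
#' literature-reported pravastatin values 0.20 and 0.50).  The *1a and *1b
#' profiles differ across ratio values only through the population-mean
#' reweighting, which is reported.
#'
#' @inheritParams predict_genotype_profiles
#' @param ratio_15_values positive *15 intrinsic activity ratios.
#' @return List with one element per ratio value (named by the value), each
#'   a named list of per-variant [simulate_pbpk()] results, plus attribute
#'   `"reweighting"`: the per-ratio *1a total clearances showing the (small)
#'   reweighting effect.
#' @export
ratio_scenario_profiles <- function(compound, physiology, spec, regimen,
                                    ratio_15_values, time_grid,
                                    rel_tol = 1e-8, abs_tol = 1e-10) {
  if (any(!is.finite(ratio_15_values)) || any(ratio_15_values <= 0))
    stop("ratio_scenario_profiles: ratio values must be > 0", call. = FALSE)
  out <- lapply(ratio_15_values, function(r) {
    sp <- spec
    sp$activity_ratio_15 <- r
    predict_genotype_profiles(compound, physiology, sp, regimen, time_grid,
                              rel_tol = rel_tol, abs_tol = abs_tol)
  })
  names(out) <- as.character(ratio_15_values)
  reweight <- vapply(ratio_15_values, function(r) {
    sp <- spec
    sp$activity_ratio_15 <- r
    genotyped_total(genotype_clearances(compound, sp))[["star1a"]]
  }, numeric(1))
  attr(out, "reweighting") <- setNames(reweight,
                                       as.character(ratio_15_values))
  out
}
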