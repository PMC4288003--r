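NG_PER_MG <- 1e6

#' State names of the PBPK system
#'
#' @param n_sub number of serial liver sub-units.
#' @return Character vector of state (amount) names, in solver order.
#' @keywords internal
pbpk_state_names <- function(n_sub) {
  c("venous_blood", "arterial_blood", "lung", "gut", "spleen", "kidney",
    "rest_of_body", "muscle_ec", "muscle_ic", "adipose_ec", "adipose_ic",
    paste0("liver_blood_", seq_len(n_sub)),
    paste0("liver_tissue_", seq_len(n_sub)),
    "bile", "lumen", "renal_eliminated", "unabsorbed")
}

#' Numeric parameter vector for the compiled right-hand side
#'
#' Flattens a compound/physiology pair (plus infusion inputs) into the fixed
#' parameter layout shared with the compiled model code.
#'
#' @param compound a [compound_spec()].
#' @param physiology a [physiology_spec()].
#' @param infusion_rate_ng_per_h,infusion_start_h,infusion_end_h square-pulse
#'   IV infusion input into venous blood.
#' @return Named numeric vector.
#' @keywords internal
pbpk_parameter_vector <- function(compound, physiology,
                                  infusion_rate_ng_per_h = 0,
                                  infusion_start_h = 0,
                                  infusion_end_h = 0) {
  v <- physiology$tissue_volumes_L
  q <- physiology$tissue_blood_flows_L_per_h
  v_liver <- as.numeric(v$liver)
  c(n_sub = physiology$n_liver_subunits,
    fu_p = compound$fu_p,
    rbp = compound$RB_P,
    fu_liver = compound$fu_liver,
    cl_renal = compound$CL_renal_L_per_h,
    cl_act = compound$CL_act_tot_L_per_h,
    cl_bile = compound$CL_bile_L_per_h,
    cl_pass_liver = compound$CL_pass_liver_L_per_h,
    cl_pass_muscle = compound$pass_ratio_muscle * compound$CL_pass_liver_L_per_h,
    cl_pass_adipose = compound$pass_ratio_adipose * compound$CL_pass_liver_L_per_h,
    ka = compound$ka_per_h,
    fafg = compound$FaFg,
    kp_lung = compound$Kp$lung,
    kp_gut = compound$Kp$gut,
    kp_spleen = compound$Kp$spleen,
    kp_kidney = compound$Kp$kidney,
    kp_rest = compound$Kp$rest_of_body,
    kp_muscle = compound$Kp$muscle,
    kp_adipose = compound$Kp$adipose,
    v_ven = v$venous_blood,
    v_art = v$arterial_blood,
    v_lung = v$lung,
    v_gut = v$gut,
    v_spleen = v$spleen,
    v_kidney = v$kidney,
    v_rest = v$rest_of_body,
    v_mus_ec = physiology$muscle_ec_fraction * v$muscle,
    v_mus_ic = (1 - physiology$muscle_ec_fraction) * v$muscle,
    v_adi_ec = physiology$adipose_ec_fraction * v$adipose,
    v_adi_ic = (1 - physiology$adipose_ec_fraction) * v$adipose,
    v_liv_blood = physiology$liver_blood_fraction * v_liver,
    v_liv_tissue = (1 - physiology$liver_blood_fraction) * v_liver,
    v_bile = physiology$V_bile_L,
    q_co = q$lung,
    q_gut = q$gut,
    q_spleen = q$spleen,
    q_kidney = q$kidney,
    q_rest = q$rest_of_body,
    q_muscle = q$muscle,
    q_adipose = q$adipose,
    q_liver = q$liver,
    q_bile = physiology$Q_liver_bile_L_per_h,
    inf_rate = infusion_rate_ng_per_h,
    inf_start = infusion_start_h,
    inf_end = infusion_end_h)
}

#' Build the PBPK ODE system
#'
#' Validates the compound/physiology pair and returns a model handle holding
#' the parameter layout, state names and a pure-R right-hand-side function
#' with the same equations as the compiled model (used as a cross-check and
#' reference implementation).
#'
#' @inheritParams pbpk_parameter_vector
#' @return An object of class `pbpk_model` with elements `compound`,
#'   `physiology`, `state_names`, `n_states` and `rhs` (an R function
#'   `(t, y, parms)` returning `list(dy)` in deSolve convention).
#' @export
build_pbpk_model <- function(compound, physiology) {
  validate_compound_spec(compound)
  validate_physiology_spec(physiology)
  n <- physiology$n_liver_subunits
  structure(list(
    compound = compound,
    physiology = physiology,
    state_names = pbpk_state_names(n),
    n_states = 15L + 2L * n,
    rhs = pbpk_rhs_r
  ), class = "pbpk_model")
}

# Reference R implementation of the right-hand side (deSolve convention).
# Mirrors src/pbpk.c term by term; kept as the in-package oracle for the
# compiled code and for readers who want the equations in one place.
pbpk_rhs_r <- function(t, y, parms) {
  p <- parms
  n <- as.integer(p[["n_sub"]])
  i_lb <- 12L; i_lt <- 12L + n
  i_bile <- 12L + 2L * n; i_lumen <- i_bile + 1L
  i_renal <- i_bile + 2L; i_unabs <- i_bile + 3L

  c_ven <- y[1] / p[["v_ven"]]; c_art <- y[2] / p[["v_art"]]
  c_lung_out <- y[3] / p[["v_lung"]] * p[["rbp"]] / p[["kp_lung"]]
  c_gut_out <- y[4] / p[["v_gut"]] * p[["rbp"]] / p[["kp_gut"]]
  c_spl_out <- y[5] / p[["v_spleen"]] * p[["rbp"]] / p[["kp_spleen"]]
  c_kid_out <- y[6] / p[["v_kidney"]] * p[["rbp"]] / p[["kp_kidney"]]
  c_rest_out <- y[7] / p[["v_rest"]] * p[["rbp"]] / p[["kp_rest"]]
  c_mus_ec <- y[8] / p[["v_mus_ec"]]; c_mus_ic <- y[9] / p[["v_mus_ic"]]
  c_adi_ec <- y[10] / p[["v_adi_ec"]]; c_adi_ic <- y[11] / p[["v_adi_ic"]]
  c_bile <- y[i_bile] / p[["v_bile"]]
  x_lumen <- y[i_lumen]

  q_ha <- p[["q_liver"]] - p[["q_gut"]] - p[["q_spleen"]]
  infusion <- if (t >= p[["inf_start"]] && t < p[["inf_end"]])
    p[["inf_rate"]] else 0

  mus_in <- p[["cl_pass_muscle"]] * p[["fu_p"]] * c_mus_ec / p[["rbp"]]
  mus_out <- p[["cl_pass_muscle"]] * (p[["fu_p"]] / p[["kp_muscle"]]) * c_mus_ic
  adi_in <- p[["cl_pass_adipose"]] * p[["fu_p"]] * c_adi_ec / p[["rbp"]]
  adi_out <- p[["cl_pass_adipose"]] * (p[["fu_p"]] / p[["kp_adipose"]]) * c_adi_ic

  vlb <- p[["v_liv_blood"]] / n
  vlt <- p[["v_liv_tissue"]] / n
  c_lb <- y[i_lb:(i_lb + n - 1L)] / vlb
  c_lt <- y[i_lt:(i_lt + n - 1L)] / vlt
  upt <- (p[["cl_act"]] + p[["cl_pass_liver"]]) / n * p[["fu_p"]] * c_lb / p[["rbp"]]
  eff <- p[["cl_pass_liver"]] / n * p[["fu_liver"]] * c_lt
  bil <- p[["cl_bile"]] / n * p[["fu_liver"]] * c_lt

  inflow <- c(q_ha * c_art + p[["q_gut"]] * c_gut_out +
                p[["q_spleen"]] * c_spl_out +
                p[["ka"]] * p[["fafg"]] * x_lumen,
              if (n > 1) p[["q_liver"]] * c_lb[-n])

  dy <- numeric(length(y))
  dy[1] <- p[["q_liver"]] * c_lb[n] + p[["q_kidney"]] * c_kid_out +
    p[["q_rest"]] * c_rest_out + p[["q_muscle"]] * c_mus_ec +
    p[["q_adipose"]] * c_adi_ec - p[["q_co"]] * c_ven -
    p[["cl_renal"]] * c_ven / p[["rbp"]] + infusion
  dy[2] <- p[["q_co"]] * c_lung_out -
    (q_ha + p[["q_gut"]] + p[["q_spleen"]] + p[["q_kidney"]] +
       p[["q_rest"]] + p[["q_muscle"]] + p[["q_adipose"]]) * c_art
  dy[3] <- p[["q_co"]] * (c_ven - c_lung_out)
  dy[4] <- p[["q_gut"]] * (c_art - c_gut_out)
  dy[5] <- p[["q_spleen"]] * (c_art - c_spl_out)
  dy[6] <- p[["q_kidney"]] * (c_art - c_kid_out)
  dy[7] <- p[["q_rest"]] * (c_art - c_rest_out)
  dy[8] <- p[["q_muscle"]] * (c_art - c_mus_ec) - mus_in + mus_out
  dy[9] <- mus_in - mus_out
  dy[10] <- p[["q_adipose"]] * (c_art - c_adi_ec) - adi_in + adi_out
  dy[11] <- adi_in - adi_out
  dy[i_lb:(i_lb + n - 1L)] <- inflow - p[["q_liver"]] * c_lb - upt + eff
  dy[i_lt:(i_lt + n - 1L)] <- upt - eff - bil
  dy[i_bile] <- sum(bil) - p[["q_bile"]] * c_bile
  dy[i_lumen] <- p[["q_bile"]] * c_bile - p[["ka"]] * x_lumen
  dy[i_renal] <- p[["cl_renal"]] * c_ven / p[["rbp"]]
  dy[i_unabs] <- p[["ka"]] * (1 - p[["fafg"]]) * x_lumen
  list(dy)
}

#' Simulate the PBPK model
#'
#' Integrates the whole-body system for one dosing regimen with the stiff
#' `lsoda` solver.  The integration is split at input discontinuities
#' (infusion start/end, oral dose time) so each segment has a smooth
#' right-hand side.  Plasma concentration is venous blood concentration
#' divided by the blood:plasma ratio; liver concentration is the
#' volume-weighted mean over the intracellular sub-units.
#'
#' @param compound a [compound_spec()].
#' @param physiology a [physiology_spec()].
#' @param regimen a [dose_regimen()].
#' @param time_grid output times (h), strictly increasing, covering the
#'   dosing events.
#' @param rel_tol,abs_tol solver tolerances (abs_tol in ng).
#' @param use_compiled integrate with the compiled right-hand side (default)
#'   or the reference R implementation.
#' @return An object of class `pbpk_sim`: list with `time_h`,
#'   `plasma_ng_per_mL`, `liver_ng_per_mL`, `state_amounts_ng` (matrix, one
#'   column per compartment), `eliminated_ng` (renal, unabsorbed columns),
#'   `amount_in_body_ng`, `dose_delivered_ng` and the inputs.
#' @export
simulate_pbpk <- function(compound, physiology, regimen, time_grid,
                          rel_tol = 1e-8, abs_tol = 1e-10,
                          use_compiled = TRUE) {
  model <- build_pbpk_model(compound, physiology)
  if (rel_tol <= 0 || abs_tol <= 0)
    stop("simulate_pbpk: tolerances must be > 0", call. = FALSE)
  time_grid <- as.numeric(time_grid)
  if (length(time_grid) < 2 || any(diff(time_grid) <= 0))
    stop("simulate_pbpk: time_grid must be strictly increasing with >= 2 points",
         call. = FALSE)
  if (time_grid[1] > regimen$start_time_h)
    stop("simulate_pbpk: time_grid must start at or before the dosing time",
         call. = FALSE)

  n <- physiology$n_liver_subunits
  nms <- model$state_names
  dose_ng <- regimen$dose_mg * NG_PER_MG

  inf_rate <- 0; inf_start <- 0; inf_end <- 0
  breaks <- numeric(0)
  if (regimen$route == "iv_infusion" && dose_ng > 0) {
    inf_start <- regimen$start_time_h
    inf_end <- regimen$start_time_h + regimen$infusion_duration_h
    inf_rate <- dose_ng / regimen$infusion_duration_h
    breaks <- c(inf_start, inf_end)
  }
  oral_time <- if (regimen$route == "oral" && dose_ng > 0)
    regimen$start_time_h else NULL

  parms <- pbpk_parameter_vector(compound, physiology,
                                 infusion_rate_ng_per_h = inf_rate,
                                 infusion_start_h = inf_start,
                                 infusion_end_h = inf_end)
  y0 <- setNames(numeric(model$n_states), nms)

  t0 <- time_grid[1]
  tend <- time_grid[length(time_grid)]
  breaks <- sort(unique(c(breaks, oral_time)))
  breaks <- breaks[breaks > t0 & breaks < tend]
  seg_bounds <- unique(c(t0, breaks, tend))

  integrate_segment <- function(y, times) {
    if (use_compiled) {
      out <- deSolve::lsoda(y, times, func = "pbpk_derivs", parms = parms,
                            dllname = "oatpbpk", initfunc = "pbpk_initmod",
                            rtol = rel_tol, atol = abs_tol, maxsteps = 50000)
    } else {
      out <- deSolve::lsoda(y, times, func = pbpk_rhs_r, parms = parms,
                            rtol = rel_tol, atol = abs_tol, maxsteps = 50000)
    }
    d <- diagnostics_ok(out, times)
    if (!d$ok)
      stop("simulate_pbpk: integration failed near t = ",
           signif(d$t_fail, 6), " h", call. = FALSE)
    out
  }

  rows <- matrix(y0, nrow = 1,
                 dimnames = list(NULL, nms))
  out_times <- t0
  y <- y0
  if (!is.null(oral_time) && oral_time == t0)
    y["lumen"] <- y["lumen"] + dose_ng
  rows[1, ] <- y
  for (k in seq_len(length(seg_bounds) - 1)) {
    a <- seg_bounds[k]; b <- seg_bounds[k + 1]
    seg_times <- unique(c(a, time_grid[time_grid > a & time_grid <= b], b))
    out <- integrate_segment(y, seg_times)
    y <- out[nrow(out), -1]
    dosed_here <- !is.null(oral_time) && isTRUE(all.equal(b, oral_time))
    if (dosed_here)
      y["lumen"] <- y["lumen"] + dose_ng
    keep <- seg_times %in% time_grid & seg_times > a
    if (any(keep)) {
      block <- out[keep, -1, drop = FALSE]
      if (dosed_here && keep[length(keep)])
        block[nrow(block), ] <- y   # report post-dose state at the dose time
      rows <- rbind(rows, block)
      out_times <- c(out_times, seg_times[keep])
    }
  }
  state <- rows
  rownames(state) <- NULL

  neg_floor <- -(1e3 * abs_tol + rel_tol * max(dose_ng, 1))
  if (min(state) < neg_floor)
    stop("simulate_pbpk: negative state amounts beyond solver tolerance; ",
         "try tighter rel_tol/abs_tol", call. = FALSE)

  v <- physiology$tissue_volumes_L
  v_lt_tot <- (1 - physiology$liver_blood_fraction) * v$liver
  lt_cols <- paste0("liver_tissue_", seq_len(n))
  liver_conc <- rowSums(state[, lt_cols, drop = FALSE]) / v_lt_tot / 1000
  plasma_conc <- state[, "venous_blood"] / v$venous_blood / compound$RB_P / 1000

  elim_cols <- c("renal_eliminated", "unabsorbed")
  body_cols <- setdiff(nms, elim_cols)
  amount_in_body <- rowSums(state[, body_cols, drop = FALSE])

  delivered <- vapply(out_times, function(tt) {
    if (regimen$route == "oral")
      if (tt >= regimen$start_time_h) dose_ng else 0
    else
      inf_rate * pmin(pmax(tt - inf_start, 0), inf_end - inf_start)
  }, numeric(1))

  structure(list(
    time_h = out_times,
    plasma_ng_per_mL = pmax(plasma_conc, 0),
    liver_ng_per_mL = pmax(liver_conc, 0),
    state_amounts_ng = state,
    eliminated_ng = state[, elim_cols, drop = FALSE],
    amount_in_body_ng = amount_in_body,
    dose_delivered_ng = delivered,
    compound = compound, physiology = physiology, regimen = regimen,
    rel_tol = rel_tol, abs_tol = abs_tol
  ), class = "pbpk_sim")
}

diagnostics_ok <- function(out, times) {
  n_ret <- nrow(out)
  if (n_ret < length(times) || any(!is.finite(out)))
    list(ok = FALSE, t_fail = out[n_ret, 1])
  else list(ok = TRUE, t_fail = NA_real_)
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat("<pbpk_sim> ", x$compound$name, ", ", x$regimen$route, " ",
      x$regimen$dose_mg, " mg, t in [", min(x$time_h), ", ",
      max(x$time_h), "] h (", length(x$time_h), " points)\n", sep = "")
  cat(sprintf("  Cmax plasma: %.4g ng/mL\n", max(x$plasma_ng_per_mL)))
  invisible(x)
}

#' Noncompartmental metrics of a simulated profile
#'
#' Trapezoidal AUC over a window of the output grid, with Cmax and tmax from
#' the grid maximum (first occurrence on ties).
#'
#' @param result a [simulate_pbpk()] result (or any list with `time_h` and a
#'   concentration trace).
#' @param t_start,t_end window bounds (h), inside the simulated range.
#' @param trace which trace to summarise: `"plasma"` or `"liver"`.
#' @return List with `AUC` (ng·h/mL), `Cmax` (ng/mL), `tmax` (h).
#' @export
pk_metrics <- function(result, t_start = NULL, t_end = NULL,
                       trace = c("plasma", "liver")) {
  trace <- match.arg(trace)
  tt <- result$time_h
  cc <- if (trace == "plasma") result$plasma_ng_per_mL else result$liver_ng_per_mL
  if (is.null(t_start)) t_start <- tt[1]
  if (is.null(t_end)) t_end <- tt[length(tt)]
  if (t_start < tt[1] || t_end > tt[length(tt)] || t_start >= t_end)
    stop("pk_metrics: window must lie within the simulated range",
         call. = FALSE)
  keep <- tt >= t_start & tt <= t_end
  if (sum(keep) < 2)
    stop("pk_metrics: fewer than 2 grid points in the window", call. = FALSE)
  tw <- tt[keep]; cw <- cc[keep]
  auc <- sum(diff(tw) * (cw[-1] + cw[-length(cw)]) / 2)
  imax <- which.max(cw)
  list(AUC = auc, Cmax = cw[imax], tmax = tw[imax])
}

#' Single-pass hepatic extraction of the serial-liver model
#'
#' Closed-form net extraction ratio of drug flowing once through the liver
#' chain at steady state: within each of the n sub-units, uptake at
#' `(CL_act_tot + CL_pass_liver)/n` (on unbound plasma) partitions between
#' biliary excretion and passive efflux back to blood in proportion
#' `CL_bile : CL_pass_liver`, giving a per-sub-unit net removal clearance
#' `k = (CL_act_tot + CL_pass_liver) (fu_p/RB_P) CL_bile /
#' (CL_pass_liver + CL_bile) / n` and extraction
#' `E = 1 - (Q_h/(Q_h + k))^n`.  This is the irreversible loss per pass;
#' under enterohepatic recirculation it exceeds the net (recirculation-
#' corrected) hepatic clearance inferred from dose/AUC.
#'
#' @param compound a [compound_spec()].
#' @param physiology a [physiology_spec()].
#' @return List with `extraction` (E), `availability` (1 - E) and
#'   `CL_hepatic_blood_L_per_h` (Q_h x E, single-pass hepatic blood
#'   clearance).
#' @export
hepatic_extraction <- function(compound, physiology) {
  validate_compound_spec(compound)
  validate_physiology_spec(physiology)
  q_h <- physiology$tissue_blood_flows_L_per_h$liver
  n <- physiology$n_liver_subunits
  cl_p <- compound$CL_pass_liver_L_per_h
  cl_b <- compound$CL_bile_L_per_h
  bile_frac <- if (cl_p + cl_b > 0) cl_b / (cl_p + cl_b) else 0
  k_sub <- (compound$CL_act_tot_L_per_h + cl_p) *
    (compound$fu_p / compound$RB_P) * bile_frac / n
  e <- 1 - (q_h / (q_h + k_sub))^n
  list(extraction = e, availability = 1 - e,
       CL_hepatic_blood_L_per_h = q_h * e)
}
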