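FREE_PARAMETERS <- c("CL_act_tot", "CL_bile", "CL_pass_liver", "ka", "FaFg")

# Map fit-parameter names to compound_spec fields.
COMPOUND_FIELD <- c(CL_act_tot = "CL_act_tot_L_per_h",
                    CL_bile = "CL_bile_L_per_h",
                    CL_pass_liver = "CL_pass_liver_L_per_h",
                    ka = "ka_per_h",
                    FaFg = "FaFg")

set_compound_parameters <- function(compound, values) {
  for (nm in names(values))
    compound[[COMPOUND_FIELD[[nm]]]] <- as.numeric(values[[nm]])
  compound
}

#' Define a parameter-estimation problem
#'
#' Joint fit of clearance/absorption parameters to one or more plasma
#' concentration-time datasets (typically one IV-infusion and one oral arm).
#' The loss is the unweighted sum of squared residuals of log-transformed
#' concentrations, pooled across datasets; log residuals match the
#' multi-order-of-magnitude range of PK profiles.
#'
#' @param datasets list of [conc_time_series()] (each carries its own dosing
#'   regimen); every dataset needs at least 3 strictly positive
#'   observations.
#' @param free_parameters subset of
#'   `CL_act_tot`, `CL_bile`, `CL_pass_liver`, `ka`, `FaFg`.
#' @param bounds named list of `c(lower, upper)` per free parameter; finite,
#'   positive, lower < upper.
#' @param fixed_compound [compound_spec()] template providing all non-free
#'   parameters.
#' @param physiology [physiology_spec()].
#' @param optimizer_config list overriding differential-evolution settings:
#'   `n_pop` (default 15 x number of parameters), `max_gen` (300), `cr`
#'   (0.7), `f_range` (dithered mutation factor, `c(0.5, 1)`), `spread_tol`
#'   (relative population spread for convergence, 1e-6), `polish`
#'   (L-BFGS-B refinement from the DE optimum, TRUE), `sim_rel_tol` /
#'   `sim_abs_tol` (solver tolerances during fitting), `lloq` (observations
#'   below this limit are excluded; default 0 = none), `boot_n_pop` /
#'   `boot_max_gen` (reduced budget for bootstrap refits).
#' @return An object of class `fit_problem`.
#' @export
fit_problem <- function(datasets, free_parameters, bounds, fixed_compound,
                        physiology, optimizer_config = list()) {
  if (!is.list(datasets) || length(datasets) < 1 ||
      !all(vapply(datasets, inherits, logical(1), "conc_time_series")))
    stop("fit_problem: datasets must be a list of conc_time_series",
         call. = FALSE)
  unknown <- setdiff(free_parameters, FREE_PARAMETERS)
  if (length(unknown) > 0)
    stop("fit_problem: unknown free parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!setequal(names(bounds), free_parameters))
    stop("fit_problem: bounds must be given for exactly the free parameters",
         call. = FALSE)
  for (nm in free_parameters) {
    b <- bounds[[nm]]
    if (length(b) != 2 || any(!is.finite(b)) || b[1] <= 0 || b[1] >= b[2])
      stop("fit_problem: bounds for ", nm,
           " must be finite with 0 < lower < upper", call. = FALSE)
  }
  if (!is.null(bounds$FaFg) && bounds$FaFg[2] > 1)
    stop("fit_problem: FaFg upper bound cannot exceed 1", call. = FALSE)
  validate_compound_spec(fixed_compound)
  validate_physiology_spec(physiology)
  cfg <- modifyList(list(
    n_pop = NULL, max_gen = 300, cr = 0.7, f_range = c(0.5, 1),
    spread_tol = 1e-6, polish = TRUE,
    sim_rel_tol = 1e-7, sim_abs_tol = 1e-9,
    lloq = 0, boot_n_pop = 10, boot_max_gen = 30
  ), optimizer_config)
  structure(list(datasets = datasets,
                 free_parameters = free_parameters,
                 bounds = bounds,
                 fixed_compound = fixed_compound,
                 physiology = physiology,
                 optimizer_config = cfg),
            class = "fit_problem")
}

# Build the pooled log-scale sum-of-squares objective over natural-scale
# parameter vectors. Simulation failures yield a large penalty, not an error.
make_objective <- function(problem) {
  cfg <- problem$optimizer_config
  obs <- lapply(problem$datasets, function(d) {
    keep <- d$conc_ng_per_mL > max(cfg$lloq, 0)
    if (sum(keep) < 3)
      stop("fit: every dataset needs >= 3 observations above the ",
           "quantification limit", call. = FALSE)
    list(times = d$times_h[keep], log_conc = log(d$conc_ng_per_mL[keep]),
         regimen = d$regimen,
         grid = sort(unique(c(0, d$regimen$start_time_h, d$times_h[keep]))))
  })
  n_fail <- 0L
  fn <- function(theta) {
    cmp <- set_compound_parameters(problem$fixed_compound,
                                   setNames(theta, problem$free_parameters))
    total <- 0
    for (d in obs) {
      pred <- tryCatch({
        sim <- simulate_pbpk(cmp, problem$physiology, d$regimen, d$grid,
                             rel_tol = cfg$sim_rel_tol,
                             abs_tol = cfg$sim_abs_tol)
        sim$plasma_ng_per_mL[match(d$times, sim$time_h)]
      }, error = function(e) NULL)
      if (is.null(pred) || any(!is.finite(pred))) {
        n_fail <<- n_fail + 1L
        return(1e10)
      }
      total <- total + sum((log(pmax(pred, 1e-12)) - d$log_conc)^2)
    }
    total
  }
  list(fn = fn, n_fail = function() n_fail)
}

# Differential evolution (rand/1/bin) with dithered mutation factor, bound
# clipping, and convergence on relative population spread.  Operates on the
# supplied (already transformed) coordinates; `init_pop` overrides the
# uniform initial population.
de_optimize <- function(fn, lower, upper, n_pop, max_gen, cr = 0.7,
                        f_range = c(0.5, 1), spread_tol = 1e-6,
                        init_pop = NULL) {
  d <- length(lower)
  if (is.null(init_pop)) {
    pop <- matrix(runif(n_pop * d, lower, upper), nrow = n_pop, ncol = d,
                  byrow = TRUE)
  } else {
    pop <- init_pop
    n_pop <- nrow(pop)
  }
  cost <- apply(pop, 1, fn)
  gen <- 0L
  spread <- Inf
  while (gen < max_gen) {
    gen <- gen + 1L
    f_mut <- runif(1, f_range[1], f_range[2])
    for (i in seq_len(n_pop)) {
      idx <- sample(seq_len(n_pop)[-i], 3)
      trial <- pop[idx[1], ] + f_mut * (pop[idx[2], ] - pop[idx[3], ])
      cross <- runif(d) < cr
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, trial, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      ct <- fn(trial)
      if (ct <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- ct
      }
    }
    rng <- apply(pop, 2, function(col) diff(range(col)))
    scale <- pmax(abs(upper - lower), 1e-12)
    spread <- max(rng / scale)
    if (spread < spread_tol) break
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best], generations = gen,
       spread = spread)
}

#' Fit clearance/absorption parameters by differential evolution
#'
#' Minimises the pooled log-concentration sum of squares with differential
#' evolution (rand/1/bin, dithered mutation factor, crossover 0.7,
#' population initialised log-uniformly within the bounds since clearances
#' span orders of magnitude), optionally followed by a bounded L-BFGS-B
#' polish from the DE optimum.  Deterministic for a fixed seed.  Candidate
#' simulations that fail are assigned a penalty loss and counted, not
#' raised.
#'
#' @param problem a [fit_problem()].
#' @param seed integer seed for the stochastic search.
#' @return An object of class `fit_result`: `estimates` (named, natural
#'   scale), `objective_value`, `at_bound` (logical flags), `convergence`
#'   (list: generations, final population spread, penalty count),
#'   `ci95` (`NULL` until [residual_bootstrap()] is run), `n_bootstrap`,
#'   `seed`, and the problem.
#' @export
fit <- function(problem, seed = 1L) {
  stopifnot(inherits(problem, "fit_problem"))
  cfg <- problem$optimizer_config
  pars <- problem$free_parameters
  d <- length(pars)
  lower <- log10(vapply(problem$bounds, `[`, numeric(1), 1)[pars])
  upper <- log10(vapply(problem$bounds, `[`, numeric(1), 2)[pars])
  obj <- make_objective(problem)
  fn_log <- function(z) obj$fn(10^z)
  n_pop <- if (is.null(cfg$n_pop)) 15L * d else cfg$n_pop

  res <- with_preserved_seed(seed, {
    de <- de_optimize(fn_log, lower, upper, n_pop = n_pop,
                      max_gen = cfg$max_gen, cr = cfg$cr,
                      f_range = cfg$f_range, spread_tol = cfg$spread_tol)
    if (isTRUE(cfg$polish)) {
      pol <- tryCatch(
        optim(de$par, fn_log, method = "L-BFGS-B",
              lower = lower, upper = upper,
              control = list(factr = 1e4, maxit = 400)),
        error = function(e) NULL)
      if (!is.null(pol) && is.finite(pol$value) && pol$value <= de$value) {
        de$par <- pol$par
        de$value <- pol$value
      }
    }
    de
  })

  if (res$value >= 1e10)
    stop("fit: no candidate simulated successfully", call. = FALSE)
  est <- setNames(10^res$par, pars)
  at_bound <- abs(res$par - lower) < 1e-6 | abs(res$par - upper) < 1e-6
  names(at_bound) <- pars
  if (any(at_bound))
    warning("fit: parameter(s) at bounds: ",
            paste(pars[at_bound], collapse = ", "), call. = FALSE)
  structure(list(
    estimates = est,
    objective_value = res$value,
    at_bound = at_bound,
    convergence = list(generations = res$generations, spread = res$spread,
                       n_penalty = obj$n_fail()),
    ci95 = NULL, n_bootstrap = 0L, seed = as.integer(seed),
    problem = problem
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> objective", signif(x$objective_value, 4), "\n")
  est <- signif(x$estimates, 4)
  for (nm in names(est)) {
    ci <- if (!is.null(x$ci95)) sprintf("  [%.4g, %.4g]", x$ci95[[nm]][1],
                                        x$ci95[[nm]][2]) else ""
    flag <- if (x$at_bound[[nm]]) "  (at bound)" else ""
    cat(sprintf("  %-14s %.4g%s%s\n", nm, est[[nm]], ci, flag))
  }
  invisible(x)
}

#' Residual-bootstrap confidence intervals
#'
#' Resamples the pooled log-scale residuals of the fitted model with
#' replacement, reconstructs pseudo-datasets, refits each with a
#' reduced-budget differential evolution initialised around the point
#' estimate, and returns percentile 2.5/97.5 intervals per parameter.
#' Deterministic for a fixed seed.  Replicates whose refit fails are dropped
#' and counted; more than 20% drops is an error.
#'
#' @param result a [fit()] result.
#' @param problem the same [fit_problem()] the result came from (defaults to
#'   the one stored in the result).
#' @param n_boot number of bootstrap replicates (>= 50 recommended).
#' @param seed integer seed.
#' @return The `fit_result` with `ci95` (named list of `c(low, high)`) and
#'   `n_bootstrap` filled in, plus `bootstrap_estimates` (matrix) and
#'   `n_dropped`.
#' @export
residual_bootstrap <- function(result, problem = result$problem,
                               n_boot = 200, seed = 1L) {
  stopifnot(inherits(result, "fit_result"), inherits(problem, "fit_problem"))
  cfg <- problem$optimizer_config
  pars <- problem$free_parameters
  cmp_hat <- set_compound_parameters(problem$fixed_compound,
                                     result$estimates)
  # fitted log-predictions and residuals, pooled across datasets
  fitted <- lapply(problem$datasets, function(d) {
    keep <- d$conc_ng_per_mL > max(cfg$lloq, 0)
    grid <- sort(unique(c(0, d$regimen$start_time_h, d$times_h[keep])))
    sim <- simulate_pbpk(cmp_hat, problem$physiology, d$regimen, grid,
                         rel_tol = cfg$sim_rel_tol, abs_tol = cfg$sim_abs_tol)
    log_pred <- log(pmax(sim$plasma_ng_per_mL[match(d$times_h[keep],
                                                    sim$time_h)], 1e-12))
    list(dataset = d, keep = keep, log_pred = log_pred,
         resid = log(d$conc_ng_per_mL[keep]) - log_pred)
  })
  pooled <- unlist(lapply(fitted, `[[`, "resid"))

  lower <- log10(vapply(problem$bounds, `[`, numeric(1), 1)[pars])
  upper <- log10(vapply(problem$bounds, `[`, numeric(1), 2)[pars])
  z_hat <- log10(result$estimates[pars])

  boot <- with_preserved_seed(seed, {
    out <- matrix(NA_real_, nrow = n_boot, ncol = length(pars),
                  dimnames = list(NULL, pars))
    for (b in seq_len(n_boot)) {
      pseudo <- lapply(fitted, function(f) {
        e_star <- sample(pooled, length(f$log_pred), replace = TRUE)
        d <- f$dataset
        conc <- d$conc_ng_per_mL
        conc[f$keep] <- exp(f$log_pred + e_star)
        conc_time_series(d$times_h, conc, sd_ng_per_mL = d$sd_ng_per_mL,
                         regimen = d$regimen, label = d$label,
                         n_subjects = d$n_subjects)
      })
      prob_b <- problem
      prob_b$datasets <- pseudo
      obj_b <- make_objective(prob_b)
      fn_log <- function(z) obj_b$fn(10^z)
      # reduced-budget DE seeded around the point estimate
      n_pop_b <- max(cfg$boot_n_pop, 5L)
      init <- matrix(rep(z_hat, each = n_pop_b), nrow = n_pop_b)
      jitter <- matrix(runif(n_pop_b * length(pars), -0.15, 0.15),
                       nrow = n_pop_b)
      jitter[1, ] <- 0
      init <- pmin(pmax(init + jitter, rep(lower, each = n_pop_b)),
                   rep(upper, each = n_pop_b))
      est_b <- tryCatch({
        de <- de_optimize(fn_log, lower, upper, n_pop = n_pop_b,
                          max_gen = cfg$boot_max_gen, cr = cfg$cr,
                          f_range = cfg$f_range, spread_tol = cfg$spread_tol,
                          init_pop = init)
        if (isTRUE(cfg$polish)) {
          pol <- tryCatch(
            optim(de$par, fn_log, method = "L-BFGS-B",
                  lower = lower, upper = upper,
                  control = list(factr = 1e6, maxit = 200)),
            error = function(e) NULL)
          if (!is.null(pol) && is.finite(pol$value) && pol$value <= de$value)
            de$par <- pol$par
        }
        if (de$value >= 1e10) NULL else 10^de$par
      }, error = function(e) NULL)
      if (!is.null(est_b)) out[b, ] <- est_b
    }
    out
  })

  ok <- stats::complete.cases(boot)
  n_dropped <- sum(!ok)
  if (n_dropped > 0.2 * n_boot)
    stop("residual_bootstrap: ", n_dropped, " of ", n_boot,
         " replicates failed to refit (> 20%)", call. = FALSE)
  ci <- lapply(pars, function(nm)
    unname(quantile(boot[ok, nm], c(0.025, 0.975), type = 7)))
  names(ci) <- pars
  for (nm in pars) {
    est <- result$estimates[[nm]]
    if (est < ci[[nm]][1] || est > ci[[nm]][2])
      warning("residual_bootstrap: point estimate of ", nm,
              " outside its 95% interval", call. = FALSE)
  }
  result$ci95 <- ci
  result$n_bootstrap <- sum(ok)
  result$n_dropped <- n_dropped
  result$bootstrap_estimates <- boot[ok, , drop = FALSE]
  result$bootstrap_seed <- as.integer(seed)
  result
}

#' Noncompartmental estimate of Fa*Fg
#'
#' Classical AUC-based cross-check: oral bioavailability
#' `F_oral = (AUC_oral/dose_oral) / (AUC_iv/dose_iv)`, hepatic blood
#' clearance `CL_h,b = (CL_plasma - CL_renal)/RB_P`, hepatic availability
#' `F_h = 1 - CL_h,b/Q_hepatic_blood`, and `Fa*Fg = F_oral/F_h`.  Under
#' enterohepatic recirculation the noncompartmental route tends to
#' overestimate Fa*Fg (finite AUC windows inflate the apparent plasma
#' clearance); values above 1 raise a warning rather than an error.
#'
#' @param auc_iv,auc_oral plasma AUCs (ng·h/mL) of the IV and oral arms.
#' @param dose_iv,dose_oral doses (mg).
#' @param CL_plasma total plasma clearance (L/h), typically dose_iv/AUC_iv.
#' @param CL_renal renal plasma clearance (L/h).
#' @param Q_hepatic_blood hepatic blood flow (L/h).
#' @param RB_P blood:plasma concentration ratio.
#' @return The noncompartmental Fa*Fg estimate.
#' @export
nca_fafg <- function(auc_iv, dose_iv, auc_oral, dose_oral,
                     CL_plasma, CL_renal, Q_hepatic_blood, RB_P) {
  vals <- c(auc_iv, dose_iv, auc_oral, dose_oral, CL_plasma, Q_hepatic_blood,
            RB_P)
  if (any(!is.finite(vals)) || any(vals <= 0) || CL_renal < 0)
    stop("nca_fafg: all inputs must be positive (CL_renal >= 0)",
         call. = FALSE)
  f_oral <- (auc_oral / dose_oral) / (auc_iv / dose_iv)
  cl_hb <- (CL_plasma - CL_renal) / RB_P
  f_h <- 1 - cl_hb / Q_hepatic_blood
  if (f_h <= 0)
    stop("nca_fafg: hepatic extraction exceeds hepatic blood flow ",
         "(F_h <= 0)", call. = FALSE)
  out <- f_oral / f_h
  if (out > 1)
    warning("nca_fafg: estimate exceeds 1; expected when enterohepatic ",
            "recirculation biases the noncompartmental analysis",
            call. = FALSE)
  out
}
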