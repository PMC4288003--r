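VARIANTS <- c("star1a", "star1b", "star15")

#' OATP1B1 genotype specification
#'
#' Population haplotype frequencies and in vitro variant data used to
#' translate the nongenotyped hepatic active uptake clearance into
#' genotype-specific clearances.  The *5 haplotype is merged into *15 and
#' diplotypes are restricted to homozygotes; heterozygote interpolation is
#' out of scope.  Intrinsic activity ratios (per-transporter uptake relative
#' to *1a) are kept separate from protein expression multipliers; the
#' effective per-variant ratio is their product.
#'
#' @param frequencies named numeric `c(star1a=, star1b=, star15=)` haplotype
#'   proportions, summing to 1.
#' @param activity_ratio_1b,activity_ratio_15 intrinsic uptake activity of
#'   *1b / *15 relative to *1a (> 0).
#' @param expression_mult_1b,expression_mult_15 protein expression relative
#'   to *1a (> 0).
#' @param f_OATP1B1 fraction of the total hepatic active uptake clearance
#'   mediated by OATP1B1, in `[0, 1]`.
#' @param ethnic_scalar multiplicative OATP1B1 activity ratio of the target
#'   population relative to the reference population (> 0; 1 = reference).
#' @return An object of class `genotype_spec`.
#' @export
genotype_spec <- function(frequencies,
                          activity_ratio_1b, activity_ratio_15,
                          expression_mult_1b = 1, expression_mult_15 = 1,
                          f_OATP1B1,
                          ethnic_scalar = 1) {
  freq <- unlist(frequencies)
  obj <- structure(list(
    frequencies = freq,
    activity_ratio_1b = activity_ratio_1b,
    activity_ratio_15 = activity_ratio_15,
    expression_mult_1b = expression_mult_1b,
    expression_mult_15 = expression_mult_15,
    f_OATP1B1 = f_OATP1B1,
    ethnic_scalar = ethnic_scalar
  ), class = "genotype_spec")
  validate_genotype_spec(obj)
  obj
}

validate_genotype_spec <- function(x) {
  stopifnot(inherits(x, "genotype_spec"))
  if (!setequal(names(x$frequencies), VARIANTS))
    stop("genotype_spec: frequencies must be named ",
         paste(VARIANTS, collapse = ", "), call. = FALSE)
  f <- x$frequencies[VARIANTS]
  if (any(!is.finite(f)) || any(f < 0))
    stop("genotype_spec: frequencies must be >= 0", call. = FALSE)
  if (abs(sum(f) - 1) > 1e-9)
    stop("genotype_spec: frequencies must sum to 1 (got ",
         signif(sum(f), 10), ")", call. = FALSE)
  r <- c(x$activity_ratio_1b, x$activity_ratio_15,
         x$expression_mult_1b, x$expression_mult_15)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("genotype_spec: activity ratios and expression multipliers must be > 0",
         call. = FALSE)
  if (!is.finite(x$f_OATP1B1) || x$f_OATP1B1 < 0 || x$f_OATP1B1 > 1)
    stop("genotype_spec: f_OATP1B1 must be in [0, 1]", call. = FALSE)
  if (!is.finite(x$ethnic_scalar) || x$ethnic_scalar <= 0)
    stop("genotype_spec: ethnic_scalar must be > 0", call. = FALSE)
  invisible(x)
}

#' @export
print.genotype_spec <- function(x, ...) {
  cat("<genotype_spec>\n")
  cat(sprintf("  frequencies: *1a %.3g, *1b %.3g, *15 %.3g\n",
              x$frequencies[["star1a"]], x$frequencies[["star1b"]],
              x$frequencies[["star15"]]))
  cat(sprintf("  activity ratios: *1b %.3g, *15 %.3g; expression: *1b %.3g, *15 %.3g\n",
              x$activity_ratio_1b, x$activity_ratio_15,
              x$expression_mult_1b, x$expression_mult_15))
  cat(sprintf("  f_OATP1B1 %.4g; ethnic scalar %.3g\n",
              x$f_OATP1B1, x$ethnic_scalar))
  invisible(x)
}

# Effective per-variant ratio relative to *1a: intrinsic activity x expression
effective_ratios <- function(spec) {
  c(star1a = 1,
    star1b = spec$activity_ratio_1b * spec$expression_mult_1b,
    star15 = spec$activity_ratio_15 * spec$expression_mult_15)
}

#' Split total active uptake into OATP1B1 and other-transporter components
#'
#' @param CL_act_tot total hepatic active uptake clearance (L/h), >= 0.
#' @param f_OATP1B1 fraction mediated by OATP1B1, in `[0, 1]`.
#' @return Named list `CL_act_OATP1B1`, `CL_act_other`; the two sum to the
#'   input exactly.
#' @export
split_uptake <- function(CL_act_tot, f_OATP1B1) {
  if (!is.finite(CL_act_tot) || CL_act_tot < 0)
    stop("split_uptake: CL_act_tot must be >= 0", call. = FALSE)
  if (!is.finite(f_OATP1B1) || f_OATP1B1 < 0 || f_OATP1B1 > 1)
    stop("split_uptake: f_OATP1B1 must be in [0, 1]", call. = FALSE)
  oatp <- f_OATP1B1 * CL_act_tot
  list(CL_act_OATP1B1 = oatp, CL_act_other = CL_act_tot - oatp)
}

#' OATP1B1 fraction from a two-stage pathway decomposition
#'
#' When a fraction of total active uptake is attributed to NTCP and a
#' fraction of the remainder to OATP1B1, the overall OATP1B1 contribution is
#' `(1 - f_NTCP) * f_OATP1B1_given_nonNTCP` (e.g. 35% NTCP with 77% of the
#' remaining 65% through OATP1B1 gives 0.5005, i.e. 50% to the nearest
#' percent).
#'
#' @param f_NTCP fraction of total active uptake due to NTCP, in `[0, 1]`.
#' @param f_OATP1B1_given_nonNTCP fraction of the non-NTCP uptake mediated by
#'   OATP1B1, in `[0, 1]`.
#' @return The overall OATP1B1 fraction of total active uptake.
#' @export
oatp1b1_fraction_from_pathways <- function(f_NTCP, f_OATP1B1_given_nonNTCP) {
  for (v in c(f_NTCP, f_OATP1B1_given_nonNTCP))
    if (!is.finite(v) || v < 0 || v > 1)
      stop("oatp1b1_fraction_from_pathways: fractions must be in [0, 1]",
           call. = FALSE)
  (1 - f_NTCP) * f_OATP1B1_given_nonNTCP
}

#' Per-variant OATP1B1 clearances from the population mean
#'
#' The nongenotyped OATP1B1 clearance is the haplotype-frequency-weighted
#' mean of the per-variant clearances.  With effective ratios
#' `r_v = activity_ratio_v * expression_mult_v` (and `r_*1a = 1`), the *1a
#' clearance is `mean / sum(P_v * r_v)` and each variant's clearance is
#' `r_v` times that, so the weighted mean of the returned clearances
#' reproduces the input exactly.
#'
#' @param CL_act_OATP1B1_mean nongenotyped (population-mean) OATP1B1
#'   clearance (L/h).
#' @param spec a [genotype_spec()].
#' @param CL_act_other non-OATP1B1 active uptake clearance (L/h) to carry in
#'   the result (default 0).
#' @return An object of class `variant_clearance_set`: list with
#'   `CL_act_OATP1B1_mean`, `CL_act_other`, `CL_act_OATP1B1` (named per
#'   variant) and `CL_act_tot` (per variant, OATP1B1 + other).
#' @export
variant_clearances <- function(CL_act_OATP1B1_mean, spec, CL_act_other = 0) {
  validate_genotype_spec(spec)
  if (!is.finite(CL_act_OATP1B1_mean) || CL_act_OATP1B1_mean < 0)
    stop("variant_clearances: mean clearance must be >= 0", call. = FALSE)
  if (!is.finite(CL_act_other) || CL_act_other < 0)
    stop("variant_clearances: CL_act_other must be >= 0", call. = FALSE)
  r <- effective_ratios(spec)
  w <- sum(spec$frequencies[VARIANTS] * r[VARIANTS])
  if (w <= 0)
    stop("variant_clearances: degenerate population (sum of P_v * r_v is 0)",
         call. = FALSE)
  cl_1a <- CL_act_OATP1B1_mean / w
  per_variant <- r * cl_1a
  structure(list(
    CL_act_OATP1B1_mean = CL_act_OATP1B1_mean,
    CL_act_other = CL_act_other,
    CL_act_OATP1B1 = per_variant,
    CL_act_tot = per_variant + CL_act_other
  ), class = "variant_clearance_set")
}

#' @export
print.variant_clearance_set <- function(x, ...) {
  cat("<variant_clearance_set> (L/h)\n")
  m <- rbind(OATP1B1 = x$CL_act_OATP1B1, total = x$CL_act_tot)
  colnames(m) <- c("*1a", "*1b", "*15")
  print(signif(m, 4))
  cat(sprintf("  mean OATP1B1: %.4g; other: %.4g\n",
              x$CL_act_OATP1B1_mean, x$CL_act_other))
  invisible(x)
}

#' Genotype-specific total active uptake clearances
#'
#' @param variant_set a [variant_clearances()] result.
#' @return Named numeric vector: `CL_act_tot` per variant
#'   (`CL_act_OATP1B1_v + CL_act_other`).
#' @export
genotyped_total <- function(variant_set) {
  stopifnot(inherits(variant_set, "variant_clearance_set"))
  variant_set$CL_act_OATP1B1 + variant_set$CL_act_other
}

#' Apply an ethnic activity scalar to all active uptake clearances
#'
#' Multiplies every active-uptake entry (the per-variant OATP1B1 clearances,
#' their mean, and the non-OATP1B1 component) by a population activity
#' ratio (e.g. 0.584 for Japanese relative to Caucasian OATP1B1 activity);
#' all other compound parameters are untouched.
#'
#' @param variant_set a [variant_clearances()] result.
#' @param scalar activity ratio (> 0).
#' @return A rescaled `variant_clearance_set`.
#' @export
apply_ethnic_scaling <- function(variant_set, scalar) {
  stopifnot(inherits(variant_set, "variant_clearance_set"))
  if (!is.finite(scalar) || scalar <= 0)
    stop("apply_ethnic_scaling: scalar must be > 0", call. = FALSE)
  out <- variant_set
  out$CL_act_OATP1B1_mean <- scalar * out$CL_act_OATP1B1_mean
  out$CL_act_other <- scalar * out$CL_act_other
  out$CL_act_OATP1B1 <- scalar * out$CL_act_OATP1B1
  out$CL_act_tot <- out$CL_act_OATP1B1 + out$CL_act_other
  out
}

#' Genotype clearances for a compound
#'
#' Convenience wrapper: splits the compound's fitted `CL_act_tot` into
#' OATP1B1 and other components with the spec's `f_OATP1B1`, derives
#' per-variant clearances, and applies the spec's ethnic scalar.
#'
#' @param compound a [compound_spec()].
#' @param spec a [genotype_spec()].
#' @return A `variant_clearance_set`.
#' @export
genotype_clearances <- function(compound, spec) {
  parts <- split_uptake(compound$CL_act_tot_L_per_h, spec$f_OATP1B1)
  vs <- variant_clearances(parts$CL_act_OATP1B1, spec,
                           CL_act_other = parts$CL_act_other)
  if (spec$ethnic_scalar != 1)
    vs <- apply_ethnic_scaling(vs, spec$ethnic_scalar)
  vs
}

#' Predict per-genotype concentration-time profiles
#'
#' Clones the compound per variant with `CL_act_tot` replaced by the
#' genotype-specific total (all other parameters unchanged) and simulates
#' each.
#'
#' @inheritParams simulate_pbpk
#' @param spec a [genotype_spec()].
#' @return Named list (star1a, star1b, star15) of [simulate_pbpk()] results.
#' @export
predict_genotype_profiles <- function(compound, physiology, spec, regimen,
                                      time_grid, rel_tol = 1e-8,
                                      abs_tol = 1e-10) {
  totals <- genotyped_total(genotype_clearances(compound, spec))
  out <- lapply(VARIANTS, function(v) {
    cmp <- compound
    cmp$CL_act_tot_L_per_h <- totals[[v]]
    simulate_pbpk(cmp, physiology, regimen, time_grid,
                  rel_tol = rel_tol, abs_tol = abs_tol)
  })
  names(out) <- VARIANTS
  out
}

#' Map c.521 genotype labels to haplotype groups
#'
#' Studies that sequence only the c.521T>C single-nucleotide polymorphism
#' report TT and CC groups; in the absence of c.388A>G information the TT
#' group is conventionally attributed to *1a and the CC group to *5/*15.
#'
#' @param labels character vector of `"c.521TT"` / `"c.521CC"` labels.
#' @return Character vector of `"star1a"` / `"star15"`.
#' @export
relabel_c521 <- function(labels) {
  map <- c(`c.521TT` = "star1a", `c.521CC` = "star15")
  unknown <- setdiff(labels, names(map))
  if (length(unknown) > 0)
    stop("relabel_c521: unknown label(s): ", paste(unknown, collapse = ", "),
         "; expected c.521TT or c.521CC", call. = FALSE)
  unname(map[labels])
}
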