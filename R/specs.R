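#' @useDynLib oatpbpk
#' @importFrom stats approx optim quantile rlnorm runif sd setNames
#' @importFrom utils modifyList read.csv write.csv packageVersion
NULL

# Tissues carrying a tissue:plasma partition coefficient.  lung, gut, spleen,
# kidney and rest_of_body are perfusion-limited; muscle and adipose use Kp to
# derive the intracellular unbound fraction of the permeability-limited pair.
KP_TISSUES <- c("lung", "gut", "spleen", "kidney", "rest_of_body",
                "muscle", "adipose")

VOLUME_TISSUES <- c("lung", "adipose", "muscle", "gut", "spleen", "kidney",
                    "liver", "rest_of_body", "arterial_blood", "venous_blood")

FLOW_TISSUES <- c("lung", "adipose", "muscle", "gut", "spleen", "kidney",
                  "liver", "rest_of_body")

#' Physiology specification
#'
#' Defines the anatomy of the whole-body model: tissue volumes (L), tissue
#' blood flows (L/h), the serial liver discretisation, and the bile
#' compartment.  The lung flow is cardiac output; the liver flow is total
#' hepatic blood flow (hepatic artery plus portal inflow from gut and
#' spleen).  The bile-duct volume is fixed at 0.318% of liver volume and the
#' bile flow defaults to 350 mL/day.
#'
#' @param body_weight_kg body weight (kg).
#' @param tissue_volumes_L named list/vector of tissue volumes (L); names must
#'   be exactly lung, adipose, muscle, gut, spleen, kidney, liver, rest_of_body, arterial_blood, venous_blood.
#' @param tissue_blood_flows_L_per_h named list/vector of blood flows (L/h)
#'   for lung, adipose, muscle, gut, spleen, kidney, liver, rest_of_body.  The lung entry is cardiac
#'   output and must equal the sum of the systemic tissue flows (adipose,
#'   muscle, kidney, rest_of_body, liver); the liver entry must be at least
#'   gut + spleen flow (the difference is the hepatic artery).
#' @param n_liver_subunits number of serial liver blood/tissue pairs
#'   (default 5).
#' @param liver_blood_fraction fraction of liver volume that is vascular.
#' @param muscle_ec_fraction,adipose_ec_fraction extracellular (vascular)
#'   volume fractions of the permeability-limited muscle and adipose pairs.
#' @param bile_flow_mL_per_day bile flow; converted to L/h internally
#'   (350 mL/day = 0.01458 L/h).
#'
#' @return An object of class `physiology_spec` with derived fields
#'   `V_bile_L` (0.00318 x liver volume) and `Q_liver_bile_L_per_h`.
#' @seealso [default_physiology()]
#' @export
physiology_spec <- function(body_weight_kg,
                            tissue_volumes_L,
                            tissue_blood_flows_L_per_h,
                            n_liver_subunits = 5L,
                            liver_blood_fraction = 0.16,
                            muscle_ec_fraction = 0.10,
                            adipose_ec_fraction = 0.05,
                            bile_flow_mL_per_day = 350) {
  vols <- as.list(tissue_volumes_L)
  flows <- as.list(tissue_blood_flows_L_per_h)
  obj <- structure(list(
    body_weight_kg = body_weight_kg,
    tissue_volumes_L = vols,
    tissue_blood_flows_L_per_h = flows,
    n_liver_subunits = as.integer(n_liver_subunits),
    liver_blood_fraction = liver_blood_fraction,
    muscle_ec_fraction = muscle_ec_fraction,
    adipose_ec_fraction = adipose_ec_fraction,
    bile_flow_mL_per_day = bile_flow_mL_per_day,
    V_bile_L = 0.00318 * as.numeric(vols[["liver"]]),
    Q_liver_bile_L_per_h = bile_flow_mL_per_day / 1000 / 24
  ), class = "physiology_spec")
  validate_physiology_spec(obj)
  obj
}

validate_physiology_spec <- function(x) {
  stopifnot(inherits(x, "physiology_spec"))
  miss <- setdiff(VOLUME_TISSUES, names(x$tissue_volumes_L))
  if (length(miss) > 0)
    stop("physiology_spec: missing tissue volume(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(x$tissue_volumes_L), VOLUME_TISSUES)
  if (length(extra) > 0)
    stop("physiology_spec: unknown tissue volume key(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  missf <- setdiff(FLOW_TISSUES, names(x$tissue_blood_flows_L_per_h))
  if (length(missf) > 0)
    stop("physiology_spec: missing blood flow(s): ",
         paste(missf, collapse = ", "), call. = FALSE)
  extraf <- setdiff(names(x$tissue_blood_flows_L_per_h), FLOW_TISSUES)
  if (length(extraf) > 0)
    stop("physiology_spec: unknown blood flow key(s): ",
         paste(extraf, collapse = ", "), call. = FALSE)
  v <- unlist(x$tissue_volumes_L)
  q <- unlist(x$tissue_blood_flows_L_per_h)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("physiology_spec: all tissue volumes must be > 0", call. = FALSE)
  if (any(!is.finite(q)) || any(q < 0))
    stop("physiology_spec: blood flows must be >= 0", call. = FALSE)
  if (q[["lung"]] <= 0)
    stop("physiology_spec: cardiac output (lung flow) must be > 0",
         call. = FALSE)
  if (x$n_liver_subunits < 1)
    stop("physiology_spec: n_liver_subunits must be >= 1", call. = FALSE)
  if (x$liver_blood_fraction <= 0 || x$liver_blood_fraction >= 1)
    stop("physiology_spec: liver_blood_fraction must be in (0,1)",
         call. = FALSE)
  # cardiac output closure: systemic tissues (gut/spleen drain via liver)
  systemic <- q[["adipose"]] + q[["muscle"]] + q[["kidney"]] +
    q[["rest_of_body"]] + q[["liver"]]
  if (abs(systemic - q[["lung"]]) > 1e-6 * q[["lung"]])
    stop("physiology_spec: systemic flows (adipose+muscle+kidney+",
         "rest_of_body+liver) must equal cardiac (lung) flow; got ",
         signif(systemic, 6), " vs ", signif(q[["lung"]], 6), call. = FALSE)
  if (q[["liver"]] < q[["gut"]] + q[["spleen"]])
    stop("physiology_spec: liver flow must be >= gut + spleen flow ",
         "(hepatic artery cannot be negative)", call. = FALSE)
  if (abs(x$V_bile_L - 0.00318 * v[["liver"]]) > 1e-9)
    stop("physiology_spec: V_bile must be 0.318% of liver volume",
         call. = FALSE)
  invisible(x)
}

#' Reference 70-kg human physiology
#'
#' A documented reference parameter set for an average 70-kg adult: tissue
#' volumes and blood flows in the range of standard physiology compilations.
#' These values are implementation fixtures for simulation and testing, not a
#' reproduction of any published fitted table.
#'
#' @return A [physiology_spec()].
#' @export
default_physiology <- function() {
  physiology_spec(
    body_weight_kg = 70,
    tissue_volumes_L = list(
      lung = 0.5, adipose = 18, muscle = 29, gut = 1.2, spleen = 0.15,
      kidney = 0.31, liver = 1.8, rest_of_body = 10,
      arterial_blood = 1.7, venous_blood = 3.9
    ),
    tissue_blood_flows_L_per_h = list(
      lung = 390,            # cardiac output
      adipose = 20, muscle = 45, gut = 60, spleen = 15, kidney = 70,
      liver = 97,            # hepatic artery 22 + portal 75 (gut + spleen)
      rest_of_body = 158
    )
  )
}

#' Compound specification
#'
#' All compound-specific parameters of the PBPK model: binding (`fu_p`,
#' `RB_P`, `fu_liver`), clearances (renal, total hepatic active uptake,
#' biliary, hepatic passive diffusion), absorption (`ka`, `FaFg`) and tissue
#' partition coefficients.  Clearance conventions: `CL_renal_L_per_h` is
#' plasma-referenced and acts on venous plasma; `CL_act_tot_L_per_h` and
#' `CL_pass_liver_L_per_h` act on unbound plasma concentration in liver
#' blood; `CL_bile_L_per_h` acts on unbound intracellular liver
#' concentration.  Muscle and adipose passive clearances are fixed ratios of
#' the hepatic passive clearance.
#'
#' @param name compound label.
#' @param fu_p unbound fraction in plasma, in (0, 1].
#' @param RB_P blood:plasma concentration ratio (> 0).
#' @param fu_liver unbound fraction in liver tissue, in (0, 1].
#' @param CL_renal_L_per_h renal clearance (L/h, plasma-referenced).
#' @param CL_act_tot_L_per_h total hepatic active uptake clearance (L/h,
#'   unbound-referenced).
#' @param CL_bile_L_per_h biliary clearance (L/h, unbound intracellular).
#' @param CL_pass_liver_L_per_h hepatic passive diffusion clearance (L/h).
#' @param pass_ratio_muscle,pass_ratio_adipose ratios of muscle/adipose
#'   passive clearance to the hepatic one.
#' @param ka_per_h first-order absorption rate constant (1/h).
#' @param FaFg fraction of an oral dose reaching the portal circulation,
#'   in (0, 1].
#' @param Kp named list of tissue:plasma partition coefficients for
#'   lung, gut, spleen, kidney, rest_of_body, muscle, adipose.
#'
#' @return An object of class `compound_spec`.
#' @export
compound_spec <- function(name,
                          fu_p, RB_P, fu_liver,
                          CL_renal_L_per_h,
                          CL_act_tot_L_per_h,
                          CL_bile_L_per_h,
                          CL_pass_liver_L_per_h,
                          pass_ratio_muscle = 1,
                          pass_ratio_adipose = 1,
                          ka_per_h = 1,
                          FaFg = 1,
                          Kp = list()) {
  obj <- structure(list(
    name = name,
    fu_p = fu_p, RB_P = RB_P, fu_liver = fu_liver,
    CL_renal_L_per_h = CL_renal_L_per_h,
    CL_act_tot_L_per_h = CL_act_tot_L_per_h,
    CL_bile_L_per_h = CL_bile_L_per_h,
    CL_pass_liver_L_per_h = CL_pass_liver_L_per_h,
    pass_ratio_muscle = pass_ratio_muscle,
    pass_ratio_adipose = pass_ratio_adipose,
    ka_per_h = ka_per_h,
    FaFg = FaFg,
    Kp = as.list(Kp)
  ), class = "compound_spec")
  validate_compound_spec(obj)
  obj
}

validate_compound_spec <- function(x) {
  stopifnot(inherits(x, "compound_spec"))
  frac_in <- function(v, nm) {
    if (!is.finite(v) || v <= 0 || v > 1)
      stop("compound_spec: ", nm, " must be in (0, 1], got ", v,
           call. = FALSE)
  }
  frac_in(x$fu_p, "fu_p")
  frac_in(x$fu_liver, "fu_liver")
  frac_in(x$FaFg, "FaFg")
  if (!is.finite(x$RB_P) || x$RB_P <= 0)
    stop("compound_spec: RB_P must be > 0", call. = FALSE)
  cls <- c(x$CL_renal_L_per_h, x$CL_act_tot_L_per_h, x$CL_bile_L_per_h,
           x$CL_pass_liver_L_per_h)
  if (any(!is.finite(cls)) || any(cls < 0))
    stop("compound_spec: clearances must be >= 0", call. = FALSE)
  if (x$pass_ratio_muscle < 0 || x$pass_ratio_adipose < 0)
    stop("compound_spec: passive-clearance ratios must be >= 0",
         call. = FALSE)
  if (!is.finite(x$ka_per_h) || x$ka_per_h <= 0)
    stop("compound_spec: ka must be > 0", call. = FALSE)
  unknown <- setdiff(names(x$Kp), KP_TISSUES)
  if (length(unknown) > 0)
    stop("compound_spec: unknown tissue in Kp map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  miss <- setdiff(KP_TISSUES, names(x$Kp))
  if (length(miss) > 0)
    stop("compound_spec: missing Kp for tissue(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  kp <- unlist(x$Kp)
  if (any(!is.finite(kp)) || any(kp <= 0))
    stop("compound_spec: all Kp values must be > 0", call. = FALSE)
  invisible(x)
}

#' Dosing regimen
#'
#' @param route `"iv_infusion"` or `"oral"`.
#' @param dose_mg dose (mg), >= 0.
#' @param infusion_duration_h infusion duration (h); required for
#'   `iv_infusion`.
#' @param start_time_h dose start time (h post reference time 0).
#'
#' @return An object of class `dose_regimen`.
#' @export
dose_regimen <- function(route = c("iv_infusion", "oral"),
                         dose_mg,
                         infusion_duration_h = NULL,
                         start_time_h = 0) {
  route <- match.arg(route)
  if (!is.finite(dose_mg) || dose_mg < 0)
    stop("dose_regimen: dose must be >= 0", call. = FALSE)
  if (route == "iv_infusion") {
    if (is.null(infusion_duration_h) || !is.finite(infusion_duration_h) ||
        infusion_duration_h <= 0)
      stop("dose_regimen: infusion_duration_h must be > 0 for iv_infusion",
           call. = FALSE)
  } else {
    infusion_duration_h <- NA_real_
  }
  if (!is.finite(start_time_h) || start_time_h < 0)
    stop("dose_regimen: start_time_h must be >= 0", call. = FALSE)
  structure(list(route = route, dose_mg = dose_mg,
                 infusion_duration_h = infusion_duration_h,
                 start_time_h = start_time_h),
            class = "dose_regimen")
}

#' @export
print.physiology_spec <- function(x, ...) {
  cat("<physiology_spec> ", x$body_weight_kg, " kg, ",
      x$n_liver_subunits, " serial liver sub-units\n", sep = "")
  cat("  cardiac output: ", x$tissue_blood_flows_L_per_h$lung, " L/h; ",
      "liver flow: ", x$tissue_blood_flows_L_per_h$liver, " L/h\n", sep = "")
  cat("  V_bile: ", signif(x$V_bile_L, 4), " L; bile flow: ",
      signif(x$Q_liver_bile_L_per_h, 4), " L/h\n", sep = "")
  invisible(x)
}

#' @export
print.compound_spec <- function(x, ...) {
  cat("<compound_spec> ", x$name, "\n", sep = "")
  cat(sprintf("  fu_p %.3g  RB_P %.3g  fu_liver %.3g\n",
              x$fu_p, x$RB_P, x$fu_liver))
  cat(sprintf("  CL (L/h): renal %.3g  act_tot %.3g  bile %.3g  pass_liver %.3g\n",
              x$CL_renal_L_per_h, x$CL_act_tot_L_per_h, x$CL_bile_L_per_h,
              x$CL_pass_liver_L_per_h))
  cat(sprintf("  ka %.3g /h  FaFg %.3g\n", x$ka_per_h, x$FaFg))
  invisible(x)
}

#' @export
print.dose_regimen <- function(x, ...) {
  if (x$route == "iv_infusion")
    cat(sprintf("<dose_regimen> IV infusion %g mg over %g h (start %g h)\n",
                x$dose_mg, x$infusion_duration_h, x$start_time_h))
  else
    cat(sprintf("<dose_regimen> oral %g mg (start %g h)\n",
                x$dose_mg, x$start_time_h))
  invisible(x)
}
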