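COMPOUND_KEYS <- c("name", "fu_p", "RB_P", "fu_liver", "CL_renal_L_per_h",
                   "CL_act_tot_L_per_h", "CL_bile_L_per_h",
                   "CL_pass_liver_L_per_h", "pass_ratio_muscle",
                   "pass_ratio_adipose", "ka_per_h", "FaFg", "Kp")
PHYSIOLOGY_KEYS <- c("body_weight_kg", "tissue_volumes_L",
                     "tissue_blood_flows_L_per_h", "n_liver_subunits",
                     "liver_blood_fraction", "muscle_ec_fraction",
                     "adipose_ec_fraction", "bile_flow_mL_per_day")
GENOTYPE_KEYS <- c("frequencies", "activity_ratio_1b", "activity_ratio_15",
                   "expression_mult_1b", "expression_mult_15", "f_OATP1B1",
                   "ethnic_scalar")
REGIMEN_KEYS <- c("route", "dose_mg", "infusion_duration_h", "start_time_h")

check_keys <- function(x, allowed, required, path, section) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0)
    stop("config error in ", path, " [", section, "]: unknown key(s): ",
         paste(unknown, collapse = ", "),
         " (keys carry explicit unit suffixes, e.g. CL_renal_L_per_h)",
         call. = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss) > 0)
    stop("config error in ", path, " [", section, "]: missing required ",
         "key(s): ", paste(miss, collapse = ", "), call. = FALSE)
  invisible(x)
}

config_section <- function(path, section) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(raw[[section]]))
    stop("config error in ", path, ": expected top-level key '", section,
         "'", call. = FALSE)
  raw[[section]]
}

#' Read a compound configuration (YAML)
#'
#' The file must hold a top-level `compound:` mapping whose keys carry
#' explicit unit suffixes (`CL_renal_L_per_h`, `ka_per_h`, ...).  Unknown
#' keys are rejected with the offending key named; the result is validated
#' against the compound invariants.
#'
#' @param path YAML file path.
#' @return A [compound_spec()].
#' @export
read_compound_config <- function(path) {
  x <- config_section(path, "compound")
  check_keys(x, COMPOUND_KEYS,
             setdiff(COMPOUND_KEYS, c("pass_ratio_muscle",
                                      "pass_ratio_adipose")),
             path, "compound")
  do.call(compound_spec, x)
}

#' Read a physiology configuration (YAML)
#'
#' Top-level `physiology:` mapping; volumes in L, flows in L/h, bile flow in
#' mL/day (converted to L/h on load; 350 mL/day = 0.01458 L/h).
#'
#' @param path YAML file path.
#' @return A [physiology_spec()].
#' @export
read_physiology_config <- function(path) {
  x <- config_section(path, "physiology")
  check_keys(x, PHYSIOLOGY_KEYS,
             c("body_weight_kg", "tissue_volumes_L",
               "tissue_blood_flows_L_per_h"),
             path, "physiology")
  do.call(physiology_spec, x)
}

#' Read a genotype configuration (YAML)
#'
#' @param path YAML file path with a top-level `genotype:` mapping.
#' @return A [genotype_spec()].
#' @export
read_genotype_config <- function(path) {
  x <- config_section(path, "genotype")
  check_keys(x, GENOTYPE_KEYS,
             c("frequencies", "activity_ratio_1b", "activity_ratio_15",
               "f_OATP1B1"),
             path, "genotype")
  x$frequencies <- unlist(x$frequencies)
  do.call(genotype_spec, x)
}

#' Read a dosing-regimen configuration (YAML)
#'
#' @param path YAML file path with a top-level `regimen:` mapping.
#' @return A [dose_regimen()].
#' @export
read_regimen_config <- function(path) {
  x <- config_section(path, "regimen")
  check_keys(x, REGIMEN_KEYS, c("route", "dose_mg"), path, "regimen")
  do.call(dose_regimen, x)
}

#' Load a set of configuration files
#'
#' Dispatches each YAML file on its top-level key (`compound`, `physiology`,
#' `genotype`, `regimen`) and returns the validated specifications.
#'
#' @param paths character vector of YAML paths.
#' @return Named list with any of `compound`, `physiology`, `genotype`,
#'   `regimen`.
#' @export
load_configs <- function(paths) {
  out <- list()
  readers <- list(compound = read_compound_config,
                  physiology = read_physiology_config,
                  genotype = read_genotype_config,
                  regimen = read_regimen_config)
  for (p in paths) {
    if (!file.exists(p))
      stop("config error: file not found: ", p, call. = FALSE)
    raw <- yaml::read_yaml(p)
    kind <- intersect(names(raw), names(readers))
    if (length(kind) != 1)
      stop("config error in ", p, ": expected exactly one of the top-level ",
           "keys compound/physiology/genotype/regimen", call. = FALSE)
    out[[kind]] <- readers[[kind]](p)
  }
  out
}

strip_class <- function(x) {
  x <- unclass(x)
  x[!vapply(x, is.null, logical(1))]
}

#' Write specification objects back to YAML
#'
#' Inverse of the config readers (round-trip property: every written file is
#' re-loadable by [load_configs()]).
#'
#' @param spec a `compound_spec`, `physiology_spec`, `genotype_spec` or
#'   `dose_regimen`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(spec, path) {
  section <- if (inherits(spec, "compound_spec")) "compound"
  else if (inherits(spec, "physiology_spec")) "physiology"
  else if (inherits(spec, "genotype_spec")) "genotype"
  else if (inherits(spec, "dose_regimen")) "regimen"
  else stop("write_config: unsupported object", call. = FALSE)
  x <- strip_class(spec)
  if (section == "physiology")
    x <- x[PHYSIOLOGY_KEYS]          # drop derived V_bile / Q_liver_bile
  if (section == "genotype")
    x$frequencies <- as.list(x$frequencies)
  if (section == "regimen" && (is.na(x$infusion_duration_h %||% NA)))
    x$infusion_duration_h <- NULL
  yaml::write_yaml(setNames(list(x), section), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a concentration-time dataset (CSV + sidecar YAML)
#'
#' The CSV must have columns `time_h`, `conc_ng_per_mL` and optionally
#' `sd_ng_per_mL`; the dosing regimen comes from `regimen` or from a sidecar
#' YAML (same basename, `.yaml` extension) holding a `regimen:` mapping.
#' Malformed rows are reported with their row number.
#'
#' @param path CSV file path.
#' @param regimen optional [dose_regimen()] overriding the sidecar.
#' @param label dataset label (defaults to the file basename).
#' @return A [conc_time_series()].
#' @export
read_dataset <- function(path, regimen = NULL, label = NULL) {
  if (!file.exists(path))
    stop("dataset error: file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "conc_ng_per_mL")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("dataset error in ", path, ": missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in intersect(c(need, "sd_ng_per_mL"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0)
      stop("dataset error in ", path, ", column ", col, ", row ", bad[1],
           ": value '", df[[col]][bad[1]], "' is not numeric", call. = FALSE)
    df[[col]] <- v
  }
  nonmono <- which(diff(df$time_h) <= 0)
  if (length(nonmono) > 0)
    stop("dataset error in ", path, ", row ", nonmono[1] + 1,
         ": times must be strictly increasing", call. = FALSE)
  if (is.null(regimen)) {
    sidecar <- sub("\\.csv$", ".yaml", path)
    if (!file.exists(sidecar))
      stop("dataset error: no regimen given and sidecar ", sidecar,
           " not found", call. = FALSE)
    regimen <- read_regimen_config(sidecar)
  }
  conc_time_series(df$time_h, df$conc_ng_per_mL,
                   sd_ng_per_mL = df$sd_ng_per_mL,
                   regimen = regimen,
                   label = label %||% sub("\\.csv$", "", basename(path)))
}

#' Write a concentration-time dataset (CSV + sidecar YAML)
#'
#' @param dataset a [conc_time_series()].
#' @param path output CSV path; the regimen sidecar YAML is written next to
#'   it.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "conc_time_series"))
  df <- data.frame(time_h = dataset$times_h,
                   conc_ng_per_mL = dataset$conc_ng_per_mL)
  if (!is.null(dataset$sd_ng_per_mL))
    df$sd_ng_per_mL <- dataset$sd_ng_per_mL
  write.csv(df, path, row.names = FALSE)
  write_config(dataset$regimen, sub("\\.csv$", ".yaml", path))
  invisible(path)
}

#' Write simulation output (profile and per-compartment amounts CSVs)
#'
#' @param sim a [simulate_pbpk()] result.
#' @param profile_path CSV with `time_h`, `plasma_ng_per_mL`,
#'   `liver_ng_per_mL`.
#' @param amounts_path optional wide CSV of per-compartment amounts (ng).
#' @return `profile_path`, invisibly.
#' @export
write_simulation <- function(sim, profile_path, amounts_path = NULL) {
  stopifnot(inherits(sim, "pbpk_sim"))
  write.csv(data.frame(time_h = sim$time_h,
                       plasma_ng_per_mL = sim$plasma_ng_per_mL,
                       liver_ng_per_mL = sim$liver_ng_per_mL),
            profile_path, row.names = FALSE)
  if (!is.null(amounts_path))
    write.csv(data.frame(time_h = sim$time_h, sim$state_amounts_ng,
                         check.names = FALSE),
              amounts_path, row.names = FALSE)
  invisible(profile_path)
}

#' Build and write a run manifest
#'
#' Captures the command, configuration paths, per-stage seeds, package
#' version and timestamp of a run, for reproducibility.
#'
#' @param command command/subcommand name.
#' @param config_paths character vector of input paths.
#' @param seeds named list of the seed used by each stochastic stage (every
#'   stochastic stage must record one).
#' @param path optional JSON output path.
#' @return The manifest list (invisibly if written).
#' @export
run_manifest <- function(command, config_paths = character(),
                         seeds = list(), path = NULL) {
  if (length(seeds) > 0 &&
      (is.null(names(seeds)) || any(!nzchar(names(seeds)))))
    stop("run_manifest: every seed must be named by its stage",
         call. = FALSE)
  manifest <- list(
    command = command,
    config_paths = as.character(config_paths),
    seeds = seeds,
    package_version = as.character(packageVersion("oatpbpk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}
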