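#' Assemble a simulation scenario
#'
#' A scenario bundles one patient, one set of ventilator settings, one ECMO
#' circuit configuration and the gas constants under a name; it is the unit
#' the runner and the sweep engine operate on.
#'
#' @param name Non-empty scenario name.
#' @param patient [patient_params()].
#' @param vent [vent_settings()].
#' @param ecmo [ecmo_settings()].
#' @param constants [gas_constants()].
#' @return An object of class `ecmo_scenario`.
#' @export
scenario <- function(name, patient, vent, ecmo, constants = gas_constants()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("scenario name must be a non-empty string", call. = FALSE)
  }
  stopifnot(inherits(patient, "patient_params"),
            inherits(vent, "vent_settings"),
            inherits(ecmo, "ecmo_settings"),
            inherits(constants, "gas_constants"))
  structure(list(name = name, patient = patient, vent = vent, ecmo = ecmo,
                 constants = constants),
            class = "ecmo_scenario")
}

#' @export
print.ecmo_scenario <- function(x, ...) {
  cat("ecmo_scenario:", x$name, "\n")
  print(x$patient)
  print(x$vent)
  print(x$ecmo)
  invisible(x)
}

required_keys <- function(section, x, keys) {
  missing <- setdiff(keys, names(x))
  if (length(missing)) {
    stop("scenario validation: section '", section, "' is missing ",
         paste0("'", missing, "'", collapse = ", "), call. = FALSE)
  }
}

call_with <- function(fn, section, args) {
  ok <- names(args) %in% names(formals(fn))
  if (any(!ok)) {
    stop("scenario validation: unknown key",
         if (sum(!ok) > 1) "s" else "", " in section '", section, "': ",
         paste0("'", names(args)[!ok], "'", collapse = ", "), call. = FALSE)
  }
  tryCatch(do.call(fn, args), error = function(e) {
    stop("scenario validation: section '", section, "': ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Load and validate a scenario configuration file
#'
#' Reads a structured config (YAML or JSON, chosen by file extension) with
#' sections `patient`, `vent`, `ecmo` and optionally `constants`. Keys are
#' case-sensitive snake_case matching the constructor arguments; units are
#' fixed as documented there (no unit parsing). Defaults applied by the
#' constructors are echoed with `message()` unless `quiet = TRUE`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param quiet Suppress the echo of applied defaults.
#' @return A validated [scenario()].
#' @export
#' @examples
#' load_scenario(ecmosim_fixture("ultraprotective_on_ecmo"), quiet = TRUE)
load_scenario <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("no such scenario file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported scenario format '.", ext, "' (use YAML or JSON)",
         call. = FALSE)
  )
  required_keys("top level", cfg, c("name", "patient", "vent", "ecmo"))
  required_keys("patient", cfg$patient,
                c("cardiac_output", "hb", "vo2", "vco2", "shunt_fraction"))
  required_keys("vent", cfg$vent, c("peep", "rr", "cst"))
  if (is.null(cfg$vent$driving_pressure) && is.null(cfg$vent$vt_ml)) {
    stop("scenario validation: section 'vent' needs 'driving_pressure' or ",
         "'vt_ml'", call. = FALSE)
  }
  required_keys("ecmo", cfg$ecmo, c("blood_flow", "sweep_flow"))

  patient <- call_with(patient_params, "patient", cfg$patient)
  vent <- call_with(vent_settings, "vent", cfg$vent)
  ecmo <- call_with(ecmo_settings, "ecmo", cfg$ecmo)
  konst <- if (is.null(cfg$constants)) gas_constants() else {
    call_with(gas_constants, "constants", cfg$constants)
  }
  if (!quiet) {
    defaulted <- function(section, obj, given) {
      nm <- setdiff(names(obj), names(given))
      nm <- nm[!vapply(obj[nm], function(z) is.null(z) ||
                         (is.atomic(z) && all(is.na(z))), logical(1))]
      if (length(nm)) {
        message("scenario '", cfg$name, "': defaults applied in ", section,
                ": ", paste(nm, vapply(obj[nm], format, character(1)),
                            sep = "=", collapse = ", "))
      }
    }
    defaulted("patient", unclass(patient), cfg$patient)
    defaulted("vent", unclass(vent), cfg$vent)
    defaulted("ecmo", unclass(ecmo), cfg$ecmo)
  }
  scenario(cfg$name, patient, vent, ecmo, konst)
}

#' Path to a packaged scenario fixture
#'
#' @param name Fixture name (without extension); see [list_fixtures()].
#' @return File path inside the installed package.
#' @export
ecmosim_fixture <- function(name) {
  path <- system.file("extdata", paste0(name, ".yaml"), package = "ecmosim")
  if (!nzchar(path)) {
    stop("no packaged fixture '", name, "'; available: ",
         paste(list_fixtures(), collapse = ", "), call. = FALSE)
  }
  path
}

#' List packaged scenario fixtures
#'
#' @return Character vector of fixture names usable with
#'   [ecmosim_fixture()] and [load_scenario()].
#' @export
list_fixtures <- function() {
  files <- list.files(system.file("extdata", package = "ecmosim"),
                      pattern = "\\.yaml$")
  sub("\\.yaml$", "", files)
}

#' Run one scenario end to end
#'
#' Solves the steady state and reports, alongside it, the mechanical power
#' of the ventilator settings and the hypoxic-vasoconstriction stimulus PO2
#' computed from the converged gas tensions (alveolar PO2 at the arterial
#' PCO2; venous tension taken from pulmonary-artery blood, i.e. after ECMO
#' mixing).
#'
#' @param s [scenario()].
#' @param ... Passed to [solve_steady_state()] (`tol`, `max_iter`,
#'   `damping`).
#' @return An object of class `ecmo_report`: the scenario, the
#'   `ecmo_steady_state`, `mechanical_power` (J/min), `alveolar_po2` and
#'   `p_stimulus_o2` (mmHg). Deterministic: identical inputs give identical
#'   output.
#' @export
#' @examples
#' run_scenario(load_scenario(ecmosim_fixture("ultraprotective_on_ecmo"),
#'                            quiet = TRUE))
run_scenario <- function(s, ...) {
  stopifnot(inherits(s, "ecmo_scenario"))
  ss <- solve_steady_state(s$patient, s$vent, s$ecmo, konst = s$constants, ...)
  mp <- mechanical_power(s$vent)
  if (ss$converged) {
    pao2_alv <- alveolar_po2(s$vent$fio2, ss$arterial$pco2, s$constants)
    pstim <- p_stimulus_o2(pao2_alv, ss$pulmonary_artery$po2)
  } else {
    pao2_alv <- NA_real_
    pstim <- NA_real_
  }
  structure(list(scenario = s, steady_state = ss, mechanical_power = mp,
                 alveolar_po2 = pao2_alv, p_stimulus_o2 = pstim),
            class = "ecmo_report")
}

#' @export
print.ecmo_report <- function(x, ...) {
  cat("== scenario:", x$scenario$name, "==\n")
  cat(sprintf("mechanical power: %.2f J/min\n", x$mechanical_power))
  print(x$steady_state)
  if (!is.na(x$p_stimulus_o2)) {
    cat(sprintf("HPV stimulus PO2: %.1f mmHg (alveolar %.1f, pulm-artery %.1f)\n",
                x$p_stimulus_o2, x$alveolar_po2, x$steady_state$pulmonary_artery$po2))
  }
  invisible(x)
}

#' @export
as.data.frame.ecmo_report <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  s <- x$scenario
  inputs <- data.frame(
    scenario = s$name,
    cardiac_output = s$patient$cardiac_output, hb = s$patient$hb,
    vo2 = s$patient$vo2, vco2 = s$patient$vco2,
    shunt_fraction = s$patient$shunt_fraction, hco3 = s$patient$hco3,
    peep = s$vent$peep, driving_pressure = s$vent$driving_pressure,
    rr = s$vent$rr, vt_ml = 1000 * tidal_volume(s$vent),
    fio2 = s$vent$fio2,
    ecmo_blood_flow = s$ecmo$blood_flow, sweep_flow = s$ecmo$sweep_flow,
    sweep_fio2 = s$ecmo$sweep_fio2,
    membrane_o2_efficiency = s$ecmo$membrane_o2_efficiency,
    membrane_co2_efficiency = s$ecmo$membrane_co2_efficiency,
    recirculation_fraction = s$ecmo$recirculation_fraction
  )
  ss <- x$steady_state
  if (ss$converged) {
    outputs <- data.frame(
      converged = TRUE,
      pao2 = ss$arterial$po2, paco2 = ss$arterial$pco2,
      ph_a = ss$arterial$ph, sat_a = ss$arterial$sat,
      pvo2 = ss$mixed_venous$po2, pvco2 = ss$mixed_venous$pco2,
      sat_v = ss$mixed_venous$sat, pa_po2 = ss$pulmonary_artery$po2,
      ecmo_o2_transfer = ss$ecmo_o2_transfer,
      lung_o2_transfer = ss$lung_o2_transfer,
      ecmo_vco2 = ss$ecmo_vco2, lung_vco2 = ss$lung_vco2,
      mechanical_power = x$mechanical_power,
      p_stimulus_o2 = x$p_stimulus_o2,
      iterations = ss$iterations
    )
  } else {
    outputs <- data.frame(
      converged = FALSE,
      pao2 = NA_real_, paco2 = NA_real_, ph_a = NA_real_, sat_a = NA_real_,
      pvo2 = NA_real_, pvco2 = NA_real_, sat_v = NA_real_, pa_po2 = NA_real_,
      ecmo_o2_transfer = NA_real_, lung_o2_transfer = NA_real_,
      ecmo_vco2 = NA_real_, lung_vco2 = NA_real_,
      mechanical_power = x$mechanical_power, p_stimulus_o2 = NA_real_,
      iterations = ss$iterations
    )
  }
  cbind(inputs, outputs)
}

# rebuild a scenario from raw field values, re-running all validation
rebuild_scenario <- function(name, pt, vt, ec, konst) {
  scenario(
    name,
    patient_params(pt$cardiac_output, pt$hb, pt$vo2, pt$vco2,
                   pt$shunt_fraction, pt$hco3, pt$ideal_body_weight),
    vent_settings(mode = vt$mode, peep = vt$peep,
                  driving_pressure = vt$driving_pressure, rr = vt$rr,
                  t_insp = vt$t_insp, raw = vt$raw, cst = vt$cst,
                  fio2 = vt$fio2, dead_space = vt$dead_space),
    ecmo_settings(ec$blood_flow, ec$sweep_flow, ec$sweep_fio2,
                  ec$membrane_o2_efficiency, ec$membrane_co2_efficiency,
                  ec$recirculation_fraction),
    konst
  )
}

#' Sweep one scenario parameter
#'
#' Re-runs the scenario once per value of a single parameter addressed by a
#' dotted path (`"ecmo.blood_flow"`, `"vent.peep"`, `"patient.hb"`, ...).
#' Rows come back in the order of `values`; a point whose steady state is
#' infeasible or non-converged is flagged in the `converged` column and the
#' sweep continues.
#'
#' @param s Base [scenario()].
#' @param parameter_path Dotted path into the scenario
#'   (`section.field`).
#' @param values Non-empty numeric vector of finite parameter values.
#' @param ... Passed to [solve_steady_state()].
#' @return `data.frame`, one row per value: all scenario inputs followed by
#'   the steady-state outputs, with a `swept_parameter` column.
#' @export
#' @examples
#' s <- load_scenario(ecmosim_fixture("ultraprotective_on_ecmo"), quiet = TRUE)
#' run_sweep(s, "ecmo.sweep_flow", c(2, 4, 6))
run_sweep <- function(s, parameter_path, values, ...) {
  stopifnot(inherits(s, "ecmo_scenario"))
  if (length(values) == 0L || any(!is.finite(values))) {
    stop("values must be a non-empty vector of finite numbers", call. = FALSE)
  }
  parts <- strsplit(parameter_path, ".", fixed = TRUE)[[1L]]
  if (length(parts) != 2L ||
      !parts[[1L]] %in% c("patient", "vent", "ecmo", "constants")) {
    stop("parameter_path must be 'patient.<field>', 'vent.<field>', ",
         "'ecmo.<field>' or 'constants.<field>'; got '", parameter_path, "'",
         call. = FALSE)
  }
  section <- parts[[1L]]
  field <- parts[[2L]]
  if (!field %in% names(s[[section]])) {
    stop("unknown field '", field, "' in section '", section, "'",
         call. = FALSE)
  }
  rows <- vector("list", length(values))
  prev <- NULL # warm start from the neighbouring converged point
  for (i in seq_along(values)) {
    val <- values[[i]]
    pt <- unclass(s$patient)
    vt <- unclass(s$vent)
    ec <- unclass(s$ecmo)
    ko <- unclass(s$constants)
    if (section == "patient") pt[[field]] <- val
    if (section == "vent") vt[[field]] <- val
    if (section == "ecmo") ec[[field]] <- val
    if (section == "constants") ko[[field]] <- val
    if (section == "vent" && field == "vt_ml") {
      vt$driving_pressure <- val / vt$cst
    }
    konst <- do.call(gas_constants, ko[names(formals(gas_constants))])
    si <- rebuild_scenario(s$name, pt, vt, ec, konst)
    rep_i <- run_scenario(si, init = prev, ...)
    ss <- rep_i$steady_state
    if (ss$converged && section != "patient") {
      prev <- list(o2_content = ss$mixed_venous$o2_content,
                   co2_content = ss$mixed_venous$co2_content)
    } else {
      prev <- NULL # Hb/contents change meaning across patient sweeps
    }
    rows[[i]] <- cbind(swept_parameter = parameter_path,
                       as.data.frame(rep_i))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a result table to CSV
#'
#' Fixed column order (inputs then outputs), `.` decimal separator, no
#' locale-dependent formatting; re-running the same scenario yields a
#' byte-identical file.
#'
#' @param x `data.frame` from [run_sweep()] or
#'   `as.data.frame(run_scenario(...))`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
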