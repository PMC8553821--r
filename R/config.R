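#' @include protocol.R
NULL

.configFieldMaps <- list(
  kon = c(k_on_min = "kOnMin", k_on_max = "kOnMax",
          e_half_scram = "eHalfScram", e_half_havdi = "eHalfHavdi",
          sharpness = "sharpness"),
  clutch = c(n_motors = "nMotors", motor_stall_force = "motorStallForce",
             unloaded_velocity = "unloadedVelocity",
             n_clutches = "nClutches", clutch_stiffness = "clutchStiffness",
             k_off0 = "kOff0", bell_force = "bellForce",
             adhesion_radius = "adhesionRadius", dt = "dt",
             n_steps = "nSteps", burn_in_fraction = "burnInFraction"),
  nucleus = c(nuclear_stiffness = "nuclearStiffness",
              nuclear_viscosity = "nuclearViscosity",
              plastic_viscosity = "plasticViscosity",
              yield_force = "yieldForce",
              baseline_flattening = "baselineFlattening"),
  yap = c(slope = "slope", intercept = "intercept",
          relaxation_time = "relaxationTime"))

.paramsFromList <- function(section, values, constructor) {
  map <- .configFieldMaps[[section]]
  unknown <- setdiff(names(values), names(map))
  if (length(unknown))
    stop(sprintf("unknown key(s) under '%s:': %s", section,
                 paste(unknown, collapse = ", ")))
  do.call(constructor, setNames(values, map[names(values)]))
}

#' Read model parameters from a YAML configuration file
#'
#' The file may contain any of the sections `kon:`, `clutch:`, `nucleus:`
#' and `yap:`, with snake_case keys named after the parameter fields (e.g.
#' `k_on_min`, `e_half_scram`, `n_motors`, `yield_force`,
#' `relaxation_time`). Missing sections and keys keep the package defaults;
#' unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A named list with elements `kon` ([KonParams]), `clutch`
#'   ([ClutchParams]), `nucleus` ([NucleusParams]) and `yap` ([YapParams]).
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines("kon:\n  sharpness: 3.0\nclutch:\n  n_steps: 20000", cfg)
#' loadParams(cfg)$kon
#' @export
loadParams <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("configuration file must be a YAML mapping")
  unknown <- setdiff(names(raw), names(.configFieldMaps))
  if (length(unknown))
    stop("unknown configuration section(s): ",
         paste(unknown, collapse = ", "))
  constructors <- list(kon = KonParams, clutch = ClutchParams,
                       nucleus = NucleusParams, yap = YapParams)
  out <- lapply(names(constructors), function(sec) {
    vals <- raw[[sec]]
    if (is.null(vals)) constructors[[sec]]()
    else .paramsFromList(sec, vals, constructors[[sec]])
  })
  setNames(out, names(constructors))
}
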