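#' @include AllGenerics.R
NULL

#' Advance the viscoelastic-plastic nucleus under constant traction
#'
#' Exact update over a constant-traction interval `dt`:
#' the elastic (Kelvin-Voigt) strain relaxes exponentially toward its
#' equilibrium `traction / nuclearStiffness` with time constant
#' `tau_e = nuclearViscosity / nuclearStiffness`, and the plastic strain
#' flows at `max(0, traction - yieldForce) / plasticViscosity` (per day).
#' Plastic strain never decreases: unloading leaves it untouched, which is
#' what makes the stored deformation a mechanical memory.
#'
#' @param state A [NucleusState].
#' @param traction Constant traction over the interval, pN (>= 0).
#' @param dt Interval length, s (> 0).
#' @param params A [NucleusParams] parameter set.
#' @return The updated [NucleusState] with `time` advanced by `dt`.
#' @examples
#' st <- updateNucleus(NucleusState(), traction = 100, dt = 3600)
#' flattening(st)
#' @export
updateNucleus <- function(state, traction, dt, params = NucleusParams()) {
  validObject(state)
  validObject(params)
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number of seconds")
  if (!is.numeric(traction) || length(traction) != 1 ||
      !is.finite(traction) || traction < 0)
    stop("traction must be a single non-negative force in pN")
  tauE <- params@nuclearViscosity / params@nuclearStiffness
  eq <- traction / params@nuclearStiffness
  epsE <- eq + (state@elasticStrain - eq) * exp(-dt / tauE)
  plasticRate <- max(0, traction - params@yieldForce) /
    (params@plasticViscosity * 86400)
  NucleusState(elasticStrain = epsE,
               plasticStrain = state@plasticStrain + plasticRate * dt,
               time = state@time + dt)
}

#' Nuclear flattening (length/height ratio)
#'
#' @rdname flattening
#' @param object A [NucleusState] (or a `NucleusGeometry`, for which the
#'   measured ratio is returned).
#' @param ... Passed to methods.
#' @return The dimensionless flattening ratio (>= baseline).
#' @param params A [NucleusParams] parameter set (nucleus-state method
#'   only).
#' @details For a [NucleusState] the nuclear flattening (length/height
#'   ratio) is `baselineFlattening * (1 + elastic + plastic strain)`; it
#'   never drops below the baseline and increases with either strain.
#' @examples
#' flattening(NucleusState(elasticStrain = 0.2, plasticStrain = 0.3),
#'            NucleusParams(baselineFlattening = 2))  # 3
#' @export
setMethod("flattening", "NucleusState", function(object, ...,
                                                 params = NucleusParams()) {
  validObject(object)
  validObject(params)
  params@baselineFlattening *
    (1 + object@elasticStrain + object@plasticStrain)
})

#' Steady-state YAP n/c ratio implied by nuclear flattening
#'
#' Linear law `R = slope * lambda + intercept`, floored at 0.1 (a ratio of
#' total intensities cannot reach zero). Mechanistically, flatter nuclei
#' have enlarged nuclear pores and a higher YAP import rate at unchanged
#' export, so the steady ratio rises linearly with flattening.
#'
#' @param lambda Nuclear flattening value(s) (>= 1).
#' @param params A [YapParams] parameter set.
#' @return Target ratio(s).
#' @examples
#' yapTarget(c(2, 4))
#' @export
yapTarget <- function(lambda, params = YapParams()) {
  validObject(params)
  if (!is.numeric(lambda) || any(!is.finite(lambda)) || any(lambda < 1))
    stop("lambda must be finite and >= 1")
  pmax(0.1, params@slope * lambda + params@intercept)
}

#' Relax the YAP n/c ratio toward its flattening-determined target
#'
#' Exact exponential update of `dR/dt = (target - R) / relaxationTime` over
#' a constant-target interval.
#'
#' @param state A [YapState].
#' @param target Target ratio (> 0).
#' @param dt Interval, s (> 0).
#' @param params A [YapParams] parameter set.
#' @return The updated [YapState].
#' @examples
#' relaxYap(YapState(ratio = 3), target = 1.3, dt = 7200)
#' @export
relaxYap <- function(state, target, dt, params = YapParams()) {
  validObject(state)
  validObject(params)
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number of seconds")
  stopifnot(is.numeric(target), length(target) == 1, is.finite(target),
            target > 0)
  YapState(ratio = target + (state@ratio - target) *
             exp(-dt / params@relaxationTime),
           time = state@time + dt)
}
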