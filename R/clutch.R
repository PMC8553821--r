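#' @include kon.R
NULL

#' Substrate spring constant from Young's modulus
#'
#' Point-contact conversion of the substrate modulus into the local spring
#' the adhesion loads: `kappa_sub = a * E_sub`, with the adhesion radius `a`
#' taken from `params`. In the package units (E in Pa, a in nm) this is
#' `E_sub * a * 1e-6` pN/nm, e.g. 20 kPa with a 1 um contact gives
#' 20 pN/nm.
#'
#' @param cond An [AdhesionCondition].
#' @param params A [ClutchParams] parameter set (uses `adhesionRadius`).
#' @return Substrate spring constant, pN/nm; strictly linear in the modulus.
#' @examples
#' substrateSpring(scramCondition(20e3))
#' @export
substrateSpring <- function(cond, params = ClutchParams()) {
  validObject(cond)
  validObject(params)
  cond@youngModulus * params@adhesionRadius * 1e-6
}

#' Bell slip-bond unbinding rate
#'
#' `k_off = k_off0 * exp(load / bellForce)`: the clutch off-rate grows
#' exponentially with the load it carries.
#'
#' @param load Clutch load, pN (>= 0; vectorized).
#' @param params A [ClutchParams] parameter set.
#' @return Unbinding rate(s), 1/s.
#' @examples
#' unbindingRate(c(0, 2, 4), ClutchParams())  # k_off0 * c(1, e, e^2)
#' @export
unbindingRate <- function(load, params = ClutchParams()) {
  validObject(params)
  if (!is.numeric(load) || any(!is.finite(load)) || any(load < 0))
    stop("load must be finite and >= 0 pN")
  params@kOff0 * exp(load / params@bellForce)
}

#' Ensemble retrograde actin velocity under load
#'
#' Linear force-velocity relation of the motor ensemble:
#' `v = v_u * (1 - F / (n_m * F_m))`, clamped at zero beyond stall. Traction
#' transiently above the ensemble stall force is tolerated with a warning
#' (it can occur for one step of the discrete scheme).
#'
#' @param traction Traction force, pN (>= 0; vectorized).
#' @param params A [ClutchParams] parameter set.
#' @return Retrograde velocity(ies), nm/s.
#' @examples
#' retrogradeVelocity(c(0, 50, 100), ClutchParams())
#' @export
retrogradeVelocity <- function(traction, params = ClutchParams()) {
  validObject(params)
  if (!is.numeric(traction) || any(!is.finite(traction)) || any(traction < 0))
    stop("traction must be finite and >= 0 pN")
  stall <- params@nMotors * params@motorStallForce
  if (any(traction > stall))
    warning("traction above ensemble stall force; velocity clamped to 0")
  pmax(0, params@unloadedVelocity * (1 - traction / stall))
}

#' Simulate steady-state traction of the motor-clutch ensemble
#'
#' Fixed-time-step Monte Carlo of `nClutches` molecular clutches engaging a
#' substrate spring under myosin pulling (see [ClutchParams] for the scheme
#' and [computeKon()] for the binding rate). Statistics are time averages
#' over the post-burn-in window; standard errors use batch means. Runs are
#' reproducible given `seed`.
#'
#' @param cond An [AdhesionCondition].
#' @param params A [ClutchParams] parameter set.
#' @param konParams A [KonParams] set mapping the condition to the binding
#'   rate; ignored when `kOn` is given.
#' @param seed Integer RNG seed.
#' @param kOn Optional fixed binding rate, 1/s (>= 0), bypassing the
#'   stiffness/HAVDI dependence (e.g. to recover the constant-`k_on` base
#'   model).
#' @param trace If `TRUE`, attach a thinned traction time series.
#' @param traceStride Steps between trace samples.
#' @param diagnostics If `TRUE`, track the worst force-balance residual over
#'   the run (machine-precision check of `kappa_sub x_sub = sum of clutch
#'   forces`), returned as attribute `maxBalanceError`.
#' @return A `TractionSummary`.
#' @examples
#' simulateTraction(scramCondition(20e3),
#'                  ClutchParams(nSteps = 2e4), seed = 1)
#' @export
simulateTraction <- function(cond, params = ClutchParams(),
                             konParams = KonParams(), seed = 1L,
                             kOn = NULL, trace = FALSE, traceStride = 100L,
                             diagnostics = FALSE) {
  validObject(cond)
  validObject(params)
  if (is.null(kOn)) {
    kOn <- computeKon(cond, konParams)
  } else {
    stopifnot(is.numeric(kOn), length(kOn) == 1, is.finite(kOn), kOn >= 0)
  }
  kappaSub <- substrateSpring(cond, params)
  set.seed(as.integer(seed))
  res <- clutch_engine(
    kappa_sub = kappaSub, kappa_c = params@clutchStiffness,
    n_clutches = params@nClutches, n_motors = params@nMotors,
    motor_stall_force = params@motorStallForce,
    unloaded_velocity = params@unloadedVelocity,
    k_on = kOn, k_off0 = params@kOff0, bell_force = params@bellForce,
    dt = params@dt, n_steps = params@nSteps,
    burn_in_fraction = params@burnInFraction,
    diagnostics = diagnostics,
    trace_stride = if (trace) as.integer(traceStride) else 0L)
  out <- new("TractionSummary",
             meanTraction = res$mean_traction,
             semTraction = res$sem_traction,
             meanVelocity = res$mean_velocity,
             meanBoundFraction = res$mean_bound_fraction,
             semBoundFraction = res$sem_bound_fraction,
             trace = res$trace,
             condition = cond@label,
             seed = as.integer(seed))
  if (diagnostics) attr(out, "maxBalanceError") <- res$max_balance_error
  out
}

#' Replicate-averaged traction over a stiffness grid
#'
#' Runs [simulateTraction()] for every combination of substrate stiffness
#' and HAVDI occupancy, averaging `nReplicates` independent runs per
#' condition. Replicate seeds are drawn deterministically from `seed`, so
#' the whole sweep is reproducible given `(seed, grid order)`.
#'
#' @param stiffnessGrid Vector of substrate Young's moduli, Pa (non-empty).
#' @param havdiOccupancy HAVDI occupancy value(s) in \[0, 1\].
#' @param params A [ClutchParams] parameter set.
#' @param konParams A [KonParams] parameter set.
#' @param nReplicates Independent runs per condition (>= 1).
#' @param seed Integer master seed.
#' @param kOn Optional fixed binding rate passed through to
#'   [simulateTraction()].
#' @return A data frame with one row per (stiffness, occupancy):
#'   `E_sub_Pa`, `havdi`, `mean_traction_pN`, `sem_traction_pN` (SEM across
#'   replicates; within-run batch SEM when `nReplicates == 1`),
#'   `mean_velocity_nm_s`, `bound_fraction`, `n_replicates`, `seed`.
#' @examples
#' stiffnessSweep(c(1e3, 15e3), havdiOccupancy = c(0, 1),
#'                params = ClutchParams(nSteps = 2e4), nReplicates = 2)
#' @export
stiffnessSweep <- function(stiffnessGrid, havdiOccupancy = c(0, 1),
                           params = ClutchParams(), konParams = KonParams(),
                           nReplicates = 10L, seed = 1L, kOn = NULL) {
  stopifnot(is.numeric(stiffnessGrid), length(stiffnessGrid) > 0,
            all(stiffnessGrid > 0),
            is.numeric(havdiOccupancy),
            all(havdiOccupancy >= 0 & havdiOccupancy <= 1),
            nReplicates >= 1)
  grid <- expand.grid(E_sub_Pa = stiffnessGrid, havdi = havdiOccupancy,
                      KEEP.OUT.ATTRS = FALSE)
  set.seed(as.integer(seed))
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             nrow(grid) * nReplicates),
                  nrow = nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cond <- AdhesionCondition(youngModulus = grid$E_sub_Pa[i],
                              havdiOccupancy = grid$havdi[i])
    reps <- lapply(seq_len(nReplicates), function(r) {
      tryCatch(
        simulateTraction(cond, params, konParams, seed = seeds[i, r],
                         kOn = kOn),
        error = function(e) stop(sprintf(
          "condition E_sub = %g Pa, havdi = %g, replicate %d: %s",
          grid$E_sub_Pa[i], grid$havdi[i], r, conditionMessage(e)),
          call. = FALSE))
    })
    tr <- vapply(reps, meanTraction, numeric(1))
    data.frame(
      E_sub_Pa = grid$E_sub_Pa[i], havdi = grid$havdi[i],
      mean_traction_pN = mean(tr),
      sem_traction_pN = if (nReplicates > 1)
        stats::sd(tr) / sqrt(nReplicates) else reps[[1]]@semTraction,
      mean_velocity_nm_s = mean(vapply(reps, meanVelocity, numeric(1))),
      bound_fraction = mean(vapply(reps, boundFraction, numeric(1))),
      n_replicates = as.integer(nReplicates), seed = as.integer(seed))
  })
  do.call(rbind, rows)
}
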