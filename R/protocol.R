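#' @include clutch.R nucleus.R
NULL

.conditionKey <- function(cond) {
  sprintf("%.8g|%.6f", cond@youngModulus, cond@havdiOccupancy)
}

# deterministic small hash of a cache key, for per-condition seed derivation
.keyHash <- function(key) {
  v <- utf8ToInt(key)
  as.integer(sum(v * seq_along(v)) %% 65536L)
}

#' Steady-state traction for a condition, replicate-averaged and cached
#'
#' The clutch ensemble equilibrates in seconds to minutes while protocols
#' run for days, so protocols use a quasi-static coupling: the Monte Carlo
#' is run to steady state once per condition and its replicate-averaged
#' mean traction is used as a constant input to the nucleus dynamics.
#' Replicate seeds derive deterministically from `seed` and the condition,
#' so results do not depend on evaluation order.
#'
#' @param cond An [AdhesionCondition].
#' @param params A [ClutchParams] parameter set.
#' @param konParams A [KonParams] parameter set.
#' @param nReplicates Independent runs averaged (>= 1).
#' @param seed Integer master seed.
#' @param cache Optional environment used to memoise tractions across calls
#'   (e.g. across the runs of a panel).
#' @return Mean steady-state traction, pN.
#' @examples
#' steadyTraction(scramCondition(20e3), ClutchParams(nSteps = 2e4),
#'                nReplicates = 2)
#' @export
steadyTraction <- function(cond, params = ClutchParams(),
                           konParams = KonParams(), nReplicates = 10L,
                           seed = 1L, cache = NULL) {
  key <- .conditionKey(cond)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  base <- (as.integer(seed) %% 1000000L) * 1000L + .keyHash(key)
  tr <- vapply(seq_len(nReplicates), function(r) {
    meanTraction(simulateTraction(cond, params, konParams,
                                  seed = base + r))
  }, numeric(1))
  out <- mean(tr)
  if (!is.null(cache)) cache[[key]] <- out
  out
}

.integrateStep <- function(nucleus, yap, traction, durationDays, dtDays,
                           nucleusParams, yapParams, startDay) {
  nSub <- max(1L, ceiling(durationDays / dtDays - 1e-9))
  dtS <- durationDays * 86400 / nSub
  timeD <- tractionOut <- lambdaOut <- ratioOut <- numeric(nSub)
  for (i in seq_len(nSub)) {
    nucleus <- updateNucleus(nucleus, traction, dtS, nucleusParams)
    lam <- flattening(nucleus, params = nucleusParams)
    yap <- relaxYap(yap, yapTarget(lam, yapParams), dtS, yapParams)
    timeD[i] <- startDay + i * dtS / 86400
    tractionOut[i] <- traction
    lambdaOut[i] <- lam
    ratioOut[i] <- yap@ratio
  }
  list(nucleus = nucleus, yap = yap,
       frame = data.frame(time_d = timeD, traction_pN = tractionOut,
                          lambda_N = lambdaOut, R_NC = ratioOut))
}

#' Run a culture/transfer protocol through the full model chain
#'
#' For each [ProtocolStep], the steady-state traction of its condition is
#' obtained once from the clutch simulation (replicate-averaged, cached per
#' condition) and the nucleus and YAP states are integrated on the protocol
#' time grid with that constant traction; state carries over across steps.
#' The cell starts from rest: zero strains, YAP at the zero-strain fixed
#' point.
#'
#' The memory residual is computed against a soft-control baseline: a
#' rest-start run of the final step's condition for the final step's
#' duration (for a single-step protocol the baseline is the run itself, so
#' the residual is exactly zero).
#'
#' @param steps A list of [ProtocolStep]s (non-empty), e.g. 10 d on TCP then
#'   10 d on a 20 kPa hydrogel.
#' @param clutchParams,konParams,nucleusParams,yapParams Model parameter
#'   sets.
#' @param seed Integer master seed for the traction simulations.
#' @param protocolDt Integration step, days.
#' @param nReplicates Clutch-simulation replicates per condition.
#' @param cache Optional environment memoising condition tractions.
#' @param computeBaseline Internal; disables baseline recursion.
#' @return A `ProtocolResult`.
#' @examples
#' fast <- ClutchParams(nSteps = 2e4)
#' runProtocol(list(ProtocolStep(tcpCondition(), 3),
#'                  ProtocolStep(scramCondition(20e3), 3)),
#'             clutchParams = fast, nReplicates = 2)
#' @export
runProtocol <- function(steps, clutchParams = ClutchParams(),
                        konParams = KonParams(),
                        nucleusParams = NucleusParams(),
                        yapParams = YapParams(), seed = 1L,
                        protocolDt = 0.05, nReplicates = 10L,
                        cache = NULL, computeBaseline = TRUE) {
  if (!is.list(steps) || length(steps) == 0 ||
      !all(vapply(steps, is, logical(1), "ProtocolStep")))
    stop("steps must be a non-empty list of ProtocolStep objects")
  for (s in steps) validObject(s)
  validObject(nucleusParams)
  validObject(yapParams)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())

  nucleus <- NucleusState()
  lam0 <- nucleusParams@baselineFlattening
  yap <- YapState(ratio = yapTarget(lam0, yapParams))
  frames <- vector("list", length(steps))
  day <- 0
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    traction <- tryCatch(
      steadyTraction(st@condition, clutchParams, konParams, nReplicates,
                     seed, cache),
      error = function(e) stop(sprintf("protocol step %d: %s", i,
                                       conditionMessage(e)), call. = FALSE))
    out <- .integrateStep(nucleus, yap, traction, st@duration, protocolDt,
                          nucleusParams, yapParams, day)
    nucleus <- out$nucleus
    yap <- out$yap
    frames[[i]] <- out$frame
    day <- day + st@duration
  }
  tc <- do.call(rbind, frames)
  endpoint <- tc$R_NC[nrow(tc)]

  baselineRatio <- endpoint
  if (computeBaseline) {
    last <- steps[[length(steps)]]
    if (length(steps) == 1) {
      baselineRatio <- endpoint   # the run is its own soft control
    } else {
      base <- runProtocol(list(last), clutchParams, konParams,
                          nucleusParams, yapParams, seed, protocolDt,
                          nReplicates, cache, computeBaseline = FALSE)
      baselineRatio <- base@endpointRatio
    }
  }
  labels <- vapply(steps, function(s) {
    lb <- s@condition@label
    if (is.na(lb)) lb <- sprintf("%.3g Pa", s@condition@youngModulus)
    sprintf("%s %g d", lb, s@duration)
  }, character(1))
  new("ProtocolResult", timeGrid = tc$time_d, traction = tc$traction_pN,
      flattening = tc$lambda_N, yapRatio = tc$R_NC,
      endpointRatio = endpoint, baselineRatio = baselineRatio,
      residual = endpoint - baselineRatio, stepLabels = labels)
}

#' Dosing/transfer memory panel
#'
#' Runs the full dosing experiment: culture on TCP for each dosing duration,
#' transfer to each soft condition for each post-transfer duration, and
#' report endpoint YAP n/c ratios and their residuals above the matching
#' soft-control baseline. Condition tractions are computed once and shared
#' across the whole panel.
#'
#' @param dosingDays Days of TCP culture (>= 0; 0 means no TCP step).
#' @param postDays Days on the soft substrate after transfer (> 0).
#' @param conditions List of post-transfer [AdhesionCondition]s; defaults to
#'   20 kPa Scram/RGD and HAVDI/RGD.
#' @param dosingCondition The stiff-priming condition (default TCP, 3 GPa).
#' @inheritParams runProtocol
#' @return A data frame with columns `dosing_d`, `post_d`, `condition`,
#'   `traction_post_pN`, `endpoint_R_NC`, `baseline_R_NC`, `residual`.
#' @examples
#' fast <- ClutchParams(nSteps = 2e4)
#' memoryPanel(c(0, 10), 1, clutchParams = fast, nReplicates = 2)
#' @export
memoryPanel <- function(dosingDays, postDays,
                        conditions = list(scramCondition(20e3),
                                          havdiCondition(20e3)),
                        dosingCondition = tcpCondition(),
                        clutchParams = ClutchParams(),
                        konParams = KonParams(),
                        nucleusParams = NucleusParams(),
                        yapParams = YapParams(), seed = 1L,
                        protocolDt = 0.05, nReplicates = 10L) {
  stopifnot(length(dosingDays) > 0, all(dosingDays >= 0),
            length(postDays) > 0, all(postDays > 0),
            length(conditions) > 0)
  cache <- new.env(parent = emptyenv())
  rows <- list()
  for (cond in conditions) {
    for (d in dosingDays) {
      for (p in postDays) {
        steps <- list(ProtocolStep(cond, p))
        if (d > 0)
          steps <- c(list(ProtocolStep(dosingCondition, d)), steps)
        res <- runProtocol(steps, clutchParams, konParams, nucleusParams,
                           yapParams, seed, protocolDt, nReplicates, cache)
        rows[[length(rows) + 1L]] <- data.frame(
          dosing_d = d, post_d = p,
          condition = if (is.na(cond@label)) .conditionKey(cond) else
            cond@label,
          traction_post_pN = res@traction[length(res@traction)],
          endpoint_R_NC = res@endpointRatio,
          baseline_R_NC = res@baselineRatio,
          residual = res@residual)
      }
    }
  }
  do.call(rbind, rows)
}

#' Calibrate the plastic yield force and plastic viscosity
#'
#' The nucleus defaults are anchored to the traction model:
#' the yield force is set to the steady traction on a 20 kPa Scram/RGD
#' substrate (so soft culture alone never writes plastic memory), and the
#' plastic viscosity is chosen so that `targetDays` of TCP culture
#' accumulate a plastic strain of `targetStrain`. This helper recomputes
#' both from the current clutch/binding parameters and returns a
#' [NucleusParams] object with the remaining slots taken from `base`.
#'
#' @param clutchParams,konParams Traction-model parameter sets.
#' @param base A [NucleusParams] supplying the non-calibrated slots.
#' @param softCondition The soft reference condition (default 20 kPa
#'   Scram/RGD).
#' @param stiffCondition The memory-writing condition (default TCP).
#' @param targetStrain,targetDays Plastic strain accumulated after
#'   `targetDays` on the stiff condition.
#' @param nReplicates,seed Replication and seeding of the traction runs.
#' @return A [NucleusParams] with calibrated `yieldForce` and
#'   `plasticViscosity`.
#' @examples
#' calibrateYieldForce(ClutchParams(nSteps = 2e4), nReplicates = 2)
#' @export
calibrateYieldForce <- function(clutchParams = ClutchParams(),
                                konParams = KonParams(),
                                base = NucleusParams(),
                                softCondition = scramCondition(20e3),
                                stiffCondition = tcpCondition(),
                                targetStrain = 0.5, targetDays = 10,
                                nReplicates = 10L, seed = 1L) {
  cache <- new.env(parent = emptyenv())
  fSoft <- steadyTraction(softCondition, clutchParams, konParams,
                          nReplicates, seed, cache)
  fStiff <- steadyTraction(stiffCondition, clutchParams, konParams,
                           nReplicates, seed, cache)
  if (fStiff <= fSoft)
    stop("stiff-condition traction does not exceed the soft reference; ",
         "cannot calibrate a plastic viscosity")
  NucleusParams(nuclearStiffness = base@nuclearStiffness,
                nuclearViscosity = base@nuclearViscosity,
                plasticViscosity = (fStiff - fSoft) * targetDays /
                  targetStrain,
                yieldForce = fSoft,
                baselineFlattening = base@baselineFlattening)
}
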