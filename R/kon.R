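#' @include AllGenerics.R
NULL

.konRate <- function(youngModulus, havdi, params) {
  eHalf <- params@eHalfScram^(1 - havdi) * params@eHalfHavdi^havdi
  act <- stats::plogis(params@sharpness * (log(youngModulus) - log(eHalf)))
  params@kOnMin + (params@kOnMax - params@kOnMin) * act
}

#' Clutch binding rate under stiffness and HAVDI ligation
#'
#' The single knob through which N-cadherin ligation alters mechanosensing
#' in this model: an activation (Boltzmann/Arrhenius-type) law in log
#' substrate stiffness,
#' \deqn{k_{on} = k_{min} + (k_{max}-k_{min})\,
#'   \left[1 + e^{-s(\ln E_{sub} - \ln E_{1/2}(h))}\right]^{-1},}
#' where the activation midpoint interpolates geometrically between the
#' Scram and full-HAVDI midpoints,
#' \eqn{E_{1/2}(h) = E_{scram}^{1-h} E_{havdi}^{h}}. The rate is
#' non-decreasing in stiffness (stiffer substrates recruit more integrin)
#' and non-increasing in HAVDI occupancy (adherens-junction signalling
#' lowers the available integrin density), so HAVDI raises the stiffness
#' threshold for fast binding without changing the plateau.
#'
#' @param cond An [AdhesionCondition].
#' @param params A [KonParams] parameter set.
#' @return Binding rate in 1/s, within `[kOnMin, kOnMax]`.
#' @examples
#' computeKon(AdhesionCondition(15e3, havdiOccupancy = 0))
#' computeKon(AdhesionCondition(15e3, havdiOccupancy = 1))
#' @export
setGeneric("computeKon", function(cond, params = KonParams())
  standardGeneric("computeKon"))

#' @rdname computeKon
setMethod("computeKon", "AdhesionCondition", function(cond, params) {
  validObject(cond)
  validObject(params)
  .konRate(cond@youngModulus, cond@havdiOccupancy, params)
})

#' Tabulate the binding rate over a stiffness grid
#'
#' @param stiffness Vector of substrate Young's moduli, Pa (> 0).
#' @param havdi HAVDI occupancy fraction(s) in \[0, 1\] (recycled against
#'   `stiffness` as a grid: one block of rows per occupancy value).
#' @param params A [KonParams] parameter set.
#' @return A data frame with columns `E_sub_Pa`, `havdi`, `k_on_per_s`.
#' @examples
#' konCurve(c(1e3, 15e3, 41e3), havdi = c(0, 1))
#' @export
konCurve <- function(stiffness, havdi = c(0, 1), params = KonParams()) {
  stopifnot(is.numeric(stiffness), length(stiffness) > 0, all(stiffness > 0),
            is.numeric(havdi), all(havdi >= 0 & havdi <= 1))
  validObject(params)
  grid <- expand.grid(E_sub_Pa = stiffness, havdi = havdi,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$havdi, grid$E_sub_Pa), , drop = FALSE]
  grid$k_on_per_s <- .konRate(grid$E_sub_Pa, grid$havdi, params)
  rownames(grid) <- NULL
  grid
}

#' Canonical substrate conditions
#'
#' Convenience constructors for the three recurring conditions: tissue
#' culture plastic (about 3 GPa, no HAVDI) and soft hydrogels with scrambled
#' or active HAVDI peptide.
#'
#' @param youngModulus Hydrogel Young's modulus, Pa.
#' @return An [AdhesionCondition].
#' @examples
#' tcpCondition()
#' scramCondition(20e3)
#' havdiCondition(20e3)
#' @export
tcpCondition <- function() {
  AdhesionCondition(youngModulus = 3e9, havdiOccupancy = 0, label = "TCP")
}

#' @rdname tcpCondition
#' @export
scramCondition <- function(youngModulus = 20e3) {
  AdhesionCondition(youngModulus = youngModulus, havdiOccupancy = 0,
                    label = "S/R")
}

#' @rdname tcpCondition
#' @export
havdiCondition <- function(youngModulus = 20e3) {
  AdhesionCondition(youngModulus = youngModulus, havdiOccupancy = 1,
                    label = "H/R")
}
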