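#' @include MechanoMemory-package.R
NULL

# ---- adhesion / kon -------------------------------------------------------

#' Substrate adhesion condition
#'
#' An `AdhesionCondition` bundles the two experimentally controlled variables
#' of the model: the substrate Young's modulus and the degree of N-cadherin
#' (HAVDI) ligation presented alongside RGD. It is the independent variable
#' of every simulated experiment.
#'
#' @param youngModulus Substrate Young's modulus in Pa (> 0). Tissue-culture
#'   plastic is about 3 GPa, the hydrogels 2-41 kPa.
#' @param havdiOccupancy Fraction in \[0, 1\] of N-cadherin ligation: 0 is a
#'   Scram/RGD (or plain RGD) surface, 1 a fully dosed HAVDI/RGD surface.
#' @param label Free-text condition label, e.g. `"S/R"`, `"H/R"`, `"TCP"`.
#'
#' @return An `AdhesionCondition` object.
#' @examples
#' AdhesionCondition(20e3, havdiOccupancy = 1, label = "H/R")
#' @aliases AdhesionCondition-class
#' @exportClass AdhesionCondition
setClass(
  "AdhesionCondition",
  representation(youngModulus = "numeric", havdiOccupancy = "numeric",
                 label = "character"),
  prototype(havdiOccupancy = 0, label = NA_character_),
  validity = function(object) {
    if (length(object@youngModulus) != 1 || !is.finite(object@youngModulus) ||
        object@youngModulus <= 0)
      return("youngModulus must be a single positive number (Pa)")
    if (length(object@havdiOccupancy) != 1 ||
        !is.finite(object@havdiOccupancy) ||
        object@havdiOccupancy < 0 || object@havdiOccupancy > 1)
      return("havdiOccupancy must be a single number in [0, 1]")
    TRUE
  })

#' @rdname AdhesionCondition-class
#' @export
AdhesionCondition <- function(youngModulus, havdiOccupancy = 0,
                              label = NA_character_) {
  new("AdhesionCondition", youngModulus = youngModulus,
      havdiOccupancy = havdiOccupancy, label = label)
}

#' Convert a HAVDI peptide dose to an occupancy fraction
#'
#' Linear saturation with the standard 1 mM dose: `min(dose / 1 mM, 1)`.
#'
#' @param doseMilliMolar HAVDI peptide concentration in mM (>= 0).
#' @return Occupancy fraction in \[0, 1\].
#' @examples
#' havdiOccupancyFromDose(c(0, 0.5, 1, 2))
#' @export
havdiOccupancyFromDose <- function(doseMilliMolar) {
  stopifnot(is.numeric(doseMilliMolar), all(doseMilliMolar >= 0))
  pmin(doseMilliMolar / 1, 1)
}

#' Parameters of the stiffness- and HAVDI-dependent clutch binding rate
#'
#' The clutch binding rate follows a Boltzmann/Arrhenius-type activation in
#' log substrate stiffness between a floor `kOnMin` and a plateau `kOnMax`,
#' with HAVDI ligation shifting the activation midpoint from `eHalfScram`
#' toward `eHalfHavdi` (geometric interpolation in occupancy). See
#' [computeKon()].
#'
#' @param kOnMin,kOnMax Binding-rate floor and plateau, 1/s
#'   (0 < kOnMin < kOnMax). The range reflects the available integrin
#'   density on the membrane.
#' @param eHalfScram,eHalfHavdi Activation midpoint stiffness, Pa, without
#'   and with full HAVDI ligation (eHalfScram < eHalfHavdi).
#' @param sharpness Dimensionless logistic slope in ln-stiffness (> 0).
#' @return A `KonParams` object.
#' @examples
#' KonParams()
#' @export KonParams
#' @exportClass KonParams
KonParams <- setClass(
  "KonParams",
  representation(kOnMin = "numeric", kOnMax = "numeric",
                 eHalfScram = "numeric", eHalfHavdi = "numeric",
                 sharpness = "numeric"),
  prototype(kOnMin = 0.05, kOnMax = 1.0, eHalfScram = 7e3, eHalfHavdi = 18e3,
            sharpness = 2.0),
  validity = function(object) {
    v <- c(object@kOnMin, object@kOnMax, object@eHalfScram,
           object@eHalfHavdi, object@sharpness)
    if (length(v) != 5 || any(!is.finite(v)) || any(v <= 0))
      return("all parameters must be single positive numbers")
    if (object@kOnMin >= object@kOnMax)
      return("kOnMin must be < kOnMax")
    if (object@eHalfScram >= object@eHalfHavdi)
      return("eHalfScram must be < eHalfHavdi")
    TRUE
  })

# ---- clutch ensemble ------------------------------------------------------

#' Motor-clutch ensemble parameters
#'
#' Canonical motor-clutch machinery: `nMotors` myosin motors of stall force
#' `motorStallForce` pull an actin filament at unloaded retrograde velocity
#' `unloadedVelocity`; `nClutches` molecular clutches of stiffness
#' `clutchStiffness` engage the substrate, unbinding as Bell slip bonds with
#' unloaded rate `kOff0` and force scale `bellForce`. `adhesionRadius`
#' converts the substrate Young's modulus to a local spring (see
#' [substrateSpring()]). The fixed-time-step Monte Carlo uses `dt`, `nSteps`
#' and discards the first `burnInFraction` of the run.
#'
#' @param nMotors,motorStallForce Motor count and per-motor stall force (pN);
#'   ensemble stall is their product (100 pN at defaults).
#' @param unloadedVelocity Unloaded retrograde flow, nm/s (>= 0; 0 switches
#'   the motors off).
#' @param nClutches Number of molecular clutches.
#' @param clutchStiffness Clutch spring constant, pN/nm.
#' @param kOff0 Unloaded clutch off-rate, 1/s (>= 0; 0 gives permanent bonds).
#' @param bellForce Bell force scale of slip-bond unbinding, pN.
#' @param adhesionRadius Adhesion contact radius, nm.
#' @param dt Monte Carlo time step, s.
#' @param nSteps Number of steps; the default 1e5 steps of 0.01 s run 1000 s,
#'   long enough to reach a steady state.
#' @param burnInFraction Fraction in \[0, 1) of the run discarded before
#'   averaging.
#' @return A `ClutchParams` object.
#' @examples
#' ClutchParams(nSteps = 2e4)
#' @export ClutchParams
#' @exportClass ClutchParams
ClutchParams <- setClass(
  "ClutchParams",
  representation(nMotors = "integer", motorStallForce = "numeric",
                 unloadedVelocity = "numeric", nClutches = "integer",
                 clutchStiffness = "numeric", kOff0 = "numeric",
                 bellForce = "numeric", adhesionRadius = "numeric",
                 dt = "numeric", nSteps = "integer",
                 burnInFraction = "numeric"),
  prototype(nMotors = 50L, motorStallForce = 2, unloadedVelocity = 120,
            nClutches = 50L, clutchStiffness = 5, kOff0 = 0.1, bellForce = 2,
            adhesionRadius = 1000, dt = 0.01, nSteps = 100000L,
            burnInFraction = 0.2),
  validity = function(object) {
    pos <- c(nMotors = object@nMotors,
             motorStallForce = object@motorStallForce,
             nClutches = object@nClutches,
             clutchStiffness = object@clutchStiffness,
             bellForce = object@bellForce,
             adhesionRadius = object@adhesionRadius,
             dt = object@dt, nSteps = object@nSteps)
    if (any(!is.finite(pos)) || any(pos <= 0))
      return(paste("non-positive parameter:",
                   paste(names(pos)[!is.finite(pos) | pos <= 0],
                         collapse = ", ")))
    if (!is.finite(object@kOff0) || object@kOff0 < 0)
      return("kOff0 must be >= 0")
    if (!is.finite(object@unloadedVelocity) || object@unloadedVelocity < 0)
      return("unloadedVelocity must be >= 0")
    if (!is.finite(object@burnInFraction) || object@burnInFraction < 0 ||
        object@burnInFraction >= 1)
      return("burnInFraction must be in [0, 1)")
    TRUE
  })

setMethod("initialize", "ClutchParams", function(.Object, ...) {
  args <- list(...)
  for (nm in c("nMotors", "nClutches", "nSteps"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(callNextMethod, c(list(.Object), args))
})

#' Summary statistics of a motor-clutch traction run
#'
#' Steady-state, post-burn-in averages of a single stochastic run (or a
#' replicate average). `semTraction` and `semBoundFraction` are batch-means
#' standard errors, so they account for the autocorrelation of the traction
#' trace.
#'
#' @seealso [simulateTraction()]
#' @exportClass TractionSummary
setClass(
  "TractionSummary",
  representation(meanTraction = "numeric", semTraction = "numeric",
                 meanVelocity = "numeric", meanBoundFraction = "numeric",
                 semBoundFraction = "numeric", trace = "ANY",
                 condition = "character", seed = "integer"),
  prototype(trace = NULL, condition = NA_character_, seed = NA_integer_),
  validity = function(object) {
    if (object@meanTraction < 0) return("meanTraction must be >= 0")
    if (object@meanBoundFraction < 0 || object@meanBoundFraction > 1)
      return("meanBoundFraction must be in [0, 1]")
    TRUE
  })

# ---- nucleus / YAP --------------------------------------------------------

#' Viscoelastic-plastic nucleus parameters
#'
#' The nucleus is a Kelvin-Voigt element (spring `nuclearStiffness`,
#' dashpot `nuclearViscosity`; elastic time constant tau_e = viscosity /
#' stiffness) in series, conceptually, with a yield-threshold plastic
#' dashpot: traction above `yieldForce` makes the plastic strain flow at
#' rate (F - F_y) / `plasticViscosity`. Plastic strain never recovers; it is
#' the stored mechanical memory. Flattening is
#' `baselineFlattening * (1 + elastic + plastic strain)`.
#'
#' Defaults are calibration choices anchored to the default traction model:
#' tau_e = 4 h (elastic recovery completes well within a day, matching
#' transfer kinetics); `yieldForce` is the steady traction on a 20 kPa
#' Scram/RGD substrate (6.67 +/- 0.04 pN at the default clutch and
#' binding-rate parameters, see [calibrateYieldForce()]), rounded up to
#' 6.8 pN so that finite-sample fluctuations of the soft-substrate traction
#' never cross the yield and soft culture alone never writes memory;
#' `plasticViscosity` is set so that 10 days on tissue-culture plastic
#' (steady traction 7.32 pN) accumulates a plastic strain of about 0.5;
#' `nuclearStiffness` places the flattening of TCP-cultured nuclei near 4-5
#' as seen in confocal stacks.
#'
#' @param nuclearStiffness Effective nuclear spring, pN per unit strain.
#' @param nuclearViscosity Elastic dashpot, pN s per unit strain.
#' @param plasticViscosity Plastic dashpot, pN day per unit strain.
#' @param yieldForce Traction threshold for plastic flow, pN.
#' @param baselineFlattening Zero-traction nuclear length/height ratio
#'   (>= 1).
#' @return A `NucleusParams` object.
#' @examples
#' NucleusParams()
#' @export NucleusParams
#' @exportClass NucleusParams
NucleusParams <- setClass(
  "NucleusParams",
  representation(nuclearStiffness = "numeric", nuclearViscosity = "numeric",
                 plasticViscosity = "numeric", yieldForce = "numeric",
                 baselineFlattening = "numeric"),
  prototype(nuclearStiffness = 7.5, nuclearViscosity = 7.5 * 14400,
            plasticViscosity = 10.4, yieldForce = 6.8,
            baselineFlattening = 2),
  validity = function(object) {
    v <- c(object@nuclearStiffness, object@nuclearViscosity,
           object@plasticViscosity, object@yieldForce,
           object@baselineFlattening)
    if (any(!is.finite(v)) || any(v <= 0))
      return("all parameters must be positive")
    if (object@baselineFlattening < 1)
      return("baselineFlattening must be >= 1")
    if (object@nuclearViscosity / object@nuclearStiffness > 86400)
      return("elastic time constant viscosity/stiffness must be <= 1 day")
    TRUE
  })

#' Nucleus deformation state
#'
#' @param elasticStrain Recoverable strain (>= 0).
#' @param plasticStrain Irreversible strain (>= 0); non-decreasing along any
#'   trajectory.
#' @param time Time, s.
#' @return A `NucleusState` object.
#' @examples
#' NucleusState()
#' @export NucleusState
#' @exportClass NucleusState
NucleusState <- setClass(
  "NucleusState",
  representation(elasticStrain = "numeric", plasticStrain = "numeric",
                 time = "numeric"),
  prototype(elasticStrain = 0, plasticStrain = 0, time = 0),
  validity = function(object) {
    if (object@elasticStrain < 0 || object@plasticStrain < 0)
      return("strains must be >= 0")
    TRUE
  })

#' Parameters of the flattening-to-YAP shuttling law
#'
#' The steady-state YAP nuclear/cytoplasmic ratio increases linearly with
#' nuclear flattening, `R = slope * lambda + intercept` (floored at 0.1 so a
#' ratio of total intensities stays positive), and the instantaneous ratio
#' relaxes exponentially toward that target with time constant
#' `relaxationTime`. The default 2 h makes nuclear localization reach steady
#' state well within one day, as observed after substrate transfer.
#'
#' @param slope Ratio units per unit flattening (> 0).
#' @param intercept Dimensionless offset of the linear law.
#' @param relaxationTime Relaxation time constant, s (<= 1 day).
#' @return A `YapParams` object.
#' @examples
#' YapParams()
#' @export YapParams
#' @exportClass YapParams
YapParams <- setClass(
  "YapParams",
  representation(slope = "numeric", intercept = "numeric",
                 relaxationTime = "numeric"),
  prototype(slope = 0.75, intercept = -0.2, relaxationTime = 7200),
  validity = function(object) {
    if (!is.finite(object@slope) || object@slope <= 0)
      return("slope must be > 0")
    if (!is.finite(object@relaxationTime) || object@relaxationTime <= 0 ||
        object@relaxationTime > 86400)
      return("relaxationTime must be in (0, 1 day]")
    TRUE
  })

#' YAP nucleocytoplasmic state
#'
#' @param ratio Current nuclear/cytoplasmic ratio (> 0).
#' @param time Time, s.
#' @return A `YapState` object.
#' @examples
#' YapState(ratio = 1.3)
#' @export YapState
#' @exportClass YapState
YapState <- setClass(
  "YapState",
  representation(ratio = "numeric", time = "numeric"),
  prototype(ratio = 1, time = 0),
  validity = function(object) {
    if (!is.finite(object@ratio) || object@ratio <= 0)
      return("ratio must be > 0")
    TRUE
  })

# ---- protocol -------------------------------------------------------------

#' One step of a culture/transfer protocol
#'
#' @param condition An [AdhesionCondition] the cells sit on during the step.
#' @param duration Step duration in days (> 0).
#' @return A `ProtocolStep` object.
#' @examples
#' ProtocolStep(tcpCondition(), duration = 10)
#' @aliases ProtocolStep-class
#' @exportClass ProtocolStep
setClass(
  "ProtocolStep",
  representation(condition = "AdhesionCondition", duration = "numeric"),
  validity = function(object) {
    if (!is.finite(object@duration) || object@duration <= 0)
      return("duration must be > 0 days")
    TRUE
  })

#' @rdname ProtocolStep-class
#' @export
ProtocolStep <- function(condition, duration) {
  new("ProtocolStep", condition = condition, duration = duration)
}

#' Result of a simulated culture/transfer protocol
#'
#' Time courses of traction, nuclear flattening and YAP n/c ratio on the
#' protocol time grid, together with the endpoint ratio and its residual
#' above the soft-control baseline (a rest-start run of the final step's
#' condition for the final step's duration).
#'
#' @seealso [runProtocol()]
#' @exportClass ProtocolResult
setClass(
  "ProtocolResult",
  representation(timeGrid = "numeric", traction = "numeric",
                 flattening = "numeric", yapRatio = "numeric",
                 endpointRatio = "numeric", baselineRatio = "numeric",
                 residual = "numeric", stepLabels = "character"),
  validity = function(object) {
    n <- length(object@timeGrid)
    if (length(object@traction) != n || length(object@flattening) != n ||
        length(object@yapRatio) != n)
      return("time course arrays must share length")
    TRUE
  })

# ---- imaging --------------------------------------------------------------

#' A labelled fluorescence image of one or more cells
#'
#' Holds one marker channel plus binary masks: one nucleus mask per nucleus
#' and a cell (sparse case) or zone (confluent case) mask. Every nucleus
#' mask must lie inside the cell/zone mask and leave a non-empty cytoplasmic
#' remainder.
#'
#' @param intensity Numeric matrix of fluorescence values (arbitrary units).
#' @param nucleusMasks A logical matrix or list of logical matrices, one per
#'   nucleus.
#' @param cellMask Logical matrix delineating the cell (or multicellular
#'   zone).
#' @param pixelSize Pixel size, micrometres (metadata only; intensity ratios
#'   are area-weighted in pixels and independent of it).
#' @param saturationValue Maximum representable intensity; pixels at or
#'   above it inside the cell mask disqualify the image from ratio
#'   quantification.
#' @return A `LabeledCellImage` object.
#' @export LabeledCellImage
#' @exportClass LabeledCellImage
LabeledCellImage <- setClass(
  "LabeledCellImage",
  representation(intensity = "matrix", nucleusMasks = "list",
                 cellMask = "matrix", pixelSize = "numeric",
                 saturationValue = "numeric"),
  prototype(pixelSize = 0.207, saturationValue = 65535),
  validity = function(object) {
    dm <- dim(object@intensity)
    if (!is.logical(object@cellMask) || !all(dim(object@cellMask) == dm))
      return("cellMask must be a logical matrix matching intensity")
    if (length(object@nucleusMasks) < 1)
      return("at least one nucleus mask is required")
    for (m in object@nucleusMasks) {
      if (!is.logical(m) || !all(dim(m) == dm))
        return("every nucleus mask must be a logical matrix matching intensity")
      if (!any(m)) return("nucleus masks must be non-empty")
      if (any(m & !object@cellMask))
        return("every nucleus mask must lie inside the cell/zone mask")
    }
    nucAll <- Reduce(`|`, object@nucleusMasks)
    if (!any(object@cellMask & !nucAll))
      return("cytoplasmic region (cell minus nuclei) must be non-empty")
    TRUE
  })

setMethod("initialize", "LabeledCellImage", function(.Object, ...,
                                                     nucleusMasks = list()) {
  if (is.matrix(nucleusMasks)) nucleusMasks <- list(nucleusMasks)
  callNextMethod(.Object, ..., nucleusMasks = nucleusMasks)
})

#' Nuclear geometry from a z-stack
#'
#' @seealso [nuclearFlattening()]
#' @exportClass NucleusGeometry
setClass(
  "NucleusGeometry",
  representation(length = "numeric", height = "numeric",
                 flattening = "numeric"),
  validity = function(object) {
    if (object@length <= 0 || object@height <= 0)
      return("length and height must be > 0")
    TRUE
  })

# ---- indentation ----------------------------------------------------------

#' A load-indentation curve from spherical indentation
#'
#' @param indentation Indentation depths h, metres (>= 0, non-decreasing,
#'   length >= 5).
#' @param load Loads P, newtons (same length as `indentation`).
#' @param tipRadius Spherical tip radius, metres.
#' @param poissonRatio Poisson's ratio of the sample in \[0, 0.5\]
#'   (0.5 = incompressible).
#' @return An `IndentationCurve` object.
#' @export IndentationCurve
#' @exportClass IndentationCurve
IndentationCurve <- setClass(
  "IndentationCurve",
  representation(indentation = "numeric", load = "numeric",
                 tipRadius = "numeric", poissonRatio = "numeric"),
  prototype(poissonRatio = 0.5),
  validity = function(object) {
    h <- object@indentation
    if (length(h) < 5) return("at least 5 points are required")
    if (length(object@load) != length(h))
      return("indentation and load must have equal length")
    if (any(h < 0)) return("indentation must be >= 0")
    if (is.unsorted(h)) return("indentation must be non-decreasing")
    if (object@tipRadius <= 0) return("tipRadius must be > 0")
    if (object@poissonRatio < 0 || object@poissonRatio > 0.5)
      return("poissonRatio must be in [0, 0.5]")
    TRUE
  })

#' Result of a Hertz-model fit
#'
#' @seealso [fitYoungModulus()]
#' @exportClass HertzFit
setClass(
  "HertzFit",
  representation(youngModulus = "numeric", residualRms = "numeric",
                 nPointsUsed = "integer"),
  validity = function(object) {
    if (object@youngModulus <= 0) return("youngModulus must be > 0")
    TRUE
  })

# ---- synthetic-data specs -------------------------------------------------

#' Specification of a synthetic labelled cell image
#'
#' Describes an elliptical cell containing an elliptical nucleus whose mean
#' intensity is `targetRatio` times the cytoplasmic mean, so the true
#' nuclear/cytoplasmic ratio of the rendered image is known by construction.
#'
#' @param imageShape Image dimensions in pixels, `c(rows, cols)`.
#' @param cellCenter,cellAxes Centre and semi-axes (pixels) of the cell
#'   ellipse; defaults centre the cell in the image.
#' @param nucleusCenter,nucleusAxes Centre and semi-axes (pixels) of the
#'   nucleus ellipse, strictly inside the cell.
#' @param targetRatio Intended nuclear/cytoplasmic intensity ratio (> 0).
#' @param cytoplasmMean Cytoplasmic mean intensity in photon-count units;
#'   the default 200 corresponds to a typical confocal photon budget.
#' @param noiseModel `"none"`, `"gaussian"` (sd = `gaussianSdFraction` of
#'   the cytoplasmic mean) or `"poisson"` (pixel values drawn with the noise
#'   free expectations as Poisson means).
#' @param gaussianSdFraction Gaussian noise sd as a fraction of
#'   `cytoplasmMean`.
#' @param saturationValue Saturation level recorded in the rendered image.
#' @param seed RNG seed making the rendered image reproducible.
#' @return An `ImageSpec` object.
#' @examples
#' ImageSpec(targetRatio = 4)
#' @export ImageSpec
#' @exportClass ImageSpec
ImageSpec <- setClass(
  "ImageSpec",
  representation(imageShape = "integer", cellCenter = "numeric",
                 cellAxes = "numeric", nucleusCenter = "numeric",
                 nucleusAxes = "numeric", targetRatio = "numeric",
                 cytoplasmMean = "numeric", noiseModel = "character",
                 gaussianSdFraction = "numeric", saturationValue = "numeric",
                 seed = "integer"),
  prototype(imageShape = c(128L, 128L), cellCenter = numeric(0),
            cellAxes = c(55, 42), nucleusCenter = numeric(0),
            nucleusAxes = c(25, 18), targetRatio = 2, cytoplasmMean = 200,
            noiseModel = "none", gaussianSdFraction = 0.05,
            saturationValue = 65535, seed = 1L),
  validity = function(object) {
    if (object@targetRatio <= 0) return("targetRatio must be > 0")
    if (!object@noiseModel %in% c("none", "gaussian", "poisson"))
      return("noiseModel must be one of 'none', 'gaussian', 'poisson'")
    if (object@cytoplasmMean <= 0) return("cytoplasmMean must be > 0")
    if (max(object@targetRatio, 1) * object@cytoplasmMean >=
        object@saturationValue)
      return("mean intensities must stay below saturationValue")
    TRUE
  })

setMethod("initialize", "ImageSpec", function(.Object, ...) {
  args <- list(...)
  if (!is.null(args$imageShape)) args$imageShape <- as.integer(args$imageShape)
  if (!is.null(args$seed)) args$seed <- as.integer(args$seed)
  do.call(callNextMethod, c(list(.Object), args))
})

#' Specification of a synthetic Hertz load-indentation curve
#'
#' @param trueModulus Ground-truth Young's modulus, Pa.
#' @param poissonRatio Poisson's ratio used by the forward model.
#' @param tipRadius Spherical tip radius, m.
#' @param maxIndentation Largest indentation depth, m (zero yields a
#'   degenerate all-zero curve that downstream fitting rejects).
#' @param nPoints Number of points on the depth grid (>= 5).
#' @param noiseFraction Multiplicative Gaussian noise sd on the load
#'   (>= 0).
#' @param seed RNG seed.
#' @return A `CurveSpec` object.
#' @examples
#' CurveSpec(trueModulus = 20e3)
#' @export CurveSpec
#' @exportClass CurveSpec
CurveSpec <- setClass(
  "CurveSpec",
  representation(trueModulus = "numeric", poissonRatio = "numeric",
                 tipRadius = "numeric", maxIndentation = "numeric",
                 nPoints = "integer", noiseFraction = "numeric",
                 seed = "integer"),
  prototype(trueModulus = 20e3, poissonRatio = 0.5, tipRadius = 1.25e-6,
            maxIndentation = 1e-6, nPoints = 50L, noiseFraction = 0,
            seed = 1L),
  validity = function(object) {
    pos <- c(object@trueModulus, object@tipRadius, object@nPoints)
    if (any(!is.finite(pos)) || any(pos <= 0))
      return("trueModulus, tipRadius and nPoints must be > 0")
    if (!is.finite(object@maxIndentation) || object@maxIndentation < 0)
      return("maxIndentation must be >= 0")
    if (object@noiseFraction < 0) return("noiseFraction must be >= 0")
    if (object@nPoints < 5) return("nPoints must be >= 5")
    TRUE
  })

setMethod("initialize", "CurveSpec", function(.Object, ...) {
  args <- list(...)
  if (!is.null(args$nPoints)) args$nPoints <- as.integer(args$nPoints)
  if (!is.null(args$seed)) args$seed <- as.integer(args$seed)
  do.call(callNextMethod, c(list(.Object), args))
})
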