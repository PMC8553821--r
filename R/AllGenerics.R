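#' @include AllClasses.R
NULL

#' Accessors for model objects
#'
#' Small set of read accessors for the S4 containers: substrate modulus and
#' HAVDI occupancy of an [AdhesionCondition]; traction statistics of a
#' `TractionSummary`; strains of a [NucleusState]; ratio of a [YapState] or
#' `ProtocolResult`; geometry of a `NucleusGeometry`.
#'
#' @param object The object to access.
#' @param ... Unused.
#' @return The requested slot value (a numeric scalar or character label);
#'   `yapRatio` on a `ProtocolResult` returns the full time course.
#' @examples
#' youngModulus(AdhesionCondition(20e3))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("youngModulus", function(object) standardGeneric("youngModulus"))
#' @rdname accessors
#' @export
setGeneric("havdiOccupancy", function(object) standardGeneric("havdiOccupancy"))
#' @rdname accessors
#' @export
setGeneric("conditionLabel", function(object) standardGeneric("conditionLabel"))
#' @rdname accessors
#' @export
setGeneric("meanTraction", function(object) standardGeneric("meanTraction"))
#' @rdname accessors
#' @export
setGeneric("semTraction", function(object) standardGeneric("semTraction"))
#' @rdname accessors
#' @export
setGeneric("meanVelocity", function(object) standardGeneric("meanVelocity"))
#' @rdname accessors
#' @export
setGeneric("boundFraction", function(object) standardGeneric("boundFraction"))
#' @rdname accessors
#' @export
setGeneric("elasticStrain", function(object) standardGeneric("elasticStrain"))
#' @rdname accessors
#' @export
setGeneric("plasticStrain", function(object) standardGeneric("plasticStrain"))
#' @rdname accessors
#' @export
setGeneric("yapRatio", function(object) standardGeneric("yapRatio"))
#' @rdname accessors
#' @export
setGeneric("endpointRatio", function(object) standardGeneric("endpointRatio"))
#' @rdname accessors
#' @export
setGeneric("memoryResidual", function(object) standardGeneric("memoryResidual"))
#' @rdname accessors
#' @export
setGeneric("nucleusLength", function(object) standardGeneric("nucleusLength"))
#' @rdname accessors
#' @export
setGeneric("nucleusHeight", function(object) standardGeneric("nucleusHeight"))

#' @rdname flattening
#' @export
setGeneric("flattening", function(object, ...) standardGeneric("flattening"))

setMethod("youngModulus", "AdhesionCondition", function(object)
  object@youngModulus)
setMethod("havdiOccupancy", "AdhesionCondition", function(object)
  object@havdiOccupancy)
setMethod("conditionLabel", "AdhesionCondition", function(object)
  object@label)

setMethod("meanTraction", "TractionSummary", function(object)
  object@meanTraction)
setMethod("semTraction", "TractionSummary", function(object)
  object@semTraction)
setMethod("meanVelocity", "TractionSummary", function(object)
  object@meanVelocity)
setMethod("boundFraction", "TractionSummary", function(object)
  object@meanBoundFraction)

setMethod("elasticStrain", "NucleusState", function(object)
  object@elasticStrain)
setMethod("plasticStrain", "NucleusState", function(object)
  object@plasticStrain)

setMethod("yapRatio", "YapState", function(object) object@ratio)
setMethod("yapRatio", "ProtocolResult", function(object) object@yapRatio)
setMethod("endpointRatio", "ProtocolResult", function(object)
  object@endpointRatio)
setMethod("memoryResidual", "ProtocolResult", function(object)
  object@residual)

setMethod("nucleusLength", "NucleusGeometry", function(object) object@length)
setMethod("nucleusHeight", "NucleusGeometry", function(object) object@height)
setMethod("flattening", "NucleusGeometry", function(object, ...)
  object@flattening)

setMethod("youngModulus", "HertzFit", function(object) object@youngModulus)

# ---- show methods ---------------------------------------------------------

setMethod("show", "AdhesionCondition", function(object) {
  cat(sprintf("AdhesionCondition: E_sub = %g Pa, HAVDI occupancy = %.2f%s\n",
              object@youngModulus, object@havdiOccupancy,
              if (is.na(object@label)) "" else
                sprintf(" [%s]", object@label)))
})

setMethod("show", "TractionSummary", function(object) {
  cat(sprintf(paste0(
    "TractionSummary%s\n",
    "  mean traction : %.2f pN (batch SEM %.3f)\n",
    "  mean velocity : %.1f nm/s\n",
    "  bound fraction: %.3f\n"),
    if (is.na(object@condition)) "" else sprintf(" [%s]", object@condition),
    object@meanTraction, object@semTraction, object@meanVelocity,
    object@meanBoundFraction))
})

setMethod("show", "NucleusState", function(object) {
  cat(sprintf(
    "NucleusState at t = %g s: elastic strain %.4f, plastic strain %.4f\n",
    object@time, object@elasticStrain, object@plasticStrain))
})

setMethod("show", "YapState", function(object) {
  cat(sprintf("YapState at t = %g s: n/c ratio %.3f\n",
              object@time, object@ratio))
})

setMethod("show", "ProtocolResult", function(object) {
  cat(sprintf(paste0(
    "ProtocolResult (%s; %d time points over %.2f d)\n",
    "  endpoint YAP n/c ratio: %.3f\n",
    "  soft-control baseline : %.3f\n",
    "  memory residual       : %.3f\n"),
    paste(object@stepLabels, collapse = " -> "),
    length(object@timeGrid), max(object@timeGrid),
    object@endpointRatio, object@baselineRatio, object@residual))
})

setMethod("show", "NucleusGeometry", function(object) {
  cat(sprintf(
    "NucleusGeometry: length %.2f um, height %.2f um, flattening %.2f\n",
    object@length, object@height, object@flattening))
})

setMethod("show", "HertzFit", function(object) {
  cat(sprintf(
    "HertzFit: E = %.4g Pa (rms residual %.3g N over %d points)\n",
    object@youngModulus, object@residualRms, object@nPointsUsed))
})
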