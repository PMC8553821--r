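#' @include AllGenerics.R
NULL

#' Hertz load for spherical indentation
#'
#' Forward Hertz model for a rigid sphere on a linear elastic, isotropic
#' half-space:
#' \deqn{P = \frac{4}{3}\,\frac{E}{1-\nu^2}\,R^{1/2}\,h^{3/2}.}
#'
#' @param youngModulus Young's modulus E, Pa (> 0).
#' @param poissonRatio Poisson's ratio (0.5 for an incompressible
#'   hydrogel).
#' @param tipRadius Sphere radius R, m (> 0).
#' @param indentation Indentation depth(s) h, m (>= 0; vectorized).
#' @return Load(s) P in newtons.
#' @examples
#' hertzLoad(20e3, 0.5, 1.25e-6, 1e-6)  # ~3.975e-8 N
#' @export
hertzLoad <- function(youngModulus, poissonRatio = 0.5, tipRadius,
                      indentation) {
  stopifnot(is.numeric(youngModulus), youngModulus > 0,
            is.numeric(tipRadius), tipRadius > 0,
            poissonRatio >= 0, poissonRatio <= 0.5)
  if (any(indentation < 0)) stop("indentation must be >= 0")
  (4 / 3) * youngModulus / (1 - poissonRatio^2) * sqrt(tipRadius) *
    indentation^1.5
}

#' Fit the Young's modulus of a load-indentation curve
#'
#' Least-squares fit of the Hertz model with the tip radius and Poisson's
#' ratio held fixed. Because the load is linear in E the estimator is
#' closed-form,
#' \deqn{\hat E = (1-\nu^2)\,\frac{\sum_i P_i h_i^{3/2}}
#'   {\tfrac{4}{3} R^{1/2} \sum_i h_i^{3}},}
#' with no iterative optimisation. Curves are assumed pre-zeroed at the
#' contact point.
#'
#' @param curve An [IndentationCurve].
#' @return A `HertzFit` with the modulus (Pa), the rms load residual (N)
#'   and the number of points used.
#' @examples
#' fitYoungModulus(makeIndentationCurve(CurveSpec(trueModulus = 20e3)))
#' @export
fitYoungModulus <- function(curve) {
  validObject(curve)
  h <- curve@indentation
  p <- curve@load
  s3 <- sum(h^3)
  if (s3 == 0)
    stop("degenerate fit: all indentation depths are zero")
  e <- (1 - curve@poissonRatio^2) * sum(p * h^1.5) /
    ((4 / 3) * sqrt(curve@tipRadius) * s3)
  if (!is.finite(e) || e <= 0)
    stop("degenerate fit: estimated modulus is not positive")
  fitted <- hertzLoad(e, curve@poissonRatio, curve@tipRadius, h)
  new("HertzFit", youngModulus = e,
      residualRms = sqrt(mean((p - fitted)^2)),
      nPointsUsed = length(h))
}
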