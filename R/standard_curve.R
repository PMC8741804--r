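# Standard-curve fitting: ordinary least squares of Ct on log10 template
# quantity; amplification efficiency from the slope via
# E = (10^(-1/slope) - 1) x 100%.

#' Amplification efficiency from a standard-curve slope
#'
#' Evaluates \eqn{E = (10^{-1/slope} - 1) \times 100} (percent). A perfect
#' doubling per cycle corresponds to slope \eqn{-1/\log_{10} 2 \approx
#' -3.3219}, i.e. E = 100.
#'
#' @param slope cycles per log10 quantity; must be negative.
#' @return Efficiency in percent.
#' @examples
#' efficiencyFromSlope(-3.3219)  # ~ 100
#' @export
efficiencyFromSlope <- function(slope) {
    if (!is.finite(slope) || slope >= 0)
        stop("'slope' must be finite and < 0")
    (10^(-1 / slope) - 1) * 100
}

#' Fit a dilution-series standard curve
#'
#' Ordinary least-squares regression of Ct on log10 relative quantity.
#' R-squared is the squared Pearson correlation of the fitted line;
#' efficiency comes from [efficiencyFromSlope()]. A non-negative slope is
#' physically invalid: the fit is returned flagged (\code{valid = FALSE})
#' with efficiency \code{NA}.
#'
#' @param d a \linkS4class{DilutionSeries} (>= 3 points, distinct
#'   quantities).
#' @return A \linkS4class{StandardCurveFit}.
#' @examples
#' d <- simulateDilutionSeries("GAPDH", efficiencyPct = 88.1)
#' fitStandardCurve(d)
#' @export
fitStandardCurve <- function(d) {
    stopifnot(is(d, "DilutionSeries"))
    validObject(d)
    if (length(unique(d@log10Quantity)) < 3L)
        stop("a standard curve needs >= 3 distinct dilution points")
    fit <- stats::lm(d@ct ~ d@log10Quantity)
    slope <- unname(coef(fit)[2L])
    intercept <- unname(coef(fit)[1L])
    r2 <- if (stats::sd(d@ct) == 0) 1 else
        unname(stats::cor(d@ct, d@log10Quantity))^2
    valid <- is.finite(slope) && slope < 0
    eff <- if (valid) efficiencyFromSlope(slope) else NA_real_
    if (!valid)
        warning("non-negative slope: efficiency undefined, fit flagged invalid")
    new("StandardCurveFit", gene = d@gene, slope = slope,
        intercept = intercept, rSquared = r2, efficiency = eff,
        valid = valid, n = length(d@ct))
}

setMethod("show", "StandardCurveFit", function(object) {
    cat(sprintf(
        "StandardCurveFit [%s]: slope %.4f, intercept %.2f, R^2 %.4f, E %s%s\n",
        object@gene, object@slope, object@intercept, object@rSquared,
        if (object@valid) sprintf("%.1f%%", object@efficiency) else "undefined",
        if (object@valid) "" else " (invalid)"))
})
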