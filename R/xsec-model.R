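#' Construct a piecewise cubic cross-section model
#'
#' @param beta numeric length 4: coefficients of
#'   \code{log(sigma) = b0 + b1*x + b2*x^2 + b3*x^3}, x = log10(E/eV).
#' @param window x window, default \code{c(6, 10)}.
#' @param outsideValue sigma outside the window, barn (default 0: neutron
#'   interactions outside the window are marginal and not modeled).
#' @param se optional standard errors of beta.
#' @param response optional label (\code{"nucleotide"} or \code{"water"}).
#' @return a [PiecewiseCubicXSecModel-class].
#' @export
PiecewiseCubicXSecModel <- function(beta, window = c(6, 10),
                                    outsideValue = 0,
                                    se = rep(NA_real_, 4),
                                    response = NA_character_) {
    new("PiecewiseCubicXSecModel", beta = as.numeric(beta),
        window = as.numeric(window), outsideValue = as.numeric(outsideValue),
        se = as.numeric(se), response = as.character(response))
}

# bundled reference coefficients for the non-elastic cross-section models of
# a nucleotide and a hydration-sphere water molecule (log sigma in barn vs
# log10 energy in eV, window [6, 10])
.REF_COEF <- list(
    nucleotide = list(
        beta = c(-201.8137711, 72.93892997, -8.51321887, 0.32227953),
        sd = c(127.0, 10.4, 1.33, 5.64e-2)),
    water = list(
        beta = c(-400.1662991, 144.52231949, -17.197389, 0.67101674),
        sd = c(159, 59.9, 7.46, 0.308)))

#' Bundled reference cross-section models
#'
#' The package ships reference coefficients for the per-nucleotide and
#' per-water non-elastic neutron cross-section models (cubic in log10
#' energy on \[1e6, 1e10\] eV, zero outside), for use by the kinetics and
#' loss modules without re-running the Monte Carlo estimation.
#'
#' @param response \code{"nucleotide"} or \code{"water"}.
#' @return a [PiecewiseCubicXSecModel-class].
#' @seealso [referenceXsecCoefficients()]
#' @export
#' @examples
#' predictSigma(referenceXsecModel("nucleotide"), 1e8)  # ~6.4 barn
referenceXsecModel <- function(response = c("nucleotide", "water")) {
    response <- match.arg(response)
    r <- .REF_COEF[[response]]
    PiecewiseCubicXSecModel(r$beta, se = r$sd, response = response)
}

#' Reference coefficient table
#' @return data.frame of the bundled model coefficients and their standard
#'   deviations for both responses.
#' @export
referenceXsecCoefficients <- function() {
    data.frame(
        term = rep(paste0("beta", 0:3), 2L),
        response = rep(c("nucleotide", "water"), each = 4L),
        coefficient = c(.REF_COEF$nucleotide$beta, .REF_COEF$water$beta),
        sd = c(.REF_COEF$nucleotide$sd, .REF_COEF$water$sd))
}

#' Evaluate a cross-section model
#'
#' @param model a [PiecewiseCubicXSecModel-class].
#' @param energy eV, vectorized; must be > 0.
#' @return sigma in barn; \code{outsideValue} (0) outside the model window.
#' @aliases predictSigma,PiecewiseCubicXSecModel-method
#' @rdname predictSigma
#' @export
setMethod("predictSigma", "PiecewiseCubicXSecModel",
function(model, energy) {
    if (any(energy <= 0)) stop("energy must be > 0")
    x <- log10(energy)
    out <- rep(model@outsideValue, length(energy))
    inw <- x >= model@window[1L] & x <= model@window[2L]
    if (any(inw)) {
        xi <- x[inw]
        b <- model@beta
        out[inw] <- exp(b[1L] + b[2L] * xi + b[3L] * xi^2 + b[4L] * xi^3)
    }
    out
})

setMethod("show", "PiecewiseCubicXSecModel", function(object) {
    cat(sprintf(
        "PiecewiseCubicXSecModel (%s): log sigma = %.4g + %.4g x + %.4g x^2 + %.4g x^3, x = log10(E) in [%g, %g]; %g barn outside\n",
        ifelse(is.na(object@response), "unlabelled", object@response),
        object@beta[1L], object@beta[2L], object@beta[3L], object@beta[4L],
        object@window[1L], object@window[2L], object@outsideValue))
})

.xsecDesign <- function(estimates, response = c("nucleotide", "water"),
                        window = c(6, 10)) {
    response <- match.arg(response)
    x <- log10(estimates$energy)
    keep <- x >= window[1L] & x <= window[2L]
    d <- estimates[keep, , drop = FALSE]
    x <- x[keep]
    if (response == "nucleotide") {
        counts <- d$hits_nucleotide
        nMol <- d$n_nucleotides_in_area
    } else {
        counts <- d$hits_water
        nMol <- d$n_waters_in_area
    }
    areaBarn <- d$sample_side^2 * .NM2_BARN
    # exposure chosen so the linear predictor equals log sigma in barn
    off <- log(d$n_impacts * nMol / areaBarn)
    list(data = d, x = x, counts = counts, offset = off)
}

#' Fit the piecewise cubic cross-section model by Poisson regression
#'
#' Hit counts from [sampleImpacts()] with energies inside the model window
#' (\[1e6, 1e10\] eV; interactions outside are marginal and excluded) are
#' modeled as Poisson with log link,
#' \code{hits ~ x + x^2 + x^3, offset = log(n_impacts * n_molecules / A)},
#' A in barn, so the fitted linear predictor is \code{log(sigma)} in barn.
#'
#' @param estimates data.frame from [sampleImpacts()] (rows may pool several
#'   slabs/seeds).
#' @param response which counts to fit, \code{"nucleotide"} or
#'   \code{"water"}.
#' @param window x window (default \code{c(6, 10)}).
#' @return a [PiecewiseCubicXSecModel-class] with coefficient standard
#'   errors in \code{@se} and the underlying \code{glm} fit in attribute
#'   \code{"fit"}.
#' @export
fitPiecewise <- function(estimates, response = c("nucleotide", "water"),
                         window = c(6, 10)) {
    response <- match.arg(response)
    dd <- .xsecDesign(estimates, response, window)
    if (nrow(dd$data) < 4L)
        stop("need at least 4 observations inside the fit window")
    if (all(dd$counts == 0))
        stop("all hit counts are zero; cross section is not identifiable")
    df <- data.frame(y = dd$counts, x = dd$x, off = dd$offset)
    fit <- stats::glm(y ~ x + I(x^2) + I(x^3) + offset(off),
                      family = stats::poisson(), data = df)
    sm <- summary(fit)
    m <- PiecewiseCubicXSecModel(stats::coef(fit), window = window,
                                 se = sm$coefficients[, "Std. Error"],
                                 response = response)
    attr(m, "fit") <- fit
    m
}

#' Test an exogenous covariate in the cross-section fit
#'
#' Refits the cubic Poisson model with one added linear term (slab thickness
#' or GC fraction) and returns the two-sided t test of that term, with
#' degrees of freedom equal to the residual degrees of freedom of the fit.
#'
#' @param estimates data.frame from [sampleImpacts()]; the covariate must
#'   vary across rows.
#' @param covariate \code{"thickness"} or \code{"gc_fraction"}.
#' @param response \code{"nucleotide"} or \code{"water"}.
#' @param window x window (default \code{c(6, 10)}).
#' @return one-row data.frame: \code{covariate}, \code{coefficient},
#'   \code{se}, \code{t}, \code{df}, \code{p}.
#' @export
covariateTest <- function(estimates,
                          covariate = c("thickness", "gc_fraction"),
                          response = c("nucleotide", "water"),
                          window = c(6, 10)) {
    covariate <- match.arg(covariate)
    response <- match.arg(response)
    dd <- .xsecDesign(estimates, response, window)
    z <- dd$data[[covariate]]
    if (length(unique(z)) < 2L)
        stop("covariate '", covariate, "' is constant across observations")
    df <- data.frame(y = dd$counts, x = dd$x, z = z, off = dd$offset)
    fit <- stats::glm(y ~ x + I(x^2) + I(x^3) + z + offset(off),
                      family = stats::poisson(), data = df)
    sm <- summary(fit)$coefficients
    est <- sm["z", "Estimate"]
    se <- sm["z", "Std. Error"]
    dof <- fit$df.residual
    tval <- est / se
    data.frame(covariate = covariate, coefficient = est, se = se,
               t = tval, df = dof,
               p = 2 * stats::pt(-abs(tval), df = dof))
}
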