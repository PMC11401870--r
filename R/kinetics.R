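#' Build damage kinetics from cross-section models and a flux spectrum
#'
#' Assembles the mass-action rate constants for neutron-induced strand
#' damage under time-averaged flux \eqn{\bar\Phi(E)}:
#' \deqn{k_{direct} = L \int \bar\Phi(E)\,\sigma_{nuc}(E)\,dE, \qquad
#'       k_{quasi} = \int \bar\Phi(E)\,\sigma_{H2O}(E)\,dE,}
#' and the per-strand loss hazard \eqn{k = k_{direct} + k_{quasi}\theta L}.
#' A strand is counted lost on any recorded interaction (a double-strand
#' break alone suffices to prevent recovery); indirect solution-phase
#' radical damage is zero under dry storage.
#'
#' @param L strand length, nucleotides (>= 1).
#' @param theta hydration ratio, waters per nucleotide (>= 0).
#' @param flux a [FluxSpectrum-class].
#' @param sigmaNuc,sigmaH2O [PiecewiseCubicXSecModel-class] objects for a
#'   nucleotide and a water molecule (defaults: the bundled reference
#'   models).
#' @return a [DamageKinetics-class].
#' @export
#' @examples
#' k <- buildKinetics(150, 4, jedecSpectrum())
#' secondsToYears(halfLife(k))
buildKinetics <- function(L, theta, flux,
                          sigmaNuc = referenceXsecModel("nucleotide"),
                          sigmaH2O = referenceXsecModel("water")) {
    stopifnot(L >= 1, theta >= 0)
    kDirect <- L * integrateFluxSigma(flux, sigmaNuc)
    kQuasi <- integrateFluxSigma(flux, sigmaH2O)
    new("DamageKinetics", kDirect = kDirect, kQuasi = kQuasi,
        theta = theta, L = L,
        perStrandRate = kDirect + kQuasi * theta * L)
}

#' Survival and half-life under damage kinetics
#'
#' \code{survivingFraction} is the expected fraction of strands still
#' undamaged after time \code{t}: \code{exp(-t * k)} with \code{k} the
#' per-strand rate. \code{expectedCopies} scales by the copy number.
#' \code{halfLife} is \code{log(2) / k}; a zero rate yields \code{Inf} with
#' a warning.
#'
#' @param kinetics a [DamageKinetics-class].
#' @param t time in seconds, >= 0 (vectorized).
#' @param C copy number.
#' @return fraction in \[0, 1\]; copies; or seconds respectively.
#' @aliases survivingFraction,DamageKinetics-method
#'   halfLife,DamageKinetics-method
#' @name kinetics-evaluation
#' @rdname kinetics-evaluation
#' @export
setMethod("survivingFraction", "DamageKinetics", function(kinetics, t) {
    if (any(t < 0)) stop("t must be >= 0")
    exp(-t * kinetics@perStrandRate)
})

#' @rdname kinetics-evaluation
#' @export
expectedCopies <- function(C, kinetics, t) C * survivingFraction(kinetics, t)

#' @rdname kinetics-evaluation
#' @export
setMethod("halfLife", "DamageKinetics", function(kinetics) {
    r <- kinetics@perStrandRate
    if (r <= 0) {
        warning("per-strand rate is zero; half-life is infinite")
        return(Inf)
    }
    log(2) / r
})

#' @rdname accessors
#' @aliases perStrandRate,DamageKinetics-method
#' @export
setMethod("perStrandRate", "DamageKinetics", function(x) x@perStrandRate)

setMethod("show", "DamageKinetics", function(object) {
    cat(sprintf(
        "DamageKinetics: L = %g nt, theta = %g\n  k_direct = %.4g /s/strand, k_quasi = %.4g /s/water\n  per-strand rate = %.4g /s (half-life %.4g yr)\n",
        object@L, object@theta, object@kDirect, object@kQuasi,
        object@perStrandRate,
        if (object@perStrandRate > 0)
            secondsToYears(log(2) / object@perStrandRate) else Inf))
})
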