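#' Construct a flux spectrum
#' @param energies eV grid, strictly ascending.
#' @param flux differential flux, n cm^-2 s^-1 eV^-1.
#' @param label provenance label.
#' @return a [FluxSpectrum-class].
#' @export
FluxSpectrum <- function(energies, flux, label = "user") {
    new("FluxSpectrum", energies = as.numeric(energies),
        flux = as.numeric(flux), label = label)
}

# JESD89A analytic ground-level differential neutron spectrum (NYC sea
# level), E in MeV, flux in n cm^-2 s^-1 MeV^-1
.jedecDifferentialMeV <- function(E_MeV) {
    u <- log(E_MeV)
    1.006e-6 * exp(-0.35 * u^2 + 2.1451 * u) +
        1.011e-3 * exp(-0.4106 * u^2 - 0.667 * u)
}

#' JEDEC reference ground-level neutron spectrum
#'
#' The JESD89A analytic differential spectrum of cosmic-ray-induced neutrons
#' at New York City sea level, tabulated on a log-spaced grid. Integrated
#' over E >= 10 MeV the implemented form gives 3.54e-3 n cm^-2 s^-1
#' (about 12.7 n cm^-2 h^-1), the conventional sea-level reference flux.
#'
#' @param scale dimensionless multiplier on the flux (> 0), e.g. for other
#'   altitudes/locations.
#' @param n number of grid points.
#' @param range energy range in eV covered by the grid (default
#'   \code{c(1e6, 1e11)}, the window on which the bundled cross-section
#'   models are nonzero and beyond).
#' @return a [FluxSpectrum-class].
#' @export
jedecSpectrum <- function(scale = 1, n = 400L, range = c(1e6, 1e11)) {
    stopifnot(scale > 0)
    E <- exp(seq(log(range[1L]), log(range[2L]), length.out = n))
    phi <- scale * .jedecDifferentialMeV(E / 1e6) / 1e6  # per MeV -> per eV
    FluxSpectrum(E, phi, label = sprintf("JESD89A NYC sea level x %g",
                                         scale))
}

#' Mono-energetic spectrum as a narrow triangular line
#'
#' Approximates a delta line at \code{energy} carrying integrated flux
#' \code{totalFlux}, for product-limit checks of spectrum integrals.
#'
#' @param energy line energy, eV.
#' @param totalFlux integrated flux, n cm^-2 s^-1.
#' @param relWidth relative half-width of the triangular line.
#' @return a [FluxSpectrum-class].
#' @export
monoenergeticSpectrum <- function(energy, totalFlux, relWidth = 1e-6) {
    w <- energy * relWidth
    peak <- totalFlux / w  # triangle area = peak * w
    FluxSpectrum(c(energy - w, energy, energy + w), c(0, peak, 0),
                 label = sprintf("mono %g eV", energy))
}

#' Read a tabulated spectrum from delimited text
#'
#' Columns \code{energy_eV} and \code{flux_per_cm2_s_eV} (CSV/TSV,
#' auto-detected); rows may be unsorted.
#'
#' @param path file path.
#' @return a [FluxSpectrum-class].
#' @export
loadSpectrum <- function(path) {
    if (!file.exists(path)) stop("spectrum file not found: ", path)
    dt <- data.table::fread(path, data.table = FALSE)
    need <- c("energy_eV", "flux_per_cm2_s_eV")
    miss <- setdiff(need, names(dt))
    if (length(miss))
        stop("spectrum file is missing column(s): ",
             paste(miss, collapse = ", "))
    o <- order(dt$energy_eV)
    FluxSpectrum(dt$energy_eV[o], dt$flux_per_cm2_s_eV[o], label = path)
}

#' Integrate flux times cross section
#'
#' Computes the per-molecule interaction rate
#' \eqn{\int \bar\Phi(E)\,\sigma(E)\,dE} by the trapezoid rule on the flux
#' grid restricted to the model window (sigma is zero outside), with sigma
#' converted from barn to cm^2.
#'
#' @param flux a [FluxSpectrum-class].
#' @param model a [PiecewiseCubicXSecModel-class].
#' @return interaction rate, s^-1 per molecule.
#' @export
integrateFluxSigma <- function(flux, model) {
    lo <- 10^model@window[1L]
    hi <- 10^model@window[2L]
    g <- .clipGrid(flux@energies, flux@flux, lo, hi)
    if (!length(g$x)) {
        warning("flux grid does not overlap the model window; rate is 0")
        return(0)
    }
    sig <- predictSigma(model, g$x) * .BARN_CM2
    .trapz(g$x, g$y * sig)
}

#' Integrated flux above a cutoff
#' @param flux a [FluxSpectrum-class].
#' @param eMin lower integration limit, eV.
#' @return integrated flux, n cm^-2 s^-1.
#' @export
integratedFlux <- function(flux, eMin = 0) {
    g <- .clipGrid(flux@energies, flux@flux, max(eMin, flux@energies[1L]),
                   flux@energies[length(flux@energies)])
    if (!length(g$x)) return(0)
    .trapz(g$x, g$y)
}

#' Equivalent exposure time for a fluence
#'
#' Converts an accelerated-beam fluence into the storage time with equal
#' neutron count per unit area under a reference spectrum:
#' \code{fluence / integral(flux, E >= eMin)}. The default cutoff of 10 MeV
#' is the conventional ground-level accounting for fast neutrons.
#'
#' @param fluence n cm^-2, >= 0.
#' @param flux a [FluxSpectrum-class] (e.g. [jedecSpectrum()]).
#' @param eMin integration cutoff, eV (default 1e7).
#' @return equivalent time in seconds.
#' @export
#' @examples
#' secondsToYears(fluenceToEquivalentTime(5.1e11, jedecSpectrum()))
fluenceToEquivalentTime <- function(fluence, flux, eMin = 1e7) {
    stopifnot(fluence >= 0)
    denom <- integratedFlux(flux, eMin)
    if (denom <= 0)
        stop("integrated flux above ", eMin, " eV is zero")
    fluence / denom
}

setMethod("show", "FluxSpectrum", function(object) {
    cat(sprintf(
        "FluxSpectrum '%s': %d points on [%.3g, %.3g] eV, total %.3g n/cm^2/s\n",
        object@label, length(object@energies), object@energies[1L],
        object@energies[length(object@energies)],
        .trapz(object@energies, object@flux)))
})
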