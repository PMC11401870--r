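#' @useDynLib neutronDNA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Nearest nucleus to a projected impact point
#'
#' Euclidean distance is measured in the xy projection (the z coordinate is
#' discarded once the stack is projected for sampling). Exact distance ties
#' resolve to the lowest atom index.
#'
#' @param slab a [StructureSlab-class].
#' @param point numeric length 2, (x, y) in nm.
#' @return the nearest atom as a one-row data.frame, with the atom index in
#'   attribute \code{"index"}.
#' @export
nearestNucleus <- function(slab, point) {
    a <- slab@atoms
    if (!nrow(a)) stop("slab has no atoms")
    i <- .nearestIndex(a$x, a$y, point[1L], point[2L])[1L]
    out <- a[i, , drop = FALSE]
    attr(out, "index") <- i
    out
}

#' Monte Carlo estimation of molecular neutron cross sections
#'
#' At each requested neutron energy, \code{nImpacts} impact points are drawn
#' uniformly on the slab's sampling square. For each point the nearest
#' nucleus (2D projection) is identified, and an interaction is recorded if
#' the point lies inside the disk of area equal to that nucleus's
#' non-elastic cross section (radius \code{sqrt(sigma/pi)}) centered on its
#' projection. Hits are attributed to the nucleus's category (nucleotide or
#' water) and converted to per-molecule cross sections:
#' \deqn{\hat\sigma_{nuc} = \frac{\mathrm{hits}_{nuc} \cdot A}
#'   {n_{impacts} \cdot n_{nucleotides\ in\ area}},}
#' with the sampling area \eqn{A} expressed in barn (1 nm^2 = 1e10 barn),
#' and analogously for water. Points inside the disk of a non-nearest
#' nucleus do not count; this nearest-only rule is a documented
#' approximation of the scheme.
#'
#' @param slab a [StructureSlab-class].
#' @param lib an [XsecLibrary-class] covering every element in the slab.
#' @param energies neutron energies in eV, each within \[10, 1e11\].
#' @param nImpacts impact points per energy (>= 1).
#' @param seed integer seed; results are deterministic given the seed.
#' @param chunkSize impact points generated per internal batch.
#' @return data.frame with one row per energy: \code{energy},
#'   \code{thickness}, \code{gc_fraction}, \code{hits_nucleotide},
#'   \code{hits_water}, \code{n_impacts}, \code{sample_side},
#'   \code{n_nucleotides_in_area}, \code{n_waters_in_area},
#'   \code{sigma_nuc_hat}, \code{sigma_h2o_hat} (barn) and
#'   \code{empty_area} flag.
#' @export
sampleImpacts <- function(slab, lib, energies, nImpacts, seed,
                          chunkSize = 1e6) {
    stopifnot(nImpacts >= 1)
    if (any(energies < 10 | energies > 1e11))
        stop("energies must lie within [10, 1e11] eV")
    a <- slab@atoms
    if (!nrow(a)) stop("slab has no atoms")
    els <- unique(a$element)
    missing <- setdiff(els, elements(lib))
    if (length(missing))
        stop("element(s) missing from cross-section library: ",
             paste(missing, collapse = ", "))
    catCode <- ifelse(a$category == "nucleotide", 1L,
               ifelse(a$category == "water", 2L, 0L))
    half <- slab@sampleSide / 2
    areaBarn <- slab@sampleSide^2 * .NM2_BARN
    nNuc <- slab@nNucleotidesInArea
    nWat <- slab@nWatersInArea
    empty <- nNuc == 0L && nWat == 0L
    if (empty)
        warning("sampling square contains no nucleotides or waters; ",
                "estimates are 0 and flagged")
    res <- .withSeed(seed, lapply(energies, function(E) {
        sig <- vapply(els, function(el) nonElastic(lib, el, E), numeric(1))
        r2 <- (sig[match(a$element, els)] * .BARN_NM2) / pi  # radius^2, nm^2
        hn <- 0L; hw <- 0L
        left <- as.integer(nImpacts)
        while (left > 0L) {
            m <- min(left, as.integer(chunkSize))
            px <- stats::runif(m, slab@center[1L] - half,
                               slab@center[1L] + half)
            py <- stats::runif(m, slab@center[2L] - half,
                               slab@center[2L] + half)
            ni <- .nearestIndex(a$x, a$y, px, py)
            h <- .countHits(ni, a$x, a$y, catCode, r2, px, py)
            hn <- hn + h[1L]; hw <- hw + h[2L]
            left <- left - m
        }
        data.frame(energy = E, thickness = slab@thickness,
                   gc_fraction = slab@gcFraction,
                   hits_nucleotide = hn, hits_water = hw,
                   n_impacts = nImpacts, sample_side = slab@sampleSide,
                   n_nucleotides_in_area = nNuc, n_waters_in_area = nWat,
                   sigma_nuc_hat = if (nNuc) hn * areaBarn /
                       (nImpacts * nNuc) else 0,
                   sigma_h2o_hat = if (nWat) hw * areaBarn /
                       (nImpacts * nWat) else 0,
                   empty_area = empty)
    }))
    do.call(rbind, res)
}
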