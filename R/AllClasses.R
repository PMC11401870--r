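#' @import methods
NULL

.validAtoms <- function(atoms) {
    need <- c("element", "x", "y", "z", "category", "residue", "gc")
    if (!is.data.frame(atoms))
        return("'atoms' must be a data.frame")
    miss <- setdiff(need, names(atoms))
    if (length(miss))
        return(paste0("atoms is missing column(s): ",
                      paste(miss, collapse = ", ")))
    if (!all(atoms$category %in% c("nucleotide", "water", "other")))
        return("atom category must be 'nucleotide', 'water' or 'other'")
    TRUE
}

#' Tabulated neutron cross sections for one nuclide
#'
#' Per-element total and elastic neutron cross sections on a strictly
#' ascending energy grid, in the style of the evaluated-data tabulations
#' distributed by national nuclear data centers. The non-elastic cross
#' section, the quantity this package treats as DNA-damaging, is the
#' difference between the total and elastic columns.
#'
#' @slot element chemical symbol (e.g. \code{"H"}).
#' @slot energies neutron energies in eV, strictly increasing, all positive.
#' @slot total total cross section in barn at each energy.
#' @slot elastic elastic cross section in barn at each energy.
#'
#' @seealso [readXsecLibrary()], [nonElastic()]
#' @export
setClass("XsecTable",
    representation(element = "character", energies = "numeric",
                   total = "numeric", elastic = "numeric"),
    validity = function(object) {
        msg <- character()
        n <- length(object@energies)
        if (length(object@element) != 1L || !nzchar(object@element))
            msg <- c(msg, "'element' must be a single non-empty symbol")
        if (n < 1L)
            msg <- c(msg, "at least one energy grid point is required")
        if (any(object@energies <= 0))
            msg <- c(msg, "energies must all be > 0")
        if (n > 1L && any(diff(object@energies) <= 0))
            msg <- c(msg, "energies must be strictly increasing")
        if (length(object@total) != n || length(object@elastic) != n)
            msg <- c(msg, "total and elastic must match the energy grid")
        if (any(object@elastic < 0))
            msg <- c(msg, "elastic cross sections must be >= 0")
        bad <- which(object@total < object@elastic)
        if (length(bad))
            msg <- c(msg, paste0("total < elastic at row(s) ",
                                 paste(head(bad, 5L), collapse = ", ")))
        if (length(msg)) msg else TRUE
    })

#' Library of per-nuclide cross-section tables
#'
#' A named collection of [XsecTable-class] objects, one per chemical element.
#' Every element present in a structure to be sampled (at minimum H, C, N, O
#' and P for hydrated DNA) must have a table.
#'
#' @slot tables named list of \code{XsecTable}, names are element symbols.
#' @export
setClass("XsecLibrary",
    representation(tables = "list"),
    validity = function(object) {
        if (!length(object@tables))
            return("library contains no tables")
        ok <- vapply(object@tables, is, logical(1), "XsecTable")
        if (!all(ok))
            return("all entries must be XsecTable objects")
        els <- vapply(object@tables, slot, character(1), "element")
        if (!identical(unname(els), names(object@tables)))
            return("list names must equal the element symbols of the tables")
        TRUE
    })

#' Atomic unit cell of a hydrated DNA structure
#'
#' Atoms of one structural repeat (for real data, the asymmetric unit of a
#' deposited duplex crystal structure with its residual waters), in
#' Cartesian nm. Coordinates read from PDB are converted from Angstrom.
#'
#' @slot atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z} (nm), \code{category} (\code{"nucleotide"}, \code{"water"} or
#'   \code{"other"}), \code{residue} (opaque residue label) and \code{gc}
#'   (logical; parent residue is G or C, meaningful for nucleotide atoms).
#' @slot extents numeric length 3, the (dx, dy, dz) cell extents in nm.
#' @export
setClass("UnitCell",
    representation(atoms = "data.frame", extents = "numeric"),
    validity = function(object) {
        msg <- .validAtoms(object@atoms)
        if (!isTRUE(msg)) return(msg)
        if (length(object@extents) != 3L || any(object@extents <= 0))
            return("'extents' must be three positive lengths (nm)")
        TRUE
    })

#' Stacked, randomized structure slab for impact sampling
#'
#' Unit cells stacked along z (the irradiation axis) with random rigid
#' rotations and in-plane translations, projected onto the xy plane for
#' Monte Carlo impact sampling over a centered square.
#'
#' @slot atoms as in [UnitCell-class].
#' @slot thickness z extent of the slab in nm.
#' @slot sampleSide side of the centered sampling square in nm (default 1).
#' @slot center xy center of the sampling square in nm.
#' @slot nNucleotidesInArea number of nucleotide residues with at least one
#'   atom projecting into the sampling square.
#' @slot nWatersInArea number of water residues projecting into the square.
#' @slot gcFraction fraction of in-area nucleotide residues that are G or C.
#' @slot nCells number of unit cells stacked.
#' @export
setClass("StructureSlab",
    representation(atoms = "data.frame", thickness = "numeric",
                   sampleSide = "numeric", center = "numeric",
                   nNucleotidesInArea = "integer", nWatersInArea = "integer",
                   gcFraction = "numeric", nCells = "integer"),
    validity = function(object) {
        msg <- .validAtoms(object@atoms)
        if (!isTRUE(msg)) return(msg)
        if (object@sampleSide <= 0) return("sampleSide must be > 0")
        if (length(object@center) != 2L) return("center must be length 2")
        zr <- diff(range(object@atoms$z))
        if (nrow(object@atoms) && abs(object@thickness - zr) >
                1e-6 * max(1, zr))
            return("thickness must equal the atom z extent")
        TRUE
    })

#' Piecewise cubic cross-section model in log10 energy
#'
#' Parametric model for a molecular non-elastic neutron cross section:
#' \deqn{\log \sigma(E) = \beta_0 + \beta_1 x + \beta_2 x^2 + \beta_3 x^3,
#'   \quad x = \log_{10}(E/\mathrm{eV}) \in [6, 10],}
#' with \eqn{\sigma(E)} equal to \code{outsideValue} (0 barn) outside the
#' window, where interactions are marginal. The log link is the natural log,
#' so \eqn{\sigma} is in barn.
#'
#' @slot beta numeric length 4, coefficients of the cubic in x.
#' @slot window numeric length 2, the x window (default \code{c(6, 10)}).
#' @slot outsideValue cross section outside the window, barn (default 0).
#' @slot se standard errors of beta where known (NA otherwise).
#' @slot response label, \code{"nucleotide"} or \code{"water"}.
#' @export
setClass("PiecewiseCubicXSecModel",
    representation(beta = "numeric", window = "numeric",
                   outsideValue = "numeric", se = "numeric",
                   response = "character"),
    prototype(window = c(6, 10), outsideValue = 0, se = rep(NA_real_, 4),
              response = NA_character_),
    validity = function(object) {
        if (length(object@beta) != 4L)
            return("beta must have length 4")
        if (length(object@window) != 2L || diff(object@window) <= 0)
            return("window must be an increasing pair")
        if (object@outsideValue < 0)
            return("outsideValue must be >= 0")
        TRUE
    })

#' Time-averaged differential neutron flux spectrum
#'
#' Point values of the differential flux \eqn{\bar\Phi(E)} on an ascending
#' energy grid. Integrals over the spectrum use trapezoid semantics on the
#' native grid.
#'
#' @slot energies eV, strictly ascending.
#' @slot flux neutrons cm^-2 s^-1 eV^-1 at each grid energy, all >= 0.
#' @slot label free-text provenance label.
#' @export
setClass("FluxSpectrum",
    representation(energies = "numeric", flux = "numeric",
                   label = "character"),
    validity = function(object) {
        if (length(object@energies) < 2L)
            return("at least two grid points are required")
        if (any(diff(object@energies) <= 0))
            return("energy grid must be strictly ascending")
        if (any(object@energies <= 0))
            return("energies must be > 0")
        if (length(object@flux) != length(object@energies))
            return("flux and energies must have equal length")
        if (any(object@flux < 0))
            return("differential flux must be >= 0")
        TRUE
    })

#' Mass-action damage kinetics of a dried DNA pool
#'
#' First-order rate constants for neutron-induced strand damage. Direct
#' damage (double-strand breaks from neutron-nucleotide interactions) and
#' quasi-direct damage (hole/electron transfer after neutron-water
#' interactions in the hydration sphere) both contribute; indirect
#' solution-phase radical damage is zero under dry storage. The per-strand
#' loss hazard is
#' \deqn{k = k_{direct} + k_{quasi}\,\theta\,L.}
#'
#' @slot kDirect s^-1 per strand, \eqn{L \int \bar\Phi \sigma_{nuc} dE}.
#' @slot kQuasi s^-1 per water molecule, \eqn{\int \bar\Phi \sigma_{H2O} dE}.
#' @slot theta hydration ratio, waters per nucleotide.
#' @slot L strand length, nucleotides.
#' @slot perStrandRate s^-1, the identity above.
#' @export
setClass("DamageKinetics",
    representation(kDirect = "numeric", kQuasi = "numeric",
                   theta = "numeric", L = "numeric",
                   perStrandRate = "numeric"),
    validity = function(object) {
        if (any(c(object@kDirect, object@kQuasi, object@theta) < 0))
            return("rates and theta must be >= 0")
        if (object@L < 1)
            return("L must be >= 1")
        expect <- object@kDirect + object@kQuasi * object@theta * object@L
        if (abs(object@perStrandRate - expect) >
                1e-12 * max(1e-300, expect))
            return("perStrandRate must equal kDirect + kQuasi*theta*L")
        TRUE
    })

#' Design parameters of a DNA data storage pool
#'
#' @slot N number of unique strands the file is encoded across.
#' @slot C copy number (physical copies per unique strand).
#' @slot L strand length in nucleotides.
#' @slot theta hydration ratio, waters per nucleotide.
#' @slot CLLOD lower limit of detection in copies; information in a strand
#'   index is lost when its intact copy count drops below this (default 10).
#' @export
setClass("PoolDesign",
    representation(N = "numeric", C = "numeric", L = "numeric",
                   theta = "numeric", CLLOD = "numeric"),
    prototype(N = 1, C = 100, L = 150, theta = 4, CLLOD = 10),
    validity = function(object) {
        if (object@N < 1) return("N must be >= 1")
        if (object@CLLOD < 0) return("CLLOD must be >= 0")
        if (object@C <= object@CLLOD) return("C must exceed CLLOD")
        if (object@L < 1) return("L must be >= 1")
        if (object@theta < 0) return("theta must be >= 0")
        whole <- function(v) abs(v - round(v)) < 1e-8
        if (!whole(object@N) || !whole(object@C) || !whole(object@CLLOD))
            return("N, C and CLLOD are counts and must be whole numbers")
        TRUE
    })
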