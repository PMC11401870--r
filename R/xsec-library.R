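#' Build a cross-section table for one element
#'
#' Rows may be given in any order; they are sorted by energy. Invariants
#' (ascending positive energies, total >= elastic >= 0) are enforced by the
#' class validity method.
#'
#' @param element chemical symbol.
#' @param energies neutron energies, eV.
#' @param total total cross sections, barn.
#' @param elastic elastic cross sections, barn.
#' @return an [XsecTable-class].
#' @export
XsecTable <- function(element, energies, total, elastic) {
    o <- order(energies)
    new("XsecTable", element = as.character(element),
        energies = as.numeric(energies)[o],
        total = as.numeric(total)[o], elastic = as.numeric(elastic)[o])
}

#' Read a cross-section library from delimited text
#'
#' The file (CSV or TSV, auto-detected) must have a header with columns
#' \code{element}, \code{energy_eV}, \code{total_barn}, \code{elastic_barn};
#' rows may be unsorted and elements interleaved. One table per element is
#' assembled and validated.
#'
#' @param path file path.
#' @return an [XsecLibrary-class].
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("element,energy_eV,total_barn,elastic_barn",
#'              "H,1e6,2.0,1.5", "H,1e8,3.0,1.0"), f)
#' lib <- readXsecLibrary(f)
#' nonElastic(lib, "H", 1e6)  # 0.5 barn
readXsecLibrary <- function(path) {
    if (!file.exists(path))
        stop("cross-section file not found: ", path)
    dt <- data.table::fread(path, data.table = FALSE)
    need <- c("element", "energy_eV", "total_barn", "elastic_barn")
    miss <- setdiff(need, names(dt))
    if (length(miss))
        stop("cross-section file is missing column(s): ",
             paste(miss, collapse = ", "))
    bad <- which(dt$total_barn < dt$elastic_barn)
    if (length(bad))
        stop("total < elastic at input row(s): ",
             paste(head(bad, 5L), collapse = ", "))
    tabs <- lapply(split(dt, dt$element), function(d)
        XsecTable(d$element[1L], d$energy_eV, d$total_barn, d$elastic_barn))
    new("XsecLibrary", tables = tabs)
}

#' Construct a library from tables
#' @param ... \code{XsecTable} objects.
#' @return an [XsecLibrary-class].
#' @export
XsecLibrary <- function(...) {
    tabs <- list(...)
    if (length(tabs) == 1L && is.list(tabs[[1L]]) && !is(tabs[[1L]], "XsecTable"))
        tabs <- tabs[[1L]]
    names(tabs) <- vapply(tabs, slot, character(1), "element")
    new("XsecLibrary", tables = tabs)
}

#' Non-elastic cross section at given energies
#'
#' The non-elastic cross section is total minus elastic. Between tabulated
#' energies it is linearly interpolated in (energy, non-elastic); above the
#' grid it is extrapolated log-linearly (linear in \code{log10(E)} vs
#' \code{log} sigma) through the two highest knots with nonzero non-elastic
#' values; below the grid it is 0, consistent with the downstream
#' cross-section model being zero below 1 MeV.
#'
#' @param object an [XsecLibrary-class] or [XsecTable-class].
#' @param element chemical symbol (ignored for a single table).
#' @param energy eV, vectorized.
#' @return non-elastic cross section(s), barn.
#' @aliases nonElastic,XsecLibrary-method nonElastic,XsecTable-method
#' @rdname nonElastic
#' @export
setMethod("nonElastic", "XsecLibrary", function(object, element, energy) {
    tab <- object@tables[[element]]
    if (is.null(tab))
        stop("element not in cross-section library: ", element)
    nonElastic(tab, element, energy)
})

#' @rdname nonElastic
#' @export
setMethod("nonElastic", "XsecTable", function(object, element, energy) {
    if (any(energy <= 0)) stop("energy must be > 0")
    e <- object@energies
    ne <- object@total - object@elastic
    n <- length(e)
    out <- numeric(length(energy))
    inb <- energy >= e[1L] & energy <= e[n]
    if (any(inb)) {
        out[inb] <- if (n == 1L) ne else
            stats::approx(e, ne, xout = energy[inb], ties = "ordered")$y
    }
    hi <- energy > e[n]
    if (any(hi)) {
        pos <- which(ne > 0)
        if (!length(pos) || max(pos) < n) {
            out[hi] <- 0  # top knot has zero non-elastic: nothing to extend
        } else if (length(pos) < 2L) {
            out[hi] <- ne[n]
        } else {
            i2 <- max(pos); i1 <- max(pos[pos < i2])
            slope <- (log(ne[i2]) - log(ne[i1])) /
                     (log10(e[i2]) - log10(e[i1]))
            out[hi] <- exp(log(ne[i2]) + slope * (log10(energy[hi]) -
                                                  log10(e[i2])))
        }
    }
    pmax(out, 0)
})

setMethod("elements", "XsecLibrary", function(x) names(x@tables))

setMethod("show", "XsecTable", function(object) {
    cat(sprintf("XsecTable for %s: %d knots on [%.3g, %.3g] eV\n",
                object@element, length(object@energies),
                object@energies[1L],
                object@energies[length(object@energies)]))
})

setMethod("show", "XsecLibrary", function(object) {
    cat("XsecLibrary with tables for:",
        paste(names(object@tables), collapse = ", "), "\n")
})
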