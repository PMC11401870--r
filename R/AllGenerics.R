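#' @rdname nonElastic
#' @export
setGeneric("nonElastic", function(object, element, energy)
    standardGeneric("nonElastic"))

#' @rdname predictSigma
#' @export
setGeneric("predictSigma", function(model, energy)
    standardGeneric("predictSigma"))

#' @rdname buildSlab
#' @export
setGeneric("buildSlab", function(cell, thickness, seed, ...)
    standardGeneric("buildSlab"))

#' @rdname kinetics-evaluation
#' @export
setGeneric("survivingFraction", function(kinetics, t)
    standardGeneric("survivingFraction"))

#' @rdname kinetics-evaluation
#' @export
setGeneric("halfLife", function(kinetics) standardGeneric("halfLife"))

#' Accessors for package objects
#'
#' Small read-only accessors: \code{atoms} returns the atom table of a
#' structure, \code{elements} the element symbols present,
#' \code{nucleotideCount}/\code{waterCount} residue tallies,
#' \code{gcFraction} the G/C residue fraction, and \code{perStrandRate}
#' the per-strand damage hazard of a kinetics object (s^-1).
#'
#' @param x an object.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))

#' @rdname accessors
#' @export
setGeneric("gcFraction", function(x) standardGeneric("gcFraction"))

#' @rdname accessors
#' @export
setGeneric("nucleotideCount", function(x) standardGeneric("nucleotideCount"))

#' @rdname accessors
#' @export
setGeneric("waterCount", function(x) standardGeneric("waterCount"))

#' @rdname accessors
#' @export
setGeneric("perStrandRate", function(x) standardGeneric("perStrandRate"))
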