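.WATER_RESID <- c("HOH", "WAT", "H2O", "DOD", "SOL", "TIP", "TIP3", "TIP4")
.NUC_RESID <- c("DA", "DT", "DG", "DC", "DU", "A", "T", "G", "C", "U",
                "ADE", "THY", "GUA", "CYT", "URA")
.GC_RESID <- c("DG", "DC", "G", "C", "GUA", "CYT")

# evaluate expr under a given seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(as.integer(seed))
    eval.parent(substitute(expr))
}

.cellFromAtoms <- function(atoms) {
    span <- function(v) max(diff(range(v)), 1e-9)
    new("UnitCell", atoms = atoms,
        extents = c(span(atoms$x), span(atoms$y), span(atoms$z)))
}

#' Construct a unit cell from an atom table
#' @param atoms data.frame with columns element, x, y, z (nm), category,
#'   residue, gc.
#' @param extents optional (dx, dy, dz) in nm; defaults to the coordinate
#'   spans.
#' @return a [UnitCell-class].
#' @export
UnitCell <- function(atoms, extents = NULL) {
    if (is.null(extents)) return(.cellFromAtoms(atoms))
    new("UnitCell", atoms = atoms, extents = as.numeric(extents))
}

#' Read a hydrated DNA structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), converts coordinates from
#' Angstrom to nm, categorizes atoms as nucleotide or water by residue name,
#' and computes the GC flag per residue. Explicit hydrogens are expected:
#' structures without any hydrogen atoms are accepted with a warning, since
#' hydrogen's non-elastic contribution is small and hydrogen placement is an
#' external problem.
#'
#' @param path PDB file path.
#' @return a [UnitCell-class] holding the asymmetric unit as read (no
#'   crystallographic symmetry expansion is performed).
#' @export
readStructure <- function(path) {
    if (!file.exists(path)) stop("PDB file not found: ", path)
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    a <- pdb$atom
    if (is.null(a) || nrow(a) == 0L)
        stop("no ATOM/HETATM records in ", path)
    ele <- trimws(as.character(a$elesy))
    blank <- is.na(ele) | !nzchar(ele)
    if (any(blank)) {
        guess <- suppressWarnings(bio3d::atom2ele(a$elety[blank]))
        ele[blank] <- guess
        still <- is.na(ele) | !nzchar(ele)
        if (any(still))
            stop("missing element field for atom record(s) eleno = ",
                 paste(head(a$eleno[still], 5L), collapse = ", "))
    }
    resid <- toupper(trimws(a$resid))
    category <- ifelse(resid %in% .WATER_RESID, "water",
                ifelse(resid %in% .NUC_RESID, "nucleotide", "other"))
    atoms <- data.frame(
        element = ele,
        x = a$x / 10, y = a$y / 10, z = a$z / 10,  # Angstrom -> nm
        category = category,
        residue = paste(a$chain, a$resno, resid, sep = "_"),
        gc = resid %in% .GC_RESID,
        stringsAsFactors = FALSE)
    if (!any(atoms$element == "H" & atoms$category == "nucleotide"))
        warning("structure has no nucleotide hydrogens; proceeding ",
                "(explicit hydrogens expected)")
    .cellFromAtoms(atoms)
}

#' Build a synthetic lattice unit cell
#'
#' Regular grid of identical atoms with exactly known areal density, used as
#' the analytic oracle geometry for the Monte Carlo sampler. Atoms sit at
#' cell-centered positions \code{(i - 0.5) * pitch}, so a grid of
#' \code{nx * ny} atoms spans extents \code{nx*pitch x ny*pitch} and has
#' areal density \code{1/pitch^2}.
#'
#' @param nx,ny,nz atoms per axis.
#' @param pitch grid spacing, nm (> 0).
#' @param element chemical symbol for every atom.
#' @param category \code{"nucleotide"} or \code{"water"}.
#' @param gc logical, recycled across residues (one residue per atom).
#' @return a [UnitCell-class] with extents \code{c(nx, ny, nz) * pitch}.
#' @export
makeSyntheticCell <- function(nx, ny, nz = 1L, pitch = 0.1, element = "C",
                              category = "nucleotide", gc = FALSE) {
    if (pitch <= 0) stop("pitch must be > 0")
    g <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
    n <- nrow(g)
    atoms <- data.frame(
        element = rep(element, n),
        x = (g$i - 0.5) * pitch, y = (g$j - 0.5) * pitch,
        z = (g$k - 0.5) * pitch,
        category = rep(category, n),
        residue = paste0("R", seq_len(n)),
        gc = rep_len(gc, n),
        stringsAsFactors = FALSE)
    new("UnitCell", atoms = atoms, extents = c(nx, ny, nz) * pitch)
}

# rigid rotation about the centroid, order x then y then z
.rotateAtoms <- function(xyz, angles) {
    cx <- colMeans(xyz)
    m <- sweep(xyz, 2, cx)
    rx <- matrix(c(1, 0, 0,
                   0, cos(angles[1]), -sin(angles[1]),
                   0, sin(angles[1]),  cos(angles[1])), 3, 3, byrow = TRUE)
    ry <- matrix(c(cos(angles[2]), 0, sin(angles[2]),
                   0, 1, 0,
                   -sin(angles[2]), 0, cos(angles[2])), 3, 3, byrow = TRUE)
    rz <- matrix(c(cos(angles[3]), -sin(angles[3]), 0,
                   sin(angles[3]),  cos(angles[3]), 0,
                   0, 0, 1), 3, 3, byrow = TRUE)
    sweep(m %*% t(rz %*% ry %*% rx), 2, cx, `+`)
}

#' Stack a unit cell into a randomized slab
#'
#' Copies of the cell are appended along z (the irradiation axis) until the
#' cumulative extent reaches \code{thickness}. Emulating an amorphous solid,
#' each copy receives independent rigid rotations about the x, y and z axes
#' drawn from U\[0, 2pi\] (applied about the cell centroid, in that order)
#' and in-plane translations drawn from U\[-10\%, +10\%\] of the cell's x/y
#' extents. The stack is then projected onto the xy plane and a centered
#' square of side \code{sampleSide} is designated for impact sampling.
#'
#' @param cell a [UnitCell-class].
#' @param thickness target slab thickness, nm; must be at least one cell.
#' @param seed integer RNG seed; the build is deterministic given the seed.
#' @param sampleSide side of the sampling square, nm (default 1).
#' @return a [StructureSlab-class].
#' @aliases buildSlab,UnitCell-method
#' @rdname buildSlab
#' @export
setMethod("buildSlab", "UnitCell",
function(cell, thickness, seed, sampleSide = 1) {
    dz <- cell@extents[3L]
    if (thickness < dz * (1 - 1e-9))
        stop("thickness (", thickness, " nm) is less than one cell (",
             dz, " nm)")
    nCellsReq <- ceiling(thickness / dz - 1e-9)
    if (!is.finite(nCellsReq) || nCellsReq > 1e5)
        stop("thickness requires ", format(nCellsReq), " cells; the cell ",
             "z extent (", format(dz), " nm) looks degenerate")
    nCells <- max(1L, as.integer(nCellsReq))
    base <- cell@atoms
    xyz0 <- as.matrix(base[, c("x", "y", "z")])
    ext <- cell@extents
    pieces <- .withSeed(seed, lapply(seq_len(nCells), function(i) {
        ang <- stats::runif(3, 0, 2 * pi)
        tr <- stats::runif(2, -0.1, 0.1) * ext[1:2]
        xyz <- .rotateAtoms(xyz0, ang)
        xyz[, 1L] <- xyz[, 1L] + tr[1L]
        xyz[, 2L] <- xyz[, 2L] + tr[2L]
        xyz[, 3L] <- xyz[, 3L] + (i - 1L) * dz
        out <- base
        out$x <- xyz[, 1L]; out$y <- xyz[, 2L]; out$z <- xyz[, 3L]
        out$residue <- paste0("c", i, ":", base$residue)
        out
    }))
    atoms <- do.call(rbind, pieces)
    center <- c(mean(atoms$x), mean(atoms$y))
    half <- sampleSide / 2
    inA <- abs(atoms$x - center[1L]) <= half &
           abs(atoms$y - center[2L]) <= half
    nucRes <- unique(atoms$residue[inA & atoms$category == "nucleotide"])
    watRes <- unique(atoms$residue[inA & atoms$category == "water"])
    gcRes <- unique(atoms$residue[inA & atoms$category == "nucleotide" &
                                  atoms$gc])
    new("StructureSlab", atoms = atoms,
        thickness = diff(range(atoms$z)),
        sampleSide = sampleSide, center = center,
        nNucleotidesInArea = length(nucRes),
        nWatersInArea = length(watRes),
        gcFraction = if (length(nucRes)) length(gcRes) / length(nucRes)
                     else NA_real_,
        nCells = nCells)
})

#' Project a unit cell as a slab without randomization
#'
#' Wraps a cell's atoms, unchanged, as a [StructureSlab-class] (single
#' cell, no rotations or translations). Intended for oracle geometries
#' whose projected layout must be exactly the constructed lattice;
#' real-structure sampling should go through [buildSlab()].
#'
#' @param cell a [UnitCell-class].
#' @param sampleSide side of the centered sampling square, nm.
#' @return a [StructureSlab-class].
#' @export
slabFromCell <- function(cell, sampleSide = 1) {
    atoms <- cell@atoms
    center <- c(mean(atoms$x), mean(atoms$y))
    half <- sampleSide / 2
    inA <- abs(atoms$x - center[1L]) <= half &
           abs(atoms$y - center[2L]) <= half
    nucRes <- unique(atoms$residue[inA & atoms$category == "nucleotide"])
    watRes <- unique(atoms$residue[inA & atoms$category == "water"])
    gcRes <- unique(atoms$residue[inA & atoms$category == "nucleotide" &
                                  atoms$gc])
    new("StructureSlab", atoms = atoms,
        thickness = diff(range(atoms$z)),
        sampleSide = sampleSide, center = center,
        nNucleotidesInArea = length(nucRes),
        nWatersInArea = length(watRes),
        gcFraction = if (length(nucRes)) length(gcRes) / length(nucRes)
                     else NA_real_,
        nCells = 1L)
}

#' @rdname accessors
#' @aliases atoms,UnitCell-method atoms,StructureSlab-method
#' @param x an object.
#' @export
setMethod("atoms", "UnitCell", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("atoms", "StructureSlab", function(x) x@atoms)

#' @rdname accessors
#' @aliases nucleotideCount,UnitCell-method waterCount,UnitCell-method
#'   gcFraction,UnitCell-method gcFraction,StructureSlab-method
#'   elements,UnitCell-method elements,XsecLibrary-method
#' @export
setMethod("nucleotideCount", "UnitCell", function(x)
    length(unique(x@atoms$residue[x@atoms$category == "nucleotide"])))

#' @rdname accessors
#' @export
setMethod("waterCount", "UnitCell", function(x)
    length(unique(x@atoms$residue[x@atoms$category == "water"])))

#' @rdname accessors
#' @export
setMethod("gcFraction", "UnitCell", function(x) {
    res <- unique(x@atoms$residue[x@atoms$category == "nucleotide"])
    if (!length(res)) return(NA_real_)
    gcres <- unique(x@atoms$residue[x@atoms$category == "nucleotide" &
                                    x@atoms$gc])
    length(gcres) / length(res)
})

#' @rdname accessors
#' @export
setMethod("gcFraction", "StructureSlab", function(x) x@gcFraction)

#' @rdname accessors
#' @export
setMethod("elements", "UnitCell", function(x) unique(x@atoms$element))

setMethod("show", "UnitCell", function(object) {
    cat(sprintf(
        "UnitCell: %d atoms (%d nucleotide residues, %d waters), extents %s nm\n",
        nrow(object@atoms), nucleotideCount(object), waterCount(object),
        paste(signif(object@extents, 3), collapse = " x ")))
})

setMethod("show", "StructureSlab", function(object) {
    cat(sprintf(
        "StructureSlab: %d atoms in %d cells, thickness %.3g nm, %g nm^2 sampling square (%d nucleotides, %d waters in area)\n",
        nrow(object@atoms), object@nCells, object@thickness,
        object@sampleSide^2, object@nNucleotidesInArea,
        object@nWatersInArea))
})
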