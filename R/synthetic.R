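#' Synthetic hydrated lattice cell
#'
#' A regular lattice mixing nucleotide and water pseudo-atoms at an exact
#' hydration ratio, emulating the composition of a dried duplex with
#' residual waters (default 3.83 waters per nucleotide). Each atom is its
#' own residue; nucleotide residues alternate G/C and A/T labels to reach
#' the requested GC fraction. Geometry and composition are exactly known,
#' so the cell serves as an analytic oracle for the Monte Carlo sampler and
#' downstream fits.
#'
#' @param nNuc number of nucleotide atoms.
#' @param theta hydration ratio; \code{round(theta * nNuc)} water atoms are
#'   added.
#' @param pitch lattice spacing, nm.
#' @param gcFraction target fraction of G/C nucleotide residues.
#' @param nucElement,waterElement element symbols (defaults C and O).
#' @return a [UnitCell-class].
#' @export
hydratedLatticeCell <- function(nNuc, theta = 3.83, pitch = 0.3,
                                gcFraction = 0.5, nucElement = "C",
                                waterElement = "O") {
    stopifnot(nNuc >= 1, theta >= 0, pitch > 0)
    nWat <- round(theta * nNuc)
    n <- nNuc + nWat
    side <- ceiling(sqrt(n))
    g <- expand.grid(i = seq_len(side), j = seq_len(side))[seq_len(n), ]
    # interleave categories so both species cover the area evenly
    cat <- rep("water", n)
    cat[round(seq(1, n, length.out = nNuc))] <- "nucleotide"
    gc <- logical(n)
    idxN <- which(cat == "nucleotide")
    gc[idxN[seq_len(round(gcFraction * nNuc))]] <- TRUE
    atoms <- data.frame(
        element = ifelse(cat == "nucleotide", nucElement, waterElement),
        x = (g$i - 0.5) * pitch, y = (g$j - 0.5) * pitch,
        # two z layers so the cell keeps a usable depth after I/O round
        # trips; the xy projection used for sampling is unchanged
        z = ifelse(seq_len(n) %% 2L == 0L, 0.25, 0.75) * pitch,
        category = cat,
        residue = paste0("R", seq_len(n)),
        gc = gc, stringsAsFactors = FALSE)
    new("UnitCell", atoms = atoms,
        extents = c(side * pitch, side * pitch, pitch))
}

#' Write a unit cell as a PDB file
#'
#' Nucleotide residues are written as DG/DC or DA/DT (per the GC flag),
#' waters as HOH HETATM records, coordinates converted nm to Angstrom.
#' Round-trips through [readStructure()].
#'
#' @param cell a [UnitCell-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSyntheticPdb <- function(cell, path) {
    a <- cell@atoms
    resno <- as.integer(factor(a$residue, levels = unique(a$residue)))
    resid <- ifelse(a$category == "water", "HOH",
             ifelse(a$gc, "DG", "DA"))
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(
                         a[, c("x", "y", "z")] * 10))),
                     type = ifelse(a$category == "water", "HETATM", "ATOM"),
                     resno = resno, resid = resid,
                     eleno = seq_len(nrow(a)),
                     elety = a$element, elesy = a$element,
                     chain = rep("A", nrow(a)))
    invisible(path)
}

#' Write a synthetic cross-section library file
#'
#' Smooth per-element tables on a log energy grid: the non-elastic part is
#' log-quadratic in log10(E) with element-specific coefficients, the
#' elastic part a slowly decaying curve. A sidecar JSON with the generating
#' parameters is written next to the file for recovery tests.
#'
#' @param path output CSV path.
#' @param elements element symbols.
#' @param energies eV grid.
#' @return \code{path}, invisibly; generating parameters in attribute
#'   \code{"truth"}.
#' @export
syntheticXsecFile <- function(path, elements = c("H", "C", "N", "O", "P"),
                              energies = 10^seq(6, 10, length.out = 9)) {
    rows <- list(); truth <- list()
    for (i in seq_along(elements)) {
        el <- elements[i]
        x <- log10(energies)
        b <- c(-2 + 0.3 * i, 0.8 - 0.05 * i, -0.05)  # log sigma_ne vs x - 8
        ne <- exp(b[1L] + b[2L] * (x - 8) + b[3L] * (x - 8)^2)
        elastic <- 2 * exp(-0.2 * (x - 6))
        rows[[i]] <- data.frame(element = el, energy_eV = energies,
                                total_barn = ne + elastic,
                                elastic_barn = elastic)
        truth[[el]] <- b
    }
    out <- do.call(rbind, rows)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
    attr(path, "truth") <- truth
    invisible(path)
}

#' Generate synthetic qPCR amplification curves
#'
#' Four-parameter logistic curves with per-sample parameters and additive
#' Gaussian noise, emulating amplification read-outs of irradiated samples
#' across a fluence series. The generating parameters are attached as
#' attribute \code{"truth"}.
#'
#' @param fluences per-sample fluences, n cm^-2.
#' @param cycles cycle grid (default 1:40).
#' @param a,d floor and ceiling fluorescence.
#' @param b slope.
#' @param midpoints per-sample midpoint cycles (recycled).
#' @param noiseSd additive noise standard deviation.
#' @param seed integer seed.
#' @return data.frame with columns \code{sample}, \code{fluence},
#'   \code{cycle}, \code{fluorescence}.
#' @export
syntheticQpcrCurves <- function(fluences, cycles = 1:40, a = 0.05, d = 1,
                                b = 8, midpoints = 20, noiseSd = 0.01,
                                seed = 1) {
    n <- length(fluences)
    midpoints <- rep_len(midpoints, n)
    out <- .withSeed(seed, do.call(rbind, lapply(seq_len(n), function(i) {
        y <- d + (a - d) / (1 + (cycles / midpoints[i])^b) +
            stats::rnorm(length(cycles), 0, noiseSd)
        data.frame(sample = paste0("S", i), fluence = fluences[i],
                   cycle = cycles, fluorescence = y)
    })))
    attr(out, "truth") <- list(a = a, b = b, d = d, midpoints = midpoints,
                               noiseSd = noiseSd)
    out
}

#' Generate synthetic reads with known per-base error rates
#'
#' Each read is a copy of its reference with independent per-base
#' substitutions, deletions and (post-base) insertions at the given rates,
#' for round-trip tests of the alignment and error-rate operations.
#'
#' @param refs character vector of reference sequences.
#' @param nReads total reads (references recycled in order).
#' @param subRate,delRate,insRate per-base error rates.
#' @param seed integer seed.
#' @return data.frame with columns \code{read}, \code{refIndex}; generating
#'   rates in attribute \code{"truth"}.
#' @export
syntheticReads <- function(refs, nReads, subRate = 0, delRate = 0,
                           insRate = 0, seed = 1) {
    bases <- c("A", "C", "G", "T")
    refIndex <- rep_len(seq_along(refs), nReads)
    reads <- .withSeed(seed, vapply(refIndex, function(ri) {
        s <- strsplit(refs[ri], "")[[1L]]
        out <- character(0)
        for (ch in s) {
            if (stats::runif(1) < delRate) {
                # base deleted
            } else if (stats::runif(1) < subRate) {
                out <- c(out, sample(setdiff(bases, ch), 1L))
            } else {
                out <- c(out, ch)
            }
            if (stats::runif(1) < insRate)
                out <- c(out, sample(bases, 1L))
        }
        paste(out, collapse = "")
    }, character(1)))
    out <- data.frame(read = reads, refIndex = refIndex,
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(subRate = subRate, delRate = delRate,
                               insRate = insRate)
    out
}

#' Simulate cross-section estimates from a known cubic model
#'
#' Draws Poisson hit counts whose means follow a given piecewise cubic
#' cross-section model at chosen energies and exposures, shaped like the
#' output of [sampleImpacts()], for regression parameter-recovery and
#' covariate null tests.
#'
#' @param model a [PiecewiseCubicXSecModel-class] (true generating model).
#' @param energies eV.
#' @param nImpacts impacts per observation.
#' @param nMolecules molecules in the sampled area.
#' @param thicknesses slab thickness per replicate block, nm.
#' @param gcFractions GC fraction per replicate block.
#' @param thicknessSlope optional effect of thickness on log sigma (0 under
#'   the null).
#' @param seed integer seed.
#' @return data.frame shaped like [sampleImpacts()] output (nucleotide
#'   columns populated; water columns zero).
#' @export
simulateEstimates <- function(model, energies, nImpacts = 1e7,
                              nMolecules = 50, thicknesses = 100,
                              gcFractions = 0.5, thicknessSlope = 0,
                              seed = 1) {
    blocks <- expand.grid(energy = energies, thickness = thicknesses)
    blocks$gc <- rep_len(gcFractions, nrow(blocks))
    areaBarn <- 1 * .NM2_BARN
    .withSeed(seed, {
        x <- log10(blocks$energy)
        logsig <- log(predictSigma(model, blocks$energy)) +
            thicknessSlope * blocks$thickness
        mu <- exp(logsig) * nImpacts * nMolecules / areaBarn
        hits <- stats::rpois(nrow(blocks), mu)
        data.frame(energy = blocks$energy, thickness = blocks$thickness,
                   gc_fraction = blocks$gc, hits_nucleotide = hits,
                   hits_water = 0L, n_impacts = nImpacts, sample_side = 1,
                   n_nucleotides_in_area = nMolecules,
                   n_waters_in_area = 0L,
                   sigma_nuc_hat = hits * areaBarn /
                       (nImpacts * nMolecules),
                   sigma_h2o_hat = 0, empty_area = FALSE)
    })
}
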