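# shared fixtures, built in code at test time

# library with one element at a flat non-elastic cross section (barn)
constantSigmaLibrary <- function(sigma, element = "C") {
    XsecLibrary(XsecTable(element, c(1e6, 1e10), rep(sigma, 2L),
                          c(0, 0)))
}

# well-separated disk lattice slab: n x n atoms at `pitch` nm spacing,
# projected as constructed (no randomization) so the disk layout is exact
latticeSlab <- function(n = 10L, pitch = 0.1, category = "nucleotide") {
    slabFromCell(makeSyntheticCell(n, n, 1L, pitch = pitch,
                                   category = category))
}

# closed-form integral of one log-gaussian flux term above E0 (MeV):
# integral of a*exp(-b u^2 + c u) e^u du from ln(E0), via the Gaussian CDF
.logGaussTermAbove <- function(a, b, c, E0) {
    cc <- c + 1
    a * exp(cc^2 / (4 * b)) * sqrt(pi / b) *
        stats::pnorm((log(E0) - cc / (2 * b)) * sqrt(2 * b),
                     lower.tail = FALSE)
}

# independent closed-form oracle for the ground-level reference flux
# above E0 eV (n cm^-2 s^-1)
jedecFluxAboveOracle <- function(E0_eV) {
    E0 <- E0_eV / 1e6
    .logGaussTermAbove(1.006e-6, 0.35, 2.1451, E0) +
        .logGaussTermAbove(1.011e-3, 0.4106, -0.667, E0)
}

# minimal hand-written PDB text: 4 nucleotide residues (2 G/C) with two
# atoms each (one H), plus 8 waters
miniPdbFile <- function() {
    path <- tempfile(fileext = ".pdb")
    recs <- character(0)
    resids <- c("DG", "DC", "DA", "DT")
    no <- 0L
    for (i in seq_along(resids)) {
        for (el in c("C", "H")) {
            no <- no + 1L
            recs <- c(recs, sprintf(
                "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                no, el, resids[i], i, i * 3.0, 1.0, 1.0, el))
        }
    }
    for (j in 1:8) {
        no <- no + 1L
        recs <- c(recs, sprintf(
            "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            no, "O", "HOH", 100L + j, j * 2.0, 5.0, 2.0, "O"))
    }
    writeLines(c(recs, "END"), path)
    path
}
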