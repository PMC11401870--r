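test_that("nearest nucleus uses projected distance with low-index ties", {
    cell <- UnitCell(data.frame(
        element = c("C", "C"), x = c(0, 1), y = c(0, 1), z = c(0, 5),
        category = "nucleotide", residue = c("r1", "r2"),
        gc = FALSE), extents = c(1, 1, 5))
    slab <- buildSlab(cell, 5, seed = 1)
    a <- atoms(slab)
    # query against the randomized coordinates directly
    p <- c(a$x[1L] + 0.01, a$y[1L] + 0.01)
    expect_equal(attr(nearestNucleus(slab, p), "index"), 1L)
    # exact tie at the projected midpoint resolves to the lower index
    mid <- c(mean(a$x), mean(a$y))
    d1 <- (a$x[1] - mid[1])^2 + (a$y[1] - mid[2])^2
    d2 <- (a$x[2] - mid[1])^2 + (a$y[2] - mid[2])^2
    if (isTRUE(all.equal(d1, d2)))
        expect_equal(attr(nearestNucleus(slab, mid), "index"), 1L)
})

test_that("nearest-neighbour search agrees with a brute-force scan", {
    set.seed(5)
    cell <- makeSyntheticCell(7, 7, 2, pitch = 0.17)
    slab <- buildSlab(cell, 0.5, seed = 8)
    a <- atoms(slab)
    for (i in 1:50) {
        p <- runif(2, -0.2, max(a$x) + 0.2)
        idx <- attr(nearestNucleus(slab, p), "index")
        d <- (a$x - p[1])^2 + (a$y - p[2])^2
        expect_equal(d[idx], min(d), tolerance = 1e-12)
    }
})

test_that("estimator recovers the known disk cross section on a lattice", {
    sigma <- 1e7  # barn; disks well separated at 0.1 nm pitch
    slab <- latticeSlab(10, 0.1)
    lib <- constantSigmaLibrary(sigma)
    n <- 2e5
    est <- sampleImpacts(slab, lib, 1e8, n, seed = 11)
    # binomial standard error of sigma_hat
    pHat <- est$hits_nucleotide / n
    seSigma <- sqrt(pHat * (1 - pHat) / n) * 1e10 /
        est$n_nucleotides_in_area
    expect_lt(abs(est$sigma_nuc_hat - sigma), 4 * seSigma)
})

test_that("hits attribute to the category of the nearest nucleus", {
    # half nucleotides, half waters, interleaved
    cell <- hydratedLatticeCell(50, theta = 1, pitch = 0.1)
    slab <- slabFromCell(cell)
    lib <- XsecLibrary(
        XsecTable("C", c(1e6, 1e10), c(1e7, 1e7), c(0, 0)),
        XsecTable("O", c(1e6, 1e10), c(1e7, 1e7), c(0, 0)))
    est <- sampleImpacts(slab, lib, 1e8, 1e5, seed = 4)
    expect_gt(est$hits_nucleotide, 0)
    expect_gt(est$hits_water, 0)
    # equal disks and near-equal areal densities: per-molecule estimates
    # agree within a factor ~2 at this depth of sampling
    expect_lt(abs(log(est$sigma_nuc_hat / est$sigma_h2o_hat)), log(2))
})

test_that("empty sampling square yields flagged zero estimates", {
    # atoms categorized 'other' only
    cell <- makeSyntheticCell(3, 3, 1, pitch = 0.1, category = "other")
    slab <- buildSlab(cell, 0.1, seed = 1)
    lib <- constantSigmaLibrary(1)
    expect_warning(est <- sampleImpacts(slab, lib, 1e8, 100, seed = 1),
                   "no nucleotides or waters")
    expect_equal(est$sigma_nuc_hat, 0)
    expect_true(est$empty_area)
})

test_that("sampling errors before starting when an element lacks a table", {
    slab <- latticeSlab(3, 0.1)
    lib <- constantSigmaLibrary(1, element = "H")
    expect_error(sampleImpacts(slab, lib, 1e8, 10, seed = 1),
                 "missing from cross-section library")
})

test_that("identical seed and configuration give identical hit counts", {
    slab <- latticeSlab(5, 0.1)
    lib <- constantSigmaLibrary(1e6)
    e1 <- sampleImpacts(slab, lib, c(1e7, 1e8), 5e4, seed = 21)
    e2 <- sampleImpacts(slab, lib, c(1e7, 1e8), 5e4, seed = 21)
    expect_identical(e1, e2)
})

test_that("energies outside the sampled range are rejected", {
    slab <- latticeSlab(3, 0.1)
    lib <- constantSigmaLibrary(1)
    expect_error(sampleImpacts(slab, lib, 5, 10, seed = 1), "\\[10, 1e11\\]")
    expect_error(sampleImpacts(slab, lib, 2e11, 10, seed = 1))
})
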