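test_that("piecewise model evaluates the cubic inside and zero outside", {
    m <- referenceXsecModel("nucleotide")
    # direct scalar evaluation of the bundled coefficients at x = 8
    b <- m@beta
    expect_equal(predictSigma(m, 1e8),
                 exp(b[1] + b[2] * 8 + b[3] * 64 + b[4] * 512))
    expect_equal(predictSigma(m, 1e8), 6.415907, tolerance = 1e-6)
    # outside the window the cross section is zero, not exp(0)
    expect_equal(predictSigma(m, 1e5), 0)
    expect_equal(predictSigma(m, 1e11), 0)
    # zero coefficients give exp(0) = 1 barn inside the window
    m0 <- PiecewiseCubicXSecModel(c(0, 0, 0, 0))
    expect_equal(predictSigma(m0, 1e8), 1)
    # continuity inside the window
    e <- 10^seq(6, 10, length.out = 200)
    s <- predictSigma(m, e)
    expect_true(all(is.finite(s) & s >= 0))
    expect_true(all(abs(diff(log(s))) < 0.5))
})

test_that("bundled reference coefficients are exposed for both responses", {
    tab <- referenceXsecCoefficients()
    expect_equal(nrow(tab), 8L)
    expect_true(all(c("coefficient", "sd") %in% names(tab)))
    mw <- referenceXsecModel("water")
    expect_equal(predictSigma(mw, 1e8), 0.3464321, tolerance = 1e-6)
})

test_that("Poisson regression recovers generating coefficients", {
    truth <- referenceXsecModel("nucleotide")
    energies <- 10^seq(6, 10, length.out = 40)
    est <- simulateEstimates(truth, energies, nImpacts = 2e8,
                             nMolecules = 5000,
                             thicknesses = c(100, 1e3, 1e4, 1e5),
                             seed = 101)
    fit <- fitPiecewise(est, "nucleotide")
    expect_true(all(abs(fit@beta - truth@beta) < 3 * fit@se))
    # GLM consistency: predictions at training energies match fitted means
    glmfit <- attr(fit, "fit")
    mu <- fitted(glmfit)
    expo <- est$n_impacts * est$n_nucleotides_in_area / 1e10
    keep <- log10(est$energy) >= 6 & log10(est$energy) <= 10
    expect_equal(predictSigma(fit, est$energy[keep]),
                 unname(mu / expo[keep]), tolerance = 1e-8)
})

test_that("higher-order terms are insignificant when absent from the truth", {
    truth <- PiecewiseCubicXSecModel(c(-15, 2, 0, 0))
    energies <- 10^seq(6, 10, length.out = 40)
    est <- simulateEstimates(truth, energies, nImpacts = 1e8,
                             nMolecules = 5e4,
                             thicknesses = c(100, 1e3, 1e4, 1e5),
                             seed = 7)
    fit <- fitPiecewise(est, "nucleotide")
    t23 <- abs(fit@beta[3:4]) / fit@se[3:4]
    expect_true(all(t23 < qnorm(0.995)))
})

test_that("fit preconditions are enforced", {
    truth <- referenceXsecModel("nucleotide")
    est <- simulateEstimates(truth, c(1e7, 1e8, 1e9), seed = 1)
    expect_error(fitPiecewise(est), "at least 4")
    est2 <- simulateEstimates(truth, 10^seq(6, 10, length.out = 10),
                              nImpacts = 10, nMolecules = 1, seed = 1)
    est2$hits_nucleotide <- 0L
    expect_error(fitPiecewise(est2), "zero")
    # observations outside the window are excluded from the fit
    e3 <- simulateEstimates(truth, 10^seq(6, 10, length.out = 12),
                            nImpacts = 2e8, nMolecules = 5000, seed = 2)
    extra <- e3[1L, ]
    extra$energy <- 1e5
    extra$hits_nucleotide <- 1e6L  # absurd out-of-window point
    fitA <- fitPiecewise(e3, "nucleotide")
    fitB <- fitPiecewise(rbind(e3, extra), "nucleotide")
    expect_equal(fitA@beta, fitB@beta)
})

test_that("covariate refits give the study's design degrees of freedom", {
    truth <- referenceXsecModel("nucleotide")
    energies <- 10^seq(6, 10, length.out = 33)
    est <- simulateEstimates(truth, energies, nImpacts = 2e8,
                             nMolecules = 5000,
                             thicknesses = c(100, 1e3, 1e4, 1e5, 1e6),
                             seed = 31)
    res <- covariateTest(est, "thickness", "nucleotide")
    expect_equal(res$df, 160)
    expect_true(res$p >= 0 && res$p <= 1)
    expect_equal(res$t, res$coefficient / res$se)
})

test_that("an injected thickness effect is detected", {
    truth <- referenceXsecModel("nucleotide")
    energies <- 10^seq(6, 10, length.out = 33)
    est <- simulateEstimates(truth, energies, nImpacts = 2e8,
                             nMolecules = 5000,
                             thicknesses = c(100, 1e3, 1e4, 1e5, 1e6),
                             thicknessSlope = 2e-6, seed = 32)
    res <- covariateTest(est, "thickness", "nucleotide")
    expect_lt(res$p, 1e-4)
})

test_that("a constant covariate is rejected", {
    truth <- referenceXsecModel("nucleotide")
    est <- simulateEstimates(truth, 10^seq(6, 10, length.out = 12),
                             thicknesses = 100, seed = 3)
    expect_error(covariateTest(est, "thickness"), "constant")
})
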