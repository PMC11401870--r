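test_that("pool design invariants are enforced", {
    expect_error(PoolDesign(N = 0, C = 100), "N must be")
    expect_error(PoolDesign(N = 1, C = 10, CLLOD = 10), "exceed")
    d <- PoolDesign(N = 7373, C = 1000)
    expect_equal(d@CLLOD, 10)
})

test_that("two-copy strand loss has its closed form", {
    d <- PoolDesign(N = 1, C = 2, CLLOD = 1)
    k <- 0.7
    ts <- c(0, 0.1, 1, 5)
    expect_equal(strandLossCdf(d, k, ts), (1 - exp(-k * ts))^2)
    # and agrees with the hypoexponential form with rates {2k, k}
    expect_equal(strandLossCdf(d, k, ts[-1]),
                 hypoexpCdf(c(2 * k, k), ts[-1]), tolerance = 1e-12)
    expect_equal(strandLossCdf(d, k, 0), 0)
    expect_equal(strandLossCdf(d, k, 1e6), 1)
    expect_error(strandLossCdf(d, k, -1), ">= 0")
})

test_that("binomial-tail CDF equals the hypoexponential law", {
    k <- 3e-2
    for (C in c(5, 12, 30)) {
        for (m in c(1, 3, 10)) {
            if (C <= m) next
            d <- PoolDesign(N = 1, C = C, CLLOD = m)
            rates <- seq(m, C) * k
            ts <- 10^seq(-1, 3, length.out = 25) / (C * k)
            # stable (uniformization) evaluation: absolute 1e-10 everywhere
            expect_lt(max(abs(strandLossCdf(d, k, ts) -
                              hypoexpCdf(rates, ts))), 1e-10)
            # textbook product form where its alternating weights are
            # small enough to be exact (few stages)
            if (C - m <= 11)
                expect_lt(max(abs(strandLossCdf(d, k, ts) -
                                  hypoexpCdf(rates, ts,
                                             method = "product"))),
                          1e-10)
        }
    }
    # the two evaluation routes agree with each other on small instances
    rr <- c(0.11, 0.35, 0.8, 1.7)
    ts <- seq(0.1, 30, length.out = 17)
    expect_lt(max(abs(hypoexpCdf(rr, ts) -
                      hypoexpCdf(rr, ts, method = "product"))), 1e-12)
})

test_that("expected strand loss time matches harmonic sum and integral", {
    k <- 0.4
    d <- PoolDesign(N = 1, C = 2, CLLOD = 1)
    expect_equal(expectedStrandLossTime(d, k), 3 / (2 * k))
    d2 <- PoolDesign(N = 1, C = 11, CLLOD = 10)
    expect_equal(expectedStrandLossTime(d2, k),
                 1 / (11 * k) + 1 / (10 * k))
    # integral of the survival function (independent numerical oracle)
    d3 <- PoolDesign(N = 1, C = 40, CLLOD = 7)
    num <- integrate(function(t) 1 - strandLossCdf(d3, k, t), 0, Inf,
                     rel.tol = 1e-10)$value
    expect_equal(expectedStrandLossTime(d3, k), num, tolerance = 1e-6)
    # and equals the pool expectation at N = 1
    expect_equal(expectedPoolLossTime(d3, k),
                 expectedStrandLossTime(d3, k), tolerance = 1e-6)
})

test_that("pool CDF reduces at N = 1 and is a valid CDF", {
    k <- 0.05
    d1 <- PoolDesign(N = 1, C = 50, CLLOD = 10)
    ts <- seq(0, 2000, length.out = 80)
    expect_equal(poolLossCdf(d1, k, ts), strandLossCdf(d1, k, ts))
    dN <- PoolDesign(N = 200, C = 50, CLLOD = 10)
    f <- poolLossCdf(dN, k, ts)
    expect_equal(f[1L], 0)
    expect_true(all(diff(f) >= -1e-12))
    expect_true(all(f >= 0 & f <= 1))
    expect_equal(poolLossCdf(dN, k, 1e6), 1)
    # more strand indices -> earlier loss, pointwise
    expect_true(all(f >= strandLossCdf(d1, k, ts) - 1e-12))
})

test_that("expected pool loss time is non-increasing in N", {
    k <- 1e-3
    es <- vapply(c(1, 10, 100, 1000, 10000), function(N)
        expectedPoolLossTime(PoolDesign(N = N, C = 100, CLLOD = 10), k),
        numeric(1))
    expect_true(all(diff(es) < 0))
})

test_that("the Gillespie simulator reproduces the analytic law", {
    k <- 0.02
    d <- PoolDesign(N = 20, C = 40, CLLOD = 10)
    nReps <- 2000
    sim <- simulatePool(d, k, nReps, seed = 97)
    # empirical CDF within the 99% DKW band of the analytic pool CDF
    eps <- sqrt(log(2 / 0.01) / (2 * nReps))
    ts <- sort(sim)
    emp <- seq_len(nReps) / nReps
    ana <- poolLossCdf(d, k, ts)
    expect_lt(max(abs(emp - ana)), eps)
    # empirical mean within 3 standard errors of the analytic expectation
    se <- sd(sim) / sqrt(nReps)
    expect_lt(abs(mean(sim) - expectedPoolLossTime(d, k)), 3 * se)
    # determinism
    expect_identical(simulatePool(d, k, 3, seed = 5),
                     simulatePool(d, k, 3, seed = 5))
})

test_that("large copy numbers evaluate stably", {
    k <- 1e-9
    d <- PoolDesign(N = 7373, C = 1e6, CLLOD = 10)
    et <- expectedPoolLossTime(d, k)
    expect_true(is.finite(et) && et > 0)
    f <- poolLossCdf(d, k, et)
    expect_true(f > 0 && f < 1)
})

test_that("sensitivity sweeps show the expected qualitative behaviour", {
    sp <- jedecSpectrum()
    base <- PoolDesign(N = 7373, C = 1000, L = 150, theta = 4)
    swC <- sensitivitySweep(base, "C", round(10^seq(2, 5, length.out = 6)),
                            sp)
    expect_true(all(diff(swC$expected_loss_s) > 0))
    swL <- sensitivitySweep(base, "L", c(50, 100, 200, 400), sp)
    expect_true(all(diff(swL$expected_loss_s) < 0))
    swT <- sensitivitySweep(base, "theta", c(0, 2, 8, 32), sp)
    expect_true(all(diff(swT$expected_loss_s) < 0))
    # theta sweep is flat when the water cross section is zero
    m0 <- PiecewiseCubicXSecModel(c(-Inf, 0, 0, 0))
    swT0 <- sensitivitySweep(base, "theta", c(0, 8, 32), sp,
                             sigmaH2O = m0)
    expect_equal(diff(swT0$expected_loss_s), c(0, 0))
    # invalid grid points yield per-point error entries
    swBad <- sensitivitySweep(base, "C", c(5, 1000), sp)
    expect_true(is.na(swBad$expected_loss_s[1L]) &&
                !is.na(swBad$error[1L]))
    expect_false(is.na(swBad$expected_loss_s[2L]))
})
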