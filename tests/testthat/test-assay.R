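test_that("noise-free 4PL curves are recovered to optimizer tolerance", {
    x <- 1:40
    a <- 0.08; b <- 7; cc <- 22; d <- 1.4
    y <- d + (a - d) / (1 + (x / cc)^b)
    fit <- fit4pl(x, y)
    expect_equal(fit$a, a, tolerance = 1e-6)
    expect_equal(fit$b, b, tolerance = 1e-6)
    expect_equal(fit$c, cc, tolerance = 1e-6)
    expect_equal(fit$d, d, tolerance = 1e-6)
    # C_half: fitted curve at half the maximum achieved amplification;
    # with max(y) < d the target sits slightly before the midpoint cycle
    target <- (a + max(y)) / 2
    yAt <- d + (a - d) / (1 + (fit$cHalf / cc)^b)
    expect_equal(yAt, target, tolerance = 1e-8)
    expect_true(fit$cHalf > min(x) && fit$cHalf < max(x))
})

test_that("C_half is nearly unbiased under 1% noise", {
    x <- 1:40
    a <- 0.05; b <- 8; cc <- 20; d <- 1
    y0 <- d + (a - d) / (1 + (x / cc)^b)
    target0 <- (a + max(y0)) / 2
    c0 <- cc * ((a - target0) / (target0 - d))^(1 / b)
    set.seed(12)
    ch <- vapply(1:50, function(i) {
        y <- y0 + rnorm(length(x), 0, 0.01)
        fit4pl(x, y)$cHalf
    }, numeric(1))
    expect_lt(abs(mean(ch) - c0), 0.1)
})

test_that("degenerate amplification curves are rejected", {
    x <- 1:20
    expect_error(fit4pl(x, rep(1, 20)), "flat")
    expect_error(fit4pl(x, 2 - 0.05 * x), "amplification")
    expect_error(fit4pl(1:5, rnorm(5)), "at least 8")
})

test_that("trend test gives exact results on noiseless lines and n-2 df", {
    flu <- c(0, 1.6e11, 2.4e11, 3.3e11, 4.2e11, 5.1e11)
    res <- suppressWarnings(trendTest(1 + 2e-12 * flu, flu))
    expect_equal(res$df, 4)  # 6 samples -> t(4)
    expect_lt(res$p, 1e-10)
    expect_equal(res$coefficient, 2e-12, tolerance = 1e-8)
    expect_error(trendTest(1:3, rep(1, 3)), "constant")
    expect_error(trendTest(1:2, 1:2), "at least 3")
})

test_that("per-base error rates count against aligned reference bases", {
    perfect <- data.frame(matches = c(100, 50), mismatches = 0,
                          insertions = 0, deletions = 0)
    r0 <- perBaseErrorRates(perfect)
    expect_equal(r0$total, 0)
    one <- data.frame(matches = 99, mismatches = 1, insertions = 0,
                      deletions = 0)
    expect_equal(perBaseErrorRates(one)$substitution, 0.01)
    expect_equal(perBaseErrorRates(one)$total, 0.01)
    mix <- data.frame(matches = 90, mismatches = 5, insertions = 3,
                      deletions = 5)
    r <- perBaseErrorRates(mix)
    expect_equal(r$aligned_bases, 100)
    expect_equal(r$total, r$insertion + r$deletion + r$substitution)
    expect_error(perBaseErrorRates(
        data.frame(matches = 0, mismatches = 0, insertions = 0,
                   deletions = 0)), "zero aligned")
})

test_that("alignment of synthetic reads recovers injected error rates", {
    set.seed(33)
    refs <- vapply(1:4, function(i)
        paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
              collapse = ""), character(1))
    rd <- syntheticReads(refs, nReads = 60, subRate = 0.01,
                         delRate = 0.01, insRate = 0.01, seed = 44)
    cnt <- alignmentCounts(rd$read, refs, rd$refIndex)
    rates <- perBaseErrorRates(cnt)
    nb <- rates$aligned_bases
    for (r in c(rates$substitution, rates$deletion, rates$insertion)) {
        se <- sqrt(0.01 * 0.99 / nb)
        expect_lt(abs(r - 0.01), 3 * se + 2e-3)
    }
    # zero-rate reads align perfectly
    rd0 <- syntheticReads(refs, nReads = 4, seed = 1)
    expect_identical(rd0$read, refs)
    cnt0 <- alignmentCounts(rd0$read, refs, rd0$refIndex)
    expect_equal(sum(cnt0$mismatches + cnt0$insertions + cnt0$deletions),
                 0)
})

test_that("copy-number arithmetic follows the quantification formulas", {
    expect_equal(copiesFromMass(0, 1)$copies, 0)
    # mass giving exactly one copy: m = (310*650*1e9)/6.022e23
    m1 <- (310 * 650 * 1e9) / 6.022e23
    q <- copiesFromMass(m1 / 100, 1)
    expect_equal(q$mass, m1)
    expect_equal(q$copies, 1, tolerance = 1e-12)
    # linear in concentration and volume
    expect_equal(copiesFromMass(2, 3)$copies,
                 6 * copiesFromMass(1, 1)$copies)
})
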