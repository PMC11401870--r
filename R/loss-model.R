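#' Construct a pool design
#'
#' @param N unique strands (>= 1).
#' @param C copy number; must exceed \code{CLLOD}.
#' @param L strand length, nucleotides.
#' @param theta hydration ratio, waters per nucleotide.
#' @param CLLOD lower limit of detection, copies (default 10).
#' @return a [PoolDesign-class].
#' @export
PoolDesign <- function(N, C, L = 150, theta = 4, CLLOD = 10) {
    # slots set individually: a slot named C cannot be passed to new(),
    # where it would partially match the Class formal
    d <- new("PoolDesign")
    d@N <- as.numeric(N); d@C <- as.numeric(C); d@L <- as.numeric(L)
    d@theta <- as.numeric(theta); d@CLLOD <- as.numeric(CLLOD)
    validObject(d)
    d
}

setMethod("show", "PoolDesign", function(object) {
    cat(sprintf(
        "PoolDesign: N = %g, C = %g, L = %g nt, theta = %g, C_LLOD = %g\n",
        object@N, object@C, object@L, object@theta, object@CLLOD))
})

#' Hypoexponential cumulative distribution function
#'
#' CDF of a sum of independent exponentials (the first-passage time of a
#' chain traversing one stage per rate). Two evaluation routes are
#' provided:
#' \describe{
#'   \item{\code{"uniformization"}}{(default) the series
#'     \eqn{F(t) = \sum_s \mathrm{Pois}(s; \Lambda t)\, A_s} with
#'     \eqn{\Lambda = \max_i \lambda_i} and \eqn{A_s} the probability of
#'     having traversed all stages within \eqn{s} uniformized jumps. Every
#'     term is positive, so the evaluation is stable for hundreds of
#'     stages; the series is truncated at a Poisson tail mass of 1e-15.}
#'   \item{\code{"product"}}{the textbook closed form
#'     \eqn{F(t) = 1 - \sum_i w_i e^{-\lambda_i t}},
#'     \eqn{w_i = \prod_{j \ne i} \lambda_j/(\lambda_j - \lambda_i)},
#'     requiring distinct rates. The alternating weights grow rapidly with
#'     the stage count (for ~20+ integer-spaced stages they exceed 1e9),
#'     so cancellation limits its accuracy; it is intended as the
#'     small-instance oracle.}
#' }
#'
#' @param rates positive stage rates (distinct for \code{"product"}).
#' @param t time, >= 0 (vectorized).
#' @param method evaluation route, see above.
#' @return probabilities.
#' @export
hypoexpCdf <- function(rates, t,
                       method = c("uniformization", "product")) {
    method <- match.arg(method)
    if (any(t < 0)) stop("t must be >= 0")
    if (any(rates <= 0)) stop("rates must be > 0")
    if (method == "product") {
        if (anyDuplicated(rates)) stop("rates must be distinct")
        w <- vapply(seq_along(rates), function(i)
            prod(rates[-i] / (rates[-i] - rates[i])), numeric(1))
        return(vapply(t, function(tt) 1 - sum(w * exp(-rates * tt)),
                      numeric(1)))
    }
    n <- length(rates)
    lam <- max(rates)
    pJump <- rates / lam
    vapply(t, function(tt) {
        if (tt == 0) return(0)
        mu <- lam * tt
        sMax <- max(n, stats::qpois(1e-15, mu, lower.tail = FALSE)) + 5L
        v <- c(1, numeric(n))  # occupancy of stages 1..n, then absorbed
        acc <- 0
        wPois <- stats::dpois(0:sMax, mu)
        for (s in 0:sMax) {
            acc <- acc + wPois[s + 1L] * v[n + 1L]
            adv <- v[seq_len(n)] * pJump
            v[seq_len(n)] <- v[seq_len(n)] - adv
            v[2:(n + 1L)] <- v[2:(n + 1L)] + adv
        }
        min(acc, 1)
    }, numeric(1))
}

.stageRates <- function(design, k) seq(design@CLLOD, design@C) * k

#' Per-strand time-to-loss distribution
#'
#' The copy count of one strand index starts at C; each intact copy is
#' damaged independently at hazard \code{k}, so the count steps down through
#' stages with rates \eqn{\lambda(c) = c k}, \eqn{c = C, \ldots, C_{LLOD}}.
#' The time to loss (count falling below \eqn{C_{LLOD}}) is hypoexponential
#' with that rate set; it is evaluated here through the equivalent
#' binomial-survival identity
#' \deqn{F(t) = P[\mathrm{Binomial}(C, e^{-kt}) \le C_{LLOD} - 1],}
#' which is stable for copy numbers up to at least 1e6 where the explicit
#' product form overflows.
#'
#' @param design a [PoolDesign-class].
#' @param k per-strand hazard, s^-1 (> 0).
#' @param t time in seconds, >= 0 (vectorized).
#' @return probability of loss of a given strand index by time \code{t}.
#' @export
strandLossCdf <- function(design, k, t) {
    if (any(t < 0)) stop("t must be >= 0")
    stopifnot(k > 0)
    stats::pbinom(design@CLLOD - 1, design@C, exp(-k * t))
}

#' Expected per-strand time to loss
#'
#' Closed form: the sum of the stage means,
#' \eqn{\sum_{c = C_{LLOD}}^{C} 1/(c k)} (a difference of harmonic numbers
#' over \code{k}).
#'
#' @inheritParams strandLossCdf
#' @return seconds.
#' @export
expectedStrandLossTime <- function(design, k) {
    stopifnot(k > 0)
    if (design@CLLOD < 1) {
        warning("CLLOD = 0: the final stage has zero rate, expected loss ",
                "time is infinite")
        return(Inf)
    }
    sum(1 / (seq(design@CLLOD, design@C) * k))
}

#' Pool time-to-loss distribution and expectation
#'
#' Strand indices are independent and identically distributed, so the pool
#' loses information when the first of its N indices does:
#' \deqn{F_{pool}(t) = 1 - [1 - F_{strand}(t)]^N,}
#' and the expected time to loss is the integral of the pool survival
#' function. The integral is evaluated in the copy-survival variable
#' \eqn{u = e^{-kt}} by adaptive quadrature, split at the pool-survival
#' median for robustness when N is large and the distribution is sharp.
#'
#' @inheritParams strandLossCdf
#' @return \code{poolLossCdf}: probability; \code{expectedPoolLossTime}:
#'   seconds.
#' @export
poolLossCdf <- function(design, k, t) {
    f <- strandLossCdf(design, k, t)
    -expm1(design@N * log1p(-f))
}

#' @rdname poolLossCdf
#' @export
expectedPoolLossTime <- function(design, k) {
    stopifnot(k > 0)
    if (design@CLLOD < 1) {
        warning("CLLOD = 0: expected loss time is infinite")
        return(Inf)
    }
    C <- design@C; m <- design@CLLOD; N <- design@N
    # log P[Bin(C, u) >= m], always evaluating the log on the minor tail
    # (pbeta's log-series underflows when asked for the dominant tail)
    logS <- function(u) {
        plo <- stats::pbinom(m - 1, C, u)
        out <- log1p(-plo)
        small <- plo >= 0.5
        if (any(small))
            out[small] <- stats::pbinom(m - 1, C, u[small],
                                        lower.tail = FALSE, log.p = TRUE)
        out
    }
    f <- function(u) exp(N * logS(u)) / u
    # split where pool survival crosses 1/2
    g <- function(u) N * logS(u) - log(0.5)
    ustar <- tryCatch(stats::uniroot(g, c(1e-12, 1 - 1e-12),
                                     tol = 1e-12)$root,
                      error = function(e) 0.5)
    i1 <- stats::integrate(f, 0, ustar, rel.tol = 1e-9,
                           subdivisions = 500L)$value
    i2 <- stats::integrate(f, ustar, 1, rel.tol = 1e-9,
                           subdivisions = 500L)$value
    (i1 + i2) / k
}

#' Stochastic pure-death simulation of pool loss
#'
#' Gillespie-style simulator: each of the N strand indices steps its copy
#' count down from C through \eqn{C_{LLOD}} with exponential stage times of
#' rates \eqn{c k}; a replicate's loss time is the minimum over indices.
#' Serves as the independent oracle for the analytic forms.
#'
#' @inheritParams strandLossCdf
#' @param nReps replicates (>= 1).
#' @param seed integer seed; deterministic given the seed.
#' @return numeric vector of \code{nReps} pool loss times, seconds.
#' @export
simulatePool <- function(design, k, nReps, seed) {
    stopifnot(nReps >= 1, k > 0)
    if (design@CLLOD < 1)
        stop("CLLOD = 0: loss never occurs in the pure-death model")
    rates <- .stageRates(design, k)
    len <- length(rates)
    N <- as.integer(design@N)
    .withSeed(seed, vapply(seq_len(nReps), function(r) {
        strandTimes <- colSums(matrix(stats::rexp(len * N, rate = rates),
                                      nrow = len))
        min(strandTimes)
    }, numeric(1)))
}

#' Sensitivity of expected loss time to design parameters
#'
#' Recomputes E\[T_loss\] across a grid of one design parameter with the
#' others held at the baseline, rebuilding the damage kinetics where the
#' parameter (L or theta) enters the per-strand hazard.
#'
#' @param design baseline [PoolDesign-class].
#' @param parameter one of \code{"N"}, \code{"C"}, \code{"L"},
#'   \code{"theta"}.
#' @param grid parameter values.
#' @param flux a [FluxSpectrum-class].
#' @param sigmaNuc,sigmaH2O cross-section models (defaults: bundled
#'   reference models).
#' @return data.frame with columns \code{parameter}, \code{value},
#'   \code{expected_loss_s}, \code{expected_loss_years} (NA where a grid
#'   value violates the design invariants, with the message in
#'   \code{error}).
#' @export
sensitivitySweep <- function(design, parameter = c("N", "C", "L", "theta"),
                             grid, flux,
                             sigmaNuc = referenceXsecModel("nucleotide"),
                             sigmaH2O = referenceXsecModel("water")) {
    parameter <- match.arg(parameter)
    rows <- lapply(grid, function(v) {
        out <- data.frame(parameter = parameter, value = v,
                          expected_loss_s = NA_real_,
                          expected_loss_years = NA_real_,
                          error = NA_character_)
        tryCatch({
            d <- design
            slot(d, if (parameter == "theta") "theta" else parameter) <-
                as.numeric(v)
            validObject(d)
            kin <- buildKinetics(d@L, d@theta, flux, sigmaNuc, sigmaH2O)
            et <- expectedPoolLossTime(d, perStrandRate(kin))
            out$expected_loss_s <- et
            out$expected_loss_years <- secondsToYears(et)
            out
        }, error = function(e) {
            out$error <- conditionMessage(e)
            out
        })
    })
    do.call(rbind, rows)
}
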