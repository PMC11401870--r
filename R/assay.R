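#' Fit a four-parameter logistic to a qPCR amplification curve
#'
#' Least-squares fit of
#' \deqn{y = d + \frac{a - d}{1 + (x/c)^b}}
#' (floor \code{a}, ceiling \code{d}, midpoint cycle \code{c}, slope
#' \code{b}) by Levenberg-Marquardt, initialized at \code{a = min(y)},
#' \code{d = max(y)}, \code{c = median(x)}, \code{b = 1}. The quantification
#' cycle \code{C_half} is the cycle at which the fitted curve reaches half
#' the maximum amplification achieved, i.e. where fitted
#' \code{y = (a + max(y_observed)) / 2}.
#'
#' @param cycles strictly increasing cycle numbers (>= 8 points).
#' @param fluorescence fluorescence readings, same length.
#' @return list with \code{a}, \code{b}, \code{c}, \code{d}, \code{cHalf},
#'   \code{fitted} and the \code{nls} object in \code{fit}.
#' @export
fit4pl <- function(cycles, fluorescence) {
    stopifnot(length(cycles) == length(fluorescence))
    if (length(cycles) < 8L) stop("need at least 8 cycles")
    if (any(diff(cycles) <= 0)) stop("cycles must be strictly increasing")
    if (stats::sd(fluorescence) < 1e-12 * max(1, abs(mean(fluorescence))))
        stop("flat curve: no amplification")
    df <- data.frame(x = cycles, y = fluorescence)
    start <- list(a = min(df$y), d = max(df$y),
                  c = stats::median(df$x), b = 1)
    fit <- tryCatch(
        minpack.lm::nlsLM(y ~ d + (a - d) / (1 + (x / c)^b),
                          data = df, start = start,
                          control = minpack.lm::nls.lm.control(
                              maxiter = 500)),
        error = function(e) stop("4PL fit did not converge: ",
                                 conditionMessage(e)))
    p <- as.list(stats::coef(fit))
    if (p$d <= p$a)
        stop("no amplification: fitted ceiling does not exceed floor")
    target <- (p$a + max(df$y)) / 2
    # invert y = d + (a-d)/(1+u), u = (x/c)^b  =>  u = (a-y)/(y-d)
    u <- (p$a - target) / (target - p$d)
    cHalf <- p$c * u^(1 / p$b)
    list(a = p$a, b = p$b, c = p$c, d = p$d, cHalf = cHalf,
         fitted = stats::fitted(fit), fit = fit)
}

#' Linear-trend t test of a statistic against fluence
#'
#' Ordinary least-squares regression of a per-sample statistic on neutron
#' fluence with a two-sided t test of the slope (uncorrected; nominal
#' acceptance at p < 0.05). With n samples the test has n - 2 degrees of
#' freedom.
#'
#' @param values per-sample statistic (e.g. qPCR C_half or an error rate).
#' @param fluences neutron fluences, n cm^-2; must vary.
#' @return one-row data.frame: \code{coefficient} (slope), \code{se},
#'   \code{t}, \code{df}, \code{p}.
#' @export
trendTest <- function(values, fluences) {
    stopifnot(length(values) == length(fluences))
    if (length(values) < 3L) stop("need at least 3 samples")
    if (length(unique(fluences)) < 2L) stop("fluence is constant")
    fit <- stats::lm(values ~ fluences)
    sm <- summary(fit)$coefficients
    data.frame(coefficient = sm["fluences", "Estimate"],
               se = sm["fluences", "Std. Error"],
               t = sm["fluences", "t value"],
               df = fit$df.residual,
               p = sm["fluences", "Pr(>|t|)"])
}

#' Per-base sequencing error rates from alignment counts
#'
#' Reduces per-read alignment operation counts against known references to
#' pooled per-base rates: each rate is the summed operation count divided
#' by the summed aligned reference bases (matches + mismatches +
#' deletions).
#'
#' @param counts data.frame with columns \code{matches},
#'   \code{mismatches}, \code{insertions}, \code{deletions} (one row per
#'   read).
#' @return one-row data.frame: \code{insertion}, \code{deletion},
#'   \code{substitution}, \code{total} rates and \code{aligned_bases}.
#' @export
perBaseErrorRates <- function(counts) {
    need <- c("matches", "mismatches", "insertions", "deletions")
    miss <- setdiff(need, names(counts))
    if (length(miss))
        stop("counts is missing column(s): ", paste(miss, collapse = ", "))
    denom <- sum(counts$matches) + sum(counts$mismatches) +
        sum(counts$deletions)
    if (denom <= 0) stop("zero aligned reference bases")
    ins <- sum(counts$insertions) / denom
    del <- sum(counts$deletions) / denom
    sub <- sum(counts$mismatches) / denom
    data.frame(insertion = ins, deletion = del, substitution = sub,
               total = ins + del + sub, aligned_bases = denom)
}

#' Alignment operation counts of reads against references
#'
#' Globally aligns each read to its reference (Needleman-Wunsch via
#' Biostrings, unit match/mismatch scores, small affine gap penalties) and
#' tabulates matches, mismatches, insertions and deletions per read, for
#' use with [perBaseErrorRates()] on synthetic data.
#'
#' @param reads character vector (or \code{DNAStringSet}) of read
#'   sequences.
#' @param refs character vector of reference sequences, recycled or
#'   matched by \code{refIndex}.
#' @param refIndex integer index of the reference for each read (default:
#'   recycled in order).
#' @return data.frame with one row per read: \code{matches},
#'   \code{mismatches}, \code{insertions}, \code{deletions}.
#' @export
alignmentCounts <- function(reads, refs, refIndex = NULL) {
    reads <- as.character(reads)
    refs <- as.character(refs)
    if (is.null(refIndex)) refIndex <- rep_len(seq_along(refs),
                                               length(reads))
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                    mismatch = -1)
    rows <- lapply(seq_along(reads), function(i) {
        al <- Biostrings::pairwiseAlignment(
            reads[i], refs[refIndex[i]], type = "global",
            substitutionMatrix = mat, gapOpening = 1, gapExtension = 1)
        p <- as.character(Biostrings::alignedPattern(al)[[1L]])
        s <- as.character(Biostrings::alignedSubject(al)[[1L]])
        pc <- strsplit(p, "")[[1L]]
        sc <- strsplit(s, "")[[1L]]
        ins <- sum(sc == "-")            # read base with no reference base
        del <- sum(pc == "-")            # reference base missing from read
        both <- pc != "-" & sc != "-"
        data.frame(matches = sum(both & pc == sc),
                   mismatches = sum(both & pc != sc),
                   insertions = ins, deletions = del)
    })
    do.call(rbind, rows)
}

#' DNA mass and copy number from qPCR concentration
#'
#' Applies the sample-quantification arithmetic: mass
#' \code{m = 100 * c * V0} (100 is the dilution factor) and copy count
#' \code{N_c = 6.022e23 * m / (310 * 650 * 1e9)} (Avogadro's number over
#' the mean molar mass of a 650 bp-equivalent double-stranded standard,
#' with m in ng).
#'
#' @param concentration measured concentration \code{c}, >= 0.
#' @param templateVolume template volume \code{V0}, >= 0.
#' @param dilution dilution factor (default 100).
#' @return one-row data.frame: \code{concentration}, \code{templateVolume},
#'   \code{dilution}, \code{mass}, \code{copies}.
#' @export
copiesFromMass <- function(concentration, templateVolume, dilution = 100) {
    stopifnot(concentration >= 0, templateVolume >= 0)
    m <- dilution * concentration * templateVolume
    nc <- 6.022e23 * m / (310 * 650 * 1e9)
    data.frame(concentration = concentration,
               templateVolume = templateVolume, dilution = dilution,
               mass = m, copies = nc)
}
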