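# unit constants used throughout; 1 barn = 1e-28 m^2 = 1e-24 cm^2 = 1e-10 nm^2
.BARN_CM2 <- 1e-24
.BARN_NM2 <- 1e-10
.NM2_BARN <- 1e10
# Julian year in seconds (365.25 d), used for all year-denominated output
.YEAR_S <- 31557600

#' Convert seconds to Julian years
#'
#' All year-denominated output of this package uses the Julian year of
#' 31,557,600 s (365.25 d).
#'
#' @param s time in seconds.
#' @return time in years.
#' @export
secondsToYears <- function(s) s / .YEAR_S

# trapezoid integral of y(x) on an ascending grid
.trapz <- function(x, y) {
    n <- length(x)
    if (n < 2L) return(0)
    sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# clip an ascending grid to [lo, hi], interpolating values at the cut points
.clipGrid <- function(x, y, lo, hi) {
    if (lo >= x[length(x)] || hi <= x[1L])
        return(list(x = numeric(0), y = numeric(0)))
    lo <- max(lo, x[1L]); hi <- min(hi, x[length(x)])
    keep <- x > lo & x < hi
    xi <- c(lo, x[keep], hi)
    yi <- c(stats::approx(x, y, xout = lo)$y, y[keep],
            stats::approx(x, y, xout = hi)$y)
    list(x = xi, y = yi)
}

# derive a reproducible child seed (< 2^31) from a base seed and a tag
.subSeed <- function(seed, tag) {
    (as.integer(seed) * 2654435L + sum(utf8ToInt(tag)) * 97L) %% 214748329L
}
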