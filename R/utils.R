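## Internal helpers shared across modules.

.gcd <- function(a, b) {
    while (b != 0L) {
        t <- b
        b <- a %% b
        a <- t
    }
    a
}

#' Nearest-rank percentile
#'
#' Deterministic percentile with no interpolation: the value at position
#' \code{ceiling(p/100 * n)} of the sorted sample. Used both for the clinical
#' similarity significance threshold and for the delete-n-out frequency
#' threshold.
#'
#' @param x numeric vector (non-empty).
#' @param p percentile in (0, 100].
#' @return a single value drawn from \code{x}.
#' @export
nearestRankPercentile <- function(x, p) {
    if (length(x) == 0L) stop("cannot take a percentile of an empty vector")
    if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 100)
        stop("p must be a single percentile in (0, 100]")
    s <- sort(x)
    k <- min(length(s), max(1L, as.integer(ceiling(p / 100 * length(s)))))
    s[[k]]
}

.assertScalarNumeric <- function(x, name, lower = -Inf, upper = Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
        stop(sprintf("%s must be a single number in [%s, %s]",
                     name, format(lower), format(upper)), call. = FALSE)
    invisible(x)
}

## Split a ";"-joined multi-value cell into a character vector (no quoting
## dialect, bit-exact round trips). Empty cells become character(0).
.splitMulti <- function(x) {
    out <- strsplit(x, ";", fixed = TRUE)
    lapply(out, function(v) v[nzchar(v)])
}

.joinMulti <- function(lst) {
    vapply(lst, function(v) paste(v, collapse = ";"), character(1L))
}
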