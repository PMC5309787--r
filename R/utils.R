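## Internal helpers shared across modules.

#' Run code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a given seed reproduces results bit-identically
#' without clobbering the session RNG.
#'
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
    if (is.null(seed)) return(code)
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("'seed' must be a single finite number")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    code
}

## extract the RPKM matrix from a SummarizedExperiment or plain matrix
.rpkm <- function(x) {
    if (methods::is(x, "SummarizedExperiment")) {
        m <- SummarizedExperiment::assay(x, "rpkm")
    } else if (is.matrix(x)) {
        m <- x
    } else {
        stop("expected a SummarizedExperiment with an 'rpkm' assay or a matrix")
    }
    if (is.null(rownames(m))) stop("expression matrix must have gene row names")
    if (is.null(colnames(m))) stop("expression matrix must have sample column names")
    m
}

.log2p1 <- function(m) log2(m + 1)

.assertCount <- function(x, name, min = 0) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
        x != round(x))
        stop(sprintf("'%s' must be a single integer >= %d", name, min))
    invisible(as.integer(x))
}

.assertFraction <- function(x, name, lo = 0, hi = 1, hiOpen = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= lo &&
        (if (hiOpen) x < hi else x <= hi)
    if (!ok)
        stop(sprintf("'%s' must be in [%g, %g%s", name, lo, hi,
                     if (hiOpen) ")" else "]"))
    invisible(as.numeric(x))
}

## spawn a stream of sub-seeds below 2^31 from a master seed
.subSeeds <- function(n) {
    sample.int(.Machine$integer.max - 1L, n)
}
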