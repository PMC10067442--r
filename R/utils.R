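# internal helpers shared across modules

#' All 384 well names in row-major order (A01 ... P24)
#' @return character vector of length 384.
#' @export
wellNames384 <- function() {
    rows <- LETTERS[1:16]
    cols <- sprintf("%02d", 1:24)
    as.vector(t(outer(rows, cols, paste0)))
}

# column number (1-24) of a well name
wellColumn <- function(well) as.integer(substr(well, 2, 3))

# lognormal meanlog/sdlog from arithmetic mean and CV
lnormPars <- function(mean, cv) {
    sdlog <- sqrt(log(1 + cv^2))
    list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rlnormMeanCv <- function(n, mean, cv) {
    if (length(mean) == 1L) {
        p <- lnormPars(mean, cv)
        stats::rlnorm(n, p$meanlog, p$sdlog)
    } else {
        sdlog <- sqrt(log(1 + cv^2))
        stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
    }
}

# stable 32-bit string hash (polynomial rolling, modulus 2^31-1), used to
# derive per-plate RNG substreams that do not depend on iteration order
stableHash <- function(s) {
    x <- utf8ToInt(s)
    h <- 0
    for (v in x) h <- (h * 31 + v) %% 2147483647
    as.integer(h)
}

# derive a child seed below 2^31 from a user seed and a string key
deriveSeed <- function(seed, key) {
    as.integer((as.numeric(seed) * 48271 + stableHash(key)) %% 2147483647)
}

checkSeed <- function(seed) {
    if (length(seed) != 1L || is.na(seed) || seed < 0 || seed != floor(seed))
        stop("seed must be a single non-negative integer")
    as.integer(seed)
}

checkCount <- function(x, name, min = 1L) {
    if (length(x) != 1L || is.na(x) || x != floor(x) || x < min)
        stop(sprintf("%s must be a single integer >= %d", name, min))
    as.integer(x)
}
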