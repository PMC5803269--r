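# internal helpers

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed)
        old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_seed)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

# Dirichlet draws via gamma normalization; n x length(alpha) matrix.
rdirichlet <- function(n, alpha) {
    k <- length(alpha)
    x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
    x / rowSums(x)
}

rowSds <- function(x) {
    n <- ncol(x)
    if (n < 2L) stop("need at least 2 columns for row standard deviations")
    m <- rowMeans(x)
    sqrt(rowSums((x - m)^2) / (n - 1L))
}

# Newton inversion of trigamma (for empirical-Bayes prior df estimation).
trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:75) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, 2L)
        y <- y + dif
        if (abs(dif) / y < 1e-10) break
    }
    y
}

stopifnot_scalar_prob <- function(p, what) {
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
        stop(what, " must be a single value in (0, 1)")
}
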