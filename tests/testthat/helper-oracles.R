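# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Upper-tail hypergeometric probability by combinatorial counting:
# number of n-subsets of an N-universe with at least k of the K specials,
# divided by C(N, n).
oraCountingOracle <- function(N, K, n, k) {
    js <- seq(from = k, to = min(K, n))
    js <- js[js >= max(0L, n - (N - K))]
    if (!length(js)) return(0)
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# The same quantity by literal enumeration of every n-subset.
oraEnumOracle <- function(N, K, n, k) {
    specials <- seq_len(K)
    subsets <- utils::combn(N, n)
    hits <- apply(subsets, 2L, function(s) sum(s %in% specials))
    mean(hits >= k)
}

# Step-by-step running-sum scan for the GSEA enrichment score: walk the
# ranked list one gene at a time, track the largest positive and negative
# deviations, report the larger in magnitude (negative on an exact tie).
bruteForceES <- function(rankedScores, inSet, weightExponent = 1) {
    N <- length(rankedScores)
    Nh <- sum(inSet)
    w <- abs(rankedScores[inSet])^weightExponent
    tot <- sum(w)
    dec <- 1 / (N - Nh)
    running <- 0
    best_pos <- 0
    best_neg <- 0
    for (i in seq_len(N)) {
        running <- running +
            (if (inSet[i]) {
                 if (tot > 0) abs(rankedScores[i])^weightExponent / tot
                 else 1 / Nh
             } else -dec)
        if (running > best_pos) best_pos <- running
        if (running < best_neg) best_neg <- running
    }
    as.numeric(if (best_pos + best_neg > 1e-10) best_pos else best_neg)
}

# Small ExprMatrix builder for fixtures.
makeExpr <- function(values, scale = "raw", genes = NULL, samples = NULL) {
    if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(values)))
    if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
    dimnames(values) <- list(genes, samples)
    ExprMatrix(values, scale = scale)
}
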