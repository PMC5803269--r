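#' @include AllClasses.R utils.R
NULL

#' Hypergeometric over-representation analysis
#'
#' For each disease set, the exact upper-tail hypergeometric probability of
#' observing at least the realized overlap between the signature and the
#' set, given the gene universe: with universe size `N`, disease set size
#' `K` (after intersection with the universe), signature size `n` and
#' overlap `k`, `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Tests
#' are one-sided (enrichment only) and reported unadjusted; results are
#' sorted by p-value.
#'
#' @param signature character vector of signature gene ids (intersected
#'   with the universe).
#' @param diseaseSets named list of character vectors.
#' @param universe character vector of all testable gene ids.
#' @return A `data.frame` with columns `set_name`, `universe_size`,
#'   `set_size`, `signature_size`, `overlap`, `p_value`.
#' @examples
#' hypergeometricORA(c("a", "b", "c"),
#'                   list(s1 = c("a", "b", "x")),
#'                   c(letters[1:10], "x"))
#' @export
hypergeometricORA <- function(signature, diseaseSets, universe) {
    universe <- unique(universe)
    if (!length(universe)) stop("empty universe")
    signature <- intersect(signature, universe)
    if (!length(signature))
        stop("signature is empty after intersection with the universe")
    if (is.null(names(diseaseSets)))
        names(diseaseSets) <- paste0("set", seq_along(diseaseSets))
    N <- length(universe)
    n <- length(signature)
    K <- vapply(diseaseSets, function(s)
        length(intersect(s, universe)), integer(1))
    k <- vapply(diseaseSets, function(s)
        length(intersect(intersect(s, universe), signature)), integer(1))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    out <- data.frame(set_name = names(diseaseSets), universe_size = N,
                      set_size = unname(K), signature_size = n,
                      overlap = unname(k), p_value = unname(p),
                      stringsAsFactors = FALSE, row.names = NULL)
    out[order(out$p_value), , drop = FALSE]
}

# Enrichment score of a pre-ranked list: weighted Kolmogorov-Smirnov
# running sum. Hits add |score|^w normalized over hit scores; misses
# subtract 1/(N - Nh). The running sum is piecewise linear between hits, so
# its extrema occur immediately after a hit (peak) or immediately before
# one (trough); ES is the extremum of largest magnitude, signed.
esFromHits <- function(scores, hitIdx, weightExponent = 1) {
    N <- length(scores)
    Nh <- length(hitIdx)
    hitIdx <- sort(hitIdx)
    w <- abs(scores[hitIdx])^weightExponent
    tot <- sum(w)
    inc <- if (tot > 0) w / tot else rep(1 / Nh, Nh)
    dec <- 1 / (N - Nh)
    cum <- cumsum(inc)
    peaks <- cum - dec * (hitIdx - seq_len(Nh))
    troughs <- c(0, cum[-Nh]) - dec * (hitIdx - seq_len(Nh))
    m_pos <- max(peaks)
    m_neg <- min(troughs, 0)
    # on a magnitude tie (to rounding) the negative extremum is reported
    if (m_pos + m_neg > 1e-10) m_pos else m_neg
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov enrichment of a gene set toward either end
#' of a score-ranked list. The running sum increments by
#' `|score|^weightExponent / sum(|hit scores|^weightExponent)` at set genes
#' and decrements by `1/(N - |S|)` elsewhere; the enrichment score (ES) is
#' the signed maximum deviation from zero. The null distribution permutes
#' gene labels (`nPerm` random sets of the same size); NES is ES divided by
#' the mean magnitude of same-sign null scores, and the permutation p-value
#' is `(1 + #same-sign nulls at least as extreme) / (#same-sign nulls + 1)`.
#' Ties in the ranking are broken by input position (stable sort).
#'
#' @param scores named numeric vector (unique gene ids); sorted internally
#'   in decreasing order.
#' @param geneSets a character vector (one set) or named list of sets.
#' @param weightExponent weighting of hit increments by score magnitude
#'   (0 = classical KS; default 1).
#' @param nPerm number of label permutations.
#' @param seed integer seed for the permutation null.
#' @return A `data.frame` with columns `set_name`, `es`, `nes`, `perm_p`,
#'   `n_perm`, `set_size`.
#' @export
prerankedGSEA <- function(scores, geneSets, weightExponent = 1,
                          nPerm = 1000L, seed = 1L) {
    if (is.null(names(scores)) || anyDuplicated(names(scores)))
        stop("scores must be uniquely named by gene")
    ord <- order(scores, decreasing = TRUE)   # stable: ties keep input order
    ranked <- scores[ord]
    genes <- names(ranked)
    N <- length(genes)
    if (is.character(geneSets)) geneSets <- list(set = geneSets)
    if (is.null(names(geneSets)))
        names(geneSets) <- paste0("set", seq_along(geneSets))
    rows <- lapply(names(geneSets), function(nm) {
        hit <- which(genes %in% geneSets[[nm]])
        Nh <- length(hit)
        if (Nh == 0L || Nh == N)
            stop("gene set '", nm, "' is disjoint from or equal to the ",
                 "ranked list")
        es <- esFromHits(ranked, hit, weightExponent)
        null_es <- withSeed(seed, vapply(seq_len(nPerm), function(i)
            esFromHits(ranked, sample.int(N, Nh), weightExponent),
            numeric(1)))
        same <- null_es[sign(null_es) == sign(es)]
        nes <- if (length(same)) es / mean(abs(same)) else NA_real_
        perm_p <- (1 + sum(abs(same) >= abs(es))) / (length(same) + 1)
        data.frame(set_name = nm, es = es, nes = nes, perm_p = perm_p,
                   n_perm = nPerm, set_size = Nh, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
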