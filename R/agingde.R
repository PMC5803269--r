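#' @include AllClasses.R AllGenerics.R ExprMatrix-methods.R signature.R
#' @importFrom limma normalizeQuantiles
NULL

#' Harmonize two microglia expression datasets
#'
#' Restricts both datasets to the genes reliably detected in each — value at
#' or above `detectThreshold` in at least `minDetectedFraction` of samples
#' of *both* datasets (detection is assessed on the scale the matrices come
#' in; the default 0.1 suits raw FPKM) — then log-transforms raw inputs and
#' optionally quantile-aligns all samples of the combined matrix so that
#' the two datasets share a common value distribution (different isolation
#' and library protocols otherwise shift them).
#'
#' @param a,b [ExprMatrix-class] objects on the same scale (raw or log2);
#'   `a` is the aged dataset, `b` the reference.
#' @param detectThreshold detection threshold.
#' @param minDetectedFraction minimum fraction of samples detected.
#' @param quantileAlign quantile-normalize the combined matrix (default
#'   TRUE).
#' @param pseudocount log2 pseudocount applied to raw inputs.
#' @return A [HarmonizedPair-class] of log2-scale matrices on the common
#'   gene universe.
#' @export
harmonizePair <- function(a, b, detectThreshold = 0.1,
                          minDetectedFraction = 0.5, quantileAlign = TRUE,
                          pseudocount = 1) {
    if (!identical(exprScale(a), exprScale(b)))
        stop("both datasets must be on the same scale")
    common <- intersect(geneIds(a), geneIds(b))
    if (!length(common)) stop("empty gene intersection")
    det <- function(m) {
        v <- exprValues(m)[common, , drop = FALSE]
        rowMeans(v >= detectThreshold) >= minDetectedFraction
    }
    keep <- common[det(a) & det(b)]
    if (!length(keep)) stop("no genes reliably detected in both datasets")
    a <- a[keep, ]
    b <- b[keep, ]
    if (identical(exprScale(a), "raw")) {
        a <- logTransform(a, pseudocount)
        b <- logTransform(b, pseudocount)
    }
    if (quantileAlign) {
        comb <- combineSamples(a, b)
        qn <- limma::normalizeQuantiles(exprValues(comb))
        a <- .newScale(a, qn[, sampleIds(a), drop = FALSE], "log2")
        b <- .newScale(b, qn[, sampleIds(b), drop = FALSE], "log2")
    }
    new("HarmonizedPair", a = a, b = b,
        params = list(detectThreshold = detectThreshold,
                      minDetectedFraction = minDetectedFraction,
                      quantileAlign = quantileAlign,
                      pseudocount = pseudocount))
}

#' Aging differential expression between two microglia datasets
#'
#' Moderated-t inference (see [moderatedT()]) of aged minus reference per
#' gene, BH adjustment, and classification: `up` when
#' `log2_fc > logfcThreshold` and `adj_p < alpha` (strict inequalities),
#' `down` symmetrically, `ns` otherwise. Swapping the datasets negates
#' every fold change and exchanges the up/down classes exactly.
#'
#' @param pair a [HarmonizedPair-class] (aged = `a`, reference = `b`).
#' @param logfcThreshold absolute log2 fold-change cutoff (default 2).
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @return A `data.frame` with per-gene `gene`, `log2_fc`, `mod_t`,
#'   `p_value`, `adj_p`, `class`, with the class counts as attribute
#'   `"counts"`.
#' @export
differentialExpression <- function(pair, logfcThreshold = 2, alpha = 0.05) {
    stopifnot(is(pair, "HarmonizedPair"))
    mod <- moderatedT(pair@a, pair@b)
    adj <- bhAdjust(mod$p_value)
    cls <- rep("ns", nrow(mod))
    cls[mod$log2_fc > logfcThreshold & adj < alpha] <- "up"
    cls[mod$log2_fc < -logfcThreshold & adj < alpha] <- "down"
    out <- data.frame(gene = mod$gene, log2_fc = mod$log2_fc,
                      mod_t = mod$mod_t, p_value = mod$p_value,
                      adj_p = adj, class = cls, stringsAsFactors = FALSE)
    attr(out, "counts") <- c(up = sum(cls == "up"),
                             down = sum(cls == "down"),
                             ns = sum(cls == "ns"))
    out
}
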