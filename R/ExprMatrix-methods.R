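#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn ExprMatrix-class the genes x samples numeric matrix.
#' @param x an `ExprMatrix`.
#' @export
setMethod("exprValues", "ExprMatrix", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' @describeIn ExprMatrix-class the scale tag (`"raw"`, `"log2"`,
#'   `"normalized"`).
#' @export
setMethod("exprScale", "ExprMatrix", function(x) metadata(x)$scale)

#' @describeIn ExprMatrix-class gene identifiers (row names).
#' @export
setMethod("geneIds", "ExprMatrix", function(x) rownames(x))

#' @describeIn ExprMatrix-class sample identifiers (column names).
#' @export
setMethod("sampleIds", "ExprMatrix", function(x) colnames(x))

setMethod("show", "ExprMatrix", function(object) {
    cat(sprintf("ExprMatrix: %d genes x %d samples [scale: %s]\n",
                nrow(object), ncol(object), exprScale(object)))
    callNextMethod()
})

.newScale <- function(x, values, scale) {
    out <- x
    SummarizedExperiment::assay(out, "exprs", withDimnames = FALSE) <- values
    metadata(out)$scale <- scale
    validObject(out)
    out
}

#' Filter lowly expressed genes
#'
#' Drops genes whose raw abundance falls below `threshold` in more than
#' `maxLowSamples` samples; a gene is retained exactly when the number of
#' samples with value `< threshold` is at most `maxLowSamples`. Gene order
#' and the sample set are preserved; the operation is idempotent. The
#' default (abundance below 0.1 in more than two samples) is the study's
#' FPKM quality filter, counting absolute sample numbers.
#'
#' @param x a raw-scale [ExprMatrix-class].
#' @param threshold abundance below which a sample counts as "low".
#' @param maxLowSamples maximum tolerated number of low samples per gene.
#' @return An `ExprMatrix` restricted to the retained genes (possibly zero
#'   genes; never an error for all-low input).
#' @export
setMethod("filterLowExpression", "ExprMatrix",
    function(x, threshold = 0.1, maxLowSamples = 2) {
        if (!identical(exprScale(x), "raw"))
            stop("filterLowExpression requires a raw-scale matrix, got '",
                 exprScale(x), "'")
        v <- exprValues(x)
        keep <- rowSums(v < threshold) <= maxLowSamples
        x[keep, ]
    })

#' Log2 transformation with pseudocount
#'
#' Maps raw abundances `v` to `log2(v + pseudocount)`.
#'
#' @param x a raw-scale [ExprMatrix-class] (nonnegative values).
#' @param pseudocount added before taking logs; default 1 so zeros map to 0.
#' @return A log2-scale `ExprMatrix`.
#' @export
setMethod("logTransform", "ExprMatrix", function(x, pseudocount = 1) {
    if (!identical(exprScale(x), "raw"))
        stop("logTransform requires a raw-scale matrix")
    v <- exprValues(x)
    if (any(v < 0, na.rm = TRUE))
        stop("negative values cannot be log transformed")
    .newScale(x, log2(v + pseudocount), "log2")
})

#' Restrict to genes with a protein identifier
#'
#' Keeps only genes flagged `has_uniprot = TRUE` in the annotation, in their
#' original order. Genes missing from the annotation are excluded
#' (conservative treatment of unannotated genes).
#'
#' @param x an [ExprMatrix-class].
#' @param annotation gene annotation `data.frame` with columns `gene_id` and
#'   `has_uniprot`.
#' @return The restricted `ExprMatrix` (possibly zero genes).
#' @export
setMethod("uniprotFilter", "ExprMatrix", function(x, annotation) {
    annotation <- as.data.frame(annotation)
    flag <- annotation$has_uniprot[match(geneIds(x), annotation$gene_id)]
    flag[is.na(flag)] <- FALSE
    x[as.logical(flag), ]
})

#' Mean-variance precision weights
#'
#' Simplified variance-stabilizing weighting for log-scale abundance data:
#' a lowess trend of the residual scale (square root of the per-gene
#' standard deviation) against the per-gene mean log expression is fitted,
#' and each observation receives weight equal to the inverse fourth power of
#' the trend's prediction at its gene's mean — i.e. the reciprocal of the
#' predicted variance. With an intercept-only gene model the fitted mean is
#' the gene's row mean, so weights are constant within a gene.
#'
#' @param x a log2-scale [ExprMatrix-class] with at least 3 samples.
#' @param span lowess smoother span.
#' @return A genes x samples matrix of strictly positive weights, with the
#'   fitted trend attached as attribute `"trend"` (data.frame `mean`,
#'   `sqrt_sd`, `weight` on the lowess grid).
#' @export
setMethod("meanVarianceWeights", "ExprMatrix", function(x, span = 0.5) {
    if (!exprScale(x) %in% c("log2", "normalized"))
        stop("meanVarianceWeights requires a log-scale matrix")
    v <- exprValues(x)
    if (ncol(v) < 3L)
        stop("mean-variance trend needs at least 3 samples")
    gm <- rowMeans(v)
    gs <- sqrt(rowSds(v))                      # quarter-root variance scale
    lo <- stats::lowess(gm, gs, f = span)
    pred <- stats::approx(lo$x, lo$y, xout = gm, rule = 2, ties = mean)$y
    floor_val <- 1e-6
    pred <- pmax(pred, floor_val)
    w <- matrix(pred^(-4), nrow = nrow(v), ncol = ncol(v),
                dimnames = dimnames(v))
    attr(w, "trend") <- data.frame(mean = lo$x, sqrt_sd = pmax(lo$y, floor_val),
                                   weight = pmax(lo$y, floor_val)^(-4))
    w
})

#' Combine two expression matrices on their shared genes
#'
#' Intersects gene universes (keeping the first matrix's order) and binds
#' samples; both inputs must share the same scale. Sample ids must not
#' collide.
#'
#' @param a,b [ExprMatrix-class] objects on the same scale.
#' @return A single `ExprMatrix` whose samples are `c(samples(a),
#'   samples(b))`, with attribute-free assay values.
#' @export
combineSamples <- function(a, b) {
    if (!identical(exprScale(a), exprScale(b)))
        stop("cannot combine matrices on different scales")
    common <- intersect(geneIds(a), geneIds(b))
    if (!length(common))
        stop("empty gene intersection")
    if (length(intersect(sampleIds(a), sampleIds(b))))
        stop("sample ids collide between the two matrices")
    va <- exprValues(a)[common, , drop = FALSE]
    vb <- exprValues(b)[common, , drop = FALSE]
    ExprMatrix(cbind(va, vb), scale = exprScale(a))
}
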