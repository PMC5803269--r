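#' @include AllClasses.R AllGenerics.R utils.R ExprMatrix-methods.R
#' @importFrom MASS rlm psi.huber
NULL

#' Robust removal of residual GC-content and gene-length artifacts
#'
#' For each sample the log ratio against the grand mean,
#' `r[g, s] = x[g, s] - mean_s'(x[g, s'])`, is regressed on GC fraction and
#' log10 gene length with a Huber M-estimator (tuning constant 1.345, IRLS,
#' up to 50 iterations), and the fitted artifact component — intercept plus
#' covariate terms — is subtracted from the sample. Genes whose deviation is
#' not explained by the covariates (e.g. true cell-type markers) are
#' residuals of the fit and are preserved; the robust loss keeps them from
#' leveraging the slopes. When contrasting two datasets, normalize their
#' combined matrix (see [residualNormalizePair()]) so that dataset-specific
#' artifacts are removed relative to the common grand mean.
#'
#' @param x a log2-scale [ExprMatrix-class].
#' @param annotation gene annotation with `gene_id`, `gc_fraction`,
#'   `length_bp`; must cover all genes of `x`.
#' @param minGenes refuse to fit with fewer genes than this (default 10).
#' @return A list with `matrix` (a `"normalized"`-scale `ExprMatrix`) and
#'   `fit` (a [NormalizationFit-class] of per-sample coefficients).
#' @export
setMethod("residualNormalize", "ExprMatrix",
    function(x, annotation, minGenes = 10L) {
        if (!exprScale(x) %in% c("log2", "normalized"))
            stop("residualNormalize requires a log2-scale matrix")
        v <- exprValues(x)
        if (nrow(v) < minGenes)
            stop("refusing to fit artifact model on fewer than ", minGenes,
                 " genes")
        annotation <- as.data.frame(annotation)
        idx <- match(rownames(v), annotation$gene_id)
        if (anyNA(idx))
            stop("annotation missing for genes: ",
                 paste(utils::head(rownames(v)[is.na(idx)], 5L),
                       collapse = ", "))
        gc <- annotation$gc_fraction[idx]
        ll <- log10(annotation$length_bp[idx])
        X <- cbind(intercept = 1, gc = gc, log10_length = ll)
        grand <- rowMeans(v)
        r <- v - grand
        coefs <- matrix(NA_real_, nrow = ncol(v), ncol = 3L,
                        dimnames = list(colnames(v),
                                        c("intercept", "gc", "log10_length")))
        conv <- logical(ncol(v))
        out <- v
        for (s in seq_len(ncol(v))) {
            fit <- MASS::rlm(X, r[, s], psi = MASS::psi.huber, k = 1.345,
                             maxit = 50, acc = 1e-8)
            coefs[s, ] <- stats::coef(fit)
            conv[s] <- fit$converged
            out[, s] <- v[, s] - drop(X %*% stats::coef(fit))
        }
        list(matrix = .newScale(x, out, "normalized"),
             fit = new("NormalizationFit", coefficients = coefs,
                       converged = conv))
    })

#' @rdname residualNormalize-ExprMatrix-method
#' @param purified,bulk log2-scale [ExprMatrix-class] objects on a shared
#'   gene universe (intersected internally).
#' @param annotation gene annotation covering the shared genes.
#' @param minGenes see above.
#' @return `residualNormalizePair` returns a list with normalized
#'   `purified` and `bulk` matrices and the joint `fit`.
#' @export
residualNormalizePair <- function(purified, bulk, annotation,
                                  minGenes = 10L) {
    combined <- combineSamples(purified, bulk)
    res <- residualNormalize(combined, annotation, minGenes = minGenes)
    norm <- res$matrix
    list(purified = norm[, sampleIds(purified)],
         bulk = norm[, sampleIds(bulk)],
         fit = res$fit)
}

#' Purified-vs-bulk fold-change contrast
#'
#' Per gene, the mean over purified samples minus the mean over bulk
#' samples, on the shared gene universe (intersected, purified order kept).
#' Both matrices must be on a log scale.
#'
#' @param purified,bulk log-scale [ExprMatrix-class] objects.
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
foldChangeContrast <- function(purified, bulk) {
    if (!exprScale(purified) %in% c("log2", "normalized") ||
        !exprScale(bulk) %in% c("log2", "normalized"))
        stop("foldChangeContrast requires log-scale matrices")
    common <- intersect(geneIds(purified), geneIds(bulk))
    if (!length(common))
        stop("empty gene intersection between purified and bulk")
    rowMeans(exprValues(purified)[common, , drop = FALSE]) -
        rowMeans(exprValues(bulk)[common, , drop = FALSE])
}

# Empirical-Bayes squeeze of per-gene sample variances toward a prior,
# s2_post = (d0*s02 + d*s2) / (d0 + d).
shrinkVariance <- function(s2, df, priorDf, priorVar) {
    if (is.infinite(priorDf)) return(rep(priorVar, length(s2)))
    if (priorDf == 0) return(s2)
    (priorDf * priorVar + df * s2) / (priorDf + df)
}

# Method-of-moments fit of the scaled-F prior of per-gene variances from
# the distribution of log s2: var(log s2) = trigamma(d/2) + trigamma(d0/2)
# and E(log s2) = log s02 + digamma(d/2) - log(d/2) - digamma(d0/2) +
# log(d0/2).
estimateVariancePrior <- function(s2, df) {
    ok <- is.finite(s2) & s2 > 1e-15
    if (sum(ok) < 2L)
        stop("too few positive variances to estimate the prior")
    z <- log(s2[ok])
    e <- z - digamma(df / 2) + log(df / 2)
    rhs <- stats::var(z) - trigamma(df / 2)
    if (rhs <= 0) {
        priorDf <- Inf
        priorVar <- exp(mean(e))
    } else {
        priorDf <- 2 * trigammaInverse(rhs)
        priorVar <- exp(mean(e) + digamma(priorDf / 2) - log(priorDf / 2))
    }
    list(priorDf = priorDf, priorVar = priorVar)
}

#' Moderated two-group t statistics
#'
#' Per gene, a two-group (optionally precision-weighted) mean difference
#' with pooled variance `s2` on `d = n1 + n2 - 2` residual degrees of
#' freedom. Variances are shrunk toward an empirical-Bayes prior,
#' `s2_post = (d0*s02 + d*s2) / (d0 + d)`, with `(d0, s02)` estimated from
#' the distribution of `log s2` by the method of moments (digamma/trigamma
#' matching). The statistic is `t = diff / (s_post * sqrt(1/n1 + 1/n2))`
#' with `d + d0` total degrees of freedom. Genes with zero variance in both
#' groups get `p = 1` when the difference is also zero, otherwise inference
#' proceeds through the shrunk (strictly positive) variance.
#'
#' @param a,b log-scale [ExprMatrix-class] objects or plain numeric
#'   matrices; genes are intersected in `a`'s order. The difference is
#'   `mean(a) - mean(b)`.
#' @param weights optional list with genes x samples precision-weight
#'   matrices `a` and `b` (e.g. from [meanVarianceWeights()]).
#' @param priorDf,priorVar optional override of the estimated prior;
#'   `priorDf = 0` gives the ordinary pooled two-sample t statistic.
#' @return A `data.frame` with columns `gene`, `log2_fc`, `mod_t`,
#'   `p_value`, `df_total`, plus attributes `priorDf` and `priorVar`.
#' @export
moderatedT <- function(a, b, weights = NULL, priorDf = NULL,
                       priorVar = NULL) {
    va <- if (is(a, "ExprMatrix")) exprValues(a) else as.matrix(a)
    vb <- if (is(b, "ExprMatrix")) exprValues(b) else as.matrix(b)
    common <- intersect(rownames(va), rownames(vb))
    if (!length(common)) stop("empty gene intersection")
    va <- va[common, , drop = FALSE]
    vb <- vb[common, , drop = FALSE]
    n1 <- ncol(va); n2 <- ncol(vb)
    if (n1 < 2L || n2 < 2L)
        stop("need at least 2 samples per group")
    if (is.null(weights)) {
        wa <- matrix(1, nrow(va), n1)
        wb <- matrix(1, nrow(vb), n2)
    } else {
        wa <- weights$a[common, , drop = FALSE]
        wb <- weights$b[common, , drop = FALSE]
        if (any(wa <= 0) || any(wb <= 0))
            stop("precision weights must be strictly positive")
    }
    swa <- rowSums(wa); swb <- rowSums(wb)
    ma <- rowSums(wa * va) / swa
    mb <- rowSums(wb * vb) / swb
    d <- n1 + n2 - 2L
    ss <- rowSums(wa * (va - ma)^2) + rowSums(wb * (vb - mb)^2)
    s2 <- ss / d
    if (is.null(priorDf)) {
        pri <- estimateVariancePrior(s2, d)
        priorDf <- pri$priorDf
        if (is.null(priorVar)) priorVar <- pri$priorVar
    } else if (is.null(priorVar)) {
        priorVar <- estimateVariancePrior(s2, d)$priorVar
    }
    s2post <- shrinkVariance(s2, d, priorDf, priorVar)
    se <- sqrt(s2post * (1 / swa + 1 / swb))
    diff <- ma - mb
    tt <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
    df_total <- d + priorDf
    p <- 2 * stats::pt(-abs(tt), df = df_total)
    p[se == 0 & diff == 0] <- 1
    out <- data.frame(gene = common, log2_fc = diff, mod_t = tt,
                      p_value = p, df_total = df_total,
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "priorDf") <- priorDf
    attr(out, "priorVar") <- priorVar
    out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone in sorted order, capped at 1),
#' permutation-equivariant in its input.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
    if (!is.numeric(p)) stop("p must be numeric")
    bad <- !is.na(p) & (p < 0 | p > 1)
    if (any(bad))
        stop("p-values outside [0, 1] at positions: ",
             paste(utils::head(which(bad), 5L), collapse = ", "))
    stats::p.adjust(p, method = "BH")
}

#' Assemble a signature from contrast and moderated-t results
#'
#' The FC set contains genes with `log2_fc >= log2(fcThreshold)` (one-sided,
#' purified > bulk, boundary inclusive); the PVAL set additionally requires
#' BH-adjusted `p < alpha`.
#'
#' @param log2fc named per-gene log2 fold changes
#'   (see [foldChangeContrast()]).
#' @param modResults optional `data.frame` from [moderatedT()]; without it
#'   the PVAL set is undefined (all `NA`).
#' @param fcThreshold linear fold-change cutoff (default 4).
#' @param alpha adjusted-significance cutoff (default 0.05).
#' @return A [SignatureResult-class].
#' @export
deriveSignature <- function(log2fc, modResults = NULL, fcThreshold = 4,
                            alpha = 0.05) {
    genes <- names(log2fc)
    if (is.null(genes)) stop("log2fc must be named by gene")
    tab <- data.frame(gene = genes, log2_fc = as.numeric(log2fc),
                      mod_t = NA_real_, p_value = NA_real_,
                      adj_p = NA_real_, stringsAsFactors = FALSE,
                      row.names = NULL)
    if (!is.null(modResults)) {
        m <- match(genes, modResults$gene)
        if (anyNA(m))
            stop("moderated-t results missing for some contrast genes")
        tab$mod_t <- modResults$mod_t[m]
        tab$p_value <- modResults$p_value[m]
        tab$adj_p <- bhAdjust(tab$p_value)
    }
    tab$in_fc_set <- tab$log2_fc >= log2(fcThreshold)
    tab$in_pval_set <- if (is.null(modResults)) NA else
        tab$in_fc_set & !is.na(tab$adj_p) & tab$adj_p < alpha
    new("SignatureResult", table = tab, fcThreshold = fcThreshold,
        alpha = alpha)
}

#' @describeIn SignatureResult-class the full per-gene table.
#' @param object a `SignatureResult`.
#' @export
setMethod("signatureTable", "SignatureResult", function(object) object@table)

#' @describeIn SignatureResult-class gene ids of the fold-change set.
#' @export
setMethod("fcSet", "SignatureResult", function(object)
    object@table$gene[object@table$in_fc_set])

#' @describeIn SignatureResult-class gene ids of the fold-change +
#'   significance set.
#' @export
setMethod("pvalSet", "SignatureResult", function(object)
    object@table$gene[object@table$in_pval_set %in% TRUE])

setMethod("show", "SignatureResult", function(object) {
    tab <- object@table
    cat(sprintf("SignatureResult: %d genes tested\n", nrow(tab)))
    cat(sprintf("  FC set (fold change >= %g, purified > bulk): %d genes\n",
                object@fcThreshold, sum(tab$in_fc_set, na.rm = TRUE)))
    if (!all(is.na(tab$in_pval_set)))
        cat(sprintf("  PVAL set (+ BH adj p < %g): %d genes\n",
                    object@alpha, sum(tab$in_pval_set, na.rm = TRUE)))
})

#' Full purified-vs-bulk signature derivation
#'
#' Convenience wrapper running the whole derivation on raw matrices:
#' low-expression filtering in each dataset, log2 transform, restriction to
#' protein-identifier genes, joint robust GC/length artifact normalization,
#' fold-change contrast, moderated-t inference and set construction.
#'
#' @param purifiedRaw,bulkRaw raw-scale [ExprMatrix-class] objects.
#' @param annotation gene annotation `data.frame`.
#' @param fcThreshold,alpha signature cutoffs.
#' @param fpkmThreshold,maxLowSamples low-expression filter parameters
#'   (applied per dataset).
#' @param pseudocount log2 pseudocount.
#' @return A list with the [SignatureResult-class] (`signature`), the joint
#'   [NormalizationFit-class] (`fit`) and the normalized `purified` and
#'   `bulk` matrices.
#' @export
deriveMicrogliaSignature <- function(purifiedRaw, bulkRaw, annotation,
                                     fcThreshold = 4, alpha = 0.05,
                                     fpkmThreshold = 0.1, maxLowSamples = 2,
                                     pseudocount = 1) {
    p <- filterLowExpression(purifiedRaw, fpkmThreshold, maxLowSamples)
    b <- filterLowExpression(bulkRaw, fpkmThreshold, maxLowSamples)
    p <- logTransform(p, pseudocount)
    b <- logTransform(b, pseudocount)
    p <- uniprotFilter(p, annotation)
    b <- uniprotFilter(b, annotation)
    norm <- residualNormalizePair(p, b, annotation)
    fc <- foldChangeContrast(norm$purified, norm$bulk)
    mod <- moderatedT(norm$purified, norm$bulk)
    sig <- deriveSignature(fc, mod, fcThreshold = fcThreshold, alpha = alpha)
    list(signature = sig, fit = norm$fit, purified = norm$purified,
         bulk = norm$bulk)
}
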