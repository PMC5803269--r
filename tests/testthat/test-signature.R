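ann_for <- function(genes, gc, len) {
    data.frame(gene_id = genes, symbol = genes, gc_fraction = gc,
               length_bp = len, has_uniprot = TRUE,
               stringsAsFactors = FALSE)
}

test_that("artifact normalization is a no-op without a planted artifact", {
    set.seed(1)
    G <- 400
    genes <- sprintf("g%04d", 1:G)
    gc <- runif(G, 0.3, 0.7)
    len <- 10^runif(G, log10(500), 5)
    base <- rnorm(G, 5, 2)
    x <- cbind(s1 = base, s2 = base, s3 = base, s4 = base)
    rownames(x) <- genes
    res <- residualNormalize(ExprMatrix(x, scale = "log2"),
                             ann_for(genes, gc, len))
    expect_lt(max(abs(res$fit@coefficients)), 1e-8)
    expect_lt(max(abs(exprValues(res$matrix) - x)), 1e-8)
})

test_that("a planted per-sample GC slope is recovered exactly without noise", {
    set.seed(2)
    G <- 500
    genes <- sprintf("g%04d", 1:G)
    gc <- runif(G, 0.3, 0.7)
    len <- 10^runif(G, log10(500), 5)
    gcc <- gc - mean(gc)
    base <- rnorm(G, 5, 2)
    x <- cbind(s1 = base + 2 * gcc, s2 = base - 2 * gcc,
               s3 = base, s4 = base)
    rownames(x) <- genes
    # exactly linear residuals make the IRLS convergence test vacuous;
    # the reported coefficients are still exact
    res <- suppressWarnings(
        residualNormalize(ExprMatrix(x, scale = "log2"),
                          ann_for(genes, gc, len)))
    expect_equal(unname(res$fit@coefficients["s1", "gc"]), 2,
                 tolerance = 1e-6)
    expect_equal(unname(res$fit@coefficients["s2", "gc"]), -2,
                 tolerance = 1e-6)
})

test_that("the robust fit resists gross outliers where least squares drifts", {
    set.seed(3)
    G <- 2000
    genes <- sprintf("g%04d", 1:G)
    gc <- runif(G, 0.3, 0.7)
    len <- 10^runif(G, log10(500), 5)
    gcc <- gc - mean(gc)
    llc <- log10(len) - mean(log10(len))
    base <- rnorm(G, 5, 2)
    noise <- matrix(rnorm(G * 4, 0, 0.3), G, 4)
    x <- cbind(s1 = base + 2 * gcc, s2 = base - 2 * gcc,
               s3 = base, s4 = base) + noise
    out_idx <- sample.int(G, G * 0.10)
    x[out_idx, "s1"] <- x[out_idx, "s1"] + 8   # one-sided gross offsets
    rownames(x) <- genes
    res <- residualNormalize(ExprMatrix(x, scale = "log2"),
                             ann_for(genes, gc, len))
    robust_slope <- unname(res$fit@coefficients["s1", "gc"])
    expect_lt(abs(robust_slope - 2) / 2, 0.05)
    r1 <- x[, "s1"] - rowMeans(x)
    ols_slope <- unname(coef(lm(r1 ~ gcc + llc))[2])
    expect_gt(abs(ols_slope - 2), abs(robust_slope - 2))
})

test_that("the purified-vs-bulk contrast is invariant to dataset-wide GC/length shifts", {
    set.seed(4)
    G <- 300
    genes <- sprintf("g%04d", 1:G)
    gc <- runif(G, 0.3, 0.7)
    len <- 10^runif(G, log10(500), 5)
    ann <- ann_for(genes, gc, len)
    base <- rnorm(G, 5, 2)
    pur <- matrix(base, G, 4, dimnames = list(genes, paste0("p", 1:4)))
    pur[1:20, ] <- pur[1:20, ] + 3              # true signal
    blk <- matrix(base, G, 6, dimnames = list(genes, paste0("b", 1:6)))
    mk <- function(m) ExprMatrix(m, scale = "log2")

    fc_clean <- foldChangeContrast(
        residualNormalizePair(mk(pur), mk(blk), ann)$purified,
        residualNormalizePair(mk(pur), mk(blk), ann)$bulk)
    shift <- 1.7 * gc + 0.8 * log10(len) + 0.5
    blk_shift <- blk + shift
    norm2 <- residualNormalizePair(mk(pur), mk(blk_shift), ann)
    fc_shift <- foldChangeContrast(norm2$purified, norm2$bulk)
    expect_equal(fc_shift, fc_clean, tolerance = 1e-6)
})

test_that("normalization refuses unstable fits and incomplete annotation", {
    x <- matrix(rnorm(8), 4, 2,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:2)))
    ann <- ann_for(paste0("g", 1:4), runif(4, .3, .7), rep(1000, 4))
    expect_error(residualNormalize(ExprMatrix(x, scale = "log2"), ann),
                 "fewer than 10")
    x2 <- matrix(rnorm(30), 15, 2,
                 dimnames = list(paste0("g", 1:15), paste0("s", 1:2)))
    ann2 <- ann_for(paste0("g", 1:10), runif(10, .3, .7), rep(1000, 10))
    expect_error(residualNormalize(ExprMatrix(x2, scale = "log2"), ann2),
                 "annotation missing")
})

test_that("fold-change contrast is mean difference on the shared universe", {
    pur <- makeExpr(matrix(5, 3, 4), scale = "log2")
    blk <- makeExpr(matrix(2, 3, 6), scale = "log2")
    fc <- foldChangeContrast(pur, blk)
    expect_true(all(fc == 3))                   # fold change 8
    expect_true(all(foldChangeContrast(pur, pur) == 0))
    blk2 <- makeExpr(matrix(1, 2, 2), genes = c("x1", "x2"),
                     scale = "log2")
    expect_error(foldChangeContrast(pur, blk2), "empty gene intersection")
})

test_that("moderated t with a vanishing prior is the ordinary pooled t", {
    set.seed(5)
    a <- matrix(rnorm(50 * 4, 5), 50, 4,
                dimnames = list(sprintf("g%02d", 1:50), paste0("a", 1:4)))
    b <- matrix(rnorm(50 * 6, 4.5), 50, 6,
                dimnames = list(sprintf("g%02d", 1:50), paste0("b", 1:6)))
    mt <- moderatedT(a, b, priorDf = 0)
    # independent pooled-t oracle
    for (g in c(1, 17, 50)) {
        n1 <- 4; n2 <- 6
        sp2 <- ((n1 - 1) * var(a[g, ]) + (n2 - 1) * var(b[g, ])) /
            (n1 + n2 - 2)
        tt <- (mean(a[g, ]) - mean(b[g, ])) /
            sqrt(sp2 * (1 / n1 + 1 / n2))
        expect_equal(mt$mod_t[g], tt, tolerance = 1e-9)
        expect_equal(mt$p_value[g],
                     2 * pt(-abs(tt), n1 + n2 - 2), tolerance = 1e-9)
    }
})

test_that("variance shrinkage follows the squeeze formula", {
    expect_equal(humiSig:::shrinkVariance(4, 4, 4, 1), 2.5)
    expect_equal(humiSig:::shrinkVariance(4, 4, 0, 1), 4)   # no shrinkage
    expect_equal(humiSig:::shrinkVariance(4, 4, Inf, 1), 1) # full shrinkage
})

test_that("moderated-t p-values are uniform under the null", {
    set.seed(6)
    G <- 2000
    a <- matrix(rnorm(G * 5), G, 5,
                dimnames = list(sprintf("g%04d", 1:G), paste0("a", 1:5)))
    b <- matrix(rnorm(G * 5), G, 5,
                dimnames = list(sprintf("g%04d", 1:G), paste0("b", 1:5)))
    mt <- moderatedT(a, b)
    ks <- suppressWarnings(ks.test(mt$p_value, "punif"))
    expect_lt(unname(ks$statistic), 0.05)
})

test_that("zero-variance genes are handled without spurious infinities", {
    a <- matrix(c(rep(3, 4), rep(1, 4), rnorm(40 * 4, 2)), 42, 4,
                byrow = TRUE,
                dimnames = list(sprintf("g%02d", 1:42), paste0("a", 1:4)))
    b <- matrix(c(rep(3, 4), rep(5, 4), rnorm(40 * 4, 2)), 42, 4,
                byrow = TRUE,
                dimnames = list(sprintf("g%02d", 1:42), paste0("b", 1:4)))
    set.seed(7)
    a[3:42, ] <- rnorm(40 * 4, 2)
    b[3:42, ] <- rnorm(40 * 4, 2)
    mt <- moderatedT(a, b)
    expect_equal(mt$p_value[1], 1)              # no difference, no variance
    expect_equal(mt$mod_t[1], 0)
    expect_true(is.finite(mt$mod_t[2]))         # shrunk variance rescues it
    expect_lt(mt$p_value[2], 0.05)
})

test_that("moderated t agrees with an established empirical-Bayes implementation", {
    set.seed(8)
    G <- 500
    a <- matrix(rnorm(G * 4, 0, rep(sqrt(rchisq(G, 5) / 5), 4)), G, 4,
                dimnames = list(sprintf("g%03d", 1:G), paste0("a", 1:4)))
    b <- matrix(rnorm(G * 4, 0, rep(sqrt(rchisq(G, 5) / 5), 4)), G, 4,
                dimnames = list(sprintf("g%03d", 1:G), paste0("b", 1:4)))
    b[1:50, ] <- b[1:50, ] + 2
    mt <- moderatedT(a, b)
    design <- cbind(1, rep(c(1, 0), each = 4))
    fit <- limma::eBayes(limma::lmFit(cbind(a, b), design))
    expect_gt(cor(mt$mod_t, fit$t[, 2]), 0.999)
    expect_equal(attr(mt, "priorDf"), fit$df.prior, tolerance = 0.1)
})

test_that("BH adjustment matches the step-up formula on hand cases", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.3), 0.3)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.5, 1.2)), "outside")
    # permutation equivariance
    p <- c(0.4, 0.01, 0.9, 0.02, 0.6)
    perm <- c(3, 1, 5, 2, 4)
    expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
    # adjusted >= raw, in [0, 1]
    expect_true(all(bhAdjust(p) >= p))
})

test_that("signature sets apply boundary-inclusive FC and nested PVAL rules", {
    fc <- c(g1 = 2.0, g2 = 1.99, g3 = 5, g4 = -3, g5 = 2.5)
    mod <- data.frame(gene = names(fc), mod_t = c(5, 5, 10, -8, 0.1),
                      p_value = c(1e-4, 1e-4, 1e-8, 1e-6, 0.8))
    sig <- deriveSignature(fc, mod, fcThreshold = 4, alpha = 0.05)
    expect_setequal(fcSet(sig), c("g1", "g3", "g5"))   # 2.0 included
    expect_true(all(pvalSet(sig) %in% fcSet(sig)))
    expect_setequal(pvalSet(sig), c("g1", "g3"))       # g5 not significant
    tab <- signatureTable(sig)
    expect_true(all(tab$adj_p >= tab$p_value))
    # without inference the PVAL set is undefined
    sig2 <- deriveSignature(fc)
    expect_true(all(is.na(signatureTable(sig2)$in_pval_set)))
    expect_length(pvalSet(sig2), 0L)
})
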