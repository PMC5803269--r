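#' @include AllClasses.R AllGenerics.R
NULL

#' Per-sample meta-feature score of a gene set
#'
#' Each gene in the set is scaled to unit variance across samples (without
#' centering, so the score tracks absolute program abundance; a centering
#' flag is provided — downstream regression slopes are unaffected either
#' way) and the scaled values are averaged over genes within each sample.
#' Zero-variance genes are dropped with a warning.
#'
#' @param x a log-scale [ExprMatrix-class].
#' @param geneSet character vector of gene ids; must intersect the matrix.
#' @param center also subtract each gene's mean before scaling.
#' @return A [MetaFeatureScore-class] with one value per sample.
#' @export
setMethod("metafeatureScore", "ExprMatrix",
    function(x, geneSet, center = FALSE) {
        genes <- intersect(geneSet, geneIds(x))
        if (!length(genes))
            stop("gene set does not intersect the expression matrix")
        v <- exprValues(x)[genes, , drop = FALSE]
        sds <- rowSds(v)
        zero <- sds <= 0
        if (any(zero)) {
            warning(sum(zero), " zero-variance gene(s) dropped from the ",
                    "meta-feature")
            v <- v[!zero, , drop = FALSE]
            sds <- sds[!zero]
            if (!nrow(v))
                stop("no genes with positive variance in the set")
        }
        if (center) v <- v - rowMeans(v)
        sc <- colMeans(v / sds)
        new("MetaFeatureScore", score = sc, nGenesUsed = nrow(v),
            geneSetName = "gene_set")
    })

#' @describeIn MetaFeatureScore-class named per-sample score vector.
#' @param object a `MetaFeatureScore`.
#' @export
setMethod("scoreValues", "MetaFeatureScore", function(object) object@score)

#' @describeIn MetaFeatureScore-class number of genes used.
#' @export
setMethod("nGenesUsed", "MetaFeatureScore", function(object)
    object@nGenesUsed)

setMethod("show", "MetaFeatureScore", function(object) {
    cat(sprintf("MetaFeatureScore: %d samples, %d genes used\n",
                length(object@score), object@nGenesUsed))
})

#' Trait association of a meta-feature score
#'
#' Per trait, a univariate linear model `score ~ trait` (continuous traits
#' as given; binary and allele-count traits as 0/1/2 numeric codes), with
#' slope, standard error, t-value and two-sided p-value — one row per
#' trait, the layout of a clinicopathological association table. Missing
#' trait values are dropped pairwise; constant traits are reported as not
#' estimable, and an exact linear fit (zero residual variance) is flagged
#' degenerate with its slope but no inference.
#'
#' @param score a [MetaFeatureScore-class] or named numeric vector.
#' @param traits trait `data.frame` with a `sample_id` column.
#' @param minN minimum non-missing observations per trait (default 3).
#' @return A `data.frame` with columns `trait`, `estimate`, `std_error`,
#'   `t_value`, `p_value`, `n`, `note`.
#' @export
associateTraits <- function(score, traits, minN = 3L) {
    if (is(score, "MetaFeatureScore")) score <- scoreValues(score)
    if (is.null(names(score))) stop("score must be named by sample id")
    if (!"sample_id" %in% names(traits))
        stop("traits must have a 'sample_id' column")
    idx <- match(names(score), traits$sample_id)
    if (anyNA(idx))
        stop("traits missing for samples: ",
             paste(utils::head(names(score)[is.na(idx)], 5L),
                   collapse = ", "))
    traits <- traits[idx, , drop = FALSE]
    trait_names <- setdiff(names(traits), "sample_id")
    rows <- lapply(trait_names, function(tn) {
        tv <- as.numeric(traits[[tn]])
        ok <- !is.na(tv) & !is.na(score)
        n <- sum(ok)
        row <- data.frame(trait = tn, estimate = NA_real_,
                          std_error = NA_real_, t_value = NA_real_,
                          p_value = NA_real_, n = n, note = "",
                          stringsAsFactors = FALSE)
        if (n < minN) {
            row$note <- "too_few_observations"
            return(row)
        }
        if (stats::var(tv[ok]) == 0) {
            row$note <- "not_estimable_constant_trait"
            return(row)
        }
        fit <- stats::lm(score[ok] ~ tv[ok])
        # degenerate (zero-residual) fits are detected and flagged below
        sm <- suppressWarnings(summary(fit))
        co <- sm$coefficients
        row$estimate <- co[2L, "Estimate"]
        if (sm$sigma < 1e-12) {
            row$std_error <- 0
            row$note <- "degenerate_exact_fit"
        } else {
            row$std_error <- co[2L, "Std. Error"]
            row$t_value <- co[2L, "t value"]
            row$p_value <- co[2L, "Pr(>|t|)"]
        }
        row
    })
    do.call(rbind, rows)
}
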