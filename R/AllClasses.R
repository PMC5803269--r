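#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

.EXPR_SCALES <- c("raw", "log2", "normalized")

#' Expression matrix container
#'
#' A genes-by-samples abundance matrix carried as a
#' [SummarizedExperiment::SummarizedExperiment] with a single `"exprs"` assay
#' and a scale tag (`"raw"` for FPKM-like nonnegative abundances, `"log2"`
#' after log transformation, `"normalized"` after artifact removal). Gene
#' annotation columns, when supplied, live in `rowData`.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @export
setClass("ExprMatrix", contains = "SummarizedExperiment")

setValidity("ExprMatrix", function(object) {
    msg <- character()
    if (!identical(SummarizedExperiment::assayNames(object)[1L], "exprs"))
        msg <- c(msg, "first assay must be named 'exprs'")
    sc <- metadata(object)$scale
    if (is.null(sc) || !is.character(sc) || length(sc) != 1L ||
        !sc %in% .EXPR_SCALES)
        msg <- c(msg, sprintf("metadata 'scale' must be one of %s",
                              paste(.EXPR_SCALES, collapse = "/")))
    rn <- rownames(object)
    cn <- colnames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, "gene ids must be present and unique")
    if (is.null(cn) || anyDuplicated(cn))
        msg <- c(msg, "sample ids must be present and unique")
    x <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(x))
        msg <- c(msg, "'exprs' assay must be numeric")
    if (identical(sc, "raw") && nrow(x) && ncol(x) &&
        any(x < 0, na.rm = TRUE))
        msg <- c(msg, "raw-scale values must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' Construct an ExprMatrix
#'
#' @param values numeric genes x samples matrix with row and column names.
#' @param scale one of `"raw"`, `"log2"`, `"normalized"`.
#' @param annotation optional gene annotation `data.frame` with a `gene_id`
#'   column (see [readGeneAnnotation()]); matched rows are stored in
#'   `rowData`.
#' @return An [ExprMatrix-class] object.
#' @examples
#' m <- ExprMatrix(matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3),
#'                                                   paste0("s", 1:2))))
#' exprScale(m)
#' @export
ExprMatrix <- function(values, scale = c("raw", "log2", "normalized"),
                       annotation = NULL) {
    scale <- match.arg(scale)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    rd <- NULL
    if (!is.null(annotation)) {
        annotation <- as.data.frame(annotation)
        idx <- match(rownames(values), annotation$gene_id)
        rd <- DataFrame(annotation[idx, , drop = FALSE])
        rownames(rd) <- rownames(values)
    }
    se <- if (is.null(rd))
        SummarizedExperiment(assays = list(exprs = values))
    else
        SummarizedExperiment(assays = list(exprs = values), rowData = rd)
    metadata(se)$scale <- scale
    new("ExprMatrix", se)
}

#' Synthetic bulk-mixture design
#'
#' Parameters of the synthetic study generator. Defaults emulate the study
#' conditions: a minority microglia fraction of 12% of cortical cells, 540
#' bulk tissue samples and 10 purified-microglia replicates.
#'
#' @slot nCellTypes number of cell types in the mixture.
#' @slot nGenes number of genes.
#' @slot markersPerType planted marker genes per cell type.
#' @slot markerLog2Effect log2 expression excess of a marker in its own cell
#'   type relative to every other type.
#' @slot meanMicrogliaFraction mean mixing proportion of microglia, in (0,1).
#' @slot fractionDispersion Dirichlet concentration of per-sample mixing
#'   proportions (larger = less sample-to-sample variation).
#' @slot noiseSd standard deviation of measurement noise on the log2 scale.
#' @slot gcArtifactCoef log2-scale slope of the planted per-sample bias on
#'   centered GC fraction.
#' @slot lengthArtifactCoef log2-scale slope on centered log10 gene length.
#' @slot nBulkSamples number of bulk tissue samples.
#' @slot nPurifiedReplicates number of purified-cell replicates.
#' @slot seed integer seed.
#' @export
setClass("MixtureDesign", representation(
    nCellTypes = "integer",
    nGenes = "integer",
    markersPerType = "integer",
    markerLog2Effect = "numeric",
    meanMicrogliaFraction = "numeric",
    fractionDispersion = "numeric",
    noiseSd = "numeric",
    gcArtifactCoef = "numeric",
    lengthArtifactCoef = "numeric",
    nBulkSamples = "integer",
    nPurifiedReplicates = "integer",
    seed = "integer"
))

setValidity("MixtureDesign", function(object) {
    msg <- character()
    counts <- c(nCellTypes = object@nCellTypes, nGenes = object@nGenes,
                markersPerType = object@markersPerType,
                nBulkSamples = object@nBulkSamples,
                nPurifiedReplicates = object@nPurifiedReplicates)
    if (any(is.na(counts)) || any(counts <= 0L))
        msg <- c(msg, "all counts must be positive integers")
    f <- object@meanMicrogliaFraction
    if (!is.finite(f) || f <= 0 || f >= 1)
        msg <- c(msg, "meanMicrogliaFraction must lie in (0, 1)")
    if (!is.finite(object@fractionDispersion) || object@fractionDispersion <= 0)
        msg <- c(msg, "fractionDispersion must be positive")
    if (!is.finite(object@noiseSd) || object@noiseSd < 0)
        msg <- c(msg, "noiseSd must be nonnegative")
    if (!any(is.na(counts)) &&
        object@markersPerType * object@nCellTypes > object@nGenes)
        msg <- c(msg, "markersPerType * nCellTypes exceeds nGenes")
    if (length(msg)) msg else TRUE
})

#' @rdname MixtureDesign-class
#' @param nCellTypes,nGenes,markersPerType,markerLog2Effect counts and marker
#'   effect size (see slots).
#' @param meanMicrogliaFraction,fractionDispersion mixing proportion model.
#' @param noiseSd,gcArtifactCoef,lengthArtifactCoef noise and technical
#'   artifact model.
#' @param nBulkSamples,nPurifiedReplicates sample sizes.
#' @param seed integer seed used by all generator operations.
#' @return A validated `MixtureDesign`.
#' @examples
#' MixtureDesign(nGenes = 500, seed = 7)
#' @export
MixtureDesign <- function(nCellTypes = 3L, nGenes = 2000L,
                          markersPerType = 50L, markerLog2Effect = 6,
                          meanMicrogliaFraction = 0.12,
                          fractionDispersion = 200,
                          noiseSd = 0.5,
                          gcArtifactCoef = 1, lengthArtifactCoef = 0.5,
                          nBulkSamples = 540L, nPurifiedReplicates = 10L,
                          seed = 1L) {
    new("MixtureDesign",
        nCellTypes = as.integer(nCellTypes), nGenes = as.integer(nGenes),
        markersPerType = as.integer(markersPerType),
        markerLog2Effect = as.numeric(markerLog2Effect),
        meanMicrogliaFraction = as.numeric(meanMicrogliaFraction),
        fractionDispersion = as.numeric(fractionDispersion),
        noiseSd = as.numeric(noiseSd),
        gcArtifactCoef = as.numeric(gcArtifactCoef),
        lengthArtifactCoef = as.numeric(lengthArtifactCoef),
        nBulkSamples = as.integer(nBulkSamples),
        nPurifiedReplicates = as.integer(nPurifiedReplicates),
        seed = as.integer(seed))
}

#' Ground truth of a synthetic study
#'
#' Records everything the generator planted so downstream recovery can be
#' quantified: marker gene sets per cell type, per-sample mixing proportions,
#' trait effect sizes on the microglial program, and the planted overlap
#' between disease gene sets and the microglia markers.
#'
#' @slot markerSets named list, cell type -> character vector of gene ids.
#' @slot proportions samples x cell-types numeric matrix, rows sum to 1.
#' @slot traitEffects named numeric, trait -> slope on the standardized
#'   microglial program (latent scale for categorical traits).
#' @slot diseaseOverlap named integer, disease set -> planted overlap count
#'   with the microglia marker set.
#' @export
setClass("SyntheticTruth", representation(
    markerSets = "list",
    proportions = "matrix",
    traitEffects = "numeric",
    diseaseOverlap = "integer"
))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    sets <- object@markerSets
    if (length(sets) > 1L) {
        all_genes <- unlist(sets, use.names = FALSE)
        if (anyDuplicated(all_genes))
            msg <- c(msg, "marker sets must be pairwise disjoint")
    }
    p <- object@proportions
    if (nrow(p) && any(abs(rowSums(p) - 1) > 1e-9))
        msg <- c(msg, "each proportions row must sum to 1 (tol 1e-9)")
    if (length(msg)) msg else TRUE
})

#' Per-sample robust artifact-normalization fit
#'
#' Coefficients of the per-sample robust (Huber M-estimator) regression of
#' the sample-vs-grand-mean log ratio on GC fraction and log10 gene length.
#'
#' @slot coefficients samples x 3 matrix (intercept, gc, log10 length).
#' @slot converged logical per sample.
#' @export
setClass("NormalizationFit", representation(
    coefficients = "matrix",
    converged = "logical"
))

#' Signature derivation result
#'
#' Per-gene purified-vs-bulk contrast with moderated-t inference and the two
#' signature definitions: the FC set (fold-change criterion alone,
#' boundary-inclusive, purified > bulk) and the PVAL set (fold change plus
#' BH-adjusted significance).
#'
#' @slot table data.frame with columns `gene`, `log2_fc`, `mod_t`,
#'   `p_value`, `adj_p`, `in_fc_set`, `in_pval_set`.
#' @slot fcThreshold linear fold-change cutoff (default 4).
#' @slot alpha adjusted-p cutoff for the PVAL set.
#' @export
setClass("SignatureResult", representation(
    table = "data.frame",
    fcThreshold = "numeric",
    alpha = "numeric"
))

setValidity("SignatureResult", function(object) {
    tab <- object@table
    need <- c("gene", "log2_fc", "mod_t", "p_value", "adj_p",
              "in_fc_set", "in_pval_set")
    msg <- character()
    if (!all(need %in% names(tab)))
        msg <- c(msg, paste("table must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (any(tab$in_fc_set & tab$log2_fc < log2(object@fcThreshold) - 1e-12,
                na.rm = TRUE))
            msg <- c(msg, "in_fc_set gene below log2 fold-change threshold")
        bad <- tab$in_pval_set &
            !(tab$in_fc_set & !is.na(tab$adj_p) & tab$adj_p < object@alpha)
        if (any(bad, na.rm = TRUE))
            msg <- c(msg, "in_pval_set must imply in_fc_set and adj_p < alpha")
        ap <- tab$adj_p[!is.na(tab$adj_p)]
        if (length(ap) && (any(ap < 0) || any(ap > 1)))
            msg <- c(msg, "adj_p must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Per-sample gene-set meta-feature score
#'
#' One scalar per sample: each used gene is scaled to unit variance across
#' samples (without centering) and the scaled values are averaged over the
#' gene set, proxying the collective abundance of the cell-type program.
#'
#' @slot score named numeric, one value per sample.
#' @slot nGenesUsed number of genes contributing after zero-variance drops.
#' @slot geneSetName label of the scored set.
#' @export
setClass("MetaFeatureScore", representation(
    score = "numeric",
    nGenesUsed = "integer",
    geneSetName = "character"
))

setValidity("MetaFeatureScore", function(object) {
    msg <- character()
    if (is.null(names(object@score)))
        msg <- c(msg, "score must be named by sample id")
    if (object@nGenesUsed < 1L)
        msg <- c(msg, "nGenesUsed must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Harmonized pair of microglia expression datasets
#'
#' Two log2-scale matrices restricted to the genes reliably detected in both
#' datasets, optionally quantile-aligned, ready for moderated-t differential
#' expression (aged vs reference).
#'
#' @slot a,b [ExprMatrix-class] objects with identical gene vectors.
#' @slot params detection / alignment parameters actually applied.
#' @export
setClass("HarmonizedPair", representation(
    a = "ExprMatrix",
    b = "ExprMatrix",
    params = "list"
))

setValidity("HarmonizedPair", function(object) {
    msg <- character()
    if (!identical(rownames(object@a), rownames(object@b)))
        msg <- c(msg, "gene vectors must be identical and in identical order")
    if (!identical(metadata(object@a)$scale, metadata(object@b)$scale))
        msg <- c(msg, "both matrices must share the same scale")
    if (length(msg)) msg else TRUE
})
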