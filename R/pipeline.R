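#' @include AllClasses.R synthgen.R signature.R setenrich.R metafeature.R
#' @include agingde.R concordance.R io.R
#' @importFrom jsonlite write_json read_json toJSON
#' @importFrom yaml read_yaml write_yaml
NULL

#' Default run configuration for a synthetic study
#'
#' Assembles the configuration consumed by [runPipeline()]: the synthetic
#' design (or, alternatively, input file paths), every stage threshold, and
#' explicit seeds for all stochastic stages.
#'
#' @param seed master integer seed; stage seeds are derived from it.
#' @param design a [MixtureDesign-class]; its seed is set from `seed`.
#' @return A named list (a run configuration).
#' @export
synthConfig <- function(seed = 1L, design = NULL) {
    seed <- as.integer(seed)
    if (is.null(design)) design <- MixtureDesign(seed = seed)
    else design@seed <- seed
    list(
        synthetic = TRUE,
        design = design,
        signature = list(fcThreshold = 4, alpha = 0.05,
                         fpkmThreshold = 0.1, maxLowSamples = 2,
                         pseudocount = 1),
        gsea = list(weightExponent = 1, nPerm = 500L, seed = seed + 100L),
        agingde = list(logfcThreshold = 2, alpha = 0.05,
                       detectThreshold = 0.1, minDetectedFraction = 0.5,
                       quantileAlign = TRUE),
        seed = seed
    )
}

#' Read a run configuration from YAML or JSON
#'
#' File-based configurations list input paths under `inputs:` (`purified`,
#' `bulk`, `annotation`, and optionally `traits`, `disease_sets`,
#' `reference`, `proteins`) plus the stage parameter blocks of
#' [synthConfig()]. Configurations round-trip through serialization.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON config file.
#' @return A run configuration list.
#' @export
readRunConfig <- function(path) {
    cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
    base <- synthConfig(seed = if (!is.null(cfg$seed)) cfg$seed else 1L)
    for (blk in c("signature", "gsea", "agingde"))
        for (nm in names(cfg[[blk]])) base[[blk]][[nm]] <- cfg[[blk]][[nm]]
    base$synthetic <- isTRUE(cfg$synthetic) || is.null(cfg$inputs)
    base$inputs <- cfg$inputs
    base
}

.loadInputs <- function(config) {
    if (isTRUE(config$synthetic)) {
        study <- synthStudy(config$design)
        aging <- generateAgingPair(config$design,
                                   seed = config$seed + 10L)
        c(study, list(aged = aging$aged, reference = aging$reference,
                      agingTruth = aging[c("up", "down")]))
    } else {
        ins <- config$inputs
        need <- c("purified", "bulk", "annotation")
        if (!all(need %in% names(ins)))
            stop("inputs must provide: ", paste(need, collapse = ", "))
        list(purified = readExprTSV(ins$purified),
             bulk = readExprTSV(ins$bulk),
             annotation = readGeneAnnotation(ins$annotation),
             traits = if (!is.null(ins$traits)) readTraitTable(ins$traits),
             diseaseSets = if (!is.null(ins$disease_sets))
                 readGMT(ins$disease_sets),
             aged = NULL,
             reference = if (!is.null(ins$reference))
                 readExprTSV(ins$reference),
             proteins = if (!is.null(ins$proteins))
                 utils::read.delim(ins$proteins, stringsAsFactors = FALSE),
             truth = NULL)
    }
}

#' Run the full analysis pipeline
#'
#' Stage order: low-expression filter, log transform, protein-identifier
#' filter, joint robust artifact normalization, signature derivation;
#' hypergeometric ORA and pre-ranked GSEA of disease sets; meta-feature
#' scoring and trait association; aging differential expression against a
#' reference dataset; proteome concordance. Stages whose inputs are absent
#' (traits, disease sets, reference, proteins) are skipped with a warning;
#' any stage error aborts with the stage name. Deterministic given the
#' configuration's seeds.
#'
#' @param config a run configuration ([synthConfig()] / [readRunConfig()]).
#' @param outDir optional directory; when given, all stage outputs are
#'   written as TSV/GMT/JSON plus a `manifest.json` of applied parameters.
#' @return A run report: list with `signature` ([SignatureResult-class]),
#'   `normalizationFit`, `ora`, `gsea`, `score`, `associations`, `de`,
#'   `deCounts`, `concordance`, `truth` (synthetic runs) and `manifest`.
#' @examples
#' cfg <- synthConfig(seed = 7, design = MixtureDesign(
#'     nGenes = 300L, nBulkSamples = 25L, nPurifiedReplicates = 5L,
#'     fractionDispersion = 100))
#' rep <- runPipeline(cfg)
#' rep$signature
#' @export
runPipeline <- function(config, outDir = NULL) {
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    dat <- stage("inputs", .loadInputs(config))
    sp <- config$signature

    sig <- stage("signature", deriveMicrogliaSignature(
        dat$purified, dat$bulk, dat$annotation,
        fcThreshold = sp$fcThreshold, alpha = sp$alpha,
        fpkmThreshold = sp$fpkmThreshold,
        maxLowSamples = sp$maxLowSamples,
        pseudocount = sp$pseudocount))
    sig_tab <- signatureTable(sig$signature)
    universe <- sig_tab$gene     # post-filter, both datasets, uniprot genes

    ora <- gsea <- NULL
    if (!is.null(dat$diseaseSets)) {
        ora <- stage("ora", hypergeometricORA(fcSet(sig$signature),
                                              dat$diseaseSets, universe))
        ranked <- stats::setNames(sig_tab$mod_t, sig_tab$gene)
        sets_in <- lapply(dat$diseaseSets, intersect, universe)
        sets_in <- sets_in[vapply(sets_in, length, 1L) > 0L]
        gsea <- stage("gsea", prerankedGSEA(
            ranked, sets_in, weightExponent = config$gsea$weightExponent,
            nPerm = config$gsea$nPerm, seed = config$gsea$seed))
    } else warning("no disease sets supplied; enrichment stage skipped")

    score <- assoc <- NULL
    mf <- stage("metafeature",
                metafeatureScore(sig$bulk, fcSet(sig$signature)))
    score <- mf
    if (!is.null(dat$traits))
        assoc <- stage("traits", associateTraits(mf, dat$traits))
    else warning("no trait table supplied; trait stage skipped")

    de <- de_counts <- NULL
    aged_in <- if (!is.null(dat$aged)) dat$aged else dat$purified
    if (!is.null(dat$reference)) {
        ap <- config$agingde
        pair <- stage("harmonize", harmonizePair(
            aged_in, dat$reference, detectThreshold = ap$detectThreshold,
            minDetectedFraction = ap$minDetectedFraction,
            quantileAlign = ap$quantileAlign))
        de <- stage("agingde", differentialExpression(
            pair, logfcThreshold = ap$logfcThreshold, alpha = ap$alpha))
        de_counts <- attr(de, "counts")
    } else warning("no reference dataset supplied; aging DE stage skipped")

    conc <- NULL
    if (!is.null(dat$proteins)) {
        purified_log <- logTransform(
            filterLowExpression(dat$purified, sp$fpkmThreshold,
                                sp$maxLowSamples), sp$pseudocount)
        conc <- stage("concordance", list(
            overlap = signatureOverlap(dat$proteins, fcSet(sig$signature)),
            correlation = rankCorrelation(dat$proteins, purified_log)))
    } else warning("no protein table supplied; concordance stage skipped")

    manifest <- list(
        package_version = as.character(utils::packageVersion("humiSig")),
        seed = config$seed,
        signature = sp, gsea = config$gsea, agingde = config$agingde,
        synthetic = isTRUE(config$synthetic),
        n_universe = length(universe),
        design = if (isTRUE(config$synthetic)) list(
            nCellTypes = config$design@nCellTypes,
            nGenes = config$design@nGenes,
            markersPerType = config$design@markersPerType,
            markerLog2Effect = config$design@markerLog2Effect,
            meanMicrogliaFraction = config$design@meanMicrogliaFraction,
            fractionDispersion = config$design@fractionDispersion,
            noiseSd = config$design@noiseSd,
            gcArtifactCoef = config$design@gcArtifactCoef,
            lengthArtifactCoef = config$design@lengthArtifactCoef,
            nBulkSamples = config$design@nBulkSamples,
            nPurifiedReplicates = config$design@nPurifiedReplicates,
            seed = config$design@seed))

    report <- list(signature = sig$signature,
                   normalizationFit = sig$fit,
                   ora = ora, gsea = gsea, score = score,
                   associations = assoc, de = de, deCounts = de_counts,
                   concordance = conc,
                   truth = dat$truth, agingTruth = dat$agingTruth,
                   manifest = manifest)

    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        utils::write.table(sig_tab, file.path(outDir, "signature.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        sig_sets <- list(fc_set = fcSet(sig$signature))
        if (length(pvalSet(sig$signature)))
            sig_sets$pval_set <- pvalSet(sig$signature)
        writeGMT(sig_sets, file.path(outDir, "signature_sets.gmt"))
        if (!is.null(ora))
            utils::write.table(ora, file.path(outDir, "ora.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(gsea))
            utils::write.table(gsea, file.path(outDir, "gsea.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(assoc))
            utils::write.table(assoc, file.path(outDir, "trait_table.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(de)) {
            utils::write.table(de, file.path(outDir, "aging_de.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            volcano <- data.frame(gene = de$gene, log2_fc = de$log2_fc,
                                  neg_log10_adj_p = -log10(de$adj_p))
            utils::write.table(volcano, file.path(outDir, "volcano.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        }
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    report
}
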