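#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' @describeIn SyntheticTruth-class planted marker sets, cell type -> genes.
#' @param object a `SyntheticTruth`.
#' @export
setMethod("markerSets", "SyntheticTruth", function(object) object@markerSets)

#' @describeIn SyntheticTruth-class samples x cell-types mixing proportions.
#' @export
setMethod("mixingProportions", "SyntheticTruth",
          function(object) object@proportions)

#' @describeIn SyntheticTruth-class planted trait effect sizes.
#' @export
setMethod("traitEffects", "SyntheticTruth", function(object)
    object@traitEffects)

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:\n",
        sprintf("  %d marker sets (%s)\n", length(object@markerSets),
                paste(names(object@markerSets), collapse = ", ")),
        sprintf("  proportions: %d samples x %d cell types\n",
                nrow(object@proportions), ncol(object@proportions)),
        sprintf("  %d trait effects, %d disease sets\n",
                length(object@traitEffects), length(object@diseaseOverlap)),
        sep = "")
})

.cellTypeNames <- function(k)
    c("microglia", if (k > 1L) paste0("celltype", seq_len(k - 1L) + 1L))

#' Generate cell-type base expression profiles
#'
#' Draws per-gene baseline abundances shared across cell types, plants
#' `markersPerType` disjoint marker genes per cell type whose expression in
#' their own type exceeds every other type by `markerLog2Effect` (log2), and
#' fabricates a gene annotation (GC fraction uniform on 0.3–0.7, length
#' log-uniform on 500–100000 bp). Marker genes are always flagged as having
#' a protein identifier (curated cell-type markers are protein coding);
#' other genes carry the flag with probability 0.9.
#'
#' @param design a [MixtureDesign-class].
#' @param seed integer seed; defaults to the design's seed.
#' @return A list with `profiles` (cell types x genes linear-scale matrix),
#'   `annotation` (gene annotation `data.frame`) and `truth`
#'   ([SyntheticTruth-class] carrying the planted marker sets).
#' @export
generateProfiles <- function(design, seed = design@seed) {
    validObject(design)
    k <- design@nCellTypes
    g <- design@nGenes
    types <- .cellTypeNames(k)
    withSeed(seed, {
        gene_ids <- sprintf("g%05d", seq_len(g))
        base_log2 <- stats::rnorm(g, mean = 3, sd = 2.5)
        marker_idx <- sample.int(g, design@markersPerType * k)
        sets <- split(gene_ids[marker_idx],
                      rep(types, each = design@markersPerType))
        sets <- sets[types]
        prof <- matrix(rep(base_log2, each = k), nrow = k,
                       dimnames = list(types, gene_ids))
        for (t in types)
            prof[t, sets[[t]]] <- prof[t, sets[[t]]] + design@markerLog2Effect
        gc <- stats::runif(g, 0.3, 0.7)
        len <- 10^stats::runif(g, log10(500), log10(1e5))
        uni <- stats::rbinom(g, 1L, 0.9) == 1L
        uni[marker_idx] <- TRUE
        ann <- data.frame(gene_id = gene_ids,
                          symbol = toupper(gene_ids),
                          gc_fraction = gc,
                          length_bp = len,
                          has_uniprot = uni,
                          stringsAsFactors = FALSE)
        truth <- new("SyntheticTruth", markerSets = sets,
                     proportions = matrix(numeric(0), 0L, 0L),
                     traitEffects = numeric(0),
                     diseaseOverlap = integer(0))
        list(profiles = 2^prof, annotation = ann, truth = truth)
    })
}

# Per-sample technical artifact multiplier on the log2 scale: each sample
# gets its own slope on centered GC and centered log10 length, drawn
# uniformly in [-coef, +coef] so that the artifact averages out across
# samples but is recoverable per sample.
.artifactExponent <- function(annotation, nSamples, gcCoef, lenCoef) {
    gc_c <- annotation$gc_fraction - mean(annotation$gc_fraction)
    ll <- log10(annotation$length_bp)
    ll_c <- ll - mean(ll)
    gc_slope <- gcCoef * stats::runif(nSamples, -1, 1)
    len_slope <- lenCoef * stats::runif(nSamples, -1, 1)
    list(exponent = outer(gc_c, gc_slope) + outer(ll_c, len_slope),
         gc_slope = gc_slope, len_slope = len_slope)
}

#' Generate a bulk-tissue mixture dataset
#'
#' Each bulk sample is a proportion-weighted mixture of the cell-type
#' profiles: `bulk[g, s] = sum_t p[s, t] * profile[t, g]`, multiplied by a
#' per-sample GC/length technical artifact (`2^` of a per-sample linear
#' exponent in centered GC fraction and centered log10 length) and lognormal
#' measurement noise. Mixing proportions are Dirichlet-distributed around
#' the design's mean microglia fraction, the remaining mass split evenly
#' among the other cell types.
#'
#' @param profiles output of [generateProfiles()] (the full list or the
#'   profiles matrix).
#' @param design the [MixtureDesign-class].
#' @param annotation gene annotation (needed for the artifact; defaults to
#'   the annotation inside `profiles` when the full list is given).
#' @param nSamples number of bulk samples.
#' @param proportions optional fixed samples x cell-types matrix overriding
#'   the Dirichlet draw.
#' @param seed integer seed.
#' @return A list with `matrix` (raw-scale [ExprMatrix-class]),
#'   `proportions` (samples x cell types), and `artifactSlopes`
#'   (per-sample planted GC / length slopes).
#' @export
generateBulk <- function(profiles, design, annotation = NULL,
                         nSamples = design@nBulkSamples,
                         proportions = NULL, seed = design@seed + 1L) {
    if (is.list(profiles)) {
        if (is.null(annotation)) annotation <- profiles$annotation
        profiles <- profiles$profiles
    }
    if (is.null(annotation))
        stop("annotation is required for the artifact model")
    k <- nrow(profiles)
    types <- rownames(profiles)
    withSeed(seed, {
        if (is.null(proportions)) {
            f <- design@meanMicrogliaFraction
            alpha <- design@fractionDispersion *
                c(f, rep((1 - f) / (k - 1L), k - 1L))
            proportions <- rdirichlet(nSamples, alpha)
        }
        nSamples <- nrow(proportions)
        dimnames(proportions) <- list(sprintf("bulk_%03d", seq_len(nSamples)),
                                      types)
        mix <- t(proportions %*% profiles)   # genes x samples
        art <- .artifactExponent(annotation, nSamples,
                                 design@gcArtifactCoef,
                                 design@lengthArtifactCoef)
        noise <- matrix(stats::rnorm(length(mix), 0, design@noiseSd),
                        nrow = nrow(mix))
        values <- mix * 2^(art$exponent + noise)
        colnames(values) <- rownames(proportions)
        list(matrix = ExprMatrix(values, scale = "raw",
                                 annotation = annotation),
             proportions = proportions,
             artifactSlopes = data.frame(
                 sample_id = rownames(proportions),
                 gc_slope = art$gc_slope, length_slope = art$len_slope,
                 stringsAsFactors = FALSE))
    })
}

#' Generate purified-cell replicates
#'
#' Replicates of one cell type's base profile plus lognormal noise, with the
#' per-sample GC/length artifact optionally applied.
#'
#' @param profiles output of [generateProfiles()] (list or matrix).
#' @param design the [MixtureDesign-class].
#' @param cellType which cell type to purify (default `"microglia"`).
#' @param nReplicates number of replicates; the default of 10 matches the
#'   purified-microglia study scale.
#' @param applyArtifact apply the per-sample artifact model (default FALSE:
#'   purified libraries come from a different protocol in which the planted
#'   artifact need not be present).
#' @param annotation gene annotation (required when `applyArtifact = TRUE`).
#' @param seed integer seed.
#' @return A raw-scale [ExprMatrix-class] of `nReplicates` samples.
#' @export
generatePurified <- function(profiles, design, cellType = "microglia",
                             nReplicates = design@nPurifiedReplicates,
                             applyArtifact = FALSE, annotation = NULL,
                             seed = design@seed + 2L) {
    if (is.list(profiles)) {
        if (is.null(annotation)) annotation <- profiles$annotation
        profiles <- profiles$profiles
    }
    if (!cellType %in% rownames(profiles))
        stop("unknown cell type '", cellType, "'; available: ",
             paste(rownames(profiles), collapse = ", "))
    prof <- profiles[cellType, ]
    withSeed(seed, {
        values <- matrix(rep(prof, nReplicates), ncol = nReplicates,
                         dimnames = list(colnames(profiles),
                                         sprintf("%s_rep%02d", cellType,
                                                 seq_len(nReplicates))))
        expo <- matrix(stats::rnorm(length(values), 0, design@noiseSd),
                       nrow = nrow(values))
        if (applyArtifact) {
            if (is.null(annotation))
                stop("annotation required when applyArtifact = TRUE")
            art <- .artifactExponent(annotation, nReplicates,
                                     design@gcArtifactCoef,
                                     design@lengthArtifactCoef)
            expo <- expo + art$exponent
        }
        ExprMatrix(values * 2^expo, scale = "raw", annotation = annotation)
    })
}

#' Default planted trait effects
#'
#' Slopes of each trait on the standardized microglial program (latent scale
#' for binary/allele-count traits). Signs follow the study's qualitative
#' findings: the program increases with age at death, is higher in women, is
#' weakly related to amyloid load, and is reduced by APOE e2 dosage; the
#' remaining traits are null.
#'
#' @return Named numeric vector of effects.
#' @export
defaultTraitEffects <- function()
    c(age_at_death = 3, sex = 0.3, clinical_AD = 0, global_pathology = 0,
      amyloid_load = 0.15, tau_tangle_density = 0,
      apoe_e2_count = -0.5, apoe_e4_count = 0)

#' Generate a per-sample clinicopathological trait table
#'
#' Each trait is built as `intercept + effect * program + noise`, where the
#' program is the standardized microglia mixing proportion; binary traits
#' are obtained by thresholding a unit-variance latent at a prevalence
#' cutpoint and APOE allele counts by a Binomial(2, p) with logit-linear p.
#'
#' @param proportions samples x cell-types mixing proportion matrix (from
#'   [generateBulk()]); must contain a `"microglia"` column.
#' @param effects named effect sizes, see [defaultTraitEffects()].
#' @param seed integer seed.
#' @return A `data.frame` with `sample_id` and the eight trait columns.
#' @export
generateTraits <- function(proportions, effects = defaultTraitEffects(),
                           seed = 1L) {
    if (!"microglia" %in% colnames(proportions))
        stop("proportions must have a 'microglia' column")
    miss <- setdiff(names(defaultTraitEffects()), names(effects))
    if (length(miss))
        stop("missing trait effects: ", paste(miss, collapse = ", "))
    z <- as.numeric(scale(proportions[, "microglia"]))
    n <- length(z)
    withSeed(seed, {
        age <- 88 + effects["age_at_death"] * z + stats::rnorm(n, 0, 5)
        sex <- as.integer(effects["sex"] * z + stats::rnorm(n) >
                              stats::qnorm(1 - 0.65))
        ad <- as.integer(effects["clinical_AD"] * z + stats::rnorm(n) >
                             stats::qnorm(1 - 0.3))
        gpath <- pmax(0, 1 + effects["global_pathology"] * z +
                          stats::rnorm(n, 0, 0.6))
        amyl <- pmax(0, 1.5 + effects["amyloid_load"] * z +
                         stats::rnorm(n, 0, 1))
        tau <- pmax(0, 1.2 + effects["tau_tangle_density"] * z +
                        stats::rnorm(n, 0, 0.8))
        p_e2 <- stats::plogis(stats::qlogis(0.08) +
                                  effects["apoe_e2_count"] * z)
        p_e4 <- stats::plogis(stats::qlogis(0.14) +
                                  effects["apoe_e4_count"] * z)
        e2 <- stats::rbinom(n, 2L, p_e2)
        e4 <- stats::rbinom(n, 2L, p_e4)
        data.frame(sample_id = rownames(proportions),
                   age_at_death = age, sex = sex, clinical_AD = ad,
                   global_pathology = gpath, amyloid_load = amyl,
                   tau_tangle_density = tau,
                   apoe_e2_count = e2, apoe_e4_count = e4,
                   stringsAsFactors = FALSE)
    })
}

#' Generate a disease gene set with planted signature overlap
#'
#' Draws a gene set of `setSize` genes from `universe` sharing exactly
#' `overlapCount` genes with the marker set (the rest drawn from
#' non-markers), emulating GWAS-catalog susceptibility gene lists.
#'
#' @param markers character vector of marker (signature) gene ids.
#' @param universe character vector of all gene ids.
#' @param overlapCount planted overlap; must satisfy
#'   `overlapCount <= min(setSize, length(markers))`.
#' @param setSize disease set size.
#' @param seed integer seed.
#' @return Character vector of gene ids.
#' @export
generateDiseaseSet <- function(markers, universe, overlapCount, setSize,
                               seed = 1L) {
    markers <- intersect(markers, universe)
    non_markers <- setdiff(universe, markers)
    if (overlapCount > min(setSize, length(markers)))
        stop("infeasible overlap: overlapCount must be <= min(setSize, ",
             "number of markers in universe)")
    if (setSize - overlapCount > length(non_markers))
        stop("infeasible set size: not enough non-marker genes in universe")
    withSeed(seed, {
        c(sample(markers, overlapCount),
          sample(non_markers, setSize - overlapCount))
    })
}

#' @rdname generateDiseaseSet
#' @param overlaps named integer vector, one planted overlap per disease set.
#' @return `generateDiseaseSets` returns a named list of gene sets
#'   (GMT-writable).
#' @export
generateDiseaseSets <- function(markers, universe,
                                overlaps = c(AD_like = 15L, MS_like = 8L,
                                             PD_like = 0L, ALS_like = 0L,
                                             SCZ_like = 0L),
                                setSize = 60L, seed = 1L) {
    sets <- lapply(seq_along(overlaps), function(i)
        generateDiseaseSet(markers, universe, overlaps[[i]], setSize,
                           seed = seed + i - 1L))
    names(sets) <- names(overlaps)
    sets
}

#' Generate a synthetic shotgun-proteomics table
#'
#' Samples genes with probability increasing in their mean transcript
#' abundance (proteomic detection skews toward abundant transcripts) and
#' assigns each a relative protein abundance that follows mRNA abundance
#' through a power law plus lognormal noise, giving a moderate positive
#' mRNA-protein rank correlation.
#'
#' @param purified a raw-scale [ExprMatrix-class] of purified-cell samples.
#' @param nProteins number of proteins detected (default 640, the study
#'   scale).
#' @param abundanceExponent power-law exponent linking protein to mRNA
#'   abundance.
#' @param noiseSd lognormal noise SD (log2 scale) on protein abundance.
#' @param seed integer seed.
#' @return A `data.frame` with `protein_id`, `gene_id`, `abundance`
#'   (iBAQ-like, nonnegative).
#' @export
generateProteins <- function(purified, nProteins = 640L,
                             abundanceExponent = 0.5, noiseSd = 2,
                             seed = 1L) {
    mean_expr <- rowMeans(exprValues(purified))
    if (nProteins > length(mean_expr))
        stop("nProteins exceeds number of genes")
    withSeed(seed, {
        prob <- mean_expr^0.7
        idx <- sample.int(length(mean_expr), nProteins, prob = prob)
        genes <- geneIds(purified)[idx]
        abundance <- mean_expr[idx]^abundanceExponent *
            2^stats::rnorm(nProteins, 0, noiseSd)
        data.frame(protein_id = paste0("prot_", genes), gene_id = genes,
                   abundance = as.numeric(abundance),
                   stringsAsFactors = FALSE)
    })
}

#' Generate an aged vs reference microglia pair with planted aging effects
#'
#' Two purified-microglia datasets sharing a baseline profile, with `nUp`
#' genes raised and `nDown` genes lowered by `log2Effect` in the aged
#' dataset, plus lognormal noise. Sample sizes default to the aged (n = 10)
#' vs middle-aged (n = 3) study scale. Effects are planted only on genes
#' whose baseline is at least `minBaseLog2`, so that the planted truth
#' remains observable: a multiplicative down-effect on a gene already at
#' the detection floor cannot be seen in abundance data and would not be a
#' detectable truth to recover.
#'
#' @param design a [MixtureDesign-class] (supplies gene count and noise SD).
#' @param nUp,nDown numbers of planted up-/down-regulated genes.
#' @param log2Effect planted log2 effect size.
#' @param nAged,nRef sample sizes of the aged and reference datasets.
#' @param minBaseLog2 minimum baseline log2 abundance of effect genes
#'   (default 3, i.e. the down-shifted value stays at or above 1 FPKM for
#'   the default effect size).
#' @param seed integer seed.
#' @return A list with `aged`, `reference` (raw-scale [ExprMatrix-class])
#'   and `up`, `down` (planted gene id vectors).
#' @export
generateAgingPair <- function(design, nUp = 50L, nDown = 50L, log2Effect = 3,
                              nAged = design@nPurifiedReplicates, nRef = 3L,
                              minBaseLog2 = 3, seed = design@seed + 10L) {
    g <- design@nGenes
    if (nUp + nDown > g) stop("more planted genes than genes available")
    withSeed(seed, {
        gene_ids <- sprintf("g%05d", seq_len(g))
        base <- stats::rnorm(g, 3, 2.5)
        eligible <- which(base >= minBaseLog2)
        if (length(eligible) < nUp + nDown)
            stop("not enough genes above minBaseLog2 to plant effects")
        de_idx <- sample(eligible, nUp + nDown)
        up <- gene_ids[de_idx[seq_len(nUp)]]
        down <- gene_ids[de_idx[nUp + seq_len(nDown)]]
        aged_prof <- base
        names(aged_prof) <- gene_ids
        aged_prof[up] <- aged_prof[up] + log2Effect
        aged_prof[down] <- aged_prof[down] - log2Effect
        mk <- function(prof, n, prefix) {
            v <- matrix(rep(prof, n), ncol = n,
                        dimnames = list(gene_ids,
                                        sprintf("%s_%02d", prefix,
                                                seq_len(n))))
            ExprMatrix(2^(v + matrix(stats::rnorm(length(v), 0,
                                                  design@noiseSd),
                                     nrow = g)), scale = "raw")
        }
        list(aged = mk(aged_prof, nAged, "aged"),
             reference = mk(stats::setNames(base, gene_ids), nRef, "ref"),
             up = up, down = down)
    })
}

#' Generate a complete synthetic study
#'
#' Runs every generator stage under seeds derived from the design's seed:
#' profiles, bulk mixture, purified microglia, traits, disease gene sets
#' with planted overlaps, and a proteomics table, and assembles the full
#' [SyntheticTruth-class].
#'
#' @param design a [MixtureDesign-class].
#' @param diseaseOverlaps named integer vector of planted overlaps between
#'   each disease set and the microglia marker set.
#' @param diseaseSetSize size of each disease set.
#' @return A list with components `design`, `profiles`, `annotation`,
#'   `bulk`, `proportions`, `purified`, `traits`, `diseaseSets`, `proteins`
#'   and `truth`.
#' @examples
#' study <- synthStudy(MixtureDesign(nGenes = 400, nBulkSamples = 30L,
#'                                   fractionDispersion = 100, seed = 42))
#' study$truth
#' @export
synthStudy <- function(design = MixtureDesign(),
                       diseaseOverlaps = c(AD_like = 15L, MS_like = 8L,
                                           PD_like = 0L, ALS_like = 0L,
                                           SCZ_like = 0L),
                       diseaseSetSize = 60L) {
    prof <- generateProfiles(design)
    bulk <- generateBulk(prof, design, seed = design@seed + 1L)
    purified <- generatePurified(prof, design, seed = design@seed + 2L)
    effects <- defaultTraitEffects()
    traits <- generateTraits(bulk$proportions, effects,
                             seed = design@seed + 3L)
    sets <- generateDiseaseSets(markerSets(prof$truth)$microglia,
                                prof$annotation$gene_id,
                                overlaps = diseaseOverlaps,
                                setSize = diseaseSetSize,
                                seed = design@seed + 4L)
    proteins <- generateProteins(purified,
                                 nProteins = min(640L, design@nGenes %/% 3L),
                                 seed = design@seed + 5L)
    truth <- new("SyntheticTruth",
                 markerSets = markerSets(prof$truth),
                 proportions = bulk$proportions,
                 traitEffects = effects,
                 diseaseOverlap = stats::setNames(
                     as.integer(diseaseOverlaps), names(diseaseOverlaps)))
    list(design = design, profiles = prof$profiles,
         annotation = prof$annotation, bulk = bulk$matrix,
         proportions = bulk$proportions,
         artifactSlopes = bulk$artifactSlopes, purified = purified,
         traits = traits, diseaseSets = sets, proteins = proteins,
         truth = truth)
}
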