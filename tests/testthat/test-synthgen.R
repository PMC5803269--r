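test_that("design validation rejects impossible parameter combinations", {
    expect_error(MixtureDesign(nCellTypes = 3, nGenes = 100,
                               markersPerType = 40), "exceeds nGenes")
    expect_error(MixtureDesign(meanMicrogliaFraction = 1.2), "0, 1")
    expect_error(MixtureDesign(nGenes = 0), "positive")
    expect_s4_class(MixtureDesign(nCellTypes = 3, nGenes = 300,
                                  markersPerType = 20), "MixtureDesign")
})

test_that("seeded generation is bit-reproducible and seeds matter", {
    d <- MixtureDesign(nGenes = 300L, nBulkSamples = 15L, seed = 5L)
    p1 <- generateProfiles(d)
    p2 <- generateProfiles(d)
    expect_identical(p1, p2)
    b1 <- generateBulk(p1, d)
    b2 <- generateBulk(p1, d)
    expect_identical(exprValues(b1$matrix), exprValues(b2$matrix))
    expect_identical(b1$proportions, b2$proportions)
    d2 <- MixtureDesign(nGenes = 300L, nBulkSamples = 15L, seed = 6L)
    expect_false(identical(exprValues(generateBulk(p1, d2)$matrix),
                           exprValues(b1$matrix)))
    tr1 <- generateTraits(b1$proportions, seed = 3L)
    expect_identical(tr1, generateTraits(b1$proportions, seed = 3L))
})

test_that("planted markers are disjoint, sized, and carry the planted contrast", {
    d <- MixtureDesign(nCellTypes = 3, nGenes = 300, markersPerType = 20,
                       seed = 2L)
    prof <- generateProfiles(d)
    sets <- markerSets(prof$truth)
    expect_length(sets, 3L)
    expect_true(all(lengths(sets) == 20L))
    all_markers <- unlist(sets)
    expect_length(all_markers, 60L)
    expect_identical(anyDuplicated(all_markers), 0L)
    # each marker exceeds every other type by exactly the log2 effect
    lp <- log2(prof$profiles)
    for (t in names(sets)) {
        own <- lp[t, sets[[t]]]
        others <- lp[setdiff(rownames(lp), t), sets[[t]], drop = FALSE]
        expect_true(all(abs(sweep(others, 2L, own) + d@markerLog2Effect) <
                        1e-12))
    }
    # degenerate effect: no contrast, but the planted labels remain
    d0 <- MixtureDesign(nCellTypes = 3, nGenes = 300, markersPerType = 20,
                        markerLog2Effect = 0, seed = 2L)
    p0 <- generateProfiles(d0)
    expect_true(all(apply(p0$profiles, 2L, function(col)
        diff(range(col)) == 0)))
    expect_true(all(lengths(markerSets(p0$truth)) == 20L))
})

test_that("noiseless artifact-free bulk equals the exact mixture product", {
    d <- MixtureDesign(nGenes = 200L, noiseSd = 0, gcArtifactCoef = 0,
                       lengthArtifactCoef = 0, nBulkSamples = 8L, seed = 3L)
    prof <- generateProfiles(d)
    P <- matrix(c(0.12, 0.5, 0.38,
                  0.2, 0.4, 0.4), nrow = 2, byrow = TRUE)
    b <- generateBulk(prof, d, proportions = P)
    oracle <- t(b$proportions %*% prof$profiles)
    expect_lt(max(abs(exprValues(b$matrix) - oracle)), 1e-9)
})

test_that("mixing proportions are simplex rows around the microglia fraction", {
    d <- MixtureDesign(nGenes = 150L, nBulkSamples = 200L, seed = 4L)
    b <- generateBulk(generateProfiles(d), d)
    expect_lt(max(abs(rowSums(b$proportions) - 1)), 1e-9)
    expect_equal(mean(b$proportions[, "microglia"]), 0.12, tolerance = 0.02)
})

test_that("planted GC bias shows up with the planted sign per sample", {
    d <- MixtureDesign(nGenes = 500L, gcArtifactCoef = 2,
                       lengthArtifactCoef = 0, noiseSd = 0.1,
                       nBulkSamples = 20L, seed = 6L)
    prof <- generateProfiles(d)
    b <- generateBulk(prof, d)
    lg <- log2(exprValues(b$matrix))
    ratio <- lg - rowMeans(lg)
    s <- which.max(b$artifactSlopes$gc_slope)
    expect_gt(cor(ratio[, s], prof$annotation$gc_fraction), 0)
    s2 <- which.min(b$artifactSlopes$gc_slope)
    expect_lt(cor(ratio[, s2], prof$annotation$gc_fraction), 0)
})

test_that("microglia proportion drives mean marker expression across bulk samples", {
    d <- MixtureDesign(seed = 1L)            # default study conditions
    prof <- generateProfiles(d)
    b <- generateBulk(prof, d)
    markers <- markerSets(prof$truth)$microglia
    mean_marker <- colMeans(log2(exprValues(b$matrix)[markers, ] + 1))
    rho <- cor(b$proportions[, "microglia"], mean_marker,
               method = "spearman")
    expect_gt(rho, 0.8)
})

test_that("purified replicates reproduce the profile and obey the law of large numbers", {
    d <- MixtureDesign(nGenes = 200L, noiseSd = 0, seed = 7L)
    prof <- generateProfiles(d)
    pur <- generatePurified(prof, d)
    expect_identical(ncol(pur), 10L)         # study-scale default
    expect_true(all(abs(exprValues(pur) -
                        prof$profiles["microglia", ]) < 1e-12))
    expect_error(generatePurified(prof, d, cellType = "oligodendrocyte"),
                 "unknown cell type")

    dn <- MixtureDesign(nGenes = 200L, noiseSd = 0.5, seed = 7L)
    big <- generatePurified(prof, dn, nReplicates = 1000L)
    # on the log2 scale replicate means are unbiased for the profile
    lm2 <- rowMeans(log2(exprValues(big)))
    se <- 0.5 / sqrt(1000)
    frac_in <- mean(abs(lm2 - log2(prof$profiles["microglia", ])) <= 3 * se)
    expect_gte(frac_in, 0.99)
})

test_that("trait generation plants the requested directions", {
    d <- MixtureDesign(seed = 1L)
    b <- generateBulk(generateProfiles(d), d)
    tr <- generateTraits(b$proportions, seed = 11L)
    z <- scale(b$proportions[, "microglia"])
    expect_gt(cor(tr$age_at_death, z), 0)          # program rises with age
    expect_lt(cor(tr$apoe_e2_count, z), 0)         # e2 reduces the program
    expect_true(all(tr$apoe_e2_count %in% 0:2))
    expect_true(all(tr$apoe_e4_count %in% 0:2))
    expect_true(all(tr$sex %in% 0:1))
    expect_identical(tr$sample_id, rownames(b$proportions))
})

test_that("disease sets carry exactly the planted overlap and round-trip as GMT", {
    universe <- sprintf("g%04d", 1:500)
    markers <- universe[1:50]
    s <- generateDiseaseSet(markers, universe, overlapCount = 7,
                            setSize = 40, seed = 3L)
    expect_length(s, 40L)
    expect_length(intersect(s, markers), 7L)
    expect_error(generateDiseaseSet(markers, universe, overlapCount = 60,
                                    setSize = 40), "infeasible")
    full <- generateDiseaseSet(markers, universe, overlapCount = 40,
                               setSize = 40, seed = 1L)
    expect_true(all(full %in% markers))

    sets <- generateDiseaseSets(markers, universe, seed = 9L)
    ov <- vapply(sets, function(x) length(intersect(x, markers)), 1L)
    expect_identical(unname(ov), c(15L, 8L, 0L, 0L, 0L))
    gmt <- withr::local_tempfile(fileext = ".gmt")
    writeGMT(sets, gmt)
    expect_identical(readGMT(gmt), sets)
})

test_that("random gene sets are not spuriously enriched (null ORA calibration)", {
    set.seed(21)
    universe <- sprintf("g%04d", 1:300)
    signature <- universe[1:40]
    ps <- replicate(1000, {
        ds <- list(s = sample(universe, 25))
        hypergeometricORA(signature, ds, universe)$p_value
    })
    # discrete upper-tail p-values are super-uniform
    expect_lte(mean(ps <= 0.05), 0.07)
    expect_gt(mean(ps <= 0.5), 0.3)
})

test_that("synthetic truth enforces its invariants", {
    expect_error(new("SyntheticTruth",
                     markerSets = list(a = c("g1", "g2"), b = c("g2")),
                     proportions = matrix(numeric(0), 0, 0),
                     traitEffects = numeric(0),
                     diseaseOverlap = integer(0)),
                 "disjoint")
    expect_error(new("SyntheticTruth",
                     markerSets = list(a = "g1"),
                     proportions = matrix(c(0.6, 0.3), 1, 2),
                     traitEffects = numeric(0),
                     diseaseOverlap = integer(0)),
                 "sum to 1")
})

test_that("aging pair plants disjoint detectable effect genes", {
    d <- MixtureDesign(nGenes = 500L, seed = 8L)
    ap <- generateAgingPair(d, nUp = 30L, nDown = 20L)
    expect_length(ap$up, 30L)
    expect_length(ap$down, 20L)
    expect_length(intersect(ap$up, ap$down), 0L)
    expect_identical(ncol(ap$aged), 10L)
    expect_identical(ncol(ap$reference), 3L)
    # planted effects sit above the detection floor in both datasets
    ref_med <- apply(exprValues(ap$reference)[c(ap$up, ap$down), ], 1,
                     median)
    expect_true(all(ref_med > 0.1))
})
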