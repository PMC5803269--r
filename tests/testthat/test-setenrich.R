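test_that("over-representation p equals exhaustive enumeration and the worked case", {
    # worked case: N=20, K=5, n=4, k=3 -> 155/4845
    universe <- sprintf("u%02d", 1:20)
    disease <- universe[1:5]
    signature <- c(universe[1:3], universe[20])        # overlap 3 of n = 4
    res <- hypergeometricORA(signature, list(ds = disease), universe)
    expect_equal(res$p_value, 155 / 4845, tolerance = 1e-12)
    expect_identical(res$overlap, 3L)
    expect_equal(res$p_value, oraEnumOracle(20, 5, 4, 3), tolerance = 1e-12)

    # counting oracle is itself validated against literal subset enumeration
    set.seed(31)
    for (i in 1:25) {
        N <- sample(4:12, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
        k <- sample(0:min(K, n), 1)
        expect_equal(oraCountingOracle(N, K, n, k), oraEnumOracle(N, K, n, k),
                     tolerance = 1e-12)
    }
})

test_that("over-representation matches enumeration for every instance with N <= 12", {
    got <- c()
    want <- c()
    for (N in 3:12) for (K in 1:(N - 1)) for (n in 1:(N - 1)) {
        universe <- sprintf("g%02d", 1:N)
        disease <- universe[1:K]
        for (k in 0:min(K, n)) {
            if (n - k > N - K) next
            signature <- c(universe[seq_len(k)],
                           universe[K + seq_len(n - k)])
            got <- c(got, hypergeometricORA(signature, list(d = disease),
                                            universe)$p_value)
            want <- c(want, oraCountingOracle(N, K, n, k))
        }
    }
    expect_equal(got, want, tolerance = 1e-12)
})

test_that("over-representation degenerate cases and monotonicity hold", {
    universe <- sprintf("g%02d", 1:20)
    # zero overlap: the upper tail from 0 is everything
    expect_equal(hypergeometricORA(universe[6:9],
                                   list(d = universe[1:5]),
                                   universe)$p_value, 1)
    # disease set = universe: overlap is certain
    res <- hypergeometricORA(universe[1:4], list(d = universe), universe)
    expect_identical(res$overlap, 4L)
    expect_equal(res$p_value, 1)
    # p nonincreasing in k at fixed N, K, n
    ps <- vapply(0:4, function(k) {
        sig <- c(universe[seq_len(k)], universe[5 + seq_len(4 - k)])
        hypergeometricORA(sig, list(d = universe[1:5]), universe)$p_value
    }, numeric(1))
    expect_true(all(diff(ps) <= 1e-15))
    expect_error(hypergeometricORA(character(), list(d = universe[1:2]),
                                   universe), "empty")
    expect_error(hypergeometricORA(universe[1:2], list(d = universe[1:2]),
                                   character()), "empty universe")
})

test_that("enrichment score matches the running-sum definition at the extremes", {
    scores <- c(a = 4, b = 3, c = 2, d = 1)
    # set = top gene, unweighted: first step reaches +1
    expect_equal(prerankedGSEA(scores, "a", weightExponent = 0,
                               nPerm = 10)$es, 1)
    # set = bottom gene: three misses of 1/(N-1) then the hit returns to 0
    expect_equal(prerankedGSEA(scores, "d", weightExponent = 0,
                               nPerm = 10)$es, -1)
    expect_error(prerankedGSEA(scores, c("x", "y")), "disjoint")
    expect_error(prerankedGSEA(scores, names(scores)), "disjoint from or")
})

test_that("enrichment score equals a brute-force scan on random instances", {
    set.seed(17)
    for (i in 1:100) {
        N <- sample(5:20, 1)
        scores <- setNames(round(rnorm(N), 3), paste0("g", seq_len(N)))
        nh <- sample(1:min(5, N - 1), 1)
        gs <- sample(names(scores), nh)
        w <- sample(c(0, 1, 1.5), 1)
        es <- prerankedGSEA(scores, gs, weightExponent = w, nPerm = 5,
                            seed = i)$es
        ord <- order(scores, decreasing = TRUE)
        oracle <- bruteForceES(scores[ord], names(scores)[ord] %in% gs, w)
        expect_equal(es, oracle, tolerance = 1e-12)
    }
})

test_that("permutation null is reproducible and p respects its support", {
    scores <- setNames(rnorm(100), paste0("g", 1:100))
    set.seed(2)
    gs <- sample(names(scores), 10)
    r1 <- prerankedGSEA(scores, gs, nPerm = 99, seed = 5)
    r2 <- prerankedGSEA(scores, gs, nPerm = 99, seed = 5)
    expect_identical(r1, r2)
    r3 <- prerankedGSEA(scores, gs, nPerm = 99, seed = 6)
    expect_false(identical(r1$perm_p, r3$perm_p))
    expect_gte(r1$perm_p, 1 / 100)
    expect_lte(r1$perm_p, 1)
    expect_true(abs(r1$es) <= 1)
})

test_that("enrichment scores agree with an independent GSEA implementation", {
    skip_if_not_installed("fgsea")
    set.seed(23)
    scores <- setNames(rnorm(200), paste0("g", 1:200))
    scores <- sort(scores, decreasing = TRUE)
    sets <- list(s1 = sample(names(scores), 12),
                 s2 = names(scores)[1:15],
                 s3 = rev(names(scores))[1:15])
    ours <- prerankedGSEA(scores, sets, weightExponent = 1, nPerm = 10,
                          seed = 1)
    theirs <- suppressWarnings(
        fgsea::fgsea(sets, scores, nPermSimple = 100, gseaParam = 1))
    expect_equal(ours$es, theirs$ES[match(ours$set_name, theirs$pathway)],
                 tolerance = 1e-9)
})
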