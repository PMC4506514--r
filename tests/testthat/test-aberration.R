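block <- function(d, c = rep(0.5, ncol(d)), role = NULL) {
    if (is.null(rownames(d))) rownames(d) <- paste0("s", seq_len(nrow(d)))
    if (is.null(colnames(d))) colnames(d) <- paste0("p", seq_len(ncol(d)))
    if (is.null(role)) role <- rep("tumour", nrow(d))
    new("GeneProbeBlock", gene = "G", change = d, normalMean = c,
        role = role)
}

test_that("gene blocks are the change tables against the panel mean", {
    set.seed(10)
    beta <- matrix(runif(5 * 8), 5, 8)
    # make the three normals identical so each equals the panel mean
    beta[, 6:8] <- beta[, 6]
    me <- tinyExperiment(beta, gene = c("A", "A", "A", "B", NA),
                         tss = c(-100, 50, 1200, 300, NA), n_normal = 3L)
    blocks <- buildGeneBlocks(me)
    expect_setequal(names(blocks), c("A", "B"))
    expect_equal(dim(blocks[["A"]]@change), c(8L, 3L))
    expect_equal(dim(blocks[["B"]]@change), c(8L, 1L))
    expect_equal(blocks[["A"]]@normalMean,
                 unname(beta[1:3, 6]), tolerance = 1e-12)
    # normals identical to the panel mean have all-zero change rows
    expect_equal(max(abs(blocks[["A"]]@change[6:8, ])), 0)

    one <- tinyExperiment(beta, gene = c("A", "A", "A", "B", NA),
                          tss = c(-100, 50, 1200, 300, NA),
                          n_normal = 1L)
    expect_error(buildGeneBlocks(one), "two normal")
})

test_that("rank-one decomposition matches the closed form and conventions", {
    # d = outer(a, b) recovers the factors exactly (up to the scale/sign
    # conventions): b = (1,2)/sqrt(5), a = (2,1,-1)*sqrt(5)/10
    d <- outer(c(2, 1, -1), c(1, 2)) / 10
    fit <- rankOneDecompose(block(d))
    expect_equal(unname(probeLoadings(fit)), c(1, 2) / sqrt(5),
                 tolerance = 1e-10)
    expect_equal(unname(sampleScores(fit)),
                 c(2, 1, -1) * sqrt(5) / 10, tolerance = 1e-10)
    expect_lt(max(abs(fit@residuals)), 1e-12)
    expect_equal(fit@explainedVariance, 1, tolerance = 1e-10)

    # single probe: loading forced to (1), scores equal the change column
    d1 <- matrix(c(0.4, -0.2, 0.1), 3, 1)
    f1 <- rankOneDecompose(block(d1))
    expect_equal(unname(probeLoadings(f1)), 1)
    expect_equal(unname(sampleScores(f1)), d1[, 1])

    # all-zero table flagged degenerate
    f0 <- rankOneDecompose(block(matrix(0, 3, 2)))
    expect_true(f0@degenerate)
    expect_equal(unname(sampleScores(f0)), c(0, 0, 0))
    expect_equal(unname(probeLoadings(f0)), c(1, 0))
})

test_that("decomposition equals the leading singular triple on random blocks", {
    set.seed(11)
    for (i in 1:20) {
        n <- sample(5:20, 1); p <- sample(2:8, 1)
        d <- matrix(runif(n * p, -1, 1), n, p)
        fit <- rankOneDecompose(block(d))
        sv <- svd(d)
        bRef <- sv$v[, 1]
        aRef <- sv$u[, 1] * sv$d[1]
        # align oracle sign to the package's convention
        if (cor(aRef, rowMeans(d)) < 0) { aRef <- -aRef; bRef <- -bRef }
        expect_lt(max(abs(unname(probeLoadings(fit)) - bRef)), 1e-8)
        expect_lt(max(abs(unname(sampleScores(fit)) - aRef)), 1e-8)
        # Pythagoras: ||d||^2 = ||ab'||^2 + ||e||^2
        expect_equal(sum(d^2),
                     sum(tcrossprod(sampleScores(fit),
                                    probeLoadings(fit))^2) +
                     sum(fit@residuals^2), tolerance = 1e-10)
        # sign convention holds
        a <- sampleScores(fit)
        if (sd(a) > 0 && sd(rowMeans(d)) > 0)
            expect_gte(cor(a, rowMeans(d)), 0)
    }
})

test_that("z-scores standardise against the normal panel", {
    mkFit <- function(gene, a) new("RankOneFit", gene = gene,
        sampleScores = a, probeLoadings = c(p1 = 1),
        residuals = matrix(0, length(a), 1), explainedVariance = 1,
        degenerate = FALSE, converged = TRUE, iterations = 1L)
    a <- c(t1 = 3, n1 = -1, n2 = 0, n3 = 1)   # normals: mean 0, sd 1
    res <- aberrationZScores(list(mkFit("G1", a)), c("n1", "n2", "n3"))
    expect_equal(res@z["t1", "G1"], 3)
    expect_equal(res@normalMean[["G1"]], 0)
    expect_equal(res@normalSD[["G1"]], 1)

    aEq <- c(t1 = 0, n1 = -1, n2 = 0, n3 = 1)  # tumour at the panel mean
    res2 <- aberrationZScores(list(mkFit("G1", aEq)), c("n1", "n2", "n3"))
    expect_equal(res2@z["t1", "G1"], 0)

    # degenerate panel hits the floor and is flagged
    aC <- c(t1 = 0.5, n1 = 0.2, n2 = 0.2, n3 = 0.2)
    res3 <- aberrationZScores(list(mkFit("G1", aC)), c("n1", "n2", "n3"))
    expect_equal(res3@flaggedGenes, "G1")
    expect_true(is.finite(res3@z["t1", "G1"]))

    # normals' z-scores have per-gene mean 0 and sd 1 by construction
    set.seed(12)
    fits <- lapply(1:10, function(i) mkFit(paste0("G", i),
        setNames(rnorm(20), c(paste0("t", 1:8), paste0("n", 1:12)))))
    resN <- aberrationZScores(fits, paste0("n", 1:12))
    zn <- resN@z[paste0("n", 1:12), ]
    expect_equal(unname(colMeans(zn)), rep(0, 10), tolerance = 1e-12)
    expect_equal(unname(apply(zn, 2, sd)), rep(1, 10), tolerance = 1e-12)
})

test_that("planted sample shifts are recovered on the z scale", {
    # shift delta on all probes of an affected sample gives a score
    # displacement ~ delta*sqrt(p), hence z ~ delta*sqrt(p)/s for noise
    # s.d. s; check the mean over 200 simulated genes within 20%
    set.seed(13)
    nT <- 20; nN <- 30; p <- 4; s <- 0.05; delta <- 0.3
    samples <- c(paste0("t", 1:nT), paste0("n", 1:nN))
    zbar <- numeric(200)
    for (g in 1:200) {
        d <- matrix(rnorm((nT + nN) * p, sd = s), nT + nN, p,
                    dimnames = list(samples, paste0("p", 1:p)))
        d[1:5, ] <- d[1:5, ] + delta
        d <- pmin(pmax(d, -1), 1)
        fit <- rankOneDecompose(block(d, c = rep(0.2, p),
            role = c(rep("tumour", nT), rep("normal", nN))))
        res <- aberrationZScores(list(fit), paste0("n", 1:nN))
        zbar[g] <- mean(res@z[paste0("t", 1:5), 1])
    }
    predicted <- delta * sqrt(p) / s
    expect_lt(abs(mean(zbar) - predicted) / predicted, 0.2)
})

test_that("the plug-in FDR curve and threshold selection follow the estimator", {
    z <- c(rep(0, 95), rep(3.5, 5))          # N = 100, R(3) = 5
    curve <- fdrCurve(z, t_grid = c(2, 3))
    expect_equal(curve$fdr[curve$T == 3], 100 * 2 * pnorm(-3) / 5,
                 tolerance = 1e-12)
    expect_equal(curve$fdr[curve$T == 3], 0.05399592, tolerance = 1e-7)
    # monotone after clean-up, tends to 0 when R(T) = 0 at large T
    curve2 <- fdrCurve(rnorm(50), t_grid = seq(0.5, 30, by = 0.5))
    expect_true(all(diff(curve2$fdr) <= 0))
    expect_lt(curve2$fdr[nrow(curve2)], 1e-10)
    expect_error(fdrCurve(z, numeric()), "grid")
    expect_error(fdrCurve(z, c(2, 1)), "increasing")

    expect_equal(as.numeric(selectThreshold(
        data.frame(T = c(2, 3), fdr = c(0.20, 0.04)), q = 0.05)), 3)
    expect_error(selectThreshold(data.frame(T = 1, fdr = 0.5), q = 1.2),
                 "q")
    expect_warning(t0 <- selectThreshold(
        data.frame(T = c(2, 3), fdr = c(0.5, 0.2)), q = 0.05),
        "grid maximum")
    expect_equal(as.numeric(t0), 3)
    expect_false(attr(t0, "qualified"))
})

test_that("aberration calls use a strict threshold and both directions", {
    z <- matrix(c(2, -3.5, 3, 1), 2, 2,
                dimnames = list(c("t1", "t2"), c("G1", "G2")))
    res <- new("AberrationResult", z = z,
               normalMean = c(0, 0), normalSD = c(1, 1),
               tumourIds = c("t1", "t2"), normalIds = character(),
               fdrCurve = data.frame(T = 3, fdr_raw = 0.01, fdr = 0.01),
               threshold = 3, q = 0.05,
               calls = data.frame(), flaggedGenes = character(),
               sigmaFloor = 1e-8)
    calls <- callAberrations(res)
    # z = 3 equals the threshold: not called (strict inequality)
    expect_false(any(calls$sample_id == "t1" & calls$gene == "G2"))
    expect_equal(calls$direction[calls$sample_id == "t2" &
                                 calls$gene == "G1"], "hypo")
})

test_that("the aberration stage is invariant to probe and sample order", {
    sim <- simulateCohort(smallConfig(seed = 14L))
    me <- preprocessMethylation(sim$experiment, fraction = 0.05)$complete
    r1 <- callMethylationAberrations(me)
    set.seed(15)
    me2 <- me[sample(nrow(me)), sample(ncol(me))]
    r2 <- callMethylationAberrations(me2)
    expect_equal(r1@threshold, r2@threshold)
    key <- function(r) {
        k <- paste(r@calls$sample_id, r@calls$gene, r@calls$direction)
        sort(k)
    }
    expect_identical(key(r1), key(r2))
    expect_equal(r1@z[rownames(r2@z), colnames(r2@z)], r2@z,
                 tolerance = 1e-6)
})
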