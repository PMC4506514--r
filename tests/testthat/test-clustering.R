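test_that("hierarchical clustering behaves on degenerate and planted cases", {
    set.seed(3)
    x <- matrix(runif(8 * 20), 8, 20)
    rownames(x) <- paste0("s", 1:8)
    cl1 <- clusterMethylation(x, k = 1)
    expect_true(all(clusterLabels(cl1) == 1L))
    expect_error(clusterMethylation(x, k = 0), "k")
    expect_error(clusterMethylation(x, k = 9), "k")

    # byte-identical samples merge first, so they always co-cluster
    x2 <- x; x2["s5", ] <- x2["s1", ]
    for (k in 2:7) {
        lab <- clusterLabels(clusterMethylation(x2, k = k))
        expect_equal(lab[["s1"]], lab[["s5"]])
    }
})

test_that("well-separated planted clusters are recovered exactly", {
    sim <- simulateCohort(smallConfig(cluster_effect = 0.35, seed = 31L))
    pp <- preprocessMethylation(sim$experiment, fraction = 0.1)
    cl <- clusterMethylation(pp$reduced, k = 4)
    truth <- sim$truth$cluster[names(clusterLabels(cl))]
    expect_equal(ari(clusterLabels(cl), truth), 1.0)

    # partition invariant to sample order (up to canonical relabelling)
    x <- t(betaValues(pp$reduced))
    perm <- sample(nrow(x))
    lab1 <- clusterLabels(clusterMethylation(x, k = 4))
    lab2 <- clusterLabels(clusterMethylation(x[perm, ], k = 4))
    expect_equal(ari(lab1[rownames(x)], lab2[rownames(x)]), 1.0)
})

test_that("rank-sum p-values are exact for small groups and handle ties", {
    set.seed(4)
    # oracle: full enumeration over all relabelings, group sizes <= 8
    for (sizes in list(c(4, 4), c(5, 3), c(8, 6))) {
        x <- matrix(runif(6 * sum(sizes)), 6)
        colnames(x) <- paste0("s", seq_len(sum(sizes)))
        ga <- colnames(x)[seq_len(sizes[1])]
        gb <- setdiff(colnames(x), ga)
        dp <- differentialProbes(x, ga, gb)
        oracle <- apply(x, 1L, function(v)
            enumWilcoxP(v[ga], v[gb]))
        expect_equal(dp$p_value, unname(oracle), tolerance = 1e-12)
        expect_true(all(dp$exact))
    }

    # identical values in both groups: p exactly 1
    xi <- matrix(rep(runif(5), each = 8), 5, 8, byrow = TRUE)
    colnames(xi) <- paste0("s", 1:8)
    dpi <- differentialProbes(xi, paste0("s", 1:4), paste0("s", 5:8))
    expect_true(all(dpi$p_value == 1))

    # tie-corrected normal approximation agrees with wilcox.test
    xt <- matrix(sample(seq(0, 1, by = 0.1), 26 * 4, replace = TRUE),
                 4, 26)
    colnames(xt) <- paste0("s", 1:26)
    ga <- paste0("s", 1:13); gb <- paste0("s", 14:26)
    dpt <- differentialProbes(xt, ga, gb, exact_max = 5L)
    ref <- apply(xt, 1L, function(v)
        suppressWarnings(wilcox.test(v[ga], v[gb], correct = FALSE,
                                     exact = FALSE)$p.value))
    expect_equal(dpt$p_value, unname(ref), tolerance = 1e-10)

    expect_error(differentialProbes(xt, ga, c(gb, "s1")), "overlap")
    expect_error(differentialProbes(xt, character(), gb), "non-empty")
})

test_that("complete separation crosses the 1e-8 threshold at 16 but not 15 per group", {
    mk <- function(n) {
        b <- matrix(c(runif(n, 0.7, 0.9), runif(n, 0.1, 0.3)), 1)
        colnames(b) <- paste0("s", seq_len(2 * n))
        rownames(b) <- "cg001"
        b
    }
    set.seed(5)
    b16 <- mk(16)
    dp16 <- differentialProbes(b16, paste0("s", 1:16), paste0("s", 17:32))
    expect_equal(dp16$p_value, 2 / choose(32, 16))
    expect_true(dp16$pass)

    b15 <- mk(15)
    dp15 <- differentialProbes(b15, paste0("s", 1:15), paste0("s", 16:30))
    expect_equal(dp15$p_value, 2 / choose(30, 15))
    expect_false(dp15$pass)   # 1.29e-8 misses the 1e-8 cut
})

test_that("probe-level type-I error is controlled under the global null", {
    set.seed(6)
    P <- 2000
    x <- matrix(runif(P * 20), P, 20)
    colnames(x) <- paste0("s", 1:20)
    dp <- differentialProbes(x, paste0("s", 1:10), paste0("s", 11:20))
    alpha <- 0.05
    expect_lte(mean(dp$p_value < alpha), alpha + 3 * sqrt(alpha / P))
    expect_false(any(dp$p_value < 1e-8))
})

test_that("gene summaries roll up passing promoter probes", {
    ann <- probeAnnotation(sprintf("cg%03d", 1:10),
                           chrom = rep("1", 10),
                           gene = c(rep("GENE1", 8), "GENE2", NA),
                           tss_distance = c(rep(100, 9), NA))
    empty <- data.frame(probe_id = sprintf("cg%03d", 1:10),
                       p_value = rep(0.5, 10), fold_change = rep(1, 10),
                       direction = rep("hyper_in_A", 10),
                       exact = rep(TRUE, 10), pass = rep(FALSE, 10))
    expect_equal(nrow(summarizeGenes(empty, ann)), 0L)

    tab <- empty
    tab$pass[1:8] <- TRUE
    tab$fold_change[1:8] <- 3
    gs <- summarizeGenes(tab, ann)
    expect_equal(gs$gene[1], "GENE1")
    expect_equal(gs$n_probes[1], 8L)
})

test_that("a planted hypermethylated gene dominates the cluster contrast", {
    # 18 vs 18 samples: complete separation reaches p = 2/C(36,18) < 1e-8
    sim <- simulateCohort(smallConfig(seed = 8L, missing_rate = 0,
        n_samples_per_cluster = c(E1 = 9L, E2 = 9L, A1 = 9L, A2 = 9L),
        aberrant_gene_plan = list(list(gene = "g0005",
                                       clusters = c("E1", "E2"),
                                       direction = "hyper",
                                       effect = 0.45))))
    me <- sim$experiment
    truth <- sim$truth$cluster
    ga <- names(truth)[truth %in% c("E1", "E2")]
    gb <- names(truth)[truth %in% c("A1", "A2")]
    dp <- differentialProbes(me, ga, gb)
    gs <- summarizeGenes(dp, probeInfo(me))
    hit <- gs[gs$gene == "g0005" & gs$direction == "hyper_in_A", ]
    expect_equal(nrow(hit), 1L)
    nProm <- sum(probeInfo(me)$gene %in% "g0005" & probeInfo(me)$promoter)
    expect_equal(hit$n_probes, nProm)   # every promoter probe passes
})
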