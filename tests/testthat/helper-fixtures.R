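# shared fixtures and independent oracles

# small synthetic-cohort configuration for fast end-to-end tests
smallConfig <- function(seed = 1L, ...) {
    args <- list(n_samples_per_cluster = c(E1 = 6L, E2 = 6L,
                                           A1 = 8L, A2 = 5L),
                 n_normals = 12L,
                 n_genes = 80L, probes_per_gene = c(2L, 5L),
                 n_intergenic_probes = 300L, n_xy_probes = 40L,
                 n_cluster_probes = 50L, missing_rate = 0.01,
                 seed = seed)
    args[names(list(...))] <- list(...)
    do.call(cohortConfig, args)
}

# a hand-built MethylationExperiment with known structure
tinyExperiment <- function(beta, chrom = NULL, gene = NULL,
                           tss = NULL, n_normal = 0L) {
    p <- nrow(beta)
    if (is.null(rownames(beta)))
        rownames(beta) <- sprintf("cg%03d", seq_len(p))
    if (is.null(colnames(beta)))
        colnames(beta) <- sprintf("s%02d", seq_len(ncol(beta)))
    if (is.null(chrom)) chrom <- rep("1", p)
    if (is.null(gene)) gene <- rep(NA_character_, p)
    if (is.null(tss)) tss <- ifelse(is.na(gene), NA_real_, 0)
    ann <- probeAnnotation(rownames(beta), chrom, gene, tss)
    role <- c(rep("tumour", ncol(beta) - n_normal),
              rep("normal", n_normal))
    MethylationExperiment(beta, ann, role)
}

# exact two-sided rank-sum p by full enumeration over relabelings
enumWilcoxP <- function(a, b) {
    v <- c(a, b)
    nA <- length(a)
    combos <- utils::combn(length(v), nA)
    r <- rank(v)
    ws <- apply(combos, 2L, function(idx) sum(r[idx]))
    wObs <- sum(r[seq_len(nA)])
    lo <- mean(ws <= wObs)
    hi <- mean(ws >= wObs)
    min(1, 2 * min(lo, hi))
}

# two-sided Fisher p by enumeration over tables with fixed margins
enumFisherP <- function(a, b, c, d) {
    m <- a + c; n <- b + d; k <- a + b
    support <- max(0, k - n):min(k, m)
    pr <- dhyper(support, m, n, k)
    pObs <- dhyper(a, m, n, k)
    sum(pr[pr <= pObs * (1 + 1e-7)])
}

ari <- function(x, y) mclust::adjustedRandIndex(x, y)
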