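#' Configuration for a synthetic methylation cohort
#'
#' Describes a fully specified synthetic study: four planted tumour
#' clusters plus a normal skeletal-muscle-style reference panel, a
#' 450K-style probe manifest with per-gene promoter probe groups,
#' intergenic and X/Y probes, planted per-gene methylation aberrations,
#' missing entries, and cluster-correlated mutation and survival tables.
#' Every random draw is governed by the single `seed`; identical
#' configurations with the same seed reproduce byte-identical outputs.
#'
#' Beta values are drawn from per-probe Beta distributions in three
#' classes (low-methylated shape (2,18), intermediate (5,5), high (18,2))
#' mixed with `class_weights`, matching the bimodal character of 450K
#' arrays. Cluster structure and planted aberrations are applied as shifts
#' of the Beta mean with a redraw at the same concentration, so values
#' stay in (0,1); shifted means are clipped into [0.02, 0.98] with a
#' clip counter kept in the ground truth.
#'
#' @param n_samples_per_cluster named positive integers, tumours per
#'   planted cluster (default `c(E1 = 11, E2 = 11, A1 = 18, A2 = 10)`).
#' @param n_normals normal-panel size (default 48).
#' @param n_genes number of genes with promoter probe groups
#'   (default 2000).
#' @param probes_per_gene inclusive integer range of promoter probes per
#'   gene (default `c(2, 8)`).
#' @param n_intergenic_probes autosomal probes without a gene
#'   (default 5000).
#' @param n_xy_probes probes on chromosomes X/Y (default 400).
#' @param baseline_beta_concentration list of Beta shape pairs per probe
#'   class (`low`, `intermediate`, `high`).
#' @param class_weights mixing weights of the probe classes.
#' @param cluster_effect mean-beta shift applied to each cluster's own
#'   probe set (default 0.3; 0 disables cluster structure).
#' @param n_cluster_probes number of probes shifted per cluster
#'   (default 300).
#' @param aberrant_gene_plan list of planted aberrations, each a list with
#'   `gene`, `clusters` (cluster names) or `samples` (explicit ids),
#'   `direction` ("hyper"/"hypo") and `effect` (mean-beta shift). The
#'   default plants one tumour-suppressor-style gene hypermethylated in
#'   clusters E1/E2 only.
#' @param missing_rate fraction of entries masked as missing
#'   (default 0.01).
#' @param mutation_rate_by_cluster named list: selector (gene or pathway
#'   tag) -> named per-cluster mutation probability.
#' @param survival_hazard_by_cluster positive per-month exponential hazard
#'   per cluster.
#' @param censoring_rate probability a subject is censored (default 0.3).
#' @param seed integer master seed.
#' @return A validated configuration of class `"SyntheticCohortConfig"`.
#' @export
cohortConfig <- function(
    n_samples_per_cluster = c(E1 = 11L, E2 = 11L, A1 = 18L, A2 = 10L),
    n_normals = 48L,
    n_genes = 2000L,
    probes_per_gene = c(2L, 8L),
    n_intergenic_probes = 5000L,
    n_xy_probes = 400L,
    baseline_beta_concentration = list(low = c(2, 18),
                                       intermediate = c(5, 5),
                                       high = c(18, 2)),
    class_weights = c(low = 0.45, intermediate = 0.15, high = 0.40),
    cluster_effect = 0.3,
    n_cluster_probes = 300L,
    aberrant_gene_plan = list(list(gene = "g0001",
                                   clusters = c("E1", "E2"),
                                   direction = "hyper", effect = 0.4)),
    missing_rate = 0.01,
    mutation_rate_by_cluster = list(
        "FGFR4/RAS/AKT" = c(E1 = 0.55, E2 = 0.82, A1 = 0.17, A2 = 0.20),
        "TP53" = c(E1 = 0.02, E2 = 0.45, A1 = 0.11, A2 = 0.10)),
    survival_hazard_by_cluster = c(E1 = 0.010, E2 = 0.035,
                                   A1 = 0.012, A2 = 0.018),
    censoring_rate = 0.3,
    seed = 1L) {
    cfg <- list(n_samples_per_cluster = n_samples_per_cluster,
                n_normals = as.integer(n_normals),
                n_genes = as.integer(n_genes),
                probes_per_gene = as.integer(probes_per_gene),
                n_intergenic_probes = as.integer(n_intergenic_probes),
                n_xy_probes = as.integer(n_xy_probes),
                baseline_beta_concentration = baseline_beta_concentration,
                class_weights = class_weights,
                cluster_effect = cluster_effect,
                n_cluster_probes = as.integer(n_cluster_probes),
                aberrant_gene_plan = aberrant_gene_plan,
                missing_rate = missing_rate,
                mutation_rate_by_cluster = mutation_rate_by_cluster,
                survival_hazard_by_cluster = survival_hazard_by_cluster,
                censoring_rate = censoring_rate,
                seed = as.integer(seed))
    .validateCohortConfig(cfg)
    structure(cfg, class = "SyntheticCohortConfig")
}

.validateCohortConfig <- function(cfg) {
    with(cfg, {
        if (is.null(names(n_samples_per_cluster)) ||
            any(n_samples_per_cluster < 1L))
            stop("n_samples_per_cluster must be named positive integers")
        if (n_normals < 1L) stop("n_normals must be positive")
        if (n_genes < 1L) stop("n_genes must be positive")
        if (length(probes_per_gene) != 2L || any(probes_per_gene < 1L) ||
            probes_per_gene[1] > probes_per_gene[2])
            stop("probes_per_gene must be a positive integer range")
        if (n_intergenic_probes < 0L || n_xy_probes < 0L)
            stop("probe counts must be non-negative")
        for (sh in baseline_beta_concentration)
            if (any(sh <= 0)) stop("Beta shapes must be positive")
        if (abs(sum(class_weights) - 1) > 1e-8 || any(class_weights < 0))
            stop("class_weights must be non-negative and sum to 1")
        if (missing_rate < 0 || missing_rate >= 1)
            stop("missing_rate must lie in [0, 1)")
        if (censoring_rate < 0 || censoring_rate >= 1)
            stop("censoring_rate must lie in [0, 1)")
        for (r in mutation_rate_by_cluster)
            if (any(r < 0 | r > 1))
                stop("mutation rates must lie in [0, 1]")
        if (any(survival_hazard_by_cluster <= 0))
            stop("survival hazards must be positive")
        for (p in aberrant_gene_plan) {
            if (is.null(p$gene) || is.null(p$direction) || is.null(p$effect))
                stop("each aberration plan entry needs gene/direction/effect")
            if (!p$direction %in% c("hyper", "hypo"))
                stop("aberration direction must be 'hyper' or 'hypo'")
        }
        invisible(TRUE)
    })
}

# deterministic per-table sub-streams from the master seed
.subSeeds <- function(seed, n = 6L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sample.int(2147483646L, n)
}

#' Generate the synthetic probe manifest
#'
#' Builds the probe annotation for a configuration: per-gene promoter
#' probe groups (every promoter probe within 1,500 bp of the transcription
#' start site), intergenic autosomal probes, and X/Y-chromosome probes.
#' Probe ids are unique.
#'
#' @param config a [cohortConfig()].
#' @return A `DataFrame` as from [probeAnnotation()].
#' @export
simulateManifest <- function(config) {
    stopifnot(inherits(config, "SyntheticCohortConfig"))
    seeds <- .subSeeds(config$seed)
    set.seed(seeds[1])
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    ppg <- seq.int(config$probes_per_gene[1], config$probes_per_gene[2])
    npp <- ppg[sample.int(length(ppg), config$n_genes, replace = TRUE)]
    geneCol <- rep(genes, times = npp)
    tss <- sample(-1500:1500, sum(npp), replace = TRUE)
    chromGene <- rep(sample(as.character(1:22), config$n_genes,
                            replace = TRUE), times = npp)
    nInter <- config$n_intergenic_probes
    nXY <- config$n_xy_probes
    chrom <- c(chromGene,
               sample(as.character(1:22), nInter, replace = TRUE),
               sample(c("X", "Y"), nXY, replace = TRUE))
    gene <- c(geneCol, rep(NA_character_, nInter + nXY))
    tssAll <- c(tss, rep(NA_real_, nInter + nXY))
    ids <- sprintf("cg%06d", seq_along(chrom))
    probeAnnotation(ids, chrom, gene, tssAll)
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Draws the beta matrix (tumours with planted cluster structure and
#' planted per-gene aberrations; normals from the baseline distributions
#' only), masks missing entries, and generates cluster-correlated
#' mutation and clinical tables. Identical config and seed give
#' byte-identical outputs.
#'
#' @param config a [cohortConfig()].
#' @return list with elements
#'   \describe{
#'     \item{experiment}{a [MethylationExperiment-class] (tumours +
#'       normals, missing entries masked).}
#'     \item{annotation}{the probe manifest.}
#'     \item{mutations}{data.frame (sample_id, gene, pathway, mutated).}
#'     \item{clinical}{data.frame (sample_id, cluster_truth, histology,
#'       os_months, event).}
#'     \item{truth}{ground truth: `cluster` (named labels),
#'       `aberrant` (gene, sample_id, direction), `cluster_probes`,
#'       `clip_count`, and the generating rates.}
#'   }
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "SyntheticCohortConfig"))
    annot <- simulateManifest(config)
    seeds <- .subSeeds(config$seed)
    clusters <- names(config$n_samples_per_cluster)
    tumourIds <- unlist(lapply(clusters, function(cl)
        sprintf("tumour_%s_%02d", cl,
                seq_len(config$n_samples_per_cluster[[cl]]))),
        use.names = FALSE)
    clusterOf <- setNames(rep(clusters, config$n_samples_per_cluster),
                          tumourIds)
    normalIds <- sprintf("normal_%02d", seq_len(config$n_normals))
    samples <- c(tumourIds, normalIds)
    P <- nrow(annot)
    S <- length(samples)

    set.seed(seeds[2])
    cls <- sample(names(config$class_weights), P, replace = TRUE,
                  prob = config$class_weights)
    # planted genes get the promoter baseline their aberration departs
    # from: unmethylated (CpG-island-like) for hyper plans, methylated
    # for hypo plans — so the planted shift is realisable within (0,1)
    for (p in config$aberrant_gene_plan) {
        rows <- which(!is.na(annot$gene) & annot$gene == p$gene &
                      annot$promoter)
        cls[rows] <- if (p$direction == "hyper") "low" else "high"
    }
    shapes <- do.call(rbind, config$baseline_beta_concentration[cls])
    a1 <- shapes[, 1]; a2 <- shapes[, 2]
    beta <- matrix(rbeta(P * S, a1, a2), nrow = P,
                   dimnames = list(annot$probe_id, samples))
    clip <- 0L
    redraw <- function(rows, cols, shift) {
        mu <- a1[rows] / (a1[rows] + a2[rows])
        nu <- a1[rows] + a2[rows]
        mu2 <- mu + shift
        clipped <- mu2 < 0.02 | mu2 > 0.98
        clip <<- clip + sum(clipped) * length(cols)
        mu2 <- pmin(pmax(mu2, 0.02), 0.98)
        k <- length(rows)
        beta[rows, cols] <<- matrix(
            rbeta(k * length(cols), mu2 * nu, (1 - mu2) * nu), nrow = k)
    }
    # cluster-specific probe sets, disjoint, autosomal, outside planted genes
    planGenes <- vapply(config$aberrant_gene_plan, function(p) p$gene,
                        character(1))
    eligible <- which(!(annot$chrom %in% c("X", "Y")) &
                      !(annot$gene %in% planGenes))
    clusterProbes <- list()
    if (config$cluster_effect > 0 && config$n_cluster_probes > 0) {
        pool <- sample(eligible)
        for (ci in seq_along(clusters)) {
            take <- pool[seq_len(config$n_cluster_probes) +
                         (ci - 1L) * config$n_cluster_probes]
            # shift towards the interior so the full effect is realisable
            dir <- ifelse(a1[take] / (a1[take] + a2[take]) >= 0.5, -1, 1)
            cols <- tumourIds[clusterOf == clusters[ci]]
            up <- take[dir > 0]; dn <- take[dir < 0]
            if (length(up)) redraw(up, cols, config$cluster_effect)
            if (length(dn)) redraw(dn, cols, -config$cluster_effect)
            clusterProbes[[clusters[ci]]] <- annot$probe_id[take]
        }
    }
    # planted per-gene aberrations on all promoter probes of the gene
    truthAb <- list()
    for (p in config$aberrant_gene_plan) {
        rows <- which(!is.na(annot$gene) & annot$gene == p$gene &
                      annot$promoter)
        if (!length(rows))
            stop("aberration plan names gene ", p$gene,
                 " with no promoter probes")
        cols <- if (!is.null(p$samples)) p$samples else
            tumourIds[clusterOf %in% p$clusters]
        shift <- if (p$direction == "hyper") p$effect else -p$effect
        redraw(rows, cols, shift)
        truthAb[[length(truthAb) + 1L]] <-
            data.frame(gene = p$gene, sample_id = cols,
                       direction = p$direction)
    }
    truthAb <- if (length(truthAb)) do.call(rbind, truthAb) else
        data.frame(gene = character(), sample_id = character(),
                   direction = character())

    set.seed(seeds[3])
    if (config$missing_rate > 0) {
        mask <- runif(P * S) < config$missing_rate
        beta[mask] <- NA_real_
    }

    set.seed(seeds[4])
    mut <- list()
    for (sel in names(config$mutation_rate_by_cluster)) {
        rates <- config$mutation_rate_by_cluster[[sel]]
        pr <- unname(rates[clusterOf])
        pr[is.na(pr)] <- 0
        mut[[sel]] <- data.frame(
            sample_id = tumourIds,
            gene = sel,
            pathway = if (grepl("/", sel)) sel else NA_character_,
            mutated = rbinom(length(tumourIds), 1L, pr))
    }
    mutations <- do.call(rbind, c(mut, list(make.row.names = FALSE)))

    set.seed(seeds[5])
    haz <- unname(config$survival_hazard_by_cluster[clusterOf])
    t0 <- rexp(length(tumourIds), rate = haz)
    cens <- rbinom(length(tumourIds), 1L, config$censoring_rate) == 1L
    os <- ifelse(cens, runif(length(tumourIds), 0, t0), t0)
    histology <- ifelse(substr(clusterOf, 1, 1) == "E",
                        ifelse(runif(length(tumourIds)) < 0.95,
                               "ERMS", "NOS"),
                        "ARMS")
    clinical <- data.frame(sample_id = tumourIds,
                           cluster_truth = unname(clusterOf),
                           histology = histology,
                           os_months = os,
                           event = as.integer(!cens))

    role <- setNames(c(rep("tumour", length(tumourIds)),
                       rep("normal", length(normalIds))), samples)
    me <- MethylationExperiment(beta, annot, role)
    list(experiment = me,
         annotation = annot,
         mutations = mutations,
         clinical = clinical,
         truth = list(cluster = clusterOf,
                      aberrant = truthAb,
                      cluster_probes = clusterProbes,
                      clip_count = clip,
                      mutation_rates = config$mutation_rate_by_cluster,
                      survival_hazards = config$survival_hazard_by_cluster))
}
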