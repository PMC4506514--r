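#' Published mutation counts for a 60-case rhabdomyosarcoma cohort
#'
#' Bundled transcription of the gene-by-methylation-cluster mutation
#' counts from targeted deep sequencing of 14 putative driver genes in a
#' published 60-case rhabdomyosarcoma cohort: per-gene case counts in the
#' methylation clusters E1 (n = 11), E2 (n = 11), A1 (n = 18), A2 (n = 10)
#' and the cluster-unavailable group (n = 10), plus the case-level totals
#' for the FGFR4/RAS/AKT pathway (some cases carry two pathway mutations,
#' so pathway case totals are below the per-gene sums).
#'
#' @return list with `counts` (data.frame gene, pathway, all, e1, e2, a1,
#'   a2, na), `pathway_cases` (named case totals for the FGFR4/RAS/AKT
#'   pathway) and `cluster_sizes` (named group sizes).
#' @export
rmsMutationCounts <- function() {
    dir <- system.file("extdata", package = "methylaber")
    counts <- read.csv(file.path(dir, "rms60_mutation_counts.csv"),
                       colClasses = c(gene = "character",
                                      pathway = "character"))
    pw <- read.csv(file.path(dir, "rms60_pathway_cases.csv"))
    sz <- read.csv(file.path(dir, "rms60_group_sizes.csv"))
    list(counts = counts,
         pathway_cases = setNames(pw$count, pw$group),
         cluster_sizes = setNames(sz$n, sz$group))
}

#' Reconstruct a per-sample mutation table from the published counts
#'
#' Expands the cluster-wise counts of [rmsMutationCounts()] into a
#' per-sample mutation table on 60 synthetic sample ids so that (i) every
#' per-gene, per-cluster case count is reproduced exactly and (ii) the
#' number of samples carrying at least one FGFR4/RAS/AKT pathway mutation
#' in each cluster equals the published case-level pathway totals.
#'
#' Within each cluster, pathway-gene mutations are first assigned to
#' distinct samples up to the pathway case total; surplus mutations become
#' second pathway mutations of already-mutated samples (the published
#' footnote reports such double-mutated cases). In two clusters the
#' printed per-gene rows carry one FEWER pathway mutation than the
#' case-level total; there a pathway-tagged record with the placeholder
#' gene `"FGFR4_RAS_AKT_other"` is added so the case totals — the numbers
#' the published percentages quote — are honoured. Non-pathway genes are
#' assigned to the first samples of each cluster independently.
#'
#' @return list with `mutations` (data.frame sample_id, gene, pathway,
#'   mutated = 1), `grouping` (named sample -> cluster map, clusters
#'   "E1", "E2", "A1", "A2", "NA"), and `cluster_sizes`.
#' @export
rmsTargetedCohort <- function() {
    dat <- rmsMutationCounts()
    clusters <- c("E1", "E2", "A1", "A2", "NA")
    key <- c(E1 = "e1", E2 = "e2", A1 = "a1", A2 = "a2", "NA" = "na")
    sizes <- dat$cluster_sizes[key]
    ids <- lapply(clusters, function(cl)
        sprintf("%s_%02d", sub("NA", "UNK", cl),
                seq_len(dat$cluster_sizes[[key[[cl]]]])))
    names(ids) <- clusters
    grouping <- setNames(rep(clusters, vapply(ids, length, integer(1))),
                         unlist(ids, use.names = FALSE))
    rec <- list()
    isPw <- !is.na(dat$counts$pathway)
    for (cl in clusters) {
        col <- key[[cl]]
        sam <- ids[[cl]]
        # pathway genes: cover exactly the published case total
        pwGenes <- rep(dat$counts$gene[isPw], dat$counts[[col]][isPw])
        target <- dat$pathway_cases[[col]]
        carried <- setNames(vector("list", length(sam)), sam)
        nextFresh <- 1L
        assign1 <- function(gene) {
            if (nextFresh <= min(target, length(sam))) {
                s <- sam[nextFresh]
                nextFresh <<- nextFresh + 1L
            } else {
                open <- sam[seq_len(nextFresh - 1L)]
                s <- open[!vapply(carried[open],
                                  function(g) gene %in% g, logical(1))][1]
            }
            carried[[s]] <<- c(carried[[s]], gene)
            s
        }
        for (g in pwGenes)
            rec[[length(rec) + 1L]] <- data.frame(
                sample_id = assign1(g), gene = g,
                pathway = "FGFR4/RAS/AKT", mutated = 1L)
        while (nextFresh <= target) {   # printed gene rows fall short
            rec[[length(rec) + 1L]] <- data.frame(
                sample_id = sam[nextFresh], gene = "FGFR4_RAS_AKT_other",
                pathway = "FGFR4/RAS/AKT", mutated = 1L)
            nextFresh <- nextFresh + 1L
        }
        # non-pathway genes: first samples of the cluster, per gene
        np <- dat$counts[!isPw, , drop = FALSE]
        for (i in seq_len(nrow(np))) {
            m <- np[[col]][i]
            if (m > 0)
                rec[[length(rec) + 1L]] <- data.frame(
                    sample_id = sam[seq_len(m)], gene = np$gene[i],
                    pathway = NA_character_, mutated = 1L)
        }
    }
    mutations <- do.call(rbind, rec)
    rownames(mutations) <- NULL
    list(mutations = mutations, grouping = grouping,
         cluster_sizes = setNames(unname(sizes), clusters))
}
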