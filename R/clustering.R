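#' Unsupervised hierarchical subtyping
#'
#' Agglomerative clustering of samples on the beta values of the selected
#' probes, cut into `k` flat clusters. Cluster labels are deterministic:
#' clusters are renumbered by the first sample (in input order) they
#' contain, so the partition is invariant to sample order up to this
#' canonical relabelling.
#'
#' @param me a complete [MethylationExperiment-class] (typically the
#'   `reduced` element of [preprocessMethylation()]), or a samples x probes
#'   numeric matrix.
#' @param k number of clusters (default 4).
#' @param distance distance metric passed to [stats::dist()]
#'   (default "euclidean").
#' @param linkage agglomeration rule passed to [stats::hclust()]
#'   (default "ward.D2").
#' @param samples sample ids to cluster; defaults to tumours when `me` is a
#'   [MethylationExperiment-class].
#' @return A [MethylClustering-class] object.
#' @export
clusterMethylation <- function(me, k = 4L, distance = "euclidean",
                               linkage = "ward.D2", samples = NULL) {
    if (is(me, "MethylationExperiment")) {
        if (is.null(samples)) samples <- tumourSamples(me)
        x <- t(betaValues(me)[, samples, drop = FALSE])
    } else {
        x <- as.matrix(me)
        if (!is.null(samples)) x <- x[samples, , drop = FALSE]
    }
    n <- nrow(x)
    k <- as.integer(k)
    if (k < 1L || k > n)
        stop("'k' must lie in 1..", n)
    if (anyNA(x))
        stop("clustering needs a complete matrix; impute first")
    tree <- hclust(dist(x, method = distance), method = linkage)
    raw <- cutree(tree, k = k)
    labels <- .canonicalLabels(raw, k)
    new("MethylClustering", labels = labels, k = k, tree = tree,
        distance = distance, linkage = linkage)
}

# renumber clusters by first occurrence in sample order
.canonicalLabels <- function(raw, k) {
    first <- order(match(seq_len(k), raw))
    map <- integer(k)
    map[first] <- seq_len(k)
    setNames(map[raw], names(raw))
}

#' @rdname clusterMethylation
#' @param x,object a [MethylClustering-class].
#' @param ... unused.
#' @export
setMethod("clusterLabels", "MethylClustering", function(x, ...) x@labels)

#' @rdname clusterMethylation
#' @export
setMethod("show", "MethylClustering", function(object) {
    cat("MethylClustering: ", length(object@labels), " samples in ",
        object@k, " clusters (", object@distance, " / ", object@linkage,
        ")\n", sep = "")
    print(table(cluster = object@labels))
    invisible(NULL)
})

#' Export a dendrogram in Newick format
#'
#' @param clustering a [MethylClustering-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDendrogram <- function(clustering, path) {
    write.tree(as.phylo(clustering@tree), file = path)
    invisible(path)
}
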