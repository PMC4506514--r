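setOldClass("hclust")

#' MethylationExperiment: beta values plus probe annotation and sample roles
#'
#' A \linkS4class{SummarizedExperiment} holding a single \code{"beta"} assay
#' (probes in rows, samples in columns, values in [0,1], \code{NA} allowed),
#' probe annotation in \code{rowData} (\code{chrom}, \code{gene},
#' \code{tss_distance}, \code{promoter}) and a \code{role} column in
#' \code{colData} marking each sample \code{"tumour"} or \code{"normal"}.
#'
#' Promoter probes are those annotated to a gene with an absolute
#' transcription-start-site distance of at most 1,500 bp; the per-gene
#' promoter probe sets drive the aberration model.
#'
#' @seealso [MethylationExperiment()] for the constructor,
#'   [betaValues()], [sampleRole()], [probeInfo()] for accessors.
#' @export
setClass("MethylationExperiment", contains = "SummarizedExperiment")

.validMethylationExperiment <- function(object) {
    msg <- NULL
    if (!"beta" %in% names(assays(object)))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- assay(object, "beta")
        bad <- b[!is.na(b)]
        if (length(bad) && (min(bad) < 0 || max(bad) > 1))
            msg <- c(msg, "non-missing beta values must lie in [0,1]")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "probe ids (rownames) must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be unique")
    if (!"role" %in% names(colData(object)))
        msg <- c(msg, "colData must contain a 'role' column")
    else if (!all(colData(object)$role %in% c("tumour", "normal")))
        msg <- c(msg, "sample roles must be 'tumour' or 'normal'")
    rd <- rowData(object)
    need <- c("chrom", "gene", "tss_distance", "promoter")
    if (!all(need %in% names(rd)))
        msg <- c(msg, paste("rowData must contain:",
                            paste(need, collapse = ", ")))
    else {
        expect <- !is.na(rd$gene) & !is.na(rd$tss_distance) &
            abs(rd$tss_distance) <= 1500
        if (!identical(as.logical(rd$promoter), as.logical(expect)))
            msg <- c(msg, "promoter flag inconsistent with gene/tss_distance")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("MethylationExperiment", .validMethylationExperiment)

#' GeneProbeBlock: per-gene two-way table of methylation changes
#'
#' For one gene, the matrix of methylation changes d[i,j] = x[i,j] - c[j]
#' where x is the beta value of sample i at promoter probe j and c[j] is the
#' mean beta of the normal reference panel at that probe. Rows cover all
#' analysed samples (tumours and normals); the normals' own changes are
#' taken relative to the panel mean so their fitted sample scores calibrate
#' the z-scores downstream.
#'
#' @slot gene gene symbol.
#' @slot change numeric matrix, samples x promoter probes, entries in [-1,1].
#' @slot normalMean per-probe mean beta over the normal panel, in [0,1].
#' @slot role character vector, "tumour"/"normal" per row of \code{change}.
#' @export
setClass("GeneProbeBlock", representation(
    gene = "character",
    change = "matrix",
    normalMean = "numeric",
    role = "character"
))

setValidity("GeneProbeBlock", function(object) {
    msg <- NULL
    if (ncol(object@change) < 1L)
        msg <- c(msg, "a gene block needs at least one promoter probe")
    if (length(object@normalMean) != ncol(object@change))
        msg <- c(msg, "normalMean length must equal probe count")
    if (length(object@normalMean) &&
        (min(object@normalMean) < 0 || max(object@normalMean) > 1))
        msg <- c(msg, "normal reference means must lie in [0,1]")
    d <- object@change[!is.na(object@change)]
    if (length(d) && (min(d) < -1 || max(d) > 1))
        msg <- c(msg, "change entries must lie in [-1,1]")
    if (length(object@role) != nrow(object@change))
        msg <- c(msg, "role length must equal sample count")
    if (is.null(msg)) TRUE else msg
})

#' RankOneFit: rank-one multiplicative decomposition of a gene block
#'
#' Best rank-one fit d[i,j] ~ a[i] * b[j] of a gene's change table, with
#' the probe loading vector b scaled to unit Euclidean norm and the sign of
#' (a, b) chosen so that a correlates non-negatively with the per-sample
#' mean beta over the gene's promoter probes.
#'
#' @slot gene gene symbol.
#' @slot sampleScores named numeric a, one score per sample.
#' @slot probeLoadings named numeric b, unit norm, one loading per probe.
#' @slot residuals matrix e = d - a b'.
#' @slot explainedVariance fraction of the squared mass of d captured.
#' @slot degenerate TRUE when d was all-zero (a = 0, b = first unit vector).
#' @slot converged,iterations alternating-least-squares diagnostics.
#' @export
setClass("RankOneFit", representation(
    gene = "character",
    sampleScores = "numeric",
    probeLoadings = "numeric",
    residuals = "matrix",
    explainedVariance = "numeric",
    degenerate = "logical",
    converged = "logical",
    iterations = "integer"
))

setValidity("RankOneFit", function(object) {
    msg <- NULL
    nb <- sqrt(sum(object@probeLoadings^2))
    if (!object@degenerate && abs(nb - 1) > 1e-6)
        msg <- c(msg, "probe loadings must have unit Euclidean norm")
    if (is.null(msg)) TRUE else msg
})

#' AberrationResult: z-scores, FDR curve and aberration calls
#'
#' Per-sample, per-gene z-scores of the rank-one sample scores against the
#' normal panel moments, the plug-in FDR curve over a threshold grid, the
#' selected threshold and the resulting aberration calls.
#'
#' @slot z samples x genes matrix of z-scores (tumours and normals).
#' @slot normalMean,normalSD per-gene moments of the normals' sample scores.
#' @slot tumourIds,normalIds sample id bookkeeping.
#' @slot fdrCurve data.frame with columns \code{T}, \code{fdr_raw},
#'   \code{fdr} (monotone non-increasing after a running-minimum clean-up).
#' @slot threshold selected threshold T*; calls require |z| strictly > T*.
#' @slot q target false-discovery level.
#' @slot calls data.frame (sample_id, gene, direction, z) over tumours.
#' @slot flaggedGenes genes whose normal-panel s.d. hit the floor.
#' @slot sigmaFloor the s.d. floor used.
#' @export
setClass("AberrationResult", representation(
    z = "matrix",
    normalMean = "numeric",
    normalSD = "numeric",
    tumourIds = "character",
    normalIds = "character",
    fdrCurve = "data.frame",
    threshold = "numeric",
    q = "numeric",
    calls = "data.frame",
    flaggedGenes = "character",
    sigmaFloor = "numeric"
))

setValidity("AberrationResult", function(object) {
    msg <- NULL
    if (any(!is.finite(object@z)))
        msg <- c(msg, "z-scores must be finite")
    if (nrow(object@fdrCurve) &&
        is.unsorted(rev(object@fdrCurve$fdr), strictly = FALSE))
        msg <- c(msg, "cleaned FDR curve must be non-increasing in T")
    if (is.null(msg)) TRUE else msg
})

#' MethylClustering: hierarchical subtype assignment
#'
#' Flat cluster labels from cutting an agglomerative dendrogram at k
#' clusters, relabelled deterministically so that cluster 1 contains the
#' first sample (in input order), cluster 2 the first sample not in
#' cluster 1, and so on.
#'
#' @slot labels named integer vector, one label in 1..k per sample.
#' @slot k requested number of clusters.
#' @slot tree the \code{hclust} dendrogram.
#' @slot distance,linkage the metric and agglomeration rule used.
#' @export
setClass("MethylClustering", representation(
    labels = "integer",
    k = "integer",
    tree = "hclust",
    distance = "character",
    linkage = "character"
))

setValidity("MethylClustering", function(object) {
    msg <- NULL
    if (!all(object@labels %in% seq_len(object@k)))
        msg <- c(msg, "labels must cover 1..k only")
    if (length(unique(object@labels)) != object@k)
        msg <- c(msg, "every label in 1..k must be used")
    if (is.null(names(object@labels)))
        msg <- c(msg, "labels must be named by sample id")
    if (is.null(msg)) TRUE else msg
})
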