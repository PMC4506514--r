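#' Build a MethylationExperiment from a beta matrix and probe annotation
#'
#' Assembles the central data container: a probes-by-samples beta matrix,
#' probe annotation (chromosome, gene, signed distance to the transcription
#' start site) and a tumour/normal role per sample. The promoter flag is
#' (re)computed as: annotated to a gene and |tss_distance| <= 1500 bp.
#'
#' @param beta numeric matrix, probes x samples, values in [0,1], `NA`
#'   allowed; rownames are probe ids, colnames sample ids.
#' @param annotation a `DataFrame`/`data.frame` as returned by
#'   [probeAnnotation()], covering every probe in `beta` (matched by
#'   `probe_id`).
#' @param role character vector, one of `"tumour"`/`"normal"` per sample;
#'   either unnamed in column order or named by sample id.
#' @return A [MethylationExperiment-class] object.
#' @examples
#' beta <- matrix(runif(12), 4, 3,
#'                dimnames = list(paste0("cg", 1:4), paste0("s", 1:3)))
#' ann <- probeAnnotation(paste0("cg", 1:4), chrom = c("1", "2", "2", "X"),
#'                        gene = c("TP53", NA, "PTEN", NA),
#'                        tss_distance = c(-200, NA, 900, NA))
#' me <- MethylationExperiment(beta, ann, role = c("tumour", "tumour", "normal"))
#' @export
MethylationExperiment <- function(beta, annotation, role) {
    beta <- as.matrix(beta)
    if (is.null(rownames(beta)) || is.null(colnames(beta)))
        stop("'beta' needs probe rownames and sample colnames")
    annotation <- as(annotation, "DataFrame")
    if (!"probe_id" %in% names(annotation))
        stop("annotation must have a 'probe_id' column")
    missing <- setdiff(rownames(beta), annotation$probe_id)
    if (length(missing))
        stop("probes absent from annotation: ",
             paste(head(missing, 5L), collapse = ", "),
             if (length(missing) > 5L) ", ...")
    idx <- match(rownames(beta), annotation$probe_id)
    rd <- annotation[idx, setdiff(names(annotation), "probe_id"),
                     drop = FALSE]
    rownames(rd) <- rownames(beta)
    rd$promoter <- !is.na(rd$gene) & !is.na(rd$tss_distance) &
        abs(rd$tss_distance) <= 1500
    if (!is.null(names(role)))
        role <- role[colnames(beta)]
    if (length(role) != ncol(beta))
        stop("'role' must give one role per sample")
    se <- SummarizedExperiment(
        assays = list(beta = beta),
        rowData = rd,
        colData = DataFrame(role = unname(role), row.names = colnames(beta)))
    new("MethylationExperiment", se)
}

#' Probe annotation table
#'
#' Builds the probe annotation used throughout the package. A probe is a
#' promoter probe of its gene when it is annotated to a gene and lies
#' within 1,500 bp of the transcription start site.
#'
#' @param probe_id unique probe identifiers.
#' @param chrom chromosome label per probe (e.g. "1".."22", "X", "Y").
#' @param gene gene symbol or `NA` for intergenic probes.
#' @param tss_distance signed distance (bp) to the gene's transcription
#'   start site; `NA` for probes without a gene.
#' @return A `DataFrame` with the input columns plus a `promoter` flag.
#' @export
probeAnnotation <- function(probe_id, chrom, gene, tss_distance) {
    probe_id <- as.character(probe_id)
    if (anyDuplicated(probe_id))
        stop("probe ids must be unique")
    gene <- as.character(gene)
    tss_distance <- as.numeric(tss_distance)
    DataFrame(probe_id = probe_id,
              chrom = as.character(chrom),
              gene = gene,
              tss_distance = tss_distance,
              promoter = !is.na(gene) & !is.na(tss_distance) &
                  abs(tss_distance) <= 1500)
}

#' Accessors for MethylationExperiment
#'
#' `betaValues()` returns the beta assay, `sampleRole()` the tumour/normal
#' role vector (named by sample), `probeInfo()` the probe annotation
#' (`rowData` plus `probe_id`).
#'
#' @param x a [MethylationExperiment-class].
#' @param ... unused.
#' @name betaValues
#' @aliases betaValues,MethylationExperiment-method
#' @export
setMethod("betaValues", "MethylationExperiment", function(x, ...)
    assay(x, "beta"))

#' @rdname betaValues
#' @export
setMethod("sampleRole", "MethylationExperiment", function(x, ...)
    setNames(colData(x)$role, colnames(x)))

#' @rdname betaValues
#' @export
setMethod("probeInfo", "MethylationExperiment", function(x, ...) {
    rd <- rowData(x)
    DataFrame(probe_id = rownames(x), rd)
})

#' @rdname betaValues
#' @param object a [MethylationExperiment-class].
#' @export
setMethod("show", "MethylationExperiment", function(object) {
    role <- colData(object)$role
    cat("MethylationExperiment:", nrow(object), "probes x",
        ncol(object), "samples\n")
    cat("  tumours:", sum(role == "tumour"),
        " normals:", sum(role == "normal"), "\n")
    b <- assay(object, "beta")
    cat("  promoter probes:", sum(rowData(object)$promoter),
        " missing beta:", sprintf("%.2f%%", 100 * mean(is.na(b))), "\n")
    invisible(NULL)
})

#' Subset helpers
#'
#' `tumourSamples()` / `normalSamples()` return the sample ids with the
#' respective role.
#'
#' @param x a [MethylationExperiment-class].
#' @export
tumourSamples <- function(x) colnames(x)[colData(x)$role == "tumour"]

#' @rdname tumourSamples
#' @export
normalSamples <- function(x) colnames(x)[colData(x)$role == "normal"]
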