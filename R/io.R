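#' Read and write the package's plain-text table dialects
#'
#' Beta matrices travel as TSV with probes as rows, samples as columns, a
#' header of sample ids and `NA` for missing cells. Manifests are CSV
#' (`probe_id`, `chrom`, `gene`, `tss_distance`); mutation and clinical
#' tables are TSV. All writers are loss-free round-trips of the readers.
#'
#' @param path file path.
#' @return `readBetaMatrix()` returns a numeric probes x samples matrix
#'   with values validated into [0,1] and missing entries preserved.
#' @name methylationIO
#' @export
readBetaMatrix <- function(path) {
    raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                      na.strings = character(0))
    probes <- raw[[1]]
    if (anyDuplicated(probes))
        stop("duplicate probe ids in ", path)
    if (anyDuplicated(names(raw)[-1]))
        stop("duplicate sample ids in ", path)
    m <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
                dimnames = list(probes, names(raw)[-1]))
    for (j in seq_len(ncol(m))) {
        cell <- raw[[j + 1L]]
        val <- suppressWarnings(as.numeric(cell))
        bad <- which(is.na(val) & !(cell %in% c("NA", "", "NaN")))
        if (length(bad))
            stop("malformed numeric cell at row '", probes[bad[1]],
                 "', column '", colnames(m)[j], "': '", cell[bad[1]], "'")
        out <- which(!is.na(val) & (val < 0 | val > 1))
        if (length(out))
            stop("beta value outside [0,1] at row '", probes[out[1]],
                 "', column '", colnames(m)[j], "': ", val[out[1]])
        m[, j] <- val
    }
    m
}

#' @rdname methylationIO
#' @param x matrix (or [MethylationExperiment-class]) to write.
#' @export
writeBetaMatrix <- function(x, path) {
    m <- if (is(x, "MethylationExperiment")) betaValues(x) else as.matrix(x)
    df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' @rdname methylationIO
#' @export
readProbeAnnotation <- function(path) {
    df <- read.csv(path, colClasses = c(probe_id = "character",
                                        chrom = "character",
                                        gene = "character",
                                        tss_distance = "numeric"))
    probeAnnotation(df$probe_id, df$chrom, df$gene, df$tss_distance)
}

#' @rdname methylationIO
#' @param annot a probe annotation `DataFrame`.
#' @export
writeProbeAnnotation <- function(annot, path) {
    df <- as.data.frame(annot)[, c("probe_id", "chrom", "gene",
                                   "tss_distance")]
    write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
    invisible(path)
}

#' @rdname methylationIO
#' @export
readMutationTable <- function(path) {
    read.delim(path, colClasses = c(sample_id = "character",
                                    gene = "character",
                                    pathway = "character",
                                    mutated = "integer"))
}

#' @rdname methylationIO
#' @param table a data.frame in the respective dialect.
#' @export
writeMutationTable <- function(table, path) {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' @rdname methylationIO
#' @export
readClinicalTable <- function(path) {
    read.delim(path, colClasses = c(sample_id = "character"))
}

#' @rdname methylationIO
#' @export
writeClinicalTable <- function(table, path) {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Assemble a MethylationExperiment from files
#'
#' @param beta_path beta-matrix TSV (tumours and normals as columns).
#' @param manifest_path probe-manifest CSV.
#' @param normal_ids sample ids to mark as the normal panel; all other
#'   samples are tumours.
#' @return A [MethylationExperiment-class].
#' @export
readMethylationExperiment <- function(beta_path, manifest_path,
                                      normal_ids = character()) {
    beta <- readBetaMatrix(beta_path)
    annot <- readProbeAnnotation(manifest_path)
    role <- ifelse(colnames(beta) %in% normal_ids, "normal", "tumour")
    MethylationExperiment(beta, annot, role)
}
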