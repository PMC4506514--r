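#' Beta/M-value conversion
#'
#' `betaToM()` maps methylation fractions to the M scale,
#' M = log2(beta / (1 - beta)), after clipping beta into
#' [eps, 1 - eps] so boundary values stay finite. `mToBeta()` is the
#' inverse, beta = 2^M / (1 + 2^M). Missing entries pass through unchanged.
#'
#' @param beta numeric vector or matrix of beta values in [0,1].
#' @param m numeric vector or matrix of M values.
#' @param eps clip constant for the logit-type transform (default 1e-6).
#' @return An object of the same shape on the other scale.
#' @examples
#' betaToM(c(0.5, 0.8, 0.2))   # 0, 2, -2
#' mToBeta(betaToM(0.37))      # 0.37
#' @export
betaToM <- function(beta, eps = 1e-6) {
    x <- as.numeric(beta)
    bad <- which(!is.na(x) & (x < 0 | x > 1))
    if (length(bad)) {
        where <- .coordLabel(beta, bad)
        stop("beta values outside [0,1] at: ",
             paste(head(where, 5L), collapse = ", "),
             if (length(bad) > 5L) ", ...")
    }
    out <- beta
    out[] <- log2(pmin(pmax(beta, eps), 1 - eps) /
                  (1 - pmin(pmax(beta, eps), 1 - eps)))
    out
}

#' @rdname betaToM
#' @export
mToBeta <- function(m) {
    out <- m
    out[] <- 2^m / (1 + 2^m)
    out
}

.coordLabel <- function(x, idx) {
    if (is.matrix(x)) {
        rc <- arrayInd(idx, dim(x))
        rn <- rownames(x); cn <- colnames(x)
        paste0("[", if (is.null(rn)) rc[, 1] else rn[rc[, 1]], ", ",
               if (is.null(cn)) rc[, 2] else cn[rc[, 2]], "]")
    } else {
        paste0("[", idx, "]")
    }
}

#' Impute missing entries by an iterative low-rank fit
#'
#' EM-style completion on the M scale: missing cells are initialised at the
#' probe (row) mean, then the matrix is repeatedly replaced by its rank-r
#' truncated SVD reconstruction at the missing positions until successive
#' imputations change by less than `tol` (max absolute difference).
#' Observed entries are never altered. This is the package's own iterative
#' SVD/EM completion, in the probabilistic-PCA family of imputers commonly
#' used for incomplete methylation arrays.
#'
#' @param m numeric matrix (probes x samples) with `NA` for missing cells.
#' @param rank rank of the low-rank fit (default 5; capped at
#'   `min(dim(m)) - 1` or 1 for degenerate shapes).
#' @param max_iter iteration cap (default 500); a warning is raised and the
#'   last iterate returned when it is hit.
#' @param tol convergence tolerance on the imputed cells (default 1e-6).
#' @return The completed matrix, with attributes `iterations` and
#'   `converged`.
#' @export
imputeMissing <- function(m, rank = 5L, max_iter = 500L, tol = 1e-6) {
    m <- as.matrix(m)
    miss <- is.na(m)
    if (!any(miss)) {
        attr(m, "iterations") <- 0L
        attr(m, "converged") <- TRUE
        return(m)
    }
    if (any(rowSums(!miss) == 0L))
        stop("rows with no observed entries; filter them before imputation")
    if (any(colSums(!miss) == 0L))
        stop("columns with no observed entries; filter them before imputation")
    r <- max(1L, min(as.integer(rank), min(dim(m)) - 1L, min(dim(m))))
    rowMu <- rowMeans(m, na.rm = TRUE)
    x <- m
    x[miss] <- rowMu[row(m)[miss]]
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
        it <- it + 1L
        sv <- svd(x, nu = r, nv = r)
        recon <- sv$u %*% (sv$d[seq_len(r)] * t(sv$v))
        delta <- max(abs(recon[miss] - x[miss]))
        x[miss] <- recon[miss]
        if (delta < tol) {
            converged <- TRUE
            break
        }
    }
    if (!converged)
        warning("imputation did not converge in ", max_iter,
                " iterations (last change ", signif(delta, 3), ")")
    attr(x, "iterations") <- it
    attr(x, "converged") <- converged
    x
}

#' Remove probes on the X and Y chromosomes
#'
#' Restricts a [MethylationExperiment-class] to autosomal probes, preserving
#' probe order and values (pure subsetting). Chromosome labels "X", "Y",
#' "chrX", "chrY" (case-insensitive) are treated as sex chromosomes.
#'
#' @param me a [MethylationExperiment-class].
#' @return The object restricted to autosomal probes.
#' @export
filterSexProbes <- function(me) {
    chrom <- sub("^chr", "", as.character(rowData(me)$chrom),
                 ignore.case = TRUE)
    if (anyNA(chrom))
        stop("probes without chromosome annotation: ",
             paste(head(rownames(me)[is.na(chrom)], 5L), collapse = ", "))
    keep <- !(toupper(chrom) %in% c("X", "Y"))
    if (!any(keep))
        stop("all probes map to X/Y; refusing to return an empty matrix")
    me[keep, ]
}

#' Select the top-variance probes
#'
#' Keeps the `floor(fraction * P)` probes with the highest unbiased sample
#' variance of beta values, computed across the chosen samples (tumours by
#' default, matching the use of the selection as clustering input). Ties
#' are broken deterministically by probe id, ascending.
#'
#' @param me a complete (imputed) [MethylationExperiment-class].
#' @param fraction fraction of probes to keep, in (0, 1] (default 0.01).
#' @param samples sample ids over which to compute the variance; defaults
#'   to the tumour samples.
#' @return The reduced [MethylationExperiment-class]; the selected probe ids
#'   are in `metadata(.)$selected_probes` (in decreasing-variance order).
#' @export
selectVariableProbes <- function(me, fraction = 0.01,
                                 samples = tumourSamples(me)) {
    if (!is.numeric(fraction) || length(fraction) != 1L ||
        fraction <= 0 || fraction > 1)
        stop("'fraction' must lie in (0, 1]")
    if (length(samples) < 2L)
        stop("variance needs at least two samples")
    b <- betaValues(me)[, samples, drop = FALSE]
    if (anyNA(b))
        stop("matrix has missing entries; impute before probe selection")
    n <- ncol(b)
    mu <- rowMeans(b)
    v <- rowSums((b - mu)^2) / (n - 1)
    nkeep <- floor(fraction * nrow(b))
    if (nkeep < 1L)
        stop("fraction * probe count is below 1; nothing to select")
    ord <- order(-v, rownames(b))
    sel <- rownames(b)[ord[seq_len(nkeep)]]
    out <- me[match(sel, rownames(me)), ]
    metadata(out)$selected_probes <- sel
    out
}

#' Run the preprocessing pipeline
#'
#' Fixed stage order: beta to M, low-rank imputation on M, M back to beta,
#' X/Y probe removal, then top-variance probe selection on the beta scale.
#' Returns both the complete autosomal matrix (input to the aberration
#' model) and the variance-reduced matrix (input to clustering).
#'
#' @param me a [MethylationExperiment-class] (missing entries allowed).
#' @param rank imputation rank (default 5).
#' @param fraction top-variance fraction (default 0.01).
#' @param max_iter,tol imputation controls, see [imputeMissing()].
#' @return A list with elements `complete` (imputed, autosomes only) and
#'   `reduced` (top-variance probes only), both
#'   [MethylationExperiment-class] objects.
#' @export
preprocessMethylation <- function(me, rank = 5L, fraction = 0.01,
                                  max_iter = 500L, tol = 1e-6) {
    b <- betaValues(me)
    if (anyNA(b)) {
        m <- betaToM(b)
        m <- imputeMissing(m, rank = rank, max_iter = max_iter, tol = tol)
        b2 <- mToBeta(m)
        b2[!is.na(b)] <- b[!is.na(b)]   # observed values untouched
        se <- me
        assay(se, "beta") <- b2
    } else {
        se <- me
    }
    se <- filterSexProbes(se)
    reduced <- selectVariableProbes(se, fraction = fraction)
    list(complete = se, reduced = reduced)
}
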