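#' Build per-gene promoter change tables against the normal panel
#'
#' For each gene with at least one promoter probe present in the matrix,
#' forms the two-way change table d[i,j] = x[i,j] - c[j], where x is the
#' beta value of sample i at promoter probe j and c[j] is the mean beta of
#' the normal reference panel at that probe. Rows cover all samples
#' (tumours and normals); the normals' rows are their deviations from
#' their own panel mean. Genes whose promoter probes are all absent from
#' the matrix are skipped with a message.
#'
#' @param me a complete [MethylationExperiment-class] containing at least
#'   two normal samples.
#' @return A named list of [GeneProbeBlock-class] objects, one per gene.
#' @export
buildGeneBlocks <- function(me) {
    b <- betaValues(me)
    if (anyNA(b))
        stop("gene blocks need complete beta values; impute first")
    normals <- normalSamples(me)
    if (length(normals) < 2L)
        stop("at least two normal samples are required")
    info <- probeInfo(me)
    prom <- info[info$promoter & !is.na(info$gene), , drop = FALSE]
    genes <- unique(as.character(prom$gene))
    blocks <- vector("list", length(genes))
    names(blocks) <- genes
    for (g in genes) {
        probes <- prom$probe_id[prom$gene == g]
        probes <- probes[probes %in% rownames(b)]
        if (!length(probes)) {
            message("gene ", g, " has no promoter probes in the matrix; ",
                    "skipped")
            next
        }
        x <- t(b[probes, , drop = FALSE])       # samples x probes
        cj <- colMeans(x[normals, , drop = FALSE])
        d <- sweep(x, 2L, cj)
        blocks[[g]] <- new("GeneProbeBlock", gene = g, change = d,
                           normalMean = unname(cj),
                           role = unname(sampleRole(me)[rownames(d)]))
    }
    blocks[!vapply(blocks, is.null, logical(1))]
}

#' Rank-one multiplicative decomposition of a gene's change table
#'
#' Fits the multiplicative model d[i,j] = a[i] * b[j] + e[i,j] by
#' alternating least squares: the per-sample methylation score a and
#' per-probe loading b that minimise the squared residual. On complete
#' data the fixed point is the leading singular triple of d. Missing
#' cells, if any, are handled by restricting each least-squares update to
#' observed entries. Scale is fixed by ||b|| = 1; the sign of (a, b) is
#' chosen so that a correlates non-negatively with the per-sample mean
#' beta over the gene's probes (falling back to a non-negative largest
#' |a| entry when that correlation is undefined).
#'
#' @param block a [GeneProbeBlock-class].
#' @param tol convergence tolerance on the loading vector (default 1e-12).
#' @param max_iter iteration cap (default 10000).
#' @return A [RankOneFit-class].
#' @export
rankOneDecompose <- function(block, tol = 1e-12, max_iter = 10000L) {
    d <- block@change
    n <- nrow(d); p <- ncol(d)
    obs <- !is.na(d)
    complete <- all(obs)
    d0 <- d
    d0[!obs] <- 0
    if (all(d0 == 0)) {
        b <- c(1, numeric(p - 1L))
        fit <- new("RankOneFit", gene = block@gene,
                   sampleScores = setNames(numeric(n), rownames(d)),
                   probeLoadings = setNames(b, colnames(d)),
                   residuals = d0, explainedVariance = 0,
                   degenerate = TRUE, converged = TRUE, iterations = 0L)
        return(fit)
    }
    # init b from the column with the largest observed mass
    j0 <- which.max(colSums(d0^2))
    a <- d0[, j0]
    if (all(a == 0)) a <- rowSums(d0)
    b <- rep(1 / sqrt(p), p)
    it <- 0L
    converged <- FALSE
    repeat {
        it <- it + 1L
        if (complete) {
            a <- drop(d %*% b)                      # ||b|| = 1
            bn <- drop(crossprod(d, a))
        } else {
            a <- vapply(seq_len(n), function(i) {
                o <- obs[i, ]
                den <- sum(b[o]^2)
                if (den == 0) 0 else sum(d[i, o] * b[o]) / den
            }, numeric(1))
            bn <- vapply(seq_len(p), function(j) {
                o <- obs[, j]
                den <- sum(a[o]^2)
                if (den == 0) 0 else sum(d[o, j] * a[o]) / den
            }, numeric(1))
        }
        nb <- sqrt(sum(bn^2))
        if (nb == 0) break
        bn <- bn / nb
        delta <- min(max(abs(bn - b)), max(abs(bn + b)))  # sign-agnostic
        b <- bn
        if (delta < tol || it >= max_iter) {
            converged <- delta < tol
            break
        }
    }
    if (complete) a <- drop(d %*% b)
    # sign convention: a proportional to the per-sample mean beta level
    meanBeta <- rowMeans(sweep(d0, 2L, block@normalMean, `+`))
    s <- if (sd(a) > 0 && sd(meanBeta) > 0) cor(a, meanBeta) else 0
    if (s == 0) s <- sign(a[which.max(abs(a))])
    if (s < 0) { a <- -a; b <- -b }
    e <- d - tcrossprod(a, b)
    ss <- sum(d0^2)
    ev <- if (ss > 0) 1 - sum(e[obs]^2) / ss else 0
    new("RankOneFit", gene = block@gene,
        sampleScores = setNames(a, rownames(d)),
        probeLoadings = setNames(b, colnames(d)),
        residuals = e, explainedVariance = ev,
        degenerate = FALSE, converged = converged, iterations = it)
}

#' @rdname rankOneDecompose
#' @param x,object a [RankOneFit-class].
#' @param ... unused.
#' @export
setMethod("sampleScores", "RankOneFit", function(x, ...) x@sampleScores)

#' @rdname rankOneDecompose
#' @export
setMethod("probeLoadings", "RankOneFit", function(x, ...) x@probeLoadings)

#' @rdname rankOneDecompose
#' @export
setMethod("show", "RankOneFit", function(object) {
    cat("RankOneFit for gene ", object@gene, ": ",
        length(object@sampleScores), " samples x ",
        length(object@probeLoadings), " probes; explained variance ",
        sprintf("%.3f", object@explainedVariance),
        if (object@degenerate) " (degenerate)", "\n", sep = "")
    invisible(NULL)
})

#' z-scores of sample methylation scores against the normal panel
#'
#' For each gene, the mean and standard deviation of the fitted sample
#' scores over the normal panel define the reference moments; every
#' sample's score is standardised as z = (a - mean) / max(sd, sigma_floor).
#' Genes whose panel s.d. falls below the floor are flagged.
#'
#' @param fits list of [RankOneFit-class], as from [rankOneDecompose()]
#'   over [buildGeneBlocks()].
#' @param normal_ids sample ids of the normal panel (>= 2).
#' @param sigma_floor lower bound for the panel s.d. (default 1e-8).
#' @return A partial [AberrationResult-class] with `z`, moments and sample
#'   bookkeeping filled; FDR fields are completed by
#'   [fdrCurve()] / [selectThreshold()] / [callAberrations()], or use
#'   [callMethylationAberrations()] for the whole chain.
#' @export
aberrationZScores <- function(fits, normal_ids, sigma_floor = 1e-8) {
    if (length(normal_ids) < 2L)
        stop("at least two normal samples are required")
    samples <- names(fits[[1]]@sampleScores)
    for (f in fits)
        if (!identical(names(f@sampleScores), samples))
            stop("all decompositions must cover the same sample set")
    genes <- unname(vapply(fits, function(f) f@gene, character(1)))
    a <- vapply(fits, function(f) f@sampleScores,
                numeric(length(samples)))     # samples x genes
    dimnames(a) <- list(samples, genes)
    an <- a[normal_ids, , drop = FALSE]
    mu <- colMeans(an)
    sigma <- apply(an, 2L, sd)
    flagged <- genes[sigma < sigma_floor]
    z <- sweep(sweep(a, 2L, mu), 2L, pmax(sigma, sigma_floor), `/`)
    new("AberrationResult",
        z = z, normalMean = mu, normalSD = sigma,
        tumourIds = setdiff(samples, normal_ids),
        normalIds = as.character(normal_ids),
        fdrCurve = data.frame(T = numeric(), fdr_raw = numeric(),
                              fdr = numeric()),
        threshold = NA_real_, q = NA_real_,
        calls = data.frame(sample_id = character(), gene = character(),
                           direction = character(), z = numeric()),
        flaggedGenes = flagged, sigmaFloor = sigma_floor)
}

#' Plug-in FDR curve over a threshold grid
#'
#' For each threshold T in the grid, estimates the false-discovery rate of
#' declaring aberrations at |z| > T by the Gaussian plug-in
#' FDR-hat(T) = min(1, N * 2 * Phi(-T) / max(1, R(T))), where N is the
#' number of tumour-sample-by-gene tests and R(T) the number of observed
#' exceedances. The returned curve is made monotone non-increasing in T by
#' a running minimum.
#'
#' @param z matrix (or vector) of tumour z-scores.
#' @param t_grid increasing grid of positive thresholds
#'   (default `seq(0.5, 10, by = 0.05)`).
#' @return data.frame with columns `T`, `fdr_raw`, `fdr`.
#' @export
fdrCurve <- function(z, t_grid = seq(0.5, 10, by = 0.05)) {
    if (!length(t_grid))
        stop("threshold grid must be non-empty")
    if (is.unsorted(t_grid, strictly = TRUE) || any(t_grid <= 0))
        stop("threshold grid must be strictly increasing and positive")
    az <- sort(abs(as.numeric(z)))
    N <- length(az)
    if (!N) stop("no z-scores supplied")
    R <- N - findInterval(t_grid, az)        # #{|z| > T}
    raw <- pmin(1, N * 2 * pnorm(-t_grid) / pmax(1, R))
    data.frame(T = t_grid, fdr_raw = raw, fdr = cummin(raw))
}

#' Select the aberration threshold from an FDR curve
#'
#' The smallest grid threshold whose estimated FDR is at or below the
#' target level `q`. When no grid point qualifies, the maximum grid
#' threshold is returned with a warning (and downstream calls are empty).
#'
#' @param curve a data.frame from [fdrCurve()].
#' @param q target FDR level in (0, 1) (default 0.05).
#' @return The selected threshold, with attribute `qualified` saying
#'   whether any grid point met the target.
#' @export
selectThreshold <- function(curve, q = 0.05) {
    if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
        stop("'q' must lie in (0, 1)")
    ok <- which(curve$fdr <= q)
    if (!length(ok)) {
        warning("no threshold reaches the target FDR level ", q,
                "; using the grid maximum (no calls will qualify)")
        return(structure(max(curve$T), qualified = FALSE))
    }
    structure(curve$T[min(ok)], qualified = TRUE)
}

#' Aberration calls at a threshold
#'
#' Declares gene k aberrant in tumour sample i when |z[i,k]| strictly
#' exceeds the selected threshold; direction is "hyper" for z > T and
#' "hypo" for z < -T.
#'
#' @param result an [AberrationResult-class] with `z` filled.
#' @param threshold the threshold T* (defaults to `result@threshold`).
#' @return data.frame (sample_id, gene, direction, z), tumour samples only.
#' @name callAberrations
#' @export
callAberrations <- function(result, threshold = result@threshold) {
    if (is.na(threshold))
        stop("no threshold set; run fdrCurve()/selectThreshold() first")
    zt <- result@z[result@tumourIds, , drop = FALSE]
    hit <- which(abs(zt) > threshold, arr.ind = TRUE)
    if (!nrow(hit))
        return(data.frame(sample_id = character(), gene = character(),
                          direction = character(), z = numeric()))
    zv <- zt[hit]
    out <- data.frame(sample_id = rownames(zt)[hit[, 1]],
                      gene = colnames(zt)[hit[, 2]],
                      direction = ifelse(zv > 0, "hyper", "hypo"),
                      z = zv)
    out[order(out$gene, out$sample_id), , drop = FALSE]
}

#' Full aberration analysis of a methylation experiment
#'
#' Chains [buildGeneBlocks()], [rankOneDecompose()], [aberrationZScores()],
#' [fdrCurve()], [selectThreshold()] and [callAberrations()].
#'
#' @param me a complete [MethylationExperiment-class] with tumour and
#'   normal samples.
#' @param q target FDR level (default 0.05).
#' @param t_grid threshold grid (default `seq(0.5, 10, by = 0.05)`).
#' @param sigma_floor panel s.d. floor (default 1e-8).
#' @return A completed [AberrationResult-class].
#' @export
callMethylationAberrations <- function(me, q = 0.05,
                                       t_grid = seq(0.5, 10, by = 0.05),
                                       sigma_floor = 1e-8) {
    blocks <- buildGeneBlocks(me)
    if (!length(blocks))
        stop("no gene has promoter probes in the matrix")
    fits <- lapply(blocks, rankOneDecompose)
    res <- aberrationZScores(fits, normalSamples(me),
                             sigma_floor = sigma_floor)
    curve <- fdrCurve(res@z[res@tumourIds, , drop = FALSE], t_grid)
    tstar <- selectThreshold(curve, q)
    res@fdrCurve <- curve
    res@threshold <- as.numeric(tstar)
    res@q <- q
    res@calls <- if (isFALSE(attr(tstar, "qualified")))
        data.frame(sample_id = character(), gene = character(),
                   direction = character(), z = numeric())
    else callAberrations(res)
    res
}

#' @rdname callAberrations
#' @param x,object an [AberrationResult-class].
#' @param ... unused.
#' @export
setMethod("zScores", "AberrationResult", function(x, ...) x@z)

#' @rdname callAberrations
#' @export
setMethod("aberrationCalls", "AberrationResult", function(x, ...) x@calls)

#' @rdname fdrCurve
#' @param x an [AberrationResult-class].
#' @param ... unused.
#' @export
setMethod("fdrThreshold", "AberrationResult", function(x, ...) x@threshold)

#' @rdname callAberrations
#' @export
setMethod("show", "AberrationResult", function(object) {
    cat("AberrationResult: ", length(object@tumourIds), " tumours x ",
        ncol(object@z), " genes\n", sep = "")
    if (!is.na(object@threshold))
        cat("  threshold T* = ", object@threshold, " (q = ", object@q,
            "); ", nrow(object@calls), " aberration calls\n", sep = "")
    if (length(object@flaggedGenes))
        cat("  ", length(object@flaggedGenes),
            " genes hit the panel s.d. floor\n", sep = "")
    invisible(NULL)
})
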