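#' Differentially methylated probes between two sample groups
#'
#' Per-probe two-sided Wilcoxon rank-sum test of group A versus group B on
#' beta values, plus a fold change on group mean beta. The p-value is exact
#' (full rank-sum null distribution) when the smaller group has at most
#' `exact_max` samples and the probe has no tied values; otherwise a
#' tie-corrected normal approximation (mid-ranks, no continuity
#' correction) is used. A probe passes when p < `p_threshold` and its fold
#' change exceeds `fc_threshold` in either direction.
#'
#' @param me a complete [MethylationExperiment-class] or probes x samples
#'   beta matrix.
#' @param groupA,groupB disjoint, non-empty sample id sets.
#' @param p_threshold probe-level p-value cut-off (default 1e-8).
#' @param fc_threshold fold-change cut-off on the beta-ratio scale
#'   (default 2; a probe passes direction-symmetrically when the ratio is
#'   > `fc_threshold` or < 1/`fc_threshold`).
#' @param exact_max largest min-group size for the exact null (default 25).
#' @return A `DataFrame` with columns `probe_id`, `p_value`, `fold_change`
#'   (mean beta A / mean beta B), `direction` ("hyper_in_A"/"hyper_in_B"),
#'   `exact`, and `pass`.
#' @export
differentialProbes <- function(me, groupA, groupB,
                               p_threshold = 1e-8, fc_threshold = 2,
                               exact_max = 25L) {
    b <- if (is(me, "MethylationExperiment")) betaValues(me) else
        as.matrix(me)
    if (is.null(rownames(b)))
        rownames(b) <- sprintf("probe_%05d", seq_len(nrow(b)))
    groupA <- as.character(groupA); groupB <- as.character(groupB)
    if (!length(groupA) || !length(groupB))
        stop("both groups must be non-empty")
    if (length(intersect(groupA, groupB)))
        stop("groups overlap: ",
             paste(head(intersect(groupA, groupB), 5L), collapse = ", "))
    missing <- setdiff(c(groupA, groupB), colnames(b))
    if (length(missing))
        stop("unknown samples: ", paste(head(missing, 5L), collapse = ", "))
    xa <- b[, groupA, drop = FALSE]
    xb <- b[, groupB, drop = FALSE]
    if (anyNA(xa) || anyNA(xb))
        stop("differential testing needs complete beta values; impute first")
    nA <- length(groupA); nB <- length(groupB)
    # exact null CDF of the Mann-Whitney U statistic, computed once
    exactCdf <- if (min(nA, nB) <= exact_max)
        pwilcox(0:(nA * nB), nA, nB) else NULL
    p <- numeric(nrow(b))
    exact <- logical(nrow(b))
    for (i in seq_len(nrow(b))) {
        v <- c(xa[i, ], xb[i, ])
        r <- rank(v)
        ties <- anyDuplicated(v) > 0L
        W <- sum(r[seq_len(nA)])
        U <- W - nA * (nA + 1) / 2
        if (!ties && !is.null(exactCdf)) {
            lo <- exactCdf[U + 1]                      # P(U <= u)
            hi <- 1 - if (U >= 1) exactCdf[U] else 0   # P(U >= u)
            p[i] <- min(1, 2 * min(lo, hi))
            exact[i] <- TRUE
        } else {
            sigma2 <- .rankSumVar(v, nA, nB)
            if (sigma2 <= 0) {
                p[i] <- 1   # all values tied: no evidence either way
            } else {
                z <- (U - nA * nB / 2) / sqrt(sigma2)
                p[i] <- min(1, 2 * pnorm(-abs(z)))
            }
        }
    }
    muA <- rowMeans(xa)
    muB <- rowMeans(xb)
    fc <- muA / muB
    pass <- (p < p_threshold) & (fc > fc_threshold | fc < 1 / fc_threshold)
    DataFrame(probe_id = rownames(b),
              p_value = p,
              fold_change = fc,
              direction = ifelse(fc >= 1, "hyper_in_A", "hyper_in_B"),
              exact = exact,
              pass = pass)
}

# tie-corrected variance of the Mann-Whitney U under the null
.rankSumVar <- function(v, nA, nB) {
    n <- nA + nB
    tab <- table(v)
    tieTerm <- sum(tab^3 - tab)
    nA * nB / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
}

#' Gene-level roll-up of passing promoter probes
#'
#' Counts, per gene and direction, the promoter probes that pass the
#' differential thresholds, ranking genes by passing-probe count and then
#' by the strongest |log2 fold change| among their passing probes.
#'
#' @param table the output of [differentialProbes()].
#' @param annot a probe annotation (`DataFrame` with `probe_id`, `gene`,
#'   `promoter`), e.g. [probeInfo()] of the experiment.
#' @return A `DataFrame` (gene, direction, n_probes, max_abs_log2_fc),
#'   ranked; empty when nothing passes.
#' @export
summarizeGenes <- function(table, annot) {
    annot <- as(annot, "DataFrame")
    idx <- match(table$probe_id, annot$probe_id)
    if (anyNA(idx))
        stop("probes absent from annotation: ",
             paste(head(table$probe_id[is.na(idx)], 5L), collapse = ", "))
    keep <- table$pass & annot$promoter[idx] & !is.na(annot$gene[idx])
    if (!any(keep))
        return(DataFrame(gene = character(), direction = character(),
                         n_probes = integer(),
                         max_abs_log2_fc = numeric()))
    df <- data.frame(gene = as.character(annot$gene[idx][keep]),
                     direction = table$direction[keep],
                     l2fc = abs(log2(table$fold_change[keep])))
    agg <- do.call(rbind, lapply(split(df, paste(df$gene, df$direction)),
        function(g) data.frame(gene = g$gene[1], direction = g$direction[1],
                               n_probes = nrow(g),
                               max_abs_log2_fc = max(g$l2fc))))
    agg <- agg[order(-agg$n_probes, -agg$max_abs_log2_fc, agg$gene), ]
    rownames(agg) <- NULL
    as(agg, "DataFrame")
}
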