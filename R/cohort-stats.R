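#' Mutation frequency by sample group
#'
#' Counts, per group, the samples carrying at least one mutation in the
#' selected genes (or pathway); a sample with several qualifying mutations
#' is counted once. Percentages are reported to one decimal.
#'
#' @param mutations data.frame with columns `sample_id`, `gene`,
#'   optionally `pathway`, and `mutated` (0/1); one row per
#'   (sample, gene) pair.
#' @param grouping named vector mapping sample id to group label; samples
#'   outside the grouping are ignored.
#' @param genes character vector of gene symbols to select, or `NULL`.
#' @param pathway single pathway tag to select, or `NULL`. At least one of
#'   `genes`/`pathway` must be given; when both are given a record
#'   qualifies if it matches either.
#' @return data.frame (group, count, total, percent) in the order the
#'   groups first appear in `grouping`.
#' @export
mutationFrequency <- function(mutations, grouping, genes = NULL,
                              pathway = NULL) {
    if (is.null(genes) && is.null(pathway))
        stop("select at least one gene or a pathway")
    if (!is.null(genes) && !length(genes))
        stop("empty gene selector")
    stopifnot(all(c("sample_id", "gene", "mutated") %in% names(mutations)))
    groups <- unique(unname(grouping))
    sel <- rep(FALSE, nrow(mutations))
    if (!is.null(genes))
        sel <- sel | mutations$gene %in% genes
    if (!is.null(pathway)) {
        if (!"pathway" %in% names(mutations))
            stop("mutation table has no 'pathway' column")
        sel <- sel | (!is.na(mutations$pathway) &
                      mutations$pathway %in% pathway)
    }
    hit <- unique(mutations$sample_id[sel & mutations$mutated == 1])
    out <- do.call(rbind, lapply(groups, function(g) {
        ids <- names(grouping)[grouping == g]
        cnt <- sum(ids %in% hit)
        data.frame(group = g, count = cnt, total = length(ids),
                   percent = round(100 * cnt / max(1L, length(ids)), 1))
    }))
    rownames(out) <- NULL
    out
}

#' Per-sample mutation burden
#'
#' Total mutation count per sample from a long-format mutation list (one
#' row per mutation), with an overall mean. Intended for whole-exome or
#' targeted mutation lists.
#'
#' @param mutations data.frame with a `sample_id` column and one row per
#'   mutation (a `mutated` column, if present, restricts to rows with 1).
#' @param samples optional sample ids to include (zero counts reported for
#'   samples with no mutations).
#' @return list with `per_sample` (data.frame sample_id, n_mutations),
#'   `mean` and `total`.
#' @export
mutationBurden <- function(mutations, samples = NULL) {
    stopifnot("sample_id" %in% names(mutations))
    if ("mutated" %in% names(mutations))
        mutations <- mutations[mutations$mutated == 1, , drop = FALSE]
    if (is.null(samples))
        samples <- unique(mutations$sample_id)
    n <- vapply(samples, function(s) sum(mutations$sample_id == s),
                integer(1))
    list(per_sample = data.frame(sample_id = as.character(samples),
                                 n_mutations = as.integer(n)),
         mean = mean(n), total = sum(n))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test with the two-sided p-value defined as the sum
#' of probabilities of tables (with the observed margins) no more likely
#' than the observed one. Thin wrapper over [stats::fisher.test()],
#' returning the conditional-MLE odds ratio.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise:
#'   rbind(c(a, b), c(c, d)).
#' @return list with `odds_ratio`, `p_value` and the `table`.
#' @examples
#' fisherExact2x2(2, 0, 0, 2)$p_value  # 1/3
#' @export
fisherExact2x2 <- function(a, b, c, d) {
    counts <- c(a, b, c, d)
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers")
    if (sum(counts) < 1) stop("table total must be at least 1")
    tab <- matrix(as.integer(counts), 2L, 2L, byrow = TRUE)
    ft <- fisher.test(tab)
    list(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
         table = tab)
}

#' Two-sample t-test on counts
#'
#' Welch's unequal-variance t-test by default (Satterthwaite degrees of
#' freedom); set `variant = "student"` for the pooled-variance form.
#' Degenerate zero-variance inputs are resolved explicitly: equal-mean
#' constant groups give p = 1, unequal-mean constant groups p = 0 with a
#' `degenerate` flag.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param variant "welch" (default) or "student".
#' @return list with `t`, `df`, `p_value`, `degenerate`.
#' @export
ttestCounts <- function(a, b, variant = c("welch", "student")) {
    variant <- match.arg(variant)
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least two values")
    if (var(a) == 0 && var(b) == 0) {
        if (mean(a) == mean(b))
            return(list(t = 0, df = NA_real_, p_value = 1,
                        degenerate = TRUE))
        return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
                    p_value = 0, degenerate = TRUE))
    }
    tt <- t.test(a, b, var.equal = (variant == "student"))
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, degenerate = FALSE)
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator per group via [survival::survfit()], returned
#' as plain step points (event/censoring times with the survival just
#' after each time). Empty groups are skipped with a warning.
#'
#' @param times non-negative follow-up times.
#' @param events event indicator (1 = death, 0 = censored).
#' @param groups group label per subject (single group if missing).
#' @return named list of data.frames (time, survival, n_risk, n_event).
#' @export
kmEstimate <- function(times, events, groups = NULL) {
    stopifnot(all(times >= 0), all(events %in% c(0, 1)))
    if (is.null(groups)) groups <- rep("all", length(times))
    groups <- as.character(groups)
    keep <- !is.na(groups)
    if (!all(keep)) {
        warning(sum(!keep), " subjects without group label skipped")
        times <- times[keep]; events <- events[keep]
        groups <- groups[keep]
    }
    out <- list()
    for (g in unique(groups)) {
        idx <- groups == g
        if (!any(idx)) { warning("empty group ", g, " skipped"); next }
        sf <- survfit(Surv(times[idx], events[idx]) ~ 1)
        out[[g]] <- data.frame(time = sf$time, survival = sf$surv,
                               n_risk = sf$n.risk, n_event = sf$n.event)
    }
    out
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square on one degree of freedom via
#' [survival::survdiff()].
#'
#' @param times non-negative follow-up times.
#' @param events event indicator (1 = death, 0 = censored).
#' @param groups two-level group label per subject.
#' @return list with `chisq`, `df`, `p_value`.
#' @export
logrankTest <- function(times, events, groups) {
    groups <- as.character(groups)
    lev <- unique(groups)
    if (length(lev) != 2L || any(table(groups) == 0L))
        stop("exactly two non-empty groups are required")
    fit <- survdiff(Surv(times, events) ~ groups)
    df <- length(fit$n) - 1L
    list(chisq = unname(fit$chisq), df = df,
         p_value = pchisq(fit$chisq, df = df, lower.tail = FALSE))
}
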