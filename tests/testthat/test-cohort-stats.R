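test_that("mutation frequencies count samples once and reaggregate", {
    mut <- data.frame(
        sample_id = c("s1", "s1", "s2", "s3", "s5"),
        gene = c("FGFR4", "NRAS", "TP53", "NRAS", "KRAS"),
        pathway = c("RAS", "RAS", NA, "RAS", "RAS"),
        mutated = c(1L, 1L, 1L, 1L, 0L))
    grp <- setNames(c("g1", "g1", "g2", "g2", "g2"), paste0("s", 1:5))
    # s1 has two pathway hits but counts once; s5 is mutated = 0
    freq <- mutationFrequency(mut, grp, pathway = "RAS")
    expect_equal(freq$count, c(1L, 1L))
    expect_equal(freq$percent, c(50.0, 33.3))
    # disjoint groups reaggregate exactly to the cohort count
    whole <- mutationFrequency(mut, setNames(rep("all", 5), paste0("s", 1:5)),
                               pathway = "RAS")
    expect_equal(sum(freq$count), whole$count)

    empty <- mutationFrequency(mut[0, ], grp, genes = "TP53")
    expect_equal(empty$count, c(0L, 0L))
    expect_equal(empty$percent, c(0, 0))
    expect_error(mutationFrequency(mut, grp), "gene or a pathway")
    expect_error(mutationFrequency(mut, grp, genes = character()), "empty")
})

test_that("mutation burden summarises per-sample counts", {
    mut <- data.frame(sample_id = c("a", "a", "a", "b"),
                      gene = c("X1", "X2", "X3", "X1"))
    bur <- mutationBurden(mut, samples = c("a", "b", "c"))
    expect_equal(bur$per_sample$n_mutations, c(3L, 1L, 0L))
    expect_equal(bur$mean, 4 / 3)
    expect_equal(bur$total, 4L)
})

test_that("Fisher exact p equals margin-constrained enumeration", {
    expect_equal(fisherExact2x2(2, 0, 0, 2)$p_value, 1 / 3,
                 tolerance = 1e-12)
    expect_equal(fisherExact2x2(0, 5, 0, 7)$p_value, 1)  # degenerate margin
    expect_error(fisherExact2x2(-1, 2, 3, 4), "non-negative")

    set.seed(16)
    for (i in 1:25) {
        tab <- as.vector(rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
        got <- do.call(fisherExact2x2, as.list(tab))$p_value
        want <- enumFisherP(tab[1], tab[2], tab[3], tab[4])
        expect_equal(got, want, tolerance = 1e-9)
    }
})

test_that("t-tests on counts follow the Welch form and its symmetries", {
    same <- ttestCounts(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$t, 0)
    expect_equal(same$p_value, 1)

    ab <- ttestCounts(c(1, 2, 3), c(4, 5, 6))
    expect_equal(ab$t, -3 / sqrt(2 / 3), tolerance = 1e-12)  # -3.674...
    ba <- ttestCounts(c(4, 5, 6), c(1, 2, 3))
    expect_equal(ba$t, -ab$t)
    expect_equal(ba$p_value, ab$p_value)

    degEq <- ttestCounts(c(2, 2), c(2, 2))
    expect_true(degEq$degenerate)
    expect_equal(degEq$p_value, 1)
    degNe <- ttestCounts(c(2, 2), c(5, 5))
    expect_true(degNe$degenerate)
    expect_equal(degNe$p_value, 0)
    expect_error(ttestCounts(1, c(1, 2)), "two values")
})

test_that("Kaplan-Meier estimates match the product-limit closed form", {
    km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))[["all"]]
    expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

    cens <- kmEstimate(c(1, 2, 3), c(0, 0, 0))[["all"]]
    expect_true(all(cens$survival == 1))

    # no censoring: KM equals the empirical survival function
    set.seed(17)
    t0 <- rexp(40, 0.2)
    km2 <- kmEstimate(t0, rep(1, 40))[["all"]]
    emp <- vapply(km2$time, function(s) mean(t0 > s), numeric(1))
    expect_equal(km2$survival, emp, tolerance = 1e-12)

    # consistency with the exponential closed form at the median
    lam <- 0.1
    t1 <- rexp(500, lam)
    km3 <- kmEstimate(t1, rep(1, 500))[["all"]]
    med <- log(2) / lam
    at <- max(which(km3$time <= med))
    expect_lt(abs(km3$survival[at] - exp(-lam * km3$time[at])), 0.05)
})

test_that("log-rank behaves on identical, relabelled and null data", {
    tm <- c(1, 3, 5, 7, 9, 2, 4, 6)
    ev <- rep(1, 8)
    g <- rep(c("x", "y"), 4)
    same <- logrankTest(rep(tm, 2), rep(ev, 2),
                        rep(c("a", "b"), each = 8))
    expect_lt(same$chisq, 1e-10)
    expect_equal(same$p_value, 1, tolerance = 1e-6)

    l1 <- logrankTest(tm, ev, g)
    l2 <- logrankTest(tm, ev, ifelse(g == "x", "y", "x"))
    expect_equal(l1$chisq, l2$chisq)
    expect_error(logrankTest(tm, ev, rep("x", 8)), "two non-empty")

    # type-I error at alpha = 0.05 under equal hazards: 0.05 +/- 0.02
    set.seed(18)
    rej <- logical(1000)
    for (i in seq_len(1000)) {
        t0 <- rexp(40, 0.1)
        cens <- rbinom(40, 1, 0.2) == 1
        tt <- ifelse(cens, runif(40, 0, t0), t0)
        rej[i] <- logrankTest(tt, as.integer(!cens),
                              rep(c("a", "b"), 20))$p_value < 0.05
    }
    expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("the bundled 60-case counts reconstruct exactly per gene and cluster", {
    dat <- rmsMutationCounts()
    rc <- rmsTargetedCohort()
    key <- c(E1 = "e1", E2 = "e2", A1 = "a1", A2 = "a2", "NA" = "na")
    for (cl in names(key)) {
        ids <- names(rc$grouping)[rc$grouping == cl]
        sub <- rc$mutations[rc$mutations$sample_id %in% ids, ]
        for (i in seq_len(nrow(dat$counts))) {
            g <- dat$counts$gene[i]
            expect_equal(sum(sub$gene == g), dat$counts[[key[[cl]]]][i],
                         info = paste(cl, g))
        }
        # pathway case totals honoured despite double-mutated cases
        pwSamples <- unique(sub$sample_id[!is.na(sub$pathway)])
        expect_equal(length(pwSamples), dat$pathway_cases[[key[[cl]]]],
                     info = cl)
    }
    expect_false(anyDuplicated(paste(rc$mutations$sample_id,
                                     rc$mutations$gene)) > 0)
})
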