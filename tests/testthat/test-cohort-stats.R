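test_that("cohort table joins metrics and dynamics with deltas", {
    man <- data.frame(
        sample_id = c("s1b", "s1o", "s2b", "s2o"),
        participant_id = c("p1", "p1", "p2", "p2"),
        arm = c("D", "D", "STRIDE", "STRIDE"),
        timepoint = rep(c("baseline", "end_of_cycle1"), 2),
        response = c("responder", "responder", "nonresponder",
                     "nonresponder"),
        file = "x.tsv", stringsAsFactors = FALSE)
    met <- data.frame(
        sample_id = man$sample_id, participant_id = man$participant_id,
        timepoint = man$timepoint,
        simpson_clonality = c(0.3, 0.2, 0.4, 0.45),
        richness_downsampled = c(100, 120, 80, 70),
        productive_fraction = c(0.9, 0.85, 0.95, 0.9),
        t_cell_fraction = c(0.1, 0.12, 0.2, 0.18),
        stringsAsFactors = FALSE)
    dyn <- data.frame(participant_id = "p1", n_expanded_total = 7L,
                      n_expanded_new = 4L, n_expanded_existing = 3L,
                      n_contracted = 1L, stringsAsFactors = FALSE)
    tab <- cohortTable(man, met, dyn)
    expect_equal(nrow(tab), 2L)
    expect_equal(tab$delta_simpson_clonality, c(-0.1, 0.05))
    expect_equal(tab$baseline_richness_downsampled, c(100, 80))
    expect_equal(tab$n_expanded_total, c(7L, NA))
    expect_equal(tab$arm, c("D", "STRIDE"))
})

test_that("one-way ANOVA recovers the textbook degenerate cases", {
    tab <- data.frame(participant_id = paste0("p", 1:9),
                      arm = rep(c("D", "STRIDE", "T"), each = 3),
                      baseline_simpson_clonality = rep(c(1, 2, 3), 3),
                      stringsAsFactors = FALSE)
    res <- baselineAnova(tab, "baseline_simpson_clonality")
    expect_equal(res$statistic, 0)     # identical groups: F = 0, p = 1
    expect_equal(res$p_value, 1)
    expect_equal(res$method, "anova")

    sep <- tab
    sep$baseline_simpson_clonality <- rep(c(1, 2, 3), each = 3)
    res2 <- suppressWarnings(   # lm warns on an essentially perfect fit
        baselineAnova(sep, "baseline_simpson_clonality"))
    expect_true(is.finite(res2$statistic))  # capped, not Inf
    expect_gt(res2$p_value, 0)              # floored, not 0
    expect_lt(res2$p_value, 1e-10)

    expect_error(baselineAnova(tab[1:4, ], "baseline_simpson_clonality"),
                 "at least two")
})

test_that("ANOVA type-I error is near nominal under a common distribution", {
    set.seed(2718)
    nRep <- 2000L
    rejections <- 0L
    arm <- rep(armLevels(), each = 6)
    for (r in seq_len(nRep)) {
        tab <- data.frame(participant_id = seq_along(arm), arm = arm,
                          baseline_simpson_clonality = rnorm(length(arm)),
                          stringsAsFactors = FALSE)
        res <- baselineAnova(tab, "baseline_simpson_clonality")
        rejections <- rejections + (res$p_value <= 0.05)
    }
    rate <- rejections / nRep
    mcse <- sqrt(0.05 * 0.95 / nRep)
    expect_lt(abs(rate - 0.05), 3 * mcse)
})

test_that("pairwise rank-sum tests match exact enumeration and BH the oracle", {
    tab <- data.frame(
        participant_id = paste0("p", 1:6),
        arm = rep(c("D", "STRIDE"), each = 3),
        n_expanded_total = c(1, 2, 3, 4, 5, 6),
        stringsAsFactors = FALSE)
    res <- pairwiseArmTest(tab, "n_expanded_total")
    expect_equal(nrow(res), 1L)
    expect_equal(res$p_value, 0.1)   # 2/20 assignments as extreme
    expect_equal(res$p_value, oracleRankSumP(c(1, 2, 3), c(4, 5, 6)))
    expect_match(res$method, "exact")

    same <- tab; same$n_expanded_total <- rep(c(1, 2, 3), 2)
    res2 <- pairwiseArmTest(same, "n_expanded_total")
    expect_equal(res2$p_value, 1)

    # five arms: 10 pairs, BH across them equals the brute-force oracle
    set.seed(61)
    tab5 <- data.frame(
        participant_id = paste0("p", 1:40),
        arm = rep(armLevels(), each = 8),
        n_expanded_total = rnorm(40), stringsAsFactors = FALSE)
    res5 <- pairwiseArmTest(tab5, "n_expanded_total")
    expect_equal(nrow(res5), 10L)
    expect_equal(res5$p_adjusted, oracleBH(res5$p_value), tolerance = 1e-12)
    # BH preserves the ordering of the raw p-values
    expect_equal(order(res5$p_adjusted[order(res5$p_value)]),
                 seq_len(10L))
})

test_that("rank-sum p-values agree with enumeration for all small tie-free cases", {
    set.seed(31)
    for (i in 1:20) {
        n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
        vals <- sample(1:100, n1 + n2)   # tie-free
        tab <- data.frame(
            participant_id = seq_len(n1 + n2),
            arm = rep(c("D", "T"), c(n1, n2)),
            n_expanded_total = vals, stringsAsFactors = FALSE)
        res <- pairwiseArmTest(tab, "n_expanded_total")
        expect_equal(res$p_value,
                     oracleRankSumP(vals[seq_len(n1)], vals[-seq_len(n1)]),
                     tolerance = 1e-12)
    }
})

test_that("paired signed-rank change test matches enumeration and handles zeros", {
    tab <- data.frame(participant_id = paste0("p", 1:6), arm = "D+B",
                      delta_productive_fraction = c(0.02, 0.01, 0.05, 0.03,
                                                    0.04, 0.06),
                      stringsAsFactors = FALSE)
    res <- pairedChangeTest(tab, "productive_fraction", "D+B")
    expect_equal(res$p_value, 2 / 64)   # all-positive deltas, n = 6
    expect_equal(res$p_value,
                 oracleSignedRankP(tab$delta_productive_fraction))

    set.seed(17)
    for (i in 1:10) {
        d <- round(rnorm(sample(4:9, 1)), 3)
        d <- d[d != 0]
        if (length(d) < 3 || anyDuplicated(abs(d))) next
        tabr <- data.frame(participant_id = seq_along(d), arm = "T",
                           delta_simpson_clonality = d,
                           stringsAsFactors = FALSE)
        res <- pairedChangeTest(tabr, "simpson_clonality", "T")
        expect_equal(res$p_value, oracleSignedRankP(d), tolerance = 1e-12)
    }

    zeros <- data.frame(participant_id = paste0("p", 1:5), arm = "D",
                        delta_t_cell_fraction = c(0, 0, 0, 0, 0),
                        stringsAsFactors = FALSE)
    expect_warning(rz <- pairedChangeTest(zeros, "t_cell_fraction", "D"),
                   "zero")
    expect_equal(rz$p_value, 1)

    oneNonzero <- zeros
    oneNonzero$delta_t_cell_fraction <- c(0, 0, 0.5, 0, 0)
    r1 <- pairedChangeTest(oneNonzero, "t_cell_fraction", "D")
    expect_equal(r1$p_value, 1)   # a single nonzero delta cannot reject

    expect_error(pairedChangeTest(zeros[1:2, ], "t_cell_fraction", "D"),
                 "at least 3")
})

test_that("signed-rank type-I error is near nominal under a symmetric null", {
    set.seed(5050)
    nRep <- 1000L
    rej <- 0L
    for (r in seq_len(nRep)) {
        tab <- data.frame(participant_id = 1:12, arm = "STRIDE",
                          delta_simpson_clonality = rnorm(12),
                          stringsAsFactors = FALSE)
        res <- pairedChangeTest(tab, "simpson_clonality", "STRIDE")
        rej <- rej + (res$p_value <= 0.05)
    }
    rate <- rej / nRep
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nRep) + 0.01)
})

test_that("response comparison imputes zeros for nonevaluable participants", {
    tab <- data.frame(
        participant_id = paste0("p", 1:6), arm = "STRIDE",
        response = c("responder", "responder", "responder",
                     "nonresponder", "nonresponder", "nonresponder"),
        n_expanded_total = c(50, 60, 70, 10, 20, 30),
        stringsAsFactors = FALSE)
    res <- responseTest(tab, "STRIDE")
    expect_equal(res$p_value, 0.1)
    expect_equal(res$p_value, oracleRankSumP(c(50, 60, 70), c(10, 20, 30)))

    # a nonevaluable participant joins the nonresponder side at zero
    tab2 <- rbind(tab, data.frame(participant_id = "p7", arm = "STRIDE",
                                  response = "nonevaluable",
                                  n_expanded_total = 999))
    res2 <- responseTest(tab2, "STRIDE")
    expect_equal(res2$p_value, oracleRankSumP(c(50, 60, 70),
                                              c(10, 20, 30, 0)))
    expect_match(res2$n_per_group, "nonresponder=4")

    # pooled tremelimumab-containing group spans T, T75+D and STRIDE
    tab3 <- tab
    tab3$arm <- c("T", "T75+D", "STRIDE", "T", "T75+D", "STRIDE")
    res3 <- responseTest(tab3, "pooled_tremelimumab")
    expect_equal(res3$p_value, 0.1)

    allNe <- tab; allNe$response <- "nonevaluable"
    expect_error(responseTest(allNe, "STRIDE"), "nonevaluable")

    noResp <- tab; noResp$response[1:3] <- "nonresponder"
    expect_warning(rNA <- responseTest(noResp, "STRIDE"), "not available")
    expect_equal(rNA$method, "not_available")
    expect_true(is.na(rNA$p_value))
})

test_that("threshold proportions use strict exceedance and an automatic median", {
    tab <- data.frame(
        participant_id = paste0("p", 1:6),
        arm = rep(c("D", "STRIDE"), each = 3),
        n_expanded_total = c(30, 32, 34, 10, 33, 40),
        stringsAsFactors = FALSE)
    res <- proportionAboveThreshold(tab)   # auto: median of D = 32
    expect_equal(unique(res$threshold), 32)
    expect_equal(res$proportion[res$arm == "STRIDE"], 2 / 3)
    expect_equal(res$proportion[res$arm == "D"], 1 / 3)

    resEq <- proportionAboveThreshold(
        data.frame(participant_id = 1:3, arm = "T",
                   n_expanded_total = c(32, 32, 32)), threshold = 32)
    expect_equal(resEq$proportion, 0)   # ties never exceed

    expect_error(proportionAboveThreshold(tab[4:6, ]), "reference arm")
})
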