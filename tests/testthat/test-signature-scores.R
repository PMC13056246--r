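test_that("GMT files round-trip signature definitions", {
    path <- tempfile(fileext = ".gmt")
    writeLines(c("setA\tdescription A\tg1\tg3\tg3\tg5",
                 "setB\t-\tg2\tg6",
                 ""), path)
    sets <- readGmt(path)
    expect_named(sets, c("setA", "setB"))
    expect_equal(sets$setA, c("g1", "g3", "g5"))  # duplicate dropped
    expect_equal(readGmt(path, toupperIds = TRUE)$setB, c("G2", "G6"))
    bad <- tempfile(fileext = ".gmt")
    writeLines("nameonly\tdesc", bad)
    expect_error(readGmt(bad), "malformed")
})

test_that("ssGSEA scores equal the brute-force running-sum oracle", {
    expr <- fixtureExpr()
    sets <- list(up = c("g1", "g5"), mixed = c("g2", "g3", "g6"))
    for (tau in c(0.25, 1)) {
        sc <- ssgseaScores(expr, sets, tau = tau, normalize = FALSE)
        for (nm in names(sets)) {
            for (j in colnames(expr)) {
                expect_equal(
                    sc[nm, j],
                    oracleSsgsea(expr[, j], rownames(expr), sets[[nm]],
                                 tau),
                    tolerance = 1e-12)
            }
        }
    }
    # normalization only rescales by the global score range
    raw <- ssgseaScores(expr, sets, normalize = FALSE)
    nrm <- ssgseaScores(expr, sets, normalize = TRUE)
    expect_equal(nrm, raw / diff(range(raw)), tolerance = 1e-12)
})

test_that("ssGSEA is rank-based: invariant under monotone transforms", {
    expr <- fixtureExpr()
    sets <- list(s = c("g1", "g4", "g6"))
    base <- ssgseaScores(expr, sets, normalize = FALSE)
    for (f in list(function(x) 2 * x + 3, exp, function(x) x^3)) {
        expect_equal(ssgseaScores(f(expr), sets, normalize = FALSE), base,
                     tolerance = 1e-12)
    }
})

test_that("degenerate and discriminating sets behave as expected", {
    # tie-free matrix: with no out-of-set genes the weight sequence is the
    # same in every sample, so the score cannot discriminate
    exprTF <- matrix(c(6:1, c(2, 5, 1, 6, 4, 3)), nrow = 6,
                     dimnames = list(paste0("g", 1:6), c("x", "y")))
    all6 <- ssgseaScores(exprTF, list(everything = rownames(exprTF)),
                         normalize = FALSE)
    expect_equal(diff(range(all6)), 0)

    # set at the top of one sample's ranking scores higher there
    expr2 <- matrix(0, nrow = 10, ncol = 2,
                    dimnames = list(paste0("g", 1:10), c("top", "bottom")))
    expr2[, "top"] <- 10:1       # g1, g2 highest
    expr2[, "bottom"] <- 1:10    # g1, g2 lowest
    sc <- ssgseaScores(expr2, list(pair = c("g1", "g2")),
                       normalize = FALSE)
    expect_gt(sc["pair", "top"], sc["pair", "bottom"])

    expect_warning(
        expect_error(ssgseaScores(fixtureExpr(),
                                  list(alien = c("x1", "x2"))),
                     "no signature overlaps"),
        "skipped")
})

test_that("signature slopes reduce to the paired estimator and its guards", {
    man <- .sigManifest(4)
    sigs <- list(s1 = paste0("SIG", 1:6))
    # constant shift d in every participant: slope d, degenerate p guard
    scores <- matrix(0, nrow = 1, ncol = nrow(man),
                     dimnames = list("s1", man$sample_id))
    scores[1, man$timepoint == "end_of_cycle1"] <- 0.7
    sl <- signatureSlopes(scores, man, "STRIDE")
    expect_equal(sl$slope, 0.7)
    expect_true(sl$degenerate)
    expect_equal(sl$p_value, .Machine$double.xmin)

    # deltas {+1, -1}: slope 0, p = 1
    man2 <- .sigManifest(2, arms = "D")
    sc2 <- matrix(0, nrow = 1, ncol = nrow(man2),
                  dimnames = list("s1", man2$sample_id))
    sc2[1, "D_1_end_of_cycle1"] <- 1
    sc2[1, "D_2_end_of_cycle1"] <- -1
    sl2 <- signatureSlopes(sc2, man2, "D")
    expect_equal(sl2$slope, 0)
    expect_equal(sl2$p_value, 1)

    # participants missing a timepoint are excluded with a message
    man3 <- .sigManifest(3, arms = "D")
    sc3 <- matrix(rnorm(5), nrow = 1,
                  dimnames = list("s1", man3$sample_id[-6]))
    expect_message(sl3 <- signatureSlopes(sc3, man3, "D"), "excluded")
    expect_equal(sl3$n_participants, 2L)
    expect_error(signatureSlopes(sc3[, 1:3, drop = FALSE], man3, "D"),
                 "fewer than 2")
})

test_that("the paired reduction agrees with a random-intercept mixed model", {
    skip_if_not_installed("lme4")
    set.seed(808)
    man <- .sigManifest(8, arms = "STRIDE")
    sigs <- list(act = paste0("ACT", 1:8))
    expr <- simulateExpression(man, sigs,
                               effects = list(STRIDE = list(act = 1.5)),
                               nGenes = 80L, seed = 31L)
    scores <- ssgseaScores(expr, sigs)
    sl <- signatureSlopes(scores, man, "STRIDE")

    dat <- data.frame(score = scores["act", man$sample_id],
                      tp = factor(man$timepoint,
                                  levels = timepointLevels()),
                      pid = man$participant_id)
    fit <- lme4::lmer(score ~ tp + (1 | pid), data = dat, REML = TRUE)
    expect_equal(sl$slope, unname(lme4::fixef(fit)[2]), tolerance = 1e-8)
})

test_that("slope estimation recovers a simulated time effect", {
    set.seed(99)
    beta <- 0.8; sigmaB <- 1; sigmaE <- 0.4
    nRep <- 400L; nPart <- 10L
    est <- replicate(nRep, {
        b <- rnorm(nPart, 0, sigmaB)
        y0 <- b + rnorm(nPart, 0, sigmaE)
        y1 <- b + beta + rnorm(nPart, 0, sigmaE)
        mean(y1 - y0)
    })
    se <- stats::sd(est) / sqrt(nRep)
    expect_lt(abs(mean(est) - beta), 3 * se)

    # through the full pipeline on one realisation
    man <- .sigManifest(10, arms = "D")
    sigs <- list(hot = paste0("HOT", 1:10))
    expr <- simulateExpression(man, sigs,
                               effects = list(D = list(hot = 2)),
                               nGenes = 100L, sigmaParticipant = 1,
                               sigmaNoise = 0.5, seed = 77L)
    sl <- signatureSlopes(ssgseaScores(expr, sigs), man, "D")
    expect_gt(sl$slope, 0)
    expect_lt(sl$p_value, 0.05)
})

test_that("signature selection applies the inclusive threshold with a BH column", {
    slopes <- data.frame(signature = c("a", "b", "c"),
                         slope = c(1, -1, 0.2),
                         p_value = c(0.01, 0.049, 0.051),
                         n_participants = 5L, degenerate = FALSE,
                         stringsAsFactors = FALSE)
    sel <- selectSignatures(slopes)
    expect_equal(sel$signature, c("a", "b"))
    expect_equal(sel$p_adjusted, oracleBH(slopes$p_value)[1:2],
                 tolerance = 1e-12)
    empty <- selectSignatures(slopes[0, ])
    expect_equal(nrow(empty), 0L)
})

test_that("expression simulation is seed-deterministic with arm-specific effects", {
    man <- .sigManifest(3)
    sigs <- list(ifng = paste0("IFN", 1:5), mye = paste0("MYE", 1:5))
    e1 <- simulateExpression(man, sigs, effects = list(STRIDE = list(ifng = 2)),
                             nGenes = 60L, seed = 12L)
    e2 <- simulateExpression(man, sigs, effects = list(STRIDE = list(ifng = 2)),
                             nGenes = 60L, seed = 12L)
    expect_identical(e1, e2)
    e3 <- simulateExpression(man, sigs, effects = list(STRIDE = list(ifng = 2)),
                             nGenes = 60L, seed = 13L)
    expect_false(identical(e1, e3))

    # the shift lands only on the targeted genes, arm and timepoint
    diff <- rowMeans(e1[, man$arm == "STRIDE" &
                          man$timepoint == "end_of_cycle1"]) -
            rowMeans(e1[, man$arm == "STRIDE" & man$timepoint == "baseline"])
    expect_gt(mean(diff[sigs$ifng]), mean(diff[sigs$mye]) + 1)
})
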