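.METRIC_COLS <- c("simpson_clonality", "richness_downsampled",
                  "productive_fraction", "t_cell_fraction")

#' Assemble the per-participant cohort table
#'
#' Joins per-sample diversity metrics (wide by timepoint, with deltas) and
#' per-participant expansion counts to arm and response labels: one row per
#' participant, the input of every group-level statistic.
#'
#' @param manifest manifest data.frame (see [readManifest()]); arm and
#'   response are taken from the participant's rows.
#' @param metrics per-sample metrics from [diversityMetrics()] (optional).
#' @param dynamics per-participant summary from [summarizeDynamics()]
#'   (optional). Participants present in the manifest but absent here (no
#'   evaluable pair) keep \code{NA} counts.
#' @return A data.frame with one row per participant: \code{participant_id},
#'   \code{arm}, \code{response}, then \code{baseline_*}, \code{on_*} and
#'   \code{delta_*} columns for each diversity metric, and the
#'   \code{n_expanded_*} / \code{n_contracted} counts.
#' @export
cohortTable <- function(manifest, metrics = NULL, dynamics = NULL) {
    manifest <- validateManifest(manifest)
    participants <- unique(manifest$participant_id)
    first <- match(participants, manifest$participant_id)
    out <- data.frame(participant_id = participants,
                      arm = manifest$arm[first],
                      response = manifest$response[first],
                      stringsAsFactors = FALSE)
    if (!is.null(metrics)) {
        for (tp in .TIMEPOINTS) {
            sub <- metrics[metrics$timepoint == tp, , drop = FALSE]
            idx <- match(participants, sub$participant_id)
            prefix <- if (tp == "baseline") "baseline_" else "on_"
            for (mcol in .METRIC_COLS)
                out[[paste0(prefix, mcol)]] <- sub[[mcol]][idx]
        }
        for (mcol in .METRIC_COLS)
            out[[paste0("delta_", mcol)]] <-
                out[[paste0("on_", mcol)]] - out[[paste0("baseline_", mcol)]]
    }
    if (!is.null(dynamics)) {
        idx <- match(participants, dynamics$participant_id)
        for (mcol in c("n_expanded_total", "n_expanded_new",
                       "n_expanded_existing", "n_contracted"))
            out[[mcol]] <- dynamics[[mcol]][idx]
    }
    out
}

.testResult <- function(comparison, statistic, p, method, nPerGroup,
                        pAdjusted = NA_real_) {
    data.frame(comparison = comparison, statistic = statistic,
               p_value = p, p_adjusted = pAdjusted, method = method,
               n_per_group = nPerGroup, stringsAsFactors = FALSE)
}

# Two-sided Wilcoxon rank-sum: exact enumeration when both groups are small
# and tie-free, tie-corrected normal approximation with continuity
# correction otherwise (recorded in the method string).
.wilcoxRankSum <- function(x, y) {
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- !ties && length(x) <= 25L && length(y) <= 25L
    wt <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                           correct = TRUE))
    list(statistic = unname(wt$statistic), p = min(1, wt$p.value),
         method = if (exact) "wilcoxon_rank_sum_exact"
                  else "wilcoxon_rank_sum_normal_approx")
}

#' One-way baseline ANOVA across arms
#'
#' Fixed-effects one-way ANOVA of a baseline metric across the treatment
#' arms, as used to check for pre-treatment differences between arms.
#'
#' @param table cohort table from [cohortTable()].
#' @param metric column name to test (e.g. \code{"baseline_simpson_clonality"}).
#' @return A one-row TestResult data.frame (comparison, F statistic,
#'   p-value, method, per-group sizes). With perfect group separation and
#'   zero residual variance, the F statistic is capped at
#'   \code{.Machine$double.xmax} and the p-value floored at
#'   \code{.Machine$double.xmin} rather than returning Inf/0.
#' @export
baselineAnova <- function(table, metric) {
    if (!metric %in% names(table)) stop("no such metric column: ", metric)
    dat <- table[!is.na(table[[metric]]), c("arm", metric)]
    counts <- table(dat$arm)
    if (length(counts) < 2L)
        stop("ANOVA needs at least two arms with data")
    if (any(counts < 2L))
        stop("every arm needs at least two participants; offending arm(s): ",
             paste(names(counts)[counts < 2L], collapse = ", "))
    dat$arm <- factor(dat$arm)
    fit <- stats::lm(dat[[metric]] ~ dat$arm)
    an <- stats::anova(fit)
    Fstat <- an[["F value"]][1L]
    p <- an[["Pr(>F)"]][1L]
    if (!is.finite(Fstat) || p <= 0) { # zero residual variance guard
        Fstat <- min(Fstat, .Machine$double.xmax, na.rm = TRUE)
        p <- max(p, .Machine$double.xmin, na.rm = TRUE)
    }
    .testResult(paste0("baseline[", metric, "] across arms"), Fstat, p,
                "anova",
                paste(names(counts), counts, sep = "=", collapse = ","))
}

#' All pairwise arm comparisons with BH adjustment
#'
#' Two-sided Wilcoxon rank-sum tests of a metric between every pair of arms,
#' with Benjamini-Hochberg adjustment across the pairs.
#'
#' @param table cohort table from [cohortTable()].
#' @param metric column name to compare (e.g. \code{"n_expanded_total"}).
#' @return A TestResult data.frame with one row per arm pair; pairs where a
#'   group is empty are skipped with a warning.
#' @export
pairwiseArmTest <- function(table, metric) {
    if (!metric %in% names(table)) stop("no such metric column: ", metric)
    armsHere <- intersect(.ARMS, unique(table$arm))
    combos <- utils::combn(armsHere, 2L, simplify = FALSE)
    rows <- list()
    for (pr in combos) {
        x <- table[[metric]][table$arm == pr[1L]]
        y <- table[[metric]][table$arm == pr[2L]]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (length(x) == 0L || length(y) == 0L) {
            warning("skipping pair ", pr[1L], " vs ", pr[2L],
                    ": empty group")
            next
        }
        w <- .wilcoxRankSum(x, y)
        rows[[length(rows) + 1L]] <- .testResult(
            paste0(metric, ": ", pr[1L], " vs ", pr[2L]),
            w$statistic, w$p, w$method,
            paste0(pr[1L], "=", length(x), ",", pr[2L], "=", length(y)))
    }
    out <- do.call(rbind, rows)
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    rownames(out) <- NULL
    out
}

#' Paired within-arm change test
#'
#' Two-sided Wilcoxon signed-rank test of the per-participant deltas
#' (on-treatment minus baseline) of a metric within one arm. Zero deltas are
#' dropped before ranking (the classical Wilcoxon convention).
#'
#' @param table cohort table from [cohortTable()].
#' @param metric base metric name (e.g. \code{"simpson_clonality"}); the
#'   \code{delta_} column is used.
#' @param arm arm label to test within.
#' @return A one-row TestResult data.frame. All-zero deltas give p = 1 with
#'   a warning.
#' @export
pairedChangeTest <- function(table, metric, arm) {
    col <- if (startsWith(metric, "delta_")) metric
           else paste0("delta_", metric)
    if (!col %in% names(table)) stop("no such delta column: ", col)
    d <- table[[col]][table$arm == arm]
    d <- d[!is.na(d)]
    if (length(d) < 3L)
        stop("paired change test needs at least 3 participants with both ",
             "timepoints in arm ", arm, "; found ", length(d))
    nZero <- sum(d == 0)
    nonzero <- d[d != 0]
    if (length(nonzero) == 0L) {
        warning("all deltas are zero in arm ", arm, "; p = 1")
        return(.testResult(paste0("delta[", metric, "] in ", arm), 0, 1,
                           "wilcoxon_signed_rank",
                           paste0(arm, "=", length(d))))
    }
    exact <- length(nonzero) <= 25L && !anyDuplicated(abs(nonzero))
    wt <- suppressWarnings(
        stats::wilcox.test(nonzero, alternative = "two.sided",
                           exact = exact, correct = TRUE))
    .testResult(paste0("delta[", metric, "] in ", arm),
                unname(wt$statistic), min(1, wt$p.value),
                if (exact) "wilcoxon_signed_rank_exact"
                else "wilcoxon_signed_rank_normal_approx",
                paste0(arm, "=", length(d),
                       if (nZero) paste0(" (", nZero, " zero dropped)")))
}

#' Responder versus nonresponder comparison of expanded clones
#'
#' Two-sided Wilcoxon rank-sum test of total expanded T-cell clones between
#' responders and nonresponders within an arm (or a pooled group of arms).
#' Participants whose response is nonevaluable are included on the
#' nonresponder side with an imputed count of zero expanded clones, matching
#' the convention that a participant without a confirmed response
#' contributes no treatment-driven expansion signal; participants with a
#' response label but no evaluable repertoire pair likewise enter with zero.
#'
#' @param table cohort table from [cohortTable()] with a
#'   \code{n_expanded_total} column.
#' @param group an arm label, \code{"pooled_tremelimumab"} (the union of the
#'   T, T75+D and STRIDE arms), or \code{"all"}.
#' @return A one-row TestResult data.frame; when either response group is
#'   empty the result row carries \code{NA} statistics and the method
#'   \code{"not_available"}.
#' @export
responseTest <- function(table, group = "all") {
    sub <- if (identical(group, "all")) table
           else if (identical(group, "pooled_tremelimumab"))
               table[table$arm %in% c("T", "T75+D", "STRIDE"), , drop = FALSE]
           else table[table$arm == group, , drop = FALSE]
    if (nrow(sub) == 0L) stop("no participants in group '", group, "'")
    vals <- sub$n_expanded_total
    vals[is.na(vals)] <- 0           # no evaluable pair: zero expansion
    resp <- sub$response
    if (all(is.na(resp) | resp == "nonevaluable"))
        stop("all participants in group '", group,
             "' are response-nonevaluable")
    isResp <- !is.na(resp) & resp == "responder"
    isNon <- !is.na(resp) & resp %in% c("nonresponder", "nonevaluable")
    vals[!is.na(resp) & resp == "nonevaluable"] <- 0
    x <- vals[isResp]; y <- vals[isNon]
    label <- paste0("n_expanded_total: responders vs nonresponders [",
                    group, "]")
    if (length(x) == 0L || length(y) == 0L) {
        warning("response comparison not available in group '", group,
                "': a response group is empty")
        return(.testResult(label, NA_real_, NA_real_, "not_available",
                           paste0("responder=", length(x),
                                  ",nonresponder=", length(y))))
    }
    w <- .wilcoxRankSum(x, y)
    .testResult(label, w$statistic, w$p, w$method,
                paste0("responder=", length(x),
                       ",nonresponder=", length(y)))
}

#' Proportion of participants above an expansion threshold
#'
#' Per arm, the fraction of participants whose total expanded clone count
#' strictly exceeds a threshold. With \code{threshold = "auto"} the
#' threshold is the median count of the reference arm (durvalumab
#' monotherapy by default).
#'
#' @param table cohort table from [cohortTable()] with
#'   \code{n_expanded_total}.
#' @param threshold a finite number, or \code{"auto"}.
#' @param referenceArm arm whose median defines the automatic threshold.
#' @return A data.frame with one row per arm: \code{arm}, \code{n},
#'   \code{n_above}, \code{proportion}, \code{threshold}.
#' @export
proportionAboveThreshold <- function(table, threshold = "auto",
                                     referenceArm = "D") {
    vals <- table$n_expanded_total
    if (identical(threshold, "auto")) {
        ref <- vals[table$arm == referenceArm & !is.na(vals)]
        if (length(ref) == 0L)
            stop("reference arm '", referenceArm,
                 "' absent; cannot derive automatic threshold")
        threshold <- stats::median(ref)
    }
    if (!is.finite(threshold)) stop("threshold must be finite")
    armsHere <- intersect(.ARMS, unique(table$arm))
    rows <- lapply(armsHere, function(a) {
        v <- vals[table$arm == a & !is.na(vals)]
        data.frame(arm = a, n = length(v), n_above = sum(v > threshold),
                   proportion = if (length(v)) mean(v > threshold)
                                else NA_real_,
                   threshold = threshold, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
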