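#' Exact two-sided binomial p-value (minimum-likelihood method)
#'
#' For observed successes k out of n trials under success probability
#' \code{q0}, sums the binomial point probabilities of every outcome no more
#' probable than the observed one: \eqn{p = \sum_j \{ \Pr(j) :
#' \Pr(j) \le \Pr(k) \}}. This is the standard exact two-sided binomial
#' test; a small relative tolerance (1e-7) guards against floating-point
#' ties at the boundary.
#'
#' @param k integer vector of observed successes, \code{0 <= k <= n}.
#' @param n integer vector of trials (recycled against k).
#' @param q0 single null success probability, strictly inside (0, 1).
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' binomialTwoSidedP(10, 10, 0.5)  # 2 * 0.5^10
#' binomialTwoSidedP(5, 10, 0.5)   # mode observed: 1
#' @export
binomialTwoSidedP <- function(k, n, q0) {
    if (length(q0) != 1L || is.na(q0) || q0 <= 0 || q0 >= 1)
        stop("q0 must be a single probability strictly inside (0, 1)")
    m <- max(length(k), length(n))
    k <- as.integer(rep_len(k, m)); n <- as.integer(rep_len(n, m))
    if (any(k < 0L | k > n)) stop("k must satisfy 0 <= k <= n")
    if (any(n < 1L)) stop("n must be >= 1")
    p <- numeric(m)
    key <- paste(k, n)
    first <- !duplicated(key)
    ku <- k[first]; nu <- n[first]; pu <- numeric(sum(first))
    for (nn in unique(nu)) {
        d <- stats::dbinom(0:nn, nn, q0)
        o <- order(d)
        cs <- cumsum(d[o])
        idx <- which(nu == nn)
        pos <- findInterval(d[ku[idx] + 1L] * (1 + 1e-7), d[o])
        pu[idx] <- pmin(1, cs[pos])
    }
    p[] <- pu[match(key, key[first])]
    p
}

#' Per-clone expansion/contraction test for one paired repertoire
#'
#' For every unique productive rearrangement present in either sample of a
#' pair, the combined template count \eqn{n = c_1 + c_2} is treated as a
#' fixed number of trials in a two-sided exact binomial test of the observed
#' on-treatment count \eqn{c_2}, under the null that templates are evenly
#' distributed between the samples relative to their repertoire sizes, i.e.
#' success probability \eqn{q_0 = N_2 / (N_1 + N_2)} with \eqn{N_1, N_2} the
#' total productive templates per sample. P-values are Benjamini-Hochberg
#' adjusted across all clones tested within the pair. A clone significant at
#' \code{q <= fdr} is called \emph{expanded} when its on-treatment frequency
#' exceeds its baseline frequency and \emph{contracted} when lower; a clone
#' with zero baseline templates is \emph{new}, otherwise \emph{existing}.
#'
#' @param pair a \linkS4class{PairedRepertoire}; both samples need at least
#'   one productive template.
#' @param fdr false discovery rate for the BH cut (default 0.01); ties at
#'   exactly \code{q == fdr} are called significant.
#' @param minTemplates optional lower bound on the combined count n of a
#'   clone for it to enter the test universe (default 0: every observed
#'   clone is tested).
#' @return A data.frame, one row per tested clone: \code{rearrangement_id},
#'   \code{count_baseline}, \code{count_on}, \code{trials},
#'   \code{null_prob}, \code{p_value}, \code{q_value}, \code{direction}
#'   (\code{expanded}/\code{contracted}/\code{unchanged}) and \code{novelty}
#'   (\code{new}/\code{existing}).
#' @seealso [binomialTwoSidedP()], [summarizeDynamics()]
#' @export
testPair <- function(pair, fdr = 0.01, minTemplates = 0L) {
    b <- clones(baseline(pair)); o <- clones(onTreatment(pair))
    b <- b[b$productive & b$templates > 0L, , drop = FALSE]
    o <- o[o$productive & o$templates > 0L, , drop = FALSE]
    N1 <- sum(b$templates); N2 <- sum(o$templates)
    if (N1 == 0L || N2 == 0L)
        stop("both samples of participant '", participantId(pair),
             "' must contain at least one productive template")
    ids <- union(b$rearrangement_id, o$rearrangement_id)
    c1 <- b$templates[match(ids, b$rearrangement_id)]
    c2 <- o$templates[match(ids, o$rearrangement_id)]
    c1[is.na(c1)] <- 0L; c2[is.na(c2)] <- 0L
    n <- c1 + c2
    keep <- n >= max(1L, minTemplates)
    ids <- ids[keep]; c1 <- c1[keep]; c2 <- c2[keep]; n <- n[keep]
    q0 <- N2 / (N1 + N2)
    p <- binomialTwoSidedP(c2, n, q0)
    q <- stats::p.adjust(p, method = "BH")
    f1 <- c1 / N1; f2 <- c2 / N2
    sig <- q <= fdr
    direction <- ifelse(sig & f2 > f1, "expanded",
                        ifelse(sig & f2 < f1, "contracted", "unchanged"))
    out <- data.frame(rearrangement_id = ids, count_baseline = c1,
                      count_on = c2, trials = n, null_prob = q0,
                      p_value = p, q_value = q, direction = direction,
                      novelty = ifelse(c1 == 0L, "new", "existing"),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Per-participant expansion summaries
#'
#' Counts expansion calls by direction and novelty for each participant's
#' call table: total expanded clones, expanded new, expanded existing and
#' contracted.
#'
#' @param calls a named list of call data.frames (one per participant, as
#'   returned by [testPair()]), or a single call data.frame.
#' @param arms optional named character vector mapping participant id to
#'   arm, attached as an \code{arm} column.
#' @param responses optional named character vector mapping participant id
#'   to response label, attached as a \code{response} column.
#' @return A data.frame with one row per participant:
#'   \code{participant_id}, \code{n_expanded_total}, \code{n_expanded_new},
#'   \code{n_expanded_existing}, \code{n_contracted} (plus \code{arm} and
#'   \code{response} when supplied).
#' @export
summarizeDynamics <- function(calls, arms = NULL, responses = NULL) {
    if (is.data.frame(calls)) calls <- list(participant = calls)
    rows <- lapply(names(calls), function(pid) {
        cc <- calls[[pid]]
        exp <- cc$direction == "expanded"
        data.frame(participant_id = pid,
                   n_expanded_total = sum(exp),
                   n_expanded_new = sum(exp & cc$novelty == "new"),
                   n_expanded_existing = sum(exp & cc$novelty == "existing"),
                   n_contracted = sum(cc$direction == "contracted"),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    if (!is.null(arms)) out$arm <- unname(arms[out$participant_id])
    if (!is.null(responses))
        out$response <- unname(responses[out$participant_id])
    out
}

#' Arm-level medians and quartiles of expansion counts
#'
#' Cohort summary in trial-table style: per arm, the median and the 25th and
#' 75th percentiles of each per-participant expansion count.
#'
#' @param summary per-participant summary with an \code{arm} column (from
#'   [summarizeDynamics()]).
#' @param metrics which count columns to summarise.
#' @param quartileType quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return A data.frame with one row per (arm, metric):
#'   \code{arm}, \code{metric}, \code{n}, \code{median}, \code{q25},
#'   \code{q75}.
#' @export
dynamicsArmSummary <- function(summary,
                               metrics = c("n_expanded_total",
                                           "n_expanded_new",
                                           "n_expanded_existing",
                                           "n_contracted"),
                               quartileType = 7) {
    if (!"arm" %in% names(summary))
        stop("summary must carry an 'arm' column (see summarizeDynamics)")
    armsHere <- intersect(.ARMS, unique(summary$arm))
    rows <- list()
    for (a in armsHere) {
        sub <- summary[summary$arm == a, , drop = FALSE]
        for (mcol in metrics) {
            qs <- stats::quantile(sub[[mcol]], c(0.25, 0.5, 0.75),
                                  type = quartileType, names = FALSE)
            rows[[length(rows) + 1L]] <- data.frame(
                arm = a, metric = mcol, n = nrow(sub),
                median = qs[2L], q25 = qs[1L], q75 = qs[3L],
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
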