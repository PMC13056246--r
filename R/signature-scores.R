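#' Read gene signatures from a GMT file
#'
#' One signature per line: name, description, then the member genes, all
#' tab-separated. Duplicate genes within a set are dropped.
#'
#' @param path path to a \code{.gmt} file.
#' @param toupperIds normalise gene ids to upper case (default FALSE; gene
#'   matching is otherwise exact and case-sensitive).
#' @return A named list of character vectors of gene ids.
#' @export
readGmt <- function(path, toupperIds = FALSE) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    sets <- list()
    for (ln in lines) {
        parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
        if (length(parts) < 3L)
            stop("malformed GMT line (need name, description, >=1 gene): ",
                 substr(ln, 1L, 60L))
        genes <- unique(parts[-(1:2)])
        genes <- genes[nzchar(genes)]
        if (toupperIds) genes <- toupper(genes)
        sets[[parts[1L]]] <- genes
    }
    sets
}

# ssGSEA running sum for one sample's rank vector and one gene set.
.ssgseaSampleScore <- function(ranks, inSet, tau) {
    ord <- order(ranks, decreasing = TRUE)
    inOrd <- inSet[ord]
    w <- abs(ranks[ord])^tau * inOrd
    sumW <- sum(w)
    nOut <- sum(!inOrd)
    Pin <- cumsum(w) / sumW
    Pout <- if (nOut > 0L) cumsum(!inOrd) / nOut else rep(0, length(ranks))
    sum(Pin - Pout)
}

#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' Rank-based per-sample signature scoring of a genes-by-samples expression
#' matrix (log2 TPM). Within each sample, genes are ranked by expression
#' (average ranks for ties) and ordered from highest to lowest; the running
#' sum is incremented for in-set genes proportionally to
#' \eqn{|\mathrm{rank}|^\tau} and decremented uniformly for out-of-set
#' genes. The score is the sum of the running-sum deviations over all
#' positions. Optionally, scores are min-max normalised across the whole
#' score matrix (divided by the range of all scores), the conventional
#' cross-sample normalisation.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns.
#' @param signatures a named list of gene-id vectors (e.g. from
#'   [readGmt()]), or a single character vector.
#' @param tau rank-weighting exponent (default 0.25).
#' @param normalize divide all scores by the overall score range (default
#'   TRUE).
#' @return A signatures-by-samples numeric matrix. Signatures with no gene
#'   in the matrix are skipped with a warning; signatures with a single
#'   matching gene are scored but flagged with a message.
#' @export
ssgseaScores <- function(expr, signatures, tau = 0.25, normalize = TRUE) {
    if (is.null(rownames(expr))) stop("expr must have gene-id rownames")
    if (!is.list(signatures))
        signatures <- list(signature = signatures)
    if (is.null(names(signatures)))
        stop("signatures must be a named list")
    if (any(!is.finite(expr))) stop("expr must be finite")
    keep <- character()
    members <- list()
    for (nm in names(signatures)) {
        g <- intersect(signatures[[nm]], rownames(expr))
        if (length(g) == 0L) {
            warning("signature '", nm, "' shares no genes with the matrix; ",
                    "skipped")
            next
        }
        if (length(g) < 2L)
            message("signature '", nm, "' matches a single gene")
        keep <- c(keep, nm)
        members[[nm]] <- g
    }
    if (length(keep) == 0L) stop("no signature overlaps the matrix")
    ranks <- apply(expr, 2L, rank, ties.method = "average")
    scores <- matrix(NA_real_, nrow = length(keep), ncol = ncol(expr),
                     dimnames = list(keep, colnames(expr)))
    for (nm in keep) {
        inSet <- rownames(expr) %in% members[[nm]]
        scores[nm, ] <- vapply(seq_len(ncol(expr)), function(j)
            .ssgseaSampleScore(ranks[, j], inSet, tau), numeric(1))
    }
    if (normalize) {
        rng <- range(scores)
        if (diff(rng) > 0) scores <- scores / diff(rng)
    }
    scores
}

#' Signature pharmacodynamic slopes within an arm
#'
#' Estimates, for each signature, the end-of-cycle-1 versus baseline effect
#' on its score within one treatment arm, under a mixed model with a fixed
#' timepoint effect and a random participant intercept. With two timepoints
#' and complete pairs this model's estimator reduces exactly to the mean of
#' the per-participant score deltas, and its test to the paired t-test; the
#' reduction is what is computed. Participants missing either timepoint are
#' excluded (with a message).
#'
#' @param scores signatures-by-samples matrix from [ssgseaScores()].
#' @param manifest manifest data.frame mapping \code{sample_id} to
#'   \code{participant_id}, \code{arm} and \code{timepoint}.
#' @param arm arm label to fit within.
#' @return A data.frame with one row per signature: \code{signature},
#'   \code{slope}, \code{p_value}, \code{n_participants},
#'   \code{degenerate} (TRUE when the deltas had zero variance and the
#'   p-value is a guard value: \code{.Machine$double.xmin} for a nonzero
#'   slope, 1 for an all-zero one).
#' @export
signatureSlopes <- function(scores, manifest, arm) {
    manifest <- validateManifest(manifest)
    sub <- manifest[manifest$arm == arm &
                    manifest$sample_id %in% colnames(scores), , drop = FALSE]
    if (nrow(sub) == 0L) stop("no scored samples in arm '", arm, "'")
    wide <- list()
    for (tp in .TIMEPOINTS) {
        s <- sub[sub$timepoint == tp, , drop = FALSE]
        wide[[tp]] <- stats::setNames(s$sample_id, s$participant_id)
    }
    pids <- intersect(names(wide$baseline), names(wide$end_of_cycle1))
    nIncomplete <- length(unique(sub$participant_id)) - length(pids)
    if (nIncomplete > 0L)
        message(nIncomplete, " participant(s) in arm ", arm,
                " lack a scored sample at one timepoint; excluded")
    if (length(pids) < 2L)
        stop("fewer than 2 complete participant pairs in arm '", arm, "'")
    rows <- lapply(rownames(scores), function(sig) {
        d <- scores[sig, wide$end_of_cycle1[pids]] -
             scores[sig, wide$baseline[pids]]
        slope <- mean(d)
        if (stats::sd(d) == 0) {
            p <- if (slope == 0) 1 else .Machine$double.xmin
            degen <- TRUE
        } else {
            p <- stats::t.test(d)$p.value
            degen <- FALSE
        }
        data.frame(signature = sig, slope = slope, p_value = p,
                   n_participants = length(pids), degenerate = degen,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Select pharmacodynamically active signatures
#'
#' Signatures whose slope p-value is at or below \code{alpha}, unadjusted
#' (the selection rule used for the heatmap displays); a BH-adjusted column
#' is attached for transparency.
#'
#' @param slopes data.frame from [signatureSlopes()].
#' @param alpha selection level (default 0.05, inclusive).
#' @return The selected subset of \code{slopes} (possibly empty), with an
#'   added \code{p_adjusted} column computed across all input signatures.
#' @export
selectSignatures <- function(slopes, alpha = 0.05) {
    if (nrow(slopes) == 0L) {
        slopes$p_adjusted <- numeric(0)
        return(slopes)
    }
    slopes$p_adjusted <- stats::p.adjust(slopes$p_value, method = "BH")
    out <- slopes[slopes$p_value <= alpha, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Simulate a log2 TPM-like expression matrix for a cohort
#'
#' Gaussian gene expression with per-(participant, gene) random intercepts
#' shared across timepoints, plus arm-by-timepoint mean shifts applied to
#' designated signature genes at the end of cycle 1. Deterministic under
#' \code{seed}.
#'
#' @param manifest manifest data.frame (one row per sample).
#' @param signatures named list of gene-id vectors; all signature genes are
#'   included among the matrix rows.
#' @param effects named list: \code{effects[[arm]][[signatureName]]} is the
#'   mean shift added to that signature's genes in that arm's end-of-cycle-1
#'   samples. Arms or signatures omitted have zero effect.
#' @param nGenes total genes in the matrix (at least the number of distinct
#'   signature genes; filled up with background genes \code{gene0001}, ...).
#' @param baseMean,baseSd mean and SD of the per-gene baseline means.
#' @param sigmaParticipant SD of the participant-by-gene random intercepts.
#' @param sigmaNoise residual SD per observation.
#' @param seed integer seed.
#' @return A genes-by-samples numeric matrix with dimnames.
#' @export
simulateExpression <- function(manifest, signatures, effects = list(),
                               nGenes = 500L, baseMean = 5, baseSd = 2,
                               sigmaParticipant = 1, sigmaNoise = 1,
                               seed = 1L) {
    manifest <- validateManifest(manifest)
    sigGenes <- unique(unlist(signatures))
    if (length(sigGenes) > nGenes)
        nGenes <- length(sigGenes)
    nBg <- nGenes - length(sigGenes)
    genes <- c(sigGenes, if (nBg > 0L) sprintf("gene%04d", seq_len(nBg)))
    participants <- unique(manifest$participant_id)
    set.seed(as.integer(seed))
    mu <- stats::rnorm(nGenes, baseMean, baseSd)
    b <- matrix(stats::rnorm(nGenes * length(participants), 0,
                             sigmaParticipant),
                nrow = nGenes,
                dimnames = list(genes, participants))
    expr <- matrix(NA_real_, nrow = nGenes, ncol = nrow(manifest),
                   dimnames = list(genes, manifest$sample_id))
    for (i in seq_len(nrow(manifest))) {
        shift <- numeric(nGenes)
        if (manifest$timepoint[i] == "end_of_cycle1") {
            armFx <- effects[[manifest$arm[i]]]
            for (nm in names(armFx)) {
                g <- intersect(signatures[[nm]], genes)
                shift[match(g, genes)] <-
                    shift[match(g, genes)] + armFx[[nm]]
            }
        }
        expr[, i] <- mu + b[, manifest$participant_id[i]] + shift +
            stats::rnorm(nGenes, 0, sigmaNoise)
    }
    expr
}
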