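.productiveCounts <- function(sample) {
    cl <- clones(sample)
    cl$templates[cl$productive & cl$templates > 0L]
}

#' Simpson clonality
#'
#' \eqn{C = \sum_{i=1}^{R} p_i^2} over the R productive rearrangements of a
#' sample, where \eqn{p_i} is the productive frequency of rearrangement i
#' (templates of clone i divided by total productive templates N). C lies in
#' \eqn{[1/R, 1]}: values near 0 indicate an even repertoire, values near 1 a
#' repertoire dominated by one or a few clones.
#'
#' @param sample a \linkS4class{RepertoireSample} with at least one
#'   productive template.
#' @return The clonality value, a number in (0, 1].
#' @examples
#' s <- RepertoireSample(data.frame(rearrangement_id = c("a", "b", "c"),
#'                                  templates = c(5L, 3L, 2L),
#'                                  productive = TRUE),
#'                       sampleId = "s1")
#' simpsonClonality(s)  # 0.25 + 0.09 + 0.04 = 0.38
#' @export
simpsonClonality <- function(sample) {
    counts <- .productiveCounts(sample)
    if (length(counts) == 0L)
        stop("Simpson clonality is undefined: sample '", sampleId(sample),
             "' has no productive templates")
    p <- counts / sum(counts)
    sum(p^2)
}

#' Downsampled richness
#'
#' The number of unique productive rearrangements after computational
#' downsampling to a common number of templates, to control for variation in
#' sample depth. The productive template multiset is sampled without
#' replacement \code{nResamples} times at depth \code{depth}; the mean count
#' of unique rearrangements over the resamples is returned.
#'
#' @param sample a \linkS4class{RepertoireSample}.
#' @param depth common downsampling depth D; must not exceed the sample's
#'   productive template total N.
#' @param nResamples number of resamples K (default 5).
#' @return Mean unique productive rearrangements over the K draws.
#' @note Uses the global RNG state; seed upstream for reproducibility.
#' @examples
#' set.seed(1)
#' s <- RepertoireSample(data.frame(rearrangement_id = c("a", "b", "c"),
#'                                  templates = c(5L, 3L, 2L),
#'                                  productive = TRUE),
#'                       sampleId = "s1")
#' downsampledRichness(s, depth = 10L)  # full draw: exactly 3
#' @export
downsampledRichness <- function(sample, depth, nResamples = 5L) {
    counts <- .productiveCounts(sample)
    N <- sum(counts)
    if (depth <= 0L) stop("downsampling depth must be positive")
    if (depth > N)
        stop("downsampling depth (", depth, ") exceeds the productive ",
             "template total (", N, ") of sample '", sampleId(sample), "'")
    expanded <- rep.int(seq_along(counts), counts)
    draws <- vapply(seq_len(nResamples), function(i) {
        length(unique(expanded[sample.int(N, depth)]))
    }, numeric(1))
    mean(draws)
}

#' Fraction of productive T cells
#'
#' Productive templates divided by total templates: the fraction of T cells
#' whose TCR-beta rearrangement is in-frame and translatable.
#'
#' @param sample a \linkS4class{RepertoireSample} with at least one template.
#' @return A number in [0, 1].
#' @export
productiveFraction <- function(sample) {
    cl <- clones(sample)
    total <- sum(cl$templates)
    if (total == 0L)
        stop("productive fraction is undefined: sample '", sampleId(sample),
             "' has no templates")
    sum(cl$templates[cl$productive]) / total
}

#' T-cell fraction
#'
#' Total T-cell templates divided by the total number of nucleated cells in
#' the sample (the reference-gene-derived denominator carried in the
#' manifest).
#'
#' @param sample a \linkS4class{RepertoireSample}.
#' @return Templates per nucleated cell, or \code{NA} (with a warning) when
#'   the nucleated-cell denominator is absent.
#' @export
tCellFraction <- function(sample) {
    nc <- nucleatedCells(sample)
    if (is.na(nc)) {
        warning("sample '", sampleId(sample), "' has no nucleated-cell ",
                "denominator; T-cell fraction reported as NA")
        return(NA_real_)
    }
    totalTemplates(sample) / nc
}

#' Per-sample diversity metrics table
#'
#' Computes all four repertoire statistics for a collection of samples at a
#' common downsampling depth. With \code{depth = "auto"} the depth is the
#' minimum productive template total across the samples, so every sample is
#' evaluable; with an explicit depth, samples whose productive total falls
#' below it get \code{NA} richness and are reported in a message.
#'
#' @param samples list of \linkS4class{RepertoireSample} objects.
#' @param depth common downsampling depth D, or \code{"auto"}.
#' @param nResamples resamples K per sample (default 5).
#' @return A data.frame with one row per sample: \code{sample_id},
#'   \code{participant_id}, \code{timepoint}, \code{n_productive_templates},
#'   \code{n_productive_rearrangements}, \code{downsample_depth},
#'   \code{n_resamples}, \code{simpson_clonality},
#'   \code{richness_downsampled}, \code{productive_fraction},
#'   \code{t_cell_fraction}.
#' @note Uses the global RNG state; seed upstream for reproducibility.
#' @export
diversityMetrics <- function(samples, depth = "auto", nResamples = 5L) {
    if (length(samples) == 0L) stop("no samples supplied")
    Ns <- vapply(samples, function(s) sum(.productiveCounts(s)), numeric(1))
    if (identical(depth, "auto")) depth <- min(Ns)
    depth <- as.integer(depth)
    shallow <- which(Ns < depth)
    if (length(shallow))
        message(length(shallow), " sample(s) with fewer than ", depth,
                " productive templates excluded from downsampled richness")
    rows <- lapply(seq_along(samples), function(i) {
        s <- samples[[i]]
        data.frame(
            sample_id = sampleId(s), participant_id = participantId(s),
            timepoint = timepoint(s),
            n_productive_templates = Ns[i],
            n_productive_rearrangements = length(.productiveCounts(s)),
            downsample_depth = depth, n_resamples = nResamples,
            simpson_clonality = simpsonClonality(s),
            richness_downsampled = if (i %in% shallow) NA_real_ else
                downsampledRichness(s, depth, nResamples),
            productive_fraction = productiveFraction(s),
            t_cell_fraction = if (is.na(nucleatedCells(s))) NA_real_ else
                totalTemplates(s) / nucleatedCells(s),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
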