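# Small in-code fixtures shared across test files.

makeSample <- function(counts, productive = TRUE, ids = NULL,
                       sampleId = "s1", participantId = "p1",
                       timepoint = "baseline", nucleatedCells = NA_real_) {
    if (is.null(ids)) ids <- paste0("r", seq_along(counts))
    RepertoireSample(
        data.frame(rearrangement_id = ids,
                   templates = as.integer(counts),
                   productive = rep_len(productive, length(counts)),
                   stringsAsFactors = FALSE),
        sampleId = sampleId, participantId = participantId,
        timepoint = timepoint, nucleatedCells = nucleatedCells)
}

makePair <- function(countsBase, countsOn, idsBase = NULL, idsOn = NULL,
                     participantId = "p1") {
    b <- makeSample(countsBase, ids = idsBase, sampleId = "b",
                    participantId = participantId, timepoint = "baseline")
    o <- makeSample(countsOn, ids = idsOn, sampleId = "o",
                    participantId = participantId,
                    timepoint = "end_of_cycle1")
    PairedRepertoire(b, o)
}

writeTsv <- function(lines, path = tempfile(fileext = ".tsv")) {
    writeLines(lines, path)
    path
}

# A 6-gene, 3-sample log2-TPM-like fixture for the ssGSEA oracle checks.
fixtureExpr <- function() {
    matrix(c(8.1, 2.0, 5.5, 1.2, 7.3, 3.9,
             1.0, 7.8, 2.2, 6.6, 3.1, 5.0,
             4.4, 4.4, 6.0, 2.8, 1.5, 7.7),
           nrow = 6,
           dimnames = list(paste0("g", 1:6), c("sA", "sB", "sC")))
}

# Manifest skeleton for expression-only cohorts (no repertoire files).
.sigManifest <- function(nPerArm, arms = c("STRIDE", "D")) {
    rows <- list()
    for (a in arms) for (i in seq_len(nPerArm)) {
        pid <- paste0(a, "_", i)
        for (tp in timepointLevels()) {
            rows[[length(rows) + 1L]] <- data.frame(
                sample_id = paste0(pid, "_", tp), participant_id = pid,
                arm = a, timepoint = tp, response = NA_character_,
                file = "none.tsv", stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

# A tiny tie-free cohort table for the group statistics tests.
smallCohortTable <- function() {
    data.frame(
        participant_id = sprintf("p%02d", 1:12),
        arm = rep(c("D", "STRIDE"), each = 6),
        response = rep(c("responder", "nonresponder", "nonresponder"), 4),
        n_expanded_total = c(10, 33, 40, 5, 20, 31, 60, 80, 55, 70, 90, 34),
        stringsAsFactors = FALSE)
}
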