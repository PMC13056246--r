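#' @import methods
NULL

.TIMEPOINTS <- c("baseline", "end_of_cycle1")
.ARMS <- c("D+B", "D", "T75+D", "STRIDE", "T")
.RESPONSES <- c("responder", "nonresponder", "nonevaluable")

#' Treatment arm and timepoint labels
#'
#' The five treatment arms of the cohort design (durvalumab plus bevacizumab,
#' durvalumab monotherapy, tremelimumab 75 mg plus durvalumab, STRIDE, and
#' tremelimumab monotherapy) and the two sampling timepoints (baseline and
#' end of the first treatment cycle), in their canonical order.
#'
#' @return A character vector of labels.
#' @examples
#' armLevels()
#' timepointLevels()
#' @export
armLevels <- function() .ARMS

#' @rdname armLevels
#' @export
timepointLevels <- function() .TIMEPOINTS

#' RepertoireSample: one blood-draw TCR-beta repertoire
#'
#' Container for all clones observed in one immunosequencing sample: a clone
#' table (one row per unique rearrangement with its template count and
#' productive status) plus sample metadata. The nucleated-cell denominator,
#' when available from the assay's reference-gene panel, supports the T-cell
#' fraction metric.
#'
#' @slot sampleId character(1), unique sample identifier.
#' @slot participantId character(1), the participant the draw belongs to.
#' @slot timepoint character(1), one of \code{timepointLevels()}.
#' @slot clones data.frame with columns \code{rearrangement_id} (character,
#'   unique), \code{templates} (non-negative integer) and \code{productive}
#'   (logical); an optional \code{cdr3_aa} character column may be present.
#' @slot nucleatedCells numeric(1), total nucleated cells in the sample, or
#'   \code{NA} when not supplied.
#'
#' @seealso [readRearrangementTable()], [simpsonClonality()], [testPair()]
#' @aliases RepertoireSample
#' @exportClass RepertoireSample
setClass("RepertoireSample",
    representation(
        sampleId = "character",
        participantId = "character",
        timepoint = "character",
        clones = "data.frame",
        nucleatedCells = "numeric"
    ),
    prototype(nucleatedCells = NA_real_)
)

setValidity("RepertoireSample", function(object) {
    msg <- character()
    cl <- object@clones
    req <- c("rearrangement_id", "templates", "productive")
    miss <- setdiff(req, names(cl))
    if (length(miss)) {
        msg <- c(msg, paste0("clones is missing column(s): ",
                             paste(miss, collapse = ", ")))
    } else {
        if (anyDuplicated(cl$rearrangement_id))
            msg <- c(msg, "rearrangement_id values must be unique within a sample")
        if (any(is.na(cl$templates)) || any(cl$templates < 0))
            msg <- c(msg, "templates must be non-negative and non-missing")
        if (any(cl$templates != round(cl$templates)))
            msg <- c(msg, "templates must be integer-valued")
        if (any(is.na(cl$productive)))
            msg <- c(msg, "productive flag must be present for every clone")
    }
    if (length(object@sampleId) != 1L || is.na(object@sampleId))
        msg <- c(msg, "sampleId must be a single non-missing string")
    if (length(object@timepoint) != 1L ||
        !(object@timepoint %in% c(.TIMEPOINTS, NA_character_)))
        msg <- c(msg, paste0("timepoint must be one of: ",
                             paste(.TIMEPOINTS, collapse = ", ")))
    if (length(object@nucleatedCells) != 1L ||
        (!is.na(object@nucleatedCells) && object@nucleatedCells <= 0))
        msg <- c(msg, "nucleatedCells must be a single positive number or NA")
    if (length(msg)) msg else TRUE
})

#' Construct a RepertoireSample
#'
#' @param clones data.frame of clones; see the class documentation for the
#'   required columns.
#' @param sampleId,participantId sample and participant identifiers.
#' @param timepoint \code{"baseline"} or \code{"end_of_cycle1"} (may be
#'   \code{NA} for ad hoc samples).
#' @param nucleatedCells positive number or \code{NA}.
#' @return A \linkS4class{RepertoireSample}.
#' @examples
#' cl <- data.frame(rearrangement_id = c("a", "b", "c"),
#'                  templates = c(5L, 3L, 2L), productive = TRUE)
#' s <- RepertoireSample(cl, sampleId = "s1", participantId = "p1",
#'                       timepoint = "baseline")
#' simpsonClonality(s)
#' @export
RepertoireSample <- function(clones, sampleId, participantId = NA_character_,
                             timepoint = NA_character_,
                             nucleatedCells = NA_real_) {
    clones$rearrangement_id <- as.character(clones$rearrangement_id)
    clones$templates <- as.integer(round(clones$templates))
    clones$productive <- as.logical(clones$productive)
    rownames(clones) <- NULL
    new("RepertoireSample", sampleId = as.character(sampleId),
        participantId = as.character(participantId),
        timepoint = as.character(timepoint), clones = clones,
        nucleatedCells = as.numeric(nucleatedCells))
}

#' PairedRepertoire: baseline and on-treatment samples from one participant
#'
#' The unit of the per-clone expansion test: the baseline draw and the draw at
#' the end of the first treatment cycle from the same participant.
#'
#' @slot participantId character(1).
#' @slot baseline,onTreatment \linkS4class{RepertoireSample} objects at the
#'   \code{"baseline"} and \code{"end_of_cycle1"} timepoints respectively.
#' @seealso [pairSamples()], [testPair()]
#' @aliases PairedRepertoire
#' @exportClass PairedRepertoire
setClass("PairedRepertoire",
    representation(
        participantId = "character",
        baseline = "RepertoireSample",
        onTreatment = "RepertoireSample"
    )
)

setValidity("PairedRepertoire", function(object) {
    msg <- character()
    if (!identical(object@baseline@participantId, object@participantId) ||
        !identical(object@onTreatment@participantId, object@participantId))
        msg <- c(msg, "both samples must carry the pair's participantId")
    if (!identical(object@baseline@timepoint, "baseline"))
        msg <- c(msg, "baseline sample must have timepoint 'baseline'")
    if (!identical(object@onTreatment@timepoint, "end_of_cycle1"))
        msg <- c(msg, "onTreatment sample must have timepoint 'end_of_cycle1'")
    if (length(msg)) msg else TRUE
})

#' Construct a PairedRepertoire
#'
#' @param baseline,onTreatment \linkS4class{RepertoireSample} objects from the
#'   same participant at the two timepoints.
#' @return A \linkS4class{PairedRepertoire}.
#' @export
PairedRepertoire <- function(baseline, onTreatment) {
    new("PairedRepertoire", participantId = baseline@participantId,
        baseline = baseline, onTreatment = onTreatment)
}

#' SimConfig: synthetic cohort generator settings
#'
#' All knobs of the synthetic paired-repertoire cohort: per-arm sample sizes,
#' the baseline clone-frequency law, sequencing depths, per-arm expansion
#' effects, response-label probabilities and the master seed. The defaults
#' (see [simConfig()]) emulate a five-arm immunotherapy trial with
#' tremelimumab-dose-dependent clonal expansion.
#'
#' @slot nParticipantsPerArm named integer vector over the five arms.
#' @slot nClonesBaseline integer(1), number of clones in the ground-truth
#'   baseline repertoire (U).
#' @slot frequencyLaw \code{"power_law"} or \code{"dirichlet"}.
#' @slot alpha numeric(1), power-law exponent over clone ranks.
#' @slot concentration numeric(1), Dirichlet concentration (flat repertoires).
#' @slot depthBaseline,depthOn integer(1), total templates drawn per sample.
#' @slot armEffects named list per arm with elements
#'   \code{nExpandedExisting}, \code{nNewClones}, \code{fold}.
#' @slot responderBoost numeric(1), multiplier on the number of expanded and
#'   new clones for responders.
#' @slot propResponders,propNonevaluable named numeric vectors (or scalars)
#'   of per-arm response-label probabilities.
#' @slot propNonproductive numeric(1), fraction of unique clones flagged
#'   nonproductive.
#' @slot maxCloneFreq numeric(1), upper frequency bound for clones eligible
#'   to be truly expanded (hyperexpanded clones are not perturbed).
#' @slot seed integer(1), master seed.
#' @aliases SimConfig
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        nParticipantsPerArm = "integer",
        nClonesBaseline = "integer",
        frequencyLaw = "character",
        alpha = "numeric",
        concentration = "numeric",
        depthBaseline = "integer",
        depthOn = "integer",
        armEffects = "list",
        responderBoost = "numeric",
        propResponders = "numeric",
        propNonevaluable = "numeric",
        propNonproductive = "numeric",
        maxCloneFreq = "numeric",
        seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    if (any(object@nParticipantsPerArm < 0L))
        msg <- c(msg, "participant counts must be >= 0")
    if (is.null(names(object@nParticipantsPerArm)) ||
        !all(names(object@nParticipantsPerArm) %in% .ARMS))
        msg <- c(msg, "nParticipantsPerArm must be named by arm")
    if (object@nClonesBaseline < 1L)
        msg <- c(msg, "nClonesBaseline must be positive")
    if (!object@frequencyLaw %in% c("power_law", "dirichlet"))
        msg <- c(msg, "frequencyLaw must be 'power_law' or 'dirichlet'")
    if (object@depthBaseline < 1L || object@depthOn < 1L)
        msg <- c(msg, "sequencing depths must be positive")
    for (a in names(object@armEffects)) {
        ef <- object@armEffects[[a]]
        if (!all(c("nExpandedExisting", "nNewClones", "fold") %in% names(ef)))
            msg <- c(msg, paste0("armEffects[['", a, "']] incomplete"))
        else if (ef$fold <= 0 || ef$nExpandedExisting < 0 || ef$nNewClones < 0)
            msg <- c(msg, paste0("armEffects[['", a,
                                 "']]: fold must be > 0, counts >= 0"))
    }
    if (any(object@propResponders < 0 | object@propResponders > 1) ||
        any(object@propNonevaluable < 0 | object@propNonevaluable > 1) ||
        object@propNonproductive < 0 || object@propNonproductive > 1)
        msg <- c(msg, "probabilities must lie in [0, 1]")
    if (object@responderBoost <= 0)
        msg <- c(msg, "responderBoost must be positive")
    if (length(msg)) msg else TRUE
})
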