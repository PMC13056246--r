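#' Accessors for repertoire objects
#'
#' @param object a \linkS4class{RepertoireSample} or
#'   \linkS4class{PairedRepertoire}.
#' @return \code{clones()} the clone data.frame; \code{sampleId()},
#'   \code{participantId()}, \code{timepoint()} the corresponding metadata
#'   strings; \code{nucleatedCells()} the nucleated-cell denominator;
#'   \code{totalTemplates()} the sum of all template counts;
#'   \code{productiveTemplates()} the sum over productive clones (N);
#'   \code{baseline()} / \code{onTreatment()} the two member samples of a
#'   pair.
#' @name repertoire-accessors
#' @aliases clones sampleId participantId timepoint nucleatedCells
#'   totalTemplates productiveTemplates baseline onTreatment
NULL

#' @rdname repertoire-accessors
#' @export
setGeneric("clones", function(object) standardGeneric("clones"))

#' @rdname repertoire-accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname repertoire-accessors
#' @export
setGeneric("participantId", function(object) standardGeneric("participantId"))

#' @rdname repertoire-accessors
#' @export
setGeneric("timepoint", function(object) standardGeneric("timepoint"))

#' @rdname repertoire-accessors
#' @export
setGeneric("nucleatedCells", function(object) standardGeneric("nucleatedCells"))

#' @rdname repertoire-accessors
#' @export
setGeneric("totalTemplates", function(object) standardGeneric("totalTemplates"))

#' @rdname repertoire-accessors
#' @export
setGeneric("productiveTemplates",
           function(object) standardGeneric("productiveTemplates"))

#' @rdname repertoire-accessors
#' @export
setGeneric("baseline", function(object) standardGeneric("baseline"))

#' @rdname repertoire-accessors
#' @export
setGeneric("onTreatment", function(object) standardGeneric("onTreatment"))

#' @rdname repertoire-accessors
setMethod("clones", "RepertoireSample", function(object) object@clones)

#' @rdname repertoire-accessors
setMethod("sampleId", "RepertoireSample", function(object) object@sampleId)

#' @rdname repertoire-accessors
setMethod("participantId", "RepertoireSample",
          function(object) object@participantId)

#' @rdname repertoire-accessors
setMethod("timepoint", "RepertoireSample", function(object) object@timepoint)

#' @rdname repertoire-accessors
setMethod("nucleatedCells", "RepertoireSample",
          function(object) object@nucleatedCells)

#' @rdname repertoire-accessors
setMethod("totalTemplates", "RepertoireSample",
          function(object) sum(object@clones$templates))

#' @rdname repertoire-accessors
setMethod("productiveTemplates", "RepertoireSample", function(object) {
    sum(object@clones$templates[object@clones$productive])
})

#' @rdname repertoire-accessors
setMethod("participantId", "PairedRepertoire",
          function(object) object@participantId)

#' @rdname repertoire-accessors
setMethod("baseline", "PairedRepertoire", function(object) object@baseline)

#' @rdname repertoire-accessors
setMethod("onTreatment", "PairedRepertoire",
          function(object) object@onTreatment)

setMethod("show", "RepertoireSample", function(object) {
    cl <- object@clones
    cat("RepertoireSample '", object@sampleId, "'",
        if (!is.na(object@participantId))
            paste0(" (participant ", object@participantId,
                   if (!is.na(object@timepoint))
                       paste0(", ", object@timepoint), ")"),
        "\n", sep = "")
    cat("  ", nrow(cl), " unique rearrangements; ",
        sum(cl$templates), " templates (",
        sum(cl$templates[cl$productive]), " productive)\n", sep = "")
    if (!is.na(object@nucleatedCells))
        cat("  nucleated cells: ", format(object@nucleatedCells), "\n",
            sep = "")
    invisible(NULL)
})

setMethod("show", "PairedRepertoire", function(object) {
    cat("PairedRepertoire for participant '", object@participantId, "'\n",
        sep = "")
    cat("  baseline:     ", nrow(object@baseline@clones), " clones, ",
        productiveTemplates(object@baseline), " productive templates\n",
        sep = "")
    cat("  end of cycle: ", nrow(object@onTreatment@clones), " clones, ",
        productiveTemplates(object@onTreatment), " productive templates\n",
        sep = "")
    invisible(NULL)
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", sum(object@nParticipantsPerArm), "participants over",
        sum(object@nParticipantsPerArm > 0L), "arm(s)\n")
    cat("  baseline clones:", object@nClonesBaseline, "; law:",
        object@frequencyLaw,
        if (object@frequencyLaw == "power_law")
            paste0("(alpha=", object@alpha, ")")
        else paste0("(concentration=", object@concentration, ")"), "\n")
    cat("  depths:", object@depthBaseline, "/", object@depthOn,
        "templates; seed:", object@seed, "\n")
    for (a in names(object@armEffects)) {
        ef <- object@armEffects[[a]]
        cat(sprintf("  %-7s expanded=%d new=%d fold=%g\n", a,
                    ef$nExpandedExisting, ef$nNewClones, ef$fold))
    }
    invisible(NULL)
})
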