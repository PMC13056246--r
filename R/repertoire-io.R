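# Dialects: modern immunoSEQ export headers and a minimal 3-column fallback.
.COLUMN_MAPS <- list(
    immunoseq = list(id = "rearrangement", templates = "templates",
                     frame = "frame_type"),
    minimal = list(id = "clone_id", templates = "count",
                   productive = "productive")
)

.resolveColumnMap <- function(columnMap, header) {
    if (is.character(columnMap) && length(columnMap) == 1L &&
        grepl("\\.ya?ml$", columnMap)) {
        columnMap <- yaml::read_yaml(columnMap)
    }
    if (!is.null(columnMap)) {
        if (is.null(columnMap$id) || is.null(columnMap$templates) ||
            (is.null(columnMap$frame) && is.null(columnMap$productive)))
            stop("columnMap must name 'id', 'templates' and one of ",
                 "'frame' or 'productive'")
        return(columnMap)
    }
    for (map in .COLUMN_MAPS) {
        if (all(unlist(map) %in% header)) return(map)
    }
    stop("rearrangement table format error: header does not match a known ",
         "dialect; expected columns ",
         paste(vapply(.COLUMN_MAPS, function(m)
             paste0("(", paste(unlist(m), collapse = ", "), ")"),
             character(1)), collapse = " or "),
         "; found (", paste(header, collapse = ", "), ")")
}

.asProductive <- function(x) {
    if (is.logical(x)) return(x)
    if (is.numeric(x)) return(x != 0)
    tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes", "in")
}

#' Read an immunoSEQ-dialect rearrangement table
#'
#' Reads a tab-separated rearrangement export (one row per unique
#' rearrangement with its template count and frame status) into a
#' \linkS4class{RepertoireSample}. Two header dialects are recognised
#' automatically: the vendor-style \code{rearrangement} / \code{templates} /
#' \code{frame_type} (frame \code{"In"}, case-insensitively, means
#' productive) and a minimal \code{clone_id} / \code{count} /
#' \code{productive} fallback. Other dialects can be declared via
#' \code{columnMap}. Rows sharing a rearrangement key are merged by summing
#' their template counts.
#'
#' @param path path to a TSV file with a header row.
#' @param sampleId sample identifier; defaults to the file name without
#'   extension.
#' @param participantId,timepoint,nucleatedCells optional sample metadata,
#'   normally supplied through the manifest (see [loadCohort()]).
#' @param columnMap \code{NULL} for auto-detection, a list with elements
#'   \code{id}, \code{templates} and \code{frame} (or \code{productive}),
#'   or the path to a YAML file holding such a list.
#' @return A \linkS4class{RepertoireSample}.
#' @seealso [writeRearrangementTable()], [loadCohort()]
#' @export
readRearrangementTable <- function(path, sampleId = NULL,
                                   participantId = NA_character_,
                                   timepoint = NA_character_,
                                   nucleatedCells = NA_real_,
                                   columnMap = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE)
    map <- .resolveColumnMap(columnMap, names(tab))
    for (col in c(map$id, map$templates, map$frame, map$productive)) {
        if (!col %in% names(tab))
            stop("rearrangement table format error: missing required ",
                 "column '", col, "' in ", path)
    }
    tmpl <- suppressWarnings(as.numeric(tab[[map$templates]]))
    bad <- which(is.na(tmpl) | tmpl < 0 | tmpl != round(tmpl))
    if (length(bad))
        stop("invalid template count in ", path, " at data row(s) ",
             paste(utils::head(bad, 5L), collapse = ", "),
             ": counts must be non-negative integers")
    productive <- if (!is.null(map$frame)) {
        tolower(trimws(as.character(tab[[map$frame]]))) == "in"
    } else {
        .asProductive(tab[[map$productive]])
    }
    cl <- data.frame(rearrangement_id = as.character(tab[[map$id]]),
                     templates = as.integer(tmpl),
                     productive = productive,
                     stringsAsFactors = FALSE)
    if ("amino_acid" %in% names(tab))
        cl$cdr3_aa <- as.character(tab[["amino_acid"]])
    if (anyDuplicated(cl$rearrangement_id)) {
        flag <- tapply(cl$productive, cl$rearrangement_id, function(x) {
            if (length(unique(x)) > 1L)
                stop("inconsistent frame status for duplicated ",
                     "rearrangement key in ", path)
            x[1L]
        })
        counts <- tapply(cl$templates, cl$rearrangement_id, sum)
        keep <- !duplicated(cl$rearrangement_id)
        merged <- cl[keep, , drop = FALSE]
        merged$templates <- as.integer(counts[merged$rearrangement_id])
        merged$productive <- as.logical(flag[merged$rearrangement_id])
        cl <- merged
    }
    if (is.null(sampleId))
        sampleId <- sub("\\.[^.]*$", "", basename(path))
    RepertoireSample(cl, sampleId = sampleId, participantId = participantId,
                     timepoint = timepoint, nucleatedCells = nucleatedCells)
}

#' Write a repertoire sample as a rearrangement TSV
#'
#' Writes the clone table in the vendor-style dialect (\code{rearrangement},
#' \code{templates}, \code{frame_type}), so that
#' \code{readRearrangementTable()} round-trips the
#' (rearrangement, templates, productive) triples exactly.
#'
#' @param sample a \linkS4class{RepertoireSample}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeRearrangementTable <- function(sample, path) {
    cl <- clones(sample)
    out <- data.frame(rearrangement = cl$rearrangement_id,
                      templates = cl$templates,
                      frame_type = ifelse(cl$productive, "In", "Out"),
                      stringsAsFactors = FALSE)
    if ("cdr3_aa" %in% names(cl)) out$amino_acid <- cl$cdr3_aa
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read and validate a sample manifest
#'
#' The manifest lists one row per sample with participant, arm, timepoint,
#' response label, the rearrangement file and (optionally) the
#' nucleated-cell denominator. CSV and YAML (a list of row records) are
#' accepted.
#'
#' @param path path to a \code{.csv} or \code{.yaml}/\code{.yml} manifest.
#' @return A data.frame with columns \code{sample_id}, \code{participant_id},
#'   \code{arm}, \code{timepoint}, \code{response}, \code{file},
#'   \code{nucleated_cells}.
#' @export
readManifest <- function(path) {
    if (grepl("\\.ya?ml$", path)) {
        rows <- yaml::read_yaml(path)
        man <- do.call(rbind, lapply(rows, function(r)
            as.data.frame(r, stringsAsFactors = FALSE)))
    } else {
        man <- utils::read.csv(path, stringsAsFactors = FALSE)
    }
    validateManifest(man)
}

#' @rdname readManifest
#' @param manifest a manifest data.frame to validate in place.
#' @export
validateManifest <- function(manifest) {
    req <- c("sample_id", "participant_id", "arm", "timepoint", "file")
    miss <- setdiff(req, names(manifest))
    if (length(miss))
        stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
    if (!"response" %in% names(manifest))
        manifest$response <- NA_character_
    if (!"nucleated_cells" %in% names(manifest))
        manifest$nucleated_cells <- NA_real_
    badArm <- setdiff(unique(manifest$arm), .ARMS)
    if (length(badArm))
        stop("unknown arm label(s): ", paste(badArm, collapse = ", "),
             "; expected one of ", paste(.ARMS, collapse = ", "))
    badTp <- setdiff(unique(manifest$timepoint), .TIMEPOINTS)
    if (length(badTp))
        stop("unknown timepoint(s): ", paste(badTp, collapse = ", "))
    badResp <- setdiff(unique(stats::na.omit(manifest$response)), .RESPONSES)
    if (length(badResp))
        stop("unknown response label(s): ", paste(badResp, collapse = ", "))
    key <- paste(manifest$participant_id, manifest$timepoint)
    if (anyDuplicated(key))
        stop("duplicate (participant, timepoint) in manifest: ",
             paste(unique(key[duplicated(key)]), collapse = "; "))
    manifest
}

#' Load all repertoire samples referenced by a manifest
#'
#' @param manifest a manifest data.frame (see [readManifest()]) or a path to
#'   one.
#' @param baseDir directory that relative \code{file} entries are resolved
#'   against; defaults to the manifest's own directory when a path is given,
#'   else the working directory.
#' @return A named list of \linkS4class{RepertoireSample} objects, one per
#'   manifest row, named by \code{sample_id}.
#' @seealso [pairSamples()]
#' @export
loadCohort <- function(manifest, baseDir = NULL) {
    if (is.character(manifest)) {
        if (is.null(baseDir)) baseDir <- dirname(manifest)
        manifest <- readManifest(manifest)
    } else {
        manifest <- validateManifest(manifest)
        if (is.null(baseDir)) baseDir <- "."
    }
    paths <- ifelse(grepl("^(/|[A-Za-z]:)", manifest$file), manifest$file,
                    file.path(baseDir, manifest$file))
    missing <- paths[!file.exists(paths)]
    if (length(missing))
        stop("manifest references missing file(s): ",
             paste(utils::head(missing, 5L), collapse = ", "))
    samples <- lapply(seq_len(nrow(manifest)), function(i) {
        readRearrangementTable(paths[i], sampleId = manifest$sample_id[i],
                               participantId = manifest$participant_id[i],
                               timepoint = manifest$timepoint[i],
                               nucleatedCells = manifest$nucleated_cells[i])
    })
    names(samples) <- manifest$sample_id
    samples
}

#' Assemble paired repertoires from a sample collection
#'
#' Pairs each participant's baseline sample with their end-of-cycle-1 sample.
#' Only participants with exactly one sample at each timepoint are evaluable;
#' the number of non-evaluable participants is reported as a message.
#'
#' @param samples a list of \linkS4class{RepertoireSample} objects (e.g. from
#'   [loadCohort()]).
#' @return A named list of \linkS4class{PairedRepertoire} objects keyed by
#'   participant id.
#' @export
pairSamples <- function(samples) {
    if (length(samples) == 0L) {
        warning("no samples supplied; returning an empty pairing")
        return(structure(list(), names = character()))
    }
    pid <- vapply(samples, participantId, character(1))
    tp <- vapply(samples, timepoint, character(1))
    key <- paste(pid, tp)
    if (anyDuplicated(key))
        stop("duplicate (participant, timepoint) samples: ",
             paste(unique(key[duplicated(key)]), collapse = "; "))
    pairs <- list()
    nDropped <- 0L
    for (p in unique(pid)) {
        b <- which(pid == p & tp == "baseline")
        o <- which(pid == p & tp == "end_of_cycle1")
        if (length(b) == 1L && length(o) == 1L) {
            pairs[[p]] <- PairedRepertoire(samples[[b]], samples[[o]])
        } else {
            nDropped <- nDropped + 1L
        }
    }
    if (nDropped > 0L)
        message(nDropped, " participant(s) lacked a sample at one ",
                "timepoint and are not evaluable for paired analyses")
    pairs
}
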