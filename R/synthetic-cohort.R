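# Default per-arm expansion effects: tremelimumab-dose-ordered,
# D+B ~ D < T75+D < STRIDE < T (qualitative ordering, not trial medians).
.DEFAULT_ARM_EFFECTS <- list(
    "D+B"    = list(nExpandedExisting = 4L,  nNewClones = 3L,  fold = 6),
    "D"      = list(nExpandedExisting = 5L,  nNewClones = 4L,  fold = 6),
    "T75+D"  = list(nExpandedExisting = 10L, nNewClones = 8L,  fold = 6),
    "STRIDE" = list(nExpandedExisting = 16L, nNewClones = 14L, fold = 6),
    "T"      = list(nExpandedExisting = 28L, nNewClones = 24L, fold = 6)
)

# immunoSEQ-evaluable sample sizes per arm in the emulated trial.
.DEFAULT_N_PER_ARM <- c("D+B" = 37L, "D" = 31L, "T75+D" = 26L,
                        "STRIDE" = 28L, "T" = 17L)

# Objective response probability per arm (biomarker-evaluable rates).
.DEFAULT_PROP_RESPONDERS <- c("D+B" = 0.297, "D" = 0.161, "T75+D" = 0.077,
                              "STRIDE" = 0.321, "T" = 0.059)

.expandPerArm <- function(x, arms, what) {
    if (is.null(names(x))) {
        if (length(x) != 1L)
            stop(what, " must be a scalar or a named per-arm vector")
        x <- stats::setNames(rep(x, length(arms)), arms)
    }
    miss <- setdiff(arms, names(x))
    if (length(miss))
        stop(what, " missing arm(s): ", paste(miss, collapse = ", "))
    x[arms]
}

#' Configure the synthetic paired-repertoire cohort
#'
#' Builds a \linkS4class{SimConfig}. Defaults emulate the structure of a
#' five-arm immunotherapy trial: per-arm sample sizes matching a
#' biomarker-evaluable population (37/31/26/28/17 for D+B, D, T75+D, STRIDE
#' and T), a power-law baseline clone-frequency distribution over
#' \eqn{2\times 10^4} clones, 50,000 templates drawn per sample, and per-arm
#' expansion effects ordered D+B \eqn{\approx} D < T75+D < STRIDE < T.
#'
#' @param nParticipantsPerArm scalar or named per-arm integer vector.
#' @param nClonesBaseline number of ground-truth baseline clones (U).
#' @param frequencyLaw \code{"power_law"} (frequencies proportional to
#'   rank^-alpha) or \code{"dirichlet"} (symmetric Dirichlet; flat
#'   repertoires).
#' @param alpha power-law exponent.
#' @param concentration Dirichlet concentration parameter.
#' @param depthBaseline,depthOn total templates per sample at the two
#'   timepoints.
#' @param armEffects named list per arm, each with
#'   \code{nExpandedExisting} (existing clones multiplied by \code{fold} in
#'   the on-treatment frequency model), \code{nNewClones} (novel clones
#'   inserted on treatment) and \code{fold}.
#' @param responderBoost multiplier on both expansion counts for responders.
#' @param propResponders,propNonevaluable per-arm probabilities of the
#'   response labels (scalar or named vector). A participant is first drawn
#'   nonevaluable with probability \code{propNonevaluable}; otherwise
#'   responder with probability \code{propResponders}.
#' @param propNonproductive fraction of unique clones flagged nonproductive.
#' @param maxCloneFreq eligibility cap: only clones with baseline frequency
#'   between \code{1/depthBaseline} and this value can be drawn as truly
#'   expanded (perturbing a hyperexpanded clone distorts the whole
#'   repertoire through renormalisation).
#' @param seed master seed; every draw is a deterministic function of it.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nParticipantsPerArm = 2L, nClonesBaseline = 500L,
#'                  depthBaseline = 2000L, depthOn = 2000L, seed = 7L)
#' cfg
#' @export
simConfig <- function(nParticipantsPerArm = .DEFAULT_N_PER_ARM,
                      nClonesBaseline = 20000L,
                      frequencyLaw = c("power_law", "dirichlet"),
                      alpha = 2.0, concentration = 1.0,
                      depthBaseline = 50000L, depthOn = 50000L,
                      armEffects = .DEFAULT_ARM_EFFECTS,
                      responderBoost = 3.0,
                      propResponders = .DEFAULT_PROP_RESPONDERS,
                      propNonevaluable = 0.1,
                      propNonproductive = 0.03,
                      maxCloneFreq = 0.01,
                      seed = 1L) {
    frequencyLaw <- match.arg(frequencyLaw)
    arms <- names(armEffects)
    if (is.null(arms)) stop("armEffects must be a named list")
    n <- .expandPerArm(nParticipantsPerArm, arms, "nParticipantsPerArm")
    new("SimConfig",
        nParticipantsPerArm = stats::setNames(as.integer(n), arms),
        nClonesBaseline = as.integer(nClonesBaseline),
        frequencyLaw = frequencyLaw, alpha = alpha,
        concentration = concentration,
        depthBaseline = as.integer(depthBaseline),
        depthOn = as.integer(depthOn),
        armEffects = armEffects, responderBoost = responderBoost,
        propResponders = .expandPerArm(propResponders, arms,
                                       "propResponders"),
        propNonevaluable = .expandPerArm(propNonevaluable, arms,
                                         "propNonevaluable"),
        propNonproductive = propNonproductive,
        maxCloneFreq = maxCloneFreq,
        seed = as.integer(seed))
}

#' A pure-null variant of a simulation configuration
#'
#' Convenience wrapper: zero expanded clones, zero novel clones and fold 1 in
#' every arm, so both samples of each pair are independent multinomial draws
#' from the same frequency vector. Used for false-discovery calibration.
#'
#' @param ... passed on to [simConfig()] (e.g. \code{nParticipantsPerArm},
#'   \code{seed}).
#' @return A \linkS4class{SimConfig} with null arm effects.
#' @export
nullSimConfig <- function(...) {
    args <- list(...)
    if (is.null(args$armEffects)) {
        arms <- if (!is.null(args$nParticipantsPerArm) &&
                    !is.null(names(args$nParticipantsPerArm)))
            names(args$nParticipantsPerArm) else .ARMS
        args$armEffects <- stats::setNames(lapply(arms, function(a)
            list(nExpandedExisting = 0L, nNewClones = 0L, fold = 1)), arms)
    }
    do.call(simConfig, args)
}

# Deterministic per-participant seed, kept inside 32-bit integer range.
.participantSeed <- function(config, arm, index) {
    armIdx <- match(arm, names(config@armEffects))
    as.integer((as.double(config@seed) * 97L + armIdx * 15485863 +
                index * 32452843) %% 2147483011)
}

.baselineFrequencies <- function(config) {
    U <- config@nClonesBaseline
    if (config@frequencyLaw == "power_law") {
        p <- seq_len(U)^(-config@alpha)
    } else {
        p <- stats::rgamma(U, shape = config@concentration, rate = 1)
        p[p <= 0] <- min(p[p > 0]) # guard against underflow at tiny shape
    }
    p / sum(p)
}

#' Simulate one participant's paired repertoire
#'
#' Draws a ground-truth baseline clone-frequency vector from the configured
#' law, samples baseline templates multinomially, applies the arm's effect
#' (selected existing clones multiplied by \code{fold}; novel clones inserted
#' at \code{fold} times the median frequency of the detectable support),
#' renormalises, and samples on-treatment templates multinomially. A
#' configurable fraction of clones is flagged nonproductive. All randomness
#' is a deterministic function of \code{(config@seed, arm, index)}, split
#' into named substreams so that changing \code{fold} leaves the frequency
#' and sampling streams aligned.
#'
#' Truly-expanded clones are drawn among clones with expected baseline count
#' of at least one template and baseline frequency at most
#' \code{maxCloneFreq}; with heavy-tailed frequency laws, clones outside this
#' window are either undetectable at the configured depth or so dominant
#' that perturbing them would be a repertoire-wide, not clone-level, effect.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param arm arm label (must be a name of \code{config@armEffects}).
#' @param index 1-based participant index within the arm (seeds the
#'   participant's substreams).
#' @param responder logical; responders have both expansion counts
#'   multiplied by \code{config@responderBoost}.
#' @return A list with elements \code{pair} (a
#'   \linkS4class{PairedRepertoire}) and \code{truth} (list with
#'   \code{expanded_ids}, \code{novel_ids}, \code{responder}).
#' @note Uses and therefore alters the global RNG state.
#' @export
simulateParticipant <- function(config, arm, index = 1L, responder = FALSE) {
    ef <- config@armEffects[[arm]]
    if (is.null(ef)) stop("unknown arm: ", arm)
    U <- config@nClonesBaseline
    boost <- if (responder) config@responderBoost else 1
    nExp <- as.integer(round(ef$nExpandedExisting * boost))
    nNew <- as.integer(round(ef$nNewClones * boost))
    if (nExp > U)
        stop("nExpandedExisting (", nExp, ") exceeds the number of ",
             "baseline clones (", U, ")")
    pseed <- .participantSeed(config, arm, index)

    # substream 1: ground-truth frequencies, flags, choice of expanded clones
    set.seed(pseed)
    p0 <- .baselineFrequencies(config)
    nonproductive <- stats::runif(U) < config@propNonproductive
    detectable <- p0 * config@depthBaseline >= 1
    eligible <- which(detectable & p0 <= config@maxCloneFreq &
                      !nonproductive)
    if (nExp > length(eligible))
        stop("only ", length(eligible), " clones are eligible for true ",
             "expansion at this depth/frequency law; requested ", nExp)
    expandedIdx <- if (nExp > 0L) sample(eligible, nExp) else integer()
    tcfBase <- stats::runif(1, 0.05, 0.25)
    tcfOn <- stats::runif(1, 0.05, 0.25)

    # on-treatment frequency model
    pOn <- p0
    pOn[expandedIdx] <- pOn[expandedIdx] * ef$fold
    novelFreq <- if (nNew > 0L) {
        support <- which(detectable & !nonproductive)
        rep(ef$fold * stats::median(p0[support]), nNew)
    } else numeric()
    pOn <- c(pOn, novelFreq)
    pOn <- pOn / sum(pOn)

    ids <- sprintf("clone%05d", seq_len(U))
    novelIds <- if (nNew > 0L) sprintf("novel%s%03d", arm, seq_len(nNew))
                else character()
    allIds <- c(ids, novelIds)
    prodFlag <- c(!nonproductive, rep(TRUE, nNew))

    # substream 2: baseline draw; substream 3: on-treatment draw
    set.seed(pseed + 1L)
    cBase <- as.integer(stats::rmultinom(1, config@depthBaseline, p0))
    set.seed(pseed + 2L)
    cOn <- as.integer(stats::rmultinom(1, config@depthOn, pOn))

    pid <- sprintf("%s_p%03d", gsub("[^A-Za-z0-9]", "", arm), index)
    mkSample <- function(counts, idsAll, prod, tp, tcf, depth) {
        obs <- which(counts > 0L)
        cl <- data.frame(rearrangement_id = idsAll[obs],
                         templates = counts[obs],
                         productive = prod[obs],
                         stringsAsFactors = FALSE)
        RepertoireSample(cl, sampleId = paste0(pid, "_", tp),
                         participantId = pid, timepoint = tp,
                         nucleatedCells = round(depth / tcf))
    }
    base <- mkSample(cBase, ids, !nonproductive, "baseline", tcfBase,
                     config@depthBaseline)
    on <- mkSample(cOn, allIds, prodFlag, "end_of_cycle1", tcfOn,
                   config@depthOn)
    list(pair = PairedRepertoire(base, on),
         truth = list(expanded_ids = ids[expandedIdx],
                      novel_ids = novelIds,
                      responder = responder))
}

#' Simulate a full multi-arm cohort
#'
#' Draws response labels per participant, simulates every paired repertoire,
#' and (optionally) writes one rearrangement TSV per sample plus a manifest
#' and a ground-truth file, fully reproducibly from \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param dir output directory; when \code{NULL} (default) nothing is
#'   written and the cohort is returned in memory only.
#' @return A list with \code{pairs} (named list of
#'   \linkS4class{PairedRepertoire}), \code{manifest} (data.frame, one row
#'   per sample), and \code{truth} (named list per participant).
#' @note Uses and therefore alters the global RNG state.
#' @examples
#' cfg <- nullSimConfig(nParticipantsPerArm = c(D = 2L),
#'                      nClonesBaseline = 300L, depthBaseline = 1000L,
#'                      depthOn = 1000L, seed = 42L)
#' coh <- simulateCohort(cfg)
#' names(coh$pairs)
#' @export
simulateCohort <- function(config, dir = NULL) {
    arms <- names(config@armEffects)
    pairs <- list(); truth <- list(); rows <- list()
    for (arm in arms) {
        n <- config@nParticipantsPerArm[[arm]]
        if (n == 0L) next
        # response labels: one substream per arm
        set.seed(.participantSeed(config, arm, 0L))
        noneval <- stats::runif(n) < config@propNonevaluable[[arm]]
        resp <- stats::runif(n) < config@propResponders[[arm]]
        labels <- ifelse(noneval, "nonevaluable",
                         ifelse(resp, "responder", "nonresponder"))
        for (i in seq_len(n)) {
            sim <- simulateParticipant(config, arm, index = i,
                                       responder = labels[i] == "responder")
            pid <- participantId(sim$pair)
            pairs[[pid]] <- sim$pair
            truth[[pid]] <- c(sim$truth, list(response = labels[i]))
            for (s in list(baseline(sim$pair), onTreatment(sim$pair))) {
                rows[[length(rows) + 1L]] <- data.frame(
                    sample_id = sampleId(s), participant_id = pid,
                    arm = arm, timepoint = timepoint(s),
                    response = labels[i],
                    nucleated_cells = nucleatedCells(s),
                    file = paste0(sampleId(s), ".tsv"),
                    stringsAsFactors = FALSE)
            }
        }
    }
    manifest <- do.call(rbind, rows)
    rownames(manifest) <- NULL
    if (!is.null(dir)) {
        if (!dir.exists(dir) &&
            !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
            stop("cannot create output directory: ", dir)
        for (pid in names(pairs)) {
            writeRearrangementTable(baseline(pairs[[pid]]),
                file.path(dir, paste0(sampleId(baseline(pairs[[pid]])),
                                      ".tsv")))
            writeRearrangementTable(onTreatment(pairs[[pid]]),
                file.path(dir, paste0(sampleId(onTreatment(pairs[[pid]])),
                                      ".tsv")))
        }
        utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                         row.names = FALSE)
        yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
    }
    list(pairs = pairs, manifest = manifest, truth = truth)
}
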