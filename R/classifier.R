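# The three interface indicators, consensus call, robust-call filter and
# per-entry monomer/multimer verdict.

# run expr under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Geometry indicator: interface core size
#'
#' Counts residues buried above the geometric threshold over both
#' partners; six or more core residues indicate a biological interface.
#'
#' @param interface An \linkS4class{Interface}.
#' @param coreCallCutoff Core-count cutoff for a BIO call (default 6).
#' @param coreBurialThreshold Burial ratio defining geometric core
#'   residues (default 0.95).
#' @return List with \code{nCore} (integer) and \code{call} ("BIO" or
#'   "XTAL"; the geometry indicator never abstains).
#' @export
geometryIndicator <- function(interface, coreCallCutoff = 6L,
                              coreBurialThreshold = 0.95) {
    reg <- assignRegions(interface, coreBurialThreshold)
    nCore <- sum(reg$a == "CORE") + sum(reg$b == "CORE")
    list(nCore = as.integer(nCore),
         call = if (nCore >= coreCallCutoff) "BIO" else "XTAL")
}

# entropy values of the residues of one partner with a given region label
.regionEntropies <- function(labels, profile, which) {
    idx <- which(labels == which)
    e <- profile@entropy[idx]
    e[!is.na(e)]
}

#' Core-rim indicator: entropy ratio of core to rim residues
#'
#' Ratio of the mean sequence entropy of core residues (both partners
#' pooled, evolutionary burial threshold) to the mean entropy of rim
#' residues. A conserved core gives a low ratio; the call is BIO iff
#' ratio < \code{callCutoff}. NOPRED when either profile is insufficient,
#' when core or rim is empty, or when the rim mean entropy is zero.
#'
#' @param interface An \linkS4class{Interface}.
#' @param profileA,profileB \linkS4class{EntropyProfile}s of the two
#'   partners (NULL when no alignment is available).
#' @param callCutoff Ratio cutoff for a BIO call (default 0.75).
#' @param coreBurialThreshold Burial ratio for the evolutionary core
#'   (default 0.70).
#' @return List with \code{ratio} (numeric or NA) and \code{call}.
#' @export
coreRimIndicator <- function(interface, profileA, profileB,
                             callCutoff = 0.75,
                             coreBurialThreshold = 0.70) {
    nopred <- list(ratio = NA_real_, call = "NOPRED")
    if (is.null(profileA) || is.null(profileB) ||
        profileA@insufficient || profileB@insufficient) return(nopred)
    reg <- assignRegions(interface, coreBurialThreshold)
    core <- c(.regionEntropies(reg$a, profileA, "CORE"),
              .regionEntropies(reg$b, profileB, "CORE"))
    rim <- c(.regionEntropies(reg$a, profileA, "RIM"),
             .regionEntropies(reg$b, profileB, "RIM"))
    if (length(core) == 0 || length(rim) == 0) return(nopred)
    if (mean(rim) <= 0) return(nopred)
    ratio <- mean(core) / mean(rim)
    list(ratio = ratio,
         call = if (ratio < callCutoff) "BIO" else "XTAL")
}

#' Core-surface indicator: differential conservation z-score
#'
#' For each partner, random subsets of its surface residues of the size
#' of its core are drawn; the score is the z-value of the pooled mean
#' core entropy against the distribution of sample means. A strongly
#' conserved core gives a negative score; the call is BIO iff
#' score < \code{callCutoff}. NOPRED when a profile is insufficient, the
#' core is empty, a partner's surface pool is smaller than its core, or
#' the sample-mean distribution is degenerate (zero spread).
#'
#' @inheritParams coreRimIndicator
#' @param nSamples Number of surface subsets (>= 100; default 10000).
#' @param seed RNG seed for the surface sampling.
#' @param callCutoff Score cutoff for a BIO call (default -1.0).
#' @return List with \code{score} (numeric or NA) and \code{call}.
#' @export
coreSurfaceIndicator <- function(interface, profileA, profileB,
                                 nSamples = 10000L, seed = 42L,
                                 callCutoff = -1.0,
                                 coreBurialThreshold = 0.70) {
    if (nSamples < 100) stop("nSamples must be >= 100")
    nopred <- list(score = NA_real_, call = "NOPRED")
    if (is.null(profileA) || is.null(profileB) ||
        profileA@insufficient || profileB@insufficient) return(nopred)
    reg <- assignRegions(interface, coreBurialThreshold)
    pools <- list()
    coreEnt <- numeric(0)
    for (p in list(list(reg$a, profileA), list(reg$b, profileB))) {
        core <- .regionEntropies(p[[1]], p[[2]], "CORE")
        surf <- .regionEntropies(p[[1]], p[[2]], "SURFACE")
        if (length(core) == 0) next
        if (length(surf) < length(core)) return(nopred)
        coreEnt <- c(coreEnt, core)
        pools[[length(pools) + 1L]] <- list(k = length(core), surf = surf)
    }
    if (length(coreEnt) == 0) return(nopred)
    sampleMeans <- .withSeed(seed, {
        vapply(seq_len(nSamples), function(s) {
            v <- unlist(lapply(pools, function(pl)
                pl$surf[sample.int(length(pl$surf), pl$k)]))
            mean(v)
        }, numeric(1))
    })
    spread <- sd(sampleMeans)
    if (!is.finite(spread) || spread <= 0) return(nopred)
    score <- (mean(coreEnt) - mean(sampleMeans)) / spread
    list(score = score,
         call = if (score < callCutoff) "BIO" else "XTAL")
}

#' Consensus of the three indicator calls
#'
#' Majority vote over the non-abstaining calls. When both evolutionary
#' indicators abstain the geometry call decides; a one-one tie with one
#' abstention is broken by the core-surface call when available (the
#' strongest single indicator), otherwise by geometry.
#'
#' @param callGeometry,callCoreRim,callCoreSurface "BIO", "XTAL" or
#'   "NOPRED".
#' @return Character(1): "BIO", "XTAL" or "NOPRED".
#' @export
consensusCall <- function(callGeometry, callCoreRim, callCoreSurface) {
    calls <- c(geometry = callGeometry, corerim = callCoreRim,
               coresurface = callCoreSurface)
    voting <- calls[calls != "NOPRED"]
    if (length(voting) == 0) return("NOPRED")
    nBio <- sum(voting == "BIO")
    nXtal <- sum(voting == "XTAL")
    if (nBio > nXtal) return("BIO")
    if (nXtal > nBio) return("XTAL")
    # one BIO, one XTAL, one NOPRED
    if (callCoreSurface != "NOPRED") return(callCoreSurface)
    callGeometry
}

#' Robust-call filter
#'
#' A call qualifies as robust iff the entry is a well-refined crystal
#' structure (resolution < 2.5 Angstrom, free R-factor < 0.3), at least
#' 30 homologs back the evolutionary scores, the three indicators agree
#' unanimously (an abstention is non-unanimous), and the core-surface
#' score is extreme: below -3.3 for biological calls, above 0.15 for
#' crystal-contact calls.
#'
#' @param structure The \linkS4class{CrystalStructure} of the entry.
#' @param call An \linkS4class{InterfaceCall}.
#' @param nHomologs Homolog count backing the profiles (take the minimum
#'   over the two partners).
#' @param maxResolution,maxRFree,minHomologs,bioScoreMax,xtalScoreMin
#'   Filter bounds (defaults 2.5, 0.3, 30, -3.3, 0.15).
#' @return Logical(1).
#' @export
robustFilter <- function(structure, call, nHomologs,
                         maxResolution = 2.5, maxRFree = 0.3,
                         minHomologs = 30L, bioScoreMax = -3.3,
                         xtalScoreMin = 0.15) {
    if (!is.finite(structure@resolution) || !is.finite(structure@rFree))
        return(FALSE)
    if (structure@resolution >= maxResolution) return(FALSE)
    if (structure@rFree >= maxRFree) return(FALSE)
    if (is.na(nHomologs) || nHomologs < minHomologs) return(FALSE)
    calls <- c(call@callGeometry, call@callCoreRim, call@callCoreSurface)
    if (any(calls == "NOPRED") || length(unique(calls)) != 1L)
        return(FALSE)
    score <- call@coreSurfaceScore
    if (!is.finite(score)) return(FALSE)
    if (call@consensus == "BIO") return(score < bioScoreMax)
    if (call@consensus == "XTAL") return(score > xtalScoreMin)
    FALSE
}

#' Monomer/multimer verdict for an entry
#'
#' An entry is multimeric iff at least one of its interfaces is called
#' biological by the consensus; otherwise (including entries with no
#' interfaces) it is monomeric.
#'
#' @param calls List of \linkS4class{InterfaceCall}.
#' @return Character(1): "MULTIMERIC" or "MONOMERIC".
#' @export
entryVerdict <- function(calls) {
    anyBio <- any(vapply(calls, function(cl)
        cl@consensus == "BIO", logical(1)))
    if (anyBio) "MULTIMERIC" else "MONOMERIC"
}

#' Run configuration with all classification thresholds
#'
#' Bundles every tunable of the pipeline with its documented default.
#'
#' @param ... Overrides by name.
#' @return Named list of settings.
#' @export
runConfig <- function(...) {
    cfg <- list(
        contactDistance = 5.9, minArea = 35, probe = 1.4, nPoints = 960L,
        minChainLength = 10L,
        geomBurialThreshold = 0.95, evolBurialThreshold = 0.70,
        surfaceMinAsa = 5,
        coreCallCutoff = 6L, coreRimCallCutoff = 0.75,
        coreSurfaceCallCutoff = -1.0,
        identityCutoff = 0.5, minHomologs = 10L,
        nSamples = 10000L, seed = 42L,
        robustMaxResolution = 2.5, robustMaxRFree = 0.3,
        robustMinHomologs = 30L, robustBioScoreMax = -3.3,
        robustXtalScoreMin = 0.15,
        binWidth = 200)
    over <- list(...)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
        stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    cfg
}

#' Classify one interface with all three indicators
#'
#' @param interface An \linkS4class{Interface}.
#' @param profileA,profileB \linkS4class{EntropyProfile}s of the two
#'   partners or NULL.
#' @param config A \code{\link{runConfig}} list.
#' @return An \linkS4class{InterfaceCall} (robust flag FALSE; apply
#'   \code{\link{robustFilter}} with the entry metadata to set it).
#' @export
classifyInterface <- function(interface, profileA = NULL, profileB = NULL,
                              config = runConfig()) {
    geo <- geometryIndicator(interface, config$coreCallCutoff,
                             config$geomBurialThreshold)
    cr <- coreRimIndicator(interface, profileA, profileB,
                           config$coreRimCallCutoff,
                           config$evolBurialThreshold)
    cs <- coreSurfaceIndicator(interface, profileA, profileB,
                               config$nSamples, config$seed,
                               config$coreSurfaceCallCutoff,
                               config$evolBurialThreshold)
    new("InterfaceCall", interfaceId = interface@id,
        nCoreGeom = geo$nCore, coreRimRatio = cr$ratio,
        coreSurfaceScore = cs$score,
        callGeometry = geo$call, callCoreRim = cr$call,
        callCoreSurface = cs$call,
        consensus = consensusCall(geo$call, cr$call, cs$call),
        robust = FALSE)
}

#' Analyze a structure end to end
#'
#' Enumerates lattice interfaces, computes entropy profiles for chains
#' with alignments, classifies every interface, applies the robust-call
#' filter and returns the entry verdict.
#'
#' @param structure A \linkS4class{CrystalStructure}.
#' @param alignments Named list of \linkS4class{HomologAlignment} keyed by
#'   chain id (chains without an alignment get geometry-only calls).
#' @param config A \code{\link{runConfig}} list.
#' @return List with \code{interfaces}, \code{calls}, \code{profiles},
#'   \code{verdict}.
#' @export
analyzeStructure <- function(structure, alignments = list(),
                             config = runConfig()) {
    interfaces <- findInterfaces(structure,
        contactDistance = config$contactDistance,
        minArea = config$minArea, probe = config$probe,
        nPoints = config$nPoints,
        minChainLength = config$minChainLength)
    profiles <- list()
    for (id in names(proteinChains(structure))) {
        if (!is.null(alignments[[id]]))
            profiles[[id]] <- entropyProfile(
                alignments[[id]], structure@chains[[id]],
                config$identityCutoff, config$minHomologs)
    }
    calls <- lapply(interfaces, function(ifc) {
        pA <- profiles[[ifc@chainA]]
        pB <- profiles[[ifc@chainB]]
        cl <- classifyInterface(ifc, pA, pB, config)
        nHom <- if (is.null(pA) || is.null(pB)) NA_integer_
                else min(pA@nHomologsUsed, pB@nHomologsUsed)
        cl@robust <- robustFilter(structure, cl, nHom,
                                  config$robustMaxResolution,
                                  config$robustMaxRFree,
                                  config$robustMinHomologs,
                                  config$robustBioScoreMax,
                                  config$robustXtalScoreMin)
        cl
    })
    list(interfaces = interfaces, calls = calls, profiles = profiles,
         verdict = entryVerdict(calls))
}

setMethod("show", "InterfaceCall", function(object) {
    cat(sprintf(
        paste0("InterfaceCall %d: consensus %s%s (geometry %s [%d core],",
               " core-rim %s [%.3g], core-surface %s [%.3g])\n"),
        object@interfaceId, object@consensus,
        if (isTRUE(object@robust)) " [robust]" else "",
        object@callGeometry, object@nCoreGeom,
        object@callCoreRim, object@coreRimRatio,
        object@callCoreSurface, object@coreSurfaceScore))
})
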