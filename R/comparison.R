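# Assembly-level prediction mapping, call-set comparison and
# confusion-matrix benchmarking.

#' Construct an assembly-level prediction
#'
#' A list of candidate assemblies, each with a stability category
#' (STABLE, GRAY or UNSTABLE), a size (number of chains) and the operator
#' fingerprints of its member interfaces.
#'
#' @param assemblies List of lists with elements \code{stability},
#'   \code{size}, \code{members} (character vector of fingerprints).
#' @return Object of class \code{AssemblyPrediction} (list-based).
#' @export
assemblyPrediction <- function(assemblies) {
    for (a in assemblies) {
        stopifnot(a$stability %in% c("STABLE", "GRAY", "UNSTABLE"),
                  a$size >= 1)
    }
    structure(list(assemblies = assemblies),
              class = "AssemblyPrediction")
}

#' Read an assembly prediction from its JSON schema
#'
#' Canonical neutral format: \code{{"assemblies": [{"stability": "STABLE",
#' "size": 2, "members": ["x,y,z|0,0,0"]}, ...]}}.
#'
#' @param path JSON file.
#' @return An \code{AssemblyPrediction}.
#' @export
readAssemblyPredictionJson <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = FALSE)
    assemblyPrediction(lapply(x$assemblies, function(a)
        list(stability = a$stability, size = a$size,
             members = unlist(a$members))))
}

#' Best-effort reader for PISA-style assembly XML
#'
#' Accepts documents with \code{<asm_set>/<assembly>} (or \code{<asu_set>})
#' nodes carrying a stability/score class, a size (\code{mmsize} or
#' \code{size}) and member interface operator triplets in
#' \code{<molecule><symop>} or \code{<interface><operator>} children.
#' Dialects vary by program version; the JSON schema of
#' \code{\link{readAssemblyPredictionJson}} is the canonical format.
#'
#' @param path XML file.
#' @return An \code{AssemblyPrediction}.
#' @export
readAssemblyPredictionXml <- function(path) {
    doc <- xml2::read_xml(path)
    nodes <- xml2::xml_find_all(doc, ".//assembly")
    assemblies <- lapply(nodes, function(nd) {
        stab <- xml2::xml_text(xml2::xml_find_first(
            nd, "./stability | ./score_class | ./@stability"))
        stab <- toupper(trimws(stab))
        if (!stab %in% c("STABLE", "GRAY", "UNSTABLE")) {
            stab <- if (grepl("GREY|GRAY", stab)) "GRAY"
                    else if (grepl("UNSTAB", stab)) "UNSTABLE"
                    else "STABLE"
        }
        sz <- xml2::xml_text(xml2::xml_find_first(
            nd, "./mmsize | ./size"))
        mem <- xml2::xml_text(xml2::xml_find_all(
            nd, ".//symop | .//operator"))
        list(stability = stab, size = as.integer(sz),
             members = mem)
    })
    assemblyPrediction(assemblies)
}

# parse "triplet|i,j,k" back into an operator
.parseFingerprint <- function(fp) {
    parts <- strsplit(fp, "|", fixed = TRUE)[[1]]
    op <- parseOperatorTriplet(parts[1])
    if (length(parts) > 1) {
        shift <- as.numeric(strsplit(parts[2], ",")[[1]])
        op <- symOperator(op@rot, op@trans, shift)
    }
    op
}

# direction-independent canonical key for a fingerprint or triplet string
.canonicalPairKey <- function(fp) fingerprintPair(.parseFingerprint(fp))

#' Map an assembly prediction onto per-interface calls
#'
#' Unstable assemblies are dropped. If only gray-region assemblies
#' remain, every interface is NOPRED. Otherwise the largest stable
#' assembly (ties: first encountered) defines the prediction: its member
#' interfaces (matched by crystallographic operator, direction
#' independent) are BIO, all others XTAL. Members matching no interface
#' produce a warning.
#'
#' @param pred An \code{AssemblyPrediction}.
#' @param interfaceFingerprints Character vector: operator fingerprint of
#'   every interface of the entry (see \code{\link{operatorFingerprint}}).
#' @return Character vector of calls ("BIO"/"XTAL"/"NOPRED"), one per
#'   interface.
#' @export
assemblyToInterfaceCalls <- function(pred, interfaceFingerprints) {
    n <- length(interfaceFingerprints)
    asm <- Filter(function(a) a$stability != "UNSTABLE",
                  pred$assemblies)
    if (length(asm) == 0) return(rep("XTAL", n))
    stable <- Filter(function(a) a$stability == "STABLE", asm)
    if (length(stable) == 0) return(rep("NOPRED", n))
    sizes <- vapply(stable, function(a) as.numeric(a$size), numeric(1))
    best <- stable[[which.max(sizes)]]  # which.max: first of the ties
    ifaceKeys <- vapply(interfaceFingerprints, .canonicalPairKey,
                        character(1))
    calls <- rep("XTAL", n)
    for (m in best$members) {
        key <- tryCatch(.canonicalPairKey(m), error = function(e) NA)
        hit <- which(ifaceKeys == key)
        if (is.na(key) || length(hit) == 0)
            warning("assembly member '", m,
                    "' matches no interface operator")
        else calls[hit] <- "BIO"
    }
    calls
}

#' Compare two per-interface call sets by area bin
#'
#' Per half-open area bin, the fractions of (BIO,BIO), (XTAL,XTAL),
#' discordant and NOPRED-involving pairs, plus the overall agreement over
#' pairs where both sides predict.
#'
#' @param callsA,callsB Character vectors of calls.
#' @param areas Numeric vector of interface areas, parallel to the calls.
#' @param binWidth Bin width, Angstrom^2 (default 200).
#' @return List with \code{table} (per-bin data.frame) and
#'   \code{agreement} (numeric(1)).
#' @export
compareCalls <- function(callsA, callsB, areas, binWidth = 200) {
    if (length(callsA) != length(callsB) ||
        length(callsA) != length(areas))
        stop("callsA, callsB and areas must have equal length")
    both <- callsA != "NOPRED" & callsB != "NOPRED"
    agreement <- if (any(both))
        mean(callsA[both] == callsB[both]) else NA_real_
    bin <- floor(areas / binWidth)
    tab <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
        i <- bin == b
        n <- sum(i)
        data.frame(bin_lo = b * binWidth, bin_hi = (b + 1) * binWidth,
                   n = n,
                   bio_bio = mean(callsA[i] == "BIO" & callsB[i] == "BIO"),
                   xtal_xtal = mean(callsA[i] == "XTAL" &
                                    callsB[i] == "XTAL"),
                   bio_xtal = mean(callsA[i] == "BIO" &
                                   callsB[i] == "XTAL"),
                   xtal_bio = mean(callsA[i] == "XTAL" &
                                   callsB[i] == "BIO"),
                   nopred = mean(callsA[i] == "NOPRED" |
                                 callsB[i] == "NOPRED"))
    }))
    list(table = tab, agreement = agreement)
}

#' Confusion-matrix benchmark metrics
#'
#' BIO is the positive class; NOPRED calls are excluded from the counts
#' (their number is reported). Returns sensitivity tp/(tp+fn),
#' specificity tn/(tn+fp), accuracy and the Matthews correlation
#' coefficient \code{(tp tn - fp fn)/sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))}
#' (0, flagged, when a marginal is empty).
#'
#' @param labels Character vector of reference labels ("BIO"/"XTAL").
#' @param calls Character vector of predicted calls
#'   ("BIO"/"XTAL"/"NOPRED").
#' @return List with tp, tn, fp, fn, sensitivity, specificity, accuracy,
#'   mcc, mccUndefined, nExcluded.
#' @export
confusionMetrics <- function(labels, calls) {
    if (length(labels) != length(calls))
        stop("labels and calls must have equal length")
    keep <- calls != "NOPRED"
    nExcluded <- sum(!keep)
    labels <- labels[keep]; calls <- calls[keep]
    if (length(labels) == 0) stop("no evaluable calls")
    tp <- sum(labels == "BIO" & calls == "BIO")
    tn <- sum(labels == "XTAL" & calls == "XTAL")
    fp <- sum(labels == "XTAL" & calls == "BIO")
    fn <- sum(labels == "BIO" & calls == "XTAL")
    den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    mccUndefined <- den == 0
    mcc <- if (mccUndefined) 0 else (tp * tn - fp * fn) / den
    list(tp = tp, tn = tn, fp = fp, fn = fn,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         accuracy = (tp + tn) / length(labels),
         mcc = mcc, mccUndefined = mccUndefined,
         nExcluded = nExcluded)
}

#' Per-interface calls from an author biological-unit annotation
#'
#' The depositor-annotated assembly is treated like a single stable
#' assembly: interfaces whose operator appears among the annotation's
#' (chain, operator) pairs are BIO, the rest XTAL.
#'
#' @param authorBiounit List of list(chainId, fingerprint) pairs (the
#'   \code{authorBiounit} slot of a \linkS4class{CrystalStructure}).
#' @param interfaceFingerprints Character vector of interface operator
#'   fingerprints.
#' @return Character vector of calls.
#' @export
authorAnnotationCalls <- function(authorBiounit, interfaceFingerprints) {
    if (length(authorBiounit) == 0)
        return(rep("NOPRED", length(interfaceFingerprints)))
    members <- vapply(authorBiounit, function(p)
        p$fingerprint, character(1))
    pred <- assemblyPrediction(list(list(
        stability = "STABLE", size = length(authorBiounit),
        members = members)))
    assemblyToInterfaceCalls(pred, interfaceFingerprints)
}
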