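# Automatic benchmark-set construction: crystal-form-conserved and
# NMR-validated biological interfaces (BioMany-style) and
# infinite-assembly crystal contacts (XtalMany-style), with the greedy
# sequence clustering standing in for BLASTClust.

.RECORD_COLUMNS <- c("entry_id", "interface_id", "sequence_a",
                     "sequence_b", "area", "operator_class", "resolution",
                     "method", "crystal_form_id", "protcid_cluster_id",
                     "n_crystal_forms_in_cluster", "fraction_forms_present",
                     "biounit_symmetry", "nmr_matched")

#' Construct an interface-record table
#'
#' The tabular input of the dataset builders: one row per interface with
#' the metadata the selection rules consume (sequences, area, operator
#' class code, resolution, crystal-form bookkeeping, NMR-match flag).
#' Missing columns are filled with neutral defaults.
#'
#' @param ... Columns by name (vectors of equal length).
#' @return data.frame with the documented columns.
#' @export
interfaceRecords <- function(...) {
    df <- data.frame(..., stringsAsFactors = FALSE)
    defaults <- list(interface_id = 1L, sequence_b = NA_character_,
                     operator_class = "AU", resolution = NA_real_,
                     method = "XRAY", crystal_form_id = NA_character_,
                     protcid_cluster_id = NA_character_,
                     n_crystal_forms_in_cluster = 0L,
                     fraction_forms_present = 0,
                     biounit_symmetry = NA_character_,
                     nmr_matched = FALSE)
    for (nm in names(defaults))
        if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
    if (is.null(df$sequence_b) || all(is.na(df$sequence_b)))
        df$sequence_b <- df$sequence_a
    miss <- setdiff(.RECORD_COLUMNS, names(df))
    if (length(miss))
        stop("missing record columns: ", paste(miss, collapse = ", "))
    df[, .RECORD_COLUMNS]
}

#' Read / write interface-record tables (TSV)
#' @param path TSV file with the \code{\link{interfaceRecords}} columns.
#' @return data.frame of records.
#' @export
readInterfaceRecords <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    do.call(interfaceRecords, df)
}

#' @rdname readInterfaceRecords
#' @param records data.frame of records.
#' @export
writeInterfaceRecords <- function(records, path) {
    write.table(records, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Pairwise sequence identity (global alignment)
#'
#' Needleman-Wunsch identity: matches divided by the length of the
#' shorter sequence.
#'
#' @param s1,s2 Character(1) sequences.
#' @return Numeric(1) in [0, 1].
#' @export
pairwiseIdentity <- function(s1, s2) {
    if (identical(s1, s2)) return(1)
    al <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(s1), Biostrings::AAString(s2),
        type = "global", substitutionMatrix = NULL,
        gapOpening = 10, gapExtension = 0.5)
    Biostrings::nmatch(al) / min(nchar(s1), nchar(s2))
}

#' Greedy single-linkage sequence clustering
#'
#' Records whose pairwise identity reaches the cutoff join the same
#' cluster; linkage is transitive (single-linkage), mirroring the
#' semantics of identity-cutoff clustering tools.
#'
#' @param seqs Character vector of sequences.
#' @param identityCutoff Fraction (default 0.8).
#' @return Integer vector of cluster ids (1-based, order of first
#'   appearance).
#' @export
clusterSequences <- function(seqs, identityCutoff = 0.8) {
    n <- length(seqs)
    if (n == 0) return(integer(0))
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        if (find(i) == find(j)) next
        if (pairwiseIdentity(seqs[i], seqs[j]) >= identityCutoff)
            parent[find(j)] <- find(i)
    }
    roots <- vapply(seq_len(n), find, integer(1))
    match(roots, unique(roots))
}

# keep one representative per cluster: longest sequence, ties by
# lexicographic entry id
.clusterRepresentative <- function(records, clusters) {
    rep <- logical(nrow(records))
    for (cl in unique(clusters)) {
        idx <- which(clusters == cl)
        len <- nchar(records$sequence_a[idx])
        best <- idx[len == max(len)]
        best <- best[order(records$entry_id[best])][1]
        rep[best] <- TRUE
    }
    rep
}

.labelTable <- function(records, provenance, clusters, representative) {
    data.frame(entry_id = records$entry_id,
               interface_id = records$interface_id,
               label = if (all(provenance == "INFINITE")) "XTAL" else "BIO",
               provenance = provenance,
               cluster = clusters,
               representative = representative,
               stringsAsFactors = FALSE)
}

#' Build a biological-interface benchmark set
#'
#' Two evidence branches: interfaces conserved across many crystal forms
#' (kept when seen in at least \code{minForms} forms and present in at
#' least \code{minFraction} of the known forms) and NMR-validated dimers
#' mapped onto X-ray structures (kept when flagged matched, resolution
#' better than \code{nmrMinResolution} and area at least
#' \code{nmrMinArea}). The union is capped at \code{maxArea} (large
#' interfaces are trivial to classify), clustered by sequence and
#' labelled BIO with branch provenance.
#'
#' @param records \code{\link{interfaceRecords}} data.frame.
#' @param minForms Minimum crystal forms (default 10).
#' @param minFraction Minimum fraction of forms present (default 0.8).
#' @param nmrMinResolution NMR-branch resolution bound, Angstrom,
#'   strict (default 2.5).
#' @param nmrMinArea NMR-branch minimum area, Angstrom^2 (default 500).
#' @param maxArea Maximum area kept, Angstrom^2 (default 2000).
#' @param identityCutoff Sequence-clustering cutoff (default 0.8).
#' @return data.frame of labels (entry, interface, label, provenance,
#'   cluster, representative flag).
#' @export
buildBioMany <- function(records, minForms = 10L, minFraction = 0.8,
                         nmrMinResolution = 2.5, nmrMinArea = 500,
                         maxArea = 2000, identityCutoff = 0.8) {
    protcid <- records$n_crystal_forms_in_cluster >= minForms &
        records$fraction_forms_present >= minFraction
    nmr <- records$nmr_matched &
        !is.na(records$resolution) &
        records$resolution < nmrMinResolution &
        records$area >= nmrMinArea
    sel <- (protcid | nmr) & records$area <= maxArea
    recs <- records[sel, , drop = FALSE]
    if (nrow(recs) == 0) return(.emptyLabels())
    provenance <- ifelse(protcid[sel], "PROTCID", "NMR")
    clusters <- clusterSequences(recs$sequence_a, identityCutoff)
    .labelTable(recs, provenance, clusters,
                .clusterRepresentative(recs, clusters))
}

.INFINITE_CODES <- c("XT", "FT", "2S", "3S", "4S", "6S")

#' Build an infinite-assembly crystal-contact benchmark set
#'
#' Keeps homomeric interfaces generated by screw axes or pure/fractional
#' translations (the operators that can only produce open assemblies),
#' with area at least \code{minArea}, resolution better than
#' \code{maxResolution} and no helical biological-unit annotation, then
#' clusters by sequence and labels XTAL.
#'
#' @param records \code{\link{interfaceRecords}} data.frame.
#' @param minArea Minimum area, Angstrom^2 (default 600).
#' @param maxResolution Resolution bound, strict (default 2.5).
#' @param identityCutoff Sequence-clustering cutoff (default 0.8).
#' @return data.frame of labels, as \code{\link{buildBioMany}}.
#' @export
buildXtalMany <- function(records, minArea = 600, maxResolution = 2.5,
                          identityCutoff = 0.8) {
    if (nrow(records) == 0) return(.emptyLabels())
    homomeric <- vapply(seq_len(nrow(records)), function(i) {
        a <- records$sequence_a[i]; b <- records$sequence_b[i]
        identical(a, b) || pairwiseIdentity(a, b) >= identityCutoff
    }, logical(1))
    sel <- homomeric &
        records$operator_class %in% .INFINITE_CODES &
        records$area >= minArea &
        !is.na(records$resolution) &
        records$resolution < maxResolution &
        (is.na(records$biounit_symmetry) |
         records$biounit_symmetry != "helical")
    recs <- records[sel, , drop = FALSE]
    if (nrow(recs) == 0) return(.emptyLabels())
    clusters <- clusterSequences(recs$sequence_a, identityCutoff)
    .labelTable(recs, rep("INFINITE", nrow(recs)), clusters,
                .clusterRepresentative(recs, clusters))
}

#' Build both benchmark sets with disjointness enforced
#'
#' Runs \code{\link{buildBioMany}} and \code{\link{buildXtalMany}} over
#' the same records and removes from both sets any record selected by
#' both rule systems (conflicting evidence: an interface conserved
#' across crystal forms or NMR-validated cannot simultaneously serve as
#' a trusted crystal contact).
#'
#' @param records \code{\link{interfaceRecords}} data.frame.
#' @param ... Threshold overrides for the two builders, by their
#'   argument names.
#' @return List with \code{bio} and \code{xtal} label data.frames,
#'   guaranteed disjoint, and \code{nConflicts}.
#' @export
buildBenchmarkSets <- function(records, ...) {
    dots <- list(...)
    pick <- function(f) dots[intersect(names(dots),
                                       names(formals(f)))]
    bio <- do.call(buildBioMany, c(list(records), pick(buildBioMany)))
    xtal <- do.call(buildXtalMany, c(list(records),
                                     pick(buildXtalMany)))
    key <- function(df) paste(df$entry_id, df$interface_id)
    clash <- intersect(key(bio), key(xtal))
    list(bio = bio[!(key(bio) %in% clash), , drop = FALSE],
         xtal = xtal[!(key(xtal) %in% clash), , drop = FALSE],
         nConflicts = length(clash))
}

.emptyLabels <- function()
    data.frame(entry_id = character(0), interface_id = integer(0),
               label = character(0), provenance = character(0),
               cluster = integer(0), representative = logical(0),
               stringsAsFactors = FALSE)

#' Write dataset labels as TSV
#' @param labels data.frame from \code{\link{buildBioMany}} or
#'   \code{\link{buildXtalMany}}.
#' @param path Output path.
#' @export
writeDatasetLabels <- function(labels, path) {
    write.table(labels, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Normalized interface-area probability curve
#'
#' Histogram of interface areas over half-open bins [lo, hi), normalized
#' to unit total mass; the area-probability view used to compare contact
#' populations (for example, the infinite-assembly subset) against
#' classical area-based classification curves.
#'
#' @param areas Numeric vector of interface areas, Angstrom^2.
#' @param binWidth Bin width, Angstrom^2 (default 200).
#' @param minArea Lower edge of the first bin (default 0).
#' @return data.frame with \code{bin_lo}, \code{bin_hi},
#'   \code{probability}.
#' @export
areaProbabilityCurve <- function(areas, binWidth = 200, minArea = 0) {
    areas <- areas[!is.na(areas) & areas >= minArea]
    if (length(areas) == 0) stop("no areas to bin")
    lo <- minArea + binWidth * (seq_len(
        floor((max(areas) - minArea) / binWidth) + 1L) - 1L)
    idx <- floor((areas - minArea) / binWidth) + 1L
    counts <- tabulate(idx, nbins = length(lo))
    data.frame(bin_lo = lo, bin_hi = lo + binWidth,
               probability = counts / sum(counts))
}
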