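# Sequence-entropy scoring: homolog filtering, alignment-to-chain mapping
# and per-residue Shannon entropy.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Filter homolog rows by identity to the query
#'
#' Retains rows whose identity to the query is at least \code{cutoff}
#' (boundary inclusive); the query row is always retained and row order
#' is preserved.
#'
#' @param aln A \linkS4class{HomologAlignment}.
#' @param identityCutoff Fraction in [0, 1] (default 0.5).
#' @return A filtered \linkS4class{HomologAlignment}.
#' @export
filterHomologs <- function(aln, identityCutoff = 0.5) {
    keep <- aln@identityToQuery >= identityCutoff
    keep[1] <- TRUE
    new("HomologAlignment", queryId = aln@queryId,
        ids = aln@ids[keep], seqs = aln@seqs[keep],
        identityToQuery = aln@identityToQuery[keep])
}

#' Map chain residues to alignment columns
#'
#' The ungapped query sequence must contain the chain's observed sequence
#' (residues missing from the structure may flank it). Each observed
#' residue maps to exactly one query column; gap columns of the query are
#' never assigned. The mapping is strictly increasing.
#'
#' @param aln A \linkS4class{HomologAlignment}.
#' @param chain A \linkS4class{ChainModel}.
#' @return Integer vector, one alignment column per chain residue.
#' @export
mapAlignmentToChain <- function(aln, chain) {
    q <- strsplit(aln@seqs[1], "")[[1]]
    nonGap <- which(q != "-")
    ungapped <- paste(q[nonGap], collapse = "")
    hit <- regexpr(chain@sequence, ungapped, fixed = TRUE)
    if (hit < 0)
        stop("chain ", chain@chainId,
             " sequence does not match the alignment query")
    offset <- as.integer(hit) - 1L
    nonGap[offset + seq_len(nchar(chain@sequence))]
}

#' Shannon entropy of one alignment column
#'
#' \code{s = -sum p_g log2 p_g} over alphabet groups with frequency
#' \code{p_g} among the column's residue symbols; gaps and symbols outside
#' the alphabet (X, B, Z, ...) are excluded from the counts. A column with
#' no countable symbols yields NA.
#'
#' @param column Character vector of one-letter symbols (one per row).
#' @param grouping Optional named character vector mapping each amino acid
#'   to a group label (reduced alphabets); default: 20 standard amino
#'   acids, each its own group.
#' @return Numeric(1), bits, or NA.
#' @examples
#' columnEntropy(c("A", "A", "A", "A"))        # 0
#' columnEntropy(c("A", "C", "D", "E"))        # 2
#' @export
columnEntropy <- function(column, grouping = NULL) {
    if (length(column) == 0) stop("empty column")
    column <- toupper(column)
    if (is.null(grouping))
        grouping <- setNames(.AA20, .AA20)
    g <- grouping[column]
    g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_real_)
    p <- table(g) / length(g)
    -sum(p * log2(p))
}

#' Per-residue entropy profile for a chain
#'
#' Homologs are filtered at \code{identityCutoff}; if fewer than
#' \code{minHomologs} remain the profile is flagged insufficient and the
#' evolutionary indicators abstain. Entropies are computed per alignment
#' column (query row included in the frequencies) and placed on the
#' chain's observed residues.
#'
#' @param aln A \linkS4class{HomologAlignment}.
#' @param chain A \linkS4class{ChainModel}.
#' @param identityCutoff Homolog identity cutoff (default 0.5).
#' @param minHomologs Minimum homolog count for a reliable profile
#'   (default 10).
#' @param grouping Optional reduced-alphabet grouping, see
#'   \code{\link{columnEntropy}}.
#' @return An \linkS4class{EntropyProfile}.
#' @export
entropyProfile <- function(aln, chain, identityCutoff = 0.5,
                           minHomologs = 10L, grouping = NULL) {
    flt <- filterHomologs(aln, identityCutoff)
    nHom <- length(flt@seqs) - 1L
    colIdx <- mapAlignmentToChain(flt, chain)
    rows <- do.call(rbind, strsplit(flt@seqs, ""))
    ent <- vapply(colIdx, function(ci)
        columnEntropy(rows[, ci], grouping), numeric(1))
    new("EntropyProfile", entropy = ent, nHomologsUsed = nHom,
        identityCutoff = identityCutoff,
        insufficient = nHom < minHomologs)
}

setMethod("show", "EntropyProfile", function(object) {
    cat(sprintf(
        "EntropyProfile: %d residues, %d homolog(s) at >= %.0f%% identity%s\n",
        length(object@entropy), object@nHomologsUsed,
        100 * object@identityCutoff,
        if (object@insufficient) " [insufficient]" else ""))
})

#' Write an entropy profile as TSV
#' @param profile An \linkS4class{EntropyProfile}.
#' @param chain The \linkS4class{ChainModel} it annotates.
#' @param path Output path.
#' @return Invisibly, the data.frame written.
#' @export
writeEntropyProfile <- function(profile, chain, path) {
    df <- data.frame(residue_index = seq_along(profile@entropy),
                     author_number = chain@resNos,
                     residue = chain@resNames,
                     entropy = profile@entropy)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}
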