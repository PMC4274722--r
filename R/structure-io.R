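# Structure and alignment input/output.
#
# PDB atom records are parsed with bio3d; the crystallographic header
# (CRYST1, REMARK 290 operators, resolution, free R) is read here since
# bio3d does not expose it. mmCIF is read by a small tag-driven reader
# keyed on the atom_site loop header (column order independent).

.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                P = 1.80, SE = 1.90)
.VDW_DEFAULT <- 1.70

#' Van der Waals radius for an element
#' @param element Character vector of element symbols.
#' @param radii Named numeric table overriding the built-in values.
#' @return Numeric vector of radii (Angstrom); unknown elements get 1.70.
#' @export
vdwRadius <- function(element, radii = .VDW_RADII) {
    r <- radii[toupper(element)]
    r[is.na(r)] <- .VDW_DEFAULT
    unname(r)
}

#' Construct a crystal cell
#'
#' @param a,b,c Cell lengths, Angstrom.
#' @param alpha,beta,gamma Cell angles, degrees.
#' @return A \linkS4class{CrystalCell} with the orthogonalization matrix
#'   (fractional -> orthogonal, PDB convention) filled in.
#' @export
crystalCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
    ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
    cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
    v <- sqrt(max(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
    orth <- matrix(c(a, b * cg, c * cb,
                     0, b * sg, c * (ca - cb * cg) / sg,
                     0, 0, c * v / sg), 3, 3, byrow = TRUE)
    new("CrystalCell", a = a, b = b, c = c,
        alpha = alpha, beta = beta, gamma = gamma, orthMat = orth)
}

#' Convert between fractional and orthogonal coordinates
#' @param cell A \linkS4class{CrystalCell}.
#' @param xyz n x 3 matrix of coordinates.
#' @return n x 3 matrix in the other frame.
#' @export
fracToOrth <- function(cell, xyz) t(cell@orthMat %*% t(xyz))

#' @rdname fracToOrth
#' @export
orthToFrac <- function(cell, xyz) t(solve(cell@orthMat) %*% t(xyz))

#' Construct a chain model from residue-wise atom records
#'
#' @param chainId Chain identifier.
#' @param resNames 3-letter residue names, in chain order.
#' @param resNos Author residue numbers.
#' @param atoms data.frame with serial, element, name, resIndex, x, y, z
#'   (radius added from the van der Waals table when missing).
#' @param isProtein Logical; inferred from residue names when NULL.
#' @return A \linkS4class{ChainModel}.
#' @export
chainModel <- function(chainId, resNames, resNos, atoms, isProtein = NULL) {
    if (is.null(atoms$radius)) atoms$radius <- vdwRadius(atoms$element)
    one <- .AA_321[toupper(resNames)]
    if (is.null(isProtein))
        isProtein <- length(resNames) > 0 && mean(!is.na(one)) >= 0.5
    one[is.na(one)] <- "X"
    # drop residues with zero atoms
    keep <- seq_along(resNames) %in% unique(atoms$resIndex)
    if (!all(keep)) {
        warning("chain ", chainId, ": dropping ", sum(!keep),
                " residue(s) with no atoms")
        remap <- cumsum(keep)
        atoms$resIndex <- remap[atoms$resIndex]
        resNames <- resNames[keep]; resNos <- resNos[keep]; one <- one[keep]
    }
    new("ChainModel", chainId = as.character(chainId),
        sequence = paste(one, collapse = ""),
        resNames = as.character(resNames), resNos = as.integer(resNos),
        atoms = atoms, isProtein = isProtein)
}

#' Construct a crystal structure
#'
#' @param entryId Entry identifier.
#' @param chains List of \linkS4class{ChainModel}.
#' @param cell A \linkS4class{CrystalCell}.
#' @param spacegroup Hermann-Mauguin symbol.
#' @param operators List of \linkS4class{SymOperator}; resolved from the
#'   space-group symbol when NULL.
#' @param resolution,rFree Numeric or NA.
#' @param experimentalMethod "XRAY", "NMR" or "OTHER".
#' @param authorBiounit Optional list of (chainId, fingerprint) pairs.
#' @return A \linkS4class{CrystalStructure}.
#' @export
crystalStructure <- function(entryId, chains, cell, spacegroup = "P 1",
                             operators = NULL, resolution = NA_real_,
                             rFree = NA_real_,
                             experimentalMethod = "XRAY",
                             authorBiounit = list()) {
    if (is.null(operators)) operators <- spaceGroupOperators(spacegroup)
    names(chains) <- vapply(chains, function(ch) ch@chainId, character(1))
    new("CrystalStructure", entryId = entryId, chains = chains,
        cell = cell, spacegroup = spacegroup, operators = operators,
        resolution = as.numeric(resolution), rFree = as.numeric(rFree),
        experimentalMethod = experimentalMethod,
        authorBiounit = authorBiounit)
}

setMethod("show", "CrystalStructure", function(object) {
    cat("CrystalStructure", object@entryId, "\n",
        " ", length(object@chains), "chain(s);",
        sum(vapply(object@chains, function(ch) ch@isProtein, logical(1))),
        "protein\n",
        "  space group", object@spacegroup, "with",
        length(object@operators), "operator(s)\n",
        sprintf("  cell %.2f %.2f %.2f / %.1f %.1f %.1f\n",
                object@cell@a, object@cell@b, object@cell@c,
                object@cell@alpha, object@cell@beta, object@cell@gamma),
        sprintf("  %s, resolution %s, Rfree %s\n", object@experimentalMethod,
                format(object@resolution), format(object@rFree)))
})

#' Protein chains of a structure
#' @param structure A \linkS4class{CrystalStructure}.
#' @return Named list of protein \linkS4class{ChainModel}s.
#' @export
proteinChains <- function(structure)
    Filter(function(ch) ch@isProtein, structure@chains)

# ---- PDB ----

.parsePdbHeader <- function(lines) {
    out <- list(cell = NULL, spacegroup = NA_character_,
                resolution = NA_real_, rFree = NA_real_,
                method = "XRAY", operators = NULL)
    cr <- grep("^CRYST1", lines, value = TRUE)
    if (length(cr)) {
        f <- cr[1]
        out$cell <- crystalCell(
            as.numeric(substr(f, 7, 15)), as.numeric(substr(f, 16, 24)),
            as.numeric(substr(f, 25, 33)), as.numeric(substr(f, 34, 40)),
            as.numeric(substr(f, 41, 47)), as.numeric(substr(f, 48, 54)))
        out$spacegroup <- trimws(substr(f, 56, 66))
    }
    ex <- grep("^EXPDTA", lines, value = TRUE)
    if (length(ex)) {
        if (grepl("NMR", ex[1])) out$method <- "NMR"
        else if (!grepl("X-RAY|DIFFRACTION", ex[1])) out$method <- "OTHER"
    }
    rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(rl)) {
        m <- regmatches(rl[1], regexpr("[0-9]+\\.[0-9]+", rl[1]))
        if (length(m)) out$resolution <- as.numeric(m)
    }
    fr <- grep("^REMARK   3   FREE R VALUE", lines, value = TRUE)
    fr <- fr[!grepl("TEST|ERROR", fr)]
    if (length(fr)) {
        m <- regmatches(fr[1], regexpr("[0-9]*\\.[0-9]+", fr[1]))
        if (length(m)) out$rFree <- as.numeric(m)
    }
    sm <- grep("^REMARK 290   SMTRY", lines, value = TRUE)
    if (length(sm) && length(sm) %% 3 == 0) {
        nops <- length(sm) / 3
        ops <- vector("list", nops)
        for (i in seq_len(nops)) {
            rows <- sm[substr(sm, 20, 22) == sprintf("%3d", i)]
            if (length(rows) != 3) { ops <- NULL; break }
            rot <- matrix(0, 3, 3); tr <- numeric(3)
            for (r in 1:3) {
                v <- as.numeric(strsplit(trimws(substr(rows[r], 24, 80)),
                                         "\\s+")[[1]])
                rot[r, ] <- v[1:3]; tr[r] <- v[4]
            }
            ops[[i]] <- symOperator(rot, tr)
        }
        if (!is.null(ops)) out$operators <- ops
    }
    out
}

.chainsFromAtomTable <- function(atom) {
    # atom: data.frame with chain, resno, resid, elety, elesy, x, y, z
    chains <- list()
    for (ch in unique(atom$chain)) {
        a <- atom[atom$chain == ch, , drop = FALSE]
        key <- paste(a$resno, a$resid)
        ridx <- match(key, unique(key))
        first <- !duplicated(key)
        atoms <- data.frame(
            serial = as.integer(a$eleno), element = toupper(a$elesy),
            name = a$elety, resIndex = ridx,
            x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
        chains[[ch]] <- chainModel(ch, a$resid[first], a$resno[first], atoms)
    }
    chains
}

.readPdbStructure <- function(path) {
    lines <- readLines(path, warn = FALSE)
    hdr <- .parsePdbHeader(lines)
    pdb <- bio3d::read.pdb(path, verbose = FALSE, hex = TRUE)
    atom <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
    if (!nrow(atom)) stop("no ATOM records in ", path)
    if (any(is.na(atom$elesy)) || any(atom$elesy == ""))
        atom$elesy <- substr(trimws(atom$elety), 1, 1)
    list(chains = .chainsFromAtomTable(atom), hdr = hdr)
}

# ---- mmCIF (internal minimal reader) ----

.cifTokens <- function(line) {
    # whitespace-separated tokens honouring single/double quotes
    toks <- regmatches(line,
        gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
    gsub("^['\"]|['\"]$", "", toks)
}

.readCifStructure <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^#", lines)]
    kv <- list()
    i <- 1L
    atomTab <- NULL; symops <- NULL
    while (i <= length(lines)) {
        ln <- trimws(lines[i])
        if (ln == "loop_") {
            cols <- character(0); i <- i + 1L
            while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
                cols <- c(cols, trimws(lines[i])); i <- i + 1L
            }
            rows <- list()
            while (i <= length(lines)) {
                ln2 <- trimws(lines[i])
                if (ln2 == "" || grepl("^(_|loop_|data_)", ln2)) break
                rows[[length(rows) + 1L]] <- .cifTokens(ln2)
                i <- i + 1L
            }
            if (length(rows) && any(grepl("^_atom_site\\.", cols))) {
                tab <- do.call(rbind, rows)
                colnames(tab) <- sub("^_atom_site\\.", "", cols)
                atomTab <- as.data.frame(tab, stringsAsFactors = FALSE)
            } else if (length(rows) &&
                       any(grepl("pos_as_xyz|operation.*xyz", cols))) {
                j <- grep("pos_as_xyz|operation.*xyz", cols)[1]
                symops <- vapply(rows, function(r) r[j], character(1))
            }
            next
        }
        if (grepl("^_", ln)) {
            toks <- .cifTokens(ln)
            if (length(toks) >= 2) kv[[toks[1]]] <- toks[2]
        }
        i <- i + 1L
    }
    if (is.null(atomTab)) stop("no atom_site loop found in ", path)
    num <- function(tag) {
        v <- kv[[tag]]
        if (is.null(v) || v %in% c(".", "?")) NA_real_ else as.numeric(v)
    }
    cellv <- c(num("_cell.length_a"), num("_cell.length_b"),
               num("_cell.length_c"))
    angv <- c(num("_cell.angle_alpha"), num("_cell.angle_beta"),
              num("_cell.angle_gamma"))
    sg <- kv[["_symmetry.space_group_name_H-M"]]
    if (is.null(sg)) sg <- kv[["_space_group.name_H-M_alt"]]
    method <- kv[["_exptl.method"]]
    method <- if (is.null(method)) "XRAY"
              else if (grepl("NMR", toupper(method))) "NMR"
              else if (grepl("X-RAY", toupper(method))) "XRAY" else "OTHER"
    pick <- function(tab, ...) {
        for (nm in c(...)) if (nm %in% names(tab)) return(tab[[nm]])
        NULL
    }
    grp <- pick(atomTab, "group_PDB")
    if (!is.null(grp)) atomTab <- atomTab[grp == "ATOM", , drop = FALSE]
    if (!nrow(atomTab)) stop("no polymer ATOM records in ", path)
    atom <- data.frame(
        eleno = as.integer(pick(atomTab, "id")),
        elesy = toupper(pick(atomTab, "type_symbol")),
        elety = pick(atomTab, "auth_atom_id", "label_atom_id"),
        resid = pick(atomTab, "auth_comp_id", "label_comp_id"),
        chain = pick(atomTab, "auth_asym_id", "label_asym_id"),
        resno = as.integer(pick(atomTab, "auth_seq_id", "label_seq_id")),
        x = as.numeric(pick(atomTab, "Cartn_x")),
        y = as.numeric(pick(atomTab, "Cartn_y")),
        z = as.numeric(pick(atomTab, "Cartn_z")),
        stringsAsFactors = FALSE)
    hdr <- list(
        cell = if (all(is.finite(cellv)))
            crystalCell(cellv[1], cellv[2], cellv[3],
                        angv[1], angv[2], angv[3]) else NULL,
        spacegroup = if (is.null(sg)) NA_character_ else sg,
        resolution = num("_refine.ls_d_res_high"),
        rFree = num("_refine.ls_R_factor_R_free"),
        method = method,
        operators = if (is.null(symops)) NULL
                    else lapply(symops, parseOperatorTriplet))
    list(chains = .chainsFromAtomTable(atom), hdr = hdr)
}

#' Read a crystal structure from PDB or mmCIF
#'
#' Polymer (ATOM) records become chain models; waters and ligands are not
#' part of interface analysis. Space-group operators are taken from the
#' file (REMARK 290 / _symmetry_equiv positions) when present, otherwise
#' resolved from the space-group symbol via the embedded operator table.
#'
#' @param path File path.
#' @param format "auto" (default, by extension), "pdb" or "mmcif".
#' @param entryId Entry identifier; defaults to the file base name.
#' @return A \linkS4class{CrystalStructure}.
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                          entryId = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto")
        format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
            "mmcif" else "pdb"
    parsed <- if (format == "mmcif") .readCifStructure(path)
              else .readPdbStructure(path)
    hdr <- parsed$hdr
    if (is.null(entryId))
        entryId <- sub("\\.[^.]+$", "", basename(path))
    if (hdr$method == "NMR") {
        return(crystalStructure(entryId, parsed$chains,
                                crystalCell(1, 1, 1), "P 1",
                                operators = list(identityOperator()),
                                resolution = hdr$resolution,
                                rFree = hdr$rFree,
                                experimentalMethod = "NMR"))
    }
    if (is.null(hdr$cell))
        stop("no unit cell in ", path, " (required for crystal entries)")
    ops <- hdr$operators
    if (is.null(ops)) {
        sg <- hdr$spacegroup
        if (is.na(sg) || is.na(.canonicalSpacegroup(sg)))
            stop("unknown space-group symbol '", sg,
                 "' and no operators in file")
        ops <- spaceGroupOperators(sg)
    }
    crystalStructure(entryId, parsed$chains, hdr$cell,
                     spacegroup = hdr$spacegroup, operators = ops,
                     resolution = hdr$resolution, rFree = hdr$rFree,
                     experimentalMethod = hdr$method)
}

# ---- structure writers ----

#' Write a structure as a PDB file
#'
#' Emits CRYST1, EXPDTA, resolution/Rfree remarks, REMARK 290 symmetry
#' operators and ATOM records (3-decimal coordinates).
#'
#' @param structure A \linkS4class{CrystalStructure}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeStructurePdb <- function(structure, path) {
    ln <- c(sprintf("HEADER    SYNTHETIC STRUCTURE                     %s",
                    structure@entryId),
            sprintf("EXPDTA    %s",
                    switch(structure@experimentalMethod,
                           XRAY = "X-RAY DIFFRACTION",
                           NMR = "SOLUTION NMR", "OTHER")))
    if (is.finite(structure@resolution))
        ln <- c(ln, sprintf(
            "REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
            structure@resolution))
    if (is.finite(structure@rFree))
        ln <- c(ln, sprintf(
            "REMARK   3   FREE R VALUE                     : %.3f",
            structure@rFree))
    for (i in seq_along(structure@operators)) {
        op <- structure@operators[[i]]
        for (r in 1:3)
            ln <- c(ln, sprintf(
                "REMARK 290   SMTRY%d %3d%10.6f%10.6f%10.6f%15.5f",
                r, i, op@rot[r, 1], op@rot[r, 2], op@rot[r, 3],
                op@trans[r]))
    }
    cl <- structure@cell
    ln <- c(ln, sprintf(
        "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
        cl@a, cl@b, cl@c, cl@alpha, cl@beta, cl@gamma,
        structure@spacegroup, 1L))
    serial <- 0L
    for (chain in structure@chains) {
        at <- chain@atoms
        for (k in seq_len(nrow(at))) {
            serial <- serial + 1L
            nm <- at$name[k]
            nm <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
            ri <- at$resIndex[k]
            ln <- c(ln, sprintf(
                "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                serial, nm, chain@resNames[ri], chain@chainId,
                chain@resNos[ri], at$x[k], at$y[k], at$z[k], 1.0, 10.0,
                at$element[k]))
        }
        ln <- c(ln, "TER")
    }
    ln <- c(ln, "END")
    writeLines(ln, path)
    invisible(path)
}

#' Write a structure as mmCIF
#'
#' Emits cell, symmetry (including equivalent positions), refinement
#' statistics and a full-column atom_site loop.
#'
#' @inheritParams writeStructurePdb
#' @return Invisibly, the path.
#' @export
writeStructureCif <- function(structure, path) {
    cl <- structure@cell
    ln <- c(paste0("data_", structure@entryId),
            sprintf("_cell.length_a    %.3f", cl@a),
            sprintf("_cell.length_b    %.3f", cl@b),
            sprintf("_cell.length_c    %.3f", cl@c),
            sprintf("_cell.angle_alpha %.2f", cl@alpha),
            sprintf("_cell.angle_beta  %.2f", cl@beta),
            sprintf("_cell.angle_gamma %.2f", cl@gamma),
            sprintf("_symmetry.space_group_name_H-M  '%s'",
                    structure@spacegroup),
            sprintf("_exptl.method  '%s'",
                    switch(structure@experimentalMethod,
                           XRAY = "X-RAY DIFFRACTION",
                           NMR = "SOLUTION NMR", "OTHER")))
    if (is.finite(structure@resolution))
        ln <- c(ln, sprintf("_refine.ls_d_res_high  %.2f",
                            structure@resolution))
    if (is.finite(structure@rFree))
        ln <- c(ln, sprintf("_refine.ls_R_factor_R_free  %.3f",
                            structure@rFree))
    ln <- c(ln, "loop_", "_symmetry_equiv.id", "_symmetry_equiv.pos_as_xyz",
            vapply(seq_along(structure@operators), function(i)
                sprintf("%d '%s'", i,
                        operatorTriplet(structure@operators[[i]])),
                character(1)))
    ln <- c(ln, "loop_",
            paste0("_atom_site.",
                   c("group_PDB", "id", "type_symbol", "label_atom_id",
                     "label_alt_id", "label_comp_id", "label_asym_id",
                     "label_entity_id", "label_seq_id",
                     "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                     "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                     "auth_seq_id", "auth_comp_id", "auth_asym_id",
                     "auth_atom_id", "pdbx_PDB_model_num")))
    serial <- 0L
    ent <- 0L
    for (chain in structure@chains) {
        ent <- ent + 1L
        at <- chain@atoms
        for (k in seq_len(nrow(at))) {
            serial <- serial + 1L
            ri <- at$resIndex[k]
            ln <- c(ln, sprintf(
                "ATOM %d %s %s . %s %s %d %d ? %.3f %.3f %.3f 1.00 10.00 ? %d %s %s %s 1",
                serial, at$element[k], at$name[k], chain@resNames[ri],
                chain@chainId, ent, ri, at$x[k], at$y[k], at$z[k],
                chain@resNos[ri], chain@resNames[ri], chain@chainId,
                at$name[k]))
        }
    }
    writeLines(c(ln, "#"), path)
    invisible(path)
}

# ---- alignments ----

.rowIdentity <- function(query, row) {
    q <- strsplit(query, "")[[1]]
    r <- strsplit(row, "")[[1]]
    keep <- q != "-"
    if (!any(keep)) return(NA_real_)
    sum(q[keep] == r[keep] & r[keep] != "-") / sum(keep)
}

#' Read an aligned-FASTA homolog alignment
#'
#' The first record is the query. Per-row identity to the query is
#' computed over the non-gap query columns (a homolog gap counts as a
#' mismatch).
#'
#' @param path Aligned FASTA file.
#' @return A \linkS4class{HomologAlignment}.
#' @export
readAlignment <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    aas <- Biostrings::readAAStringSet(path)
    if (length(aas) == 0) stop("empty alignment file: ", path)
    w <- Biostrings::width(aas)
    if (length(unique(w)) != 1)
        stop("ragged alignment (row lengths ",
             paste(unique(w), collapse = ", "), ") in ", path)
    seqs <- toupper(as.character(aas))
    ids <- sub("\\s.*$", "", names(aas))
    homologAlignment(ids[1], ids, unname(seqs))
}

#' Construct a homolog alignment from aligned rows
#' @param queryId Identifier of the query row.
#' @param ids Row identifiers (query first).
#' @param seqs Aligned sequences with "-" gaps (query first).
#' @return A \linkS4class{HomologAlignment}.
#' @export
homologAlignment <- function(queryId, ids, seqs) {
    idt <- vapply(seqs, function(s) .rowIdentity(seqs[1], s), numeric(1))
    new("HomologAlignment", queryId = queryId, ids = as.character(ids),
        seqs = unname(seqs), identityToQuery = unname(idt))
}

#' Write an alignment as aligned FASTA
#' @param aln A \linkS4class{HomologAlignment}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeAlignmentFasta <- function(aln, path) {
    x <- Biostrings::AAStringSet(setNames(aln@seqs, aln@ids))
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

setMethod("show", "HomologAlignment", function(object) {
    cat("HomologAlignment:", length(object@seqs), "rows x",
        nchar(object@seqs[1]), "columns; query", object@queryId, "\n")
})

# ---- interface report ----

#' Tabulate interface calls for reporting
#'
#' One row per interface: partners, operator fingerprint and class code,
#' infinite-assembly flag, buried area, the three indicator values and
#' calls, the consensus and the robust flag.
#'
#' @param interfaces List of \linkS4class{Interface}.
#' @param calls List of \linkS4class{InterfaceCall} parallel to
#'   \code{interfaces} (optional; indicator columns are NA when absent).
#' @return data.frame.
#' @export
interfaceReportTable <- function(interfaces, calls = NULL) {
    n <- length(interfaces)
    get <- function(i, fld, def = NA)
        if (is.null(calls)) def else slot(calls[[i]], fld)
    df <- data.frame(
        interface_id = vapply(interfaces, function(x) x@id, integer(1)),
        chain_a = vapply(interfaces, function(x) x@chainA, character(1)),
        chain_b = vapply(interfaces, function(x) x@chainB, character(1)),
        operator = vapply(interfaces, function(x)
            operatorFingerprint(x@operator), character(1)),
        operator_class = vapply(interfaces, function(x)
            x@opClass@code, character(1)),
        infinite = vapply(interfaces, function(x)
            x@opClass@isInfinite, logical(1)),
        area = vapply(interfaces, function(x) x@area, numeric(1)),
        stringsAsFactors = FALSE)
    if (n == 0)
        df <- df[0, , drop = FALSE]
    df$n_core_geom <- vapply(seq_len(n), function(i)
        as.integer(get(i, "nCoreGeom", NA_integer_)), integer(1))
    df$core_rim_ratio <- vapply(seq_len(n), function(i)
        as.numeric(get(i, "coreRimRatio", NA_real_)), numeric(1))
    df$core_surface_score <- vapply(seq_len(n), function(i)
        as.numeric(get(i, "coreSurfaceScore", NA_real_)), numeric(1))
    df$call_geometry <- vapply(seq_len(n), function(i)
        as.character(get(i, "callGeometry", NA_character_)), character(1))
    df$call_core_rim <- vapply(seq_len(n), function(i)
        as.character(get(i, "callCoreRim", NA_character_)), character(1))
    df$call_core_surface <- vapply(seq_len(n), function(i)
        as.character(get(i, "callCoreSurface", NA_character_)), character(1))
    df$consensus <- vapply(seq_len(n), function(i)
        as.character(get(i, "consensus", NA_character_)), character(1))
    df$robust <- vapply(seq_len(n), function(i)
        as.logical(get(i, "robust", NA)), logical(1))
    df
}

#' Write an interface report as TSV or JSON
#'
#' @param interfaces List of \linkS4class{Interface}.
#' @param calls Optional parallel list of \linkS4class{InterfaceCall}.
#' @param path Output path.
#' @param format "tsv" or "json".
#' @return Invisibly, the report data.frame.
#' @export
writeInterfaceReport <- function(interfaces, calls = NULL, path,
                                 format = c("tsv", "json")) {
    format <- match.arg(format)
    df <- interfaceReportTable(interfaces, calls)
    if (format == "tsv")
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    else
        jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                             na = "null")
    invisible(df)
}

#' Read back an interface report
#' @param path Report path.
#' @param format "tsv" or "json".
#' @return data.frame with the columns of \code{interfaceReportTable}.
#' @export
readInterfaceReport <- function(path, format = c("tsv", "json")) {
    format <- match.arg(format)
    if (format == "tsv")
        read.delim(path, stringsAsFactors = FALSE)
    else
        as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
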