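# Lattice interface enumeration, accessible/buried surface area and
# core/rim/surface region assignment.

#' Shrake-Rupley accessible surface area
#'
#' Quasi-uniform points (deterministic Fibonacci spiral, no RNG) on each
#' atom's expanded sphere of radius r_vdw + probe; a point is accessible
#' iff it lies outside every neighbouring expanded sphere; the atom area
#' is 4 pi (r_vdw + probe)^2 times the accessible fraction.
#'
#' @param xyz n x 3 matrix of atom coordinates (Angstrom).
#' @param radii Numeric(n), van der Waals radii.
#' @param resIndex Optional integer(n) residue index per atom; when given,
#'   per-residue areas are returned as well.
#' @param probe Probe radius, Angstrom (default 1.4, water).
#' @param nPoints Sphere sample size (>= 92; default 960).
#' @return List with \code{atomArea} (numeric(n), Angstrom^2),
#'   \code{residueArea} (named by residue index, or NULL),
#'   \code{probeRadius}, \code{nSpherePoints}.
#' @examples
#' computeAsa(matrix(0, 1, 3), 1.7)$atomArea  # 4*pi*3.1^2
#' @export
computeAsa <- function(xyz, radii, resIndex = NULL, probe = 1.4,
                       nPoints = 960L) {
    xyz <- matrix(as.numeric(xyz), ncol = 3)
    if (nrow(xyz) == 0) stop("empty atom list")
    if (probe <= 0) stop("probe radius must be positive")
    if (nPoints < 92) stop("nPoints must be >= 92")
    atomArea <- .cppAsa(xyz, as.numeric(radii), probe, as.integer(nPoints))
    residueArea <- NULL
    if (!is.null(resIndex)) {
        s <- tapply(atomArea, factor(resIndex), sum)
        residueArea <- as.numeric(s)
        names(residueArea) <- names(s)
    }
    list(atomArea = atomArea, residueArea = residueArea,
         probeRadius = probe, nSpherePoints = as.integer(nPoints))
}

# per-residue ASA over a fixed residue count (residues without atoms -> 0)
.residueAsa <- function(atomArea, resIndex, nRes) {
    out <- numeric(nRes)
    s <- tapply(atomArea, factor(resIndex, levels = seq_len(nRes)), sum)
    out[as.integer(names(s))] <- ifelse(is.na(s), 0, s)
    out
}

.chainCoords <- function(chain)
    as.matrix(chain@atoms[, c("x", "y", "z"), drop = FALSE])

#' Apply a symmetry operator to orthogonal coordinates
#'
#' Coordinates are taken to fractional space, transformed by
#' \code{rot x + trans + cellShift}, and returned to the orthogonal frame.
#'
#' @param op A \linkS4class{SymOperator}.
#' @param xyz n x 3 orthogonal coordinates.
#' @param cell A \linkS4class{CrystalCell}.
#' @return n x 3 transformed orthogonal coordinates.
#' @export
applyOperator <- function(op, xyz, cell) {
    frac <- orthToFrac(cell, xyz)
    frac <- t(op@rot %*% t(frac)) +
        matrix(totalTranslation(op), nrow(frac), 3, byrow = TRUE)
    fracToOrth(cell, frac)
}

# shift range needed so that images within contact reach of the reference
# copy are enumerated even for cells smaller than the chain extent
.shiftRange <- function(cell, diameter, cutoff) {
    need <- ceiling((diameter + cutoff) /
                    c(cell@a, cell@b, cell@c))
    pmax(1L, pmin(4L, as.integer(need)))
}

#' Enumerate unique pairwise lattice interfaces
#'
#' Generates all chain images under the space-group operators and
#' unit-cell translations, detects contacting pairs (any interatomic
#' distance within \code{contactDistance}), deduplicates symmetry-
#' equivalent copies (by unordered operator-fingerprint pair and by
#' congruent contact sets), computes buried surface area
#' \code{(ASA_A + ASA_B - ASA_AB)/2} and per-residue burial, and returns
#' interfaces sorted by descending area.
#'
#' @param structure A \linkS4class{CrystalStructure}.
#' @param contactDistance Heavy-atom contact cutoff, Angstrom
#'   (default 5.9).
#' @param minArea Minimum buried surface area, Angstrom^2 (default 35).
#' @param probe ASA probe radius (default 1.4).
#' @param nPoints ASA sphere sample size (default 960).
#' @param minChainLength Chains shorter than this many residues are
#'   skipped (default 10).
#' @return List of \linkS4class{Interface}.
#' @export
findInterfaces <- function(structure, contactDistance = 5.9, minArea = 35,
                           probe = 1.4, nPoints = 960L,
                           minChainLength = 10L) {
    chains <- proteinChains(structure)
    chains <- Filter(function(ch)
        length(ch@resNames) >= minChainLength, chains)
    if (length(chains) == 0) return(list())
    if (structure@experimentalMethod == "XRAY" &&
        is.null(structure@cell))
        stop("missing cell for X-ray entry")
    cell <- structure@cell
    ids <- names(chains)

    # hydrogens excluded from contacts and ASA
    chains <- lapply(chains, function(ch) {
        heavy <- toupper(ch@atoms$element) != "H"
        ch@atoms <- ch@atoms[heavy, , drop = FALSE]
        ch
    })
    coords <- lapply(chains, .chainCoords)
    radii <- lapply(chains, function(ch) ch@atoms$radius)
    nres <- vapply(chains, function(ch) length(ch@resNames), integer(1))
    asaRef <- lapply(seq_along(chains), function(i) {
        a <- computeAsa(coords[[i]], radii[[i]], probe = probe,
                        nPoints = nPoints)
        .residueAsa(a$atomArea, chains[[i]]@atoms$resIndex, nres[i])
    })
    centers <- lapply(coords, colMeans)
    bradius <- vapply(seq_along(coords), function(i)
        sqrt(max(rowSums((coords[[i]] -
            matrix(centers[[i]], nrow(coords[[i]]), 3,
                   byrow = TRUE))^2))), numeric(1))
    diameter <- 2 * max(bradius)

    isNcs <- structure@experimentalMethod != "XRAY"
    ops <- structure@operators
    rng <- if (isNcs) c(0L, 0L, 0L)
           else .shiftRange(cell, diameter, contactDistance)
    shifts <- as.matrix(expand.grid(x = -rng[1]:rng[1],
                                    y = -rng[2]:rng[2],
                                    z = -rng[3]:rng[3]))

    seenOp <- character(0)
    cand <- list()
    for (i in seq_along(chains)) for (j in seq_along(chains)) {
        if (j < i) next
        for (k in seq_along(ops)) for (s in seq_len(nrow(shifts))) {
            op <- symOperator(ops[[k]]@rot, ops[[k]]@trans, shifts[s, ])
            if (i == j && isIdentityOperator(op)) next
            # g and g^-1 describe the same contact only when both members
            # are images of the same chain
            opKey <- if (i == j) fingerprintPair(op)
                     else operatorFingerprint(op)
            key <- paste(ids[i], ids[j], opKey, sep = "@")
            if (key %in% seenOp) next
            # bounding-sphere prefilter
            cB <- applyOperator(op, matrix(centers[[j]], 1, 3), cell)
            if (sqrt(sum((cB - centers[[i]])^2)) >
                bradius[i] + bradius[j] + contactDistance) next
            xyzB <- applyOperator(op, coords[[j]], cell)
            if (.cppMinDist(coords[[i]], xyzB) > contactDistance) next
            seenOp <- c(seenOp, key)
            pr <- .cppContactPairs(coords[[i]], xyzB, contactDistance)
            contacts <- unique(data.frame(
                resA = chains[[i]]@atoms$resIndex[pr[, 1]],
                resB = chains[[j]]@atoms$resIndex[pr[, 2]]))
            cand[[length(cand) + 1L]] <- list(
                i = i, j = j, op = op, xyzB = xyzB, contacts = contacts)
        }
    }
    if (length(cand) == 0) return(list())

    # congruence dedup: same chain pair and same unordered contact set
    ckey <- vapply(cand, function(cd) {
        p <- cd$contacts
        if (cd$i == cd$j) {
            a <- pmin(p$resA, p$resB); b <- pmax(p$resA, p$resB)
        } else {
            a <- p$resA; b <- p$resB
        }
        o <- order(a, b)
        paste(cd$i, cd$j, paste(a[o], b[o], sep = ":", collapse = ","),
              sep = "@")
    }, character(1))
    cand <- cand[!duplicated(ckey)]

    out <- list()
    for (cd in cand) {
        i <- cd$i; j <- cd$j
        resIdxAB <- c(chains[[i]]@atoms$resIndex,
                      chains[[j]]@atoms$resIndex + nres[i])
        asaAB <- computeAsa(rbind(coords[[i]], cd$xyzB),
                            c(radii[[i]], radii[[j]]),
                            probe = probe, nPoints = nPoints)
        resAB <- .residueAsa(asaAB$atomArea, resIdxAB, nres[i] + nres[j])
        boundA <- resAB[seq_len(nres[i])]
        boundB <- resAB[nres[i] + seq_len(nres[j])]
        bsaA <- pmax(0, asaRef[[i]] - boundA)
        bsaB <- pmax(0, asaRef[[j]] - boundB)
        area <- (sum(bsaA) + sum(bsaB)) / 2
        if (area < minArea) next
        out[[length(out) + 1L]] <- new("Interface",
            id = NA_integer_, chainA = ids[i], chainB = ids[j],
            operator = cd$op, opClass = classifyOperator(cd$op),
            area = area, contacts = cd$contacts,
            asaA = asaRef[[i]], asaB = asaRef[[j]],
            bsaA = bsaA, bsaB = bsaB)
    }
    if (length(out) == 0) return(list())
    out <- out[order(vapply(out, function(x) x@area, numeric(1)),
                     decreasing = TRUE)]
    for (i in seq_along(out)) out[[i]]@id <- as.integer(i)
    out
}

#' Assign core/rim/surface/interior region labels
#'
#' Per residue, the burial ratio is (ASA_unbound - ASA_bound)/ASA_unbound.
#' CORE: ratio >= \code{coreBurialThreshold}; RIM: 0 < ratio < threshold;
#' SURFACE: ratio = 0 and ASA_unbound >= \code{surfaceMinAsa}; INTERIOR
#' otherwise (including residues with no accessible area in the monomer).
#'
#' @param interface An \linkS4class{Interface}.
#' @param coreBurialThreshold Burial-ratio cutoff in (0, 1); 0.95 for the
#'   geometry indicator, 0.70 for the evolutionary scores.
#' @param surfaceMinAsa Minimum unbound ASA (Angstrom^2) for a
#'   non-interface residue to count as surface (default 5).
#' @return List with factors \code{a} and \code{b} (levels CORE, RIM,
#'   SURFACE, INTERIOR), one label per residue of each partner.
#' @export
assignRegions <- function(interface, coreBurialThreshold,
                          surfaceMinAsa = 5) {
    if (coreBurialThreshold <= 0 || coreBurialThreshold > 1)
        stop("coreBurialThreshold must lie in (0, 1]")
    lab <- function(asa, bsa) {
        ratio <- ifelse(asa > 0, bsa / asa, 0)
        out <- rep("INTERIOR", length(asa))
        out[asa > 0 & ratio >= coreBurialThreshold] <- "CORE"
        out[asa > 0 & ratio > 1e-9 & ratio < coreBurialThreshold] <- "RIM"
        out[asa >= surfaceMinAsa & ratio <= 1e-9] <- "SURFACE"
        factor(out, levels = c("CORE", "RIM", "SURFACE", "INTERIOR"))
    }
    list(a = lab(interface@asaA, interface@bsaA),
         b = lab(interface@asaB, interface@bsaB))
}

setMethod("show", "Interface", function(object) {
    cat(sprintf(
        "Interface %s: %s-%s via %s [%s]%s, area %.1f A^2, %d contact pairs\n",
        format(object@id), object@chainA, object@chainB,
        operatorFingerprint(object@operator), object@opClass@code,
        if (object@opClass@isInfinite) " (infinite)" else "",
        object@area, nrow(object@contacts)))
})

#' Buried surface area of an interface
#' @param interface An \linkS4class{Interface}.
#' @return Numeric(1), Angstrom^2.
#' @export
interfaceArea <- function(interface) interface@area

#' Operator class of an interface
#' @param interface An \linkS4class{Interface}.
#' @return The \linkS4class{OperatorClass}.
#' @export
interfaceOperatorClass <- function(interface) interface@opClass
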