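# Synthetic toy crystals and toy alignments with controlled statistical
# structure. Backbone geometry is schematic (collision-free pseudo-atoms
# with realistic radii), which is all the contact/ASA machinery measures;
# no stereochemical validity is attempted.

.AA_123 <- setNames(names(.AA_321)[1:20], .AA_321[1:20])

.randomSequence <- function(n) paste(sample(.AA20, n, TRUE), collapse = "")

# a slab-shaped chain: residues on an nx x nz grid in the y = 0 plane,
# one CA at the grid point and one CB 1.5 A above, with positional jitter
.slabChain <- function(chainId, nRes, spacing = 3.8, jitter = 0.25,
                       sequence = NULL) {
    nx <- ceiling(sqrt(nRes))
    grid <- expand.grid(ix = seq_len(nx) - 1,
                        iz = seq_len(ceiling(nRes / nx)) - 1)
    grid <- grid[seq_len(nRes), , drop = FALSE]
    ca <- cbind((grid$ix - mean(grid$ix)) * spacing, 0,
                (grid$iz - mean(grid$iz)) * spacing)
    ca <- ca + matrix(runif(3 * nRes, -jitter, jitter), nRes, 3)
    cb <- ca + matrix(c(0, 1.5, 0), nRes, 3, byrow = TRUE)
    # interleave CA/CB per residue
    xyz <- matrix(NA_real_, 2 * nRes, 3)
    xyz[seq(1, 2 * nRes, 2), ] <- ca
    xyz[seq(2, 2 * nRes, 2), ] <- cb
    if (is.null(sequence)) sequence <- .randomSequence(nRes)
    resNames <- unname(.AA_123[strsplit(sequence, "")[[1]]])
    atoms <- data.frame(
        serial = seq_len(2 * nRes), element = "C",
        name = rep(c("CA", "CB"), nRes),
        resIndex = rep(seq_len(nRes), each = 2),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        stringsAsFactors = FALSE)
    chainModel(chainId, resNames, seq_len(nRes), atoms,
               isProtein = TRUE)
}

.translateChain <- function(chain, v) {
    chain@atoms$x <- chain@atoms$x + v[1]
    chain@atoms$y <- chain@atoms$y + v[2]
    chain@atoms$z <- chain@atoms$z + v[3]
    chain
}

.chainExtent <- function(chain) {
    xyz <- .chainCoords(chain)
    apply(xyz, 2, max) - apply(xyz, 2, min)
}

.pinv <- function(m, tol = 1e-8) {
    s <- svd(m)
    d <- ifelse(s$d > tol, 1 / s$d, 0)
    s$v %*% diag(d) %*% t(s$u)
}

# independent simple all-images contact scan used as ground truth
#' Brute-force lattice contact scan
#'
#' Independent reference enumeration: every chain image under every
#' operator and unit-cell shift is tested for contact against every
#' reference chain with a plain distance computation, and contacts are
#' deduplicated by chain pair and direction-independent operator
#' fingerprint. Used as the oracle for the optimized enumerator.
#'
#' @param structure A \linkS4class{CrystalStructure}.
#' @param contactDistance Contact cutoff, Angstrom (default 5.9).
#' @param minChainLength Minimum chain length (default 10).
#' @return data.frame with chain_a, chain_b, fingerprint (unordered pair
#'   key), operator_class.
#' @export
bruteForceContactScan <- function(structure, contactDistance = 5.9,
                                  minChainLength = 10L) {
    chains <- Filter(function(ch)
        ch@isProtein && length(ch@resNames) >= minChainLength,
        structure@chains)
    ids <- names(chains)
    cell <- structure@cell
    coords <- lapply(chains, function(ch) {
        xyz <- .chainCoords(ch)
        xyz[toupper(ch@atoms$element) != "H", , drop = FALSE]
    })
    diam <- max(vapply(coords, function(x)
        sqrt(max(rowSums((x - matrix(colMeans(x), nrow(x), 3,
                                     byrow = TRUE))^2))), numeric(1))) * 2
    rng <- pmax(1L, pmin(4L, as.integer(ceiling(
        (diam + contactDistance) / c(cell@a, cell@b, cell@c)))))
    if (structure@experimentalMethod != "XRAY") rng <- c(0L, 0L, 0L)
    shifts <- as.matrix(expand.grid(-rng[1]:rng[1], -rng[2]:rng[2],
                                    -rng[3]:rng[3]))
    out <- list()
    minDist <- function(a, b) {
        # plain distance computation, no shared C++ path
        d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
        sqrt(max(0, min(d2)))
    }
    for (i in seq_along(chains)) for (j in seq_along(chains)) {
        if (j < i) next
        for (k in seq_along(structure@operators))
            for (s in seq_len(nrow(shifts))) {
                base <- structure@operators[[k]]
                op <- symOperator(base@rot, base@trans, shifts[s, ])
                if (i == j && isIdentityOperator(op)) next
                xyzB <- applyOperator(op, coords[[j]], cell)
                if (minDist(coords[[i]], xyzB) > contactDistance) next
                key <- if (i == j) fingerprintPair(op)
                       else operatorFingerprint(op)
                out[[length(out) + 1L]] <- data.frame(
                    chain_a = ids[i], chain_b = ids[j],
                    fingerprint = key,
                    operator_class = classifyOperator(op)@code,
                    stringsAsFactors = FALSE)
            }
    }
    if (length(out) == 0)
        return(data.frame(chain_a = character(0), chain_b = character(0),
                          fingerprint = character(0),
                          operator_class = character(0),
                          stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    res[!duplicated(paste(res$chain_a, res$chain_b, res$fingerprint)), ,
        drop = FALSE]
}

# smallest non-zero screw step among a group's operators, with its axis
.stackingOperator <- function(ops) {
    best <- NULL
    for (op in ops) {
        cls <- classifyOperator(op)
        if (!(cls@code %in% c("2S", "3S", "4S", "6S"))) next
        step <- sqrt(sum(cls@screw^2))
        if (is.null(best) || step < best$step)
            best <- list(op = op, cls = cls, step = step,
                         axis = which(abs(cls@screw) > 1e-6))
    }
    best
}

#' Generate a toy crystal with a controlled interface size class
#'
#' Builds a compact slab-like pseudo-protein and places it in the
#' requested space group so that lattice images either stay apart
#' (\code{"NONE"}), touch through a small contact (\code{"SMALL"},
#' < 600 A^2), or stack face-on through the group's screw (or cell
#' translation) axis (\code{"LARGE"}, > 600 A^2). Deterministic given
#' the seed; the independent \code{\link{bruteForceContactScan}} of the
#' result is returned as ground truth.
#'
#' @param spacegroup One of \code{\link{supportedSpaceGroups}} (aliases
#'   accepted).
#' @param chainLength Residue count (default 16 for SMALL, 49 for LARGE).
#' @param interfaceTarget "NONE", "SMALL" or "LARGE".
#' @param seed Integer RNG seed.
#' @param resolution,rFree Entry metadata to stamp on the fixture.
#' @return List with \code{structure}, \code{groundTruth} (brute-force
#'   contact table), \code{seed}.
#' @export
makeCrystalFixture <- function(spacegroup = "P 1", chainLength = NULL,
                               interfaceTarget = c("SMALL", "LARGE",
                                                   "NONE"),
                               seed = 1L, resolution = 2.0,
                               rFree = 0.25) {
    interfaceTarget <- match.arg(interfaceTarget)
    canon <- .canonicalSpacegroup(spacegroup)
    if (is.na(canon))
        stop("unsupported space group '", spacegroup, "'; supported: ",
             paste(supportedSpaceGroups(), collapse = ", "))
    if (is.null(chainLength))
        chainLength <- if (interfaceTarget == "LARGE") 49L else 16L
    ops <- spaceGroupOperators(canon)
    hexagonal <- canon %in% c("P 61", "P 31", "P 32 2 1", "P 65 2 2")
    angles <- if (hexagonal) c(90, 90, 120) else c(90, 90, 90)

    structure <- .withSeed(seed, {
        chain <- .slabChain("A", chainLength)
        if (interfaceTarget == "LARGE")
            .buildStackedCrystal(chain, canon, ops, angles,
                                 resolution, rFree)
        else
            .buildScaledCrystal(chain, canon, ops, angles,
                                none = interfaceTarget == "NONE",
                                resolution, rFree)
    })
    gt <- bruteForceContactScan(structure)
    if (interfaceTarget == "NONE" && nrow(gt) > 0)
        stop("fixture generation failed: unintended contact")
    if (interfaceTarget != "NONE" && nrow(gt) == 0)
        stop("fixture generation failed: no contact achieved")
    list(structure = structure, groundTruth = gt, seed = seed)
}

# place the slab on the screw axis and set the axis length so that
# successive screw images stack face-on
.buildStackedCrystal <- function(chain, canon, ops, angles,
                                 resolution, rFree) {
    stk <- .stackingOperator(ops)
    gap <- 4.2
    ext <- .chainExtent(chain)
    if (is.null(stk)) {
        # no screw operator: stack via the cell translation along y
        lens <- ext + c(60, 0, 60)
        lens[2] <- ext[2] + gap
        cell <- crystalCell(lens[1], lens[2], lens[3],
                            angles[1], angles[2], angles[3])
        chain <- .translateChain(chain,
            as.numeric(cell@orthMat %*% c(0.5, 0.5, 0.5)))
    } else {
        axis <- stk$axis[1]
        # slab plane is y = 0; rotate roles so the slab normal lies on
        # the screw axis: swap y and the axis coordinate
        if (axis != 2L) {
            xyz <- .chainCoords(chain)
            perm <- c(1, 2, 3)
            perm[c(2, axis)] <- perm[c(axis, 2)]
            xyz <- xyz[, perm, drop = FALSE]
            chain@atoms$x <- xyz[, 1]
            chain@atoms$y <- xyz[, 2]
            chain@atoms$z <- xyz[, 3]
        }
        ext <- .chainExtent(chain)
        step <- abs(stk$cls@screw[stk$axis[1]])
        lens <- ext + 60
        lens[axis] <- (ext[axis] + gap) / step
        cell <- crystalCell(lens[1], lens[2], lens[3],
                            angles[1], angles[2], angles[3])
        # axis location x0 solves (I - R) x0 = location part of t
        R <- stk$op@rot
        tloc <- totalTranslation(stk$op) - stk$cls@screw
        x0 <- as.numeric(.pinv(diag(3) - R) %*% tloc)
        chain <- .translateChain(chain,
            as.numeric(cell@orthMat %*% x0))
    }
    crystalStructure("FIX", list(chain), cell, canon, ops,
                     resolution = resolution, rFree = rFree)
}

# generic placement: pad the cell generously, then shrink the padding
# uniformly until the closest lattice image sits at contact distance
.buildScaledCrystal <- function(chain, canon, ops, angles, none,
                                resolution, rFree) {
    ext <- .chainExtent(chain)
    pad0 <- c(30, 30, 30)
    fracCenter <- c(0.31, 0.27, 0.29) + runif(3, -0.02, 0.02)
    build <- function(t) {
        lens <- ext + pad0 * t
        cell <- crystalCell(lens[1], lens[2], lens[3],
                            angles[1], angles[2], angles[3])
        ch <- .translateChain(chain,
            as.numeric(cell@orthMat %*% fracCenter) -
                colMeans(.chainCoords(chain)))
        crystalStructure("FIX", list(ch), cell, canon, ops,
                         resolution = resolution, rFree = rFree)
    }
    if (none) {
        s <- build(1)
        if (.minImageDistance(s) < 8)
            s <- build(1.5)
        return(s)
    }
    lo <- 0.02; hi <- 1
    target <- c(3.8, 4.4)
    for (it in 1:40) {
        mid <- (lo + hi) / 2
        d <- .minImageDistance(build(mid))
        if (d < target[1]) lo <- mid
        else if (d > target[2]) hi <- mid
        else return(build(mid))
    }
    build(hi)
}

# minimum distance from the reference copy to any lattice image
.minImageDistance <- function(structure) {
    cell <- structure@cell
    chain <- structure@chains[[1]]
    xyz <- .chainCoords(chain)
    best <- Inf
    shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    for (k in seq_along(structure@operators))
        for (s in seq_len(nrow(shifts))) {
            base <- structure@operators[[k]]
            op <- symOperator(base@rot, base@trans, shifts[s, ])
            if (isIdentityOperator(op)) next
            d <- .cppMinDist(xyz, applyOperator(op, xyz, cell))
            if (d < best) best <- d
        }
    best
}

#' Generate a biological-like dimer fixture
#'
#' Two pseudo-protein chains in a spacious P1 cell: chain A carries a
#' protruding "finger" of \code{coreSize} residues that inserts into a
#' complementary ring-tube "socket" on chain B, so that the finger
#' residues are almost completely buried on complexation (the geometric
#' hallmark of a biological interface), while both partners keep large
#' free surfaces. Ground-truth core positions are returned for building
#' matched conserved alignments.
#'
#' @param coreSize Finger length in residues (default 8).
#' @param ballResidues Shell residues per chain body (default 42).
#' @param seed Integer RNG seed.
#' @param resolution,rFree Entry metadata (defaults 1.8, 0.22: a
#'   well-refined structure).
#' @return List with \code{structure}, \code{corePositionsA} (finger
#'   residue indices in chain A), \code{socketPositionsB} (tube residue
#'   indices in chain B), \code{seed}.
#' @export
makeDimerFixture <- function(coreSize = 8L, ballResidues = 42L,
                             seed = 1L, resolution = 1.8, rFree = 0.22) {
    .withSeed(seed, {
        ballA <- .shellCoords(ballResidues, radius = 10)
        fingerX <- 12 + 3.0 * (seq_len(coreSize) - 1)
        nA <- ballResidues + coreSize
        seqA <- .randomSequence(nA)
        atomsA <- .shellAtoms(ballA)
        for (i in seq_len(coreSize)) {
            atomsA <- rbind(atomsA, data.frame(
                serial = 0L, element = "C", name = "CA",
                resIndex = ballResidues + i,
                x = fingerX[i], y = 0, z = 0))
            atomsA <- rbind(atomsA, data.frame(
                serial = 0L, element = "C", name = "CB",
                resIndex = ballResidues + i,
                x = fingerX[i] + 1.0, y = 1.1, z = 0))
        }
        atomsA$serial <- seq_len(nrow(atomsA))
        chainA <- chainModel("A", unname(.AA_123[strsplit(seqA, "")[[1]]]),
                             seq_len(nA), atomsA, isProtein = TRUE)

        # chain B: ring tube around the finger, capped, plus its own shell
        tubeR <- 4.5
        ringX <- seq(min(fingerX) - 1.5, max(fingerX) + 1.5, by = 2.4)
        nRings <- length(ringX)
        atomsB <- NULL
        for (r in seq_len(nRings)) {
            ang <- 2 * pi * (seq_len(8) - 1) / 8 +
                (r %% 2) * pi / 8
            atomsB <- rbind(atomsB, data.frame(
                serial = 0L, element = "C", name = "C",
                resIndex = r,
                x = ringX[r], y = tubeR * cos(ang),
                z = tubeR * sin(ang)))
        }
        # cap disc beyond the finger tip
        capX <- max(fingerX) + 4.0
        cap <- expand.grid(y = c(-2.2, 0, 2.2), z = c(-2.2, 0, 2.2))
        atomsB <- rbind(atomsB, data.frame(
            serial = 0L, element = "C", name = "C",
            resIndex = nRings + 1L,
            x = capX, y = cap$y, z = cap$z))
        ballB <- .shellCoords(ballResidues, radius = 10)
        ballB[, 1] <- ballB[, 1] + capX + 12
        atomsShellB <- .shellAtoms(ballB)
        atomsShellB$resIndex <- atomsShellB$resIndex + nRings + 1L
        atomsB <- rbind(atomsB, atomsShellB)
        atomsB$serial <- seq_len(nrow(atomsB))
        nB <- nRings + 1L + ballResidues
        seqB <- .randomSequence(nB)
        chainB <- chainModel("B", unname(.AA_123[strsplit(seqB, "")[[1]]]),
                             seq_len(nB), atomsB, isProtein = TRUE)

        cell <- crystalCell(150, 120, 120)
        shift <- as.numeric(cell@orthMat %*% c(0.35, 0.5, 0.5))
        chainA <- .translateChain(chainA, shift)
        chainB <- .translateChain(chainB, shift)
        structure <- crystalStructure("DIM", list(chainA, chainB), cell,
                                      "P 1", resolution = resolution,
                                      rFree = rFree)
        list(structure = structure,
             corePositionsA = ballResidues + seq_len(coreSize),
             socketPositionsB = seq_len(nRings + 1L),
             seed = seed)
    })
}

# quasi-uniform spherical shell of residues (2 atoms each)
.shellCoords <- function(n, radius) {
    golden <- pi * (3 - sqrt(5))
    i <- seq_len(n) - 1
    z <- 1 - (2 * i + 1) / n
    r <- sqrt(pmax(0, 1 - z^2))
    phi <- golden * i
    radius * cbind(r * cos(phi), r * sin(phi), z)
}

.shellAtoms <- function(shell) {
    n <- nrow(shell)
    out <- NULL
    for (i in seq_len(n)) {
        u <- shell[i, ] / sqrt(sum(shell[i, ]^2))
        out <- rbind(out,
            data.frame(serial = 0L, element = "C", name = "CA",
                       resIndex = i, x = shell[i, 1], y = shell[i, 2],
                       z = shell[i, 3]),
            data.frame(serial = 0L, element = "C", name = "CB",
                       resIndex = i, x = shell[i, 1] + 1.4 * u[1],
                       y = shell[i, 2] + 1.4 * u[2],
                       z = shell[i, 3] + 1.4 * u[3]))
    }
    out
}

#' Generate a toy homolog alignment with controlled conservation
#'
#' Homolog rows reproduce the query exactly at conserved positions and
#' draw uniformly from a fixed per-column symbol set of size
#' \code{nSymbols} at variable positions (column entropy tends to
#' log2(nSymbols) as rows accumulate). When \code{identityToQuery} is
#' given, each row instead matches the query at exactly
#' \code{round(identityToQuery * L)} positions (conserved positions
#' always included; infeasible targets raise an error).
#'
#' @param query Character(1), the query sequence.
#' @param nHomologs Number of homolog rows.
#' @param conservedPositions Integer indices of conserved columns.
#' @param nSymbols Symbol-set size at variable columns (default 4).
#' @param identityToQuery Optional exact per-row identity target.
#' @param seed Integer RNG seed.
#' @return A \linkS4class{HomologAlignment} (no gaps).
#' @export
makeAlignmentFixture <- function(query, nHomologs,
                                 conservedPositions = integer(0),
                                 nSymbols = 4L, identityToQuery = NA,
                                 seed = 1L) {
    L <- nchar(query)
    qc <- strsplit(query, "")[[1]]
    conserved <- seq_len(L) %in% conservedPositions
    .withSeed(seed, {
        symbolSets <- lapply(seq_len(L), function(i)
            sample(.AA20, nSymbols))
        rows <- character(nHomologs)
        for (h in seq_len(nHomologs)) {
            r <- character(L)
            r[conserved] <- qc[conserved]
            if (is.na(identityToQuery)) {
                for (i in which(!conserved))
                    r[i] <- sample(symbolSets[[i]], 1)
            } else {
                m <- round(identityToQuery * L)
                if (m < sum(conserved) || m > L)
                    stop("identity target ", identityToQuery,
                         " infeasible with ", sum(conserved),
                         " conserved positions")
                extra <- sample(which(!conserved), m - sum(conserved))
                r[extra] <- qc[extra]
                for (i in setdiff(which(!conserved), extra))
                    r[i] <- sample(setdiff(.AA20, qc[i]), 1)
            }
            rows[h] <- paste(r, collapse = "")
        }
        homologAlignment("query",
                         c("query", sprintf("hom%04d", seq_len(nHomologs))),
                         c(query, rows))
    })
}
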