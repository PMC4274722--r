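# Independent oracles and small construction helpers shared by the tests.

# Infinite-assembly oracle: an operator generates a finite cycle iff some
# power k <= 12 is exactly the identity with zero net translation.
oracleIsInfinite <- function(op) {
    rot <- diag(3)
    tr <- c(0, 0, 0)
    for (k in 1:12) {
        tr <- op@rot %*% tr + totalTranslation(op)
        rot <- op@rot %*% rot
        if (all(abs(rot - diag(3)) < 1e-9) && all(abs(tr) < 1e-9))
            return(FALSE)
    }
    TRUE
}

# Plain-R Shrake-Rupley with its own point set, used as a denser oracle.
asaOracle <- function(xyz, radii, probe = 1.4, nPoints = 9600) {
    i <- seq_len(nPoints) - 1
    z <- 1 - (2 * i + 1) / nPoints
    r <- sqrt(pmax(0, 1 - z^2))
    phi <- pi * (3 - sqrt(5)) * i
    pts <- cbind(r * cos(phi), r * sin(phi), z)
    n <- nrow(xyz)
    vapply(seq_len(n), function(a) {
        ra <- radii[a] + probe
        p <- pts * ra + matrix(xyz[a, ], nPoints, 3, byrow = TRUE)
        free <- rep(TRUE, nPoints)
        for (b in seq_len(n)[-a]) {
            rb <- radii[b] + probe
            d2 <- (p[, 1] - xyz[b, 1])^2 + (p[, 2] - xyz[b, 2])^2 +
                (p[, 3] - xyz[b, 3])^2
            free <- free & d2 >= rb^2
        }
        4 * pi * ra^2 * mean(free)
    }, numeric(1))
}

# one-CA-per-residue chain for mapping/entropy tests
tinyChain <- function(sequence, chainId = "A", resNoOffset = 0L) {
    n <- nchar(sequence)
    atoms <- data.frame(serial = seq_len(n), element = "C", name = "CA",
                        resIndex = seq_len(n), x = 3.8 * seq_len(n),
                        y = 0, z = 0, stringsAsFactors = FALSE)
    aa123 <- setNames(
        c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL"),
        strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
    chainModel(chainId, unname(aa123[strsplit(sequence, "")[[1]]]),
               seq_len(n) + resNoOffset, atoms, isProtein = TRUE)
}

# fabricate an interface with prescribed per-residue burial ratios
syntheticInterface <- function(burialA, burialB, unboundAsa = 100,
                               area = 500) {
    idOp <- identityOperator()
    asaA <- rep(unboundAsa, length(burialA))
    asaB <- rep(unboundAsa, length(burialB))
    new("Interface", id = 1L, chainA = "A", chainB = "B",
        operator = idOp, opClass = classifyOperator(idOp),
        area = area,
        contacts = data.frame(resA = integer(0), resB = integer(0)),
        asaA = asaA, asaB = asaB,
        bsaA = asaA * burialA, bsaB = asaB * burialB)
}

syntheticCall <- function(geometry = "BIO", coreRim = "BIO",
                          coreSurface = "BIO", score = -4,
                          consensus = NULL, nCore = 8L) {
    if (is.null(consensus))
        consensus <- consensusCall(geometry, coreRim, coreSurface)
    new("InterfaceCall", interfaceId = 1L, nCoreGeom = nCore,
        coreRimRatio = 0.5, coreSurfaceScore = score,
        callGeometry = geometry, callCoreRim = coreRim,
        callCoreSurface = coreSurface, consensus = consensus,
        robust = FALSE)
}

syntheticEntry <- function(resolution = 1.8, rFree = 0.22) {
    crystalStructure("SYN", list(tinyChain("ACDEFGHIKL")),
                     crystalCell(50, 50, 50), "P 1",
                     resolution = resolution, rFree = rFree)
}

# entropy profile with prescribed per-residue values
syntheticProfile <- function(entropy, nHomologs = 40L) {
    new("EntropyProfile", entropy = entropy,
        nHomologsUsed = as.integer(nHomologs), identityCutoff = 0.5,
        insufficient = nHomologs < 10L)
}
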