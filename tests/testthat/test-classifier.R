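# Indicators, consensus, robust filter and entry verdict.

test_that("the geometry call flips at the core-count cutoff", {
    mk <- function(n) syntheticInterface(
        burialA = c(rep(1, n), rep(0.3, 4)), burialB = rep(0.2, 3))
    expect_equal(geometryIndicator(mk(0))$call, "XTAL")
    expect_equal(geometryIndicator(mk(5))$call, "XTAL")
    g6 <- geometryIndicator(mk(6))
    expect_equal(g6$nCore, 6L)
    expect_equal(g6$call, "BIO")
    # lowering the cutoff can only move calls toward BIO
    expect_equal(geometryIndicator(mk(5), coreCallCutoff = 5L)$call, "BIO")
})

test_that("core residues on both partners are summed", {
    ifc <- syntheticInterface(burialA = c(1, 1, 1, 0.2),
                              burialB = c(0.99, 0.98, 0.97, 0.96))
    expect_equal(geometryIndicator(ifc)$nCore, 7L)
    expect_equal(geometryIndicator(ifc)$call, "BIO")
})

test_that("the core-rim ratio compares pooled means", {
    ifc <- syntheticInterface(burialA = c(0.9, 0.8, 0.5, 0.3, 0, 0),
                              burialB = c(0, 0))
    # core = residues 1,2 (>= 0.7); rim = 3,4
    pA <- syntheticProfile(c(0.5, 0.5, 1.0, 1.0, 2, 2))
    pB <- syntheticProfile(c(2, 2))
    cr <- coreRimIndicator(ifc, pA, pB)
    expect_equal(cr$ratio, 0.5)
    expect_equal(cr$call, "BIO")
    # conserved core against a variable rim
    p0 <- syntheticProfile(c(0, 0, 1.0, 1.0, 2, 2))
    expect_equal(coreRimIndicator(ifc, p0, pB)$ratio, 0)
    # equal core and rim entropies sit at ratio 1 -> XTAL
    p1 <- syntheticProfile(c(1, 1, 1, 1, 2, 2))
    cr1 <- coreRimIndicator(ifc, p1, pB)
    expect_equal(cr1$ratio, 1)
    expect_equal(cr1$call, "XTAL")
})

test_that("the core-rim indicator abstains on degenerate inputs", {
    ifc <- syntheticInterface(burialA = c(0.9, 0.8, 0.5, 0.3, 0, 0),
                              burialB = c(0, 0))
    pA <- syntheticProfile(c(0.5, 0.5, 1, 1, 2, 2))
    pB <- syntheticProfile(c(2, 2))
    expect_equal(coreRimIndicator(ifc, NULL, pB)$call, "NOPRED")
    insuf <- syntheticProfile(c(0.5, 0.5, 1, 1, 2, 2), nHomologs = 3L)
    expect_equal(coreRimIndicator(ifc, insuf, pB)$call, "NOPRED")
    # zero rim entropy
    pZ <- syntheticProfile(c(0.5, 0.5, 0, 0, 2, 2))
    expect_equal(coreRimIndicator(ifc, pZ, pB)$call, "NOPRED")
    # no rim residues at all
    ifc2 <- syntheticInterface(burialA = c(1, 1, 0, 0, 0, 0, 0, 0),
                               burialB = c(0, 0))
    expect_equal(coreRimIndicator(ifc2, syntheticProfile(rep(1, 8)),
                                  pB)$call, "NOPRED")
})

test_that("the core-surface score is negative for conserved cores", {
    set.seed(9)
    burial <- c(rep(0.9, 6), rep(0, 24))
    ifc <- syntheticInterface(burialA = burial, burialB = c(0, 0))
    entA <- c(rep(0, 6), runif(24, 1.5, 2.5))
    pA <- syntheticProfile(entA)
    pB <- syntheticProfile(c(2, 2))
    cs <- coreSurfaceIndicator(ifc, pA, pB, nSamples = 2000L, seed = 1)
    expect_lt(cs$score, -3)
    expect_equal(cs$call, "BIO")
    # unconserved core scores near zero
    pU <- syntheticProfile(c(runif(6, 1.5, 2.5), entA[7:30]))
    csU <- coreSurfaceIndicator(ifc, pU, pB, nSamples = 2000L, seed = 1)
    expect_gt(csU$score, -1)
})

test_that("core-surface sampling is seeded and convergent", {
    set.seed(10)
    burial <- c(rep(0.9, 5), rep(0, 30))
    ifc <- syntheticInterface(burialA = burial, burialB = c(0, 0))
    pA <- syntheticProfile(c(rep(0.2, 5), runif(30, 0.5, 2.5)))
    pB <- syntheticProfile(c(2, 2))
    s1 <- coreSurfaceIndicator(ifc, pA, pB, nSamples = 10000L, seed = 7)
    s2 <- coreSurfaceIndicator(ifc, pA, pB, nSamples = 10000L, seed = 7)
    expect_identical(s1$score, s2$score)
    s3 <- coreSurfaceIndicator(ifc, pA, pB, nSamples = 10000L, seed = 8)
    expect_lt(abs(s1$score - s3$score), 0.1)
})

test_that("the core-surface indicator abstains on degenerate pools", {
    # constant profile: zero spread of sample means
    burial <- c(rep(0.9, 4), rep(0, 10))
    ifc <- syntheticInterface(burialA = burial, burialB = c(0, 0))
    pC <- syntheticProfile(rep(1.5, 14))
    expect_equal(coreSurfaceIndicator(ifc, pC, syntheticProfile(c(2, 2)),
                                      nSamples = 500L)$call, "NOPRED")
    # surface pool smaller than the core
    ifc2 <- syntheticInterface(burialA = c(rep(0.9, 5), 0),
                               burialB = c(0, 0))
    pS <- syntheticProfile(c(rep(0, 5), 2))
    expect_equal(coreSurfaceIndicator(ifc2, pS, syntheticProfile(c(2, 2)),
                                      nSamples = 500L)$call, "NOPRED")
    expect_error(coreSurfaceIndicator(ifc, pC, pC, nSamples = 50L),
                 "nSamples")
})

test_that("consensus follows majority with documented tie-breaks", {
    expect_equal(consensusCall("BIO", "BIO", "XTAL"), "BIO")
    expect_equal(consensusCall("XTAL", "BIO", "XTAL"), "XTAL")
    expect_equal(consensusCall("XTAL", "NOPRED", "NOPRED"), "XTAL")
    expect_equal(consensusCall("BIO", "NOPRED", "NOPRED"), "BIO")
    # 1-1 tie with an abstention: core-surface wins when present
    expect_equal(consensusCall("BIO", "NOPRED", "XTAL"), "XTAL")
    expect_equal(consensusCall("XTAL", "NOPRED", "BIO"), "BIO")
    expect_equal(consensusCall("BIO", "XTAL", "NOPRED"), "BIO")
    expect_equal(consensusCall("XTAL", "XTAL", "BIO"), "XTAL")
})

test_that("the robust filter requires every stated condition", {
    entry <- syntheticEntry(resolution = 1.8, rFree = 0.22)
    bio <- syntheticCall("BIO", "BIO", "BIO", score = -4)
    expect_true(robustFilter(entry, bio, 45))
    # each violated condition alone disqualifies
    expect_false(robustFilter(syntheticEntry(2.5, 0.22), bio, 45))
    expect_false(robustFilter(syntheticEntry(1.8, 0.30), bio, 45))
    expect_false(robustFilter(syntheticEntry(NA, 0.22), bio, 45))
    expect_false(robustFilter(entry, bio, 29))
    expect_true(robustFilter(entry, bio, 30))
    expect_false(robustFilter(entry,
        syntheticCall("BIO", "XTAL", "BIO", score = -4), 45))
    expect_false(robustFilter(entry,
        syntheticCall("BIO", "NOPRED", "BIO", score = -4), 45))
    # score extremes: strictly below -3.3 / strictly above 0.15
    expect_false(robustFilter(entry,
        syntheticCall("BIO", "BIO", "BIO", score = -2.0), 45))
    expect_false(robustFilter(entry,
        syntheticCall("BIO", "BIO", "BIO", score = -3.3), 45))
    expect_true(robustFilter(entry,
        syntheticCall("BIO", "BIO", "BIO", score = -3.31), 45))
    xtal <- function(s) syntheticCall("XTAL", "XTAL", "XTAL", score = s)
    expect_true(robustFilter(entry, xtal(0.2), 45))
    expect_false(robustFilter(entry, xtal(0.15), 45))
    expect_false(robustFilter(entry, xtal(-1), 45))
})

test_that("entries are multimeric iff any interface is biological", {
    xt <- syntheticCall("XTAL", "XTAL", "XTAL", score = 1)
    bi <- syntheticCall("BIO", "BIO", "BIO", score = -4)
    expect_equal(entryVerdict(list(xt, xt, xt)), "MONOMERIC")
    expect_equal(entryVerdict(c(rep(list(xt), 9), list(bi))),
                 "MULTIMERIC")
    expect_equal(entryVerdict(list()), "MONOMERIC")
})

test_that("biological and crystal fixtures classify end to end", {
    cfg <- runConfig(nSamples = 2000L)
    fx <- makeDimerFixture(seed = 12)
    chA <- fx$structure@chains[["A"]]
    chB <- fx$structure@chains[["B"]]
    alnA <- makeAlignmentFixture(chA@sequence, 40, fx$corePositionsA,
                                 identityToQuery = 0.6, seed = 1)
    alnB <- makeAlignmentFixture(chB@sequence, 40, fx$socketPositionsB,
                                 identityToQuery = 0.6, seed = 2)
    res <- analyzeStructure(fx$structure,
                            list(A = alnA, B = alnB), cfg)
    expect_length(res$calls, 1L)
    cl <- res$calls[[1]]
    expect_equal(cl@callGeometry, "BIO")
    expect_equal(cl@callCoreRim, "BIO")
    expect_equal(cl@callCoreSurface, "BIO")
    expect_equal(cl@consensus, "BIO")
    expect_true(cl@robust)
    expect_equal(res$verdict, "MULTIMERIC")

    # small unconserved interface: crystal contact on all three counts
    fx2 <- makeDimerFixture(coreSize = 3L, seed = 13)
    chA2 <- fx2$structure@chains[["A"]]
    chB2 <- fx2$structure@chains[["B"]]
    aln2 <- list(
        A = makeAlignmentFixture(chA2@sequence, 40, integer(0),
                                 identityToQuery = 0.6, seed = 3),
        B = makeAlignmentFixture(chB2@sequence, 40, integer(0),
                                 identityToQuery = 0.6, seed = 4))
    res2 <- analyzeStructure(fx2$structure, aln2, cfg)
    cl2 <- res2$calls[[1]]
    expect_equal(cl2@callGeometry, "XTAL")
    expect_false(cl2@consensus == "BIO")
    expect_equal(res2$verdict, "MONOMERIC")
})
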