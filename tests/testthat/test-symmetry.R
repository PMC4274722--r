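# Operator algebra and geometric classification.

test_that("triplet parsing and writing round-trip the embedded groups", {
    for (sg in supportedSpaceGroups()) {
        ops <- spaceGroupOperators(sg)
        expect_true(isIdentityOperator(ops[[1]]))
        for (op in ops) {
            trip <- operatorTriplet(op)
            back <- parseOperatorTriplet(trip)
            expect_equal(back@rot, op@rot)
            expect_equal(back@trans %% 1, op@trans %% 1, tolerance = 1e-9)
        }
    }
})

test_that("the 2_1 operator matches the International Tables entry", {
    ops <- spaceGroupOperators("P 1 21 1")
    expect_length(ops, 2L)
    op <- ops[[2]]
    expect_equal(sum(diag(op@rot)), -1)     # trace -1, two-fold
    expect_equal(det(op@rot), 1)            # proper
    expect_equal(op@trans, c(0, 1/2, 0))
})

test_that("composition obeys the group laws", {
    op <- spaceGroupOperators("P 1 21 1")[[2]]
    expect_equal(composeOperators(identityOperator(), op)@rot, op@rot)
    expect_equal(composeOperators(identityOperator(), op)@trans, op@trans)
    inv <- invertOperator(op)
    expect_true(isIdentityOperator(composeOperators(op, inv),
                                   includeShift = FALSE))
    # 2_1 composed with itself is the unit-cell translation (0,1,0)
    sq <- composeOperators(op, op)
    expect_equal(sq@rot, diag(3))
    expect_equal(totalTranslation(sq), c(0, 1, 0))
    expect_equal(classifyOperator(sq)@code, "XT")
})

test_that("operator sets are closed under composition modulo lattice", {
    for (sg in supportedSpaceGroups()) {
        ops <- spaceGroupOperators(sg)
        keys <- vapply(ops, function(o)
            operatorFingerprint(symOperator(o@rot, o@trans %% 1)),
            character(1))
        for (a in ops) for (b in ops) {
            ab <- composeOperators(a, b)
            k <- operatorFingerprint(
                symOperator(ab@rot, totalTranslation(ab) %% 1))
            expect_true(k %in% keys,
                        label = paste(sg, "closure of", k))
        }
    }
})

test_that("operator classification covers the code vocabulary", {
    expect_equal(classifyOperator(identityOperator())@code, "AU")
    xt <- symOperator(cellShift = c(1, 0, 0))
    expect_equal(classifyOperator(xt)@code, "XT")
    expect_true(classifyOperator(xt)@isInfinite)
    ft <- symOperator(trans = c(1/2, 1/2, 0))
    expect_equal(classifyOperator(ft)@code, "FT")
    screw <- symOperator(diag(c(-1, 1, -1)), c(0, 1/2, 0))
    cls <- classifyOperator(screw)
    expect_equal(cls@code, "2S")
    expect_equal(cls@screw, c(0, 1/2, 0))
    expect_true(cls@isInfinite)
    # translation perpendicular to the axis is location, not screw
    pure2 <- symOperator(diag(c(-1, 1, -1)), c(1/2, 0, 0))
    expect_equal(classifyOperator(pure2)@code, "2")
    expect_false(classifyOperator(pure2)@isInfinite)
    inv <- symOperator(-diag(3))
    expect_equal(classifyOperator(inv)@code, "-1")
    # mirror z -> -z with in-plane translation: glide
    gl <- symOperator(diag(c(1, 1, -1)), c(1/2, 0, 0))
    expect_equal(classifyOperator(gl)@code, "GL")
    expect_false(classifyOperator(gl)@isInfinite)
    # -4 about z
    m4 <- symOperator(matrix(c(0, 1, 0, -1, 0, 0, 0, 0, -1), 3, 3))
    expect_equal(classifyOperator(m4)@code, "-4")
})

test_that("proper rotation folds respect the crystallographic restriction", {
    for (sg in supportedSpaceGroups()) {
        for (op in spaceGroupOperators(sg)) {
            cls <- classifyOperator(op)
            expect_true(cls@fold %in% c(1L, 2L, 3L, 4L, 6L))
        }
    }
})

test_that("non-crystallographic rotation matrices are rejected", {
    bad <- symOperator(matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3,
                              byrow = TRUE))
    expect_equal(classifyOperator(bad)@fold, 3L)  # permutation = 3-fold
    expect_error(classifyOperator(
        symOperator(matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 1), 3, 3))),
        "crystallographic")
})

test_that("fingerprints are canonical and direction-independent", {
    expect_equal(operatorFingerprint(identityOperator()), "x,y,z|0,0,0")
    op <- symOperator(diag(c(-1, 1, -1)), c(0, 1/2, 0), c(0, -1, 0))
    fp <- operatorFingerprint(op)
    reparsed <- parseOperatorTriplet(strsplit(fp, "|", fixed = TRUE)[[1]][1])
    expect_equal(operatorFingerprint(
        symOperator(reparsed@rot, reparsed@trans,
                    as.numeric(strsplit(strsplit(fp, "|", fixed = TRUE)[[1]][2],
                                        ",")[[1]]))), fp)
    expect_equal(fingerprintPair(op), fingerprintPair(invertOperator(op)))
})

test_that("classification agrees with the iteration oracle on lattice shifts", {
    set.seed(1)
    for (sg in supportedSpaceGroups()) {
        for (base in spaceGroupOperators(sg)) {
            for (r in 1:5) {
                op <- symOperator(base@rot, base@trans,
                                  sample(-2:2, 3, TRUE))
                expect_identical(classifyOperator(op)@isInfinite,
                                 oracleIsInfinite(op),
                                 label = paste(sg, operatorFingerprint(op)))
            }
        }
    }
})
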