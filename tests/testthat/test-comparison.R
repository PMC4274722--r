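# Assembly-call mapping, call comparison and confusion metrics.

fps <- c("x,y,z|1,0,0", "-x,y+1/2,-z|0,0,0", "x,y,z|0,1,0")

test_that("the largest stable assembly defines the interface calls", {
    pred <- assemblyPrediction(list(
        list(stability = "UNSTABLE", size = 4, members = fps[3]),
        list(stability = "STABLE", size = 2, members = fps[1])))
    expect_equal(assemblyToInterfaceCalls(pred, fps),
                 c("BIO", "XTAL", "XTAL"))
})

test_that("gray-only assembly lists abstain on every interface", {
    pred <- assemblyPrediction(list(
        list(stability = "GRAY", size = 2, members = fps[1]),
        list(stability = "UNSTABLE", size = 6, members = fps[2])))
    expect_equal(assemblyToInterfaceCalls(pred, fps),
                 rep("NOPRED", 3))
})

test_that("equal-size stable assemblies resolve to the first encountered", {
    pred <- assemblyPrediction(list(
        list(stability = "STABLE", size = 2, members = fps[1]),
        list(stability = "STABLE", size = 2, members = fps[2])))
    expect_equal(assemblyToInterfaceCalls(pred, fps),
                 c("BIO", "XTAL", "XTAL"))
})

test_that("operator matching is direction-independent", {
    # the inverse of the 2_1 operator written as a different triplet
    inv <- operatorFingerprint(
        invertOperator(parseOperatorTriplet("-x,y+1/2,-z")))
    pred <- assemblyPrediction(list(
        list(stability = "STABLE", size = 2, members = inv)))
    expect_equal(assemblyToInterfaceCalls(pred, fps),
                 c("XTAL", "BIO", "XTAL"))
    # a member matching nothing warns and leaves calls intact
    predBad <- assemblyPrediction(list(
        list(stability = "STABLE", size = 2,
             members = c(fps[1], "x,y,z+1/2|9,9,9"))))
    expect_warning(out <- assemblyToInterfaceCalls(predBad, fps),
                   "matches no interface")
    expect_equal(out, c("BIO", "XTAL", "XTAL"))
})

test_that("assembly predictions read from JSON and PISA-style XML", {
    j <- tempfile(fileext = ".json")
    jsonlite::write_json(list(assemblies = list(
        list(stability = "STABLE", size = 2,
             members = list("x,y,z|1,0,0")),
        list(stability = "GRAY", size = 1, members = list()))),
        j, auto_unbox = TRUE)
    pj <- readAssemblyPredictionJson(j)
    expect_length(pj$assemblies, 2L)
    expect_equal(pj$assemblies[[1]]$members, "x,y,z|1,0,0")

    x <- tempfile(fileext = ".xml")
    writeLines(c("<pisa>", "<asm_set>",
                 "<assembly><stability>stable</stability>",
                 "<mmsize>2</mmsize>",
                 "<interface><operator>x,y,z|1,0,0</operator></interface>",
                 "</assembly>",
                 "<assembly><stability>grey region</stability>",
                 "<mmsize>1</mmsize></assembly>",
                 "</asm_set>", "</pisa>"), x)
    px <- readAssemblyPredictionXml(x)
    expect_length(px$assemblies, 2L)
    expect_equal(px$assemblies[[1]]$stability, "STABLE")
    expect_equal(px$assemblies[[2]]$stability, "GRAY")
    expect_equal(assemblyToInterfaceCalls(px, fps),
                 c("BIO", "XTAL", "XTAL"))
})

test_that("per-bin agreement fractions behave at the extremes", {
    calls <- c(rep("BIO", 4), rep("XTAL", 4))
    areas <- c(100, 300, 500, 700, 100, 300, 500, 700)
    same <- compareCalls(calls, calls, areas)
    expect_equal(same$agreement, 1)
    expect_true(all(same$table$bio_bio + same$table$xtal_xtal == 1))
    flip <- ifelse(calls == "BIO", "XTAL", "BIO")
    expect_equal(compareCalls(calls, flip, areas)$agreement, 0)
    # symmetry of the overall agreement
    set.seed(3)
    a <- sample(c("BIO", "XTAL", "NOPRED"), 60, TRUE)
    b <- sample(c("BIO", "XTAL", "NOPRED"), 60, TRUE)
    ar <- runif(60, 0, 1500)
    expect_equal(compareCalls(a, b, ar)$agreement,
                 compareCalls(b, a, ar)$agreement)
    expect_error(compareCalls(a, b[-1], ar), "equal length")
})

test_that("a counted fixture reproduces its agreement fraction", {
    calls_a <- rep("BIO", 100)
    calls_b <- c(rep("BIO", 88), rep("XTAL", 12))
    expect_equal(compareCalls(calls_a, calls_b,
                              rep(500, 100))$agreement, 0.88)
})

test_that("confusion metrics match direct arithmetic", {
    met <- confusionMetrics(c("BIO", "BIO", "XTAL", "XTAL"),
                            c("BIO", "BIO", "XTAL", "XTAL"))
    expect_equal(c(met$sensitivity, met$specificity, met$accuracy,
                   met$mcc), rep(1, 4))
    # all-BIO predictor on balanced labels
    met2 <- confusionMetrics(c("BIO", "BIO", "XTAL", "XTAL"),
                             rep("BIO", 4))
    expect_equal(met2$sensitivity, 1)
    expect_equal(met2$specificity, 0)
    expect_equal(met2$mcc, 0)
    expect_true(met2$mccUndefined)
    # counted confusion matrix against the closed formulas
    labels <- c(rep("BIO", 2140 + 368), rep("XTAL", 2142 + 226))
    calls <- c(rep("BIO", 2140), rep("XTAL", 368),
               rep("XTAL", 2142), rep("BIO", 226))
    met3 <- confusionMetrics(labels, calls)
    expect_equal(met3$sensitivity, 2140 / (2140 + 368),
                 tolerance = 1e-12)
    expect_equal(met3$specificity, 2142 / (2142 + 226),
                 tolerance = 1e-12)
    expect_equal(met3$accuracy, (2140 + 2142) / 4876,
                 tolerance = 1e-12)
    expect_equal(met3$mcc,
                 (2140 * 2142 - 226 * 368) /
                     sqrt((2140 + 226) * (2140 + 368) *
                          (2142 + 226) * (2142 + 368)),
                 tolerance = 1e-12)
})

test_that("swapping the positive class swaps sensitivity and specificity", {
    set.seed(4)
    labels <- sample(c("BIO", "XTAL"), 200, TRUE)
    calls <- sample(c("BIO", "XTAL"), 200, TRUE)
    m1 <- confusionMetrics(labels, calls)
    sw <- function(x) ifelse(x == "BIO", "XTAL", "BIO")
    m2 <- confusionMetrics(sw(labels), sw(calls))
    expect_equal(m1$sensitivity, m2$specificity)
    expect_equal(m1$specificity, m2$sensitivity)
    expect_equal(m1$accuracy, m2$accuracy)
    expect_equal(abs(m1$mcc), abs(m2$mcc))
})

test_that("abstaining calls are excluded and counted", {
    met <- confusionMetrics(c("BIO", "BIO", "XTAL"),
                            c("BIO", "NOPRED", "XTAL"))
    expect_equal(met$nExcluded, 1L)
    expect_equal(met$tp + met$tn + met$fp + met$fn, 2)
    expect_error(confusionMetrics("BIO", "NOPRED"), "no evaluable")
})

test_that("author annotations map through the same operator machinery", {
    bu <- list(list(chainId = "A", fingerprint = "x,y,z|1,0,0"))
    expect_equal(authorAnnotationCalls(bu, fps),
                 c("BIO", "XTAL", "XTAL"))
    expect_equal(authorAnnotationCalls(list(), fps), rep("NOPRED", 3))
})
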