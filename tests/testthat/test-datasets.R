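# Benchmark-set construction rules and sequence clustering.

mkSeq <- function(template, nDiff = 0) {
    s <- strsplit(template, "")[[1]]
    if (nDiff > 0) s[seq_len(nDiff)] <- "W"
    paste(s, collapse = "")
}

baseSeq <- paste(rep("ACDEFGHIKL", 2), collapse = "")  # 20 residues

test_that("sequence clustering is single-linkage at the identity cutoff", {
    s <- baseSeq
    expect_equal(clusterSequences(c(s, s)), c(1L, 1L))
    far <- paste(rep("W", 20), collapse = "")
    expect_equal(clusterSequences(c(s, far, mkSeq(s, 10))),
                 c(1L, 2L, 3L))
    # chain A~B (0.85), B~C (0.85), A~C (0.7): one cluster by linkage
    a <- s
    b <- mkSeq(s, 3)                       # 17/20 = 0.85 to a
    cseq <- paste(c(rep("W", 3),
                    strsplit(mkSeq(s, 6), "")[[1]][4:6],
                    strsplit(s, "")[[1]][7:20]), collapse = "")
    expect_gte(pairwiseIdentity(a, b), 0.8)
    expect_lt(pairwiseIdentity(a, cseq), 0.8)
    expect_gte(pairwiseIdentity(b, cseq), 0.7)
})

test_that("identity at exactly the cutoff joins a cluster", {
    a <- baseSeq
    b <- mkSeq(a, 4)                       # 16/20 = 0.80
    expect_equal(pairwiseIdentity(a, b), 0.8)
    expect_equal(clusterSequences(c(a, b), 0.8), c(1L, 1L))
    b2 <- mkSeq(a, 5)                      # 0.75 < cutoff
    expect_equal(clusterSequences(c(a, b2), 0.8), c(1L, 2L))
})

test_that("crystal-form conservation thresholds flip at 10 forms and 80%", {
    rec <- function(forms, fraction, area = 1500)
        interfaceRecords(entry_id = "E1", sequence_a = baseSeq,
                         area = area,
                         n_crystal_forms_in_cluster = forms,
                         fraction_forms_present = fraction,
                         resolution = 2.0)
    expect_equal(nrow(buildBioMany(rec(10, 0.8))), 1L)
    expect_equal(nrow(buildBioMany(rec(9, 0.9))), 0L)
    expect_equal(nrow(buildBioMany(rec(12, 0.79))), 0L)
    expect_equal(buildBioMany(rec(12, 0.85))$provenance, "PROTCID")
})

test_that("the NMR branch enforces resolution and area bounds", {
    rec <- function(res, area)
        interfaceRecords(entry_id = "E2", sequence_a = baseSeq,
                         area = area, nmr_matched = TRUE,
                         resolution = res)
    expect_equal(buildBioMany(rec(1.9, 550))$provenance, "NMR")
    expect_equal(nrow(buildBioMany(rec(2.5, 550))), 0L)   # strict <
    expect_equal(nrow(buildBioMany(rec(2.49, 550))), 1L)
    expect_equal(nrow(buildBioMany(rec(1.9, 499.9))), 0L) # >= 500
    expect_equal(nrow(buildBioMany(rec(1.9, 500))), 1L)
})

test_that("oversized interfaces are excluded from the biological set", {
    rec <- function(area)
        interfaceRecords(entry_id = "E3", sequence_a = baseSeq,
                         area = area,
                         n_crystal_forms_in_cluster = 12,
                         fraction_forms_present = 0.9,
                         resolution = 1.8)
    expect_equal(nrow(buildBioMany(rec(2000))), 1L)
    expect_equal(nrow(buildBioMany(rec(2000.5))), 0L)
    expect_equal(nrow(buildBioMany(rec(2400))), 0L)
})

test_that("infinite-assembly selection follows operator, area, resolution", {
    rec <- function(cls = "2S", area = 800, res = 2.0, sym = "C2")
        interfaceRecords(entry_id = "E4", sequence_a = baseSeq,
                         sequence_b = baseSeq, area = area,
                         operator_class = cls, resolution = res,
                         biounit_symmetry = sym)
    expect_equal(nrow(buildXtalMany(rec())), 1L)
    expect_equal(buildXtalMany(rec())$label, "XTAL")
    expect_equal(nrow(buildXtalMany(rec(cls = "2"))), 0L)
    expect_equal(nrow(buildXtalMany(rec(cls = "AU"))), 0L)
    expect_equal(nrow(buildXtalMany(rec(cls = "XT", area = 550))), 0L)
    expect_equal(nrow(buildXtalMany(rec(area = 600))), 1L)
    expect_equal(nrow(buildXtalMany(rec(area = 599.9))), 0L)
    expect_equal(nrow(buildXtalMany(rec(res = 2.5))), 0L)
    expect_equal(nrow(buildXtalMany(rec(sym = "helical"))), 0L)
    # heteromeric contacts are never infinite-assembly candidates
    het <- interfaceRecords(entry_id = "E5", sequence_a = baseSeq,
                            sequence_b = paste(rep("W", 20), collapse = ""),
                            area = 800, operator_class = "2S",
                            resolution = 2.0)
    expect_equal(nrow(buildXtalMany(het)), 0L)
})

test_that("filters commute and a build never labels a record twice", {
    set.seed(5)
    n <- 30
    recs <- interfaceRecords(
        entry_id = sprintf("E%02d", seq_len(n)),
        sequence_a = vapply(seq_len(n), function(i)
            paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                         20, TRUE), collapse = ""), ""),
        area = runif(n, 100, 2500),
        operator_class = sample(c("2S", "XT", "2", "AU"), n, TRUE),
        resolution = runif(n, 1.2, 3.2),
        n_crystal_forms_in_cluster = sample(0:20, n, TRUE),
        fraction_forms_present = runif(n),
        nmr_matched = sample(c(TRUE, FALSE), n, TRUE))
    both <- buildBenchmarkSets(recs)
    keys <- function(df) paste(df$entry_id, df$interface_id)
    expect_length(intersect(keys(both$bio), keys(both$xtal)), 0L)
    expect_true(all(both$bio$label == "BIO"))
    expect_true(all(both$xtal$label == "XTAL"))
    bio <- buildBioMany(recs)
    # order of area and resolution filters does not matter
    f1 <- recs[recs$area >= 600 & !is.na(recs$resolution) &
               recs$resolution < 2.5, ]
    f2 <- recs[!is.na(recs$resolution) & recs$resolution < 2.5, ]
    f2 <- f2[f2$area >= 600, ]
    expect_equal(f1, f2)
    # tightening the form threshold never grows the output
    expect_lte(nrow(buildBioMany(recs, minForms = 15L)), nrow(bio))
})

test_that("records survive a TSV round-trip", {
    recs <- interfaceRecords(entry_id = c("A1", "B2"),
                             sequence_a = c(baseSeq, baseSeq),
                             area = c(640.25, 1200),
                             operator_class = c("2S", "AU"),
                             resolution = c(1.8, 2.2))
    f <- tempfile(fileext = ".tsv")
    writeInterfaceRecords(recs, f)
    back <- readInterfaceRecords(f)
    expect_equal(back$area, recs$area)
    expect_equal(back$operator_class, recs$operator_class)
})

test_that("the area histogram is a normalized probability curve", {
    h0 <- areaProbabilityCurve(rep(350, 7), 200)
    expect_equal(max(h0$probability), 1)   # all mass in the [200,400) bin
    expect_equal(sum(h0$probability), 1)
    set.seed(2)
    areas <- runif(500, 0, 2000)
    h <- areaProbabilityCurve(areas, 100)
    expect_equal(sum(h$probability), 1, tolerance = 1e-9)
    h2 <- areaProbabilityCurve(c(areas, areas), 100)
    expect_equal(h$probability, h2$probability)
    expect_error(areaProbabilityCurve(numeric(0), 100), "no areas")
    # half-open bins: a value on the edge belongs to the upper bin
    hb <- areaProbabilityCurve(c(100, 199.999, 200), 100, 100)
    expect_equal(hb$probability, c(2/3, 1/3))
})
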