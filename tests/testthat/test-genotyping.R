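test_that("peak scoring applies the dominance and noise rules", {
    expect_equal(scoreAllele(152.1, 5000), 152.1)
    expect_true(is.na(scoreAllele(c(152.1, 154.0), c(1000, 600))))
    expect_true(is.na(scoreAllele(152.1, 399)))
    expect_equal(scoreAllele(c(152.1, 154.0), c(1000, 500)), 152.1)
    # tie for the largest peak can never dominate
    expect_true(is.na(scoreAllele(c(150, 152), c(800, 800))))
    # empty peak list is a no-call, negative areas are rejected
    expect_true(is.na(scoreAllele(numeric(), numeric())))
    expect_error(scoreAllele(c(150, 152), c(500, -1)), "non-negative")
})

test_that("peak scoring is invariant under permutation of the peak list", {
    set.seed(11)
    for (rep in 1:25) {
        k <- sample(1:5, 1)
        sizes <- round(runif(k, 100, 300), 1)
        areas <- round(runif(k, 0, 3000))
        ref <- scoreAllele(sizes, areas)
        perm <- sample(k)
        expect_identical(scoreAllele(sizes[perm], areas[perm]), ref)
    }
})

test_that("scorePeakTable scores each sample x marker cell", {
    peaks <- data.frame(
        sample_id = c("s1", "s1", "s1", "s2", "s2"),
        marker = c("A", "A", "B", "A", "B"),
        size_bp = c(100, 104, 150, 104, 150),
        area = c(2000, 1100, 1200, 5000, 350))
    out <- scorePeakTable(peaks)
    expect_equal(out$A, c(NA, 104))     # 2000 < 2 x 1100 -> no-call
    expect_equal(out$B, c(150, NA))     # 350 < 400 -> no-call
})

test_that("diagnostic marker selection keeps fixed differences with good call rates", {
    pI <- data.frame(A = rep(100, 10), B = rep(150, 10),
                     C = c(rep(200, 9), 202),
                     D = c(rep(120, 7), NA, NA, NA))
    pII <- data.frame(A = rep(104, 10), B = rep(150, 10),
                      C = rep(204, 10), D = rep(124, 10))
    panel <- selectDiagnosticMarkers(pI, pII)
    # A: fixed difference; B: same allele; C: polymorphic in I; D: 70% < 80%
    expect_identical(markerNames(panel), "A")
    expect_equal(unname(diagnosticAlleles(panel)["A", ]), c(100, 104))
    # relaxing the call-rate threshold rescues D
    expect_setequal(markerNames(selectDiagnosticMarkers(pI, pII, minCallRate = 0.6)),
                    c("A", "D"))
    expect_warning(p0 <- selectDiagnosticMarkers(pI[, "B", drop = FALSE],
                                                 pII[, "B", drop = FALSE]),
                   "empty panel")
    expect_length(markerNames(p0), 0)
})

test_that("recoding maps diagnostic alleles to lineage and flags non-parental calls", {
    panel <- MarkerPanel(c("A", "B"), lineageI = c(100, 150),
                         lineageII = c(104, 148))
    raw <- data.frame(sample_id = c("s1", "s2", "s3"),
                      phenotype = c("viable", "viable", "inviable"),
                      cytotype = c("I", "II", "I"),
                      A = c(100, 104, 102), B = c(148, NA, 150))
    expect_warning(hg <- recodeToLineage(raw, panel), "neither diagnostic")
    expect_identical(unname(alleleCalls(hg)["A", ]), c("I", "II", NA))
    expect_identical(unname(alleleCalls(hg)["B", ]), c("II", NA, "I"))
    expect_error(recodeToLineage(raw[, -4], panel), "absent")
})

test_that("sample filtering uses the more-than-maxMissing exclusion boundary", {
    calls <- matrix("I", nrow = 8, ncol = 3,
                    dimnames = list(LETTERS[1:8], paste0("s", 1:3)))
    calls[1:3, 1] <- NA   # 3 missing of 8 -> excluded
    calls[1:2, 2] <- NA   # 2 missing of 8 -> retained (boundary)
    hg <- HybridGenotypes(calls, phenotype = rep("viable", 3),
                          cytotype = rep("I", 3))
    flt <- suppressMessages(filterHybridSamples(hg, maxMissing = 2))
    expect_identical(colnames(flt), c("s2", "s3"))
})

test_that("recode-then-filter equals filter-then-recode on panel-only alleles", {
    panel <- MarkerPanel(LETTERS[1:4], lineageI = 1:4 * 100,
                         lineageII = 1:4 * 100 + 4)
    set.seed(3)
    n <- 40
    raw <- data.frame(sample_id = paste0("s", 1:n),
                      phenotype = sample(c("viable", "inviable"), n, TRUE),
                      cytotype = sample(c("I", "II"), n, TRUE))
    for (i in 1:4) {
        x <- ifelse(runif(n) < 0.5, i * 100, i * 100 + 4)
        x[runif(n) < 0.2] <- NA
        raw[[LETTERS[i]]] <- x
    }
    a <- suppressMessages(filterHybridSamples(recodeToLineage(raw, panel),
                                              maxMissing = 1))
    rawKeep <- raw[rowSums(is.na(raw[LETTERS[1:4]])) <= 1, ]
    b <- recodeToLineage(rawKeep, panel)
    expect_identical(colnames(a), colnames(b))
    expect_identical(alleleCalls(a), alleleCalls(b))
})

test_that("hybrid groups partition the table with all four labels present", {
    g <- hybridGroups(toyHybrids())
    expect_named(g, c("viable.I", "viable.II", "inviable.I", "inviable.II"))
    expect_true(all(vapply(g, ncol, integer(1)) == 1L))
    # empty table -> four empty groups
    g0 <- hybridGroups(toyHybrids()[, FALSE])
    expect_true(all(vapply(g0, ncol, integer(1)) == 0L))
    # group sizes always sum to the table size
    hg <- simulateHybridData(simConfig(seed = 5))
    expect_equal(sum(vapply(hybridGroups(hg), ncol, integer(1))), ncol(hg))
    # unknown labels are rejected
    expect_error(HybridGenotypes(alleleCalls(toyHybrids()),
                                 phenotype = c("viable", "dead", "inviable", "viable"),
                                 cytotype = c("I", "II", "I", "II")))
})

test_that("marker pairs are enumerated in lexicographic order", {
    mp <- markerPairs(LETTERS[1:8])
    expect_equal(nrow(mp), 28L)
    expect_identical(mp$pair[1:3], c("AB", "AC", "AD"))
    expect_true(all(mp$markerA < mp$markerB))
    expect_error(markerPairs("A"), "at least two")
})
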