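test_that("allele indicator is the sum of the two viable-row locus residuals", {
    lr <- matrix(c(2, -2, -1, 1), nrow = 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("I", "II")))
    expect_equal(alleleIndicator(c("A", "B"), "I.I", lr), 1)    # 2 + (-1)
    expect_equal(alleleIndicator(c("A", "B"), "I.II", lr), 3)   # 2 + 1
    expect_equal(alleleIndicator(c("A", "B"), "II.I", lr), -3)
    expect_equal(alleleIndicator(c("A", "B"), "II.II", lr), -1)
    expect_equal(alleleIndicator(c("A", "B"), "I.I",
                                 matrix(0, 2, 2, dimnames = dimnames(lr))), 0)
    expect_error(alleleIndicator(c("A", "B"), "I-II", lr), "invalid haplotype")
})

test_that("the residual dataset has one record per defined haplotype cell", {
    hg <- suppressMessages(filterHybridSamples(simulateHybridData(simConfig(seed = 1))))
    g <- hybridGroups(hg)
    rec <- buildResidualDataset(g$viable.I, g$inviable.I)
    expect_equal(nrow(rec), 112L)           # 28 pairs x 4 haplotypes
    expect_equal(attr(rec, "nAttempted"), 112L)
    expect_equal(attr(rec, "nUndefined"), 0L)
    expect_identical(levels(rec$hapClass), c("parental", "recombinant"))
    # class assignment follows the haplotype
    expect_true(all((rec$haplotype %in% c("I.I", "II.II")) ==
                    (rec$hapClass == "parental")))
    # removing one haplotype from one pair loses exactly one record
    hg1 <- removeHaplotype(hg)
    g1 <- hybridGroups(hg1)
    rec1 <- suppressMessages(buildResidualDataset(g1$viable.I, g1$inviable.I))
    expect_equal(nrow(rec1), 111L)
    expect_equal(attr(rec1, "nUndefined"), 1L)
    expect_error(buildResidualDataset(g$viable.I[, FALSE], g$inviable.I),
                 "individuals")
})

test_that("swapping the viable and inviable groups negates residuals and indicators", {
    hg <- suppressMessages(filterHybridSamples(simulateHybridData(simConfig(seed = 2))))
    g <- hybridGroups(hg)
    a <- buildResidualDataset(g$viable.II, g$inviable.II)
    b <- buildResidualDataset(g$inviable.II, g$viable.II)
    expect_equal(b$residual, -a$residual, tolerance = 1e-12)
    expect_equal(b$indicator, -a$indicator, tolerance = 1e-12)
})

test_that("residual-model degrees of freedom account for estimated coefficients", {
    hg <- suppressMessages(filterHybridSamples(simulateHybridData(simConfig(seed = 1))))
    g <- hybridGroups(hg)
    rec <- buildResidualDataset(g$viable.I, g$inviable.I)
    fit <- fitResidualModel(rec)
    expect_equal(length(coef(fit)), 57L)    # 1 + 1 + 27 + 1 + 27
    expect_equal(df.residual(fit), 55L)     # 112 - 57
    omni <- interactionTest(fit)
    expect_equal(omni$df1, 27L)
    expect_equal(omni$df2, 55L)
    # one inestimable haplotype cell: 111 records, residual df 54
    g1 <- hybridGroups(removeHaplotype(hg))
    rec1 <- suppressMessages(buildResidualDataset(g1$viable.I, g1$inviable.I))
    fit1 <- fitResidualModel(rec1)
    expect_equal(df.residual(fit1), 54L)
    expect_equal(interactionTest(fit1)$df2, 54L)
})

test_that("a zero response gives zero coefficients and zero RSS", {
    rec <- expand.grid(pair = c("AB", "AC", "BC"),
                       haplotype = c("I.I", "I.II", "II.I", "II.II"))
    rec$hapClass <- ifelse(rec$haplotype %in% c("I.I", "II.II"),
                           "parental", "recombinant")
    rec$indicator <- 0
    rec$residual <- 0
    fit <- suppressWarnings(fitResidualModel(rec))
    expect_equal(unname(deviance(fit)), 0)
    expect_true(all(coef(fit)[!is.na(coef(fit))] == 0))
})

test_that("an exactly indicator-linear response yields no interaction signal", {
    set.seed(31)
    pairs <- apply(combn(LETTERS[1:5], 2), 2, paste0, collapse = "")
    rec <- expand.grid(pair = pairs,
                       haplotype = c("I.I", "I.II", "II.I", "II.II"),
                       stringsAsFactors = FALSE)
    rec$hapClass <- ifelse(rec$haplotype %in% c("I.I", "II.II"),
                           "parental", "recombinant")
    rec$indicator <- rnorm(nrow(rec))
    rec$residual <- 0.4 + 1.7 * rec$indicator
    fit <- fitResidualModel(rec)
    omni <- interactionTest(fit)
    expect_equal(omni$F, 0)
    expect_equal(omni$p.F, 1)
    ct <- pairwiseContrasts(fit)
    expect_true(all(abs(ct$estimate) < 1e-10))
})

test_that("contrasts recover constructed parental-recombinant cell differences", {
    pairs <- apply(combn(LETTERS[1:4], 2), 2, paste0, collapse = "")
    rec <- expand.grid(pair = pairs,
                       haplotype = c("I.I", "I.II", "II.I", "II.II"),
                       stringsAsFactors = FALSE)
    rec$hapClass <- ifelse(rec$haplotype %in% c("I.I", "II.II"),
                           "parental", "recombinant")
    rec$indicator <- 0
    rec$residual <- 0
    rec$residual[rec$pair == "AB" & rec$hapClass == "parental"] <- 2
    rec$residual[rec$pair == "AB" & rec$hapClass == "recombinant"] <- -2
    fit <- suppressWarnings(fitResidualModel(rec))
    ct <- pairwiseContrasts(fit, adjust = "none")
    expect_equal(ct$estimate[ct$pair == "AB"], 4)
    expect_true(all(abs(ct$estimate[ct$pair != "AB"]) < 1e-12))
    # identical parental and recombinant residuals in every pair: all 0, p = 1
    rec$residual <- rep(c(1, -1, 2, 0, 1, -2), length.out = nrow(rec))[
        order(rec$pair)]  # varies by pair only through reordering
    rec$residual <- ave(rec$residual, rec$pair)  # constant within pair
    fit0 <- suppressWarnings(fitResidualModel(rec))
    ct0 <- pairwiseContrasts(fit0, adjust = "none")
    expect_true(all(ct0$estimate == 0))
    expect_true(all(ct0$p == 1))
})

test_that("classification follows the sign-and-significance rule", {
    ct <- data.frame(pair = c("AB", "AC", "AD"),
                     estimate = c(1.2, -0.8, -2.0),
                     p = c(0.01, 0.30, 0.001),
                     p.adj = c(0.01, 0.30, 0.001))
    cls <- classifyPairs(ct, alpha = 0.05)
    expect_identical(as.character(cls$label), c("BDM", "none", "heterosis"))
    expect_equal(unname(as.integer(classificationCounts(cls))), c(1L, 1L, 1L))
    # inestimable contrast counts as 'none' so labels partition the pairs
    ct$estimate[2] <- NA; ct$p.adj[2] <- NA
    cls <- classifyPairs(ct)
    expect_identical(as.character(cls$label[2]), "none")
    expect_false(cls$estimable[2])
})

test_that("negating the viable-row residuals swaps BDM and heterosis exactly", {
    hg <- suppressMessages(filterHybridSamples(simulateHybridData(
        simConfig(seed = 7, model = viabilityModel(
            epistasis = data.frame(markerA = "C", markerB = "F",
                                   class = "recombinant", s = 0.9))))))
    g <- hybridGroups(hg)
    rec <- buildResidualDataset(g$viable.I, g$inviable.I)
    neg <- rec
    neg$residual <- -neg$residual
    neg$indicator <- -neg$indicator
    clsA <- classifyPairs(pairwiseContrasts(fitResidualModel(rec)))
    clsB <- classifyPairs(pairwiseContrasts(fitResidualModel(neg)))
    expect_equal(clsB$estimate, -clsA$estimate, tolerance = 1e-10)
    expect_equal(clsB$p, clsA$p, tolerance = 1e-10)
    swap <- c(BDM = "heterosis", none = "none", heterosis = "BDM")
    expect_identical(as.character(clsB$label),
                     unname(swap[as.character(clsA$label)]))
    # the injected pair is flagged as BDM in the original orientation
    expect_identical(as.character(clsA$label[clsA$pair == "CF"]), "BDM")
})

test_that("the cytonuclear scan flags only loci with real frequency differences", {
    # balanced locus: p = 1, not flagged
    calls <- matrix(rep(c("I", "II"), 40), nrow = 1,
                    dimnames = list("A", paste0("s", 1:80)))
    vI <- HybridGenotypes(calls[, 1:40, drop = FALSE],
                          phenotype = rep("viable", 40), cytotype = rep("I", 40))
    vII <- HybridGenotypes(calls[, 41:80, drop = FALSE],
                           phenotype = rep("viable", 40), cytotype = rep("II", 40))
    sc <- cytonuclearScan(vI, vII)
    expect_equal(sc$p, 1)
    expect_false(sc$significant)
    # one extreme locus among eight balanced ones survives Holm
    set.seed(33)
    mk <- LETTERS[1:8]
    cI <- matrix(sample(c("I", "II"), 8 * 20, TRUE), 8, 20,
                 dimnames = list(mk, paste0("a", 1:20)))
    cII <- matrix(sample(c("I", "II"), 8 * 20, TRUE), 8, 20,
                  dimnames = list(mk, paste0("b", 1:20)))
    cI["D", ] <- "I"; cII["D", ] <- "II"
    vI <- HybridGenotypes(cI, rep("viable", 20), rep("I", 20))
    vII <- HybridGenotypes(cII, rep("viable", 20), rep("II", 20))
    sc <- cytonuclearScan(vI, vII)
    expect_true(sc$significant[sc$marker == "D"])
    expect_identical(sc$direction[sc$marker == "D"], "more I in viable I")
    expect_true(sc$p.adj[sc$marker == "D"] < 0.05)
})
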