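## Replicate runners for the simulation-based validation suites.

## One no-epistasis, no-cytonuclear replicate at study-scale group sizes:
## returns the omnibus interaction p-value and whether any pair was
## labelled BDM or heterosis after Holm adjustment.
runNullReplicate <- function(seed, alpha = 0.05) {
    hg <- suppressMessages(filterHybridSamples(
        simulateHybridData(simConfig(seed = seed))))
    g <- hybridGroups(hg)
    rec <- suppressMessages(buildResidualDataset(g$viable.I, g$inviable.I))
    fit <- suppressWarnings(fitResidualModel(rec))
    cls <- classifyPairs(pairwiseContrasts(fit, adjust = "holm"),
                         alpha = alpha)
    list(p = interactionTest(fit)$p.F,
         anyLabel = any(cls$label != "none"))
}

## One replicate with a single injected two-locus penalty (s = 0.9) at the
## C-F pair; returns the label assigned to that pair and whether it carries
## the most extreme contrast in the expected direction.
runInjectionReplicate <- function(seed, class = c("recombinant", "parental")) {
    class <- match.arg(class)
    cfg <- simConfig(seed = seed, model = viabilityModel(
        epistasis = data.frame(markerA = "C", markerB = "F",
                               class = class, s = 0.9)))
    hg <- suppressMessages(filterHybridSamples(simulateHybridData(cfg)))
    g <- hybridGroups(hg)
    rec <- suppressMessages(buildResidualDataset(g$viable.I, g$inviable.I))
    fit <- suppressWarnings(fitResidualModel(rec))
    cls <- classifyPairs(pairwiseContrasts(fit, adjust = "holm"))
    i <- which(cls$pair == "CF")
    extreme <- if (class == "recombinant")
        which.max(cls$estimate) else which.min(cls$estimate)
    list(label = as.character(cls$label[i]),
         mostExtreme = length(extreme) == 1L && extreme == i,
         records = rec)
}

## One cytonuclear replicate: optionally inject an allele x cytotype
## penalty (c = 0.9: lineage-II allele at locus F is deleterious on a
## lineage-I cytoplasm) and scan viable I vs viable II.
runCytoReplicate <- function(seed, inject = FALSE, alpha = 0.05) {
    model <- if (inject)
        viabilityModel(cytonuclear = data.frame(
            marker = "F", allele = "II", cytotype = "I", c = 0.9))
    else viabilityModel()
    hg <- suppressMessages(filterHybridSamples(
        simulateHybridData(simConfig(seed = seed, model = model))))
    g <- hybridGroups(hg)
    sc <- cytonuclearScan(g$viable.I, g$viable.II, alpha = alpha)
    flagged <- as.character(sc$marker[which(sc$significant)])
    list(flagged = flagged,
         targetFlagged = "F" %in% flagged,
         anyFlagged = length(flagged) > 0L)
}
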