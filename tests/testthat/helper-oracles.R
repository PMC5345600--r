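## Independent oracles used across test files. These deliberately avoid the
## package's own code paths.

## Two-sided Fisher p by full enumeration of fixed-margin 2x2 tables: each
## table's probability from the binomial-coefficient identity, summing the
## probabilities of all tables at most as probable as the observed one.
fisherEnumOracle <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
    c1 <- sum(tab[, 1]); N <- r1 + r2
    support <- max(0, c1 - r2):min(r1, c1)
    prob <- choose(r1, support) * choose(r2, c1 - support) / choose(N, c1)
    pObs <- prob[support == tab[1, 1]]
    sum(prob[prob <= pObs * (1 + 1e-7)])
}

## Pearson chi-square statistic computed from first principles.
pearsonChisqOracle <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
}

## Adjusted residual of one cell evaluated directly from the textbook
## formula, scalar at a time.
adjResidCellOracle <- function(tab, i, j) {
    N <- sum(tab)
    ri <- sum(tab[i, ]); cj <- sum(tab[, j])
    E <- ri * cj / N
    (tab[i, j] - E) / sqrt(E * (1 - ri / N) * (1 - cj / N))
}

## Random 2 x C count table with no empty rows/columns.
randomCountTable <- function(C = 4, lambda = 8) {
    repeat {
        m <- matrix(stats::rpois(2 * C, lambda), nrow = 2)
        if (all(rowSums(m) > 0) && all(colSums(m) > 0))
            return(m)
    }
}

## Small deterministic genotype fixture: four individuals, one per hybrid
## group, plus controllable extras.
toyHybrids <- function() {
    calls <- matrix(c("I",  "I",
                      "II", "I",
                      "I",  "II",
                      "II", "II"),
                    nrow = 2,
                    dimnames = list(c("A", "B"), paste0("s", 1:4)))
    HybridGenotypes(calls,
                    phenotype = c("viable", "viable", "inviable", "inviable"),
                    cytotype = c("I", "II", "I", "II"))
}

## Drop one haplotype (II.I at the alphabetically first marker pair) from a
## simulated dataset by recoding the second locus, creating exactly one
## zero-expectation haplotype cell for that pair.
removeHaplotype <- function(hg, markerA = "A", markerB = "B") {
    calls <- alleleCalls(hg)
    hit <- !is.na(calls[markerA, ]) & !is.na(calls[markerB, ]) &
        calls[markerA, ] == "II" & calls[markerB, ] == "I"
    calls[markerB, hit] <- "II"
    HybridGenotypes(calls, phenotype = phenotype(hg), cytotype = cytotype(hg))
}
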