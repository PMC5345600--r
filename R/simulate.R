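#' Simulate recombinant haploid F2 male genotypes
#'
#' Draws the gametes of F1 hybrid females. An F1 female carries one full
#' chromosome set from each lineage, so her unfertilized (male) eggs are
#' single recombinant haploid genomes: the allele at the first marker of
#' the map follows the marker's transmission bias (probability of the
#' lineage-I allele; 0.5 = Mendelian), and each subsequent marker switches
#' lineage with its recombination fraction (0.5 = unlinked). Uses the
#' current R random-number state; callers control reproducibility with
#' `set.seed()` (or use [simulateHybridData()], which seeds itself).
#'
#' @param config a [simConfig()].
#' @param n number of genomes to draw.
#' @return Character matrix, markers x individuals, of `"I"`/`"II"` codes.
#' @examples
#' set.seed(1)
#' simulateF2Genomes(simConfig(), 3)
#' @export
simulateF2Genomes <- function(config, n) {
    mk <- config@markers
    m <- length(mk)
    bias <- rep(0.5, m)
    names(bias) <- mk
    tb <- config@model@transmissionBias
    bias[names(tb)] <- tb
    g <- matrix(NA_integer_, m, n)   # 1 = lineage I, 2 = lineage II
    g[1, ] <- ifelse(stats::runif(n) < bias[1], 1L, 2L)
    for (j in seq_len(m - 1L)) {
        r <- config@recombFractions[j]
        if (r == 0.5) {
            ## unlinked: an independent draw, which lets a per-marker
            ## transmission bias act at markers beyond the first
            g[j + 1L, ] <- ifelse(stats::runif(n) < bias[j + 1L], 1L, 2L)
        } else {
            ## linked: Markov switch; bias at a linked marker is carried
            ## only through the first marker of its linkage block
            g[j + 1L, ] <- ifelse(stats::runif(n) < r, 3L - g[j, ], g[j, ])
        }
    }
    matrix(c("I", "II")[g], m, n, dimnames = list(mk, NULL))
}

#' Viability probability of haploid genotypes
#'
#' Applies a [viabilityModel()] to lineage-coded genotypes: survival starts
#' at the baseline `v0` and is multiplied by (1 - s) for every epistatic
#' penalty whose penalized haplotype class (parental or recombinant) the
#' genotype carries at the penalty's marker pair, and by (1 - c) for every
#' cytonuclear penalty whose allele is present on the matching cytoplasmic
#' background.
#'
#' @param genotypes character matrix of `"I"`/`"II"` calls, markers x
#'   individuals (missing calls are not expected here: viability acts on
#'   the true genome, before genotyping).
#' @param cytotype a single cytotype (`"I"`/`"II"`) or one per individual.
#' @param model a [viabilityModel()].
#' @return Numeric vector of survival probabilities, one per individual.
#' @examples
#' m <- viabilityModel(v0 = 0.9, epistasis = data.frame(
#'     markerA = "A", markerB = "B", class = "recombinant", s = 1))
#' g <- matrix(c("I", "II"), 2, 1, dimnames = list(c("A", "B"), NULL))
#' viabilityProbability(g, "I", m)  # recombinant at (A,B): 0
#' @export
viabilityProbability <- function(genotypes, cytotype, model) {
    n <- ncol(genotypes)
    cytotype <- rep_len(as.character(cytotype), n)
    v <- rep(model@v0, n)
    ep <- model@epistasis
    for (i in seq_len(nrow(ep))) {
        a <- genotypes[ep$markerA[i], ]
        b <- genotypes[ep$markerB[i], ]
        isParental <- a == b
        hit <- if (ep$class[i] == "parental") isParental else !isParental
        v <- v * ifelse(hit, 1 - ep$s[i], 1)
    }
    cy <- model@cytonuclear
    for (i in seq_len(nrow(cy))) {
        hit <- genotypes[cy$marker[i], ] == cy$allele[i] &
            cytotype == cy$cytotype[i]
        v <- v * ifelse(hit, 1 - cy$c[i], 1)
    }
    unname(v)
}

#' Simulate a full reciprocal-cross hybrid genotype dataset
#'
#' Generates, for each maternal cytotype, `nF2` recombinant F2 male
#' genomes, lets each survive with its [viabilityProbability()] (survivors
#' are the viable group, the rest the inviable group), and finally injects
#' missing calls independently at `missingRate` — emulating a genotype
#' table of viable males and unhatched male eggs from two reciprocal
#' crosses. The cytotype is inherited maternally and is independent of the
#' nuclear draw. The whole procedure is driven by `set.seed(config@seed)`,
#' so a given configuration reproduces bit-for-bit.
#'
#' @param config a [simConfig()].
#' @return A [HybridGenotypes] with the seed and configuration stored in
#'   its metadata.
#' @examples
#' hg <- simulateHybridData(simConfig(seed = 42))
#' table(phenotype(hg), cytotype(hg))
#' @export
simulateHybridData <- function(config) {
    methods::validObject(config)
    set.seed(config@seed)
    parts <- lapply(c("I", "II"), function(ct) {
        n <- config@nF2[[ct]]
        g <- simulateF2Genomes(config, n)
        v <- viabilityProbability(g, ct, config@model)
        viable <- stats::runif(n) < v
        list(calls = g, phenotype = ifelse(viable, "viable", "inviable"),
             cytotype = rep(ct, n))
    })
    calls <- cbind(parts[[1]]$calls, parts[[2]]$calls)
    colnames(calls) <- sprintf("F2_%04d", seq_len(ncol(calls)))
    if (config@missingRate > 0) {
        drop <- matrix(stats::runif(length(calls)) < config@missingRate,
                       nrow(calls), ncol(calls))
        calls[drop] <- NA_character_
    }
    phen <- c(parts[[1]]$phenotype, parts[[2]]$phenotype)
    cyt <- c(parts[[1]]$cytotype, parts[[2]]$cytotype)
    emptyGroups <- setdiff(c("viable.I", "viable.II", "inviable.I", "inviable.II"),
                           unique(paste(phen, cyt, sep = ".")))
    if (length(emptyGroups))
        warning("simulated dataset has empty group(s): ",
                paste(emptyGroups, collapse = ", "))
    HybridGenotypes(calls, phenotype = phen, cytotype = cyt,
                    metadata = list(seed = config@seed, config = config))
}
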