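#' Container for haploid hybrid genotypes
#'
#' `HybridGenotypes` extends [SummarizedExperiment::SummarizedExperiment] to
#' hold lineage-coded allele calls of haploid individuals. The single assay,
#' `"calls"`, is a character matrix with diagnostic markers as rows and
#' individuals as columns; every entry is `"I"`, `"II"` or `NA` (missing
#' call). Per-individual phenotype (`"viable"`/`"inviable"`) and maternally
#' inherited cytotype (`"I"`/`"II"`) live in the `colData`.
#'
#' @param calls character matrix of `"I"`/`"II"`/`NA` calls, markers in rows,
#'   individuals in columns. Row and column names are required.
#' @param phenotype character or factor, one of `"viable"`/`"inviable"` per
#'   individual.
#' @param cytotype character or factor, one of `"I"`/`"II"` per individual.
#' @param metadata optional list stored in the object metadata.
#'
#' @return A `HybridGenotypes` object.
#' @examples
#' calls <- matrix(c("I", "II", "I", "I"), nrow = 2,
#'                 dimnames = list(c("A", "B"), c("s1", "s2")))
#' hg <- HybridGenotypes(calls, phenotype = c("viable", "inviable"),
#'                       cytotype = c("I", "I"))
#' phenotype(hg)
#' @aliases HybridGenotypes-class
#' @export
HybridGenotypes <- function(calls, phenotype, cytotype, metadata = list()) {
    calls <- as.matrix(calls)
    if (!is.character(calls))
        mode(calls) <- "character"
    if (is.null(rownames(calls)))
        stop("'calls' must have marker names as rownames")
    if (is.null(colnames(calls)))
        colnames(calls) <- paste0("sample", seq_len(ncol(calls)))
    phenotype <- factor(as.character(phenotype), levels = c("viable", "inviable"))
    cytotype <- factor(as.character(cytotype), levels = c("I", "II"))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(calls = calls),
        colData = S4Vectors::DataFrame(phenotype = phenotype,
                                       cytotype = cytotype,
                                       row.names = colnames(calls)),
        metadata = metadata)
    methods::new("HybridGenotypes", se)
}

#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("HybridGenotypes", contains = "SummarizedExperiment")

setValidity("HybridGenotypes", function(object) {
    msg <- character()
    if (!"calls" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'calls' is required")
    else {
        calls <- SummarizedExperiment::assay(object, "calls")
        bad <- !is.na(calls) & !(calls %in% c("I", "II"))
        if (any(bad))
            msg <- c(msg, "allele calls must be 'I', 'II' or NA")
    }
    cd <- SummarizedExperiment::colData(object)
    for (fld in c("phenotype", "cytotype")) {
        if (!fld %in% colnames(cd)) {
            msg <- c(msg, sprintf("colData column '%s' is required", fld))
            next
        }
        v <- cd[[fld]]
        lv <- if (fld == "phenotype") c("viable", "inviable") else c("I", "II")
        if (!all(as.character(v[!is.na(v)]) %in% lv))
            msg <- c(msg, sprintf("'%s' must be one of %s",
                                  fld, paste(lv, collapse = "/")))
        if (anyNA(v))
            msg <- c(msg, sprintf("'%s' must not contain NA", fld))
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "marker names must be unique")
    if (length(msg)) msg else TRUE
})

#' Panel of diagnostic markers
#'
#' A diagnostic marker is fixed for different alleles in the two parental
#' populations, so that the lineage of origin of any hybrid allele is
#' unambiguous. `MarkerPanel` records, for each marker, the allele (fragment
#' size) fixed in lineage I and the one fixed in lineage II. Marker order is
#' lexicographic and fixed once constructed, so marker-pair labels derived
#' from it are deterministic.
#'
#' @param markers character vector of marker names.
#' @param lineageI,lineageII numeric vectors of the allele sizes fixed in
#'   each parental lineage, parallel to `markers`.
#' @return A `MarkerPanel` object.
#' @examples
#' MarkerPanel(c("A", "B"), lineageI = c(100, 150), lineageII = c(104, 148))
#' @aliases MarkerPanel-class
#' @export
MarkerPanel <- function(markers, lineageI, lineageII) {
    ord <- order(as.character(markers))
    methods::new("MarkerPanel",
                 markers = as.character(markers)[ord],
                 lineageI = stats::setNames(as.numeric(lineageI)[ord],
                                            as.character(markers)[ord]),
                 lineageII = stats::setNames(as.numeric(lineageII)[ord],
                                             as.character(markers)[ord]))
}

setClass("MarkerPanel",
         representation(markers = "character",
                        lineageI = "numeric",
                        lineageII = "numeric"))

setValidity("MarkerPanel", function(object) {
    msg <- character()
    n <- length(object@markers)
    if (length(object@lineageI) != n || length(object@lineageII) != n)
        msg <- c(msg, "diagnostic allele vectors must match the marker list")
    if (anyDuplicated(object@markers))
        msg <- c(msg, "marker names must be unique")
    if (n > 0 && any(object@lineageI == object@lineageII, na.rm = TRUE))
        msg <- c(msg, "the two diagnostic alleles of a marker must differ")
    if (length(msg)) msg else TRUE
})

#' Two-locus haplotype count table
#'
#' For a pair of biallelic markers there are four possible allele
#' combinations ("haplotypes"): I.I, I.II, II.I and II.II, where the first
#' symbol is the allele at the alphabetically first marker of the pair.
#' I.I and II.II are parental haplotypes; I.II and II.I are recombinant.
#' A `HaplotypeCountTable` tallies, for two hybrid groups, how many
#' individuals carry each haplotype, using only individuals with non-missing
#' calls at both loci (pairwise-complete deletion).
#'
#' @slot pair character(2), the two marker names in alphabetical order.
#' @slot counts 2 x 4 integer matrix, groups in rows, haplotypes
#'   (I.I, I.II, II.I, II.II) in columns.
#' @aliases HaplotypeCountTable-class
#' @export
setClass("HaplotypeCountTable",
         representation(pair = "character", counts = "matrix"))

setValidity("HaplotypeCountTable", function(object) {
    msg <- character()
    if (length(object@pair) != 2L || object@pair[1] == object@pair[2])
        msg <- c(msg, "'pair' must name two distinct markers")
    cn <- colnames(object@counts)
    if (!identical(cn, c("I.I", "I.II", "II.I", "II.II")))
        msg <- c(msg, "columns must be I.I, I.II, II.I, II.II in that order")
    if (nrow(object@counts) != 2L)
        msg <- c(msg, "exactly two group rows are required")
    if (any(object@counts < 0) || any(object@counts != round(object@counts)))
        msg <- c(msg, "counts must be non-negative integers")
    if (length(msg)) msg else TRUE
})

#' Viability model for the haplodiploid F2 simulator
#'
#' Describes how genotype and cytotype determine the survival probability of
#' a recombinant F2 male. Survival is multiplicative: a baseline viability
#' `v0` is reduced by a factor (1 - s) for every two-locus epistatic penalty
#' whose penalized haplotype class the genotype carries, and by (1 - c) for
#' every cytonuclear penalty whose allele/cytotype combination matches.
#' Transmission bias sets the per-marker probability that an F1 mother
#' transmits her lineage-I allele (0.5 = Mendelian segregation).
#'
#' @param v0 baseline viability probability in (0, 1].
#' @param epistasis `NULL` or data.frame with columns `markerA`, `markerB`,
#'   `class` (`"recombinant"` for a BDM-type penalty, `"parental"` for a
#'   heterosis-type penalty) and `s` (selection coefficient in `[0, 1]`).
#' @param cytonuclear `NULL` or data.frame with columns `marker`, `allele`
#'   (`"I"`/`"II"`), `cytotype` (`"I"`/`"II"`) and `c` (penalty in `[0, 1]`).
#' @param transmissionBias `NULL` (0.5 everywhere) or a named numeric vector
#'   of lineage-I transmission probabilities per marker.
#' @return A `ViabilityModel` object.
#' @examples
#' viabilityModel(v0 = 0.41,
#'                epistasis = data.frame(markerA = "A", markerB = "B",
#'                                       class = "recombinant", s = 0.9))
#' @aliases ViabilityModel-class
#' @export
viabilityModel <- function(v0 = 0.41, epistasis = NULL, cytonuclear = NULL,
                           transmissionBias = NULL) {
    if (is.null(epistasis))
        epistasis <- data.frame(markerA = character(), markerB = character(),
                                class = character(), s = numeric())
    if (is.null(cytonuclear))
        cytonuclear <- data.frame(marker = character(), allele = character(),
                                  cytotype = character(), c = numeric())
    if (is.null(transmissionBias))
        transmissionBias <- numeric()
    methods::new("ViabilityModel", v0 = v0,
                 epistasis = as.data.frame(epistasis),
                 cytonuclear = as.data.frame(cytonuclear),
                 transmissionBias = transmissionBias)
}

setClass("ViabilityModel",
         representation(v0 = "numeric", epistasis = "data.frame",
                        cytonuclear = "data.frame",
                        transmissionBias = "numeric"))

setValidity("ViabilityModel", function(object) {
    msg <- character()
    if (length(object@v0) != 1L || object@v0 < 0 || object@v0 > 1)
        msg <- c(msg, "'v0' must be a probability")
    ep <- object@epistasis
    if (!all(c("markerA", "markerB", "class", "s") %in% colnames(ep)))
        msg <- c(msg, "epistasis needs columns markerA, markerB, class, s")
    else {
        if (nrow(ep) && !all(ep$class %in% c("recombinant", "parental")))
            msg <- c(msg, "epistasis class must be 'recombinant' or 'parental'")
        if (nrow(ep) && (any(ep$s < 0) || any(ep$s > 1)))
            msg <- c(msg, "selection coefficients must lie in [0, 1]")
        if (nrow(ep) && any(ep$markerA == ep$markerB))
            msg <- c(msg, "an epistatic pair must involve two distinct markers")
    }
    cy <- object@cytonuclear
    if (!all(c("marker", "allele", "cytotype", "c") %in% colnames(cy)))
        msg <- c(msg, "cytonuclear needs columns marker, allele, cytotype, c")
    else if (nrow(cy) && (any(cy$c < 0) || any(cy$c > 1)))
        msg <- c(msg, "cytonuclear penalties must lie in [0, 1]")
    tb <- object@transmissionBias
    if (length(tb) && (any(tb < 0) || any(tb > 1)))
        msg <- c(msg, "transmission bias must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Configuration of a simulated reciprocal-cross experiment
#'
#' Defines the marker map, per-cytotype F2 sample sizes, viability model,
#' missing-call rate and seed for [simulateHybridData()]. Defaults emulate a
#' study design with 8 unlinked diagnostic markers and the pre-filtering
#' totals of 226 (cytotype I) and 228 (cytotype II) F2 males per reciprocal
#' cross, a baseline viability of 0.41 and a 9% missing-call rate.
#'
#' @param markers character vector of marker names (sorted internally).
#' @param recombFractions numeric vector of recombination fractions between
#'   adjacent markers in map order, length `length(markers) - 1`; 0.5 means
#'   unlinked (the default).
#' @param nF2 named integer vector `c(I = ..., II = ...)`: number of F2 male
#'   eggs drawn per maternal cytotype.
#' @param model a [viabilityModel()].
#' @param missingRate probability that any single call is missing.
#' @param seed integer seed used by [simulateHybridData()].
#' @return A `SimConfig` object.
#' @examples
#' simConfig(seed = 7)
#' @aliases SimConfig-class
#' @export
simConfig <- function(markers = LETTERS[1:8],
                      recombFractions = rep(0.5, length(markers) - 1L),
                      nF2 = c(I = 226L, II = 228L),
                      model = viabilityModel(),
                      missingRate = 0.09,
                      seed = 1L) {
    markers <- sort(as.character(markers))
    methods::new("SimConfig", markers = markers,
                 recombFractions = as.numeric(recombFractions),
                 nF2 = stats::setNames(as.integer(nF2), names(nF2)),
                 model = model, missingRate = missingRate,
                 seed = as.integer(seed))
}

setClass("SimConfig",
         representation(markers = "character", recombFractions = "numeric",
                        nF2 = "integer", model = "ViabilityModel",
                        missingRate = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (length(object@markers) < 2L)
        msg <- c(msg, "at least two markers are required")
    if (length(object@recombFractions) != length(object@markers) - 1L)
        msg <- c(msg, "need one recombination fraction per adjacent marker pair")
    if (any(object@recombFractions < 0) || any(object@recombFractions > 0.5))
        msg <- c(msg, "recombination fractions must lie in [0, 0.5]")
    if (!identical(sort(names(object@nF2)), c("I", "II")))
        msg <- c(msg, "'nF2' must be named c(I = , II = )")
    if (any(object@nF2 <= 0L))
        msg <- c(msg, "'nF2' must be positive")
    if (object@missingRate < 0 || object@missingRate >= 1)
        msg <- c(msg, "'missingRate' must lie in [0, 1)")
    ep <- object@model@epistasis
    cy <- object@model@cytonuclear
    refd <- c(ep$markerA, ep$markerB, cy$marker,
              names(object@model@transmissionBias))
    if (!all(refd %in% object@markers))
        msg <- c(msg, "viability model references markers absent from the map")
    if (length(msg)) msg else TRUE
})
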