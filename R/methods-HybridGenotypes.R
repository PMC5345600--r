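#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn HybridGenotypes phenotype factor (`viable`/`inviable`) per
#'   individual.
#' @param x a `HybridGenotypes` object.
#' @export
setMethod("phenotype", "HybridGenotypes", function(x, ...)
    SummarizedExperiment::colData(x)$phenotype)

#' @describeIn HybridGenotypes cytotype factor (`I`/`II`) per individual.
#' @export
setMethod("cytotype", "HybridGenotypes", function(x, ...)
    SummarizedExperiment::colData(x)$cytotype)

#' @describeIn HybridGenotypes the markers x individuals call matrix.
#' @export
setMethod("alleleCalls", "HybridGenotypes", function(x, ...)
    SummarizedExperiment::assay(x, "calls"))

#' @describeIn HybridGenotypes marker names (rownames).
#' @export
setMethod("markerNames", "HybridGenotypes", function(x, ...) rownames(x))

#' @describeIn MarkerPanel marker names of the panel.
#' @param x a `MarkerPanel`.
#' @export
setMethod("markerNames", "MarkerPanel", function(x, ...) x@markers)

#' @describeIn MarkerPanel two-column matrix of diagnostic allele sizes,
#'   markers in rows, lineages in columns.
#' @export
setMethod("diagnosticAlleles", "MarkerPanel", function(x, ...) {
    cbind(I = x@lineageI, II = x@lineageII)
})

setMethod("show", "MarkerPanel", function(object) {
    cat(sprintf("MarkerPanel with %d diagnostic marker(s)\n",
                length(object@markers)))
    if (length(object@markers))
        print(diagnosticAlleles(object))
})

setMethod("show", "HaplotypeCountTable", function(object) {
    cat(sprintf("HaplotypeCountTable for marker pair %s-%s\n",
                object@pair[1], object@pair[2]))
    print(object@counts)
})

setMethod("show", "ViabilityModel", function(object) {
    cat(sprintf("ViabilityModel: v0 = %g, %d epistatic penalt%s, %d cytonuclear penalt%s\n",
                object@v0, nrow(object@epistasis),
                if (nrow(object@epistasis) == 1) "y" else "ies",
                nrow(object@cytonuclear),
                if (nrow(object@cytonuclear) == 1) "y" else "ies"))
    biased <- object@transmissionBias[object@transmissionBias != 0.5]
    if (length(biased))
        cat("  transmission bias at:", paste(names(biased), collapse = ", "), "\n")
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf("SimConfig: %d markers, nF2 = (I: %d, II: %d), missing rate %.2f, seed %d\n",
                length(object@markers), object@nF2[["I"]], object@nF2[["II"]],
                object@missingRate, object@seed))
})

#' Split a genotype table into the four hybrid groups
#'
#' Partitions individuals by phenotype and cytotype into the four hybrid
#' groups used throughout the analysis: viable I, viable II, inviable I and
#' inviable II. All four groups are always present in the output, possibly
#' with zero individuals.
#'
#' @param x a [HybridGenotypes] object.
#' @return Named list of four `HybridGenotypes` objects, names
#'   `"viable.I"`, `"viable.II"`, `"inviable.I"`, `"inviable.II"`.
#' @examples
#' hg <- simulateHybridData(simConfig(seed = 1))
#' vapply(hybridGroups(hg), ncol, integer(1))
#' @export
setMethod("hybridGroups", "HybridGenotypes", function(x, ...) {
    ph <- phenotype(x)
    cy <- cytotype(x)
    if (anyNA(ph) || anyNA(cy))
        stop("phenotype and cytotype must be known for every individual")
    grps <- list()
    for (p in c("viable", "inviable"))
        for (ct in c("I", "II"))
            grps[[paste(p, ct, sep = ".")]] <- x[, ph == p & cy == ct]
    grps
})

#' Exclude individuals with too many missing calls
#'
#' Individuals with missing calls at more than `maxMissing` markers are
#' removed; with the 8-marker default panel and `maxMissing = 2` this is the
#' "no allele scored at more than two of eight markers" exclusion rule.
#' Per-group retained counts are reported as a message.
#'
#' @param x a [HybridGenotypes] object.
#' @param maxMissing maximum number of missing calls an individual may have
#'   and still be retained (default 2).
#' @return The filtered `HybridGenotypes`; the numbers retained per hybrid
#'   group are stored in `metadata(x)$retained`.
#' @examples
#' hg <- simulateHybridData(simConfig(seed = 1))
#' ncol(filterHybridSamples(hg))
#' @export
setMethod("filterHybridSamples", "HybridGenotypes",
          function(x, maxMissing = 2, ...) {
    nmiss <- colSums(is.na(alleleCalls(x)))
    keep <- nmiss <= maxMissing
    out <- x[, keep]
    grp <- paste(phenotype(out), cytotype(out), sep = ".")
    lv <- c("viable.I", "viable.II", "inviable.I", "inviable.II")
    retained <- table(factor(grp, levels = lv))
    S4Vectors::metadata(out)$retained <- retained
    message(sprintf("retained %d/%d individuals (max %d missing calls): %s",
                    sum(keep), length(keep), maxMissing,
                    paste(lv, as.integer(retained), sep = "=", collapse = ", ")))
    out
})

setMethod("show", "HybridGenotypes", function(object) {
    cat(sprintf("HybridGenotypes: %d markers x %d individuals\n",
                nrow(object), ncol(object)))
    tab <- table(phenotype(object), cytotype(object))
    if (ncol(object)) {
        cat("  groups:\n")
        print(tab)
        cat(sprintf("  missing calls: %.1f%%\n",
                    100 * mean(is.na(alleleCalls(object)))))
    }
})
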