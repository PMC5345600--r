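#' Score a haploid allele from fragment-analysis peaks
#'
#' Capillary electrophoresis of a microsatellite PCR product from a haploid
#' individual should show one peak, but stutter and other PCR artefacts can
#' add more. The scoring rule: call the fragment size of the largest-area
#' peak, but only if its area is at least `dominanceRatio` times the area of
#' every other peak at the locus and at least `noiseCutoff` fluorescence
#' units; otherwise no allele is scored. Two peaks tied for the maximum area
#' can never dominate each other, so a tie yields a no-call.
#'
#' @param sizes numeric vector of fragment sizes (bp).
#' @param areas numeric vector of peak areas (fluorescence units), parallel
#'   to `sizes`; must be non-negative.
#' @param noiseCutoff background-noise cutoff; a candidate peak below this
#'   area is never called (default 400 units).
#' @param dominanceRatio how many times larger than every other peak the
#'   called peak must be (default 2).
#' @return The called allele size, or `NA_real_` for a no-call.
#' @examples
#' scoreAllele(c(152.1, 154.0), c(1000, 500))  # exactly double: called
#' scoreAllele(c(152.1, 154.0), c(1000, 600))  # ambiguous: no-call
#' scoreAllele(152.1, 399)                     # below noise cutoff: no-call
#' @export
scoreAllele <- function(sizes, areas, noiseCutoff = 400, dominanceRatio = 2) {
    stopifnot(length(sizes) == length(areas),
              noiseCutoff > 0, dominanceRatio >= 1)
    if (length(areas) == 0L)
        return(NA_real_)
    if (any(areas < 0))
        stop("peak areas must be non-negative")
    top <- which.max(areas)
    a <- areas[top]
    if (a < noiseCutoff)
        return(NA_real_)
    others <- areas[-top]
    if (length(others) && a < dominanceRatio * max(others))
        return(NA_real_)
    sizes[top]
}

#' Score every sample x marker cell of a peak table
#'
#' Applies [scoreAllele()] to each (sample, marker) group of a long-format
#' peak table and returns a wide table of raw allele sizes, ready for
#' [recodeToLineage()].
#'
#' @param peaks data.frame with columns `sample_id`, `marker`, `size_bp`,
#'   `area` (one row per peak), as read by [readPeakTable()].
#' @inheritParams scoreAllele
#' @return data.frame with one row per sample (`sample_id` column) and one
#'   numeric column per marker holding the called size or `NA`.
#' @export
scorePeakTable <- function(peaks, noiseCutoff = 400, dominanceRatio = 2) {
    need <- c("sample_id", "marker", "size_bp", "area")
    if (!all(need %in% colnames(peaks)))
        stop("peak table needs columns ", paste(need, collapse = ", "))
    samples <- unique(as.character(peaks$sample_id))
    markers <- sort(unique(as.character(peaks$marker)))
    out <- matrix(NA_real_, length(samples), length(markers),
                  dimnames = list(samples, markers))
    key <- split(seq_len(nrow(peaks)),
                 list(factor(as.character(peaks$sample_id), samples),
                      factor(as.character(peaks$marker), markers)),
                 drop = TRUE)
    for (k in names(key)) {
        idx <- key[[k]]
        out[as.character(peaks$sample_id[idx[1]]),
            as.character(peaks$marker[idx[1]])] <-
            scoreAllele(peaks$size_bp[idx], peaks$area[idx],
                        noiseCutoff, dominanceRatio)
    }
    data.frame(sample_id = samples, out, check.names = FALSE,
               row.names = NULL)
}

#' Select diagnostic markers from parental-population genotypes
#'
#' Screens candidate markers genotyped in both parental populations and
#' keeps those that are diagnostic: each population is fixed for a single
#' allele, the two alleles differ, and amplification is consistent (call
#' rate at least `minCallRate` in both populations).
#'
#' @param parentalI,parentalII data.frames of raw allele sizes for the two
#'   parental populations: one row per individual, one numeric column per
#'   candidate marker (a `sample_id` column, if present, is ignored).
#'   Missing calls are `NA`.
#' @param minCallRate minimum fraction of non-missing calls required in each
#'   population (default 0.8).
#' @return A [MarkerPanel] of the retained markers (lexicographic order).
#'   If no marker passes, an empty panel is returned with a warning.
#' @examples
#' pI <- data.frame(A = c(100, 100), B = c(150, 150))
#' pII <- data.frame(A = c(104, 104), B = c(150, 150))
#' markerNames(selectDiagnosticMarkers(pI, pII))  # only A is diagnostic
#' @export
selectDiagnosticMarkers <- function(parentalI, parentalII, minCallRate = 0.8) {
    dropId <- function(d) d[, setdiff(colnames(d), "sample_id"), drop = FALSE]
    pI <- dropId(as.data.frame(parentalI))
    pII <- dropId(as.data.frame(parentalII))
    if (nrow(pI) == 0L || nrow(pII) == 0L)
        stop("both parental tables must contain individuals")
    cand <- intersect(colnames(pI), colnames(pII))
    if (length(cand) == 0L)
        stop("the parental tables share no candidate markers")
    keep <- character(); aI <- numeric(); aII <- numeric()
    for (m in cand) {
        xI <- pI[[m]]; xII <- pII[[m]]
        uI <- unique(xI[!is.na(xI)]); uII <- unique(xII[!is.na(xII)])
        fixedDiff <- length(uI) == 1L && length(uII) == 1L && uI != uII
        amplified <- mean(!is.na(xI)) >= minCallRate &&
            mean(!is.na(xII)) >= minCallRate
        if (fixedDiff && amplified) {
            keep <- c(keep, m); aI <- c(aI, uI); aII <- c(aII, uII)
        }
    }
    if (length(keep) == 0L) {
        warning("no candidate marker is diagnostic; returning an empty panel")
        return(MarkerPanel(character(), numeric(), numeric()))
    }
    MarkerPanel(keep, aI, aII)
}

#' Recode raw allele sizes to lineage of origin
#'
#' Maps each raw allele call to `"I"` or `"II"` by matching the diagnostic
#' alleles of the panel. A call matching neither diagnostic allele (a
#' non-parental allele) is treated as missing and reported with a warning.
#'
#' @param raw data.frame with columns `sample_id`, `phenotype`, `cytotype`
#'   and one numeric column of raw sizes per panel marker.
#' @param panel a [MarkerPanel]; every panel marker must be a column of
#'   `raw`.
#' @return A [HybridGenotypes] object with markers in panel order.
#' @export
recodeToLineage <- function(raw, panel) {
    raw <- as.data.frame(raw)
    mk <- markerNames(panel)
    if (length(mk) == 0L)
        stop("the marker panel is empty")
    if (!all(mk %in% colnames(raw)))
        stop("markers absent from the genotype table: ",
             paste(setdiff(mk, colnames(raw)), collapse = ", "))
    da <- diagnosticAlleles(panel)
    calls <- matrix(NA_character_, length(mk), nrow(raw),
                    dimnames = list(mk, as.character(raw$sample_id)))
    nonparental <- 0L
    for (m in mk) {
        x <- as.numeric(raw[[m]])
        cl <- ifelse(is.na(x), NA_character_,
              ifelse(x == da[m, "I"], "I",
              ifelse(x == da[m, "II"], "II", "nonparental")))
        bad <- !is.na(cl) & cl == "nonparental"
        nonparental <- nonparental + sum(bad)
        cl[bad] <- NA_character_
        calls[m, ] <- cl
    }
    if (nonparental > 0L)
        warning(sprintf("%d call(s) matched neither diagnostic allele; treated as missing",
                        nonparental))
    HybridGenotypes(calls, phenotype = raw$phenotype, cytotype = raw$cytotype)
}

#' Enumerate the marker pairs of a panel
#'
#' All unordered pairs of distinct markers, in lexicographic order; the
#' pair label concatenates the two names (e.g. `"AB"`) when both are single
#' characters and joins them with `":"` otherwise. 8 markers give 28 pairs.
#'
#' @param markers character vector of marker names, a [MarkerPanel], or a
#'   [HybridGenotypes].
#' @return data.frame with columns `pair`, `markerA`, `markerB`.
#' @examples
#' nrow(markerPairs(LETTERS[1:8]))  # 28
#' @export
markerPairs <- function(markers) {
    if (methods::is(markers, "MarkerPanel") ||
        methods::is(markers, "HybridGenotypes"))
        markers <- markerNames(markers)
    markers <- sort(as.character(markers))
    if (length(markers) < 2L)
        stop("at least two markers are required to form pairs")
    idx <- utils::combn(length(markers), 2L)
    a <- markers[idx[1, ]]; b <- markers[idx[2, ]]
    lab <- if (all(nchar(markers) == 1L)) paste0(a, b) else paste(a, b, sep = ":")
    data.frame(pair = lab, markerA = a, markerB = b)
}
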