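#' Run the full hybrid-incompatibility analysis
#'
#' End-to-end orchestration: read or simulate a genotype table, exclude
#' individuals with too many missing calls, assemble the four hybrid
#' groups, then run the configured comparisons. The cytonuclear comparison
#' (`"viableI-viableII"`) runs the per-locus Fisher scan; the two nuclear
#' comparisons (`"viableI-inviableI"`, `"viableII-inviableII"`) each run
#' the generalized CMH test across all marker-pair strata, the residual
#' regression with its interaction test, the per-pair post-hoc contrasts
#' and the BDM/heterosis classification. CMH p-values are additionally
#' Holm-adjusted across the nuclear comparisons run. An empty group makes
#' the affected comparison report `status = "skipped"` while the run
#' continues.
#'
#' @param x a [HybridGenotypes], a path to a genotype CSV
#'   ([readGenotypeTable()]), or a [simConfig()] (the table is simulated).
#' @param comparisons subset of `"viableI-inviableI"`,
#'   `"viableII-inviableII"`, `"viableI-viableII"` (default: all three).
#' @param alpha significance level (default 0.05).
#' @param adjust post-hoc contrast adjustment, `"holm"` or `"none"`.
#' @param maxMissing missing-call filter threshold (default 2).
#' @param outDir if non-`NULL`, the report is written there with
#'   [writeReport()].
#' @return A list of class `"bdmReport"`: `comparisons` (one entry each),
#'   `groupSizes`, `provenance`.
#' @examples
#' rep <- runFullAnalysis(simConfig(seed = 3),
#'                        comparisons = "viableI-inviableI")
#' rep$comparisons[["viableI-inviableI"]]$counts
#' @export
runFullAnalysis <- function(x,
                            comparisons = c("viableI-inviableI",
                                            "viableII-inviableII",
                                            "viableI-viableII"),
                            alpha = 0.05, adjust = c("holm", "none"),
                            maxMissing = 2, outDir = NULL) {
    adjust <- match.arg(adjust)
    comparisons <- match.arg(comparisons, several.ok = TRUE)
    seed <- NA_integer_
    if (methods::is(x, "SimConfig")) {
        seed <- x@seed
        x <- simulateHybridData(x)
    } else if (is.character(x)) {
        x <- readGenotypeTable(x)
        if (!methods::is(x, "HybridGenotypes"))
            stop("the genotype table must be lineage-coded (I/II)")
    }
    if (!is.na(S4Vectors::metadata(x)$seed %||% NA))
        seed <- S4Vectors::metadata(x)$seed
    flt <- filterHybridSamples(x, maxMissing = maxMissing)
    grp <- hybridGroups(flt)
    sizes <- vapply(grp, ncol, integer(1))
    groupsOf <- list(
        "viableI-inviableI" = c("viable.I", "inviable.I"),
        "viableII-inviableII" = c("viable.II", "inviable.II"),
        "viableI-viableII" = c("viable.I", "viable.II"))
    out <- list()
    for (cmp in comparisons) {
        gs <- groupsOf[[cmp]]
        if (any(sizes[gs] == 0L)) {
            message("comparison ", cmp, " skipped: empty group")
            out[[cmp]] <- list(status = "skipped",
                               reason = "empty group after filtering")
            next
        }
        a <- grp[[gs[1]]]; b <- grp[[gs[2]]]
        if (cmp == "viableI-viableII") {
            out[[cmp]] <- list(status = "ok", type = "cytonuclear",
                               scan = cytonuclearScan(a, b, alpha = alpha))
        } else {
            pairs <- markerPairs(flt)
            strata <- lapply(seq_len(nrow(pairs)), function(i)
                haplotypeCounts(a, b, c(pairs$markerA[i], pairs$markerB[i]),
                                labels = c("viable", "inviable")))
            names(strata) <- pairs$pair
            cmh <- generalizedCMH(strata)
            records <- buildResidualDataset(a, b)
            fit <- fitResidualModel(records)
            omni <- interactionTest(fit)
            cls <- classifyPairs(pairwiseContrasts(fit, adjust = adjust),
                                 alpha = alpha)
            out[[cmp]] <- list(status = "ok", type = "nuclear",
                               cmh = cmh, records = records, fit = fit,
                               interaction = omni, pairs = cls,
                               counts = classificationCounts(cls),
                               nAttempted = attr(records, "nAttempted"),
                               nUndefined = attr(records, "nUndefined"))
        }
    }
    nuclear <- names(out)[vapply(out, function(z)
        identical(z$type, "nuclear"), logical(1))]
    if (length(nuclear)) {
        adj <- sequentialBonferroni(
            vapply(nuclear, function(cmp) out[[cmp]]$cmh$p.value, numeric(1)),
            alpha = alpha)
        for (i in seq_along(nuclear))
            out[[nuclear[i]]]$cmh.p.adj <- adj$p.adj[i]
    }
    report <- structure(
        list(comparisons = out, groupSizes = sizes,
             provenance = list(
                 package = "hapBDM",
                 version = as.character(utils::packageVersion("hapBDM")),
                 seed = seed, alpha = alpha, adjust = adjust,
                 maxMissing = maxMissing,
                 nSamplesInput = ncol(x), nSamplesRetained = ncol(flt))),
        class = "bdmReport")
    if (!is.null(outDir))
        writeReport(report, outDir)
    report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bdmReport <- function(x, ...) {
    cat("hapBDM analysis report\n")
    cat("  group sizes:",
        paste(names(x$groupSizes), x$groupSizes, sep = "=", collapse = ", "),
        "\n")
    for (nm in names(x$comparisons)) {
        z <- x$comparisons[[nm]]
        cat(sprintf("  %s [%s]\n", nm, z$status))
        if (z$status != "ok")
            next
        if (identical(z$type, "nuclear")) {
            cat(sprintf("    CMH: M2 = %.2f, df = %d, P = %.3g\n",
                        z$cmh$statistic, z$cmh$parameter, z$cmh$p.value))
            cat(sprintf("    interaction: F(%d, %d) = %.2f, P = %.3g\n",
                        z$interaction$df1, z$interaction$df2,
                        z$interaction$F, z$interaction$p.F))
            cat("    pairs:",
                paste(names(z$counts), as.integer(z$counts),
                      sep = "=", collapse = ", "), "\n")
        } else {
            sig <- z$scan$marker[which(z$scan$significant)]
            cat(sprintf("    cytonuclear scan: %d of %d loci significant%s\n",
                        length(sig), nrow(z$scan),
                        if (length(sig)) paste0(" (",
                            paste(sig, collapse = ", "), ")") else ""))
        }
    }
    invisible(x)
}

#' Write an analysis report to disk
#'
#' Serializes a [runFullAnalysis()] report to `report.json` plus flat CSVs:
#' `pairs.csv` (per-pair contrast, p-values, label per nuclear comparison),
#' `residuals.csv` (the residual datasets: indicator vs haplotype residual,
#' the content of a per-pair scatter plot) and `cytonuclear.csv` (per-locus
#' scan). Output contains no timestamps, so identical inputs and seed give
#' byte-identical files.
#'
#' @param report a `"bdmReport"`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pairsTab <- list(); residTab <- list(); cytoTab <- NULL
    json <- list(provenance = report$provenance,
                 groupSizes = as.list(report$groupSizes),
                 comparisons = list())
    for (nm in names(report$comparisons)) {
        z <- report$comparisons[[nm]]
        if (z$status != "ok") {
            json$comparisons[[nm]] <- list(status = z$status,
                                           reason = z$reason)
            next
        }
        if (identical(z$type, "nuclear")) {
            cls <- z$pairs
            cls$comparison <- nm
            pairsTab[[nm]] <- cls
            rec <- z$records
            rec$comparison <- nm
            residTab[[nm]] <- rec
            json$comparisons[[nm]] <- list(
                status = "ok", type = "nuclear",
                cmh = list(M2 = unname(z$cmh$statistic),
                           df = unname(z$cmh$parameter),
                           p = z$cmh$p.value, p.adj = z$cmh.p.adj),
                interaction = unclass(z$interaction),
                counts = as.list(z$counts),
                residualCells = list(attempted = z$nAttempted,
                                     undefined = z$nUndefined),
                pairs = cls[, c("pair", "estimate", "p", "p.adj", "label")])
        } else {
            cytoTab <- z$scan
            json$comparisons[[nm]] <- list(status = "ok",
                                           type = "cytonuclear",
                                           scan = z$scan)
        }
    }
    jsonlite::write_json(json, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null", force = TRUE)
    if (length(pairsTab))
        utils::write.csv(do.call(rbind, pairsTab),
                         file.path(dir, "pairs.csv"), row.names = FALSE)
    if (length(residTab))
        utils::write.csv(do.call(rbind, residTab),
                         file.path(dir, "residuals.csv"), row.names = FALSE)
    if (!is.null(cytoTab))
        utils::write.csv(cytoTab, file.path(dir, "cytonuclear.csv"),
                         row.names = FALSE)
    invisible(dir)
}
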