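#' Viable-row allele residuals per locus
#'
#' For each marker, builds the 2 x 2 (group x allele) count table of the
#' viable versus inviable group and returns the adjusted residuals of the
#' viable row. These single-locus residuals are the building blocks of the
#' allele indicator: in a 2 x 2 table the residual of allele II is the exact
#' negative of the residual of allele I.
#'
#' @param viable,inviable [HybridGenotypes] groups of one comparison.
#' @param markers markers to use (default: all shared markers, sorted).
#' @return Numeric matrix, markers x alleles (`I`, `II`), of viable-row
#'   adjusted residuals; `NA` where undefined.
#' @export
alleleResiduals <- function(viable, inviable, markers = NULL) {
    if (is.null(markers))
        markers <- sort(intersect(markerNames(viable), markerNames(inviable)))
    out <- matrix(NA_real_, length(markers), 2L,
                  dimnames = list(markers, c("I", "II")))
    for (m in markers) {
        tab <- alleleCounts(viable, inviable, m,
                            labels = c("viable", "inviable"))
        if (sum(tab) == 0)
            next
        out[m, ] <- adjustedResiduals(tab)["viable", ]
    }
    out
}

#' Allele indicator of a two-locus haplotype
#'
#' The allele indicator of haplotype x.y at marker pair (A, B) is the sum
#' of the viable-row adjusted allele residuals d_A(x) + d_B(y). It captures
#' the part of a haplotype's group difference that is explained by the
#' marginal allele-frequency differences at its two loci; regressing
#' haplotype residuals on the indicator therefore isolates genuinely
#' two-locus (epistatic) signal.
#'
#' @param pair character(2) marker names (alphabetical order is enforced).
#' @param haplotype one of `"I.I"`, `"I.II"`, `"II.I"`, `"II.II"`.
#' @param locusResiduals matrix as returned by [alleleResiduals()].
#' @return The indicator value, or `NA` if either locus residual is
#'   undefined.
#' @export
alleleIndicator <- function(pair, haplotype, locusResiduals) {
    pair <- sort(as.character(pair))
    al <- strsplit(haplotype, ".", fixed = TRUE)[[1]]
    if (length(al) != 2L || !all(al %in% c("I", "II")))
        stop("invalid haplotype label: ", haplotype)
    locusResiduals[pair[1], al[1]] + locusResiduals[pair[2], al[2]]
}

#' Assemble the residual dataset of a viable-inviable comparison
#'
#' For every marker pair, tallies the 2 x 4 haplotype table
#' ([haplotypeCounts()]), computes its adjusted residuals, and turns the
#' viable-row residuals into records carrying the haplotype class
#' (parental: I.I, II.II; recombinant: I.II, II.I) and the allele indicator.
#' Cells with zero expected counts have no defined residual and are
#' omitted; a complete 8-marker design yields 28 x 4 = 112 records.
#'
#' @param viable,inviable [HybridGenotypes] groups of one comparison.
#' @param markers markers to use (default: all shared markers, sorted).
#' @return data.frame with columns `pair`, `markerA`, `markerB`,
#'   `haplotype`, `hapClass`, `residual`, `indicator`. Attributes:
#'   `nAttempted` (4 x number of pairs), `nUndefined` (residual cells with
#'   zero expectation), `alleleResiduals` (the [alleleResiduals()] matrix).
#' @examples
#' hg <- filterHybridSamples(simulateHybridData(simConfig(seed = 1)))
#' g <- hybridGroups(hg)
#' nrow(buildResidualDataset(g$viable.I, g$inviable.I))
#' @export
buildResidualDataset <- function(viable, inviable, markers = NULL) {
    if (ncol(viable) == 0L || ncol(inviable) == 0L)
        stop("both groups must contain individuals")
    if (is.null(markers))
        markers <- sort(intersect(markerNames(viable), markerNames(inviable)))
    if (length(markers) < 2L)
        stop("at least two markers are required")
    pairs <- markerPairs(markers)
    locusRes <- alleleResiduals(viable, inviable, markers)
    haps <- c("I.I", "I.II", "II.I", "II.II")
    parental <- c("I.I", "II.II")
    rec <- vector("list", nrow(pairs))
    nUndefined <- 0L
    for (i in seq_len(nrow(pairs))) {
        a <- pairs$markerA[i]; b <- pairs$markerB[i]
        hct <- haplotypeCounts(viable, inviable, c(a, b),
                               labels = c("viable", "inviable"))
        d <- adjustedResiduals(hct)["viable", ]
        ind <- vapply(haps, function(h)
            alleleIndicator(c(a, b), h, locusRes), numeric(1))
        keep <- !is.na(d) & !is.na(ind)
        nUndefined <- nUndefined + sum(is.na(d))
        rec[[i]] <- data.frame(pair = pairs$pair[i], markerA = a, markerB = b,
                               haplotype = haps[keep],
                               hapClass = ifelse(haps[keep] %in% parental,
                                                 "parental", "recombinant"),
                               residual = unname(d[keep]),
                               indicator = unname(ind[keep]))
    }
    out <- do.call(rbind, rec)
    out$pair <- factor(out$pair, levels = pairs$pair)
    out$hapClass <- factor(out$hapClass, levels = c("parental", "recombinant"))
    if (nUndefined > 0L)
        message(sprintf("%d of %d haplotype residual cells undefined (zero expected counts) and omitted",
                        nUndefined, 4L * nrow(pairs)))
    attr(out, "nAttempted") <- 4L * nrow(pairs)
    attr(out, "nUndefined") <- nUndefined
    attr(out, "alleleResiduals") <- locusRes
    out
}

#' Fit the residual regression with pair x haplotype-class interaction
#'
#' Ordinary least squares of the viable-row haplotype residuals on the
#' allele indicator (continuous) plus the interaction of marker pair and
#' haplotype class: `residual ~ indicator + pair * hapClass`. For a
#' complete design of 28 pairs this estimates 1 + 1 + 27 + 1 + 27 = 57
#' coefficients, leaving 112 - 57 = 55 residual degrees of freedom (54 when
#' one haplotype cell is inestimable). If a pair lacks an entire haplotype
#' class its interaction coefficient is inestimable; `lm` drops it and a
#' warning reports the aliased terms.
#'
#' @param records data.frame from [buildResidualDataset()] (columns `pair`,
#'   `hapClass`, `residual`, `indicator`).
#' @return The fitted [stats::lm] object.
#' @export
fitResidualModel <- function(records) {
    records <- as.data.frame(records)
    need <- c("pair", "hapClass", "residual", "indicator")
    if (!all(need %in% colnames(records)))
        stop("records need columns ", paste(need, collapse = ", "))
    records$pair <- factor(records$pair)
    records$hapClass <- factor(as.character(records$hapClass),
                               levels = c("parental", "recombinant"))
    if (nrow(records) < nlevels(records$pair) * 2L + 2L)
        stop("too few records to fit the interaction model")
    fit <- stats::lm(residual ~ indicator + pair * hapClass, data = records)
    if (anyNA(stats::coef(fit)))
        warning(sprintf("%d inestimable coefficient(s) dropped (a pair is missing a haplotype class)",
                        sum(is.na(stats::coef(fit)))))
    fit
}

#' Omnibus test of the pair x class interaction
#'
#' Compares the full residual model with the reduced model lacking the
#' `pair:hapClass` interaction block. Reported both as the partial F-test
#' \eqn{F = ((RSS_r - RSS_f)/df_1) / (RSS_f/df_2)} and as the Gaussian
#' likelihood-ratio chi-square \eqn{n \log(RSS_r/RSS_f)}. A significant
#' interaction means the deviation of haplotype residuals from the
#' allele-indicator line differs between parental and recombinant
#' haplotypes in a pair-specific way — the signature of two-locus epistasis.
#'
#' @param fit full-model fit from [fitResidualModel()].
#' @param reduced optional reduced fit; refit from the model frame of `fit`
#'   when omitted.
#' @return List of class `"bdmInteractionTest"` with elements `F`, `df1`,
#'   `df2`, `p.F`, `LR`, `df.LR`, `p.LR`, `RSS.full`, `RSS.reduced`.
#' @export
interactionTest <- function(fit, reduced = NULL) {
    if (is.null(reduced))
        reduced <- stats::lm(residual ~ indicator + pair + hapClass,
                             data = fit$model)
    RSSf <- stats::deviance(fit)
    RSSr <- stats::deviance(reduced)
    df1 <- stats::df.residual(reduced) - stats::df.residual(fit)
    df2 <- stats::df.residual(fit)
    n <- stats::nobs(fit)
    extra <- max(RSSr - RSSf, 0)
    if (df1 == 0L || extra <= 1e-12 * max(RSSr, 1)) {
        ## no interaction columns removed, or the interaction block explains
        ## nothing (e.g. the response is an exact linear function of the
        ## indicator, so both models fit perfectly)
        Fstat <- 0; pF <- 1; LR <- 0; pLR <- 1
    } else if (RSSf <= 0) {
        warning("zero residual sum of squares; F reported as infinite")
        Fstat <- Inf; pF <- 0; LR <- Inf; pLR <- 0
    } else {
        Fstat <- ((RSSr - RSSf) / df1) / (RSSf / df2)
        pF <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
        LR <- n * log(RSSr / RSSf)
        pLR <- stats::pchisq(LR, df1, lower.tail = FALSE)
    }
    structure(list(F = Fstat, df1 = df1, df2 = df2, p.F = pF,
                   LR = LR, df.LR = df1, p.LR = pLR,
                   RSS.full = RSSf, RSS.reduced = RSSr),
              class = "bdmInteractionTest")
}

#' @export
print.bdmInteractionTest <- function(x, ...) {
    cat(sprintf("Marker-pair x haplotype-class interaction: F(%d, %d) = %.2f, P = %.3g\n",
                x$df1, x$df2, x$F, x$p.F))
    cat(sprintf("  likelihood ratio: chi-square(%d) = %.2f, P = %.3g\n",
                x$df.LR, x$LR, x$p.LR))
    invisible(x)
}

#' Post-hoc parental-versus-recombinant contrasts per marker pair
#'
#' For each marker pair, the contrast is the fitted mean residual of the
#' parental haplotype cells minus that of the recombinant cells, evaluated
#' at a common allele-indicator value of 0 (the indicator enters the model
#' additively, so the choice of evaluation point cancels). Each contrast is
#' tested with a t-statistic using the model's residual variance. A pair
#' with only one estimable class has an undefined contrast, reported as
#' `NA`.
#'
#' @param fit fit from [fitResidualModel()].
#' @param adjust `"holm"` (default) to apply Holm's sequential Bonferroni
#'   across the pairs, or `"none"`.
#' @return data.frame with columns `pair`, `estimate`, `se`, `df`,
#'   `statistic`, `p`, `p.adj`.
#' @export
pairwiseContrasts <- function(fit, adjust = c("holm", "none")) {
    adjust <- match.arg(adjust)
    pairs <- fit$xlevels$pair
    tt <- stats::delete.response(stats::terms(fit))
    beta <- stats::coef(fit)
    aliased <- is.na(beta)
    y <- fit$model[[1]]
    ## an (numerically) exact fit has no residual variance to test against:
    ## zero contrasts get p = 1, non-zero ones p = 0
    sigma0 <- stats::df.residual(fit) == 0L ||
        stats::deviance(fit) <= 1e-12 * max(sum((y - mean(y))^2), 1)
    zeroTol <- 1e-8 * max(1, max(abs(y)))
    V <- if (sigma0) NULL else stats::vcov(fit)
    est <- se <- tstat <- pval <- rep(NA_real_, length(pairs))
    for (i in seq_along(pairs)) {
        nd <- data.frame(pair = factor(pairs[i], levels = pairs),
                         hapClass = factor(c("parental", "recombinant"),
                                           levels = c("parental", "recombinant")),
                         indicator = 0)
        X <- stats::model.matrix(tt, nd, xlev = fit$xlevels)
        cvec <- X[1, ] - X[2, ]
        if (any(cvec[aliased] != 0))
            next   # contrast touches an inestimable coefficient
        cv <- cvec[!aliased]
        est[i] <- sum(cv * beta[!aliased])
        if (sigma0) {
            if (abs(est[i]) <= zeroTol) est[i] <- 0
            se[i] <- 0
            tstat[i] <- if (est[i] == 0) 0 else Inf * sign(est[i])
            pval[i] <- if (est[i] == 0) 1 else 0
        } else {
            se[i] <- sqrt(drop(t(cv) %*% V %*% cv))
            if (se[i] == 0) {
                tstat[i] <- if (est[i] == 0) 0 else Inf * sign(est[i])
                pval[i] <- if (est[i] == 0) 1 else 0
            } else {
                tstat[i] <- est[i] / se[i]
                pval[i] <- 2 * stats::pt(-abs(tstat[i]),
                                         stats::df.residual(fit))
            }
        }
    }
    padj <- if (adjust == "holm") stats::p.adjust(pval, method = "holm")
            else pval
    data.frame(pair = pairs, estimate = est, se = se,
               df = stats::df.residual(fit), statistic = tstat,
               p = pval, p.adj = padj)
}

#' Classify marker pairs as BDM, heterotic or neutral
#'
#' A significant positive contrast (viable individuals carry more parental
#' and fewer recombinant haplotypes than inviable ones) is the signature of
#' a BDM incompatibility; a significant negative contrast (viable
#' individuals enriched for recombinant haplotypes) indicates heterosis;
#' anything else — including an inestimable contrast — is labelled `none`.
#'
#' @param contrasts data.frame from [pairwiseContrasts()]; classification
#'   uses the `p.adj` column (equal to `p` when no adjustment was applied).
#' @param alpha significance level (default 0.05).
#' @return The input data.frame with added columns `label` (factor `BDM` /
#'   `none` / `heterosis`) and `estimable`; the label counts in Table-1
#'   order are in `attr(, "counts")` and via [classificationCounts()].
#' @export
classifyPairs <- function(contrasts, alpha = 0.05) {
    p <- contrasts$p.adj
    e <- contrasts$estimate
    lab <- rep("none", nrow(contrasts))
    ok <- !is.na(e) & !is.na(p)
    lab[ok & e > 0 & p < alpha] <- "BDM"
    lab[ok & e < 0 & p < alpha] <- "heterosis"
    contrasts$label <- factor(lab, levels = c("BDM", "none", "heterosis"))
    contrasts$estimable <- ok
    attr(contrasts, "counts") <- table(contrasts$label)
    contrasts
}

#' @rdname classifyPairs
#' @param classified output of [classifyPairs()].
#' @return `classificationCounts()`: named integer vector of label counts
#'   (`BDM`, `none`, `heterosis`), summing to the number of marker pairs.
#' @export
classificationCounts <- function(classified) {
    table(factor(classified$label, levels = c("BDM", "none", "heterosis")))
}

#' Per-locus cytonuclear incompatibility scan
#'
#' Compares allele frequencies of the two viable groups (which differ only
#' in cytotype) marker by marker with two-sided Fisher exact tests, then
#' applies Holm's sequential Bonferroni across the loci. A significant
#' locus indicates a nuclear allele whose effect on viability depends on
#' the cytoplasmic background.
#'
#' @param viableI,viableII the viable [HybridGenotypes] groups of the two
#'   reciprocal crosses.
#' @param markers markers to scan (default: all shared markers, sorted).
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with one row per locus: allele counts in each group,
#'   lineage-I allele frequencies, `p`, `p.adj`, `significant` and
#'   `direction` (which lineage's allele is overrepresented in viable I).
#' @export
cytonuclearScan <- function(viableI, viableII, markers = NULL, alpha = 0.05) {
    if (ncol(viableI) == 0L || ncol(viableII) == 0L)
        stop("both viable groups must contain individuals")
    if (is.null(markers))
        markers <- sort(intersect(markerNames(viableI), markerNames(viableII)))
    res <- lapply(markers, function(m) {
        tab <- alleleCounts(viableI, viableII, m,
                            labels = c("viable.I", "viable.II"))
        nI <- rowSums(tab)
        p <- if (any(nI == 0)) NA_real_ else fisherExactTwoSided(tab)
        fI <- tab[, "I"] / nI
        data.frame(marker = m,
                   I.viableI = tab["viable.I", "I"],
                   II.viableI = tab["viable.I", "II"],
                   I.viableII = tab["viable.II", "I"],
                   II.viableII = tab["viable.II", "II"],
                   freqI.viableI = fI[["viable.I"]],
                   freqI.viableII = fI[["viable.II"]],
                   p = p)
    })
    out <- do.call(rbind, res)
    hb <- sequentialBonferroni(out$p, alpha = alpha)
    out$p.adj <- hb$p.adj
    out$significant <- hb$significant
    dfr <- out$freqI.viableI - out$freqI.viableII
    out$direction <- ifelse(is.na(dfr) | dfr == 0, "equal",
                     ifelse(dfr > 0, "more I in viable I", "more II in viable I"))
    out
}
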