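#' Two-locus haplotype counts for a pair of hybrid groups
#'
#' Tallies the four two-locus haplotypes (I.I, I.II, II.I, II.II) in each of
#' two hybrid groups at a marker pair. The first symbol of a haplotype is
#' the allele at the alphabetically first marker of the pair. Individuals
#' missing a call at either locus are excluded from this pair's table only
#' (pairwise-complete deletion).
#'
#' @param groupA,groupB [HybridGenotypes] objects, e.g. the viable and
#'   inviable group of one cytotype.
#' @param pair character(2): the two (distinct) marker names.
#' @param labels rownames for the two groups in the table.
#' @return A [HaplotypeCountTable-class] object.
#' @examples
#' hg <- simulateHybridData(simConfig(seed = 1))
#' g <- hybridGroups(hg)
#' haplotypeCounts(g$viable.I, g$inviable.I, c("A", "B"))
#' @export
haplotypeCounts <- function(groupA, groupB, pair,
                            labels = c("groupA", "groupB")) {
    pair <- sort(as.character(pair))
    if (length(pair) != 2L || pair[1] == pair[2])
        stop("'pair' must name two distinct markers")
    haps <- c("I.I", "I.II", "II.I", "II.II")
    tally <- function(g) {
        if (!all(pair %in% markerNames(g)))
            stop("markers not in the genotype table: ",
                 paste(setdiff(pair, markerNames(g)), collapse = ", "))
        calls <- alleleCalls(g)[pair, , drop = FALSE]
        ok <- colSums(is.na(calls)) == 0L
        h <- paste(calls[1, ok], calls[2, ok], sep = ".")
        as.integer(table(factor(h, levels = haps)))
    }
    counts <- rbind(tally(groupA), tally(groupB))
    dimnames(counts) <- list(labels, haps)
    methods::new("HaplotypeCountTable", pair = pair, counts = counts)
}

#' Per-locus allele counts for a pair of hybrid groups
#'
#' The 2 x 2 (group x allele) count table of non-missing calls at one
#' marker, the single-locus analogue of [haplotypeCounts()].
#'
#' @inheritParams haplotypeCounts
#' @param marker one marker name.
#' @return 2 x 2 integer matrix with columns `I`, `II`.
#' @export
alleleCounts <- function(groupA, groupB, marker,
                         labels = c("groupA", "groupB")) {
    tally <- function(g) {
        x <- alleleCalls(g)[marker, ]
        as.integer(table(factor(x, levels = c("I", "II"))))
    }
    counts <- rbind(tally(groupA), tally(groupB))
    dimnames(counts) <- list(labels, c("I", "II"))
    counts
}

#' Adjusted (standardized) contingency-table residuals
#'
#' For each cell of a count table, the adjusted residual is the Pearson
#' residual divided by its estimated standard error,
#' \deqn{d_{ij} = (n_{ij} - E_{ij}) / \sqrt{E_{ij}(1 - n_{i+}/N)(1 - n_{+j}/N)},}
#' where \eqn{E_{ij} = n_{i+} n_{+j} / N}. Under independence these are
#' approximate z-scores with zero mean and unit standard deviation, so the
#' residuals of tables with different sample sizes and margins are
#' comparable. Cells whose expected count is zero (or whose standard error
#' is zero) are undefined and returned as `NA`. In a two-row table the
#' defined residuals satisfy \eqn{d_{1j} = -d_{2j}} exactly.
#'
#' @param x a matrix of non-negative counts, or a
#'   [HaplotypeCountTable-class].
#' @return Numeric matrix of the same shape; `NA` marks undefined cells.
#' @examples
#' adjustedResiduals(matrix(c(10, 0, 0, 10), 2))  # +/- 4.47214
#' @export
setMethod("adjustedResiduals", "matrix", function(x, ...) {
    if (any(x < 0))
        stop("counts must be non-negative")
    N <- sum(x)
    if (N == 0)
        stop("the table is all zero")
    r <- rowSums(x); cc <- colSums(x)
    E <- outer(r, cc) / N
    se2 <- E * outer(1 - r / N, 1 - cc / N)
    d <- (x - E) / sqrt(se2)
    d[E == 0 | se2 <= 0] <- NA_real_
    d
})

#' @rdname adjustedResiduals
#' @export
setMethod("adjustedResiduals", "HaplotypeCountTable", function(x, ...)
    adjustedResiduals(x@counts))

#' Two-sided Fisher exact test of independence for a 2 x 2 table
#'
#' The two-sided p-value is the total hypergeometric probability of all
#' tables with the observed margins that are at most as probable as the
#' observed table (probability-mass definition, with a relative tolerance
#' of 1e-7 on the comparison), as in [stats::fisher.test()].
#'
#' @param x 2 x 2 matrix of non-negative counts.
#' @return The two-sided p-value.
#' @examples
#' fisherExactTwoSided(matrix(c(3, 0, 0, 3), 2))  # 0.1
#' @export
fisherExactTwoSided <- function(x) {
    x <- as.matrix(x)
    if (!all(dim(x) == 2L))
        stop("a 2 x 2 table is required")
    if (any(x < 0))
        stop("counts must be non-negative")
    if (sum(x) == 0)
        stop("the table is all zero")
    min(stats::fisher.test(x, alternative = "two.sided")$p.value, 1)
}

#' Holm's sequential Bonferroni correction
#'
#' Step-down multiple-testing procedure: the sorted p-values \eqn{p_{(i)}}
#' are compared with \eqn{\alpha/(m - i + 1)}; testing stops at the first
#' failure and all later hypotheses are retained. Adjusted p-values are the
#' Holm values of [stats::p.adjust()] (monotone, capped at 1); the
#' significance decisions implement the step-down rule directly.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame with columns `p`, `p.adj`, `significant`, in the input
#'   order; zero rows for empty input.
#' @examples
#' sequentialBonferroni(c(0.004, 0.04))$significant  # both TRUE
#' sequentialBonferroni(c(0.03, 0.04))$significant   # both FALSE
#' @export
sequentialBonferroni <- function(p, alpha = 0.05) {
    if (length(p) == 0L)
        return(data.frame(p = numeric(), p.adj = numeric(),
                          significant = logical()))
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    m <- length(p)
    ord <- order(p, na.last = TRUE)
    pass <- rep(NA, m)
    ok <- TRUE
    for (i in seq_len(m)) {
        pi <- p[ord[i]]
        ok <- ok && !is.na(pi) && pi < alpha / (m - i + 1)
        pass[ord[i]] <- ok
    }
    data.frame(p = p, p.adj = stats::p.adjust(p, method = "holm"),
               significant = pass)
}

#' Generalized Cochran-Mantel-Haenszel test of general association
#'
#' Tests association between a two-level group factor and a C-category
#' response, summed over K strata (here: the 28 marker-pair haplotype
#' tables). For stratum k with row-1 counts \eqn{x_k}, column totals
#' \eqn{m_k} and total \eqn{N_k}, the statistic is
#' \eqn{M^2 = U^\top V^{-1} U} with \eqn{U = \sum_k (x_k' - n_{1k} m_k'/N_k)}
#' over the first C-1 columns and V the summed multivariate hypergeometric
#' covariance; under the null \eqn{M^2 \sim \chi^2_{C-1}}. Columns empty in
#' every stratum are dropped before computing the degrees of freedom; strata
#' with fewer than two observations or an empty row contribute nothing. If V
#' is singular after dropping, a Moore-Penrose inverse is used and the
#' degrees of freedom reduce to the rank of V, with a warning.
#'
#' @param strata a list of 2 x C count matrices sharing column labels, or a
#'   single such matrix, or a list of [HaplotypeCountTable-class] objects.
#' @return An object of class `"htest"` with the statistic (`M2`), degrees
#'   of freedom and p-value.
#' @examples
#' generalizedCMH(matrix(c(10, 0, 0, 10), 2))  # M2 = 19, df = 1
#' @export
generalizedCMH <- function(strata) {
    if (is.matrix(strata))
        strata <- list(strata)
    strata <- lapply(strata, function(s)
        if (methods::is(s, "HaplotypeCountTable")) s@counts else as.matrix(s))
    if (length(strata) == 0L)
        stop("at least one stratum is required")
    C <- unique(vapply(strata, ncol, integer(1)))
    if (length(C) != 1L)
        stop("all strata must share the same columns")
    if (any(vapply(strata, nrow, integer(1)) != 2L))
        stop("strata must have exactly two rows")
    colTot <- Reduce(`+`, lapply(strata, colSums))
    keep <- colTot > 0
    if (sum(keep) < 2L)
        stop("fewer than two response categories carry observations")
    Ck <- sum(keep)
    U <- numeric(Ck - 1L)
    V <- matrix(0, Ck - 1L, Ck - 1L)
    for (s in strata) {
        s <- s[, keep, drop = FALSE]
        N <- sum(s)
        n1 <- sum(s[1, ]); n2 <- sum(s[2, ])
        if (N < 2 || n1 == 0 || n2 == 0)
            next
        m <- colSums(s)[-Ck]
        U <- U + s[1, -Ck] - n1 * m / N
        V <- V + n1 * n2 / (N^2 * (N - 1)) * (N * diag(m, nrow = Ck - 1L) -
                                              outer(m, m))
    }
    qrV <- qr(V)
    df <- Ck - 1L
    if (qrV$rank < df) {
        warning("singular covariance; using a generalized inverse with reduced df")
        Vinv <- MASS::ginv(V)
        df <- qrV$rank
    } else {
        Vinv <- solve(V)
    }
    M2 <- drop(t(U) %*% Vinv %*% U)
    structure(list(statistic = c(M2 = M2), parameter = c(df = df),
                   p.value = stats::pchisq(M2, df, lower.tail = FALSE),
                   method = "Generalized Cochran-Mantel-Haenszel test (general association)",
                   data.name = sprintf("%d strata, %d response categories",
                                       length(strata), Ck)),
              class = "htest")
}
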