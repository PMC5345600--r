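## Flat-file readers/writers. Both readers sniff the delimiter (comma or
## tab) from the header line; missing values may be empty fields or NA.

sniffDelim <- function(path) {
    header <- readLines(path, n = 1L)
    if (lengths(regmatches(header, gregexpr("\t", header))) > 0L) "\t" else ","
}

#' Read a long-format fragment peak table
#'
#' @param path CSV/TSV file with columns `sample_id`, `marker`, `size_bp`,
#'   `area`, one row per observed peak.
#' @return data.frame with those four columns.
#' @seealso [scorePeakTable()]
#' @export
readPeakTable <- function(path) {
    d <- utils::read.table(path, header = TRUE, sep = sniffDelim(path),
                           stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
    need <- c("sample_id", "marker", "size_bp", "area")
    if (!all(need %in% colnames(d)))
        stop("peak table needs columns ", paste(need, collapse = ", "))
    d
}

#' Read a genotype table
#'
#' Reads a per-individual genotype table with columns `sample_id`,
#' `phenotype`, `cytotype` followed by one column per marker. Marker columns
#' may hold lineage codes (`I`/`II`) — in which case a [HybridGenotypes] is
#' returned — or raw allele sizes, returned as a data.frame for
#' [recodeToLineage()].
#'
#' @param path CSV/TSV file.
#' @return A [HybridGenotypes] when the marker columns are lineage-coded,
#'   otherwise the raw data.frame.
#' @export
readGenotypeTable <- function(path) {
    d <- utils::read.table(path, header = TRUE, sep = sniffDelim(path),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"))
    need <- c("sample_id", "phenotype", "cytotype")
    if (!all(need %in% colnames(d)))
        stop("genotype table needs columns ", paste(need, collapse = ", "))
    mk <- setdiff(colnames(d), need)
    if (length(mk) == 0L)
        stop("genotype table contains no marker columns")
    vals <- unlist(lapply(d[mk], as.character), use.names = FALSE)
    if (all(is.na(vals) | vals %in% c("I", "II"))) {
        calls <- t(as.matrix(vapply(d[mk], as.character,
                                    character(nrow(d)))))
        if (nrow(d) == 1L) {
            calls <- matrix(vapply(d[mk], as.character, character(1L)),
                            ncol = 1L)
            rownames(calls) <- mk
        }
        colnames(calls) <- as.character(d$sample_id)
        return(HybridGenotypes(calls[sort(mk), , drop = FALSE],
                               phenotype = d$phenotype,
                               cytotype = d$cytotype))
    }
    d
}

#' Write a genotype table
#'
#' Writes the CSV dialect read back by [readGenotypeTable()]: columns
#' `sample_id`, `phenotype`, `cytotype`, then one lineage-coded column per
#' marker with missing calls as empty fields.
#'
#' @param x a [HybridGenotypes].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypeTable <- function(x, path) {
    d <- data.frame(sample_id = colnames(x),
                    phenotype = as.character(phenotype(x)),
                    cytotype = as.character(cytotype(x)),
                    t(alleleCalls(x)),
                    check.names = FALSE, row.names = NULL)
    utils::write.table(d, path, sep = ",", quote = FALSE, na = "",
                       row.names = FALSE)
    invisible(path)
}
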