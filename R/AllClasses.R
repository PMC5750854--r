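#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
NULL

#' EvidenceMatrix: binary multi-source gene evidence
#'
#' An \code{EvidenceMatrix} holds the genes-by-categories indicator matrix
#' consumed by the prioritizer: one row per gene, one column per evidence
#' category (e.g. association study, linkage scan, expression profiling,
#' literature search), each entry 1 if the gene was reported by that source
#' and 0 otherwise.  The curated core gene set (the gold standard steering
#' the weight optimization) is stored as a logical \code{isCore} column of
#' the row annotation.  The class extends
#' \linkS4class{SummarizedExperiment}, so all its subsetting and annotation
#' machinery applies.
#'
#' Validity requires at least two categories, entries exactly 0 or 1,
#' unique uppercase gene symbols as rownames, and at least one positive
#' indicator per gene -- except for core genes absent from every source
#' column, which are retained with an all-zero row (the constructor warns
#' about them rather than silently dropping gold-standard genes).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; the single assay is
#'   named \code{"indicator"}.
#'
#' @seealso [EvidenceMatrix()] (constructor), [readEvidenceCSV()],
#'   [categories()], [coreGenes()], [indicatorMatrix()]
#' @export
setClass("EvidenceMatrix", contains = "SummarizedExperiment")

setValidity("EvidenceMatrix", function(object) {
    msg <- character()
    if (!"indicator" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'indicator' is missing")
    else {
        ind <- assay(object, "indicator")
        if (!all(ind %in% c(0L, 1L)))
            msg <- c(msg, "indicator entries must be exactly 0 or 1")
        if (ncol(ind) < 2L)
            msg <- c(msg, "at least 2 evidence categories are required (N >= 2)")
        if (is.null(rownames(ind)) || anyDuplicated(rownames(ind)))
            msg <- c(msg, "gene symbols (rownames) must be present and unique")
        if (!"isCore" %in% colnames(rowData(object)))
            msg <- c(msg, "rowData must contain a logical 'isCore' column")
        else {
            core <- rowData(object)$isCore
            zero <- rowSums(ind) == 0
            if (any(zero & !core))
                msg <- c(msg, "non-core genes must have at least one indicator equal to 1")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct an EvidenceMatrix
#'
#' @param indicator numeric/integer matrix of 0/1 indicators with gene
#'   symbols as rownames and category names as colnames (N >= 2 columns).
#' @param core character vector of core gene symbols (normalized against
#'   the rownames with [normalizeSymbol()]).  Core symbols absent from the
#'   matrix rows are appended as all-zero rows with a warning.
#' @return A validated [EvidenceMatrix-class] object.
#' @examples
#' ind <- matrix(c(1, 1, 0, 0, 1, 1), nrow = 3,
#'               dimnames = list(c("A", "B", "C"), c("assoc", "expr")))
#' em <- EvidenceMatrix(ind, core = "B")
#' coreGenes(em)
#' @export
EvidenceMatrix <- function(indicator, core = character()) {
    indicator <- as.matrix(indicator)
    storage.mode(indicator) <- "integer"
    if (is.null(rownames(indicator)))
        stop("'indicator' must have gene symbols as rownames")
    rownames(indicator) <- vapply(rownames(indicator), normalizeSymbol, "")
    core <- unique(vapply(core, normalizeSymbol, "", USE.NAMES = FALSE))
    orphan <- setdiff(core, rownames(indicator))
    if (length(orphan)) {
        warning("core gene(s) absent from every source column kept with ",
                "all-zero evidence: ", paste(orphan, collapse = ", "))
        pad <- matrix(0L, nrow = length(orphan), ncol = ncol(indicator),
                      dimnames = list(orphan, colnames(indicator)))
        indicator <- rbind(indicator, pad)
    }
    indicator <- indicator[order(rownames(indicator)), , drop = FALSE]
    se <- SummarizedExperiment(
        assays = list(indicator = indicator),
        rowData = DataFrame(isCore = rownames(indicator) %in% core))
    new("EvidenceMatrix", se)
}

setMethod("show", "EvidenceMatrix", function(object) {
    cat(sprintf("EvidenceMatrix: %d genes x %d categories, %d core genes\n",
                nrow(object), ncol(object), length(coreGenes(object))))
    cat("categories:", paste(categories(object), collapse = ", "), "\n")
})
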