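#' Accessors for EvidenceMatrix
#'
#' \code{categories} returns the ordered evidence-source names;
#' \code{geneSymbols} the ordered (lexicographic) gene symbols;
#' \code{coreGenes} the symbols flagged as the gold-standard core set;
#' \code{indicatorMatrix} the underlying 0/1 genes-by-categories matrix.
#'
#' @param x an [EvidenceMatrix-class] object.
#' @return character vectors, or an integer matrix for
#'   \code{indicatorMatrix}.
#' @name EvidenceMatrix-accessors
#' @examples
#' em <- EvidenceMatrix(matrix(c(1, 0, 1, 1), 2,
#'                             dimnames = list(c("A", "B"), c("c1", "c2"))),
#'                      core = "A")
#' categories(em)
#' indicatorMatrix(em)
NULL

#' @rdname EvidenceMatrix-accessors
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' @rdname EvidenceMatrix-accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname EvidenceMatrix-accessors
#' @export
setGeneric("coreGenes", function(x) standardGeneric("coreGenes"))

#' @rdname EvidenceMatrix-accessors
#' @export
setGeneric("indicatorMatrix", function(x) standardGeneric("indicatorMatrix"))

#' @rdname EvidenceMatrix-accessors
setMethod("categories", "EvidenceMatrix", function(x) colnames(x))

#' @rdname EvidenceMatrix-accessors
setMethod("geneSymbols", "EvidenceMatrix", function(x) rownames(x))

#' @rdname EvidenceMatrix-accessors
setMethod("coreGenes", "EvidenceMatrix",
          function(x) rownames(x)[rowData(x)$isCore])

#' @rdname EvidenceMatrix-accessors
setMethod("indicatorMatrix", "EvidenceMatrix",
          function(x) assay(x, "indicator"))
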