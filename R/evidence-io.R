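#' Normalize a gene symbol
#'
#' Symbols are matched exactly after normalization: uppercase, leading and
#' trailing whitespace trimmed, internal whitespace runs collapsed to a
#' single space.  Normalization is idempotent.  No alias expansion happens
#' here; aliases are handled by the literature-screening layer.
#'
#' @param raw a single character string with at least one non-whitespace
#'   character.
#' @return the normalized symbol.
#' @examples
#' normalizeSymbol(" drd2 ")   # "DRD2"
#' normalizeSymbol("chrna  4") # "CHRNA 4"
#' @export
normalizeSymbol <- function(raw) {
    if (!is.character(raw) || length(raw) != 1L || is.na(raw))
        stop("'raw' must be a single character string")
    out <- toupper(gsub("[[:space:]]+", " ", trimws(raw)))
    if (!nzchar(out))
        stop("empty gene symbol after normalization (input was ",
             deparse(raw), ")")
    out
}

#' Read a multi-source evidence CSV
#'
#' The upload format is a comma-delimited file whose first row names the
#' evidence sources; every column lists the gene symbols reported by one
#' source and the \emph{last} column lists the core gene set -- the genes
#' already known to be associated with the phenotype.  Columns may have
#' unequal length (short rows are padded with empties); empty cells are
#' ignored; duplicate symbols within a column collapse to one.
#'
#' @param path path to the CSV file.
#' @return an [EvidenceMatrix-class] whose categories are all header names
#'   except the last, genes the union of normalized symbols over the
#'   source columns, and core set the normalized last column.  A warning
#'   is emitted (and recorded in \code{metadata(x)$warnings}) for core
#'   genes absent from every source column; they are kept with an
#'   all-zero row so the gold standard is never silently truncated.
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' writeLines(c("assoc,linkage,expr,core", "A,B,C,B", "B,C,,"), csv)
#' readEvidenceCSV(csv)
#' @export
readEvidenceCSV <- function(path) {
    if (!file.exists(path))
        stop("evidence CSV not found: ", path)
    raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, fill = TRUE,
                           blank.lines.skip = TRUE, fileEncoding = "UTF-8")
    if (ncol(raw) < 3L)
        stop("evidence CSV must have at least 3 columns ",
             "(>= 2 sources plus the core column); got ", ncol(raw))
    header <- colnames(raw)
    cats <- header[-length(header)]
    if (anyDuplicated(cats))
        stop("duplicate category names in header: ",
             paste(unique(cats[duplicated(cats)]), collapse = ", "))
    normCol <- function(j) {
        cells <- raw[[j]]
        cells <- cells[!is.na(cells) & nzchar(trimws(cells))]
        unique(vapply(cells, normalizeSymbol, "", USE.NAMES = FALSE))
    }
    sources <- lapply(seq_along(cats), normCol)
    core <- normCol(ncol(raw))
    genes <- sort(unique(unlist(sources)))
    if (!length(genes))
        stop("no gene symbols found in any source column of ", path)
    ind <- matrix(0L, nrow = length(genes), ncol = length(cats),
                  dimnames = list(genes, cats))
    for (j in seq_along(sources)) ind[sources[[j]], j] <- 1L
    warn <- character()
    em <- withCallingHandlers(
        EvidenceMatrix(ind, core = core),
        warning = function(w) {
            warn <<- c(warn, conditionMessage(w))
            invokeRestart("muffleWarning")
        })
    if (length(warn)) {
        metadata(em)$warnings <- warn
        for (w in warn) warning(w, call. = FALSE)
    }
    em
}

#' Write an evidence CSV
#'
#' Serializes an [EvidenceMatrix-class] back to the column-per-source
#' upload format (last column = core genes), the inverse of
#' [readEvidenceCSV()] up to row padding.
#'
#' @param x an EvidenceMatrix.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeEvidenceCSV <- function(x, path) {
    stopifnot(is(x, "EvidenceMatrix"))
    ind <- indicatorMatrix(x)
    cols <- c(lapply(seq_len(ncol(ind)),
                     function(j) rownames(ind)[ind[, j] == 1L]),
              list(coreGenes(x)))
    names(cols) <- c(categories(x), "core")
    depth <- max(1L, vapply(cols, length, 1L))
    padded <- vapply(cols, function(v) c(v, rep("", depth - length(v))),
                     character(depth))
    if (depth == 1L) padded <- matrix(padded, nrow = 1L,
                                      dimnames = list(NULL, names(cols)))
    utils::write.table(padded, path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = TRUE,
                       fileEncoding = "UTF-8")
    invisible(path)
}

#' Write / read the binary matrix as TSV
#'
#' \code{writeMatrixTSV} dumps the indicator matrix as a TSV with columns
#' \code{gene}, one 0/1 column per category and \code{is_core}; rows are
#' sorted by gene symbol.  \code{readMatrixTSV} is its lossless inverse.
#'
#' @param x an EvidenceMatrix.
#' @param path file path.
#' @return \code{writeMatrixTSV} invisibly returns \code{path};
#'   \code{readMatrixTSV} returns an [EvidenceMatrix-class].
#' @export
writeMatrixTSV <- function(x, path) {
    stopifnot(is(x, "EvidenceMatrix"))
    ind <- indicatorMatrix(x)
    df <- data.frame(gene = rownames(ind), ind,
                     is_core = as.integer(rowData(x)$isCore),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, fileEncoding = "UTF-8")
    stopifnot(colnames(df)[1] == "gene",
              colnames(df)[ncol(df)] == "is_core")
    ind <- as.matrix(df[, -c(1, ncol(df)), drop = FALSE])
    rownames(ind) <- df$gene
    EvidenceMatrix(ind, core = df$gene[df$is_core == 1L])
}

#' Summarize an evidence matrix
#'
#' @param x an EvidenceMatrix.
#' @return a list \code{n_genes}, \code{n_categories}, \code{n_core},
#'   \code{warnings} (reader warnings, if any) suitable for JSON export.
#' @export
evidenceSummary <- function(x) {
    stopifnot(is(x, "EvidenceMatrix"))
    w <- metadata(x)$warnings
    list(n_genes = nrow(x), n_categories = ncol(x),
         n_core = length(coreGenes(x)),
         warnings = if (is.null(w)) character() else w)
}
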