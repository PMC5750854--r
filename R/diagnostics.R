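#' Comparative score distribution of core vs all genes
#'
#' Bins the combined scores of every gene into equal-width bins over
#' [0, 1] (last bin right-inclusive) and counts all genes and core genes
#' per bin.  An informative weight vector shows most core genes piled in
#' the high-score bins while the candidate bulk sits lower; this is the
#' histogram overlay users inspect before choosing a threshold.
#'
#' @param table a ranking from [rankGenes()].
#' @param nBins number of bins (>= 1); default 20, enough to resolve the
#'   distinct score levels achievable with a handful of categories.
#' @return a list with \code{bin_edges} (length \code{nBins + 1}),
#'   \code{all_counts}, \code{core_counts}.
#' @export
scoreDistribution <- function(table, nBins = 20L) {
    if (nBins < 1L) stop("'nBins' must be at least 1")
    edges <- seq(0, 1, length.out = nBins + 1L)
    bin <- function(s) pmin(pmax(findInterval(s, edges,
                                              rightmost.closed = TRUE),
                                 1L), nBins)
    allB <- bin(table$score)
    list(bin_edges = edges,
         all_counts = tabulate(allB, nbins = nBins),
         core_counts = tabulate(allB[table$is_core], nbins = nBins))
}

#' Rank/score curve with cumulative core-gene coverage
#'
#' For each display rank, the combined score at that rank and the number
#' of core genes at or above it.  Plotted with score on the left axis
#' and core coverage on the right, this is the curve used to pick the
#' prioritization threshold: an efficient weight vector pulls the core
#' genes (or their majority) into the leading ranks, so the coverage
#' curve saturates early.
#'
#' @param table a non-empty ranking from [rankGenes()].
#' @return a data.frame with columns \code{rank}, \code{score},
#'   \code{cumulative_core_count}.
#' @export
thresholdCurve <- function(table) {
    if (nrow(table) == 0L) stop("ranked table is empty")
    if (!any(table$is_core))
        warning("no core genes in table; coverage curve is identically 0")
    data.frame(rank = table$rank,
               score = table$score,
               cumulative_core_count = cumsum(as.integer(table$is_core)))
}

#' Plot score-distribution and threshold diagnostics
#'
#' Thin base-graphics layer over the tabular diagnostics:
#' \code{plotScoreDistribution} overlays the core-gene histogram on the
#' all-gene histogram; \code{plotThresholdCurve} draws score by rank with
#' the cumulative core count on a second axis.
#'
#' @param dist result of [scoreDistribution()].
#' @param curve result of [thresholdCurve()].
#' @param ... passed to the underlying plotting calls.
#' @return invisibly, NULL (called for the plot side effect).
#' @export
plotScoreDistribution <- function(dist, ...) {
    mids <- (dist$bin_edges[-1] + dist$bin_edges[-length(dist$bin_edges)]) / 2
    graphics::barplot(rbind(dist$all_counts, dist$core_counts),
                      beside = TRUE, names.arg = formatC(mids, digits = 2),
                      col = c("grey70", "firebrick"),
                      xlab = "combined score", ylab = "genes",
                      legend.text = c("all genes", "core genes"), ...)
    invisible(NULL)
}

#' @rdname plotScoreDistribution
#' @export
plotThresholdCurve <- function(curve, ...) {
    op <- graphics::par(mar = c(5, 4, 2, 4))
    on.exit(graphics::par(op))
    plot(curve$rank, curve$score, type = "s", col = "grey30",
         xlab = "rank", ylab = "combined score", ylim = c(0, 1), ...)
    graphics::par(new = TRUE)
    plot(curve$rank, curve$cumulative_core_count, type = "s",
         col = "firebrick", axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4, col = "firebrick", col.axis = "firebrick")
    graphics::mtext("cumulative core genes", side = 4, line = 2.5,
                    col = "firebrick")
    invisible(NULL)
}

#' Write diagnostics tables as TSV
#'
#' @param dist result of [scoreDistribution()].
#' @param curve result of [thresholdCurve()].
#' @param dir output directory; writes \code{score_distribution.tsv} and
#'   \code{threshold_curve.tsv}.
#' @return invisibly, the two paths.
#' @export
writeDiagnostics <- function(dist, curve, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    dd <- data.frame(bin_lo = dist$bin_edges[-length(dist$bin_edges)],
                     bin_hi = dist$bin_edges[-1],
                     all_count = dist$all_counts,
                     core_count = dist$core_counts)
    p1 <- file.path(dir, "score_distribution.tsv")
    utils::write.table(dd, p1, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    p2 <- file.path(dir, "threshold_curve.tsv")
    utils::write.table(curve, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(c(p1, p2))
}
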