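#' Combined evidence score
#'
#' The combined score of a gene is the weighted sum of its category
#' indicators, \eqn{S_{combined} = \sum_{i=1}^{N} w_i S_i}, where
#' \eqn{S_i \in \{0,1\}} says whether the gene was reported by source
#' \eqn{i} and \eqn{w_i \ge 0} is that source's contribution weight.
#' With weights on the unit simplex the score lies in [0, 1] and equals
#' 1 exactly when every category supports the gene.
#'
#' @param evidence numeric vector of 0/1 indicators, length N.
#' @param weights numeric weight vector of the same length, nonnegative,
#'   summing to 1 (see [uniformWeights()], [normalizeWeights()]).
#' @return the combined score, a single number in [0, 1].
#' @examples
#' combinedScore(c(1, 0, 1, 0), c(0.4, 0.3, 0.2, 0.1)) # 0.6
#' @export
combinedScore <- function(evidence, weights) {
    if (length(evidence) != length(weights))
        stop("evidence vector and weight vector differ in length (",
             length(evidence), " vs ", length(weights), ")")
    .checkWeights(weights)
    if (!all(evidence %in% c(0, 1)))
        stop("evidence indicators must be exactly 0 or 1")
    ## clamp against sub-ulp overshoot so the score honours its [0, 1] range
    min(max(sum(weights * evidence), 0), 1)
}

.checkWeights <- function(weights, tol = 1e-8) {
    if (!is.numeric(weights) || length(weights) < 2L)
        stop("'weights' must be a numeric vector of length >= 2")
    if (any(weights < 0))
        stop("weights must be nonnegative")
    if (abs(sum(weights) - 1) > tol)
        stop("weights must sum to 1 (got ", format(sum(weights)), ")")
    invisible(TRUE)
}

#' Weight-vector helpers
#'
#' \code{uniformWeights} returns the uninformative starting point 1/N per
#' category; \code{normalizeWeights} clips negatives to zero and rescales
#' onto the unit simplex.  Rankings are invariant to positive rescaling of
#' the weights, so the simplex constraint removes a flat direction from
#' the search space without restricting the achievable rankings.
#'
#' @param n number of categories.
#' @param w numeric vector.
#' @return a weight vector on the unit simplex.
#' @export
uniformWeights <- function(n) rep(1 / n, n)

#' @rdname uniformWeights
#' @export
normalizeWeights <- function(w) {
    w[w < 0] <- 0
    s <- sum(w)
    if (s == 0) stop("cannot normalize an all-zero weight vector")
    w <- w / s
    ## compensate the division rounding so the sum is exactly 1 in double
    ## precision: fold the residual into the smallest coordinate that can
    ## absorb it without rounding away
    for (it in 1:10) {
        d <- 1 - sum(w)
        if (d == 0) break
        j <- which.min(replace(w, w < 1e-6, Inf))
        w[j] <- w[j] + d
    }
    w[w < 0] <- 0
    w
}

.scoresFor <- function(ind, weights)
    pmin(pmax(as.numeric(ind %*% weights), 0), 1)

#' Core-gene ranking objective
#'
#' The quality of a weight vector is measured by how high the core genes
#' sit in the score ranking: the mean fractional tie-averaged rank of the
#' core genes, \eqn{(1/|C|) \sum_{g \in C} \bar r(g) / M}, where ranks
#' are assigned by descending combined score with ties taking the mean of
#' the positions they occupy and \eqn{M} is the total number of genes.
#' Lower is better; the value lies in (0, 1] and attains its minimum
#' \eqn{(|C|+1)/(2M)} exactly when the core genes occupy the top
#' \eqn{|C|} positions without ties against non-core genes.  The measure
#' is scale-free in \eqn{M} and equivalent to a Mann-Whitney separation
#' statistic between core and non-core score distributions.
#'
#' @param x an [EvidenceMatrix-class] with a non-empty core set.
#' @param weights weight vector on the unit simplex, length
#'   \code{ncol(x)}.
#' @return the objective value (smaller = core genes higher).
#' @export
coreRankObjective <- function(x, weights) {
    stopifnot(is(x, "EvidenceMatrix"))
    core <- rowData(x)$isCore
    if (!any(core))
        stop("core gene set is empty; the ranking objective is undefined")
    .checkWeights(weights)
    ind <- indicatorMatrix(x)
    if (length(weights) != ncol(ind))
        stop("weight vector length must equal the number of categories")
    avgRank <- rank(-.scoresFor(ind, weights), ties.method = "average")
    mean(avgRank[core]) / nrow(ind)
}

## objective on a plain indicator matrix + logical core mask (hot loop)
.objective <- function(ind, coreMask, weights) {
    avgRank <- rank(-as.numeric(ind %*% weights), ties.method = "average")
    mean(avgRank[coreMask]) / nrow(ind)
}

#' Simulated-annealing configuration
#'
#' Schedule parameters for [simulatedAnnealing()].  The defaults
#' (5000 proposals total) solve problems with up to about six categories
#' in seconds; all are overridable.
#'
#' @param initialTemperature starting temperature (> 0).
#' @param coolingFactor geometric cooling multiplier in (0, 1), applied
#'   after each temperature block.
#' @param stepsPerTemperature proposals per temperature block.
#' @param nTemperatures number of temperature blocks.
#' @param proposalSd standard deviation of the Gaussian perturbation
#'   applied to one randomly chosen weight coordinate per proposal.
#' @param seed integer seed making the whole search reproducible.
#' @return a list of class \code{"SAConfig"}.
#' @export
saConfig <- function(initialTemperature = 1.0, coolingFactor = 0.95,
                     stepsPerTemperature = 50L, nTemperatures = 100L,
                     proposalSd = 0.1, seed = 42L) {
    stopifnot(initialTemperature > 0,
              coolingFactor > 0, coolingFactor < 1,
              stepsPerTemperature >= 1, nTemperatures >= 1,
              proposalSd > 0, is.finite(seed))
    structure(list(initialTemperature = initialTemperature,
                   coolingFactor = coolingFactor,
                   stepsPerTemperature = as.integer(stepsPerTemperature),
                   nTemperatures = as.integer(nTemperatures),
                   proposalSd = proposalSd,
                   seed = as.integer(seed)),
              class = "SAConfig")
}

#' Optimize category weights by simulated annealing
#'
#' Searches the unit simplex for the weight vector minimizing
#' [coreRankObjective()].  The walk starts from uniform weights; each
#' proposal perturbs one randomly chosen coordinate with Gaussian noise
#' of sd \code{proposalSd}, clips negatives to zero and renormalizes
#' (an all-zero proposal is redrawn, never emitted).  A proposal with
#' objective change \eqn{\Delta E} is accepted with probability
#' \eqn{\min(1, e^{-\Delta E / T})}; the temperature cools geometrically,
#' \eqn{T \leftarrow c\,T}, after each block.  The best-ever weights are
#' returned, so the reported objective trace is non-increasing.  The run
#' is fully reproducible from \code{config$seed} (the session RNG seed is
#' set as a side effect).
#'
#' @param x an [EvidenceMatrix-class] with non-empty core set.
#' @param config an [saConfig()] list.
#' @return a list with elements \code{weights} (named, on the simplex),
#'   \code{objective} (best value found), \code{trace} (data.frame of
#'   \code{iteration}, \code{temperature}, \code{current}, \code{best})
#'   and \code{config}.
#' @examples
#' em <- genEvidenceMatrix(matrixSpec(n_genes = 60, category_probs = c(.1, .3),
#'                                    core_size = 8, core_boost = c(.6, 0),
#'                                    seed = 7))
#' fit <- simulatedAnnealing(em, saConfig(nTemperatures = 20, seed = 1))
#' fit$weights
#' @export
simulatedAnnealing <- function(x, config = saConfig()) {
    stopifnot(is(x, "EvidenceMatrix"), inherits(config, "SAConfig"))
    coreMask <- rowData(x)$isCore
    if (!any(coreMask))
        stop("core gene set is empty; cannot optimize weights")
    ind <- indicatorMatrix(x)
    n <- ncol(ind)
    set.seed(config$seed)

    w <- uniformWeights(n)
    e <- .objective(ind, coreMask, w)
    bestW <- w
    bestE <- e
    temp <- config$initialTemperature
    total <- config$stepsPerTemperature * config$nTemperatures
    trace <- data.frame(iteration = seq_len(total),
                        temperature = NA_real_,
                        current = NA_real_, best = NA_real_)
    it <- 0L
    for (blk in seq_len(config$nTemperatures)) {
        for (s in seq_len(config$stepsPerTemperature)) {
            it <- it + 1L
            repeat {
                wNew <- w
                j <- sample.int(n, 1L)
                wNew[j] <- wNew[j] + stats::rnorm(1L, 0, config$proposalSd)
                wNew[wNew < 0] <- 0
                if (sum(wNew) > 0) break
            }
            wNew <- normalizeWeights(wNew)
            eNew <- .objective(ind, coreMask, wNew)
            dE <- eNew - e
            if (dE <= 0 || stats::runif(1L) < exp(-dE / temp)) {
                w <- wNew
                e <- eNew
            }
            if (e < bestE) {
                bestE <- e
                bestW <- w
            }
            trace$temperature[it] <- temp
            trace$current[it] <- e
            trace$best[it] <- bestE
        }
        temp <- temp * config$coolingFactor
    }
    names(bestW) <- colnames(ind)
    list(weights = bestW, objective = bestE, trace = trace, config = config)
}

## all nonnegative integer N-vectors summing to k, deterministic order
.compositions <- function(n, k) {
    if (n == 1L) return(matrix(k, nrow = 1L))
    out <- vector("list", k + 1L)
    for (first in 0:k) {
        rest <- .compositions(n - 1L, k - first)
        out[[first + 1L]] <- cbind(first, rest, deparse.level = 0)
    }
    do.call(rbind, out)
}

#' Exhaustive simplex-grid oracle
#'
#' Brute-force reference optimizer: enumerates every weight composition
#' on the unit simplex at resolution \code{step} (all nonnegative
#' multiples of \code{step} summing to 1) and evaluates
#' [coreRankObjective()] at each.  Deterministic; intended for validating
#' the annealer on small problems (N <= 5, step >= 0.05).
#'
#' @param x an [EvidenceMatrix-class] with non-empty core set.
#' @param step grid resolution; \code{1/step} must be an integer.
#' @return list with \code{weights} (best grid point, first in
#'   enumeration order on ties), \code{objective}, and \code{nEvaluated}.
#' @export
gridOracle <- function(x, step = 0.05) {
    stopifnot(is(x, "EvidenceMatrix"))
    coreMask <- rowData(x)$isCore
    if (!any(coreMask)) stop("core gene set is empty")
    k <- round(1 / step)
    if (abs(k - 1 / step) > 1e-9)
        stop("1/step must be an integer (got step = ", step, ")")
    ind <- indicatorMatrix(x)
    comps <- .compositions(ncol(ind), k)
    grid <- comps / k
    objs <- apply(grid, 1L, function(w) .objective(ind, coreMask, w))
    best <- which.min(objs)
    w <- grid[best, ]
    names(w) <- colnames(ind)
    list(weights = w, objective = objs[best], nEvaluated = nrow(grid))
}

#' Rank genes by combined score
#'
#' Scores every gene with [combinedScore()] under the given weights and
#' returns the ranked table: sorted by descending score with ties broken
#' by ascending symbol for a deterministic listing.  \code{rank} is the
#' 1-based display position; \code{avg_rank} is the tie-averaged rank
#' used by the objective.  The \code{above_threshold} flag is set by the
#' chosen policy:
#' \describe{
#'   \item{\code{"cover-core"}}{threshold at the score of the
#'     \code{ceiling(value * |C|)}-th best-scoring core gene, i.e. the
#'     smallest score cutoff flagging at least that fraction of the core
#'     set (default \code{value = 1}: cover every core gene).}
#'   \item{\code{"top-k"}}{flag the \code{value} best-ranked genes.}
#'   \item{\code{"score-cutoff"}}{flag genes with score >= \code{value}.}
#' }
#' Core genes stay in the output, flagged \code{is_core}, so their
#' placement can be inspected against the full list.
#'
#' @param x an [EvidenceMatrix-class].
#' @param weights weight vector on the unit simplex.
#' @param policy one of \code{"cover-core"}, \code{"top-k"},
#'   \code{"score-cutoff"}.
#' @param value the policy parameter (fraction, count, or score).
#' @return a [S4Vectors::DataFrame] with columns \code{gene},
#'   \code{score}, \code{rank}, \code{avg_rank}, \code{is_core},
#'   \code{above_threshold}; \code{metadata()} carries \code{weights},
#'   \code{objective} (when a core set exists), \code{policy} and
#'   \code{value}.
#' @export
rankGenes <- function(x, weights,
                      policy = c("cover-core", "top-k", "score-cutoff"),
                      value = NULL) {
    stopifnot(is(x, "EvidenceMatrix"))
    policy <- match.arg(policy)
    if (is.null(value))
        value <- switch(policy, "cover-core" = 1.0, "top-k" = 10L,
                        "score-cutoff" = 0.5)
    .checkWeights(weights)
    ind <- indicatorMatrix(x)
    if (length(weights) != ncol(ind))
        stop("weight vector length must equal the number of categories")
    score <- .scoresFor(ind, weights)
    avgRank <- rank(-score, ties.method = "average")
    ord <- order(-score, rownames(ind))
    core <- rowData(x)$isCore[ord]
    score <- score[ord]
    tab <- DataFrame(gene = rownames(ind)[ord],
                     score = score,
                     rank = seq_along(ord),
                     avg_rank = avgRank[ord],
                     is_core = core)
    tab$above_threshold <- switch(
        policy,
        "top-k" = tab$rank <= value,
        "score-cutoff" = tab$score >= value,
        "cover-core" = {
            nC <- sum(core)
            if (nC == 0L) {
                warning("cover-core policy with empty core set: ",
                        "no genes flagged")
                rep(FALSE, nrow(tab))
            } else {
                need <- max(1L, ceiling(value * nC))
                cut <- score[core][order(-score[core])][min(need, nC)]
                tab$score >= cut
            }
        })
    metadata(tab) <- list(
        weights = stats::setNames(weights, colnames(ind)),
        objective = if (any(core)) mean(avgRank[rowData(x)$isCore]) /
                        nrow(ind) else NA_real_,
        policy = policy, value = value)
    tab
}

#' Write a ranked table as TSV
#'
#' One row per gene with its per-category 0/1 indicators, combined score,
#' rank, core flag and threshold flag; scores are printed with full
#' precision so that reruns under the same seed are byte-identical.
#'
#' @param table a ranking from [rankGenes()].
#' @param x the [EvidenceMatrix-class] the ranking came from.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeRankingTSV <- function(table, x, path) {
    ind <- indicatorMatrix(x)[table$gene, , drop = FALSE]
    df <- data.frame(gene = table$gene, ind,
                     score = formatC(table$score, digits = 15,
                                     format = "g"),
                     rank = table$rank,
                     avg_rank = formatC(table$avg_rank, digits = 15,
                                        format = "g"),
                     is_core = as.integer(table$is_core),
                     above_threshold = as.integer(table$above_threshold),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
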