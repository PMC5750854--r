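#' Specification for a synthetic evidence matrix
#'
#' Defines the generative model used in tests and benchmarks: each gene's
#' indicator in category \eqn{i} is Bernoulli with the category's
#' background rate, boosted (additively, capped at 1) for the designated
#' core genes.  Categories thus differ in how strongly they enrich true
#' phenotype genes -- exactly the structure the weight optimization is
#' meant to exploit.
#'
#' @param n_genes total number of genes.
#' @param category_probs background Bernoulli rate per category (length
#'   N, each in [0, 1]).
#' @param core_size number of core genes (<= \code{n_genes}).
#' @param core_boost per-category additive rate boost for core genes
#'   (length N; boosted rates capped at 1).
#' @param seed integer seed.
#' @param categories optional category names; default \code{cat1..catN}.
#' @return a list of class \code{"MatrixSpec"}.
#' @export
matrixSpec <- function(n_genes, category_probs, core_size, core_boost,
                       seed = 1L, categories = NULL) {
    n <- length(category_probs)
    if (length(core_boost) != n)
        stop("'core_boost' must have the same length as 'category_probs'")
    if (n < 2L) stop("at least 2 categories are required")
    if (core_size > n_genes)
        stop("'core_size' cannot exceed 'n_genes'")
    if (any(category_probs < 0 | category_probs > 1))
        stop("'category_probs' must lie in [0, 1]")
    if (is.null(categories)) categories <- paste0("cat", seq_len(n))
    structure(list(n_genes = as.integer(n_genes),
                   category_probs = category_probs,
                   core_size = as.integer(core_size),
                   core_boost = core_boost,
                   seed = as.integer(seed),
                   categories = categories),
              class = "MatrixSpec")
}

#' Generate a synthetic evidence matrix
#'
#' Draws the indicator matrix from the generative model of
#' [matrixSpec()].  Core genes are a random subset of size
#' \code{core_size}; any all-zero row is repaired by switching one
#' uniformly chosen category to 1 (rather than rejection sampling, which
#' would distort per-category rates at low probabilities and need not
#' terminate).  Fully reproducible from \code{spec$seed}.
#'
#' @param spec a [matrixSpec()].
#' @return an [EvidenceMatrix-class]; \code{metadata()} records the spec
#'   and the number of repaired rows.
#' @export
genEvidenceMatrix <- function(spec) {
    stopifnot(inherits(spec, "MatrixSpec"))
    set.seed(spec$seed)
    genes <- sprintf("G%05d", seq_len(spec$n_genes))
    coreIdx <- sort(sample.int(spec$n_genes, spec$core_size))
    n <- length(spec$category_probs)
    rates <- matrix(rep(spec$category_probs, each = spec$n_genes),
                    nrow = spec$n_genes)
    rates[coreIdx, ] <- pmin(sweep(rates[coreIdx, , drop = FALSE], 2,
                                   spec$core_boost, `+`), 1)
    ind <- matrix(as.integer(stats::runif(spec$n_genes * n) <
                             as.vector(rates)),
                  nrow = spec$n_genes,
                  dimnames = list(genes, spec$categories))
    zero <- which(rowSums(ind) == 0L)
    for (i in zero) ind[i, sample.int(n, 1L)] <- 1L
    em <- EvidenceMatrix(ind, core = genes[coreIdx])
    metadata(em)$spec <- spec
    metadata(em)$n_repaired <- length(zero)
    em
}

#' Specification for a synthetic corpus with planted co-occurrences
#'
#' @param planted data.frame with columns \code{alias}, \code{phrase},
#'   \code{count} (intended number of documents containing exactly that
#'   alias-phrase pair; counts >= 0).
#' @param n_noise_docs number of documents containing neither any alias
#'   nor any phrase.
#' @param seed integer seed.
#' @return a list of class \code{"CorpusSpec"}.
#' @export
corpusSpec <- function(planted, n_noise_docs = 0L, seed = 1L) {
    stopifnot(all(c("alias", "phrase", "count") %in% colnames(planted)),
              all(planted$count >= 0), n_noise_docs >= 0)
    structure(list(planted = planted,
                   n_noise_docs = as.integer(n_noise_docs),
                   seed = as.integer(seed)),
              class = "CorpusSpec")
}

## filler vocabulary for synthetic abstracts; screened at generation time
## against the planted aliases/phrases so no accidental co-occurrence can
## arise
.noiseVocab <- c("cell", "protein", "pathway", "signal", "expression",
                 "analysis", "receptor", "neuron", "cortex", "binding",
                 "assay", "cohort", "sample", "variant", "response",
                 "model", "tissue", "membrane", "kinase", "study")

#' Generate a synthetic corpus with planted co-occurrence counts
#'
#' Emits exactly \code{count} documents for every planted (alias,
#' phrase) pair -- each containing that alias and that phrase as whole
#' words and nothing from the rest of the alias/phrase vocabulary --
#' plus \code{n_noise_docs} documents built solely from a filler word
#' list disjoint from all aliases and phrases.  [countHits()] on the
#' result therefore recovers every planted count exactly, which is what
#' makes the screening tests assertable rather than probabilistic.
#'
#' @param spec a [corpusSpec()].
#' @return a corpus data.frame (\code{doc_id}, \code{title},
#'   \code{abstract}).
#' @export
genCorpus <- function(spec) {
    stopifnot(inherits(spec, "CorpusSpec"))
    set.seed(spec$seed)
    reserved <- toupper(unlist(lapply(
        c(spec$planted$alias, spec$planted$phrase), .tokenize)))
    vocab <- .noiseVocab[!toupper(.noiseVocab) %in% reserved]
    if (length(vocab) < 3L)
        stop("planted terms exhaust the filler vocabulary")
    docs <- list()
    k <- 0L
    for (i in seq_len(nrow(spec$planted))) {
        for (j in seq_len(spec$planted$count[i])) {
            k <- k + 1L
            filler <- sample(vocab, 5L, replace = TRUE)
            docs[[k]] <- data.frame(
                doc_id = sprintf("SYN%06d", k),
                title = paste(spec$planted$alias[i],
                              paste(filler[1:2], collapse = " ")),
                abstract = paste(paste(filler[3:5], collapse = " "),
                                 spec$planted$phrase[i]))
        }
    }
    for (j in seq_len(spec$n_noise_docs)) {
        k <- k + 1L
        filler <- sample(vocab, 8L, replace = TRUE)
        docs[[k]] <- data.frame(
            doc_id = sprintf("SYN%06d", k),
            title = paste(filler[1:3], collapse = " "),
            abstract = paste(filler[4:8], collapse = " "))
    }
    if (k == 0L)
        return(data.frame(doc_id = character(), title = character(),
                          abstract = character()))
    do.call(rbind, docs)
}
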