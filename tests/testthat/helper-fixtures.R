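## Shared fixtures built in code.

## Perfectly separable 2-category matrix: every core gene has row (1, 0),
## every non-core gene (0, 1).  Any w1 > w2 puts the core genes in the
## top |C| positions, so the optimal objective is (|C| + 1) / (2 M).
separableMatrix <- function(nCore = 5L, nOther = 15L) {
    genes <- c(sprintf("CORE%02d", seq_len(nCore)),
               sprintf("OTHER%02d", seq_len(nOther)))
    ind <- rbind(
        matrix(c(1L, 0L), nCore, 2, byrow = TRUE),
        matrix(c(0L, 1L), nOther, 2, byrow = TRUE))
    dimnames(ind) <- list(genes, c("strong", "weak"))
    EvidenceMatrix(ind, core = genes[seq_len(nCore)])
}

## Every gene shares one identical evidence row: all scores tie, every
## rank is tie-averaged to (M + 1) / 2, and the objective is constant
## (M + 1) / (2 M) whatever the weights.
identicalRowMatrix <- function(m = 12L, nCore = 3L) {
    genes <- sprintf("G%02d", seq_len(m))
    ind <- matrix(c(1L, 0L, 1L), m, 3, byrow = TRUE,
                  dimnames = list(genes, c("a", "b", "c")))
    EvidenceMatrix(ind, core = genes[seq_len(nCore)])
}

## Random valid matrix via the package generator with mild enrichment.
randomMatrix <- function(seed, nGenes = 80L, nCore = 10L) {
    genEvidenceMatrix(matrixSpec(
        n_genes = nGenes,
        category_probs = c(0.15, 0.3, 0.5),
        core_size = nCore,
        core_boost = c(0.5, 0.2, 0),
        seed = seed))
}

## Random point on the unit simplex (exact unit sum via normalizeWeights).
randomSimplexWeights <- function(n) normalizeWeights(stats::runif(n))

## Write a small evidence CSV and return its path.
writeFixtureCSV <- function(lines, path = tempfile(fileext = ".csv")) {
    writeLines(lines, path)
    path
}

rscriptBin <- function() file.path(R.home("bin"), "Rscript")

cliPath <- function() system.file("scripts", "evirank.R", package = "EviRank")

## child Rscript processes must see the library this package is installed
## in, which may be a session-local .libPaths() entry
libsEnv <- function()
    paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
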