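test_that("combined score is the weighted indicator sum with the right bounds", {
    expect_equal(combinedScore(c(1, 0, 1, 0), c(0.4, 0.3, 0.2, 0.1)), 0.6)
    w <- normalizeWeights(c(2, 1, 1))
    expect_identical(combinedScore(c(1, 1, 1), w), 1.0)
    expect_identical(combinedScore(c(0, 0, 0), w), 0.0)
    expect_error(combinedScore(c(1, 0), c(0.5, 0.3, 0.2)), "length")
    expect_error(combinedScore(c(1, 2), c(0.5, 0.5)), "0 or 1")
    expect_error(combinedScore(c(1, 0), c(0.8, 0.8)), "sum to 1")
    expect_error(combinedScore(c(1, 0), c(1.2, -0.2)), "nonnegative")
})

test_that("normalized weights land exactly on the unit simplex", {
    set.seed(99)
    for (i in 1:200) {
        w <- normalizeWeights(runif(sample(2:6, 1)))
        expect_true(all(w >= 0))
        expect_identical(sum(w), 1)
    }
    expect_error(normalizeWeights(c(0, 0)), "all-zero")
})

test_that("core rank objective implements mean fractional tie-averaged rank", {
    ## M = 10, single core gene strictly on top -> 1/10
    genes <- sprintf("G%02d", 1:10)
    ind <- cbind(a = c(1L, rep(0L, 9)), b = c(0L, rep(1L, 9)))
    rownames(ind) <- genes
    em <- EvidenceMatrix(ind, core = "G01")
    expect_equal(coreRankObjective(em, c(0.9, 0.1)), 0.1)

    ## two core genes at ranks 1 and 2 -> mean(0.1, 0.2) = 0.15
    ind2 <- cbind(a = c(1L, 1L, rep(0L, 8)), b = c(1L, 0L, rep(1L, 8)))
    rownames(ind2) <- genes
    em2 <- EvidenceMatrix(ind2, core = c("G01", "G02"))
    expect_equal(coreRankObjective(em2, c(0.6, 0.4)), 0.15)

    ## M = 4, two genes tied on top, one core -> avg rank 1.5, 1.5/4
    ind3 <- cbind(a = c(1L, 1L, 0L, 0L), b = c(0L, 0L, 1L, 1L))
    rownames(ind3) <- c("A", "B", "C", "D")
    em3 <- EvidenceMatrix(ind3, core = "A")
    expect_equal(coreRankObjective(em3, c(0.7, 0.3)), 0.375)

    noCore <- EvidenceMatrix(
        matrix(c(1L, 0L, 0L, 1L), 2, dimnames = list(c("A", "B"),
                                                     c("x", "y"))))
    expect_error(coreRankObjective(noCore, c(0.5, 0.5)), "empty")
})

test_that("rankings are invariant to positive rescaling of the weights", {
    set.seed(5)
    for (seed in 1:5) {
        em <- randomMatrix(seed)
        w <- randomSimplexWeights(3)
        base <- rankGenes(em, w)
        for (c in c(0.2, 3)) {
            scaled <- rankGenes(em, normalizeWeights(c * w))
            expect_identical(scaled$gene, base$gene)
            expect_identical(scaled$rank, base$rank)
        }
    }
})

test_that("annealing solves the perfectly separable construction", {
    em <- separableMatrix(nCore = 5L, nOther = 15L)
    fit <- simulatedAnnealing(em, saConfig(nTemperatures = 20L, seed = 3L))
    expect_gt(fit$weights[["strong"]], fit$weights[["weak"]])
    expect_equal(fit$objective, (5 + 1) / (2 * 20))
    orc <- gridOracle(em, step = 0.25)
    expect_equal(orc$objective, fit$objective)
})

test_that("identical evidence rows give the constant tie objective", {
    em <- identicalRowMatrix(m = 12L, nCore = 3L)
    for (w in list(c(1, 0, 0), c(0.2, 0.3, 0.5), uniformWeights(3)))
        expect_equal(coreRankObjective(em, normalizeWeights(w)),
                     (12 + 1) / (2 * 12))
    fit <- simulatedAnnealing(em, saConfig(nTemperatures = 5L, seed = 1L))
    expect_equal(fit$objective, (12 + 1) / (2 * 12))
})

test_that("annealing is reproducible from its seed and traces non-increasing bests", {
    em <- randomMatrix(4)
    cfg <- saConfig(nTemperatures = 15L, seed = 77L)
    a <- simulatedAnnealing(em, cfg)
    b <- simulatedAnnealing(em, cfg)
    expect_identical(a$weights, b$weights)
    expect_identical(a$objective, b$objective)
    expect_identical(a$trace, b$trace)
    expect_true(all(diff(a$trace$best) <= 0))
    expect_equal(min(a$trace$best), a$objective)
    expect_true(all(a$weights >= 0))
    expect_identical(sum(a$weights), 1)
})

test_that("grid oracle enumerates the exact simplex compositions", {
    em2 <- separableMatrix(3L, 7L)
    orc <- gridOracle(em2, step = 0.5)
    expect_identical(orc$nEvaluated, 3L)       # (0,1) (.5,.5) (1,0)
    em3 <- identicalRowMatrix()
    orc3 <- gridOracle(em3, step = 0.5)
    expect_identical(orc3$nEvaluated, 6L)      # C(4,2) compositions
    expect_error(gridOracle(em2, step = 0.3), "integer")
})

test_that("annealing never does worse than the grid oracle on small problems", {
    for (seed in 1:5) {
        em <- randomMatrix(seed, nGenes = 60L, nCore = 8L)
        fit <- simulatedAnnealing(em, saConfig(nTemperatures = 40L,
                                               seed = seed))
        orc <- gridOracle(em, step = 0.1)
        expect_lte(fit$objective, orc$objective + 1e-6)
    }
})

test_that("an uninformative extra category never hurts the optimum", {
    set.seed(21)
    for (seed in 1:3) {
        em <- randomMatrix(seed, nGenes = 50L, nCore = 6L)
        ind <- indicatorMatrix(em)
        extra <- cbind(ind, noise = rbinom(nrow(ind), 1L, 0.5))
        emx <- EvidenceMatrix(extra, core = coreGenes(em))
        base <- gridOracle(em, step = 0.1)$objective
        wider <- gridOracle(emx, step = 0.1)$objective
        expect_lte(wider, base + 1e-12)
    }
})

test_that("ranked table is deterministic, ordered, and policy flags are exact", {
    em <- separableMatrix(5L, 15L)
    w <- normalizeWeights(c(0.7, 0.3))
    tab <- rankGenes(em, w, policy = "score-cutoff", value = 0.5)
    expect_identical(tab$rank, seq_len(nrow(tab)))
    expect_true(all(diff(tab$score) <= 0))
    expect_true(all(tab$score >= 0 & tab$score <= 1))
    ## scores 0.7 vs 0.3: flagged set is exactly the core set
    expect_identical(tab$above_threshold, tab$is_core)

    topk <- rankGenes(em, w, policy = "top-k", value = 5)
    expect_identical(sum(topk$above_threshold), 5L)
    expect_identical(topk$gene[topk$above_threshold],
                     sort(coreGenes(em)))

    cover <- rankGenes(em, w, policy = "cover-core", value = 1.0)
    expect_true(all(cover$above_threshold[cover$is_core]))
    expect_identical(min(cover$score[cover$above_threshold]),
                     min(cover$score[cover$is_core]))

    expect_error(rankGenes(em, w, policy = "nonsense"), "arg")
})

test_that("top-k flags everything when k exceeds the gene count", {
    em <- separableMatrix(2L, 3L)
    tab <- rankGenes(em, uniformWeights(2), policy = "top-k", value = 50)
    expect_true(all(tab$above_threshold))
})

test_that("objective lower bound is attained exactly at perfect separation", {
    em <- separableMatrix(4L, 16L)
    expect_equal(coreRankObjective(em, normalizeWeights(c(0.8, 0.2))),
                 (4 + 1) / (2 * 20))
    ## and not under uninformative weights, where every score ties
    expect_equal(coreRankObjective(em, uniformWeights(2)),
                 (20 + 1) / (2 * 20))
})
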