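test_that("query construction is the alias-by-phrase cross product", {
    q <- buildQueries(c("DRD2", "D2R"), "nicotine")
    expect_identical(q$alias, c("DRD2", "D2R"))
    expect_identical(q$phrase, c("nicotine", "nicotine"))
    expect_identical(nrow(buildQueries("CHRNA4")), 4L)
    expect_identical(nrow(buildQueries(c("A", "B", "C"))), 12L)
    expect_identical(defaultPhrases(),
                     c("nicotine", "nicotinic", "tobacco", "smoking"))
    ## deterministic order: alias-major, phrase-minor
    q2 <- buildQueries(c("A", "B"), c("x", "y"))
    expect_identical(paste(q2$alias, q2$phrase),
                     c("A x", "A y", "B x", "B y"))
})

test_that("hit counting is whole-word, case-insensitive co-occurrence", {
    corpus <- data.frame(
        doc_id = c("d1", "d2", "d3"),
        title = c("CHRNA4 variants", "Effects of chrna4 signalling",
                  "A DRD22 study"),
        abstract = c("nicotine dependence cohort",
                     "nicotine-evoked responses",
                     "nicotine exposure with CHRNA44"))
    expect_identical(countHits(corpus, "CHRNA4", "nicotine"), 2L)
    expect_identical(countHits(corpus, "ABSENT", "nicotine"), 0L)
    ## substring of a longer token never matches
    expect_identical(countHits(corpus, "DRD2", "nicotine"), 0L)
    expect_identical(countHits(corpus, "CHRNA4", "NICOTINE"), 2L)
})

test_that("pooling sums per-pair counts, with the worked 106 + 9 example", {
    planted <- data.frame(alias = c("DRD2", "D2R"),
                          phrase = "nicotine",
                          count = c(106L, 9L))
    corpus <- genCorpus(corpusSpec(planted, n_noise_docs = 30L, seed = 8L))
    expect_identical(countHits(corpus, "DRD2", "nicotine"), 106L)
    expect_identical(countHits(corpus, "D2R", "nicotine"), 9L)
    aliases <- data.frame(symbol = "DRD2",
                          aliases = I(list(c("DRD2", "D2R"))))
    screen <- screenLiterature(corpus, aliases)
    expect_identical(screen$report$total_hits, 115L)
    ## planted documents are disjoint, so the dedup variant agrees here
    expect_identical(screen$report$distinct_docs, 115L)
    expect_identical(screen$report$status, "auto_include")

    expect_identical(poolHits(c(2L, 3L)), 5L)
    expect_identical(poolHits(integer()), 0L)
    expect_identical(poolHits(c(a = 106L, b = 9L)), 115L)
})

test_that("dedup variant counts a shared document once, summed variant per pair", {
    corpus <- data.frame(doc_id = "d1",
                         title = "DRD2 and D2R in one report",
                         abstract = "nicotine response")
    aliases <- data.frame(symbol = "DRD2",
                          aliases = I(list(c("DRD2", "D2R"))))
    screen <- screenLiterature(corpus, aliases, phrases = "nicotine")
    expect_identical(screen$report$total_hits, 2L)
    expect_identical(screen$report$distinct_docs, 1L)
    expect_identical(screen$matchedDocs$DRD2, "d1")
})

test_that("triage partitions genes exactly at the hit thresholds", {
    totals <- c(g0 = 0L, g1 = 1L, g4 = 4L, g5 = 5L, g9 = 9L)
    st <- triage(totals, minHits = 5L)
    expect_identical(unname(st),
                     c("excluded", "manual_review", "manual_review",
                       "auto_include", "auto_include"))
    ## min_hits 1 collapses the manual-review class
    expect_false("manual_review" %in% triage(totals, minHits = 1L))
    expect_error(triage(totals, minHits = 0L), "minHits")
    expect_error(triage(c(-1L)), ">= 0")
})

test_that("counts are additive over corpora with disjoint documents", {
    planted <- data.frame(alias = "CHRNA4", phrase = "smoking", count = 3L)
    a <- genCorpus(corpusSpec(planted, n_noise_docs = 5L, seed = 1L))
    b <- genCorpus(corpusSpec(planted, n_noise_docs = 0L, seed = 2L))
    b$doc_id <- paste0("B", b$doc_id)
    expect_identical(countHits(rbind(a, b), "CHRNA4", "smoking"),
                     countHits(a, "CHRNA4", "smoking") +
                     countHits(b, "CHRNA4", "smoking"))
})

test_that("alias table TSV round-trips and always contains the symbol", {
    tab <- data.frame(symbol = c("DRD2", "CHRNA4"),
                      aliases = I(list(c("DRD2", "D2R"), "CHRNA4")))
    path <- tempfile(fileext = ".tsv")
    writeAliasTable(tab, path)
    back <- readAliasTable(path)
    expect_identical(back$symbol, tab$symbol)
    expect_identical(back$aliases[[1]], c("DRD2", "D2R"))
    expect_identical(back$aliases[[2]], "CHRNA4")

    bad <- tempfile(fileext = ".tsv")
    writeLines(c("symbol\taliases", "DRD2\tD2R", "drd2\tX"), bad)
    expect_error(readAliasTable(bad), "duplicate")
})

test_that("corpus formats round-trip through both MEDLINE and JSON-lines", {
    corpus <- data.frame(
        doc_id = c("100", "200"),
        title = c("CHRNB2 subunit function", "A smoking cessation trial"),
        abstract = c("nicotinic receptors in cortex",
                     "tobacco use outcomes"))
    for (fmt in c("jsonl", "medline")) {
        path <- tempfile()
        writeCorpus(corpus, path, fmt)
        back <- readCorpus(path)
        expect_identical(back$doc_id, corpus$doc_id)
        expect_identical(back$title, corpus$title)
        expect_identical(back$abstract, corpus$abstract)
    }
})

test_that("MEDLINE continuation lines fold into the open field", {
    path <- tempfile()
    writeLines(c("PMID- 42",
                 "TI  - Long title about",
                 "      nicotinic receptors",
                 "AB  - First abstract sentence.",
                 "      Second sentence mentions CHRNA7.",
                 ""), path)
    corpus <- readCorpus(path, format = "medline")
    expect_identical(corpus$title, "Long title about nicotinic receptors")
    expect_match(corpus$abstract, "Second sentence mentions CHRNA7")
    expect_identical(countHits(corpus, "CHRNA7", "nicotinic"), 1L)
})
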