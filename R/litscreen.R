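#' Tokenize text for whole-word matching
#'
#' Hit counting treats a document as a bag of tokens: text is uppercased
#' and split on every non-alphanumeric character (hyphens separate), so
#' "DRD2" never matches inside "DRD22" but matches "drd2-mediated".
#' Multi-token terms match as a contiguous token run.
#'
#' @param x a character string.
#' @return character vector of uppercase tokens.
#' @keywords internal
.tokenize <- function(x) {
    t <- strsplit(toupper(x), "[^A-Z0-9]+")[[1]]
    t[nzchar(t)]
}

.containsTerm <- function(tokens, term) {
    tt <- .tokenize(term)
    nt <- length(tt)
    if (nt == 0L) return(FALSE)
    if (nt == 1L) return(tt %in% tokens)
    if (length(tokens) < nt) return(FALSE)
    for (i in seq_len(length(tokens) - nt + 1L))
        if (all(tokens[i:(i + nt - 1L)] == tt)) return(TRUE)
    FALSE
}

#' Default co-occurrence phrases
#'
#' The four phenotype phrases paired with every gene alias when screening
#' the literature for nicotine/smoking involvement.
#' @return character vector of the four phrases.
#' @export
defaultPhrases <- function() c("nicotine", "nicotinic", "tobacco", "smoking")

#' Build per-alias co-occurrence queries
#'
#' For one gene, the query set is the full cross product of its aliases
#' and the phenotype phrases; each pair is searched separately and the
#' hits are pooled.  For example DRD2 with aliases DRD2 and D2R and the
#' phrase "nicotine" yields the two queries (DRD2, nicotine) and
#' (D2R, nicotine).
#'
#' @param aliases character vector of aliases for one gene (non-empty).
#' @param phrases character vector of phrases; defaults to
#'   [defaultPhrases()].
#' @return a data.frame with columns \code{alias}, \code{phrase} in
#'   deterministic order (alias order, then phrase order).
#' @export
buildQueries <- function(aliases, phrases = defaultPhrases()) {
    stopifnot(length(aliases) >= 1L, length(phrases) >= 1L)
    data.frame(alias = rep(aliases, each = length(phrases)),
               phrase = rep(phrases, times = length(aliases)))
}

#' Read a gene-alias table
#'
#' Two-column TSV: normalized gene symbol, then the pipe-separated alias
#' set.  The symbol itself is always included among its aliases; symbols
#' must be unique.
#'
#' @param path TSV path (header \code{symbol}, \code{aliases}).
#' @return a data.frame with columns \code{symbol} (character) and
#'   \code{aliases} (list of character vectors).
#' @export
readAliasTable <- function(path) {
    df <- utils::read.delim(path, colClasses = "character",
                            fileEncoding = "UTF-8")
    stopifnot(all(c("symbol", "aliases") %in% colnames(df)))
    symbols <- vapply(df$symbol, normalizeSymbol, "", USE.NAMES = FALSE)
    if (anyDuplicated(symbols))
        stop("duplicate symbols in alias table: ",
             paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
    aliases <- lapply(seq_along(symbols), function(i) {
        al <- strsplit(df$aliases[i], "|", fixed = TRUE)[[1]]
        al <- al[nzchar(trimws(al))]
        unique(c(symbols[i],
                 vapply(al, normalizeSymbol, "", USE.NAMES = FALSE)))
    })
    data.frame(symbol = symbols,
               aliases = I(aliases))
}

#' @rdname readAliasTable
#' @param x an alias table data.frame as returned by [readAliasTable()].
#' @export
writeAliasTable <- function(x, path) {
    df <- data.frame(symbol = x$symbol,
                     aliases = vapply(x$aliases, paste, "",
                                      collapse = "|"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a local document corpus
#'
#' Two interchangeable plain-text formats stand in for a PubMed snapshot
#' at desk scale: JSON-lines (one object \code{\{"id","title","abstract"\}}
#' per line) and MEDLINE flat format (line-tagged \code{PMID-}, \code{TI-},
#' \code{AB-} fields, continuation lines indented, records separated by
#' blank lines).
#'
#' @param path input file.
#' @param format \code{"jsonl"} or \code{"medline"}; the default guesses
#'   from the first non-blank character (\code{\{} means JSON-lines).
#' @return a data.frame with columns \code{doc_id}, \code{title},
#'   \code{abstract}; doc_ids must be unique.
#' @export
readCorpus <- function(path, format = c("auto", "jsonl", "medline")) {
    format <- match.arg(format)
    lines <- readLines(path, encoding = "UTF-8")
    if (format == "auto") {
        probe <- trimws(lines[nzchar(trimws(lines))][1])
        format <- if (startsWith(probe, "{")) "jsonl" else "medline"
    }
    corpus <- if (format == "jsonl") .readJSONL(lines) else .readMedline(lines)
    if (anyDuplicated(corpus$doc_id))
        stop("duplicate document ids in corpus: ", path)
    corpus
}

.readJSONL <- function(lines) {
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
    data.frame(
        doc_id = vapply(recs, function(r) as.character(r$id), ""),
        title = vapply(recs, function(r) {
            if (is.null(r$title)) "" else as.character(r$title)
        }, ""),
        abstract = vapply(recs, function(r) {
            if (is.null(r$abstract)) "" else as.character(r$abstract)
        }, ""))
}

.readMedline <- function(lines) {
    ids <- titles <- abstracts <- character()
    cur <- list(PMID = "", TI = "", AB = "")
    field <- NULL
    flush <- function() {
        if (nzchar(cur$PMID)) {
            ids <<- c(ids, cur$PMID)
            titles <<- c(titles, cur$TI)
            abstracts <<- c(abstracts, cur$AB)
        }
        cur <<- list(PMID = "", TI = "", AB = "")
    }
    for (ln in lines) {
        if (!nzchar(trimws(ln))) {
            flush(); field <- NULL; next
        }
        if (grepl("^[A-Z]{2,4}\\s*- ", ln)) {
            tag <- trimws(sub("^([A-Z]{2,4})\\s*- .*$", "\\1", ln))
            val <- sub("^[A-Z]{2,4}\\s*- ", "", ln)
            field <- tag
            if (tag %in% names(cur))
                cur[[tag]] <- if (nzchar(cur[[tag]]))
                    paste(cur[[tag]], val) else val
        } else if (grepl("^\\s+", ln) && !is.null(field) &&
                   field %in% names(cur)) {
            cur[[field]] <- paste(cur[[field]], trimws(ln))
        }
    }
    flush()
    data.frame(doc_id = ids, title = titles, abstract = abstracts)
}

#' Write a corpus
#'
#' Inverse of [readCorpus()] for either format.
#' @param corpus a corpus data.frame (\code{doc_id}, \code{title},
#'   \code{abstract}).
#' @param path output file.
#' @param format \code{"jsonl"} or \code{"medline"}.
#' @return invisibly, \code{path}.
#' @export
writeCorpus <- function(corpus, path, format = c("jsonl", "medline")) {
    format <- match.arg(format)
    if (format == "jsonl") {
        lines <- vapply(seq_len(nrow(corpus)), function(i) {
            jsonlite::toJSON(list(id = corpus$doc_id[i],
                                  title = corpus$title[i],
                                  abstract = corpus$abstract[i]),
                             auto_unbox = TRUE)
        }, "")
    } else {
        lines <- unlist(lapply(seq_len(nrow(corpus)), function(i) {
            c(paste0("PMID- ", corpus$doc_id[i]),
              paste0("TI  - ", corpus$title[i]),
              paste0("AB  - ", corpus$abstract[i]),
              "")
        }))
    }
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

.corpusTokens <- function(corpus) {
    lapply(paste(corpus$title, corpus$abstract),
           function(tx) .tokenize(tx))
}

#' Count co-occurrence hits for one (alias, phrase) query
#'
#' A hit is a document whose title+abstract contains both the alias and
#' the phrase as case-insensitive whole-word token matches (see
#' [.tokenize()] semantics: tokens split on non-alphanumerics, hyphen a
#' separator).
#'
#' @param corpus a corpus data.frame from [readCorpus()] or
#'   [genCorpus()].
#' @param alias gene alias to match.
#' @param phrase phenotype phrase to match.
#' @return integer hit count.
#' @export
countHits <- function(corpus, alias, phrase) {
    toks <- .corpusTokens(corpus)
    sum(vapply(toks, function(tk)
        .containsTerm(tk, alias) && .containsTerm(tk, phrase), TRUE))
}

#' Pool per-query hit counts for a gene
#'
#' The gene's total is the arithmetic sum over all its (alias, phrase)
#' queries, mirroring the convention of summing separately-returned
#' query results (e.g. DRD2-alias counts 106 and 9 pool to 115).  A
#' document matched by several pairs therefore counts once per pair; the
#' de-duplicated distinct-document count is reported alongside by
#' [screenLiterature()].
#'
#' @param counts integer vector of per-pair hit counts.
#' @return the pooled total.
#' @export
poolHits <- function(counts) {
    stopifnot(all(counts >= 0))
    as.integer(sum(counts))
}

#' Triage genes by pooled literature hits
#'
#' Three-way classification on the pooled hit totals: at least
#' \code{minHits} (default 5) co-occurrence hits auto-includes a gene;
#' 1 to \code{minHits - 1} hits sends it to the manual-review worklist
#' (the abstracts are few enough to read); zero hits excludes it.
#'
#' @param totals named integer vector of pooled hits per gene.
#' @param minHits auto-inclusion threshold (>= 1).
#' @return character vector of statuses (\code{auto_include},
#'   \code{manual_review}, \code{excluded}) parallel to \code{totals}.
#' @export
triage <- function(totals, minHits = 5L) {
    stopifnot(minHits >= 1L, all(totals >= 0))
    ifelse(totals >= minHits, "auto_include",
           ifelse(totals >= 1L, "manual_review", "excluded"))
}

#' Screen a corpus for gene-phenotype co-occurrence
#'
#' Runs the whole literature-collection stage on a local corpus: builds
#' the alias-by-phrase query cross product per gene, counts whole-word
#' co-occurrence hits per query, pools them (summed convention, with the
#' distinct-document variant alongside) and triages every gene.
#'
#' @param corpus a corpus data.frame.
#' @param aliasTable an alias table from [readAliasTable()] (columns
#'   \code{symbol}, \code{aliases}).
#' @param phrases phenotype phrases; default [defaultPhrases()].
#' @param minHits triage threshold, default 5.
#' @return a list with
#'   \describe{
#'     \item{report}{data.frame \code{symbol}, \code{total_hits} (summed
#'       over pairs), \code{distinct_docs} (de-duplicated), \code{status}.}
#'     \item{pairCounts}{data.frame \code{symbol}, \code{alias},
#'       \code{phrase}, \code{hits}.}
#'     \item{matchedDocs}{named list of matched doc_id vectors per gene
#'       (the manual-review worklist).}
#'   }
#' @export
screenLiterature <- function(corpus, aliasTable,
                             phrases = defaultPhrases(), minHits = 5L) {
    stopifnot(all(c("symbol", "aliases") %in% colnames(aliasTable)),
              length(phrases) >= 1L)
    toks <- .corpusTokens(corpus)
    terms <- unique(c(unlist(aliasTable$aliases), phrases))
    hitSets <- lapply(terms, function(tm)
        which(vapply(toks, .containsTerm, TRUE, term = tm)))
    names(hitSets) <- toupper(terms)

    pc <- list()
    totals <- integer(nrow(aliasTable))
    distinct <- integer(nrow(aliasTable))
    matched <- vector("list", nrow(aliasTable))
    for (i in seq_len(nrow(aliasTable))) {
        q <- buildQueries(aliasTable$aliases[[i]], phrases)
        docs <- integer()
        hits <- integer(nrow(q))
        for (k in seq_len(nrow(q))) {
            both <- intersect(hitSets[[toupper(q$alias[k])]],
                              hitSets[[toupper(q$phrase[k])]])
            hits[k] <- length(both)
            docs <- c(docs, both)
        }
        pc[[i]] <- cbind(symbol = aliasTable$symbol[i], q, hits = hits)
        totals[i] <- poolHits(hits)
        distinct[i] <- length(unique(docs))
        matched[[i]] <- corpus$doc_id[sort(unique(docs))]
    }
    names(matched) <- aliasTable$symbol
    list(report = data.frame(symbol = aliasTable$symbol,
                             total_hits = totals,
                             distinct_docs = distinct,
                             status = triage(totals, minHits)),
         pairCounts = do.call(rbind, pc),
         matchedDocs = matched)
}

#' Write the triage report
#'
#' @param screen result of [screenLiterature()].
#' @param dir output directory; writes \code{triage.tsv} and
#'   \code{matched_docs.json}.
#' @return invisibly, the two paths.
#' @export
writeTriage <- function(screen, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- file.path(dir, "triage.tsv")
    utils::write.table(screen$report, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    js <- file.path(dir, "matched_docs.json")
    jsonlite::write_json(screen$matchedDocs, js, auto_unbox = FALSE)
    invisible(c(tsv, js))
}
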