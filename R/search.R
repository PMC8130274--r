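# Frequency-weighted search over aggregate records.
#
# Results are ranked by a tradeoff between query matching and the logarithm
# of the number of occurrences: combined = match * (1 + ln(occurrences)).
# Matching is disjunctive token matching (partial matches score, lower),
# with inverse-document-frequency weighting and a field weight favouring
# the question text, plus a whole-query exact-question bonus.

#' Tokenize text for indexing and querying
#'
#' Lowercases and splits on non-alphanumeric characters; no stemming, no
#' stop words. Returns unique tokens.
#'
#' @param x character vector.
#' @return character vector of unique tokens.
#' @export
tokenize <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(character(0))
  toks <- unlist(strsplit(tolower(norm_text(x)), "[^[:alnum:]]+"))
  unique(toks[nzchar(toks)])
}

# weighted text fields of a record's element
FIELD_WEIGHTS <- c(question = 2.0, name = 1.0, description = 0.5,
                   decode = 0.5, alias = 0.5)

record_fields <- function(element, config) {
  decodes <- character(0)
  collect_decodes <- function(el) {
    if (el$kind == "CodeListItem") {
      d <- el$translated_texts$Decode
      if (!is.null(d)) decodes <<- c(decodes, unname(d))
    }
    for (ch in el$children) collect_decodes(ch)
  }
  collect_decodes(element)
  list(
    question = english_text(element, "Question", config = config),
    name = unname(element$attributes["Name"]),
    description = english_text(element, "Description", config = config),
    decode = if (length(decodes)) paste(decodes, collapse = " ") else NA_character_,
    alias = if (nrow(element$aliases)) paste(element$aliases$name, collapse = " ")
            else NA_character_
  )
}

#' Build a search index over a store
#'
#' Tokenized inverted index over the text fields of every aggregate record
#' (English question, name, description, code-list item decodes, alias
#' names), per resource kind. Rebuilding the index on the same store yields
#' identical search results.
#'
#' @param store an [mdr_store()].
#' @param kinds resource kinds to index (default: all configured kinds).
#' @return an object of class `mdr_index`.
#' @export
build_index <- function(store, kinds = NULL) {
  stopifnot(inherits(store, "mdr_store"))
  config <- store$config
  kinds <- kinds %||% config$kinds
  per_kind <- list()
  for (kind in kinds) {
    recs <- list_records(store, kind)
    n <- length(recs)
    if (n == 0) {
      per_kind[[kind]] <- list(n = 0L, keys = character(0))
      next
    }
    keys <- vapply(recs, function(r) r$key, character(1))
    occs <- vapply(recs, function(r) r$occurrences, integer(1))
    fields <- lapply(recs, function(r) record_fields(r$element, config))
    questions <- vapply(fields, function(f) f$question %||% NA_character_, character(1))
    # token -> (record index, best field weight); and postings token -> indices
    tokmaps <- vector("list", n)
    postings <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      tw <- numeric(0)
      for (fname in names(FIELD_WEIGHTS)) {
        ftoks <- tokenize(fields[[i]][[fname]])
        if (length(ftoks) == 0) next
        w <- FIELD_WEIGHTS[[fname]]
        for (tk in ftoks) {
          cur <- tw[tk]
          tw[tk] <- if (is.na(cur)) w else max(cur, w)
        }
      }
      tokmaps[[i]] <- tw
      for (tk in names(tw)) {
        assign(tk, c(get0(tk, envir = postings, inherits = FALSE), i), envir = postings)
      }
    }
    df <- vapply(ls(postings), function(tk) length(get(tk, envir = postings)),
                 integer(1))
    per_kind[[kind]] <- list(
      n = n, keys = keys, occurrences = occs, questions = questions,
      question_norm = ifelse(is.na(questions), NA, tolower(norm_text(
        ifelse(is.na(questions), "", questions)))),
      tokmaps = tokmaps, postings = postings,
      df = df, fields = fields)
  }
  structure(list(kinds = per_kind, config = config), class = "mdr_index")
}

idf_of <- function(ki, token) {
  df <- ki$df[token]
  if (is.na(df)) return(NA_real_)
  log(1 + ki$n / df)
}

# score one indexed record against pre-tokenized query tokens
score_record <- function(ki, i, qtokens, query_norm) {
  tw <- ki$tokmaps[[i]]
  s <- 0
  matched <- character(0)
  for (tk in qtokens) {
    w <- unname(tw[tk])
    if (!is.na(w)) {
      s <- s + log(1 + ki$n / ki$df[[tk]]) * w
      matched <- c(matched, tk)
    }
  }
  if (s > 0 && !is.na(ki$question_norm[i]) && identical(ki$question_norm[i], query_norm)) {
    s <- 2 * s
  }
  list(score = s, matched = matched)
}

#' Match score of a query against one record
#'
#' Disjunctive (OR) token scoring: for each query token present in the
#' record, `idf(token) * field_weight` is added, where
#' `idf = ln(1 + U/df)` (U = unique records of the kind in the index, df =
#' records containing the token) and the field weight is the maximum over
#' the fields containing the token (question 2.0, name 1.0, others 0.5). A
#' whole-query exact match of the question field doubles the sum. Records
#' sharing no token score 0.
#'
#' @param index an `mdr_index`.
#' @param query query string (non-empty after tokenization).
#' @param key canonical key of the record to score.
#' @param kind resource kind of the record.
#' @return a non-negative number.
#' @export
match_score <- function(index, query, key, kind = "Item") {
  stopifnot(inherits(index, "mdr_index"))
  qtokens <- tokenize(query)
  if (length(qtokens) == 0) {
    odmdr_error("mdr_input_error", "query is empty after tokenization")
  }
  ki <- index$kinds[[kind]]
  if (is.null(ki)) odmdr_error("odm_kind_error", sprintf("kind not indexed: %s", kind))
  i <- match(key, ki$keys)
  if (is.na(i)) odmdr_error("mdr_not_found", sprintf("no indexed record with key %s", key))
  score_record(ki, i, qtokens, tolower(norm_text(query)))$score
}

#' Search the index
#'
#' Ranks all records of a kind with positive match score by
#' `combined = match_score * (1 + ln(occurrences))`, descending; ties are
#' broken by (occurrences desc, key asc). `total_matches` counts all
#' matching records before truncation to `limit`.
#'
#' @param index an `mdr_index`.
#' @param query query string.
#' @param kind resource kind to search (default `"Item"`).
#' @param limit maximum number of hits returned (`Inf` for all).
#' @return a list with `hits` (a [tibble::tibble] with columns `key`,
#'   `kind`, `match_score`, `occurrences`, `combined_score`,
#'   `matched_fields`, `question`) and `total_matches`.
#' @export
search <- function(index, query, kind = "Item", limit = 20L) {
  stopifnot(inherits(index, "mdr_index"), limit >= 1)
  qtokens <- tokenize(query)
  if (length(qtokens) == 0) {
    odmdr_error("mdr_input_error", "query is empty after tokenization")
  }
  ki <- index$kinds[[kind]]
  if (is.null(ki)) odmdr_error("odm_kind_error", sprintf("kind not indexed: %s", kind))
  empty <- tibble::tibble(key = character(0), kind = character(0),
                          match_score = numeric(0), occurrences = integer(0),
                          combined_score = numeric(0), matched_fields = list(),
                          question = character(0))
  if (ki$n == 0) return(list(hits = empty, total_matches = 0L))
  cand <- sort(unique(unlist(lapply(qtokens, function(tk) {
    get0(tk, envir = ki$postings, inherits = FALSE)
  }))))
  if (length(cand) == 0) return(list(hits = empty, total_matches = 0L))
  query_norm <- tolower(norm_text(query))
  scored <- lapply(cand, function(i) score_record(ki, i, qtokens, query_norm))
  ms <- vapply(scored, function(s) s$score, numeric(1))
  keep <- ms > 0
  cand <- cand[keep]; ms <- ms[keep]; scored <- scored[keep]
  total <- length(cand)
  if (total == 0) return(list(hits = empty, total_matches = 0L))
  occ <- ki$occurrences[cand]
  combined <- ms * (1 + log(occ))
  ord <- order(-combined, -occ, ki$keys[cand], method = "radix")
  take <- ord[seq_len(min(limit, total))]
  hits <- tibble::tibble(
    key = ki$keys[cand[take]],
    kind = kind,
    match_score = ms[take],
    occurrences = occ[take],
    combined_score = combined[take],
    matched_fields = lapply(scored[take], function(s) s$matched),
    question = ki$questions[cand[take]])
  list(hits = hits, total_matches = total)
}
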