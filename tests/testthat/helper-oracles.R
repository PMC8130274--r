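# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation paths they
# verify: plain loops, direct formulas, full scans.

# --- tree walk oracle: multiset of kinds via plain recursion ---------------
oracle_kind_multiset <- function(document) {
  kinds <- character(0)
  rec <- function(el) {
    kinds <<- c(kinds, el$kind)
    for (ch in el$children) rec(ch)
  }
  for (r in document$roots) rec(r)
  sort(kinds)
}

# --- brute-force dedup oracle: canonical serialization string -> count -----
oracle_dedup_counts <- function(documents, config = odm_config()) {
  counts <- new.env(parent = emptyenv())
  visit <- function(el) {
    s <- canonical_serialize(el, config = config)
    assign(s, (get0(s, envir = counts, inherits = FALSE) %||% 0L) + 1L,
           envir = counts)
    for (ch in el$children) visit(ch)
  }
  for (doc in documents) for (r in doc$roots) visit(r)
  counts
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# --- full-scan search scoring oracle ---------------------------------------
# Recomputes match and combined scores from the raw store records with its
# own tokenizer, field extraction and arithmetic, then sorts.
oracle_tokens <- function(s) {
  s <- s[!is.na(s)]
  if (length(s) == 0) return(character(0))
  s <- stringi::stri_trans_nfc(tolower(s))
  toks <- unlist(strsplit(s, "[^[:alnum:]]+"))
  unique(toks[nzchar(toks)])
}

oracle_record_text <- function(el) {
  decodes <- character(0)
  grab <- function(e) {
    if (e$kind == "CodeListItem" && !is.null(e$translated_texts$Decode)) {
      decodes <<- c(decodes, unname(e$translated_texts$Decode))
    }
    for (ch in e$children) grab(ch)
  }
  grab(el)
  q <- el$translated_texts$Question
  en <- if (!is.null(q)) {
    hit <- which(names(q) == "en" | startsWith(names(q), "en-"))
    if (length(hit)) unname(q[hit[1]])
    else if (all(names(q) == "")) unname(q[[1]]) else NA_character_
  } else NA_character_
  d <- el$translated_texts$Description
  en_d <- if (!is.null(d)) {
    hit <- which(names(d) == "en" | startsWith(names(d), "en-"))
    if (length(hit)) unname(d[hit[1]])
    else if (all(names(d) == "")) unname(d[[1]]) else NA_character_
  } else NA_character_
  list(question = en, name = unname(el$attributes["Name"]),
       description = en_d,
       decode = if (length(decodes)) paste(decodes, collapse = " ") else NA,
       alias = if (nrow(el$aliases)) paste(el$aliases$name, collapse = " ") else NA)
}

oracle_search <- function(store, query, kind = "Item") {
  recs <- list_records(store, kind)
  U <- length(recs)
  qt <- oracle_tokens(query)
  weights <- c(question = 2, name = 1, description = 0.5, decode = 0.5, alias = 0.5)
  texts <- lapply(recs, function(r) oracle_record_text(r$element))
  tokens_by_field <- lapply(texts, function(tx) lapply(tx, oracle_tokens))
  df <- sapply(qt, function(tk) {
    sum(sapply(tokens_by_field, function(tf) any(sapply(tf, function(v) tk %in% v))))
  })
  norm_q <- trimws(gsub("[[:space:]]+", " ", tolower(stringi::stri_trans_nfc(query))))
  rows <- lapply(seq_along(recs), function(i) {
    s <- 0
    for (tk in qt) {
      w <- weights[sapply(tokens_by_field[[i]], function(v) tk %in% v)]
      if (length(w)) s <- s + log(1 + U / df[[tk]]) * max(w)
    }
    qtext <- texts[[i]]$question
    if (s > 0 && !is.na(qtext) &&
        trimws(gsub("[[:space:]]+", " ", tolower(stringi::stri_trans_nfc(qtext)))) == norm_q) {
      s <- 2 * s
    }
    data.frame(key = recs[[i]]$key, match_score = s,
               occurrences = recs[[i]]$occurrences,
               combined_score = s * (1 + log(recs[[i]]$occurrences)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$match_score > 0, , drop = FALSE]
  out[order(-out$combined_score, -out$occurrences, out$key, method = "radix"), ,
      drop = FALSE]
}

# --- sort-and-scan cumulative curve oracle ---------------------------------
oracle_curve <- function(occ) {
  if (length(occ) == 0) return(integer(0))
  occ <- sort(occ, decreasing = TRUE)
  sapply(seq_len(max(occ)), function(t) {
    n <- 0L
    for (o in occ) if (o >= t) n <- n + 1L
    n
  })
}

# --- two-pass variance oracle ----------------------------------------------
oracle_mean_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / (n - 1)
  c(mean = m, sd = sqrt(v))
}

# --- brute-force ordinal Krippendorff alpha --------------------------------
# Direct enumeration of ordered pairable pairs and loop-built distances.
oracle_alpha <- function(m, metric = "ordinal") {
  K <- 5L
  o <- matrix(0, K, K)
  for (u in seq_len(nrow(m))) {
    v <- m[u, ]
    v <- v[!is.na(v)]
    mu <- length(v)
    if (mu < 2) next
    for (i in seq_len(mu)) {
      for (j in seq_len(mu)) {
        if (i != j) o[v[i], v[j]] <- o[v[i], v[j]] + 1 / (mu - 1)
      }
    }
  }
  n_c <- rowSums(o)
  n <- sum(n_c)
  d2 <- matrix(0, K, K)
  for (a in seq_len(K)) {
    for (b in seq_len(K)) {
      if (a == b) next
      if (metric == "ordinal") {
        s <- 0
        for (g in min(a, b):max(a, b)) s <- s + n_c[g]
        d2[a, b] <- (s - (n_c[a] + n_c[b]) / 2)^2
      } else if (metric == "nominal") {
        d2[a, b] <- 1
      } else {
        d2[a, b] <- (a - b)^2
      }
    }
  }
  Do <- 0; De <- 0
  for (a in seq_len(K)) {
    for (b in seq_len(K)) {
      Do <- Do + o[a, b] * d2[a, b]
      De <- De + n_c[a] * n_c[b] * d2[a, b]
    }
  }
  if (De == 0) return(if (Do == 0) 1 else NA_real_)
  1 - (Do / n) / (De / (n * (n - 1)))
}

# random rating matrix with missing values, for oracle comparisons
random_rating_matrix <- function(n_units, n_raters, missing_rate = 0.1, seed = 1) {
  set.seed(seed)
  m <- matrix(sample.int(5L, n_units * n_raters, replace = TRUE),
              n_units, n_raters)
  m[matrix(runif(length(m)) < missing_rate, n_units, n_raters)] <- NA_integer_
  rating_matrix(m)
}
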