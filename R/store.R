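# The aggregation store: one record per unique definition.
#
# Ingesting a document decomposes it into atomic elements; each element
# either creates a new aggregate record (occurrences = 1) or increments an
# existing record, while the original occurrences (document id + path) are
# kept track of. The number of occurrences drives frequency-based scoring
# during search.

#' Create an empty metadata repository store
#'
#' @param config see [odm_config()]; fixes the equivalence settings used for
#'   every document ingested into this store.
#' @return an object of class `mdr_store`.
#' @export
mdr_store <- function(config = odm_config()) {
  env <- new.env(parent = emptyenv())
  env$records <- new.env(parent = emptyenv())   # digest -> record
  env$documents <- character(0)
  env$kind_ingested <- stats::setNames(integer(length(config$kinds)), config$kinds)
  structure(list(env = env, config = as_odm_config(config)), class = "mdr_store")
}

#' @export
print.mdr_store <- function(x, ...) {
  n <- length(ls(x$env$records))
  cat(sprintf("<mdr_store: %d documents, %d unique definitions, %d ingested elements>\n",
              length(x$env$documents), n, sum(x$env$kind_ingested)))
  invisible(x)
}

#' Ingest a document into the store
#'
#' Splits the document into atomic elements and aggregates equivalent
#' elements: every decomposed element either creates a new aggregate record
#' or increments an existing record's occurrence count and appends its
#' provenance. The operation is atomic: on any error the store is unchanged.
#' A definition used twice in one document counts twice (occurrences count
#' usages).
#'
#' @param store an [mdr_store()].
#' @param document an [odm_document()] whose `document_id` is not yet in the
#'   store; re-ingesting a known id raises a classed error and changes
#'   nothing.
#' @return an ingest report: a [tibble::tibble] with one row per kind and
#'   columns `kind`, `elements_seen`, `new_uniques`, `merged_into_existing`.
#' @export
ingest_document <- function(store, document) {
  stopifnot(inherits(store, "mdr_store"), inherits(document, "odm_document"))
  env <- store$env
  if (document$document_id %in% env$documents) {
    odmdr_error("mdr_duplicate_document",
                sprintf("document '%s' is already in the store", document$document_id))
  }
  nodes <- keyed_decompose(document, config = store$config)  # may fail: store untouched
  kinds <- store$config$kinds
  seen <- new_u <- merged <- stats::setNames(integer(length(kinds)), kinds)
  for (nd in nodes) {
    rec <- get0(nd$key, envir = env$records, inherits = FALSE)
    seen[nd$kind] <- seen[nd$kind] + 1L
    if (is.null(rec)) {
      new_u[nd$kind] <- new_u[nd$kind] + 1L
      assign(nd$key, list(key = nd$key, kind = nd$kind, element = nd$element,
                          occurrences = 1L,
                          provenance = list(list(document_id = document$document_id,
                                                 path = nd$path))),
             envir = env$records)
    } else {
      merged[nd$kind] <- merged[nd$kind] + 1L
      rec$occurrences <- rec$occurrences + 1L
      rec$provenance[[length(rec$provenance) + 1L]] <-
        list(document_id = document$document_id, path = nd$path)
      assign(nd$key, rec, envir = env$records)
    }
  }
  env$documents <- c(env$documents, document$document_id)
  env$kind_ingested <- env$kind_ingested + seen
  tibble::tibble(kind = kinds, elements_seen = unname(seen),
                 new_uniques = unname(new_u),
                 merged_into_existing = unname(merged))
}

#' Retrieve one aggregate record by canonical key
#'
#' @param store an [mdr_store()].
#' @param key canonical key digest.
#' @return the aggregate record (a list with `key`, `kind`, `element`,
#'   `occurrences`, `provenance`), or `NULL` when the key is unknown. The
#'   returned copy is independent of the store.
#' @export
get_record <- function(store, key) {
  stopifnot(inherits(store, "mdr_store"))
  get0(key, envir = store$env$records, inherits = FALSE)
}

#' List aggregate records of one kind
#'
#' @param store an [mdr_store()].
#' @param kind resource kind.
#' @param min_occurrences only records with at least this many occurrences.
#' @return list of records sorted by (occurrences desc, key asc).
#' @export
list_records <- function(store, kind, min_occurrences = 1L) {
  stopifnot(inherits(store, "mdr_store"))
  if (!kind %in% store$config$kinds) {
    odmdr_error("odm_kind_error", sprintf("unknown resource kind: %s", kind))
  }
  keys <- ls(store$env$records, sorted = TRUE)
  recs <- lapply(keys, get0, envir = store$env$records, inherits = FALSE)
  recs <- Filter(function(r) r$kind == kind && r$occurrences >= min_occurrences, recs)
  if (length(recs) == 0) return(list())
  occ <- vapply(recs, function(r) r$occurrences, integer(1))
  recs[order(-occ)]  # keys already ascending; order() is stable
}

#' Corpus statistics: totals, uniques and reuse per kind
#'
#' Reuse is the ratio of total and unique resources, i.e. the average number
#' of equivalent definitions aggregated into one record. Kinds with zero
#' records report `NA` reuse (undefined, not zero).
#'
#' @param store an [mdr_store()].
#' @return a [tibble::tibble] with columns `kind`, `total`, `unique`,
#'   `reuse`, plus a final `Total` row with the grand totals.
#' @export
corpus_statistics <- function(store) {
  stopifnot(inherits(store, "mdr_store"))
  kinds <- store$config$kinds
  uniq <- stats::setNames(integer(length(kinds)), kinds)
  tot <- stats::setNames(integer(length(kinds)), kinds)
  for (key in ls(store$env$records)) {
    r <- get0(key, envir = store$env$records, inherits = FALSE)
    uniq[r$kind] <- uniq[r$kind] + 1L
    tot[r$kind] <- tot[r$kind] + r$occurrences
  }
  stats <- tibble::tibble(
    kind = c(kinds, "Total"),
    total = c(unname(tot), sum(tot)),
    unique = c(unname(uniq), sum(uniq)))
  stats$reuse <- ifelse(stats$unique > 0, stats$total / stats$unique, NA_real_)
  stats
}

#' Export semantic codes for a set of items
#'
#' Looks up item definitions by OID or canonical key and returns their alias
#' pairs (e.g. UMLS codes), mirroring the transfer of semantic annotations
#' from a shared metadata pool into a local data dictionary. The report
#' includes an expert-time-saved estimate: coding a single item takes a
#' medical expert about one minute, so each item with at least one code
#' saves `minutes_per_item` minutes of manual work.
#'
#' @param store an [mdr_store()].
#' @param identifiers character vector of item identifiers.
#' @param by `"oid"` (match item OIDs; an OID carried by several unique
#'   records contributes the union of their codes) or `"key"` (canonical
#'   keys).
#' @param minutes_per_item minutes of expert work saved per coded item.
#' @return a list: `codes` (named list, identifier to data frame with
#'   columns `context`, `code`), `skipped` (unresolvable identifiers),
#'   `n_items_with_codes`, and `time_saved_hours`.
#' @export
export_semantic_codes <- function(store, identifiers, by = c("oid", "key"),
                                  minutes_per_item = 1) {
  stopifnot(inherits(store, "mdr_store"), is.character(identifiers))
  by <- match.arg(by)
  items <- list_records(store, "Item")
  by_id <- new.env(parent = emptyenv())
  for (r in items) {
    id <- if (by == "key") r$key else r$element$oid
    assign(id, c(get0(id, envir = by_id, inherits = FALSE), list(r)), envir = by_id)
  }
  codes <- list()
  skipped <- character(0)
  for (id in identifiers) {
    recs <- get0(id, envir = by_id, inherits = FALSE)
    if (is.null(recs)) {
      skipped <- c(skipped, id)
      next
    }
    al <- unique(do.call(rbind, lapply(recs, function(r) r$element$aliases)))
    codes[[id]] <- data.frame(context = al$context, code = al$name,
                              stringsAsFactors = FALSE)
  }
  n_coded <- sum(vapply(codes, nrow, integer(1)) > 0)
  list(codes = codes, skipped = skipped, n_items_with_codes = n_coded,
       time_saved_hours = n_coded * minutes_per_item / 60)
}
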