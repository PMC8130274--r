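# Resource-oriented JSON API over the store and the search index.
#
# Every resource kind has a collection endpoint (/items, /forms, ...) that
# supports ranked search (`query`) or paged listing by occurrences, and a
# single-resource endpoint addressed by canonical key digest. All endpoints
# are read-only GET and secured with an API key. The handlers are pure
# functions of (store, index, request), so they can be driven by any HTTP
# front end; a minimal httpuv adapter is provided.

#' API configuration
#'
#' @param api_keys character vector of opaque API keys; requests must
#'   present one of them (header `X-API-Key`, query-parameter fallback
#'   `api_key`). With `auth = FALSE` no key is required.
#' @param page_size default collection page size.
#' @param max_page_size upper bound for the `limit` parameter.
#' @param auth enable API-key checking (default: on when keys are given).
#' @return an object of class `api_config`.
#' @export
api_config <- function(api_keys = character(0), page_size = 20L,
                       max_page_size = 100L, auth = length(api_keys) > 0) {
  if (auth && length(api_keys) == 0) {
    odmdr_error("mdr_config_error", "auth enabled but no API key configured")
  }
  structure(list(api_keys = api_keys, page_size = as.integer(page_size),
                 max_page_size = as.integer(max_page_size), auth = isTRUE(auth)),
            class = "api_config")
}

#' Endpoint paths of the API
#'
#' @return named character vector mapping collection path to resource kind.
#' @export
api_routes <- function() {
  c("/studies" = "Study", "/protocols" = "Protocol", "/studyevents" = "StudyEvent",
    "/forms" = "Form", "/itemgroups" = "ItemGroup", "/items" = "Item",
    "/codelists" = "CodeList", "/codelistitems" = "CodeListItem",
    "/measurementunits" = "MeasurementUnit")
}

#' Bundle store, index and configuration into an API object
#'
#' @param store an [mdr_store()].
#' @param index an `mdr_index` built over the store (built on the fly when
#'   omitted).
#' @param config an [api_config()].
#' @return an object of class `mdr_api`.
#' @export
mdr_api <- function(store, index = NULL, config = api_config()) {
  stopifnot(inherits(store, "mdr_store"), inherits(config, "api_config"))
  if (is.null(index)) index <- build_index(store)
  structure(list(store = store, index = index, config = config),
            class = "mdr_api")
}

api_response <- function(status, body) {
  list(status = status, body = body)
}

check_auth <- function(api, api_key) {
  if (!api$config$auth) return(NULL)
  if (is.null(api_key) || !api_key %in% api$config$api_keys) {
    return(api_response(401L, NULL))
  }
  NULL
}

record_summary <- function(rec, config) {
  f <- record_fields(rec$element, config)
  list(id = rec$key, kind = rec$kind, oid = rec$element$oid,
       name = f$name %|na|% NULL, question = f$question %|na|% NULL,
       occurrences = rec$occurrences)
}

#' Handle a collection request
#'
#' With a `query` parameter: ranked search hits with embedded resource
#' summaries and the total number of matches. Without: a paged listing of
#' the kind's records by occurrences descending. GET only; read-only.
#'
#' @param api an [mdr_api()].
#' @param kind resource kind of the collection.
#' @param params list with optional entries `query`, `limit`, `offset`.
#' @param api_key presented API key (or `NULL`).
#' @return a list `(status, body)`; `body` is a JSON-ready list (`NULL` for
#'   an authorization failure).
#' @export
handle_collection <- function(api, kind, params = list(), api_key = NULL) {
  stopifnot(inherits(api, "mdr_api"))
  denied <- check_auth(api, api_key)
  if (!is.null(denied)) return(denied)
  if (!kind %in% api$store$config$kinds) {
    return(api_response(404L, list(error = sprintf("unknown resource kind: %s", kind))))
  }
  lim <- params$limit %||% api$config$page_size
  off <- params$offset %||% 0L
  lim <- suppressWarnings(as.integer(lim)); off <- suppressWarnings(as.integer(off))
  if (is.na(lim) || lim < 1 || is.na(off) || off < 0) {
    return(api_response(400L, list(error = "limit must be >= 1 and offset >= 0")))
  }
  lim <- min(lim, api$config$max_page_size)
  cfg <- api$store$config

  if (!is.null(params$query) && nzchar(params$query)) {
    res <- tryCatch(search(api$index, params$query, kind = kind, limit = Inf),
                    odmdr_error = function(e) e)
    if (inherits(res, "odmdr_error")) {
      return(api_response(400L, list(error = conditionMessage(res))))
    }
    n <- nrow(res$hits)
    rows <- seq_len(n)
    rows <- rows[rows > off & rows <= off + lim]
    page <- res$hits[rows, , drop = FALSE]
    hits <- lapply(seq_len(nrow(page)), function(i) {
      rec <- get_record(api$store, page$key[i])
      c(list(match_score = page$match_score[i],
             combined_score = page$combined_score[i]),
        record_summary(rec, cfg))
    })
    return(api_response(200L, list(kind = kind, query = params$query,
                                   total_matches = res$total_matches,
                                   limit = lim, offset = off, hits = hits)))
  }

  recs <- list_records(api$store, kind)
  total <- length(recs)
  idx <- seq_len(total)
  idx <- idx[idx > off & idx <= off + lim]
  items <- lapply(recs[idx], record_summary, config = cfg)
  api_response(200L, list(kind = kind, total = total, limit = lim,
                          offset = off, resources = items))
}

#' Handle a single-resource request
#'
#' Returns the full JSON representation of one aggregate record: the
#' element (attributes, translated texts, aliases, range checks, nested
#' children), its occurrence count and its provenance. The representation
#' is lossless for equivalence: decoding the element and re-keying it
#' reproduces the resource id.
#'
#' @param api an [mdr_api()].
#' @param kind resource kind; must match the record's kind.
#' @param id canonical key digest of the record.
#' @param api_key presented API key (or `NULL`).
#' @return a list `(status, body)`.
#' @export
handle_resource <- function(api, kind, id, api_key = NULL) {
  stopifnot(inherits(api, "mdr_api"))
  denied <- check_auth(api, api_key)
  if (!is.null(denied)) return(denied)
  rec <- get_record(api$store, id)
  if (is.null(rec) || rec$kind != kind) {
    return(api_response(404L, list(error = sprintf("no %s resource with id %s", kind, id))))
  }
  api_response(200L, list(
    id = rec$key, kind = rec$kind, occurrences = rec$occurrences,
    provenance = lapply(rec$provenance, function(p) {
      list(document_id = p$document_id, path = as.list(p$path))
    }),
    element = element_as_list(rec$element)))
}

response_json <- function(resp) {
  if (is.null(resp$body)) return("")
  jsonlite::toJSON(resp$body, auto_unbox = TRUE, null = "null", digits = NA)
}

#' httpuv application wrapping the API handlers
#'
#' @param api an [mdr_api()].
#' @return a list with a `call` function in the form httpuv expects.
#' @export
mdr_app <- function(api) {
  routes <- api_routes()
  list(call = function(req) {
    if (!identical(req$REQUEST_METHOD, "GET")) {
      return(list(status = 405L, headers = list("Content-Type" = "application/json"),
                  body = '{"error":"GET only"}'))
    }
    path <- req$PATH_INFO
    q <- parse_query_string(req$QUERY_STRING %||% "")
    key <- req$HTTP_X_API_KEY %||% q$api_key
    parts <- strsplit(sub("^/", "", path), "/")[[1]]
    resp <- if (length(parts) == 1 && paste0("/", parts[1]) %in% names(routes)) {
      handle_collection(api, routes[[paste0("/", parts[1])]],
                        params = q[names(q) %in% c("query", "limit", "offset")],
                        api_key = key)
    } else if (length(parts) == 2 && paste0("/", parts[1]) %in% names(routes)) {
      handle_resource(api, routes[[paste0("/", parts[1])]], parts[2], api_key = key)
    } else {
      api_response(404L, list(error = "unknown endpoint"))
    }
    list(status = resp$status,
         headers = list("Content-Type" = "application/json"),
         body = response_json(resp))
  })
}

parse_query_string <- function(qs) {
  qs <- sub("^\\?", "", qs)
  if (!nzchar(qs)) return(list())
  parts <- strsplit(qs, "&", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) >= 1 && nzchar(p[1])) {
      out[[utils::URLdecode(p[1])]] <-
        if (length(p) >= 2) utils::URLdecode(chartr("+", " ", p[2])) else ""
    }
  }
  out
}

#' Serve the API over HTTP
#'
#' Thin wrapper around httpuv; blocks until interrupted.
#'
#' @param api an [mdr_api()].
#' @param host bind address.
#' @param port TCP port.
#' @export
serve_mdr <- function(api, host = "127.0.0.1", port = 8080L) {
  if (!requireNamespace("httpuv", quietly = TRUE)) {
    odmdr_error("mdr_config_error", "serving over HTTP requires the httpuv package")
  }
  message(sprintf("serving metadata repository API on http://%s:%d", host, port))
  httpuv::runServer(host, port, mdr_app(api))
}
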