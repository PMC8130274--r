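#' Construct an atomic metadata element
#'
#' An `odm_element` is one node of the ODM-derived metadata tree: a study, a
#' protocol, a form, an item group, an item (data element), a code list, a
#' code list item or a measurement unit, together with its attributes,
#' translated texts, aliases (semantic codes), range checks and children.
#'
#' @param kind resource kind; must be a member of the configured closed set
#'   (see [odm_resource_kinds()]).
#' @param oid non-empty identifier string.
#' @param attributes named character vector of ODM attributes
#'   (e.g. `Name`, `DataType`, `Length`, `Repeating`). Values are
#'   whitespace-trimmed.
#' @param translated_texts named list: role (`"Question"`, `"Description"`,
#'   `"Decode"`, `"Symbol"`) to a named character vector mapping
#'   language tags (lowercased; `""` for untagged) to text.
#' @param aliases data frame with columns `context` and `name`, one row per
#'   `Alias` element (e.g. UMLS codes).
#' @param range_checks list of range checks; each a list with fields
#'   `comparator`, `soft_hard`, `check_values` (character vector) and
#'   `measurement_unit_oid` (string or `NA`).
#' @param children ordered list of child `odm_element`s.
#' @param config repository configuration, see [odm_config()].
#' @return an object of class `odm_element`.
#' @export
odm_element <- function(kind, oid,
                        attributes = character(),
                        translated_texts = list(),
                        aliases = NULL,
                        range_checks = list(),
                        children = list(),
                        config = odm_config()) {
  config <- as_odm_config(config)
  if (!is.character(kind) || length(kind) != 1 || !kind %in% config$kinds) {
    odmdr_error("odm_kind_error",
                sprintf("unknown or disabled resource kind: %s",
                        paste(kind, collapse = "/")))
  }
  if (!is.character(oid) || length(oid) != 1 || is.na(oid) || !nzchar(trimws(oid))) {
    odmdr_error("odm_structure_error", sprintf("%s element requires a non-empty OID", kind))
  }
  attributes <- trim_map(attributes)
  translated_texts <- normalize_texts(translated_texts)
  aliases <- normalize_aliases(aliases)
  range_checks <- lapply(range_checks, normalize_range_check)
  stopifnot(is.list(children))
  for (ch in children) {
    if (!inherits(ch, "odm_element")) odmdr_error("odm_structure_error", "children must be odm_element objects")
  }
  structure(
    list(kind = kind, oid = trimws(oid), attributes = attributes,
         translated_texts = translated_texts, aliases = aliases,
         range_checks = range_checks, children = children),
    class = "odm_element"
  )
}

trim_map <- function(x) {
  if (length(x) == 0) return(stats::setNames(character(0), character(0)))
  stopifnot(is.character(x), !is.null(names(x)), all(nzchar(names(x))))
  stats::setNames(trimws(x), names(x))
}

normalize_texts <- function(texts) {
  if (length(texts) == 0) return(list())
  stopifnot(is.list(texts), !is.null(names(texts)))
  lapply(texts, function(v) {
    stopifnot(is.character(v))
    if (is.null(names(v))) names(v) <- rep("", length(v))
    names(v) <- tolower(names(v))
    v
  })
}

normalize_aliases <- function(aliases) {
  if (is.null(aliases)) {
    return(data.frame(context = character(0), name = character(0),
                      stringsAsFactors = FALSE))
  }
  aliases <- as.data.frame(aliases, stringsAsFactors = FALSE)
  stopifnot(all(c("context", "name") %in% names(aliases)))
  data.frame(context = as.character(aliases$context),
             name = as.character(aliases$name), stringsAsFactors = FALSE)
}

normalize_range_check <- function(rc) {
  stopifnot(is.list(rc))
  list(comparator = as.character(rc$comparator %||% ""),
       soft_hard = as.character(rc$soft_hard %||% "Soft"),
       check_values = as.character(rc$check_values %||% character(0)),
       measurement_unit_oid = as.character(rc$measurement_unit_oid %||% NA_character_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.odm_element <- function(x, ...) {
  cat(sprintf("<odm_element %s oid=%s", x$kind, x$oid))
  q <- english_text(x, "Question")
  if (!is.na(q)) cat(sprintf(" question=%s", dQuote(q, FALSE)))
  cat(sprintf(" children=%d>\n", length(x$children)))
  invisible(x)
}

#' Extract an English translated text from an element
#'
#' An English text is any translated text whose language tag is `"en"` or
#' starts with `"en-"`. Texts with no language tag count as English only
#' when the element carries no tagged text for that role at all (and the
#' configuration allows it).
#'
#' @param element an `odm_element`.
#' @param role text role, e.g. `"Question"`.
#' @param config see [odm_config()].
#' @return the text string, or `NA_character_` when absent.
#' @export
english_text <- function(element, role = "Question", config = odm_config()) {
  config <- as_odm_config(config)
  v <- element$translated_texts[[role]]
  if (is.null(v) || length(v) == 0) return(NA_character_)
  langs <- names(v)
  en <- langs == "en" | startsWith(langs, "en-")
  if (any(en)) return(unname(v[which(en)[1]]))
  if (config$untagged_text_is_english && all(langs == "")) return(unname(v[[1]]))
  NA_character_
}

#' Construct a source document
#'
#' A parsed ODM file: a unique document id, a free-text origin label and one
#' or more resolved `Study` trees.
#'
#' @param document_id unique string identifying the document within a store.
#' @param roots list of `odm_element`s of kind `Study`.
#' @param origin_label free text, e.g. the portal form id or file name.
#' @return an object of class `odm_document`.
#' @export
odm_document <- function(document_id, roots, origin_label = document_id) {
  stopifnot(is.character(document_id), length(document_id) == 1, nzchar(document_id))
  stopifnot(is.list(roots), length(roots) >= 1)
  for (r in roots) {
    if (!inherits(r, "odm_element") || r$kind != "Study") {
      odmdr_error("odm_structure_error", "document roots must be Study elements")
    }
  }
  structure(list(document_id = document_id, origin_label = origin_label,
                 roots = roots),
            class = "odm_document")
}

#' @export
print.odm_document <- function(x, ...) {
  cat(sprintf("<odm_document %s: %d study root(s)>\n", x$document_id, length(x$roots)))
  invisible(x)
}

#' Convert an element to/from a plain list (JSON representation)
#'
#' `element_as_list()` produces a nested plain-list representation that is
#' lossless for equivalence: rebuilding the element with
#' `element_from_list()` and re-keying it reproduces the original canonical
#' key. This is the representation the JSON API serves.
#'
#' @param element an `odm_element`.
#' @return `element_as_list()`: a nested list; `element_from_list()`: an
#'   `odm_element`.
#' @export
element_as_list <- function(element) {
  stopifnot(inherits(element, "odm_element"))
  list(
    kind = element$kind,
    oid = element$oid,
    attributes = as.list(element$attributes),
    translated_texts = lapply(element$translated_texts, as.list),
    aliases = lapply(seq_len(nrow(element$aliases)), function(i) {
      list(context = element$aliases$context[i], name = element$aliases$name[i])
    }),
    range_checks = lapply(element$range_checks, function(rc) {
      rc$check_values <- as.list(rc$check_values)
      rc
    }),
    children = lapply(element$children, element_as_list)
  )
}

#' @rdname element_as_list
#' @param x a nested list as produced by `element_as_list()` (possibly after
#'   a JSON round trip).
#' @param config see [odm_config()].
#' @export
element_from_list <- function(x, config = odm_config()) {
  aliases <- if (length(x$aliases)) {
    data.frame(context = vapply(x$aliases, function(a) a$context, character(1)),
               name = vapply(x$aliases, function(a) a$name, character(1)),
               stringsAsFactors = FALSE)
  } else NULL
  odm_element(
    kind = x$kind, oid = x$oid,
    attributes = unlist2chr(x$attributes),
    translated_texts = lapply(x$translated_texts, unlist2chr),
    aliases = aliases,
    range_checks = lapply(x$range_checks, function(rc) {
      rc$check_values <- as.character(unlist(rc$check_values))
      mu <- rc$measurement_unit_oid
      rc$measurement_unit_oid <- if (is.null(mu) || length(mu) == 0) NA_character_ else as.character(mu)
      rc
    }),
    children = lapply(x$children, element_from_list, config = config),
    config = config
  )
}

unlist2chr <- function(x) {
  if (length(x) == 0) return(character(0))
  stats::setNames(vapply(x, as.character, character(1)), names(x))
}

# number of nodes in an element tree
count_nodes <- function(element) {
  1L + sum(vapply(element$children, count_nodes, integer(1)))
}
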