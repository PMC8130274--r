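# Canonical serialization and Merkle keys.
#
# Two definitions are strictly equivalent when they agree in every ODM
# property, including (recursively) all of their children. This is realized
# by a canonical serialization: a deterministic text rendering in which
# attribute order, XML whitespace artifacts and Unicode representation no
# longer matter, and every child is represented by the digest of its own
# canonical serialization (a Merkle construction, so any change in a
# descendant propagates to every ancestor's key).

norm_text <- function(x) {
  x <- stringi::stri_trans_nfc(enc2utf8(x))
  x <- gsub("[[:space:]]+", " ", x, perl = TRUE)
  trimws(x)
}

#' Canonical serialization of an element
#'
#' Deterministic UTF-8, NFC-normalized rendering: attributes sorted by name,
#' translated texts sorted by (role, language), aliases and range checks in
#' document order, children represented by their canonical key digests.
#' Leading/trailing whitespace is trimmed and internal whitespace runs are
#' collapsed to a single space in text payloads.
#'
#' @param element an `odm_element`.
#' @param config see [odm_config()]; `ignore_oids = TRUE` drops the element
#'   OID from the serialization.
#' @param .depth internal recursion guard.
#' @return a single string; equal strings define strict equivalence.
#' @export
canonical_serialize <- function(element, config = odm_config(), .depth = 0L) {
  stopifnot(inherits(element, "odm_element"))
  config <- as_odm_config(config)
  if (.depth > 200L) {
    odmdr_error("odm_structure_error", "element tree too deep (cyclic child structure?)")
  }
  child_digests <- vapply(element$children, function(ch) {
    canonical_key(ch, config = config, .depth = .depth + 1L)
  }, character(1))
  serialize_with_child_digests(element, child_digests, config)
}

# shared by canonical_serialize() and the bottom-up pass in keyed_decompose()
serialize_with_child_digests <- function(element, child_digests, config) {
  lines <- c(paste0("kind=", element$kind))
  if (!config$ignore_oids) lines <- c(lines, paste0("oid=", norm_text(element$oid)))
  a <- element$attributes
  if (length(a)) {
    a <- a[order(names(a), method = "radix")]
    lines <- c(lines, paste0("attr:", names(a), "=", norm_text(a)))
  }
  tt <- element$translated_texts
  if (length(tt)) {
    rows <- character(0)
    for (role in sort(names(tt), method = "radix")) {
      v <- tt[[role]]
      v <- v[order(names(v), method = "radix")]
      rows <- c(rows, paste0("text:", role, ":", names(v), "=", norm_text(v)))
    }
    lines <- c(lines, rows)
  }
  if (nrow(element$aliases)) {
    lines <- c(lines, paste0("alias:", norm_text(element$aliases$context), "=",
                             norm_text(element$aliases$name)))
  }
  for (rc in element$range_checks) {
    lines <- c(lines, paste0(
      "rangecheck:", norm_text(rc$comparator), ":", norm_text(rc$soft_hard), ":",
      paste(norm_text(rc$check_values), collapse = ","), ":",
      if (is.na(rc$measurement_unit_oid)) "" else norm_text(rc$measurement_unit_oid)))
  }
  if (length(child_digests)) lines <- c(lines, paste0("child:", child_digests))
  paste(lines, collapse = "\n")
}

#' Canonical (Merkle) key of an element
#'
#' SHA-1 digest of [canonical_serialize()]; stable across runs and
#' platforms. Equal keys define strict equivalence of definitions.
#'
#' @inheritParams canonical_serialize
#' @return a 40-character hexadecimal string.
#' @export
canonical_key <- function(element, config = odm_config(), .depth = 0L) {
  digest::digest(canonical_serialize(element, config = config, .depth = .depth),
                 algo = "sha1", serialize = FALSE)
}

#' Relaxed equivalence key of an item
#'
#' The relaxed equivalence definition only requires the English question
#' text, in lower case, to coincide: the question is the text displayed to
#' users, so items that differ in other properties but ask the same question
#' cluster together.
#'
#' @param item an `odm_element` of kind `Item`.
#' @param config see [odm_config()].
#' @return the lowercased English question (after trimming and whitespace
#'   collapse), or `NA_character_` when the item has no English question.
#' @export
relaxed_question_key <- function(item, config = odm_config()) {
  stopifnot(inherits(item, "odm_element"))
  if (item$kind != "Item") {
    odmdr_error("odm_kind_error",
                sprintf("relaxed_question_key() is defined for Items, not %s", item$kind))
  }
  q <- english_text(item, "Question", config = config)
  if (is.na(q)) return(NA_character_)
  tolower(norm_text(q))
}

#' Decompose a document into atomic resources
#'
#' Walks every root tree of a parsed document and returns every node exactly
#' once in document order, together with its path from the root.
#'
#' @param document an `odm_document`.
#' @return a list with one entry per node: `element`, `kind`, `oid`, and
#'   `path` (character vector of `"Kind:OID"` steps from the root to the
#'   node, inclusive).
#' @export
decompose <- function(document) {
  stopifnot(inherits(document, "odm_document"))
  out <- vector("list", 0L)
  walk <- function(el, prefix) {
    path <- c(prefix, paste0(el$kind, ":", el$oid))
    out[[length(out) + 1L]] <<- list(element = el, kind = el$kind,
                                     oid = el$oid, path = path)
    for (ch in el$children) walk(ch, path)
  }
  for (root in document$roots) walk(root, character(0))
  out
}

# Single bottom-up pass computing canonical keys for every node of a
# document; avoids re-hashing shared subtrees once per ancestor level.
# Returns decompose() output augmented with $key and $serialization.
keyed_decompose <- function(document, config = odm_config()) {
  config <- as_odm_config(config)
  out <- vector("list", 0L)
  walk <- function(el, prefix, depth) {
    if (depth > 200L) odmdr_error("odm_structure_error", "element tree too deep")
    path <- c(prefix, paste0(el$kind, ":", el$oid))
    idx <- length(out) + 1L
    out[idx] <<- list(NULL)  # placeholder keeps document order
    child_digests <- vapply(el$children, walk, character(1),
                            prefix = path, depth = depth + 1L)
    ser <- serialize_with_child_digests(el, child_digests, config)
    key <- digest::digest(ser, algo = "sha1", serialize = FALSE)
    out[[idx]] <<- list(element = el, kind = el$kind, oid = el$oid,
                        path = path, key = key, serialization = ser)
    key
  }
  for (root in document$roots) walk(root, character(0), 1L)
  out
}
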