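#' Atomic resource kinds of the metadata model
#'
#' The repository decomposes ODM documents into a closed set of atomic
#' resource kinds. The default set covers the element kinds a form-centric
#' metadata collection actually reuses: `Study`, `Protocol`, `Form`,
#' `ItemGroup`, `Item`, `CodeList`, `CodeListItem`, `MeasurementUnit`.
#' `StudyEvent` can be enabled for corpora that organise forms into visits.
#'
#' @param include_study_event logical; also treat `StudyEvent` as an atomic
#'   resource, nesting forms under the events that reference them.
#' @return character vector of kind names.
#' @export
odm_resource_kinds <- function(include_study_event = FALSE) {
  kinds <- c("Study", "Protocol", "Form", "ItemGroup", "Item",
             "CodeList", "CodeListItem", "MeasurementUnit")
  if (include_study_event) kinds <- append(kinds, "StudyEvent", after = 2L)
  kinds
}

#' Repository configuration
#'
#' Bundles the switches that govern decomposition and equivalence.
#'
#' @param kinds closed set of accepted resource kinds; elements of other
#'   kinds are rejected by constructors, never silently coerced.
#' @param ignore_oids logical; when `TRUE` the element OID is excluded from
#'   the canonical serialization, so corpora with machine-generated OIDs can
#'   still aggregate structurally identical definitions. The default keeps
#'   OIDs in the key: strict equivalence means agreement in every property.
#' @param untagged_text_is_english logical; a translated text with no
#'   language tag counts as English only when the element carries no tagged
#'   text at all.
#' @param unknown_elements one of `"skip"` or `"error"`: what to do when an
#'   ODM document contains a definition kind outside `kinds`.
#' @return an object of class `odm_config`.
#' @export
odm_config <- function(kinds = odm_resource_kinds(),
                       ignore_oids = FALSE,
                       untagged_text_is_english = TRUE,
                       unknown_elements = c("skip", "error")) {
  stopifnot(is.character(kinds), length(kinds) >= 1,
            all(kinds %in% odm_resource_kinds(include_study_event = TRUE)))
  structure(
    list(kinds = kinds,
         ignore_oids = isTRUE(ignore_oids),
         untagged_text_is_english = isTRUE(untagged_text_is_english),
         unknown_elements = match.arg(unknown_elements)),
    class = "odm_config"
  )
}

as_odm_config <- function(config) {
  if (is.null(config)) return(odm_config())
  if (!inherits(config, "odm_config")) stop("`config` must be an odm_config object")
  config
}

# classed conditions used across the package
odmdr_error <- function(class, message, ...) {
  stop(structure(class = c(class, "odmdr_error", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}
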