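# Writing the internal element model back out as ODM 1.3 metadata XML.
#
# The writer regenerates Def/Ref structure from containment: each unique
# definition (by OID, first occurrence wins) is written once under the
# MetaDataVersion and referenced from its parents in child order. The
# CreationDateTime is fixed so that identical inputs produce byte-identical
# output.

ODM_XMLNS <- "http://www.cdisc.org/ns/odm/v1.3"
ODM_CREATION_STAMP <- "2000-01-01T00:00:00"

#' Serialize a document (or list of documents) to ODM XML
#'
#' @param document an [odm_document()].
#' @param path optional file path; when given the XML is written there.
#' @return the XML as a single string (invisibly when `path` is given).
#' @export
write_odm <- function(document, path = NULL) {
  stopifnot(inherits(document, "odm_document"))
  doc <- xml2::xml_new_root(
    "ODM",
    xmlns = ODM_XMLNS,
    FileType = "Snapshot",
    FileOID = document$document_id,
    CreationDateTime = ODM_CREATION_STAMP,
    ODMVersion = "1.3",
    Granularity = "Metadata")
  for (study in document$roots) write_study(doc, study)
  out <- as.character(doc)
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

add_translated_texts <- function(parent, wrapper, texts) {
  if (is.null(texts) || length(texts) == 0) return(invisible(NULL))
  w <- xml2::xml_add_child(parent, wrapper)
  for (i in seq_along(texts)) {
    lang <- names(texts)[i]
    tt <- xml2::xml_add_child(w, "TranslatedText", texts[[i]])
    if (nzchar(lang)) xml2::xml_set_attr(tt, "xml:lang", lang)
  }
  invisible(NULL)
}

add_aliases <- function(parent, aliases) {
  if (nrow(aliases) == 0) return(invisible(NULL))
  for (i in seq_len(nrow(aliases))) {
    xml2::xml_add_child(parent, "Alias", Context = aliases$context[i],
                        Name = aliases$name[i])
  }
  invisible(NULL)
}

set_attrs <- function(node, attrs) {
  for (nm in names(attrs)) xml2::xml_set_attr(node, nm, attrs[[nm]])
  invisible(node)
}

write_study <- function(doc, study) {
  study_node <- xml2::xml_add_child(doc, "Study", OID = study$oid)
  gv <- xml2::xml_add_child(study_node, "GlobalVariables")
  a <- study$attributes
  xml2::xml_add_child(gv, "StudyName", unname(a["StudyName"] %|na|% study$oid))
  xml2::xml_add_child(gv, "StudyDescription", unname(a["StudyDescription"] %|na|% ""))
  xml2::xml_add_child(gv, "ProtocolName", unname(a["ProtocolName"] %|na|% study$oid))

  # collect unique definitions per kind (first occurrence wins)
  defs <- list(StudyEvent = list(), Form = list(), ItemGroup = list(),
               Item = list(), CodeList = list(), MeasurementUnit = list())
  protocol <- NULL
  collect <- function(el) {
    if (el$kind == "Protocol") {
      if (is.null(protocol)) protocol <<- el
    } else if (el$kind %in% names(defs)) {
      if (is.null(defs[[el$kind]][[el$oid]])) defs[[el$kind]][[el$oid]] <<- el
    }
    for (ch in el$children) collect(ch)
  }
  for (ch in study$children) collect(ch)

  if (length(defs$MeasurementUnit)) {
    bd <- xml2::xml_add_child(study_node, "BasicDefinitions")
    for (mu in defs$MeasurementUnit) {
      mu_node <- xml2::xml_add_child(bd, "MeasurementUnit", OID = mu$oid)
      set_attrs(mu_node, mu$attributes)
      add_translated_texts(mu_node, "Symbol", mu$translated_texts$Symbol)
    }
  }

  mdv <- xml2::xml_add_child(study_node, "MetaDataVersion",
                             OID = paste0(study$oid, ".MDV"), Name = "Metadata version")
  proto_node <- xml2::xml_add_child(mdv, "Protocol")
  if (!is.null(protocol)) {
    add_translated_texts(proto_node, "Description", protocol$translated_texts$Description)
  }
  for (se in defs$StudyEvent) {
    se_node <- xml2::xml_add_child(mdv, "StudyEventDef", OID = se$oid)
    set_attrs(se_node, se$attributes)
    for (ch in se$children) {
      if (ch$kind == "Form") {
        xml2::xml_add_child(se_node, "FormRef", FormOID = ch$oid, Mandatory = "Yes")
      }
    }
    xml2::xml_add_child(proto_node, "StudyEventRef", StudyEventOID = se$oid,
                        Mandatory = "Yes")
  }
  for (form in defs$Form) {
    f_node <- xml2::xml_add_child(mdv, "FormDef", OID = form$oid)
    set_attrs(f_node, form$attributes)
    add_translated_texts(f_node, "Description", form$translated_texts$Description)
    for (ch in form$children) {
      if (ch$kind == "ItemGroup") {
        xml2::xml_add_child(f_node, "ItemGroupRef", ItemGroupOID = ch$oid,
                            Mandatory = "Yes")
      }
    }
    add_aliases(f_node, form$aliases)
  }
  for (ig in defs$ItemGroup) {
    ig_node <- xml2::xml_add_child(mdv, "ItemGroupDef", OID = ig$oid)
    set_attrs(ig_node, ig$attributes)
    add_translated_texts(ig_node, "Description", ig$translated_texts$Description)
    for (ch in ig$children) {
      if (ch$kind == "Item") {
        xml2::xml_add_child(ig_node, "ItemRef", ItemOID = ch$oid, Mandatory = "Yes")
      }
    }
    add_aliases(ig_node, ig$aliases)
  }
  for (item in defs$Item) {
    i_node <- xml2::xml_add_child(mdv, "ItemDef", OID = item$oid)
    set_attrs(i_node, item$attributes)
    add_translated_texts(i_node, "Description", item$translated_texts$Description)
    add_translated_texts(i_node, "Question", item$translated_texts$Question)
    for (ch in item$children) {
      if (ch$kind == "MeasurementUnit") {
        xml2::xml_add_child(i_node, "MeasurementUnitRef", MeasurementUnitOID = ch$oid)
      }
    }
    for (rc in item$range_checks) {
      rc_node <- xml2::xml_add_child(i_node, "RangeCheck",
                                     Comparator = rc$comparator, SoftHard = rc$soft_hard)
      for (cv in rc$check_values) xml2::xml_add_child(rc_node, "CheckValue", cv)
      if (!is.na(rc$measurement_unit_oid)) {
        xml2::xml_add_child(rc_node, "MeasurementUnitRef",
                            MeasurementUnitOID = rc$measurement_unit_oid)
      }
    }
    for (ch in item$children) {
      if (ch$kind == "CodeList") {
        xml2::xml_add_child(i_node, "CodeListRef", CodeListOID = ch$oid)
      }
    }
    add_aliases(i_node, item$aliases)
  }
  for (cl in defs$CodeList) {
    cl_node <- xml2::xml_add_child(mdv, "CodeList", OID = cl$oid)
    set_attrs(cl_node, cl$attributes)
    for (cli in cl$children) {
      if (cli$kind != "CodeListItem") next
      cli_node <- xml2::xml_add_child(cl_node, "CodeListItem")
      set_attrs(cli_node, cli$attributes)
      if (!"CodedValue" %in% names(cli$attributes)) {
        xml2::xml_set_attr(cli_node, "CodedValue", cli$oid)
      }
      add_translated_texts(cli_node, "Decode", cli$translated_texts$Decode)
      add_aliases(cli_node, cli$aliases)
    }
    add_aliases(cl_node, cl$aliases)
  }
  invisible(study_node)
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Serialize a single element as a standalone ODM fragment
#'
#' Emits a self-contained ODM metadata document containing the element and
#' all of its descendants, with regenerated `Ref` elements and (where the
#' kind requires it) minimal synthetic wrapper elements so that the fragment
#' is reparseable by [parse_odm()]. The element's own canonical key is
#' preserved by the round trip.
#'
#' @param element an `odm_element` of kind `Form`, `ItemGroup`, `Item`,
#'   `CodeList`, `CodeListItem` or `MeasurementUnit`.
#' @param path optional output file path.
#' @return the fragment XML as a string.
#' @export
serialize_fragment <- function(element, path = NULL) {
  stopifnot(inherits(element, "odm_element"))
  supported <- c("Form", "ItemGroup", "Item", "CodeList", "CodeListItem",
                 "MeasurementUnit")
  if (!element$kind %in% supported) {
    odmdr_error("odm_kind_error",
                sprintf("serialize_fragment() supports kinds %s, not %s",
                        paste(supported, collapse = ", "), element$kind))
  }
  wrap_item <- function(el) {
    odm_element("Item", "FRAGMENT.ITEM", attributes = c(Name = "Fragment item"),
                children = list(el))
  }
  el <- element
  if (el$kind %in% c("CodeListItem")) {
    el <- odm_element("CodeList", "FRAGMENT.CL",
                      attributes = c(Name = "Fragment code list"),
                      children = list(el))
  }
  if (el$kind %in% c("CodeList", "MeasurementUnit")) el <- wrap_item(el)
  if (el$kind == "Item") {
    el <- odm_element("ItemGroup", "FRAGMENT.IG",
                      attributes = c(Name = "Fragment item group"),
                      children = list(el))
  }
  if (el$kind == "ItemGroup") {
    el <- odm_element("Form", "FRAGMENT.FORM",
                      attributes = c(Name = "Fragment form"), children = list(el))
  }
  study <- odm_element("Study", "FRAGMENT.STUDY",
                       attributes = c(StudyName = "Fragment"),
                       children = list(el))
  write_odm(odm_document("fragment", list(study)), path = path)
}
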