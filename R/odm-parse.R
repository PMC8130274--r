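# Reading CDISC ODM 1.3 metadata XML into the internal element model.
#
# Only the metadata subset is read: Study, GlobalVariables, MetaDataVersion,
# Protocol, StudyEventDef/Ref, FormDef/Ref, ItemGroupDef/Ref, ItemDef/Ref,
# Question/Description TranslatedText, CodeList/CodeListItem/Decode,
# MeasurementUnit, Alias, RangeCheck. ClinicalData sections and vendor
# extensions are ignored.

#' Parse a CDISC ODM metadata document
#'
#' Reads an ODM 1.3 XML file (or string) and resolves its references
#' (`FormRef`, `ItemGroupRef`, `ItemRef`, `CodeListRef`,
#' `MeasurementUnitRef`) into a containment tree, preserving reference order
#' as child order. A code list referenced by two items appears under both:
#' occurrences count usages.
#'
#' @param xml_source path to an ODM XML file, an XML string, or a raw
#'   vector.
#' @param document_id unique id for the document; defaults to the ODM
#'   `FileOID` (falling back to the file name).
#' @param config see [odm_config()]; when `StudyEvent` is among the
#'   configured kinds, forms are nested under the study events that
#'   reference them.
#' @return an [odm_document()].
#' @export
parse_odm <- function(xml_source, document_id = NULL, config = odm_config()) {
  config <- as_odm_config(config)
  doc <- tryCatch(
    xml2::read_xml(xml_source),
    error = function(e) {
      odmdr_error("odm_parse_error", paste0("malformed XML: ", conditionMessage(e)))
    }
  )
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(doc) != "ODM") {
    odmdr_error("odm_parse_error", "root element is not <ODM>")
  }
  if (is.null(document_id)) {
    document_id <- xml2::xml_attr(doc, "FileOID")
    if (is.na(document_id) || !nzchar(document_id)) {
      document_id <- if (is.character(xml_source) && length(xml_source) == 1 &&
                         file.exists(xml_source)) basename(xml_source) else "odm-document"
    }
  }
  studies <- xml2::xml_find_all(doc, "./Study")
  if (length(studies) == 0) {
    odmdr_error("odm_parse_error", "ODM document contains no Study element")
  }
  roots <- lapply(studies, parse_study, config = config)
  odm_document(document_id = document_id, roots = roots,
               origin_label = document_id)
}

integrity_error <- function(ref_kind, oid) {
  odmdr_error("odm_integrity_error",
              sprintf("dangling %s reference: no definition with OID '%s'", ref_kind, oid))
}

xml_attrs_no_oid <- function(node, drop = "OID") {
  a <- xml2::xml_attrs(node)
  a <- a[!names(a) %in% drop]
  # xml namespace attributes are not ODM properties
  a[!grepl("^xmlns", names(a))]
}

parse_translated_texts <- function(node, xpath) {
  tts <- xml2::xml_find_all(node, xpath)
  if (length(tts) == 0) return(NULL)
  langs <- xml2::xml_attr(tts, "lang")
  langs[is.na(langs)] <- ""
  stats::setNames(xml2::xml_text(tts), tolower(langs))
}

parse_aliases <- function(node) {
  al <- xml2::xml_find_all(node, "./Alias")
  if (length(al) == 0) return(NULL)
  data.frame(context = xml2::xml_attr(al, "Context"),
             name = xml2::xml_attr(al, "Name"), stringsAsFactors = FALSE)
}

parse_range_checks <- function(node) {
  rcs <- xml2::xml_find_all(node, "./RangeCheck")
  lapply(rcs, function(rc) {
    mu <- xml2::xml_find_first(rc, "./MeasurementUnitRef")
    list(comparator = xml2::xml_attr(rc, "Comparator"),
         soft_hard = xml2::xml_attr(rc, "SoftHard"),
         check_values = xml2::xml_text(xml2::xml_find_all(rc, "./CheckValue")),
         measurement_unit_oid = if (inherits(mu, "xml_missing")) NA_character_
                                else xml2::xml_attr(mu, "MeasurementUnitOID"))
  })
}

parse_study <- function(study_node, config) {
  study_oid <- xml2::xml_attr(study_node, "OID")
  gv <- xml2::xml_find_first(study_node, "./GlobalVariables")
  attrs <- character(0)
  if (!inherits(gv, "xml_missing")) {
    for (f in c("StudyName", "StudyDescription", "ProtocolName")) {
      v <- xml2::xml_find_first(gv, paste0("./", f))
      if (!inherits(v, "xml_missing")) attrs[f] <- xml2::xml_text(v)
    }
  }

  # measurement unit definitions (BasicDefinitions)
  mu_defs <- new.env(parent = emptyenv())
  for (mu in xml2::xml_find_all(study_node, "./BasicDefinitions/MeasurementUnit")) {
    el <- odm_element(
      kind = "MeasurementUnit", oid = xml2::xml_attr(mu, "OID"),
      attributes = xml_attrs_no_oid(mu),
      translated_texts = drop_null(list(
        Symbol = parse_translated_texts(mu, "./Symbol/TranslatedText"))),
      config = config)
    assign(el$oid, el, envir = mu_defs)
  }

  mdv <- xml2::xml_find_first(study_node, "./MetaDataVersion")
  children <- list()
  if (!inherits(mdv, "xml_missing")) {
    defs <- index_defs(mdv)
    build_item <- function(oid) {
      node <- defs$Item[[oid]]
      if (is.null(node)) integrity_error("Item", oid)
      item_children <- list()
      for (mu_ref in xml2::xml_find_all(node, "./MeasurementUnitRef")) {
        mu_oid <- xml2::xml_attr(mu_ref, "MeasurementUnitOID")
        mu_el <- get0(mu_oid, envir = mu_defs, inherits = FALSE)
        if (is.null(mu_el)) integrity_error("MeasurementUnit", mu_oid)
        item_children <- c(item_children, list(mu_el))
      }
      for (cl_ref in xml2::xml_find_all(node, "./CodeListRef")) {
        cl_oid <- xml2::xml_attr(cl_ref, "CodeListOID")
        cl_node <- defs$CodeList[[cl_oid]]
        if (is.null(cl_node)) integrity_error("CodeList", cl_oid)
        item_children <- c(item_children, list(build_codelist(cl_node, config)))
      }
      odm_element(
        kind = "Item", oid = oid,
        attributes = xml_attrs_no_oid(node),
        translated_texts = drop_null(list(
          Question = parse_translated_texts(node, "./Question/TranslatedText"),
          Description = parse_translated_texts(node, "./Description/TranslatedText"))),
        aliases = parse_aliases(node),
        range_checks = parse_range_checks(node),
        children = item_children, config = config)
    }
    build_itemgroup <- function(oid) {
      node <- defs$ItemGroup[[oid]]
      if (is.null(node)) integrity_error("ItemGroup", oid)
      refs <- xml2::xml_attr(xml2::xml_find_all(node, "./ItemRef"), "ItemOID")
      odm_element(
        kind = "ItemGroup", oid = oid,
        attributes = xml_attrs_no_oid(node),
        translated_texts = drop_null(list(
          Description = parse_translated_texts(node, "./Description/TranslatedText"))),
        aliases = parse_aliases(node),
        children = lapply(refs, build_item), config = config)
    }
    build_form <- function(oid) {
      node <- defs$Form[[oid]]
      if (is.null(node)) integrity_error("Form", oid)
      refs <- xml2::xml_attr(xml2::xml_find_all(node, "./ItemGroupRef"), "ItemGroupOID")
      odm_element(
        kind = "Form", oid = oid,
        attributes = xml_attrs_no_oid(node),
        translated_texts = drop_null(list(
          Description = parse_translated_texts(node, "./Description/TranslatedText"))),
        aliases = parse_aliases(node),
        children = lapply(refs, build_itemgroup), config = config)
    }

    proto_node <- xml2::xml_find_first(mdv, "./Protocol")
    if (!inherits(proto_node, "xml_missing") && "Protocol" %in% config$kinds) {
      children <- c(children, list(odm_element(
        kind = "Protocol",
        oid = paste0(study_oid, ".Protocol"),
        translated_texts = drop_null(list(
          Description = parse_translated_texts(proto_node, "./Description/TranslatedText"))),
        config = config)))
    }

    form_oids <- names(defs$Form)
    if ("StudyEvent" %in% config$kinds && length(defs$StudyEvent) > 0) {
      referenced <- character(0)
      for (se_oid in names(defs$StudyEvent)) {
        node <- defs$StudyEvent[[se_oid]]
        refs <- xml2::xml_attr(xml2::xml_find_all(node, "./FormRef"), "FormOID")
        referenced <- c(referenced, refs)
        children <- c(children, list(odm_element(
          kind = "StudyEvent", oid = se_oid,
          attributes = xml_attrs_no_oid(node),
          children = lapply(refs, build_form), config = config)))
      }
      form_oids <- setdiff(form_oids, referenced)
    }
    children <- c(children, lapply(form_oids, build_form))
  }

  odm_element(kind = "Study", oid = study_oid, attributes = attrs,
              children = children, config = config)
}

# definitions of a MetaDataVersion, keyed by OID, in document order
index_defs <- function(mdv) {
  grab <- function(tag) {
    nodes <- xml2::xml_find_all(mdv, paste0("./", tag))
    stats::setNames(as.list(nodes), xml2::xml_attr(nodes, "OID"))
  }
  list(StudyEvent = grab("StudyEventDef"), Form = grab("FormDef"),
       ItemGroup = grab("ItemGroupDef"), Item = grab("ItemDef"),
       CodeList = grab("CodeList"))
}

build_codelist <- function(node, config) {
  clis <- lapply(xml2::xml_find_all(node, "./CodeListItem"), function(cli) {
    cv <- xml2::xml_attr(cli, "CodedValue")
    odm_element(
      kind = "CodeListItem", oid = cv,
      attributes = xml_attrs_no_oid(cli, drop = character(0)),
      translated_texts = drop_null(list(
        Decode = parse_translated_texts(cli, "./Decode/TranslatedText"))),
      aliases = parse_aliases(cli), config = config)
  })
  odm_element(
    kind = "CodeList", oid = xml2::xml_attr(node, "OID"),
    attributes = xml_attrs_no_oid(node),
    aliases = parse_aliases(node),
    children = clis, config = config)
}

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
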