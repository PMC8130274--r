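# Shared fixture builders: small hand-made elements and documents.

make_codelist <- function(oid = "CL.BW", decodes = c("Underweight", "Normal", "Overweight"),
                          name = "Body weight classes") {
  odm_element("CodeList", oid,
              attributes = c(Name = name, DataType = "integer"),
              children = lapply(seq_along(decodes), function(j) {
                odm_element("CodeListItem", as.character(j),
                            attributes = c(CodedValue = as.character(j)),
                            translated_texts = list(Decode = c(en = decodes[j])))
              }))
}

make_item <- function(oid = "I.BW", question = "Body weight classification",
                      lang = "en", name = "Body weight", datatype = "integer",
                      codelist = make_codelist(), aliases = NULL,
                      range_checks = list(), children_extra = list()) {
  children <- children_extra
  if (!is.null(codelist)) children <- c(children, list(codelist))
  odm_element("Item", oid,
              attributes = c(Name = name, DataType = datatype, Length = "2"),
              translated_texts = list(Question = stats::setNames(question, lang)),
              aliases = aliases, range_checks = range_checks,
              children = children)
}

make_study <- function(oid = "S.1", forms = list()) {
  odm_element("Study", oid,
              attributes = c(StudyName = paste("Study", oid),
                             StudyDescription = "", ProtocolName = oid),
              children = c(list(odm_element("Protocol", paste0(oid, ".Protocol"))),
                           forms))
}

make_form <- function(oid = "F.1", items = list(), name = paste("Form", oid)) {
  ig <- odm_element("ItemGroup", paste0("IG.", oid),
                    attributes = c(Name = paste("Group", oid)),
                    children = items)
  odm_element("Form", oid, attributes = c(Name = name), children = list(ig))
}

# the aggregation scenario of two models sharing one item + code list:
# model 1 carries Form A with Item B, model 2 carries Form C with Item B
fig2_documents <- function() {
  item_b <- make_item(oid = "I.B", question = "Item B question",
                      codelist = make_codelist(oid = "CL.B"))
  doc1 <- odm_document("model-1", list(make_study("S.A", list(
    make_form("F.A", list(item_b))))))
  doc2 <- odm_document("model-2", list(make_study("S.C", list(
    make_form("F.C", list(item_b))))))
  list(doc1, doc2)
}

# a one-form / one-item document (single data element with a code list)
single_item_document <- function() {
  odm_document("bw-doc", list(make_study("S.BW", list(
    make_form("F.BW", list(make_item()))))))
}

# a store filled from a small synthetic corpus
synthetic_store <- function(config) {
  corp <- generate_corpus(config)
  st <- mdr_store()
  for (d in corp$documents) ingest_document(st, d)
  list(store = st, corpus = corp)
}

# a raw ODM XML string fixture written by hand (not by write_odm)
HAND_ODM_XML <- '<?xml version="1.0" encoding="UTF-8"?>
<ODM xmlns="http://www.cdisc.org/ns/odm/v1.3" FileOID="hand-odm" FileType="Snapshot"
     CreationDateTime="2020-01-01T00:00:00" ODMVersion="1.3">
  <Study OID="S.HAND">
    <GlobalVariables>
      <StudyName>Hand study</StudyName>
      <StudyDescription>Example</StudyDescription>
      <ProtocolName>S.HAND</ProtocolName>
    </GlobalVariables>
    <MetaDataVersion OID="MDV.1" Name="v1">
      <Protocol/>
      <FormDef OID="F.1" Name="Vital signs" Repeating="No">
        <ItemGroupRef ItemGroupOID="IG.1" Mandatory="Yes"/>
      </FormDef>
      <ItemGroupDef OID="IG.1" Name="Anthropometry" Repeating="No">
        <ItemRef ItemOID="I.1" Mandatory="Yes"/>
      </ItemGroupDef>
      <ItemDef OID="I.1" Name="Body weight classification" DataType="integer" Length="1">
        <Question>
          <TranslatedText xml:lang="en">Body weight classification</TranslatedText>
        </Question>
        <CodeListRef CodeListOID="CL.1"/>
        <Alias Context="UMLS" Name="C1305855"/>
      </ItemDef>
      <CodeList OID="CL.1" Name="Weight classes" DataType="integer">
        <CodeListItem CodedValue="1">
          <Decode><TranslatedText xml:lang="en">Underweight</TranslatedText></Decode>
        </CodeListItem>
        <CodeListItem CodedValue="2">
          <Decode><TranslatedText xml:lang="en">Normal weight</TranslatedText></Decode>
        </CodeListItem>
      </CodeList>
    </MetaDataVersion>
  </Study>
</ODM>'

# builds a store whose item records have prescribed texts and occurrences
occurrence_store <- function(spec) {
  items <- lapply(seq_len(nrow(spec)), function(i) {
    make_item(oid = spec$oid[i], question = spec$question[i],
              name = spec$name[i], codelist = NULL)
  })
  st <- mdr_store()
  for (d in seq_len(max(spec$occ))) {
    in_doc <- which(spec$occ >= d)
    doc <- odm_document(sprintf("doc-%d", d), list(
      make_study(sprintf("S.%d", d), list(
        make_form(sprintf("F.%d", d), items[in_doc])))))
    ingest_document(st, doc)
  }
  st
}

hemoglobin_spec <- data.frame(
  oid = c("I.HB1", "I.HB2", "I.HB3", "I.BW", "I.P"),
  question = c("Hemoglobin", "Hemoglobin ctc", "Serum hemoglobin level",
               "Body weight", "Pulse"),
  name = c("Hemoglobin", "Hemoglobin", "Hb", "Weight", "Pulse"),
  occ = c(7L, 29L, 29L, 50L, 5L),
  stringsAsFactors = FALSE)
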