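test_that("parsing resolves references into containment in document order", {
  doc <- parse_odm(HAND_ODM_XML)
  expect_s3_class(doc, "odm_document")
  expect_equal(doc$document_id, "hand-odm")
  study <- doc$roots[[1]]
  expect_equal(study$kind, "Study")
  expect_equal(unname(study$attributes["StudyName"]), "Hand study")
  kinds <- vapply(decompose(doc), `[[`, character(1), "kind")
  expect_equal(sort(kinds),
               sort(c("Study", "Protocol", "Form", "ItemGroup", "Item",
                      "CodeList", "CodeListItem", "CodeListItem")))
  # the code list is resolved under the item
  item <- Filter(function(n) n$kind == "Item", decompose(doc))[[1]]
  expect_equal(item$element$children[[1]]$kind, "CodeList")
  expect_equal(english_text(item$element, "Question"), "Body weight classification")
  # paths run from the study root to the node
  cl <- Filter(function(n) n$kind == "CodeList", decompose(doc))[[1]]
  expect_equal(cl$path,
               c("Study:S.HAND", "Form:F.1", "ItemGroup:IG.1", "Item:I.1",
                 "CodeList:CL.1"))
})

test_that("empty metadata and malformed input are handled", {
  empty <- '<ODM FileOID="e"><Study OID="S"><GlobalVariables>
    <StudyName>E</StudyName></GlobalVariables>
    <MetaDataVersion OID="M" Name="m"/></Study></ODM>'
  doc <- parse_odm(empty)
  kinds <- vapply(decompose(doc), `[[`, character(1), "kind")
  expect_equal(sum(kinds %in% c("Form", "Item")), 0)
  expect_equal(kinds[1], "Study")

  expect_error(parse_odm("<ODM><Study"), class = "odm_parse_error")
  expect_error(parse_odm("<NotOdm/>"), class = "odm_parse_error")
  dangling <- sub('ItemOID="I.1"', 'ItemOID="I.MISSING"', HAND_ODM_XML)
  err <- tryCatch(parse_odm(dangling), error = function(e) e)
  expect_s3_class(err, "odm_integrity_error")
  expect_match(conditionMessage(err), "I.MISSING", fixed = TRUE)
})

test_that("decompose is a bijection onto tree nodes", {
  corp <- generate_corpus(synth_config(seed = 11, n_concepts = 8, n_documents = 6))
  for (doc in corp$documents) {
    nodes <- decompose(doc)
    n_expected <- sum(vapply(doc$roots, odmdr:::count_nodes, integer(1)))
    expect_length(nodes, n_expected)
    expect_equal(sort(vapply(nodes, `[[`, character(1), "kind")),
                 oracle_kind_multiset(doc))
  }
})

test_that("canonical serialization is invariant to attribute order, whitespace and NFC", {
  a <- odm_element("Item", "I.1",
                   attributes = c(Name = "Weight", DataType = "float"),
                   translated_texts = list(Question = c(en = "Body  weight ")))
  b <- odm_element("Item", "I.1",
                   attributes = c(DataType = "float", Name = "Weight"),
                   translated_texts = list(Question = c(en = " Body\tweight")))
  expect_identical(canonical_serialize(a), canonical_serialize(b))
  expect_identical(canonical_key(a), canonical_key(b))

  composed <- odm_element("Item", "I.2",
                          translated_texts = list(Question = c(en = "café")))
  decomposed <- odm_element("Item", "I.2",
                            translated_texts = list(Question = c(en = "café")))
  expect_identical(canonical_key(composed), canonical_key(decomposed))
})

test_that("changing a descendant property propagates to every ancestor key", {
  item <- make_item()
  item2 <- make_item()
  item2$children[[1]]$children[[2]]$attributes["CodedValue"] <- "9"
  expect_false(canonical_serialize(item) == canonical_serialize(item2))
  expect_false(canonical_key(item) == canonical_key(item2))
  # and up through form and study
  s1 <- make_study("S.X", list(make_form("F.X", list(item))))
  s2 <- make_study("S.X", list(make_form("F.X", list(item2))))
  expect_false(canonical_key(s1) == canonical_key(s2))
  expect_false(canonical_key(s1$children[[2]]) == canonical_key(s2$children[[2]]))
})

test_that("oid handling follows the ignore_oids switch", {
  a <- make_item(oid = "I.1")
  b <- make_item(oid = "I.2")
  expect_false(canonical_key(a) == canonical_key(b))
  relaxed_cfg <- odm_config(ignore_oids = TRUE)
  expect_identical(canonical_key(a, config = relaxed_cfg),
                   canonical_key(b, config = relaxed_cfg))
})

test_that("random single-property mutations always change serialization and key", {
  set.seed(42)
  base <- make_item(aliases = data.frame(context = "UMLS", name = "C0005910"))
  base_ser <- canonical_serialize(base)
  base_key <- canonical_key(base)
  seen <- character(0)
  for (i in 1:100) {
    mut <- base
    kind <- sample(c("attr", "question", "alias", "decode", "codedvalue"), 1)
    tag <- paste0("mut", i)
    if (kind == "attr") {
      mut$attributes["Length"] <- tag
    } else if (kind == "question") {
      mut$translated_texts$Question[["en"]] <- paste("Q", tag)
    } else if (kind == "alias") {
      mut$aliases$name <- tag
    } else if (kind == "decode") {
      j <- sample(3, 1)
      mut$children[[1]]$children[[j]]$translated_texts$Decode[["en"]] <- tag
    } else {
      j <- sample(3, 1)
      mut$children[[1]]$children[[j]]$attributes["CodedValue"] <- tag
    }
    ser <- canonical_serialize(mut)
    expect_false(ser == base_ser)
    expect_false(canonical_key(mut) == base_key)
    seen <- c(seen, ser)
  }
  expect_equal(length(unique(seen)), 100)
})

test_that("key equality coincides with serialization equality on random pairs", {
  set.seed(7)
  pool <- lapply(1:40, function(i) {
    make_item(oid = sample(c("I.1", "I.2"), 1),
              question = sample(c("Body weight", "Body height", "Pulse"), 1),
              datatype = sample(c("integer", "float"), 1),
              codelist = if (runif(1) < 0.5) make_codelist() else NULL)
  })
  for (i in 1:200) {
    pair <- sample(length(pool), 2, replace = TRUE)
    a <- pool[[pair[1]]]; b <- pool[[pair[2]]]
    expect_equal(canonical_key(a) == canonical_key(b),
                 canonical_serialize(a) == canonical_serialize(b))
  }
})

test_that("relaxed question key lowercases and collapses the English question", {
  it <- make_item(question = "Diastolic BP", codelist = NULL)
  expect_equal(relaxed_question_key(it), "diastolic bp")
  it2 <- make_item(question = "  diastolic   bp ", codelist = NULL)
  expect_equal(relaxed_question_key(it2), "diastolic bp")
  # idempotence: already-lowercase question maps to itself
  expect_equal(relaxed_question_key(make_item(question = "pulse", codelist = NULL)),
               "pulse")
  # no English question -> absent
  de <- make_item(question = "Gewicht", lang = "de", codelist = NULL)
  expect_true(is.na(relaxed_question_key(de)))
  # non-Item input is a kind error
  expect_error(relaxed_question_key(make_codelist()), class = "odm_kind_error")
  # equality oracle on random strings
  set.seed(9)
  for (i in 1:50) {
    s <- paste(sample(c("Body", "WEIGHT", "pulse", "BP"), 3, replace = TRUE),
               collapse = " ")
    t <- paste(sample(c("Body", "WEIGHT", "pulse", "BP"), 3, replace = TRUE),
               collapse = " ")
    ks <- relaxed_question_key(make_item(question = s, codelist = NULL))
    kt <- relaxed_question_key(make_item(question = t, codelist = NULL))
    expect_equal(ks == kt, tolower(s) == tolower(t))
  }
})

test_that("English text selection follows the language-tag rules", {
  tagged <- odm_element("Item", "I.1", translated_texts = list(
    Question = c(de = "Gewicht", `en-gb` = "Weight")))
  expect_equal(english_text(tagged), "Weight")
  untagged_only <- odm_element("Item", "I.2", translated_texts = list(
    Question = stats::setNames("Weight", "")))
  expect_equal(english_text(untagged_only), "Weight")
  expect_true(is.na(english_text(untagged_only,
                                 config = odm_config(untagged_text_is_english = FALSE))))
  mixed <- odm_element("Item", "I.3", translated_texts = list(
    Question = stats::setNames(c("Gewicht", "Weight"), c("de", ""))))
  expect_true(is.na(english_text(mixed)))
})

test_that("fragments round-trip with unchanged canonical keys for all supported kinds", {
  mu <- odm_element("MeasurementUnit", "MU.kg", attributes = c(Name = "kg"),
                    translated_texts = list(Symbol = c(en = "kg")))
  item <- make_item(aliases = data.frame(context = "UMLS", name = "C1305855"),
                    range_checks = list(list(comparator = "GE", soft_hard = "Soft",
                                             check_values = "0",
                                             measurement_unit_oid = "MU.kg")),
                    children_extra = list(mu))
  form <- make_form("F.RT", list(item))
  targets <- list(form, form$children[[1]], item, item$children[[2]],
                  item$children[[2]]$children[[1]], mu)
  for (el in targets) {
    frag <- serialize_fragment(el)
    reparsed <- parse_odm(frag)
    nodes <- Filter(function(n) n$kind == el$kind && n$oid == el$oid,
                    decompose(reparsed))
    expect_length(nodes, 1)
    expect_identical(canonical_key(nodes[[1]]$element), canonical_key(el))
  }
  expect_error(serialize_fragment(make_study()), class = "odm_kind_error")
})

test_that("random synthetic records round-trip through fragments", {
  res <- synthetic_store(synth_config(seed = 5, n_concepts = 10, n_documents = 10))
  recs <- c(list_records(res$store, "Item"), list_records(res$store, "CodeList"),
            list_records(res$store, "MeasurementUnit"))
  recs <- recs[seq_len(min(50, length(recs)))]
  for (r in recs) {
    reparsed <- parse_odm(serialize_fragment(r$element))
    nodes <- Filter(function(n) n$kind == r$kind && n$oid == r$element$oid,
                    decompose(reparsed))
    expect_length(nodes, 1)
    expect_identical(canonical_key(nodes[[1]]$element), r$key)
  }
})

test_that("generated corpora survive an XML round trip exactly", {
  corp <- generate_corpus(synth_config(seed = 3, n_concepts = 6, n_documents = 5))
  for (doc in corp$documents) {
    xml <- write_odm(doc)
    # byte-identical on re-serialization (determinism)
    expect_identical(write_odm(doc), xml)
    reparsed <- parse_odm(xml)
    k1 <- vapply(odmdr:::keyed_decompose(doc), `[[`, character(1), "key")
    k2 <- vapply(odmdr:::keyed_decompose(reparsed), `[[`, character(1), "key")
    expect_identical(sort(k1), sort(k2))
  }
})

test_that("unknown resource kinds are rejected, never coerced", {
  expect_error(odm_element("Banana", "B.1"), class = "odm_kind_error")
  expect_error(odm_element("StudyEvent", "SE.1"), class = "odm_kind_error")
  se_cfg <- odm_config(kinds = odm_resource_kinds(include_study_event = TRUE))
  expect_silent(odm_element("StudyEvent", "SE.1", config = se_cfg))
})
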