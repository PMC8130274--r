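# Synthetic ODM corpus generator with known ground truth.
#
# Real metadata collections show a heavy-tailed reuse distribution: a few
# definitions occur very often while a long tail occurs once or twice. The
# generator emulates this by giving every medical concept a small family of
# variant definitions whose usage frequencies follow a Zipf law; the rank-1
# variant is the planted "bottom-up standard". Variants differ by
# controlled perturbations: question casing (collides under relaxed but not
# strict equivalence), question rewording with qualifiers (e.g. "body
# weight" vs "Body weight - unit"), datatype changes, and code-list
# changes. A ground-truth ledger records every definition's canonical key,
# occurrences and planted aliases, so store, search and evaluation modules
# can be tested against exact expectations.

CONCEPT_POOL <- c(
  "body weight", "body height", "body temperature", "pulse rate",
  "blood pressure", "heart rate", "serum glucose", "serum sodium",
  "serum potassium", "serum creatinine", "hemoglobin", "hematocrit",
  "urea nitrogen", "platelet count", "leukocyte count", "respiratory rate",
  "oxygen saturation", "waist circumference", "hip circumference",
  "grip strength", "smoking status", "alcohol intake", "physical activity",
  "pain score", "quality of life", "medication dose", "allergy status",
  "vaccination date", "marital status", "education level",
  "employment status", "stroke history", "diabetes status",
  "asthma severity", "kidney function", "liver enzyme",
  "cholesterol level", "triglyceride level", "vitamin d",
  "thyroid hormone", "blood group", "visual acuity", "hearing threshold",
  "lung capacity", "bone density", "tumor stage", "biopsy result",
  "ecg rhythm", "sleep duration", "fasting state")

QUALIFIER_POOL <- c("unit", "measured", "at baseline", "at follow up",
                    "self reported", "category", "code", "current",
                    "past year", "left", "right", "in si units")

UNIT_POOL <- c("kg", "cm", "mmHg", "bpm", "mmol/L", "g/dL", "percent")

DECODE_POOL <- list(c("No", "Yes", "Unknown"),
                    c("Never", "Former", "Current"),
                    c("Mild", "Moderate", "Severe"))

#' Configuration for the synthetic corpus generator
#'
#' @param seed integer seed; identical configuration implies an identical
#'   corpus, byte for byte.
#' @param n_concepts number of medical concepts (at most the size of the
#'   built-in concept vocabulary).
#' @param n_documents number of ODM documents.
#' @param zipf_exponent positive exponent of the Zipf law governing variant
#'   usage frequencies (larger = more concentrated on the planted standard).
#' @param defs_per_concept number of variant definitions per concept.
#' @param perturbation_probs named probabilities for `question_case`,
#'   `question_rewording`, `datatype_change`, `codelist_change`.
#' @param alias_rate probability that a definition carries a semantic code
#'   (synthetic UMLS-style alias).
#' @param english_rate probability that a non-planted variant's question is
#'   tagged English (others are tagged German); the planted standard is
#'   always English.
#' @param items_per_document number of concepts sampled into each document.
#' @param codelist_rate probability that a concept's definitions carry a
#'   code list.
#' @param measurement_unit_rate probability that a concept's definitions
#'   reference a measurement unit.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_concepts = 25L,
                         n_documents = 50L,
                         zipf_exponent = 1.5,
                         defs_per_concept = 4L,
                         perturbation_probs = c(question_case = 0.35,
                                                question_rewording = 0.45,
                                                datatype_change = 0.25,
                                                codelist_change = 0.25),
                         alias_rate = 0.6,
                         english_rate = 0.9,
                         items_per_document = 5L,
                         codelist_rate = 0.5,
                         measurement_unit_rate = 0.3) {
  pp <- perturbation_probs
  needed <- c("question_case", "question_rewording", "datatype_change",
              "codelist_change")
  if (!all(needed %in% names(pp))) {
    odmdr_error("mdr_config_error",
                paste("perturbation_probs must name:", paste(needed, collapse = ", ")))
  }
  probs <- c(pp, alias_rate = alias_rate, english_rate = english_rate,
             codelist_rate = codelist_rate,
             measurement_unit_rate = measurement_unit_rate)
  if (any(probs < 0 | probs > 1)) {
    odmdr_error("mdr_config_error", "probabilities must lie in [0, 1]")
  }
  if (n_concepts < 1 || n_concepts > length(CONCEPT_POOL)) {
    odmdr_error("mdr_config_error",
                sprintf("n_concepts must be in 1..%d (concept vocabulary size)",
                        length(CONCEPT_POOL)))
  }
  if (defs_per_concept < 1 || defs_per_concept > length(QUALIFIER_POOL) + 1) {
    odmdr_error("mdr_config_error",
                sprintf("defs_per_concept must be in 1..%d (qualifier pool size)",
                        length(QUALIFIER_POOL) + 1))
  }
  if (n_documents < 1 || zipf_exponent <= 0 || items_per_document < 1) {
    odmdr_error("mdr_config_error", "counts must be positive and zipf_exponent > 0")
  }
  if (items_per_document > n_concepts) {
    odmdr_error("mdr_config_error", "items_per_document cannot exceed n_concepts")
  }
  structure(list(seed = as.integer(seed), n_concepts = as.integer(n_concepts),
                 n_documents = as.integer(n_documents),
                 zipf_exponent = zipf_exponent,
                 defs_per_concept = as.integer(defs_per_concept),
                 perturbation_probs = pp[needed], alias_rate = alias_rate,
                 english_rate = english_rate,
                 items_per_document = as.integer(items_per_document),
                 codelist_rate = codelist_rate,
                 measurement_unit_rate = measurement_unit_rate),
            class = "synth_config")
}

title_case <- function(x) {
  gsub("\\b([a-z])", "\\U\\1", x, perl = TRUE)
}

first_upper <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

#' Generate a synthetic ODM corpus with ground truth
#'
#' @param config a [synth_config()].
#' @return a list with `documents` (list of [odm_document()]) and `ledger`,
#'   itself a list of: `definitions` (tibble: one row per generated variant
#'   with `concept`, `concept_name`, `variant`, `oid`, `key`, `relaxed_key`,
#'   `planted`, `occurrences`, `n_documents`, `alias_context`,
#'   `alias_code`), `by_key` (occurrences aggregated over variants sharing a
#'   canonical key), `kind_totals` (elements per kind across all
#'   documents), and `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed_local(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  nc <- config$n_concepts
  V <- config$defs_per_concept
  concepts <- CONCEPT_POOL[seq_len(nc)]
  pp <- config$perturbation_probs
  zipf_w <- seq_len(V)^(-config$zipf_exponent)
  zipf_p <- zipf_w / sum(zipf_w)

  # shared measurement unit elements (high reuse, like real corpora)
  mu_elements <- lapply(UNIT_POOL, function(u) {
    odm_element("MeasurementUnit", paste0("MU.", gsub("[^[:alnum:]]", "", u)),
                attributes = c(Name = u),
                translated_texts = list(Symbol = c(en = u)))
  })
  names(mu_elements) <- UNIT_POOL

  # per-concept base properties
  variants <- vector("list", nc)   # variants[[ci]][[r]] -> odm_element (Item)
  meta <- list()
  for (ci in seq_len(nc)) {
    cname <- concepts[ci]
    has_cl <- stats::runif(1) < config$codelist_rate
    has_mu <- stats::runif(1) < config$measurement_unit_rate
    decode_set <- DECODE_POOL[[sample.int(length(DECODE_POOL), 1)]]
    unit <- UNIT_POOL[sample.int(length(UNIT_POOL), 1)]
    base_cl <- if (has_cl) {
      odm_element("CodeList", sprintf("CL.%d.1", ci),
                  attributes = c(Name = paste(first_upper(cname), "codes"),
                                 DataType = "integer"),
                  children = lapply(seq_along(decode_set), function(j) {
                    odm_element("CodeListItem", as.character(j),
                                attributes = c(CodedValue = as.character(j)),
                                translated_texts = list(Decode = c(en = decode_set[j])))
                  }))
    } else NULL
    qualifiers <- sample(QUALIFIER_POOL, V)  # distinct rewordings per variant

    vlist <- vector("list", V)
    for (r in seq_len(V)) {
      question <- first_upper(cname)
      lang <- "en"
      datatype <- "float"
      cl <- base_cl
      alias <- NULL
      if (r > 1) {
        if (stats::runif(1) < pp["question_case"]) {
          question <- switch((r %% 3) + 1, tolower(cname), toupper(cname),
                             title_case(cname))
        }
        if (stats::runif(1) < pp["question_rewording"]) {
          question <- paste0(question, " - ", qualifiers[r])
        }
        if (stats::runif(1) < pp["datatype_change"]) {
          datatype <- c("integer", "text", "date")[(r %% 3) + 1]
        }
        if (stats::runif(1) < pp["codelist_change"]) {
          cl <- odm_element("CodeList", sprintf("CL.%d.%d", ci, r),
                            attributes = c(Name = paste(first_upper(cname), "codes"),
                                           DataType = "integer"),
                            children = lapply(seq_along(decode_set), function(j) {
                              odm_element("CodeListItem", as.character(j),
                                          attributes = c(CodedValue = as.character(j)),
                                          translated_texts = list(
                                            Decode = c(en = paste0(decode_set[j],
                                                                   " (v", r, ")"))))
                            }))
        }
        if (stats::runif(1) >= config$english_rate) {
          lang <- "de"
          question <- paste("Frage:", question)
        }
      }
      if (stats::runif(1) < config$alias_rate) {
        alias <- data.frame(context = "UMLS",
                            name = sprintf("C%07d", ci * 1000L + r),
                            stringsAsFactors = FALSE)
      }
      children <- list()
      if (has_mu) children <- c(children, list(mu_elements[[unit]]))
      if (!is.null(cl)) children <- c(children, list(cl))
      vlist[[r]] <- odm_element(
        "Item", sprintf("I.%d.%d", ci, r),
        attributes = c(Name = first_upper(cname), DataType = datatype,
                       Length = "8"),
        translated_texts = list(Question = stats::setNames(question, lang)),
        aliases = alias, children = children)
      meta[[length(meta) + 1L]] <- list(
        concept = ci, concept_name = cname, variant = r, planted = r == 1L,
        oid = sprintf("I.%d.%d", ci, r),
        alias_context = if (is.null(alias)) NA_character_ else alias$context,
        alias_code = if (is.null(alias)) NA_character_ else alias$name)
    }
    variants[[ci]] <- vlist
  }

  # documents: each samples concepts uniformly, then a variant ~ Zipf
  usage <- matrix(0L, nrow = nc, ncol = V)
  usage_docs <- array(FALSE, dim = c(nc, V, config$n_documents))
  documents <- vector("list", config$n_documents)
  for (d in seq_len(config$n_documents)) {
    chosen <- sort(sample.int(nc, config$items_per_document))
    items <- vector("list", length(chosen))
    for (j in seq_along(chosen)) {
      ci <- chosen[j]
      r <- sample.int(V, 1, prob = zipf_p)
      usage[ci, r] <- usage[ci, r] + 1L
      usage_docs[ci, r, d] <- TRUE
      items[[j]] <- variants[[ci]][[r]]
    }
    study_oid <- sprintf("S.%d", d)
    ig <- odm_element("ItemGroup", sprintf("IG.%d", d),
                      attributes = c(Name = sprintf("Item group %d", d)),
                      children = items)
    form <- odm_element("Form", sprintf("F.%d", d),
                        attributes = c(Name = sprintf("Synthetic form %d", d)),
                        children = list(ig))
    protocol <- odm_element("Protocol", paste0(study_oid, ".Protocol"))
    study <- odm_element("Study", study_oid,
                         attributes = c(StudyName = sprintf("Synthetic study %d", d),
                                        StudyDescription = "",
                                        ProtocolName = study_oid),
                         children = list(protocol, form))
    documents[[d]] <- odm_document(sprintf("doc-%03d", d), list(study))
  }

  defs <- dplyr::bind_rows(lapply(meta, tibble::as_tibble))
  defs$key <- NA_character_
  defs$relaxed_key <- NA_character_
  for (i in seq_len(nrow(defs))) {
    el <- variants[[defs$concept[i]]][[defs$variant[i]]]
    defs$key[i] <- canonical_key(el)
    defs$relaxed_key[i] <- relaxed_question_key(el)
  }
  defs$occurrences <- usage[cbind(defs$concept, defs$variant)]
  defs$n_documents <- vapply(seq_len(nrow(defs)), function(i) {
    sum(usage_docs[defs$concept[i], defs$variant[i], ])
  }, integer(1))

  by_key <- dplyr::summarise(
    dplyr::group_by(defs, .data$key),
    occurrences = sum(.data$occurrences),
    n_variants = dplyr::n(), .groups = "drop")

  kind_totals <- count_kinds(documents)

  list(documents = documents,
       ledger = list(definitions = defs, by_key = by_key,
                     kind_totals = kind_totals, config = config))
}

# element counts per kind over a list of documents (plain tree walk)
count_kinds <- function(documents) {
  counts <- integer(0)
  for (doc in documents) {
    for (nd in decompose(doc)) {
      counts[nd$kind] <- (if (is.na(counts[nd$kind])) 0L else counts[nd$kind]) + 1L
    }
  }
  tibble::tibble(kind = names(counts), total = unname(counts))
}

#' Write a synthetic corpus to disk
#'
#' One ODM XML file per document, plus the definition ledger as CSV and the
#' configuration as JSON.
#'
#' @param corpus result of [generate_corpus()].
#' @param dir output directory (created if missing).
#' @return invisibly, the output directory.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (doc in corpus$documents) {
    write_odm(doc, file.path(dir, paste0(doc$document_id, ".xml")))
  }
  utils::write.csv(corpus$ledger$definitions,
                   file.path(dir, "ledger_definitions.csv"), row.names = FALSE)
  utils::write.csv(corpus$ledger$kind_totals,
                   file.path(dir, "ledger_kind_totals.csv"), row.names = FALSE)
  cfg <- corpus$ledger$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Generate a synthetic rating matrix with known agreement
#'
#' Each unit has a latent ordinal truth drawn uniformly from 1..5; each
#' rater reports the truth with probability `agreement_level` and otherwise
#' a neighbouring category (one step towards the interior at the scale
#' bounds). Entries are missing with probability `missing_rate`.
#'
#' @param n_units number of survey units.
#' @param n_raters number of raters (>= 2).
#' @param agreement_level probability of reporting the latent truth.
#' @param missing_rate probability that a rating is missing.
#' @param seed integer seed.
#' @return a [rating_matrix()].
#' @export
generate_ratings <- function(n_units, n_raters = 2L, agreement_level = 0.8,
                             missing_rate = 0, seed = 1L) {
  if (n_raters < 2) odmdr_error("mdr_config_error", "n_raters must be >= 2")
  if (agreement_level < 0 || agreement_level > 1 ||
      missing_rate < 0 || missing_rate > 1) {
    odmdr_error("mdr_config_error", "probabilities must lie in [0, 1]")
  }
  with_seed_local(seed, {
    truth <- sample.int(5L, n_units, replace = TRUE)
    m <- matrix(NA_integer_, n_units, n_raters,
                dimnames = list(paste0("u", seq_len(n_units)),
                                paste0("rater", seq_len(n_raters))))
    for (j in seq_len(n_raters)) {
      agree <- stats::runif(n_units) < agreement_level
      step <- ifelse(stats::runif(n_units) < 0.5, -1L, 1L)
      noisy <- truth + step
      noisy[noisy < 1L] <- 2L
      noisy[noisy > 5L] <- 4L
      v <- ifelse(agree, truth, noisy)
      v[stats::runif(n_units) < missing_rate] <- NA_integer_
      m[, j] <- v
    }
    rating_matrix(m)
  })
}
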