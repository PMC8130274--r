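---
title: "Bottom-up standardization of clinical metadata: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up standardization of clinical metadata: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odmdr)
```

## The problem

Medical documentation is built from *data elements* — a question with a
name, a datatype, optionally a code list, measurement units and semantic
codes. Different institutions define the same clinical concept in slightly
different ways, which blocks data integration. Classical metadata
repositories address this top-down: an expert committee blesses one
definition per concept. `odmdr` implements the complementary *bottom-up*
idea: collect a large body of real-world metadata, detect equivalent
definitions automatically, count how often each unique definition is
actually used, and let frequently reused definitions surface as de facto
standards. Frequency acts as a proxy for quality: a definition used in
many real data collections has been tested in practice, and adopting it
yields data compatible with those collections.

The package covers the whole pipeline at desk scale: CDISC ODM 1.3
metadata parsing, decomposition into atomic resources, canonical
equivalence hashing, an aggregating store with occurrence counting,
frequency-weighted search, a read-only JSON API, evaluation statistics for
the emergence of standards, ordinal interrater agreement for quality
surveys, and a synthetic corpus generator that makes every stage testable
against known ground truth.

## The metadata model and strict equivalence

Documents are decomposed into a closed set of atomic resource kinds:
`Study`, `Protocol`, `Form`, `ItemGroup`, `Item`, `CodeList`,
`CodeListItem`, `MeasurementUnit` (`StudyEvent` can be enabled for
visit-structured corpora). References (`ItemGroupRef`, `ItemRef`,
`CodeListRef`, `MeasurementUnitRef`) are resolved into containment,
preserving reference order; a code list referenced by two items appears
under both, so occurrences count *usages*.

**Strict equivalence** means agreement in every ODM property, including
the whole subtree. This is realized by a canonical serialization that is
invariant to XML serialization artifacts — attributes sorted by name,
translated texts sorted by role and language tag, whitespace trimmed and
collapsed, Unicode NFC-normalized — in which each child is represented by
the SHA-1 digest of its own canonical serialization. The construction is a
Merkle tree: any change in any descendant property changes every
ancestor's key, so two items with byte-identical item-level properties but
different code-list decodes are correctly kept apart.

Two deliberate choices:

* **OIDs are part of the key by default** (`ignore_oids = FALSE`): strict
  equivalence is taken literally as agreement in *every* property. For
  corpora whose OIDs are machine-generated noise, `ignore_oids = TRUE`
  aggregates structurally identical definitions regardless of identifier.
* **Definition-level properties only.** Attributes that live on `Ref`
  elements in ODM (e.g. `Mandatory`, `OrderNumber` on `ItemRef`) describe
  the *usage* of a definition inside one form, not the definition itself,
  and are not merged into the resolved element; otherwise the same item
  used as optional in one form and mandatory in another would never
  aggregate.

Two representation details extend the text-role vocabulary: code list
item `Decode` texts and measurement-unit `Symbol` texts are stored as
additional translated-text roles next to `Question` and `Description`, so
they take part in equivalence, search, and round-tripping.

**Relaxed equivalence** only requires the English question text, in lower
case (trimmed, internal whitespace collapsed), to coincide — the question
is what users actually see. An English text is one tagged `en` or `en-*`;
untagged texts count as English only when the element carries no tagged
text at all (configurable).

## The store and frequency-based scoring

Ingesting a document either creates a new aggregate record
(occurrences = 1) or increments an existing record while appending
provenance (document id + path). Ingestion is atomic, re-ingestion of a
known document id is rejected, and a definition used twice within one
document counts twice. Corpus statistics report, per kind, total ingested
elements, unique records, and the *reuse* ratio total/unique (undefined,
not zero, for empty kinds).

Search ranks records by

$$\mathrm{combined} = m \cdot (1 + \ln c)$$

where $c$ is the occurrence count and $m$ the match score. The $1+$ keeps
singletons ($c = 1$) visible rather than zeroing them out. The match score
is disjunctive token scoring: for every query token present in the
record, $\mathrm{idf} \times w_\mathrm{field}$ is added, with
$\mathrm{idf} = \ln(1 + U/\mathrm{df})$ ($U$ = unique records of the
kind, df = records containing the token), field weights question 2.0,
name 1.0, all other fields 0.5 (maximum over fields per token), and a
whole-query exact match of the question doubling the sum. Tokenization is
lowercase splitting on non-alphanumerics with no stemming and no stop
words — deliberately simple so that hand-computed oracles are exact and
behavior is language-neutral. More sophisticated schemes (BM25, fuzzy
matching) were considered and rejected: the package's claims are about
the frequency tradeoff, and a fully deterministic scorer keeps every test
a closed-form check. Ties are broken by (occurrences desc, key asc) so
orderings are total and reproducible.

This reproduces the qualitative behaviors that matter: partial matches
are found with positive but lower scores, and a better-matching
definition with fewer occurrences can outrank a worse-matching one with
more — with the fixtures used in the tests, an exact question match with
7 occurrences beats a partial match with 29 because
$m_1(1+\ln 7) > m_2(1+\ln 29)$.

## Evaluation of emerging standards

For a concept query, the evaluation restricts hits to items with an
English question and reports the total number of results, the top-k
(default 3) questions with occurrence counts, and the **top-k occurrence
ratio**: summed occurrences of the top k over summed occurrences of all
matches. In relaxed mode hits are first merged by lowercase question
(occurrences summed, representative = highest-occurrence member) and
clusters re-ranked with the summed occurrences; merging can only reduce
the number of distinct results and conserves total occurrences — both are
asserted as invariants. "All results" means every record with positive
match score, without truncation. Cumulative occurrence curves report, for
each threshold $t$, how many definitions occurred at least $t$ times;
they are non-increasing with curve(1) equal to the number of distinct
matches. Group summaries are mean ± sample standard deviation
($n-1$ denominator) of the ratios, in percent with two decimals.

A fixture of 24 concept queries in four groups (vital signs, common
laboratory codes, and two disease-related groups) ships with the package
(`concept_queries()`) so the full evaluation can be driven as in a real
deployment. Ratios computed on synthetic corpora are *not* comparable to
the ones a production-size portal snapshot would give — they describe the
generated corpus, and the tests therefore check them against
recomputations from the full hit list, not against external values.

## Interrater agreement

The quality-survey module computes Krippendorff's alpha,
$\alpha = 1 - D_o/D_e$, from the coincidence matrix of all pairable
values (units with at least two non-missing ratings). The default
difference function is the ordinal one: a disagreement between categories
$c < k$ is weighted by the squared sum of coincidence-marginal
frequencies of all categories lying between them,
$\left(\sum_{g=c}^{k} n_g - \tfrac{n_c + n_k}{2}\right)^2$, so distant
disagreements on the SD < D < N < A < SA scale count more than adjacent
ones. Nominal and interval metrics are also provided; when only two
adjacent categories occur, ordinal and nominal alpha coincide (a test
asserts this). When observed disagreement is zero, alpha is 1 even if
expected disagreement degenerates.

Confidence intervals are percentile bootstrap over survey *units* (the
item × property pairs), the natural exchangeable unit here; degenerate
resamples are redrawn and counted. Per-unit coincidence contributions are
precomputed once so each resample is a column sum, which keeps B = 1000
fast. Given a seed the interval is bit-reproducible and the caller's RNG
state is untouched. A simulation test checks calibration: across 500
synthetic surveys of 300 units, about 95% of the intervals cover the
large-sample alpha.

Likert summaries count SD/D/N/A/SA responses per item property and rater,
with missing (unratable, optional ODM properties) tracked as *undefined*
and invalid responses treated as missing. The reported median of an
even-length ordinal sample with two distinct middle values is the lower
middle category, matching the convention of reporting a single bold
category per row.

## The synthetic corpus generator

Real metadata collections show a heavy-tailed reuse distribution — few
definitions occur very often, a long tail occurs once or twice. The
generator emulates exactly this: each concept (drawn from a controlled
vocabulary of 50 clinical concept names) has `defs_per_concept` variant
definitions whose usage frequencies follow a Zipf law with configurable
exponent; each document samples `items_per_document` concepts uniformly
and draws a variant from the Zipf weights. The rank-1 variant is the
planted bottom-up standard. Variants are perturbed with configurable
probabilities:

* `question_case` — casing-only changes, which collide under relaxed but
  not strict equivalence;
* `question_rewording` — appended qualifiers ("body weight" vs
  "Body weight - unit"), mimicking the clustered-question phenomena of
  real corpora;
* `datatype_change`, `codelist_change` — non-display property changes
  that split strict equivalence classes invisibly to users.

Aliases (synthetic UMLS-style codes) are planted at `alias_rate` and
recorded in the ledger, driving the semantic-code-export oracle. Question
language is English with probability `english_rate` (planted standards
are always English, since both search and the evaluation are
question-centric). Shared measurement-unit definitions produce the high
reuse ratios that unit resources show in practice. All randomness flows
from a single seeded generator: identical configurations give
byte-identical ODM output.

Defaults (25 concepts, 50 documents, 5 items per document, 4 variants per
concept, exponent 1.5, mild perturbation probabilities 0.25–0.45) give a
corpus of roughly a thousand atomic elements — large enough for the
heavy-tail phenomena to appear, small enough that the brute-force oracles
(full serialization tallies, full-scan scoring) run in seconds. The
planted-standard recovery check uses 20 concepts over 500 documents.

What the generator does *not* emulate: medically coherent content (names
and codes are synthetic tokens), multi-study files, vendor extensions,
within-document repetition of one definition, and the sheer scale of a
production portal. Passing tests therefore demonstrate correctness of the
aggregation, ranking and evaluation machinery under a realistic reuse
*shape*, not performance or retrieval quality on real clinical text.

## Numerical and degenerate-input choices

* Canonical keys are SHA-1 over the canonical serialization; key equality
  is verified against serialization string equality in tests (the
  collision-free working assumption).
* Reuse for kinds with zero records is `NA`, never 0; zero-match concept
  reports carry an undefined ratio flag instead of raising.
* Group summaries require at least two defined ratios; alpha requires at
  least one pairable unit; both fail with classed, descriptive errors.
* Bootstrap intervals warn below B = 100; degenerate resamples are
  redrawn with a hard cap to guarantee termination.
* Blank search queries (empty after tokenization) are input errors, not
  empty result sets.

## Worked example

```{r example, eval = FALSE}
corp <- generate_corpus(synth_config(seed = 7, n_concepts = 20,
                                     n_documents = 500))
store <- mdr_store()
for (doc in corp$documents) ingest_document(store, doc)
corpus_statistics(store)

index <- build_index(store)
search(index, "body weight", limit = 3)

report <- evaluate_concept(index, store, "body weight", mode = "relaxed")
report$top_k
report$topk_ratio

ratings <- generate_ratings(720, 2, agreement_level = 0.72,
                            missing_rate = 0.1, seed = 42)
bootstrap_ci(ratings, B = 1000, seed = 42)
```

The chunk is not evaluated during vignette building to keep installation
light; `README.md` shows the exact numbers this pipeline prints, and
`scripts/acceptance.R` recomputes all headline quantities from scratch.

## Known limitations

* Only the ODM metadata subset is read; `ClinicalData`, ODM 2.0 and
  vendor extensions are out of scope, as are versioning and deletion
  workflows in the store.
* The first `MetaDataVersion` of each study is used.
* The search index is in-memory and rebuilt from the store on demand;
  there is no incremental indexing.
* The API is read-only by design: sharing happens through ingestion, not
  through write endpoints.
* Search quality on real multilingual corpora would need analyzers beyond
  the deterministic tokenizer used here.
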