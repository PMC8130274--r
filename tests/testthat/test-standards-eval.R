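test_that("cumulative curves count definitions at or above each threshold", {
  cc <- cumulative_curve(c(3, 2, 2, 1))
  expect_equal(cc$count, c(4L, 3L, 1L))
  expect_equal(cc$threshold, 1:3)
  expect_equal(nrow(cumulative_curve(numeric(0))), 0)
  expect_error(cumulative_curve(c(1, 0)), class = "mdr_input_error")
  set.seed(8)
  for (i in 1:20) {
    occ <- sample.int(30, sample(1:60, 1), replace = TRUE)
    cc <- cumulative_curve(occ)
    expect_equal(cc$count, oracle_curve(occ))
    expect_true(all(diff(cc$count) <= 0))      # non-increasing
    expect_equal(cc$count[1], length(occ))     # curve(1) = distinct matches
  }
})

test_that("top-k occurrence ratios follow the forced arithmetic", {
  # ranked occurrence list 10,5,3,1,1 with k = 3 gives 18/20
  spec <- data.frame(oid = paste0("I.", 1:5),
                     question = c("Pulse", "Pulse taken", "Pulse rate",
                                  "Pulse measured twice", "Pulse at rest"),
                     name = "Pulse", occ = c(10L, 5L, 3L, 1L, 1L),
                     stringsAsFactors = FALSE)
  st <- local({
    items <- lapply(seq_len(nrow(spec)), function(i) {
      make_item(oid = spec$oid[i], question = spec$question[i],
                name = spec$name[i], codelist = NULL)
    })
    st <- mdr_store()
    for (d in seq_len(max(spec$occ))) {
      in_doc <- which(spec$occ >= d)
      ingest_document(st, odm_document(sprintf("d%d", d), list(
        make_study(sprintf("S.%d", d), list(make_form(sprintf("F.%d", d),
                                                      items[in_doc]))))))
    }
    st
  })
  ix <- build_index(st)
  rep <- evaluate_concept(ix, st, "Pulse", mode = "strict")
  expect_equal(rep$total_results, 5L)
  expect_equal(rep$topk_ratio, 18 / 20)
  expect_equal(rep$top_k$occurrences, c(10, 5, 3))
  # exactly three matching definitions exhaust the ratio
  rep3 <- evaluate_concept(ix, st, "pulse rate", mode = "strict")
  expect_true(rep3$total_results >= 3)
  repk <- evaluate_concept(ix, st, "Pulse", k = 1000L, mode = "strict")
  expect_equal(repk$topk_ratio, 1.0)
  # non-decreasing in k
  ratios <- vapply(1:5, function(k) {
    evaluate_concept(ix, st, "Pulse", k = k, mode = "strict")$topk_ratio
  }, numeric(1))
  expect_true(all(diff(ratios) >= 0))
})

test_that("relaxed mode merges by lowercase question and conserves occurrences", {
  spec <- data.frame(
    oid = paste0("I.", 1:4),
    question = c("Diastolic BP", "Diastolic bp", "DIASTOLIC BP", "Semi-supine BP diastolic"),
    name = "BP", occ = c(18L, 21L, 3L, 10L), stringsAsFactors = FALSE)
  items <- lapply(seq_len(nrow(spec)), function(i) {
    make_item(oid = spec$oid[i], question = spec$question[i],
              name = spec$name[i], codelist = NULL)
  })
  st <- mdr_store()
  for (d in seq_len(max(spec$occ))) {
    in_doc <- which(spec$occ >= d)
    ingest_document(st, odm_document(sprintf("d%d", d), list(
      make_study(sprintf("S.%d", d), list(make_form(sprintf("F.%d", d),
                                                    items[in_doc]))))))
  }
  ix <- build_index(st)
  strict <- evaluate_concept(ix, st, "Diastolic BP", mode = "strict")
  relaxed <- evaluate_concept(ix, st, "Diastolic BP", mode = "relaxed")
  expect_equal(strict$total_results, 4L)
  expect_equal(relaxed$total_results, 2L)          # merging only reduces
  expect_lte(relaxed$total_results, strict$total_results)
  expect_equal(sum(relaxed$occurrences_all), sum(strict$occurrences_all))
  # the merged cluster sums the three casing variants: 18 + 21 + 3 = 42
  expect_equal(relaxed$top_k$occurrences[1], 42)
  # representative question is the highest-occurrence member's
  expect_equal(relaxed$top_k$question[1], "Diastolic bp")
  expect_equal(relaxed$n_strict_matches, 4L)
})

test_that("items without an English question are excluded from the evaluation", {
  items <- list(
    make_item(oid = "I.EN", question = "Body weight", codelist = NULL),
    make_item(oid = "I.DE", question = "Body weight", lang = "de", codelist = NULL))
  st <- mdr_store()
  ingest_document(st, odm_document("d1", list(
    make_study("S.1", list(make_form("F.1", items))))))
  ix <- build_index(st)
  rep <- evaluate_concept(ix, st, "Body weight", mode = "strict")
  # only the English item qualifies (the German one has no English question,
  # though its Name still matches the query tokens)
  expect_equal(rep$total_results, 1L)
  expect_equal(rep$top_k$question, "Body weight")
})

test_that("zero matches produce a flagged report, not an error", {
  st <- mdr_store()
  ingest_document(st, single_item_document())
  ix <- build_index(st)
  rep <- evaluate_concept(ix, st, "xylophone", mode = "strict")
  expect_equal(rep$total_results, 0L)
  expect_false(rep$ratio_defined)
  expect_true(is.na(rep$topk_ratio))
})

test_that("ratios equal a brute-force recomputation from the full hit list", {
  res <- synthetic_store(synth_config(seed = 55, n_concepts = 20, n_documents = 40))
  ix <- build_index(res$store)
  for (q in c("body weight", "serum glucose", "grip strength")) {
    for (mode in c("strict", "relaxed")) {
      rep <- evaluate_concept(ix, res$store, q, mode = mode)
      if (rep$total_results == 0) next
      # brute-force: ratio recomputed from the full hit list
      expect_equal(sum(rep$top_k$occurrences) / sum(rep$occurrences_all),
                   rep$topk_ratio, tolerance = 1e-12)
      # the top-k occurrences are the leading entries of the full multiset
      expect_equal(rep$top_k$occurrences,
                   rep$occurrences_all[seq_len(nrow(rep$top_k))])
    }
  }
})

test_that("group summaries use the sample standard deviation in percent", {
  s <- group_summary(c(0.1, 0.2, 0.3))
  expect_equal(s$mean_pct, 20.00, tolerance = 1e-12)
  expect_equal(s$sd_pct, 10.00, tolerance = 1e-12)
  same <- group_summary(c(0.25, 0.25, 0.25))
  expect_equal(same$sd_pct, 0)
  expect_error(group_summary(c(0.5)), class = "mdr_insufficient_data")
  set.seed(12)
  for (i in 1:20) {
    x <- runif(sample(2:10, 1))
    s <- group_summary(x)
    o <- oracle_mean_sd(x * 100)
    expect_equal(s$mean_pct, unname(o["mean"]), tolerance = 1e-12)
    expect_equal(s$sd_pct, unname(o["sd"]), tolerance = 1e-12)
  }
})

test_that("the concept query fixture carries 24 queries in four groups", {
  cq <- concept_queries()
  expect_equal(nrow(cq), 24)
  expect_equal(names(cq), c("group", "query"))
  expect_equal(as.integer(table(cq$group)[unique(cq$group)]), rep(6L, 4))
  expect_true("Diastolic BP" %in% cq$query)
  expect_true(all(nzchar(cq$query)))
})

test_that("reports render to CSV plus plots and round-trip losslessly", {
  res <- synthetic_store(synth_config(seed = 19, n_concepts = 12, n_documents = 30))
  ix <- build_index(res$store)
  queries <- c("body weight", "body height", "pulse rate", "serum glucose")
  reports <- list()
  for (q in queries) {
    for (mode in c("strict", "relaxed")) {
      reports[[length(reports) + 1L]] <-
        evaluate_concept(ix, res$store, q, group = "vitals", mode = mode)
    }
  }
  out <- withr::local_tempdir()
  paths <- render_report(reports, out)
  tab <- utils::read.csv(file.path(out, "report.csv"))
  expect_equal(names(tab), c("group", "query", "mode", "total", "rank",
                             "question", "occurrences", "ratio"))
  expect_true(any(grepl("cumulative_curves_strict", paths)))
  expect_true(file.exists(file.path(out, "cumulative_curves_relaxed.png")))

  back <- read_report(file.path(out, "report.csv"))
  expect_length(back, length(reports))
  for (i in seq_along(reports)) {
    orig <- reports[[i]]
    match_i <- Filter(function(r) r$query == orig$query && r$mode == orig$mode,
                      back)[[1]]
    expect_equal(match_i$total_results, orig$total_results)
    expect_equal(match_i$topk_ratio, orig$topk_ratio)
    expect_equal(match_i$top_k$question, orig$top_k$question)
    expect_equal(match_i$top_k$occurrences, orig$top_k$occurrences)
  }
  # empty report list yields a header-only CSV
  out2 <- withr::local_tempdir()
  render_report(list(), out2)
  empty <- utils::read.csv(file.path(out2, "report.csv"))
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty), names(tab))
})
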