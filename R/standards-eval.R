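# Evaluation of bottom-up standardization: per-concept search reports,
# cumulative occurrence curves, and top-k occurrence ratios.
#
# A concept's bottom-up standards are the top-ranked definitions for its
# query. The top-k occurrence ratio — summed occurrences of the top k
# results over summed occurrences of all results — measures how much of the
# real-world usage the emerging standards cover. The evaluation is
# restricted to items with an English question text and runs in two modes:
# strict (whole-definition equivalence) and relaxed (items clustered by
# their lowercase question text, occurrences summed).

#' Load the bundled concept query fixture
#'
#' 24 medical concept queries from four groups (CDASH vital signs, most
#' frequent LOINC codes, ischaemic heart disease related concepts, stroke
#' related concepts), shipped as a plain-text fixture.
#'
#' @return a [tibble::tibble] with columns `group` and `query`.
#' @export
concept_queries <- function() {
  path <- system.file("extdata", "concept_queries.tsv", package = "odmdr",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Evaluate one concept query
#'
#' Searches the index for the query, restricts results to items with an
#' English question, and reports the total number of results, the top-k
#' questions with their occurrences, and the top-k occurrence ratio. In
#' relaxed mode, hits are first merged by their lowercase English question
#' (occurrences summed; representative = highest-occurrence member) and
#' clusters are re-ranked by combined score using the summed occurrences.
#'
#' @param index an `mdr_index` built over `store`.
#' @param store the [mdr_store()].
#' @param query concept query string.
#' @param group free-text group label carried into the report.
#' @param k number of top results (default 3).
#' @param mode `"strict"` or `"relaxed"`.
#' @return an object of class `concept_report`: a list with `group`,
#'   `query`, `mode`, `k`, `total_results`, `n_strict_matches`, `top_k`
#'   (tibble `rank`, `question`, `occurrences`, `key`), `topk_ratio`
#'   (`NA` and `ratio_defined = FALSE` when there are no matches), and
#'   `occurrences_all` (occurrence multiset of all matches, for curves).
#' @export
evaluate_concept <- function(index, store, query, group = "",
                             k = 3L, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  res <- search(index, query, kind = "Item", limit = Inf)
  hits <- res$hits[!is.na(res$hits$question), , drop = FALSE]
  n_strict <- nrow(hits)

  if (mode == "relaxed" && n_strict > 0) {
    rk <- tolower(norm_text(hits$question))
    groups <- split(seq_len(n_strict), rk)
    cl <- lapply(groups, function(ix) {
      sub <- hits[ix, , drop = FALSE]
      rep_i <- order(-sub$occurrences, sub$key, method = "radix")[1]
      occ_sum <- sum(sub$occurrences)
      list(question = sub$question[rep_i], key = sub$key[rep_i],
           match_score = sub$match_score[rep_i], occurrences = occ_sum,
           combined_score = sub$match_score[rep_i] * (1 + log(occ_sum)))
    })
    hits <- tibble::tibble(
      key = unname(vapply(cl, `[[`, character(1), "key")),
      match_score = unname(vapply(cl, `[[`, numeric(1), "match_score")),
      occurrences = unname(vapply(cl, `[[`, numeric(1), "occurrences")),
      combined_score = unname(vapply(cl, `[[`, numeric(1), "combined_score")),
      question = unname(vapply(cl, `[[`, character(1), "question")))
    hits <- hits[order(-hits$combined_score, -hits$occurrences, hits$key,
                       method = "radix"), , drop = FALSE]
  }

  total <- nrow(hits)
  if (total == 0) {
    report <- list(group = group, query = query, mode = mode, k = k,
                   total_results = 0L, n_strict_matches = n_strict,
                   top_k = tibble::tibble(rank = integer(0), question = character(0),
                                          occurrences = numeric(0), key = character(0)),
                   topk_ratio = NA_real_, ratio_defined = FALSE,
                   occurrences_all = numeric(0))
    return(structure(report, class = "concept_report"))
  }
  kk <- min(k, total)
  top <- hits[seq_len(kk), , drop = FALSE]
  ratio <- sum(top$occurrences) / sum(hits$occurrences)
  structure(
    list(group = group, query = query, mode = mode, k = k,
         total_results = total, n_strict_matches = n_strict,
         top_k = tibble::tibble(rank = seq_len(kk), question = top$question,
                                occurrences = top$occurrences, key = top$key),
         topk_ratio = ratio, ratio_defined = TRUE,
         occurrences_all = hits$occurrences),
    class = "concept_report")
}

#' @export
print.concept_report <- function(x, ...) {
  cat(sprintf("<concept_report '%s' [%s, %s]: %d results, top-%d ratio %s>\n",
              x$query, x$group, x$mode, x$total_results, x$k,
              if (x$ratio_defined) sprintf("%.4f", x$topk_ratio) else "undefined"))
  invisible(x)
}

#' Cumulative occurrence curve
#'
#' For each occurrence threshold t (1 to the maximum observed), the number
#' of definitions that occurred at least t times. The curve is
#' non-increasing and its value at t = 1 is the number of distinct matching
#' definitions.
#'
#' @param occurrences multiset (numeric vector) of positive integer
#'   occurrence counts.
#' @return a [tibble::tibble] with columns `threshold` and `count`; empty
#'   input yields an empty curve.
#' @export
cumulative_curve <- function(occurrences) {
  if (length(occurrences) == 0) {
    return(tibble::tibble(threshold = integer(0), count = integer(0)))
  }
  if (any(is.na(occurrences)) || any(occurrences < 1)) {
    odmdr_error("mdr_input_error", "occurrence counts must be positive integers")
  }
  thresholds <- seq_len(max(occurrences))
  counts <- vapply(thresholds, function(t) sum(occurrences >= t), integer(1))
  tibble::tibble(threshold = thresholds, count = counts)
}

#' Group summary of top-k occurrence ratios
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' top-k occurrence ratios of a set of concept reports, expressed as
#' percentages.
#'
#' @param reports list of `concept_report`s (or a numeric vector of ratios).
#' @return a list with `mean_pct`, `sd_pct` and `n`.
#' @export
group_summary <- function(reports) {
  ratios <- if (is.numeric(reports)) reports else {
    vapply(reports, function(r) {
      stopifnot(inherits(r, "concept_report"))
      if (isTRUE(r$ratio_defined)) r$topk_ratio else NA_real_
    }, numeric(1))
  }
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) < 2) {
    odmdr_error("mdr_insufficient_data",
                "group summary requires at least 2 defined ratios")
  }
  list(mean_pct = mean(ratios) * 100, sd_pct = stats::sd(ratios) * 100,
       n = length(ratios))
}

#' Write a tabular + graphical evaluation report
#'
#' Writes `report.csv` (one row per top-k entry, columns `group`, `query`,
#' `mode`, `total`, `rank`, `question`, `occurrences`, `ratio`) and
#' `cumulative_curves_<mode>.png` (one panel per group, one curve per
#' query) under `output_dir`.
#'
#' @param reports list of `concept_report`s.
#' @param output_dir output directory (created if missing).
#' @return invisibly, the paths of the written files.
#' @export
render_report <- function(reports, output_dir) {
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) odmdr_error("mdr_io_error", sprintf("cannot create '%s'", output_dir))
  }
  rows <- lapply(reports, function(r) {
    if (nrow(r$top_k) == 0) {
      return(data.frame(group = r$group, query = r$query, mode = r$mode,
                        total = r$total_results, rank = NA_integer_,
                        question = NA_character_, occurrences = NA_real_,
                        ratio = r$topk_ratio, stringsAsFactors = FALSE))
    }
    data.frame(group = r$group, query = r$query, mode = r$mode,
               total = r$total_results, rank = r$top_k$rank,
               question = r$top_k$question, occurrences = r$top_k$occurrences,
               ratio = r$topk_ratio, stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(0), query = character(0), mode = character(0),
               total = integer(0), rank = integer(0), question = character(0),
               occurrences = numeric(0), ratio = numeric(0))
  csv_path <- file.path(output_dir, "report.csv")
  utils::write.csv(tab, csv_path, row.names = FALSE)
  paths <- csv_path

  curve_df <- do.call(rbind, lapply(reports, function(r) {
    if (length(r$occurrences_all) == 0) return(NULL)
    cc <- cumulative_curve(r$occurrences_all)
    data.frame(group = r$group, query = r$query, mode = r$mode,
               threshold = cc$threshold, count = cc$count,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(curve_df) && nrow(curve_df) > 0) {
    for (md in unique(curve_df$mode)) {
      sub <- curve_df[curve_df$mode == md, , drop = FALSE]
      p <- ggplot2::ggplot(sub, ggplot2::aes(x = .data$threshold, y = .data$count,
                                             colour = .data$query)) +
        ggplot2::geom_step(direction = "hv") +
        ggplot2::scale_y_log10() +
        ggplot2::facet_wrap(~group, scales = "free") +
        ggplot2::labs(x = "occurrence threshold t",
                      y = "definitions with occurrences ≥ t",
                      title = sprintf("Cumulative occurrences (%s equivalence)", md)) +
        ggplot2::theme_bw()
      png_path <- file.path(output_dir, sprintf("cumulative_curves_%s.png", md))
      ggplot2::ggsave(png_path, p, width = 10, height = 7, dpi = 120)
      paths <- c(paths, png_path)
    }
  }
  invisible(paths)
}

#' Reload an evaluation report CSV
#'
#' Inverse of the tabular part of [render_report()]: reconstructs one
#' `concept_report` per (group, query, mode) with its `total_results`,
#' `top_k` table and `topk_ratio` (the full occurrence multiset is not part
#' of the CSV and comes back empty).
#'
#' @param path path to a `report.csv` written by [render_report()].
#' @return list of `concept_report`s.
#' @export
read_report <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) return(list())
  keys <- unique(tab[, c("group", "query", "mode")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- tab[tab$group == keys$group[i] & tab$query == keys$query[i] &
               tab$mode == keys$mode[i], , drop = FALSE]
    has_rows <- !all(is.na(sub$rank))
    top_k <- if (has_rows) {
      sub <- sub[order(sub$rank), , drop = FALSE]
      tibble::tibble(rank = as.integer(sub$rank), question = sub$question,
                     occurrences = sub$occurrences,
                     key = rep(NA_character_, nrow(sub)))
    } else {
      tibble::tibble(rank = integer(0), question = character(0),
                     occurrences = numeric(0), key = character(0))
    }
    structure(
      list(group = keys$group[i], query = keys$query[i], mode = keys$mode[i],
           k = max(3L, nrow(top_k)), total_results = sub$total[1],
           n_strict_matches = NA_integer_, top_k = top_k,
           topk_ratio = sub$ratio[1], ratio_defined = !is.na(sub$ratio[1]),
           occurrences_all = numeric(0)),
      class = "concept_report")
  })
}
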