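# Interrater agreement for the quality survey: ordinal Krippendorff's alpha
# with bootstrap confidence intervals, plus Likert response summaries.
#
# Ratings use a five-point ordinal Likert scale: strongly disagree (SD) <
# disagree (D) < neither (N) < agree (A) < strongly agree (SA), coded 1..5.
# Missing ratings are allowed; a unit contributes to alpha only when it has
# at least two non-missing ratings (pairability).

LIKERT_LABELS <- c("SD", "D", "N", "A", "SA")

#' Construct a rating matrix
#'
#' @param ratings integer matrix, units in rows, raters in columns, values
#'   in 1..5 or `NA`; or a long data frame with columns `unit`, `rater`,
#'   `rating` and optionally `property`.
#' @param properties optional character vector, one property label per unit
#'   (used by [summarize_likert()]).
#' @return an integer matrix of class `rating_matrix` with a `properties`
#'   attribute.
#' @export
rating_matrix <- function(ratings, properties = NULL) {
  if (is.data.frame(ratings)) {
    stopifnot(all(c("unit", "rater", "rating") %in% names(ratings)))
    units <- unique(ratings$unit)
    raters <- unique(ratings$rater)
    m <- matrix(NA_integer_, nrow = length(units), ncol = length(raters),
                dimnames = list(units, raters))
    m[cbind(match(ratings$unit, units), match(ratings$rater, raters))] <-
      as.integer(ratings$rating)
    if (is.null(properties) && "property" %in% names(ratings)) {
      properties <- ratings$property[match(units, ratings$unit)]
    }
    ratings <- m
  }
  ratings <- as.matrix(ratings)
  storage.mode(ratings) <- "integer"
  bad <- !is.na(ratings) & (ratings < 1L | ratings > 5L)
  if (any(bad)) odmdr_error("mdr_input_error", "ratings must be in 1..5 or missing")
  if (!is.null(properties)) stopifnot(length(properties) == nrow(ratings))
  structure(ratings, properties = properties, class = c("rating_matrix", "matrix"))
}

#' Read a rating matrix from CSV
#'
#' Expected columns: `unit`, `property`, `rater`, `rating` (1-5 or empty;
#' empty and out-of-scale entries are treated as missing).
#'
#' @param path CSV file path.
#' @return a [rating_matrix()].
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("unit", "rater", "rating") %in% names(df)))
  r <- suppressWarnings(as.integer(df$rating))
  r[!is.na(r) & (r < 1L | r > 5L)] <- NA_integer_
  df$rating <- r
  rating_matrix(df)
}

# per-unit contributions to the coincidence matrix, as K*K columns; the
# coincidence matrix of any (re)sample of units is the column sum of the
# sampled rows, which makes the bootstrap a single matrix product.
coincidence_contributions <- function(m, K = 5L) {
  n_units <- nrow(m)
  contrib <- matrix(0, nrow = n_units, ncol = K * K)
  pairable <- logical(n_units)
  for (u in seq_len(n_units)) {
    v <- m[u, ]
    v <- v[!is.na(v)]
    mu <- length(v)
    if (mu < 2) next
    pairable[u] <- TRUE
    tab <- tabulate(v, nbins = K)
    # ordered pairs (c, k), c != k: n_c * n_k; c == k: n_c * (n_c - 1)
    pairs <- outer(tab, tab)
    diag(pairs) <- tab * (tab - 1)
    contrib[u, ] <- as.numeric(pairs) / (mu - 1)
  }
  list(contrib = contrib, pairable = pairable)
}

# squared ordinal distances between categories from coincidence marginals:
# delta2[c,k] = (sum_{g=c..k} n_g - (n_c + n_k)/2)^2
ordinal_delta2 <- function(n_c) {
  K <- length(n_c)
  S <- cumsum(n_c)
  d2 <- matrix(0, K, K)
  for (c in seq_len(K)) {
    for (k in seq_len(K)) {
      if (c == k) next
      lo <- min(c, k); hi <- max(c, k)
      between <- S[hi] - if (lo > 1) S[lo - 1] else 0
      d2[c, k] <- (between - (n_c[c] + n_c[k]) / 2)^2
    }
  }
  d2
}

metric_delta2 <- function(n_c, metric) {
  K <- length(n_c)
  switch(metric,
    ordinal = ordinal_delta2(n_c),
    nominal = 1 - diag(K),
    interval = outer(seq_len(K), seq_len(K), function(a, b) (a - b)^2))
}

alpha_from_coincidence <- function(o, metric = "ordinal") {
  K <- nrow(o)
  n_c <- rowSums(o)
  n <- sum(n_c)
  if (n <= 1) return(NA_real_)
  d2 <- metric_delta2(n_c, metric)
  D_o <- sum(o * d2) / n
  D_e <- sum(outer(n_c, n_c) * d2) / (n * (n - 1))
  if (D_e == 0) {
    if (D_o == 0) return(1) else return(NA_real_)
  }
  1 - D_o / D_e
}

#' Krippendorff's alpha
#'
#' Chance-corrected interrater agreement, `alpha = 1 - D_o / D_e`, computed
#' from the coincidence matrix of all pairable values. The default ordinal
#' difference function weights a disagreement between two categories by the
#' squared sum of the category frequencies lying between them (taken from
#' the coincidence-matrix marginals), so distant disagreements on the
#' ordered Likert scale count more than adjacent ones. Missing ratings are
#' excluded by pairability. When observed disagreement is zero, alpha is 1
#' even if expected disagreement is degenerate.
#'
#' @param matrix a [rating_matrix()] (or plain units x raters matrix).
#' @param metric `"ordinal"` (default), `"nominal"` or `"interval"`.
#' @return alpha in \[-1, 1\].
#' @export
krippendorff_alpha <- function(matrix, metric = c("ordinal", "nominal", "interval")) {
  metric <- match.arg(metric)
  m <- unclass(matrix)
  cc <- coincidence_contributions(m)
  if (!any(cc$pairable)) {
    odmdr_error("mdr_insufficient_data", "no unit has two or more ratings")
  }
  o <- matrix(colSums(cc$contrib), 5L, 5L)
  a <- alpha_from_coincidence(o, metric)
  if (is.na(a)) {
    odmdr_error("mdr_insufficient_data",
                "expected disagreement is zero with nonzero observed disagreement")
  }
  a
}

#' Bootstrap confidence interval for Krippendorff's alpha
#'
#' Resamples survey units with replacement `B` times, recomputes alpha on
#' each resample, and reports the percentile interval. Degenerate resamples
#' (no pairable values, or zero expected disagreement with nonzero observed)
#' are redrawn and counted.
#'
#' @param matrix a [rating_matrix()].
#' @param B number of bootstrap resamples (a warning is issued below 100).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; given the same seed the interval is identical
#'   across runs. The caller's RNG state is left untouched.
#' @param metric difference function, see [krippendorff_alpha()].
#' @return an object of class `alpha_result`: `alpha`, `ci_low`, `ci_high`,
#'   `n_units_used`, and `bootstrap = list(B, seed, level, redraws)`.
#' @export
bootstrap_ci <- function(matrix, B = 1000L, level = 0.95, seed = NULL,
                         metric = c("ordinal", "nominal", "interval")) {
  metric <- match.arg(metric)
  if (B < 100) warning("fewer than 100 bootstrap resamples; interval will be unstable")
  m <- unclass(matrix)
  cc <- coincidence_contributions(m)
  if (!any(cc$pairable)) {
    odmdr_error("mdr_insufficient_data", "no unit has two or more ratings")
  }
  o_full <- matrix(colSums(cc$contrib), 5L, 5L)
  alpha_hat <- alpha_from_coincidence(o_full, metric)
  n_units <- nrow(m)

  alphas <- numeric(B)
  redraws <- 0L
  with_seed_local(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n_units, n_units, replace = TRUE)
        o <- matrix(colSums(cc$contrib[idx, , drop = FALSE]), 5L, 5L)
        a <- if (sum(o) > 1) alpha_from_coincidence(o, metric) else NA_real_
        if (!is.na(a)) break
        redraws <- redraws + 1L
        if (redraws > 100L * B) {
          odmdr_error("mdr_insufficient_data", "bootstrap resamples are degenerate")
        }
      }
      alphas[b] <- a
    }
  })
  qs <- stats::quantile(alphas, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(
    list(alpha = alpha_hat, ci_low = qs[1], ci_high = qs[2],
         n_units_used = sum(cc$pairable),
         bootstrap = list(B = B, seed = seed, level = level, redraws = redraws)),
    class = "alpha_result")
}

#' @export
print.alpha_result <- function(x, ...) {
  cat(sprintf("Krippendorff's alpha = %.3f (%d%% CI %.3f-%.3f, B = %d, units = %d)\n",
              x$alpha, round(x$bootstrap$level * 100), x$ci_low, x$ci_high,
              x$bootstrap$B, x$n_units_used))
  invisible(x)
}

# evaluate `code` under a fixed seed, restoring the caller's RNG state
with_seed_local <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Summarize Likert responses per property and rater
#'
#' Counts of SD/D/N/A/SA responses, missing (undefined) units and the median
#' category for every (property, rater) combination. The median of an
#' even-length sample with two distinct middle values reports the lower
#' middle category. Counts plus undefined sum to the number of units per
#' property.
#'
#' @param matrix a [rating_matrix()] whose units carry property labels
#'   (see [rating_matrix()]), or a long data frame with columns `unit`,
#'   `property`, `rater`, `rating`.
#' @return a [tibble::tibble] with columns `property`, `rater`, `SD`, `D`,
#'   `N`, `A`, `SA`, `undefined`, `median` (factor over the Likert labels).
#' @export
summarize_likert <- function(matrix) {
  if (is.data.frame(matrix)) matrix <- rating_matrix(matrix)
  props <- attr(matrix, "properties")
  if (is.null(props)) props <- rep("all", nrow(matrix))
  m <- unclass(matrix)
  raters <- colnames(m) %||% paste0("rater", seq_len(ncol(m)))
  out <- list()
  for (p in unique(props)) {
    rows <- props == p
    for (j in seq_len(ncol(m))) {
      v <- m[rows, j]
      counts <- tabulate(v[!is.na(v)], nbins = 5L)
      med <- lower_median(v[!is.na(v)])
      out[[length(out) + 1L]] <- tibble::tibble(
        property = p, rater = raters[j],
        SD = counts[1], D = counts[2], N = counts[3], A = counts[4], SA = counts[5],
        undefined = sum(is.na(v)),
        median = factor(if (is.na(med)) NA_character_ else LIKERT_LABELS[med],
                        levels = LIKERT_LABELS))
    }
  }
  dplyr::bind_rows(out)
}

# lower-middle median of an ordinal sample (integer categories): the value
# at sorted position ceiling(n/2), i.e. the lower of two middle values
lower_median <- function(v) {
  n <- length(v)
  if (n == 0) return(NA_integer_)
  sort(v)[ceiling(n / 2)]
}
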