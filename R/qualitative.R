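# Ordinal (Likert) aggregation of reviewer scores and two-rater reliability.

likert_levels <- c("very poor", "poor", "fair", "good", "very good")

#' Map a 1-5 Likert score to its label (and back)
#'
#' Scale: 1 = very poor, 2 = poor, 3 = fair, 4 = good, 5 = very good.
#'
#' @param score Integer vector in 1..5.
#' @return Character labels.
#' @export
likert_label <- function(score) {
  if (any(is.na(score)) || any(score %% 1 != 0) || any(score < 1 | score > 5)) {
    stop("Likert scores must be integers in 1..5", call. = FALSE)
  }
  likert_levels[score]
}

#' @rdname likert_label
#' @param label Character vector of labels; case-insensitive, `_`/space
#'   tolerant (`"very_poor"` parses).
#' @export
likert_score <- function(label) {
  norm <- gsub("_", " ", tolower(trimws(label)))
  idx <- match(norm, likert_levels)
  if (any(is.na(idx))) {
    stop("unknown Likert label(s): ",
         paste(unique(label[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}

round_half <- function(x, tie = c("half_up", "half_even")) {
  tie <- match.arg(tie)
  if (tie == "half_up") round_half_up(x) else round(x)
}

#' Consensus rating for one criterion
#'
#' Median of the raters' scores, rounded to the nearest integer. With two
#' raters one level apart the median is a half-integer; the default tie
#' rule rounds half *up* (toward the better rating), with `tie =
#' "half_even"` available for sensitivity analysis.
#'
#' @param scores Integer vector of per-rater scores in 1..5.
#' @param tie `"half_up"` (default) or `"half_even"`.
#' @return Integer consensus score with the label as the `"label"` attribute.
#' @examples
#' consensus_rating(c(2, 3))
#' @export
consensus_rating <- function(scores, tie = c("half_up", "half_even")) {
  if (length(scores) == 0) stop("`scores` must be nonempty", call. = FALSE)
  if (any(is.na(scores)) || any(scores %% 1 != 0) || any(scores < 1 | scores > 5)) {
    stop("scores must be integers in 1..5", call. = FALSE)
  }
  out <- as.integer(round_half(stats::median(scores), tie))
  structure(out, label = likert_label(out))
}

#' Overall rating across criteria
#'
#' Unweighted arithmetic mean of the per-criterion consensus ratings,
#' rounded to the nearest integer (same tie rule as
#' [consensus_rating()]) and mapped to its label.
#'
#' @param consensus_by_criterion Integer vector of consensus scores, 1..5.
#' @inheritParams consensus_rating
#' @return Integer overall score with a `"label"` attribute.
#' @examples
#' overall_rating(c(2, 2, 4, 2, 2, 1, 2, 2))
#' @export
overall_rating <- function(consensus_by_criterion, tie = c("half_up", "half_even")) {
  if (length(consensus_by_criterion) == 0) {
    stop("`consensus_by_criterion` must be nonempty", call. = FALSE)
  }
  if (any(is.na(consensus_by_criterion)) ||
      any(consensus_by_criterion < 1 | consensus_by_criterion > 5)) {
    stop("consensus scores must lie in 1..5", call. = FALSE)
  }
  out <- as.integer(round_half(mean(consensus_by_criterion), tie))
  structure(out, label = likert_label(out))
}

#' Cronbach's alpha with raters as the test components
#'
#' For a raters-by-items score matrix, treats each rater as one component
#' scored across the items:
#' `alpha = k/(k-1) * (1 - sum_i var(rater_i) / var(item totals))`,
#' with sample variances (n-1). Used here as a two-rater reliability
#' coefficient; identical raters over items with spread give exactly 1.
#'
#' @param scores Numeric matrix, raters in rows (>= 2), items in columns
#'   (>= 2).
#' @return Alpha, a single number <= 1 (unbounded below).
#' @examples
#' cronbach_alpha(rbind(c(1, 2, 3, 4), c(1, 2, 3, 4)))
#' @export
cronbach_alpha <- function(scores) {
  scores <- as.matrix(scores)
  if (!is.numeric(scores) || nrow(scores) < 2 || ncol(scores) < 2) {
    stop("`scores` must be a numeric matrix with >= 2 raters and >= 2 items",
         call. = FALSE)
  }
  if (anyNA(scores)) stop("`scores` must be complete", call. = FALSE)
  k <- nrow(scores)
  total_var <- stats::var(colSums(scores))
  if (total_var == 0) {
    stop("total score variance is zero: alpha is undefined for constant totals",
         call. = FALSE)
  }
  rater_vars <- apply(scores, 1, stats::var)
  k / (k - 1) * (1 - sum(rater_vars) / total_var)
}

#' Count rater disagreements
#'
#' @param scores 2-by-items score matrix.
#' @return Number of items where the two raters differ.
#' @export
disagreement_count <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) != 2) stop("`scores` must have exactly 2 raters", call. = FALSE)
  sum(scores[1, ] != scores[2, ])
}

#' Summarise a two-rater rating sheet
#'
#' Per-criterion consensus (median, tie rule as configured), overall
#' rating, disagreement count and Cronbach's alpha for one respondent's
#' sheet.
#'
#' @param scores 2-by-criteria integer matrix in 1..5.
#' @param criteria Criterion names; defaults to the matrix column names.
#' @inheritParams consensus_rating
#' @return List: `consensus` tibble (criterion, rater scores, consensus,
#'   label), `overall` score, `overall_label`, `disagreements`, `alpha`.
#' @export
rating_summary <- function(scores, criteria = colnames(scores),
                           tie = c("half_up", "half_even")) {
  tie <- match.arg(tie)
  scores <- as.matrix(scores)
  if (is.null(criteria)) criteria <- paste0("criterion_", seq_len(ncol(scores)))
  cons <- vapply(seq_len(ncol(scores)),
                 function(j) as.integer(consensus_rating(scores[, j], tie)),
                 integer(1))
  overall <- overall_rating(cons, tie)
  list(
    consensus = tibble::tibble(
      criterion = criteria,
      rater_1 = scores[1, ], rater_2 = scores[2, ],
      consensus = cons, label = likert_label(cons)
    ),
    overall = as.integer(overall),
    overall_label = attr(overall, "label"),
    disagreements = disagreement_count(scores),
    alpha = tryCatch(cronbach_alpha(scores), error = function(e) NA_real_)
  )
}
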