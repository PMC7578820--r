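## Stage metrics: exact-match entity-level precision/recall/F1, intraclass
## correlation (two-way random effects, absolute agreement) with an
## F-distribution 95% CI, and Likert score summaries.

#' Entity-level precision/recall/F1
#'
#' A prediction is a true positive iff its (start, end, span type) triple
#' exactly matches a gold mention of the same document. F1 = 2PR/(P+R),
#' with the 0/0 convention mapped to 0.
#'
#' @param gold,pred Lists (one element per document) of mention data.frames
#'   with columns `start`, `end`, `sem_type`; a single data.frame is treated
#'   as a one-document corpus. Both must cover the same document set, in the
#'   same order.
#' @return List with `micro` (precision/recall/f1/support) and `per_type`
#'   data.frame.
#' @export
ner_metrics <- function(gold, pred) {
  if (is.data.frame(gold)) gold <- list(gold)
  if (is.data.frame(pred)) pred <- list(pred)
  if (length(gold) != length(pred)) stopf("gold and pred must cover the same documents")
  key <- function(df, doc) if (nrow(df)) sprintf("%d:%d:%d:%s", doc, df$start, df$end, df$sem_type) else character()
  gk <- unlist(lapply(seq_along(gold), function(i) key(gold[[i]], i)))
  pk <- unlist(lapply(seq_along(pred), function(i) key(pred[[i]], i)))
  gt <- unlist(lapply(gold, function(df) df$sem_type))
  pt <- unlist(lapply(pred, function(df) df$sem_type))
  tp_mask <- pk %in% gk
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f)
  }
  types <- sort(unique(c(gt, pt)))
  per_type <- do.call(rbind, lapply(types, function(ty) {
    tp <- sum(tp_mask & pt == ty)
    fp <- sum(!tp_mask & pt == ty)
    fn <- sum(!(gk[gt == ty] %in% pk))
    data.frame(sem_type = ty, t(prf(tp, fp, fn)), support = sum(gt == ty),
               stringsAsFactors = FALSE)
  }))
  tp <- sum(tp_mask); fp <- sum(!tp_mask); fn <- sum(!(gk %in% pk))
  list(micro = c(prf(tp, fp, fn), support = length(gk), tp = tp, fp = fp, fn = fn),
       per_type = per_type %||% data.frame())
}

#' Reliability category for an intraclass correlation value
#'
#' Bands: 1.0 perfect, (0.81, 1) excellent, (0.60, 0.81] substantial,
#' (0.40, 0.60] moderate, (0.20, 0.40] fair, otherwise slight. The printed
#' bands leave (0.80, 0.81] unassigned; it is folded into "substantial"
#' (half-open intervals, "excellent" strictly above 0.81).
#'
#' @param icc Numeric ICC value.
#' @return One of perfect/excellent/substantial/moderate/fair/slight.
#' @export
icc_category <- function(icc) {
  if (icc >= 1 - 1e-12) "perfect"
  else if (icc > 0.81) "excellent"
  else if (icc > 0.60) "substantial"
  else if (icc > 0.40) "moderate"
  else if (icc > 0.20) "fair"
  else "slight"
}

#' Intraclass correlation coefficient with 95% CI
#'
#' Two-way random-effects, absolute-agreement ICC. The default
#' average-measures form (ICC(A,k) in McGraw & Wong terms) fits a panel in
#' which every rater scored every item and one coefficient is reported per
#' dimension; `form = "single"` gives ICC(A,1). The 95% CI uses the
#' F-distribution approximation with Satterthwaite degrees of freedom;
#' average-measures bounds are the Spearman-Brown step-up of the
#' single-measure bounds.
#'
#' @param ratings Numeric matrix, raters in rows and items in columns, no
#'   missing cells.
#' @param form `"average"` (default) or `"single"`.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, `category`, `form`,
#'   `n_items`, `n_raters`.
#' @export
icc <- function(ratings, form = c("average", "single"), conf_level = 0.95) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2 || ncol(ratings) < 2) stopf("need >= 2 raters and >= 2 items")
  if (anyNA(ratings)) stopf("missing cells not supported")
  x <- t(ratings) # items (subjects) x raters
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  if (stats::var(as.vector(x)) < .Machine$double.eps)
    stopf("degenerate ratings: no variance across items or raters")
  MSR <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  MSC <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  SSE <- sum((x - outer(rowMeans(x), colMeans(x), `+`) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc_k <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
  icc_1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  alpha <- 1 - conf_level
  if (MSE < .Machine$double.eps && MSC < .Machine$double.eps) {
    lo1 <- hi1 <- 1 # perfect agreement: all rater/error variance zero
  } else {
    r <- icc_1
    a <- k * r / (n * (1 - r))
    b <- 1 + k * r * (n - 1) / (n * (1 - r))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lo1 <- n * (MSR - FL * MSE) / (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi1 <- n * (FU * MSR - MSE) / (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  }
  sb <- function(r1) k * r1 / (1 + (k - 1) * r1)
  est <- if (form == "average") icc_k else icc_1
  ci <- if (form == "average") c(sb(lo1), sb(hi1)) else c(lo1, hi1)
  list(icc = est, ci_low = ci[1], ci_high = ci[2], category = icc_category(est),
       form = form, n_items = n, n_raters = k)
}

#' Summarize Likert-scale quality scores
#'
#' @param scores Numeric matrix of scores in 1..5, raters in rows, metrics
#'   in columns (column names are metric names).
#' @return List with `per_metric` means and the `overall` mean.
#' @export
likert_summary <- function(scores) {
  scores <- as.matrix(scores)
  if (any(is.na(scores)) || any(scores < 1) || any(scores > 5))
    stopf("scores must lie in 1..5 with no missing values")
  list(per_metric = colMeans(scores), overall = mean(scores))
}
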