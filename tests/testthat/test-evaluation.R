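gold1 <- data.frame(start = c(0L, 10L), end = c(4L, 12L),
                    sem_type = c("disease", "symptom"), stringsAsFactors = FALSE)

test_that("ner_metrics counts exact (start, end, type) matches", {
  expect_equal(unname(ner_metrics(gold1, gold1)$micro[c("precision", "recall", "f1")]),
               c(1, 1, 1))
  none <- gold1[0, ]
  m <- ner_metrics(gold1, none)$micro
  expect_equal(unname(m[c("precision", "recall", "f1")]), c(0, 0, 0))
  ## 2 gold, 1 correct + 1 spurious: P = R = F1 = 0.5
  pred <- data.frame(start = c(0L, 20L), end = c(4L, 22L),
                     sem_type = c("disease", "sign"), stringsAsFactors = FALSE)
  m2 <- ner_metrics(gold1, pred)$micro
  expect_equal(unname(m2[c("precision", "recall", "f1")]), c(0.5, 0.5, 0.5))
  ## a type mismatch at the right offsets is both a FP and a FN
  predt <- gold1; predt$sem_type[1] <- "test"
  m3 <- ner_metrics(gold1, predt)$micro
  expect_equal(unname(m3["tp"]), 1)
  ## swapping gold and predicted swaps precision and recall
  m4 <- ner_metrics(pred, gold1)$micro
  expect_equal(m4[["precision"]], m2[["recall"]])
  expect_equal(m4[["recall"]], m2[["precision"]])
})

test_that("icc matches the independent reference implementation", {
  ## expected values computed with pingouin.intraclass_corr (ICC(A,1)/(A,k),
  ## two-way random effects, absolute agreement) and frozen here
  m1 <- matrix(c(3.2, 3.4, 4.3, 2.6, 2.0, 2.8, 2.3, 4.9,
                 1.1, 2.4, 1.4, 3.9, 2.7, 3.0, 4.9, 3.7,
                 4.5, 3.7, 3.0, 2.1, 3.8, 3.4, 4.5, 3.9,
                 2.2, 4.4, 3.6, 1.7, 2.1, 4.2, 1.4, 3.1,
                 3.0, 2.4, 3.6, 3.9, 3.5, 4.8, 3.9, 4.5), nrow = 5, byrow = TRUE)
  r1 <- icc(m1, form = "single")
  expect_lt(abs(r1$icc - (-0.019989)), 1e-5)
  expect_equal(c(r1$ci_low, r1$ci_high), c(-0.152432, 0.364529), tolerance = 1e-5)
  rk <- icc(m1)
  expect_equal(rk$icc, -0.108632, tolerance = 1e-5)
  expect_equal(c(rk$ci_low, rk$ci_high), c(-1.952895, 0.741480), tolerance = 1e-5)
  m2 <- matrix(c(3.7, 4.7, 4.1, 1.5, 2.2, 4.8, 1.0, 4.1, 3.4, 2.4,
                 2.8, 4.5, 3.6, 2.0, 2.3, 4.4, 1.0, 4.1, 4.2, 2.9,
                 2.9, 4.4, 3.7, 1.6, 2.6, 4.2, 1.0, 4.6, 4.0, 2.8,
                 3.5, 4.6, 3.6, 1.9, 2.7, 3.9, 1.4, 4.3, 3.9, 3.7,
                 3.8, 4.1, 4.1, 2.1, 2.1, 4.8, 1.0, 4.6, 4.8, 2.6), nrow = 5, byrow = TRUE)
  r2 <- icc(m2)
  expect_equal(r2$icc, 0.98266156, tolerance = 1e-6)
  expect_equal(icc(m2, form = "single")$icc, 0.91893030, tolerance = 1e-6)
  expect_equal(r2$category, "excellent")
})

test_that("icc handles perfect and degenerate agreement", {
  perfect <- matrix(rep(1:6, each = 4), nrow = 4) # raters identical, items vary
  r <- icc(perfect)
  expect_equal(r$icc, 1)
  expect_equal(r$category, "perfect")
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))
  expect_error(icc(matrix(3, 4, 5)), "degenerate")
  expect_error(icc(matrix(1:4, 1)), ">= 2 raters")
})

test_that("icc recovers the analytic value on simulated two-way data", {
  set.seed(99)
  n <- 1000; k <- 5
  s_item <- 1.0; s_rater <- 0.3; s_err <- 0.5 # variance components
  item <- rnorm(n, sd = sqrt(s_item))
  ## rescale the k=5 rater effects to their exact nominal variance, else
  ## their sampling noise dominates the Monte-Carlo error at any n_items
  rater <- rnorm(k); rater <- (rater - mean(rater)) / stats::sd(rater) * sqrt(s_rater)
  x <- outer(rater, item, `+`) + rnorm(n * k, sd = sqrt(s_err))
  analytic <- s_item / (s_item + (s_rater + s_err) / k) # ICC(A,k)
  expect_equal(icc(x)$icc, analytic, tolerance = 0.02)
})

test_that("reliability categories follow the printed bands", {
  expect_equal(icc_category(0.97), "excellent")
  expect_equal(icc_category(0.76), "substantial")
  expect_equal(icc_category(0.23), "fair")
  expect_equal(icc_category(0.55), "moderate")
  expect_equal(icc_category(0.1), "slight")
  expect_equal(icc_category(1.0), "perfect")
})

test_that("likert_summary computes plain means and validates the scale", {
  expect_equal(likert_summary(matrix(5, 3, 4))$overall, 5)
  one <- matrix(c(4, 3, 5), 1, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(likert_summary(one)$per_metric, c(a = 4, b = 3, c = 5))
  set.seed(12)
  m <- matrix(sample(1:5, 45, replace = TRUE), 5, 9)
  ls <- likert_summary(m)
  expect_equal(unname(ls$per_metric), apply(m, 2, function(col) sum(col) / length(col)))
  expect_equal(ls$overall, sum(m) / length(m))
  expect_error(likert_summary(matrix(c(1, 6), 1)), "1..5")
})
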