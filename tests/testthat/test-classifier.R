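test_that("metric formulas hold exactly on integer confusion counts", {
  mk <- function(tp, tn, fp, fn) {
    y <- c(rep("non-LTS", tp + fn), rep("LTS", tn + fp))
    p <- c(rep(0.9, tp), rep(0.1, fn), rep(0.1, tn), rep(0.9, fp))
    compute_metrics(y, p)
  }
  m <- mk(9, 9, 1, 1)
  expect_equal(m$accuracy, 0.90)
  expect_equal(m$precision, 0.90)
  expect_equal(m$recall, 0.90)
  expect_equal(m$f1, 0.90)
  expect_equal(unname(m$confusion), c(9L, 9L, 1L, 1L))

  ## every prediction positive on a 4-positive / 1-negative toy
  m2 <- compute_metrics(c(rep("non-LTS", 4), "LTS"), rep(0.8, 5))
  expect_equal(m2$recall, 1.0)
  expect_equal(m2$precision, 0.8)

  ## f1 is the harmonic mean of reported precision and recall
  set.seed(2)
  for (i in 1:10) {
    cm <- mk(sample(0:20, 1), sample(0:20, 1), sample(1:20, 1), sample(1:20, 1))
    if (is.na(cm$f1)) next
    expect_equal(cm$f1,
                 2 * cm$precision * cm$recall / (cm$precision + cm$recall),
                 tolerance = 1e-9)
  }

  ## undefined precision -> NA, mirroring all-negative predictions
  m3 <- compute_metrics(c("non-LTS", "LTS"), c(0.1, 0.2))
  expect_true(is.na(m3$precision))
  expect_true(is.na(m3$f1))
})

test_that("rank-statistic AUC behaves like a proper ROC area", {
  y <- c(rep("non-LTS", 3), rep("LTS", 3))
  expect_equal(compute_metrics(y, c(.9, .8, .7, .3, .2, .1))$auc, 1.0)
  expect_equal(compute_metrics(y, c(.1, .2, .3, .7, .8, .9))$auc, 0.0)

  ## invariant under strictly monotone transforms of the scores
  set.seed(9)
  sc <- runif(40); yy <- sample(c("LTS", "non-LTS"), 40, replace = TRUE)
  a1 <- compute_metrics(yy, sc)$auc
  a2 <- compute_metrics(yy, plogis(5 * sc - 2))$auc
  expect_equal(a1, a2)

  ## agrees with an independent ROC implementation
  skip_if_not_installed("pROC")
  a3 <- as.numeric(pROC::auc(pROC::roc(yy, sc, levels = c("LTS", "non-LTS"),
                                       direction = "<", quiet = TRUE)))
  expect_equal(a1, a3, tolerance = 1e-12)

  ## single-class input: NA with a warning
  expect_warning(m <- compute_metrics(rep("LTS", 4), runif(4)), "one class")
  expect_true(is.na(m$auc))

  ## probability matrices must be normalized
  bad <- matrix(c(0.6, 0.6, 0.3, 0.3), 2, dimnames = list(NULL, c("LTS", "non-LTS")))
  expect_error(compute_metrics(c("LTS", "LTS"), bad), "sum to 1")
})

test_that("stratified folds preserve class proportions and partition the cohort", {
  y <- c(rep("A", 23), rep("B", 37))
  f <- stratified_folds(y, k = 5, seed = 3)
  expect_setequal(unique(f), 1:5)
  glob <- mean(y == "A")
  for (k in 1:5) {
    nk <- sum(f == k)
    expect_lte(abs(sum(y[f == k] == "A") - glob * nk), 1)  # within one sample
  }
  ## 5 per class, k = 5: every fold has one of each
  y2 <- rep(c("A", "B"), each = 5)
  f2 <- stratified_folds(y2, 5, seed = 1)
  for (k in 1:5) expect_equal(sort(y2[f2 == k]), c("A", "B"))
  expect_error(stratified_folds(y2, 6, seed = 1), "smallest class")
})

test_that("cross-validation partitions the cohort and pools correctly", {
  co <- small_cohort(seed = 13)
  ds <- small_dataset(co)
  cv <- cross_validate(ds, co$pathways, n_pcs = 1L, k = 3L,
                       mode = "fold-safe", cnn = tiny_cnn(epochs = 4L),
                       seed = 21)
  ## fold test sets are disjoint and exhaustive
  ids <- unlist(lapply(cv$folds, `[[`, "test_ids"))
  expect_setequal(ids, ds$samples)
  expect_equal(length(ids), length(ds$samples))
  ## pooled report covers everyone; metrics are well-formed
  expect_equal(cv$pooled$n, length(ds$samples))
  expect_equal(sum(cv$pooled$confusion), length(ds$samples))
  expect_true(cv$pooled$auc >= 0 && cv$pooled$auc <= 1)
  ## fold-safe images carry both class blocks
  expect_equal(dim(cv$prob)[2], 2L)
})
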