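## classifier: evaluation metrics (accuracy, precision, recall, F1, AUC,
## confusion counts) and stratified k-fold cross-validation over pathway-PC
## image stacks.  The non-long-term survivor class is the positive class
## throughout.

#' Compute the binary classification metric suite
#'
#' Counts TP/TN/FP/FN at a probability threshold on the positive class,
#' then accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' the F1 harmonic mean, and the AUC computed by the rank (Mann-Whitney)
#' statistic over positive-class probabilities (tie-robust via midranks).
#' Precision and F1 are reported as `NA` when no positive predictions are
#' made; AUC is `NA` (with a warning) when only one class is present.
#'
#' @param y_true true labels (factor/character).
#' @param y_prob matrix of class probabilities with class column names, or a
#'   numeric vector of positive-class probabilities.
#' @param positive_class label of the positive class (default `"non-LTS"`).
#' @param threshold decision threshold on the positive-class probability
#'   (default 0.5).
#' @return object of class `metrics_report`.
#' @export
compute_metrics <- function(y_true, y_prob, positive_class = "non-LTS",
                            threshold = 0.5) {
  y_true <- as.character(y_true)
  if (is.matrix(y_prob)) {
    if (!positive_class %in% colnames(y_prob)) {
      stop("probability matrix has no column '", positive_class, "'", call. = FALSE)
    }
    sums <- rowSums(y_prob)
    if (any(abs(sums - 1) > 1e-6)) {
      stop("probability rows must sum to 1", call. = FALSE)
    }
    p_pos <- y_prob[, positive_class]
  } else {
    p_pos <- as.numeric(y_prob)
  }
  stopifnot(length(p_pos) == length(y_true))
  is_pos <- y_true == positive_class
  pred_pos <- p_pos >= threshold
  TP <- sum(pred_pos & is_pos); FP <- sum(pred_pos & !is_pos)
  FN <- sum(!pred_pos & is_pos); TN <- sum(!pred_pos & !is_pos)
  acc <- (TP + TN) / length(y_true)
  prec <- if (TP + FP == 0L) NA_real_ else TP / (TP + FP)
  rec <- if (TP + FN == 0L) NA_real_ else TP / (TP + FN)
  f1 <- if (is.na(prec) || is.na(rec) || (prec + rec) == 0) NA_real_ else
    2 * prec * rec / (prec + rec)
  auc <- auc_rank(p_pos, is_pos)
  structure(list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
                 auc = auc,
                 confusion = c(TP = TP, TN = TN, FP = FP, FN = FN),
                 n = length(y_true), positive_class = positive_class,
                 threshold = threshold),
            class = "metrics_report")
}

## AUC via the Mann-Whitney rank statistic (equals the trapezoidal ROC area).
auc_rank <- function(scores, is_pos) {
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) {
    warning("AUC undefined: only one class present", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf("accuracy %s  precision %s  recall %s  f1 %s  auc %s  (n = %d, positive = %s)\n",
              fmt(x$accuracy), fmt(x$precision), fmt(x$recall), fmt(x$f1),
              fmt(x$auc), x$n, x$positive_class))
  cm <- x$confusion
  cat(sprintf("confusion: TP %d  TN %d  FP %d  FN %d\n",
              cm["TP"], cm["TN"], cm["FP"], cm["FN"]))
  invisible(x)
}

#' Stratified fold assignment
#'
#' Deals each class's shuffled samples round-robin over `k` folds, so every
#' fold's class proportions are within one sample of the cohort's.
#'
#' @param y class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`, aligned with `y`.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  y <- as.character(y)
  if (k > min(table(y))) {
    stop("k = ", k, " exceeds the smallest class size (", min(table(y)), ")",
         call. = FALSE)
  }
  folds <- integer(length(y))
  with_seed(derive_seed(seed, "folds"), {
    for (cl in unique(y)) {
      ix <- sample(which(y == cl))
      folds[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  folds
}

#' Stratified k-fold cross-validation of the pathway-CNN classifier
#'
#' In `"fold-safe"` mode the PCA embedding bank is refitted on each training
#' fold only, every sample is embedded under both classes' models, training
#' images are additionally cross-fitted (see [build_image_stack()]) so that
#' every image is an out-of-sample projection, and column normalization
#' uses training statistics: no label information reaches the held-out
#' samples and no in-sample artifact separates train from test.  In `"own-class"` mode a single
#' all-sample, own-class embedding is built once and only the CNN is
#' cross-validated (the method's original formulation; its embedding
#' consults labels, so treat its scores as optimistic).
#'
#' @param dataset a `harmonized_dataset`.
#' @param pathways a [pathway_collection()].
#' @param n_pcs principal components per (class, omics, pathway) model.
#' @param k number of folds (default 5).
#' @param mode `"fold-safe"` (default) or `"own-class"`.
#' @param cnn a [cnn_config()].
#' @param seed master seed for fold assignment and per-fold training.
#' @param labels optional label override aligned with `dataset$samples`
#'   (used by permutation controls); defaults to the dataset's labels.
#' @param keep_models keep each fold's trained `cnn_model` (default FALSE).
#' @return object of class `cv_result`: per-fold metrics, pooled
#'   (micro-averaged) metrics over the concatenated held-out predictions,
#'   fold assignment, and the pooled out-of-fold probability matrix.
#' @export
cross_validate <- function(dataset, pathways, n_pcs = 2L, k = 5L,
                           mode = c("fold-safe", "own-class"),
                           cnn = cnn_config(), seed = 1L, labels = NULL,
                           keep_models = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "harmonized_dataset"))
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(dataset$samples))
    dataset$labels <- data.frame(sample_id = dataset$samples,
                                 class = factor(labels),
                                 stringsAsFactors = FALSE)
  }
  y <- dataset$labels$class[match(dataset$samples, dataset$labels$sample_id)]
  folds <- stratified_folds(y, k, seed)
  ids <- dataset$samples

  full_stack <- NULL
  if (mode == "own-class") {
    full_stack <- build_image_stack(dataset, pathways, n_pcs, mode = "own-class")
  }
  fold_res <- vector("list", k)
  all_prob <- NULL; all_true <- character(); all_ids <- character()
  for (f in seq_len(k)) {
    te <- which(folds == f); tr <- which(folds != f)
    stack <- if (mode == "fold-safe") {
      build_image_stack(dataset, pathways, n_pcs, mode = "fold-safe",
                        train_ids = ids[tr],
                        seed = derive_seed(seed, paste0("embed", f)))
    } else full_stack
    cfg <- cnn
    cfg$seed <- derive_seed(seed, paste0("fold", f))
    fit <- train_cnn(NULL, stack$images[tr, , , drop = FALSE], y[tr], cfg)
    prob <- predict(fit, stack$images[te, , , drop = FALSE])
    m <- compute_metrics(y[te], prob)
    fold_res[[f]] <- list(fold = f, test_ids = ids[te], metrics = m,
                          prob = prob,
                          model = if (keep_models) fit else NULL)
    all_prob <- rbind(all_prob, prob)
    all_true <- c(all_true, as.character(y[te]))
    all_ids <- c(all_ids, ids[te])
  }
  pooled <- compute_metrics(all_true, all_prob)
  structure(list(folds = fold_res, pooled = pooled, mode = mode, k = k,
                 fold_assignment = stats::setNames(folds, ids),
                 prob = all_prob, true = all_true, ids = all_ids,
                 n_pcs = n_pcs, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d-fold, %s embedding>\npooled: ", x$k, x$mode))
  print(x$pooled)
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) {
  print(object)
  per <- t(vapply(object$folds, function(f) {
    m <- f$metrics
    c(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
      f1 = m$f1, auc = m$auc)
  }, numeric(5)))
  rownames(per) <- paste0("fold", seq_len(nrow(per)))
  print(round(per, 4))
  invisible(object)
}

#' Metrics report as a one-row data frame
#' @param x a `metrics_report`.
#' @param ... unused.
#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(accuracy = x$accuracy, precision = x$precision,
             recall = x$recall, f1 = x$f1, auc = x$auc,
             TP = x$confusion[["TP"]], TN = x$confusion[["TN"]],
             FP = x$confusion[["FP"]], FN = x$confusion[["FN"]],
             n = x$n)
}
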