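## attribution: Monte-Carlo path-integral (gradient SHAP style) feature
## attribution over the trained CNN, class-global aggregation, top-k
## feature selection, and pathway/omics roll-up with common/unique set
## analysis across classes.

#' Gradient-SHAP configuration
#'
#' Attributions are estimated as the Monte-Carlo average, over sampled
#' baselines and uniform path positions (stratified over the unit interval
#' within each baseline, which leaves every draw marginally uniform but
#' sharply reduces integration variance), of the input gradient of the
#' target-class probability at interpolated points, scaled by
#' (input - baseline).  Baselines are training images perturbed with
#' Gaussian noise, which decouples the estimate from any single reference
#' point.
#'
#' @param n_baselines baselines drawn (with replacement) from the training
#'   images per explained input (default 50).
#' @param n_path_samples uniform interpolation points per baseline
#'   (default 4), so `n_baselines * n_path_samples` gradient evaluations.
#' @param noise_sd standard deviation of the Gaussian baseline perturbation;
#'   `NULL` (default) uses 0.1 x the per-cell standard deviation of the
#'   training images.
#' @param seed integer seed; attributions are deterministic given it.
#' @return list of class `gradient_shap_config`.
#' @export
gradient_shap_config <- function(n_baselines = 50L, n_path_samples = 4L,
                                 noise_sd = NULL, seed = 1L) {
  stopifnot(n_baselines >= 1L, n_path_samples >= 1L,
            is.null(noise_sd) || noise_sd >= 0)
  structure(list(n_baselines = as.integer(n_baselines),
                 n_path_samples = as.integer(n_path_samples),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "gradient_shap_config")
}

#' Gradient-SHAP attribution map for one input image
#'
#' Estimates, for every cell i of the image,
#' `phi_i = E[ d f_target(x' + a (x - x')) / d x_i * (x_i - x'_i) ]`
#' with baselines `x'` drawn from `baselines` plus Gaussian noise and
#' `a ~ Uniform(0, 1)`.  All `n_baselines * n_path_samples` interpolated
#' points are pushed through the network as one batch, and gradients come
#' from the analytic backward pass.  By the completeness property of
#' path-integral attributions, `sum(phi)` approximates
#' `f_target(x) - mean f_target(x')`.
#'
#' @param model a trained `cnn_model`.
#' @param x the image to explain (`n_pathways x n_cols` matrix).
#' @param target_class class whose probability is attributed (label or
#'   column index).
#' @param baselines array `(M, H, W)` of reference images (typically the
#'   training stack), or a single image matrix.
#' @param config a [gradient_shap_config()].
#' @param output attribute the softmax `"prob"` (default) or the raw
#'   `"logit"` of the target class; for a linear logit the path integral is
#'   exact.
#' @return matrix of attributions, same shape and dimnames as `x`, of class
#'   `attribution_map`; attributes `target_class`, `f_x`, `f_baseline_mean`.
#' @export
gradient_shap <- function(model, x, target_class, baselines,
                          config = gradient_shap_config(),
                          output = c("prob", "logit")) {
  output <- match.arg(output)
  stopifnot(inherits(model, "cnn_model"), model$trained)
  dn <- dimnames(x)
  x <- as.matrix(x)
  if (is.matrix(baselines)) baselines <- array(baselines, c(1L, dim(baselines)))
  if (length(dim(baselines)) != 3L || dim(baselines)[1L] < 1L) {
    stop("need at least one baseline image", call. = FALSE)
  }
  if (is.character(target_class)) {
    tc <- match(target_class, model$classes)
    if (is.na(tc)) stop("unknown class '", target_class, "'", call. = FALSE)
  } else tc <- as.integer(target_class)

  H <- dim(x)[1L]; W <- dim(x)[2L]
  ns <- config$n_baselines * config$n_path_samples
  with_seed(config$seed, {
    sd0 <- config$noise_sd
    if (is.null(sd0)) sd0 <- 0.1 * mean(apply(baselines, c(2L, 3L), stats::sd))
    bi <- rep(sample.int(dim(baselines)[1L], config$n_baselines, replace = TRUE),
              each = config$n_path_samples)
    bl <- baselines[bi, , , drop = FALSE]
    if (sd0 > 0) bl <- bl + array(stats::rnorm(length(bl), 0, sd0), dim(bl))
    ## each baseline's path positions are stratified over [0, 1]: every
    ## draw is still marginally uniform, with far lower integration variance
    np <- config$n_path_samples
    alpha <- (rep(seq_len(np), config$n_baselines) - stats::runif(ns)) / np
    xs <- array(rep(x, each = ns), c(ns, H, W))
    diffs <- xs - bl
    ## interpolate: x' + alpha (x - x'); alpha varies along the batch dim
    pts <- bl + diffs * array(alpha, dim(diffs))
    grads <- cnn_input_gradient(model, pts, tc, output = output)
    phi <- apply(grads * diffs, c(2L, 3L), mean)
    fv <- function(z) {
      fw <- cnn_forward(model, z)
      if (output == "prob") fw$probs[, tc] else fw$logits[, tc]
    }
    f_x <- fv(array(x, c(1L, H, W)))[1L]
    f_b <- mean(fv(bl))
    dimnames(phi) <- dn
    structure(phi, class = c("attribution_map", "matrix"),
              target_class = model$classes[tc] %||% tc,
              f_x = f_x, f_baseline_mean = f_b)
  })
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf("<attribution_map (%dx%d) target '%s': sum(phi) = %.4f, f(x) - E f(x') = %.4f>\n",
              nrow(x), ncol(x), attr(x, "target_class"),
              sum(x), attr(x, "f_x") - attr(x, "f_baseline_mean")))
  invisible(x)
}

#' Attribution maps for a whole cohort
#'
#' Computes one class-targeted map per sample (target = the sample's own
#' class by default, or the model's predicted class).
#'
#' @param model trained `cnn_model`.
#' @param stack an `image_stack` (its images are also the baseline pool).
#' @param labels class labels aligned with `stack$sample_ids`.
#' @param config a [gradient_shap_config()]; each sample derives its own
#'   sub-seed so results are independent of cohort order.
#' @param target `"true"` (default) or `"predicted"`.
#' @param baseline_ids optional subset of sample ids to use as the baseline
#'   pool (e.g. training samples only).
#' @return list of `attribution_map`s named by sample id.
#' @export
cohort_attributions <- function(model, stack, labels,
                                config = gradient_shap_config(),
                                target = c("true", "predicted"),
                                baseline_ids = NULL) {
  target <- match.arg(target)
  labels <- as.character(labels)
  stopifnot(length(labels) == length(stack$sample_ids))
  pool <- stack$images
  if (!is.null(baseline_ids)) {
    pool <- stack$images[match(baseline_ids, stack$sample_ids), , , drop = FALSE]
  }
  if (target == "predicted") {
    labels <- as.character(predict(model, stack, type = "class"))
  }
  maps <- vector("list", length(stack$sample_ids))
  names(maps) <- stack$sample_ids
  for (i in seq_along(stack$sample_ids)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("shap", i))
    img <- stack$images[i, , ]
    dimnames(img) <- list(stack$row_labels, stack$col_labels)
    maps[[i]] <- gradient_shap(model, img, labels[i], pool, cfg)
  }
  maps
}

#' Aggregate per-sample attributions into class-global feature scores
#'
#' For each class, the per-cell mean over that class's samples of the
#' class-targeted attribution (signed), and the mean of absolute values.
#' The default ranking key is the mean absolute attribution, which captures
#' a cell's influence irrespective of direction; ties break deterministically
#' by (pathway order, column order).
#'
#' @param maps list of `attribution_map`s (from [cohort_attributions()]).
#' @param labels class labels aligned with `maps`.
#' @param rank_by `"abs"` (default) or `"signed"`.
#' @return named list of `global_feature_scores` objects, one per class,
#'   each with `signed`, `absolute` (matrices) and `ranking` (data frame of
#'   all cells in rank order).
#' @export
aggregate_class_attributions <- function(maps, labels, rank_by = c("abs", "signed")) {
  rank_by <- match.arg(rank_by)
  labels <- as.character(labels)
  stopifnot(length(maps) == length(labels))
  out <- list()
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    if (!length(ix)) stop("empty class '", cl, "'", call. = FALSE)
    sg <- Reduce(`+`, lapply(maps[ix], unclass)) / length(ix)
    ab <- Reduce(`+`, lapply(maps[ix], function(m) abs(unclass(m)))) / length(ix)
    key <- if (rank_by == "abs") ab else sg
    ord <- order(-as.vector(key),
                 rep(seq_len(nrow(key)), ncol(key)),     # pathway order
                 rep(seq_len(ncol(key)), each = nrow(key)))  # column order
    rk <- data.frame(
      rank = seq_along(ord),
      pathway = rownames(key)[(ord - 1L) %% nrow(key) + 1L],
      column = colnames(key)[(ord - 1L) %/% nrow(key) + 1L],
      score = as.vector(key)[ord],
      signed_mean = as.vector(sg)[ord],
      stringsAsFactors = FALSE)
    out[[cl]] <- structure(list(class_label = cl, signed = sg, absolute = ab,
                                ranking = rk, rank_by = rank_by,
                                n_samples = length(ix)),
                           class = "global_feature_scores")
  }
  out
}

#' @export
print.global_feature_scores <- function(x, ...) {
  cat(sprintf("<global_feature_scores class '%s' (%d samples, ranked by %s)>\n",
              x$class_label, x$n_samples, x$rank_by))
  print(utils::head(x$ranking, 5L))
  invisible(x)
}

#' Top-k image cells by global score
#'
#' A pathway may legitimately appear more than once when several of its
#' (omics, PC) cells rank highly; de-duplication happens only at the
#' pathway-set level in [pathway_set_analysis()].
#'
#' @param scores a `global_feature_scores` object.
#' @param k number of cells (default 10).
#' @return data frame of the k top-ranked cells with pathway, column label,
#'   and scores.
#' @export
top_k_features <- function(scores, k = 10L) {
  stopifnot(inherits(scores, "global_feature_scores"))
  if (k > nrow(scores$ranking)) {
    stop("k exceeds the number of image cells (", nrow(scores$ranking), ")",
         call. = FALSE)
  }
  utils::head(scores$ranking, k)
}

#' Common/unique significant-pathway analysis across classes
#'
#' Rolls each class's top-k cells up to a de-duplicated pathway set, then
#' reports the intersection over all classes (`common`) and each class's
#' complement (`unique`), retaining omics/PC provenance for every entry.
#'
#' @param scores_by_class named list of `global_feature_scores` (one per
#'   class), from [aggregate_class_attributions()].
#' @param k top cells per class (default 10).
#' @return object of class `pathway_report`: list with `top_cells` (per
#'   class), `pathway_sets` (per class), `common`, `unique` (per class),
#'   and a long-format `table`.
#' @export
pathway_set_analysis <- function(scores_by_class, k = 10L) {
  if (length(scores_by_class) < 2L) stop("need >= 2 classes", call. = FALSE)
  top_cells <- lapply(scores_by_class, top_k_features, k = k)
  sets <- lapply(top_cells, function(tc) unique(tc$pathway))
  common <- Reduce(intersect, sets)
  uniq <- lapply(sets, setdiff, y = common)
  tab <- do.call(rbind, lapply(names(top_cells), function(cl) {
    tc <- top_cells[[cl]]
    data.frame(class = cl, rank = tc$rank, pathway = tc$pathway,
               column = tc$column, score = tc$score,
               signed_mean = tc$signed_mean,
               membership = ifelse(tc$pathway %in% common, "common", "unique"),
               stringsAsFactors = FALSE)
  }))
  structure(list(top_cells = top_cells, pathway_sets = sets, common = common,
                 unique = uniq, k = k, table = tab),
            class = "pathway_report")
}

#' @export
print.pathway_report <- function(x, ...) {
  cat(sprintf("<pathway_report: top-%d cells per class>\n", x$k))
  cat("common pathways:", if (length(x$common)) paste(x$common, collapse = ", ")
      else "(none)", "\n")
  for (cl in names(x$unique)) {
    cat(sprintf("unique to %s: %s\n", cl,
                if (length(x$unique[[cl]])) paste(x$unique[[cl]], collapse = ", ")
                else "(none)"))
  }
  invisible(x)
}

#' Write a pathway report as TSV
#' @param x a `pathway_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pathway_report <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
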