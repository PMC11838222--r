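## embedding: class-specific sample separation, pathway-specific gene
## isolation, per-matrix PCA, and pathway-PC image assembly.  A sample's
## image has pathways as rows and (omics x principal component) scores as
## columns, in omics-major order.

bank_key <- function(class, omics, pathway) paste(class, omics, pathway, sep = "\r")

#' Split a harmonized dataset by survival class
#'
#' For an n-class problem with t omics layers this yields n x t matrices,
#' one per (class, omics) pair, each holding only that class's samples.
#'
#' @param dataset a `harmonized_dataset`.
#' @return named list: `result[[class]][[omics]]` is a samples x genes matrix.
#' @export
split_by_class <- function(dataset) {
  stopifnot(inherits(dataset, "harmonized_dataset"))
  classes <- levels(dataset$labels$class)
  classes <- classes[classes %in% dataset$labels$class]
  if (length(classes) < 2L) stop("need >= 2 classes present", call. = FALSE)
  out <- lapply(classes, function(cl) {
    ids <- dataset$labels$sample_id[dataset$labels$class == cl]
    if (length(ids) < 3L) {
      stop("class '", cl, "' has ", length(ids),
           " samples; >= 3 required for per-class PCA", call. = FALSE)
    }
    lapply(dataset$omics, function(o) o$values[ids, , drop = FALSE])
  })
  names(out) <- classes
  out
}

#' Isolate pathway-specific gene-value matrices
#'
#' Restricts each (class, omics) matrix to each pathway's genes, yielding up
#' to n_classes x n_omics x n_pathways matrices.  Pathways with zero genes
#' in the dataset's gene universe are recorded as degenerate and skipped
#' rather than raising an error.
#'
#' @param class_matrices result of [split_by_class()].
#' @param pathways a [pathway_collection()].
#' @return list of records with fields `class`, `omics`, `pathway`,
#'   `values`; attribute `"degenerate"` names pathways with no overlap.
#' @export
isolate_pathway_matrices <- function(class_matrices, pathways) {
  stopifnot(inherits(pathways, "pathway_collection"))
  universe <- colnames(class_matrices[[1L]][[1L]])
  genes_in <- lapply(pathways$pathways, intersect, y = universe)
  degenerate <- names(genes_in)[lengths(genes_in) == 0L]
  if (length(degenerate)) {
    pcn_log(length(degenerate), " pathway(s) have no genes in the universe: ",
            paste(degenerate, collapse = ", "))
  }
  out <- list()
  i <- 0L
  for (cl in names(class_matrices)) {
    for (om in names(class_matrices[[cl]])) {
      m <- class_matrices[[cl]][[om]]
      for (pw in names(genes_in)) {
        g <- genes_in[[pw]]
        if (length(g) == 0L) next
        i <- i + 1L
        out[[i]] <- list(class = cl, omics = om, pathway = pw,
                         values = m[, g, drop = FALSE])
      }
    }
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' Fit a per-pathway PCA model on one class's gene values
#'
#' Columns are centred (and z-scored when `standardize = TRUE`); constant
#' columns are dropped before the fit.  Loadings come from the singular
#' value decomposition; each component's sign is fixed so its
#' largest-magnitude loading entry is positive, making results reproducible
#' across linear-algebra backends.  If the requested number of components
#' exceeds the feasible rank `min(n_samples - 1, n_genes)`, the model keeps
#' the feasible count and projections are zero-padded.
#'
#' @param values samples x genes numeric matrix (>= 2 rows).
#' @param n_pcs number of principal components requested.
#' @param standardize z-score columns before the fit (default TRUE).
#' @param class_label,omics_name,pathway_id optional provenance labels.
#' @return object of class `pca_model` with fields `gene_ids`, `center`,
#'   `scale`, `loadings` (genes x n_pcs_eff), `evr` (explained-variance
#'   ratios), `n_pcs`, `n_pcs_eff`, `degenerate`.
#' @export
fit_class_pca <- function(values, n_pcs, standardize = TRUE,
                          class_label = NA_character_, omics_name = NA_character_,
                          pathway_id = NA_character_) {
  stopifnot(is.matrix(values), nrow(values) >= 2L, ncol(values) >= 1L, n_pcs >= 1L)
  mu <- colMeans(values)
  sdv <- apply(values, 2L, stats::sd)
  keep <- sdv > 1e-12
  dropped <- colnames(values)[!keep]
  if (length(dropped)) {
    warning(sprintf("dropping %d constant gene column(s) before PCA (%s/%s/%s)",
                    length(dropped), class_label, omics_name, pathway_id),
            call. = FALSE)
  }
  base <- list(class_label = class_label, omics_name = omics_name,
               pathway_id = pathway_id, n_pcs = as.integer(n_pcs),
               dropped_genes = dropped)
  if (!any(keep)) {
    out <- c(base, list(gene_ids = character(), center = numeric(),
                        scale = numeric(), loadings = NULL, evr = numeric(),
                        sdev = numeric(), n_pcs_eff = 0L, degenerate = TRUE))
    return(structure(out, class = "pca_model"))
  }
  x <- values[, keep, drop = FALSE]
  mu <- mu[keep]
  sc <- if (standardize) sdv[keep] else rep(1, sum(keep))
  xc <- sweep(sweep(x, 2L, mu, "-"), 2L, sc, "/")
  r <- min(nrow(x) - 1L, ncol(x))
  k <- min(n_pcs, r)
  sv <- svd(xc, nu = 0L, nv = k)
  load <- sv$v
  ## deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(load))) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(x)
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  vars <- sv$d^2
  out <- c(base, list(gene_ids = colnames(x), center = mu, scale = sc,
                      loadings = load,
                      evr = vars[seq_len(k)] / sum(vars),
                      sdev = sv$d[seq_len(k)] / sqrt(max(1, nrow(x) - 1L)),
                      n_pcs_eff = as.integer(k),
                      degenerate = FALSE))
  structure(out, class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model %s/%s/%s: %d genes, %d/%d PCs%s>\n",
              x$class_label, x$omics_name, x$pathway_id, length(x$gene_ids),
              x$n_pcs_eff, x$n_pcs, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Project a sample (or matrix of samples) onto a fitted PCA model
#'
#' Scores are `t(loadings) %*% ((x - center) / scale)`, zero-padded to the
#' requested number of components when the model's feasible rank is lower.
#'
#' @param model a `pca_model`.
#' @param sample_values named numeric vector over (at least) the model's
#'   gene ids, or a samples x genes matrix with column names.
#' @return numeric vector of length `n_pcs` (or a samples x n_pcs matrix).
#' @export
project_sample <- function(model, sample_values) {
  stopifnot(inherits(model, "pca_model"))
  one <- is.null(dim(sample_values))
  x <- if (one) matrix(sample_values, 1L, dimnames = list(NULL, names(sample_values)))
       else sample_values
  if (model$degenerate) {
    sc <- matrix(0, nrow(x), model$n_pcs)
  } else {
    if (!all(model$gene_ids %in% colnames(x))) {
      miss <- setdiff(model$gene_ids, colnames(x))
      stop("sample lacks gene(s): ", paste(utils::head(miss, 5L), collapse = ", "),
           call. = FALSE)
    }
    xc <- sweep(sweep(x[, model$gene_ids, drop = FALSE], 2L, model$center, "-"),
                2L, model$scale, "/")
    sc <- xc %*% model$loadings
    if (model$n_pcs_eff < model$n_pcs) {
      sc <- cbind(sc, matrix(0, nrow(sc), model$n_pcs - model$n_pcs_eff))
    }
  }
  colnames(sc) <- paste0("PC", seq_len(model$n_pcs))
  if (one) drop(sc) else sc
}

#' Fit the full class x omics x pathway PCA bank
#'
#' @param dataset a `harmonized_dataset`.
#' @param pathways a [pathway_collection()].
#' @param n_pcs components per (class, omics, pathway) model (default 2).
#' @param standardize z-score genes within each class matrix (default TRUE).
#' @param train_ids sample ids used for fitting (default: all samples); in
#'   fold-safe cross-validation only the training fold is passed.
#' @return object of class `pca_bank`: fitted models keyed by
#'   (class, omics, pathway), plus layout metadata.
#' @export
fit_embedding_bank <- function(dataset, pathways, n_pcs = 2L, standardize = TRUE,
                               train_ids = NULL) {
  stopifnot(inherits(dataset, "harmonized_dataset"))
  train_ids <- train_ids %||% dataset$samples
  sub <- dataset
  keep <- dataset$labels$sample_id %in% train_ids
  sub$labels <- dataset$labels[keep, , drop = FALSE]
  sub$samples <- sub$labels$sample_id
  sub$omics <- lapply(dataset$omics, function(o) {
    omics_matrix(o$values[sub$samples, , drop = FALSE], o$omics_name)
  })
  cm <- split_by_class(sub)
  recs <- isolate_pathway_matrices(cm, pathways)
  models <- new.env(parent = emptyenv(), hash = TRUE)
  for (r in recs) {
    assign(bank_key(r$class, r$omics, r$pathway),
           fit_class_pca(r$values, n_pcs, standardize,
                         class_label = r$class, omics_name = r$omics,
                         pathway_id = r$pathway),
           envir = models)
  }
  structure(list(models = models,
                 classes = names(cm),
                 omics_names = names(dataset$omics),
                 pathway_ids = names(pathways$pathways),
                 degenerate = attr(recs, "degenerate"),
                 n_pcs = as.integer(n_pcs),
                 standardize = standardize,
                 train_ids = train_ids),
            class = "pca_bank")
}

#' @export
print.pca_bank <- function(x, ...) {
  cat(sprintf(paste0("<pca_bank: %d classes x %d omics x %d pathways, %d PCs",
                     " (%d degenerate pathways)>\n"),
              length(x$classes), length(x$omics_names), length(x$pathway_ids),
              x$n_pcs, length(x$degenerate)))
  invisible(x)
}

## Rotate every model of `bank` into the coordinate frame of the matching
## model in `ref` (orthogonal Procrustes on the shared genes' loadings).
## Inner cross-fit banks are refit on different sample subsets, so their PC
## axes rotate/permute freely; without alignment the same image cell is a
## different linear functional for different samples.  Alignment restores
## cross-sample comparability while keeping projections out-of-sample.
align_bank_to <- function(bank, ref) {
  for (key in ls(bank$models)) {
    m <- get(key, envir = bank$models, inherits = FALSE)
    if (m$degenerate) next
    if (!exists(key, envir = ref$models, inherits = FALSE)) next
    r <- get(key, envir = ref$models, inherits = FALSE)
    if (r$degenerate || m$n_pcs_eff != r$n_pcs_eff) next
    common <- intersect(m$gene_ids, r$gene_ids)
    if (length(common) < m$n_pcs_eff) next
    a <- crossprod(m$loadings[common, , drop = FALSE],
                   r$loadings[common, , drop = FALSE])
    sv <- svd(a)
    m$loadings <- m$loadings %*% (sv$u %*% t(sv$v))
    assign(key, m, envir = bank$models)
  }
  bank
}

bank_model <- function(bank, class, omics, pathway) {
  key <- bank_key(class, omics, pathway)
  if (!exists(key, envir = bank$models, inherits = FALSE)) return(NULL)
  get(key, envir = bank$models, inherits = FALSE)
}

#' Build one sample's pathway-PC image from a fitted bank
#'
#' Row `p`, omics block `o` holds the scores of the sample's pathway-`p`
#' genes in layer `o` under the `embed_class` PCA models.  Cells of
#' degenerate pathways are zero.
#'
#' @param bank a `pca_bank`.
#' @param dataset the `harmonized_dataset` holding the sample's values.
#' @param sample_id sample identifier.
#' @param embed_class which class's models to embed with.
#' @return numeric matrix `n_pathways x (n_omics * n_pcs)` with labelled
#'   dimnames; attribute `"sample_id"`.
#' @export
build_image <- function(bank, dataset, sample_id, embed_class) {
  stopifnot(inherits(bank, "pca_bank"))
  if (!sample_id %in% dataset$samples) stop("unknown sample '", sample_id, "'", call. = FALSE)
  if (!embed_class %in% bank$classes) stop("unknown class '", embed_class, "'", call. = FALSE)
  np <- length(bank$pathway_ids); no <- length(bank$omics_names); k <- bank$n_pcs
  img <- matrix(0, np, no * k,
                dimnames = list(bank$pathway_ids,
                                paste(rep(bank$omics_names, each = k),
                                      paste0("PC", seq_len(k)), sep = "-")))
  for (o in seq_len(no)) {
    om <- bank$omics_names[o]
    xrow <- dataset$omics[[om]]$values[sample_id, ]
    for (p in seq_len(np)) {
      m <- bank_model(bank, embed_class, om, bank$pathway_ids[p])
      if (is.null(m)) next
      img[p, ((o - 1L) * k + 1L):(o * k)] <- project_sample(m, xrow)
    }
  }
  attr(img, "sample_id") <- sample_id
  img
}

## Vectorized embedding of many samples under one class's models:
## returns array (n_samples, n_pathways, n_omics * n_pcs).
embed_all_samples <- function(bank, dataset, embed_class, sample_ids) {
  np <- length(bank$pathway_ids); no <- length(bank$omics_names); k <- bank$n_pcs
  ns <- length(sample_ids)
  arr <- array(0, dim = c(ns, np, no * k))
  for (o in seq_len(no)) {
    om <- bank$omics_names[o]
    vals <- dataset$omics[[om]]$values[sample_ids, , drop = FALSE]
    for (p in seq_len(np)) {
      m <- bank_model(bank, embed_class, om, bank$pathway_ids[p])
      if (is.null(m) || m$degenerate) next
      arr[, p, ((o - 1L) * k + 1L):(o * k)] <- project_sample(m, vals)
    }
  }
  arr
}

#' Build the cohort's image stack
#'
#' Two embedding modes are provided because class-specific PCA needs a class
#' label at embedding time:
#' \describe{
#'   \item{`"own-class"`}{each sample is embedded with its own class's
#'     models, fitted on all samples of that class; columns are
#'     `n_omics * n_pcs`.  This is the method's original formulation but uses
#'     the label when constructing features.}
#'   \item{`"fold-safe"`}{models are fitted on training-fold samples only and
#'     every sample is embedded under BOTH classes' models, doubling the
#'     columns (class-major blocks); no label is consulted at embedding
#'     time, making held-out evaluation honest.}
#' }
#' After assembly every column is min-max normalized to `[0, 1]` using
#' training-sample statistics; values outside the training range are
#' clipped.
#'
#' @param dataset a `harmonized_dataset`.
#' @param pathways a [pathway_collection()].
#' @param n_pcs components per model (default 2).
#' @param mode `"own-class"` or `"fold-safe"`.
#' @param train_ids training sample ids (required for `"fold-safe"`;
#'   defaults to all samples in `"own-class"`).
#' @param standardize z-score genes before PCA (default TRUE).
#' @param bank optionally, a pre-fitted `pca_bank` to reuse.
#' @param cross_fit in fold-safe mode, the number of inner folds used to
#'   embed the *training* samples out-of-sample (default 4; values < 2
#'   disable it).  A sample projected by a PCA model that was fitted on it
#'   has systematically tamer scores than an unseen sample, and because the
#'   models are class-specific this in-sample/out-of-sample asymmetry is
#'   label-correlated for training images — a leak a flexible classifier
#'   will exploit and that collapses on held-out data.  Cross-fitting
#'   removes it: each training sample's image comes from banks fitted on
#'   the other inner folds, while held-out samples use the full-training
#'   bank, so every image is an out-of-sample projection.
#' @param seed seed for the inner cross-fit split (fold-safe only).
#' @return object of class `image_stack`: list with `images` (array
#'   `n_samples x n_pathways x n_cols`), `sample_ids`, `row_labels`,
#'   `col_labels`, `norm` (per-column training min/max), `mode`, `bank`.
#' @export
build_image_stack <- function(dataset, pathways, n_pcs = 2L,
                              mode = c("own-class", "fold-safe"),
                              train_ids = NULL, standardize = TRUE, bank = NULL,
                              cross_fit = 4L, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "fold-safe" && is.null(train_ids) && is.null(bank)) {
    stop("fold-safe mode requires `train_ids` (the training fold)", call. = FALSE)
  }
  train_ids <- train_ids %||% dataset$samples
  if (is.null(bank)) {
    bank <- fit_embedding_bank(dataset, pathways, n_pcs, standardize, train_ids)
  }
  k <- bank$n_pcs; no <- length(bank$omics_names); np <- length(bank$pathway_ids)
  ids <- dataset$samples
  base_cols <- paste(rep(bank$omics_names, each = k),
                     paste0("PC", seq_len(k)), sep = "-")
  if (mode == "own-class") {
    arr <- array(0, dim = c(length(ids), np, no * k))
    for (cl in bank$classes) {
      cl_ids <- dataset$labels$sample_id[dataset$labels$class == cl]
      cl_ids <- intersect(ids, cl_ids)
      if (!length(cl_ids)) next
      arr[match(cl_ids, ids), , ] <- embed_all_samples(bank, dataset, cl, cl_ids)
    }
    col_labels <- base_cols
  } else {
    embed_blocks <- function(b, which_ids) {
      out <- array(0, dim = c(length(which_ids), np, no * k * length(b$classes)))
      for (bi in seq_along(b$classes)) {
        out[, , ((bi - 1L) * no * k + 1L):(bi * no * k)] <-
          embed_all_samples(b, dataset, b$classes[bi], which_ids)
      }
      out
    }
    arr <- array(0, dim = c(length(ids), np, no * k * length(bank$classes)))
    test_ids <- setdiff(ids, train_ids)
    ytr <- dataset$labels$class[match(train_ids, dataset$labels$sample_id)]
    m <- min(as.integer(cross_fit), min(table(droplevels(ytr))))
    if (m >= 2L) {
      ## Training samples are embedded by the inner bank that excludes them,
      ## with each inner bank's PC axes Procrustes-aligned to the full
      ## training bank so that a given image cell is the same linear
      ## functional for every sample; held-out samples use the full training
      ## bank directly.  Every image is therefore an out-of-sample
      ## projection expressed in one common coordinate frame.
      inner <- stratified_folds(ytr, m, seed = derive_seed(seed, "cross-fit"))
      for (g in seq_len(m)) {
        hold <- train_ids[inner == g]
        bank_g <- fit_embedding_bank(dataset, pathways, n_pcs, standardize,
                                     setdiff(train_ids, hold))
        bank_g <- align_bank_to(bank_g, bank)
        arr[match(hold, ids), , ] <- embed_blocks(bank_g, hold)
      }
    } else {
      arr[match(train_ids, ids), , ] <- embed_blocks(bank, train_ids)
    }
    if (length(test_ids)) {
      arr[match(test_ids, ids), , ] <- embed_blocks(bank, test_ids)
    }
    col_labels <- paste(rep(bank$classes, each = no * k), base_cols, sep = ":")
  }
  ## per-column min-max normalization from training statistics
  tr <- match(intersect(train_ids, ids), ids)
  cmin <- apply(arr[tr, , , drop = FALSE], 3L, min)
  cmax <- apply(arr[tr, , , drop = FALSE], 3L, max)
  rng <- cmax - cmin
  rng[rng < 1e-12] <- 1
  for (j in seq_len(dim(arr)[3L])) {
    arr[, , j] <- pmin(pmax((arr[, , j] - cmin[j]) / rng[j], 0), 1)
  }
  structure(list(images = arr, sample_ids = ids,
                 row_labels = bank$pathway_ids, col_labels = col_labels,
                 norm = list(min = cmin, max = cmax), mode = mode, bank = bank),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<image_stack (%s): %d images of %d pathways x %d columns>\n",
              x$mode, d[1L], d[2L], d[3L]))
  invisible(x)
}

#' Extract one image from a stack
#' @param stack an `image_stack`.
#' @param sample_id sample identifier.
#' @return labelled matrix `n_pathways x n_cols`.
#' @export
stack_image <- function(stack, sample_id) {
  i <- match(sample_id, stack$sample_ids)
  if (is.na(i)) stop("unknown sample '", sample_id, "'", call. = FALSE)
  img <- stack$images[i, , ]
  dimnames(img) <- list(stack$row_labels, stack$col_labels)
  img
}

#' Write an image stack to disk as plain text
#'
#' The dense tensor goes to a TSV (one row per sample, cells flattened
#' row-major by pathway then column) plus a sidecar TSV of row/column labels
#' and normalization parameters.
#'
#' @param stack an `image_stack`.
#' @param path base path; `<path>.tsv` and `<path>.labels.tsv` are written.
#' @return invisible vector of the two paths.
#' @export
write_image_stack <- function(stack, path) {
  d <- dim(stack$images)
  flat <- matrix(aperm(stack$images, c(1L, 3L, 2L)), nrow = d[1L])
  ## columns ordered pathway-major: (pathway 1, col 1..C), (pathway 2, ...)
  cn <- as.vector(outer(stack$col_labels, stack$row_labels,
                        function(co, ro) paste(ro, co, sep = "|")))
  dat <- file.path(paste0(path, ".tsv"))
  writeLines(c(paste(c("sample_id", cn), collapse = "\t"),
               vapply(seq_len(d[1L]), function(i) {
                 paste(c(stack$sample_ids[i], sprintf("%.10g", flat[i, ])),
                       collapse = "\t")
               }, character(1))), dat)
  lab <- file.path(paste0(path, ".labels.tsv"))
  writeLines(c("kind\tindex\tlabel\tnorm_min\tnorm_max",
               sprintf("row\t%d\t%s\tNA\tNA", seq_along(stack$row_labels),
                       stack$row_labels),
               sprintf("col\t%d\t%s\t%.10g\t%.10g", seq_along(stack$col_labels),
                       stack$col_labels, stack$norm$min, stack$norm$max)), lab)
  invisible(c(dat, lab))
}
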