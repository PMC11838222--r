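test_that("class split yields one matrix per (class, omics) with disjoint samples", {
  co <- small_cohort()
  ds <- small_dataset(co)
  cm <- split_by_class(ds)
  expect_length(cm, 2L)                        # 2 classes
  expect_length(cm[[1]], 3L)                   # 3 omics
  ids1 <- rownames(cm[["LTS"]][["EXP"]])
  ids2 <- rownames(cm[["non-LTS"]][["EXP"]])
  expect_length(intersect(ids1, ids2), 0L)
  expect_setequal(c(ids1, ids2), ds$samples)

  ## a class with < 3 samples is a validation error
  ds_bad <- ds
  keep <- c(ds$labels$sample_id[ds$labels$class == "LTS"][1:2],
            ds$labels$sample_id[ds$labels$class == "non-LTS"])
  ds_bad$labels <- ds$labels[ds$labels$sample_id %in% keep, ]
  ds_bad$samples <- ds_bad$labels$sample_id
  ds_bad$omics <- lapply(ds$omics, function(o)
    omics_matrix(o$values[ds_bad$samples, , drop = FALSE], o$omics_name))
  expect_error(split_by_class(ds_bad), ">= 3 required")
})

test_that("pathway isolation conserves counts and flags empty overlaps", {
  co <- small_cohort()
  ds <- small_dataset(co)
  cm <- split_by_class(ds)
  recs <- isolate_pathway_matrices(cm, co$pathways)
  expect_length(recs, 2L * 3L * 8L)            # classes x omics x pathways
  expect_true(all(vapply(recs, function(r)
    all(colnames(r$values) %in% co$pathways$pathways[[r$pathway]]), logical(1))))

  ## a pathway whose genes are absent is degenerate, not an error
  pw2 <- pathway_collection(c(co$pathways$pathways,
                              list(GHOST = c("NO_SUCH_GENE"))))
  recs2 <- isolate_pathway_matrices(cm, pw2)
  expect_equal(attr(recs2, "degenerate"), "GHOST")
  expect_length(recs2, 2L * 3L * 8L)           # ghost contributed nothing
})

test_that("per-class PCA matches the eigendecomposition oracle", {
  set.seed(10)
  for (dims in list(c(20L, 8L), c(15L, 15L), c(40L, 5L))) {
    x <- matrix(rnorm(prod(dims)), dims[1L], dims[2L],
                dimnames = list(NULL, paste0("g", seq_len(dims[2L]))))
    x[, 1] <- x[, 1] * 3 + x[, 2]              # give it structure
    m <- fit_class_pca(x, n_pcs = 4L, standardize = FALSE)
    ## oracle: eigendecomposition of the covariance matrix
    eg <- eigen(stats::cov(x), symmetric = TRUE)
    expect_equal(m$evr, (eg$values / sum(eg$values))[1:4], tolerance = 1e-8)
    for (j in 1:4) {                           # loadings up to sign
      expect_equal(abs(drop(crossprod(m$loadings[, j], eg$vectors[, j]))), 1,
                   tolerance = 1e-8)
    }
    expect_equal(crossprod(m$loadings), diag(4), tolerance = 1e-8,
                 ignore_attr = TRUE)           # orthonormality
  }
})

test_that("PCA sign convention, rank padding and degenerate input behave", {
  ## point cloud along y = x: PC1 is (1, 1)/sqrt(2), sign-fixed positive
  s <- rnorm(30)
  x <- cbind(a = s, b = s + rnorm(30, 0, 1e-3))
  m <- fit_class_pca(x, 1L, standardize = FALSE)
  expect_equal(unname(m$loadings[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-2)
  expect_true(all(m$loadings[which.max(abs(m$loadings[, 1])), 1] > 0))

  ## requested PCs beyond feasible rank: projections zero-padded
  x2 <- matrix(rnorm(6), 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  m2 <- fit_class_pca(x2, 3L, standardize = FALSE)
  expect_equal(m2$n_pcs_eff, 1L)               # rank = n - 1 = 1
  sc <- project_sample(m2, x2[1, ])
  expect_length(sc, 3L)
  expect_equal(unname(sc[2:3]), c(0, 0))

  ## constant gene column dropped with a warning
  x3 <- cbind(a = rnorm(10), b = rep(2, 10), c = rnorm(10))
  expect_warning(m3 <- fit_class_pca(x3, 2L), "constant gene column")
  expect_equal(m3$gene_ids, c("a", "c"))

  ## all-constant matrix: degenerate, projects to zero
  x4 <- matrix(1, 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(m4 <- fit_class_pca(x4, 2L))
  expect_true(m4$degenerate)
  expect_equal(unname(project_sample(m4, c(a = 9, b = 9))), c(0, 0))
})

test_that("projection is centred, consistent, and matches hand arithmetic", {
  set.seed(3)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
  m <- fit_class_pca(x, 2L, standardize = TRUE)
  ## the fitting class's own cloud projects to per-PC mean zero
  sc <- project_sample(m, x)
  expect_lt(max(abs(colMeans(sc))), 1e-8)
  ## the class mean itself maps to the origin
  expect_equal(unname(project_sample(m, colMeans(x))), c(0, 0),
               tolerance = 1e-10)
  ## hand-computed: standardize then multiply by loadings
  v <- x[7, ]
  hand <- drop(crossprod(m$loadings, (v[m$gene_ids] - m$center) / m$scale))
  expect_equal(unname(project_sample(m, v)), unname(hand), tolerance = 1e-12)
})

test_that("image geometry follows the (pathways x omics*PCs) layout", {
  co <- small_cohort()
  ds <- small_dataset(co)
  bank <- fit_embedding_bank(ds, co$pathways, n_pcs = 2L)
  img <- build_image(bank, ds, ds$samples[1], "LTS")
  expect_equal(dim(img), c(8L, 6L))
  expect_equal(colnames(img)[1:3], c("CNV-PC1", "CNV-PC2", "EXP-PC1"))
  expect_equal(rownames(img), names(co$pathways$pathways))
  ## identical calls are bit-identical (pure function of bank + values)
  expect_identical(img, build_image(bank, ds, ds$samples[1], "LTS"))
  expect_error(build_image(bank, ds, "nope", "LTS"), "unknown sample")

  ## stacks: own-class 6 columns, fold-safe doubles to 12
  stk <- build_image_stack(ds, co$pathways, 2L, mode = "own-class")
  expect_equal(dim(stk$images), c(length(ds$samples), 8L, 6L))
  tr <- ds$samples[seq(1, length(ds$samples), by = 2)]
  stk2 <- build_image_stack(ds, co$pathways, 2L, mode = "fold-safe",
                            train_ids = tr)
  expect_equal(dim(stk2$images)[3], 12L)
  expect_true(startsWith(stk2$col_labels[1], "LTS:"))
  expect_error(build_image_stack(ds, co$pathways, 2L, mode = "fold-safe"),
               "train_ids")
  ## normalization bounds
  expect_gte(min(stk$images), 0); expect_lte(max(stk$images), 1)
  expect_gte(min(stk2$images), 0); expect_lte(max(stk2$images), 1)

  ## rebuilding with the same inputs is bit-identical
  stk_b <- build_image_stack(ds, co$pathways, 2L, mode = "own-class")
  expect_identical(stk$images, stk_b$images)

  ## a raw image row agrees with build_image before normalization
  raw <- pathwaycnn:::embed_all_samples(stk$bank, ds, "LTS",
                                        ds$labels$sample_id[ds$labels$class == "LTS"][1])
  img1 <- build_image(stk$bank, ds,
                      ds$labels$sample_id[ds$labels$class == "LTS"][1], "LTS")
  expect_equal(as.vector(raw[1, , ]), as.vector(img1), tolerance = 1e-12)
})

test_that("a planted pathway's expression PCs separate the classes", {
  ## class-specific PCA is blind to between-class variance, so the planted
  ## mean shift lands on an arbitrary PC of each class model; the signal
  ## must surface in at least one expression column of the planted row
  co <- small_cohort(seed = 19, delta = 2)     # planted: pathway 2, EXP
  ds <- small_dataset(co)
  y <- ds$labels$class[match(ds$samples, ds$labels$sample_id)]
  tr <- ds$samples[stratified_folds(y, 2, seed = 4) == 1]
  stk <- build_image_stack(ds, co$pathways, 2L, mode = "fold-safe",
                           train_ids = tr)
  exp_cols <- grep("EXP-PC", stk$col_labels)
  p_planted <- vapply(exp_cols, function(cc)
    t.test(stk$images[, 2L, cc] ~ y)$p.value, numeric(1))
  expect_lt(min(p_planted), 0.01)
  ## and stays out of a background pathway's columns
  p_bg <- vapply(exp_cols, function(cc)
    t.test(stk$images[, 5L, cc] ~ y)$p.value, numeric(1))
  expect_gt(min(p_bg), 1e-4)
})

test_that("image stack serializes to labelled plain text", {
  co <- small_cohort()
  ds <- small_dataset(co)
  stk <- build_image_stack(ds, co$pathways, 2L, mode = "own-class")
  base <- file.path(withr::local_tempdir(), "stk")
  paths <- write_image_stack(stk, base)
  dat <- read.delim(paths[1], check.names = FALSE)
  expect_equal(nrow(dat), length(ds$samples))
  expect_equal(ncol(dat), 1L + 8L * 6L)
  expect_equal(dat[["PW002|EXP-PC1"]],
               unname(stk$images[, 2, match("EXP-PC1", stk$col_labels)]),
               tolerance = 1e-9)
})
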