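
test_that("attribution vanishes when the input is the sole baseline", {
  tm <- trained_small_model()
  img <- pathwaycnn:::stack_image(tm$stack, tm$dataset$samples[1])
  cfg <- gradient_shap_config(n_baselines = 5L, n_path_samples = 2L,
                              noise_sd = 0, seed = 1)
  phi <- gradient_shap(tm$fit, img, "LTS", img, cfg)
  expect_equal(max(abs(phi)), 0)               # (x - x') factor is exactly 0
})

test_that("a linear map is attributed in closed form", {
  set.seed(2)
  W <- matrix(rnorm(12 * 2), 12, 2)
  m <- dense_model(W, input_shape = c(4L, 3L))
  x <- matrix(rnorm(12), 4, 3)
  bl <- matrix(rnorm(12), 4, 3)
  cfg <- gradient_shap_config(n_baselines = 3L, n_path_samples = 2L,
                              noise_sd = 0, seed = 5)
  phi <- gradient_shap(m, x, 2L, bl, cfg, output = "logit")
  ## gradient of logit_2 is constant = W[, 2]: phi_i = w_i (x_i - x'_i)
  expected <- matrix(W[, 2], 4, 3) * (x - bl)
  expect_equal(unclass(phi), expected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("attributions satisfy completeness on a trained network", {
  tm <- trained_small_model()
  cfg <- gradient_shap_config(n_baselines = 120L, n_path_samples = 5L,
                              noise_sd = 0, seed = 9)   # 600 path samples
  ## explain the sample with the largest f(x) - E f(x') gap, where the
  ## relative completeness error is well-conditioned
  probs <- predict(tm$fit, tm$stack)[, "non-LTS"]
  cand <- tm$dataset$samples[order(abs(probs - mean(probs)),
                                   decreasing = TRUE)[1:3]]
  ok <- 0L
  for (sid in cand) {
    img <- pathwaycnn:::stack_image(tm$stack, sid)
    phi <- gradient_shap(tm$fit, img, "non-LTS", tm$stack$images, cfg)
    gap <- attr(phi, "f_x") - attr(phi, "f_baseline_mean")
    if (abs(gap) < 0.15) next                  # relative error ill-posed
    expect_lt(abs(sum(phi) - gap) / abs(gap), 0.05)
    ok <- ok + 1L
  }
  expect_gte(ok, 1L)                           # at least one informative case
})

test_that("Monte-Carlo attribution agrees with the quadrature reference", {
  tm <- trained_small_model()
  img <- pathwaycnn:::stack_image(tm$stack, tm$dataset$samples[3])
  bl <- tm$stack$images[c(5, 12, 20, 28), , , drop = FALSE]
  cfg <- gradient_shap_config(n_baselines = 80L, n_path_samples = 5L,
                              noise_sd = 0, seed = 3)
  phi <- gradient_shap(tm$fit, img, "non-LTS", bl, cfg)
  ref <- ref_path_attribution(tm$fit, img, match("non-LTS", tm$fit$classes), bl)
  expect_gt(stats::cor(as.vector(phi), as.vector(ref)), 0.95)
})

test_that("attribution is deterministic given a seed and converges as 1/sqrt(n)", {
  tm <- trained_small_model()
  img <- pathwaycnn:::stack_image(tm$stack, tm$dataset$samples[4])
  cfg <- gradient_shap_config(n_baselines = 10L, n_path_samples = 2L, seed = 77)
  a <- gradient_shap(tm$fit, img, "LTS", tm$stack$images, cfg)
  b <- gradient_shap(tm$fit, img, "LTS", tm$stack$images, cfg)
  expect_identical(unclass(a), unclass(b))

  ## spread of the estimate across seeds shrinks roughly as 1/sqrt(n)
  spread <- function(n_path) {
    v <- vapply(1:12, function(s) {
      cfg <- gradient_shap_config(n_baselines = 4L, n_path_samples = n_path,
                                  noise_sd = 0.05, seed = s)
      sum(gradient_shap(tm$fit, img, "LTS", tm$stack$images, cfg))
    }, numeric(1))
    stats::sd(v)
  }
  s_small <- spread(2L); s_big <- spread(32L)  # 16x more path samples
  expect_gt(s_small / s_big, 1.8)              # ideal ratio 4, loose band
})

test_that("two features with identical roles receive equal attributions", {
  set.seed(6)
  W <- matrix(rnorm(6 * 2), 6, 2)
  W[2, ] <- W[5, ]                             # cells 2 and 5 interchangeable
  m <- dense_model(W, input_shape = c(3L, 2L))
  x <- matrix(rnorm(6), 3, 2)
  x[5] <- x[2]
  bl <- array(0, c(1L, 3L, 2L))
  cfg <- gradient_shap_config(n_baselines = 50L, n_path_samples = 4L,
                              noise_sd = 0.1, seed = 8)
  phi <- gradient_shap(m, x, 1L, bl, cfg)
  expect_equal(phi[2], phi[5], tolerance = 0.05)
})

test_that("class-global aggregation stores signed and absolute summaries", {
  v <- matrix(c(1, -2, 3, -4), 2, 2, dimnames = list(c("P1", "P2"), c("c1", "c2")))
  m1 <- structure(v, class = c("attribution_map", "matrix"))
  m2 <- structure(-v, class = c("attribution_map", "matrix"))
  ## single-sample class: global equals the map
  g1 <- aggregate_class_attributions(list(a = m1), labels = "X")$X
  expect_equal(g1$signed, v, ignore_attr = TRUE)
  ## v and -v cancel in the signed mean but not the absolute mean
  g2 <- aggregate_class_attributions(list(a = m1, b = m2), c("X", "X"))$X
  expect_equal(unname(g2$signed), matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(g2$absolute, abs(v), ignore_attr = TRUE)
  expect_error(aggregate_class_attributions(list(m1), character(0)))
})

test_that("top-k ranking is ordered with deterministic tie-breaks", {
  v <- matrix(c(3, 1, 2, 1), 2, 2,
              dimnames = list(c("P1", "P2"), c("c1", "c2")))
  g <- aggregate_class_attributions(
    list(structure(v, class = c("attribution_map", "matrix"))), "X")$X
  top <- top_k_features(g, 2)
  expect_equal(top$pathway, c("P1", "P1"))     # scores 3 then 2
  expect_equal(top$column, c("c1", "c2"))
  ## ties (two cells at 1) break by pathway order then column order
  full <- top_k_features(g, 4)
  expect_equal(full$score, c(3, 2, 1, 1))
  expect_equal(full$pathway[3:4], c("P2", "P2"))
  expect_equal(full$column[3:4], c("c1", "c2"))
  expect_error(top_k_features(g, 5), "exceeds")
})

test_that("pathway set analysis splits common from unique membership", {
  mk_scores <- function(vals, cls) {
    v <- matrix(vals, length(vals), 1,
                dimnames = list(paste0("P", seq_along(vals)), "c1"))
    aggregate_class_attributions(
      list(structure(v, class = c("attribution_map", "matrix"))), cls)[[cls]]
  }
  ## identical top sets: all common, none unique
  a <- mk_scores(c(5, 4, 3, 2, 1), "A"); b <- mk_scores(c(5, 4, 3, 2, 1), "B")
  r <- pathway_set_analysis(list(A = a, B = b), k = 3)
  expect_setequal(r$common, c("P1", "P2", "P3"))
  expect_length(r$unique$A, 0)
  ## disjoint top sets: zero common
  c2 <- mk_scores(c(1, 2, 10, 9, 8), "B")
  r2 <- pathway_set_analysis(list(A = a, B = c2), k = 2)
  expect_length(r2$common, 0)
  expect_setequal(r2$unique$A, c("P1", "P2"))

  ## constructed top-10 lists mapping to 8 pathways each with 6 shared ->
  ## 6 common, 2 unique per class; one pathway contributes two cells
  mk2 <- function(order_ids, dup_id, extra_id) {
    v <- matrix(0, 12, 2, dimnames = list(paste0("P", 1:12), c("c1", "c2")))
    v[cbind(order_ids, 1L)] <- seq(20, by = -1, length.out = length(order_ids))
    v[dup_id, 2] <- 19.5                       # second cell of a top pathway
    v[extra_id, 2] <- 12.5                     # tenth cell
    aggregate_class_attributions(
      list(structure(v, class = c("attribution_map", "matrix"))), "Z")$Z
  }
  sA <- mk2(1:8, dup_id = 1, extra_id = 2)     # set {P1..P8}, P1 twice
  sB <- mk2(c(1:6, 9, 10), dup_id = 9, extra_id = 10)  # set {P1..P6, P9, P10}
  rr <- pathway_set_analysis(list(A = sA, B = sB), k = 10)
  tA <- rr$top_cells$A
  expect_equal(nrow(tA), 10L)
  expect_equal(sum(tA$pathway == "P1"), 2L)    # duplicate kept at cell level
  expect_setequal(rr$common, paste0("P", 1:6))
  expect_setequal(rr$unique$A, c("P7", "P8"))
  expect_setequal(rr$unique$B, c("P9", "P10"))
})
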