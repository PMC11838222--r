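# Shared fixtures: all built in code, sized for speed.

# A small planted-signal cohort: 8 pathways, 3 omics, ~45 labelled samples.
small_cohort <- function(seed = 7, delta = 2, n_pathways = 8L,
                         n_lts = 20L, n_nonlts = 25L, n_excluded = 3L) {
  generate_multiomics(synthetic_config(
    n_per_class = c("LTS" = n_lts, "non-LTS" = n_nonlts),
    n_excluded = n_excluded, n_pathways = n_pathways,
    genes_per_pathway = c(5L, 10L),
    planted = data.frame(pathway = 2L, omics = 2L, delta = delta),
    seed = seed))
}

small_dataset <- function(cohort = small_cohort()) {
  labels <- assign_survival_labels(cohort$clinical)
  harmonize(cohort$omics, labels, cohort$clinical)
}

# Tiny CNN config whose pooling fits an 8-row image; trains in seconds.
tiny_cnn <- function(epochs = 5L, seed = 3L, dropout = 0) {
  cnn_config(filters = c(4L, 8L), pool = list(c(2L, 1L), c(2L, 2L)),
             dense = 8L, dropout = dropout, epochs = epochs,
             batch_size = 16L, seed = seed)
}

# Hand-built dense-softmax model (flatten -> dense) for attribution tests
# where analytic control over the mapping is needed.
dense_model <- function(W, b = NULL, input_shape, classes = c("A", "B")) {
  d_in <- prod(input_shape)
  stopifnot(nrow(W) == d_in)
  if (is.null(b)) b <- numeric(ncol(W))
  plan <- list(list(type = "flatten", H = input_shape[1L], W = input_shape[2L],
                    C = 1L),
               list(type = "dense", d_in = d_in, d_out = ncol(W)))
  structure(list(plan = plan, params = list(NULL, list(W = W, b = b)),
                 config = cnn_config(seed = 1L),
                 input_shape = as.integer(input_shape),
                 n_classes = ncol(W), n_parameters = length(W) + length(b),
                 trained = TRUE, history = NULL, classes = classes),
            class = "cnn_model")
}

# Train a small real CNN on the small cohort's own-class stack; cached
# per test session so several attribution tests can share it.
trained_small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- small_cohort()
      ds <- small_dataset(co)
      stk <- build_image_stack(ds, co$pathways, n_pcs = 2,
                               mode = "own-class")
      y <- ds$labels$class[match(ds$samples, ds$labels$sample_id)]
      fit <- train_cnn(NULL, stk, y, tiny_cnn(epochs = 15L))
      cache <<- list(cohort = co, dataset = ds, stack = stk, y = y, fit = fit)
    }
    cache
  }
})
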