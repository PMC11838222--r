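# Independent reference attributor used as oracle: deterministic midpoint
# quadrature over the interpolation path and central finite-difference
# gradients; shares no code with the package's analytic/Monte-Carlo path.
ref_path_attribution <- function(model, x, tc, baselines, n_alpha = 24L,
                                 output = "prob") {
  f <- function(img) {
    fw <- pathwaycnn:::cnn_forward(model, array(img, c(1L, dim(img))))
    if (output == "prob") fw$probs[1L, tc] else fw$logits[1L, tc]
  }
  num_grad <- function(img) {
    g <- img * 0
    h <- 1e-4
    for (j in seq_along(img)) {
      up <- img; up[j] <- up[j] + h
      dn <- img; dn[j] <- dn[j] - h
      g[j] <- (f(up) - f(dn)) / (2 * h)
    }
    g
  }
  alphas <- (seq_len(n_alpha) - 0.5) / n_alpha
  phi <- x * 0
  M <- dim(baselines)[1L]
  for (b in seq_len(M)) {
    bl <- baselines[b, , ]
    diff <- x - bl
    acc <- x * 0
    for (a in alphas) acc <- acc + num_grad(bl + a * diff)
    phi <- phi + (acc / n_alpha) * diff
  }
  phi / M
}
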