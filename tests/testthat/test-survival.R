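test_that("coefficients are recovered and agree with the survival package", {
  skip_if_not_installed("survival")
  sim <- generate_survival_data(2000, c(g1 = 0.7, g2 = -0.4),
                                censoring_rate = 0.2, seed = 31)
  fit <- fit_coxph(sim$clinical$time, sim$clinical$event, sim$covariates)
  expect_true(fit$converged)
  expect_lt(fit$score_norm, 1e-8)              # score vanishes at the MLE
  expect_equal(unname(coef(fit)), c(0.7, -0.4), tolerance = 0.1)

  orc <- survival::coxph(
    survival::Surv(sim$clinical$time, sim$clinical$event) ~ scale(sim$covariates),
    ties = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(orc)), tolerance = 1e-4)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(stats::vcov(orc)))), tolerance = 1e-4)
  w <- wald_test(fit)
  orc_p <- 2 * stats::pnorm(-abs(coef(orc) / sqrt(diag(stats::vcov(orc)))))
  expect_equal(w$p, unname(orc_p), tolerance = 1e-4)
})

test_that("oracle equivalence holds across a simulation battery with ties", {
  skip_if_not_installed("survival")
  set.seed(17)
  worst <- 0
  for (r in 1:25) {
    sim <- generate_survival_data(120, rnorm(3, 0, 0.4),
                                  censoring_rate = runif(1, 0, 0.4),
                                  seed = 1000 + r)
    tt <- sim$clinical$time
    if (r %% 2 == 0) tt <- round(tt, 1)        # induce ties -> Breslow path
    keep <- tt > 0
    tt <- tt[keep]
    ev <- sim$clinical$event[keep]
    X <- sim$covariates[keep, , drop = FALSE]
    if (sum(ev) < 3) next
    fit <- fit_coxph(tt, ev, X)
    if (fit$failed) next
    orc <- survival::coxph(survival::Surv(tt, ev) ~ scale(X), ties = "breslow")
    worst <- max(worst,
                 max(abs(unname(coef(fit)) - unname(coef(orc)))),
                 max(abs(unname(fit$se) - unname(sqrt(diag(stats::vcov(orc)))))))
  }
  expect_lt(worst, 1e-4)
})

test_that("Wald algebra and hazard-ratio intervals are exact", {
  ## constructed fit: beta = 0 gives W = 0, p = 1; beta = 1.96 SE gives p ~ 0.05
  fit <- structure(list(coefficients = c(a = 0, b = 1.96 * 0.5),
                        se = c(a = 0.3, b = 0.5), failed = FALSE),
                   class = "cox_fit")
  w <- wald_test(fit)
  expect_equal(w$wald, c(0, 1.96))
  expect_equal(w$p[1], 1)
  expect_equal(w$p[2], 0.05, tolerance = 1e-3)

  r <- gene_survival_records(fit, alpha = 0.01)
  expect_equal(r$hr, exp(r$beta))
  expect_true(all(r$ci_low < r$hr & r$hr < r$ci_high))
  ## CI is log-symmetric about the estimate, exactly
  expect_equal(log(r$ci_high) - r$beta, r$beta - log(r$ci_low))

  recs <- data.frame(gene = c("x", "y", "z"), p = c(0.009, 0.011, 0.5))
  sel <- select_significant_genes(recs, alpha = 0.01)
  expect_equal(sel$gene, "x")
  expect_equal(nrow(select_significant_genes(recs, alpha = 1e-6)), 0L)
})

test_that("degenerate covariates and failed fits are handled", {
  sim <- generate_survival_data(80, c(g1 = 0.5), seed = 4)
  X <- cbind(sim$covariates, flat = rep(1, 80))
  expect_warning(fit <- fit_coxph(sim$clinical$time, sim$clinical$event, X),
                 "zero-variance")
  expect_equal(names(coef(fit)), "g1")

  ## perfect separation: the gene that exactly orders deaths first
  tt <- c(1:10 / 10, 2:11)
  ev <- rep(1L, 20)
  Xs <- cbind(sep = -(tt), noise = rnorm(20))
  fit2 <- fit_coxph(tt, ev, Xs)
  if (fit2$failed) {
    expect_warning(w <- wald_test(fit2), "did not converge")
    expect_equal(nrow(w), 0L)
  } else {
    succeed("monotone covariate still converged at this n")
  }
})

test_that("power simulation recovers planted effects among nulls", {
  betas <- c(rep(0.8, 2), -0.8, rep(0, 20))
  names(betas) <- paste0("g", seq_along(betas))
  sim <- generate_survival_data(500, betas, censoring_rate = 0.2, seed = 55)
  fit <- fit_coxph(sim$clinical$time, sim$clinical$event, sim$covariates)
  rec <- gene_survival_records(fit, alpha = 0.01)
  hits <- rec$gene[rec$significant]
  expect_gte(length(intersect(hits, c("g1", "g2", "g3"))), 2L)
  expect_lte(length(setdiff(hits, c("g1", "g2", "g3"))), 2L)
  ## recovered signs match the truth
  sig_true <- rec[rec$gene %in% c("g1", "g2", "g3") & rec$significant, ]
  expect_true(all(sign(sig_true$beta) == sign(betas[sig_true$gene])))
})

test_that("the pathway survival screen ties the stages together", {
  co <- small_cohort(seed = 23)
  ds <- small_dataset(co)
  ## treat two pathways as 'significant'; one gene pathway exercises the
  ## univariate edge case
  pw <- co$pathways
  pw$pathways$SOLO <- pw$pathways[[3]][1]
  res <- run_pathway_survival(ds, c("PW002", "SOLO"), pw, omics = "EXP")
  expect_s3_class(res, "pathway_survival")
  expect_setequal(names(res$records), c("PW002", "SOLO"))
  expect_equal(nrow(res$records$SOLO), 1L)
  ## deterministic: identical rerun
  res2 <- run_pathway_survival(ds, c("PW002", "SOLO"), pw, omics = "EXP")
  expect_identical(res$combined, res2$combined)
  ## unknown pathway errors; absent genes are skipped with a warning
  expect_error(run_pathway_survival(ds, "NOPE", pw), "unknown pathway")
  pw$pathways$GHOST <- "NOT_A_GENE"
  expect_warning(run_pathway_survival(ds, c("PW002", "GHOST"), pw),
                 "no genes")

  ## the planted survival genes surface in the significant table
  big <- generate_multiomics(synthetic_config(
    n_per_class = c("LTS" = 150L, "non-LTS" = 150L), n_excluded = 0L,
    n_pathways = 10L, genes_per_pathway = c(6L, 10L),
    planted = data.frame(pathway = 2L, omics = 2L, delta = 0.5),
    survival_betas = "auto", censoring_rate = 0.1, seed = 71))
  lab <- assign_survival_labels(big$clinical)
  dsb <- harmonize(big$omics, lab, big$clinical)
  out <- run_pathway_survival(dsb, names(big$pathways$pathways)[2],
                              big$pathways, omics = "EXP")
  sig <- out$significant
  expect_gte(length(intersect(sig$gene, names(big$truth$betas))), 2L)
  top_true <- sig[sig$gene %in% names(big$truth$betas), ]
  expect_true(all(sign(top_true$beta) ==
                    sign(big$truth$betas[top_true$gene])))
})
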