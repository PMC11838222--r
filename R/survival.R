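## survival: Cox proportional hazards over the genes of significant
## pathways.  The partial likelihood (Breslow tie handling) is maximized by
## Newton-Raphson with analytic gradient and observed information; the
## baseline hazard cancels and is never estimated.  Wald statistics
## W = beta / SE(beta) against a standard normal give per-gene p-values,
## and hazard ratios exp(beta) with 95% CIs exp(beta +/- 1.96 SE) form the
## forest-plot table.

## Core Newton-Raphson engine on a fixed design matrix.  Vectorized: risk-set
## suffix sums via reverse cumulative sums; the S2/S0 part of the information
## collapses to one weighted cross-product via the per-sample cumulative
## hazard weights.
cox_engine <- function(time, event, X, max_iter = 100L, tol = 1e-8) {
  n <- length(time)
  p <- ncol(X)
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; X_s <- X[ord, , drop = FALSE]
  grp <- match(t_s, t_s)               # first index of each tie group
  ## distinct event times: first position of each tied group containing events
  ev_pos <- which(e_s == 1L)
  if (!length(ev_pos)) stop("no events in the data", call. = FALSE)
  dj <- rowsum(rep(1, length(ev_pos)), grp[ev_pos])     # deaths per time
  sj <- as.integer(rownames(dj))                        # group start index
  dj <- as.vector(dj)
  sum_x_events <- colSums(X_s[ev_pos, , drop = FALSE])

  beta <- numeric(p)
  ll_old <- -Inf
  converged <- FALSE; failed <- FALSE
  info <- NULL; U <- rep(Inf, p)
  for (it in seq_len(max_iter)) {
    lp <- drop(X_s %*% beta)
    if (any(abs(lp) > 500) || any(abs(beta) > 50)) { failed <- TRUE; break }
    w <- exp(lp)
    rcum0 <- rev(cumsum(rev(w)))
    wX <- w * X_s
    rcum1 <- apply(wX, 2L, function(cc) rev(cumsum(rev(cc))))
    if (is.null(dim(rcum1))) rcum1 <- matrix(rcum1, nrow = n)
    S0 <- rcum0[sj]
    M <- rcum1[sj, , drop = FALSE] / S0            # mu_j, D x p
    ll <- sum(lp[ev_pos]) - sum(dj * log(S0))
    U <- sum_x_events - colSums(dj * M)
    ## information: sum_j d_j (S2_j/S0_j - mu_j mu_j')
    a <- numeric(n); a[sj] <- dj / S0
    cw <- cumsum(a)                                # per-sample hazard weight
    term1 <- crossprod(X_s, (w * cw) * X_s)
    term2 <- crossprod(M, dj * M)
    info <- term1 - term2
    if (max(abs(U)) < tol) { converged <- TRUE; ll_old <- ll; break }
    step <- tryCatch(solve(info, U), error = function(e) NULL)
    if (is.null(step)) { failed <- TRUE; break }
    ## step-halving if the likelihood would decrease
    ok <- FALSE
    for (h in 0:8) {
      cand <- beta + step / 2^h
      lp_c <- drop(X_s %*% cand)
      if (any(abs(lp_c) > 500)) next
      w_c <- exp(lp_c)
      S0_c <- rev(cumsum(rev(w_c)))[sj]
      ll_c <- sum(lp_c[ev_pos]) - sum(dj * log(S0_c))
      if (ll_c >= ll - 1e-12) { beta <- cand; ok <- TRUE; break }
    }
    if (!ok) { failed <- TRUE; break }
    ll_old <- ll
  }
  if (!converged && !failed) failed <- max(abs(U)) > 1e-4
  vcov <- if (!failed) tryCatch(solve(info), error = function(e) NULL) else NULL
  if (is.null(vcov)) failed <- TRUE
  list(beta = beta, vcov = vcov,
       se = if (!failed) sqrt(diag(vcov)) else rep(NA_real_, p),
       loglik = ll_old, iter = it, converged = converged && !failed,
       failed = failed, score_norm = max(abs(U)),
       n = n, nevent = length(ev_pos))
}

#' Fit a Cox proportional hazards model by partial likelihood
#'
#' Covariates are z-scored before the fit (so coefficients are per standard
#' deviation) and zero-variance columns are dropped.  `"multivariate"` mode
#' fits all covariates jointly (one model per pathway in the pipeline);
#' `"univariate"` fits each covariate alone.  Non-convergence or a monotone
#' likelihood (perfect separation) marks the fit failed rather than
#' returning unusable estimates.
#'
#' @param time survival/censoring times.
#' @param event 0/1 event indicator.
#' @param covariates numeric matrix (samples x genes) with column names.
#' @param mode `"multivariate"` (default) or `"univariate"`.
#' @param standardize z-score covariates before fitting (default TRUE).
#' @param pathway_id optional provenance label.
#' @return object of class `cox_fit` (or, in univariate mode, a named list
#'   of them with class `cox_fit_list`).
#' @export
fit_coxph <- function(time, event, covariates,
                      mode = c("multivariate", "univariate"),
                      standardize = TRUE, pathway_id = NA_character_) {
  mode <- match.arg(mode)
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  stopifnot(length(time) == nrow(X), length(event) == nrow(X))
  if (nrow(X) < 10L) stop("need >= 10 samples for a Cox fit", call. = FALSE)
  if (sum(event) < 1L) stop("need >= 1 observed event", call. = FALSE)
  sdv <- apply(X, 2L, stats::sd)
  drop_cols <- colnames(X)[sdv < 1e-12]
  if (length(drop_cols)) {
    warning("dropping zero-variance covariate(s): ",
            paste(drop_cols, collapse = ", "), call. = FALSE)
    X <- X[, sdv >= 1e-12, drop = FALSE]
    sdv <- sdv[sdv >= 1e-12]
  }
  if (ncol(X) == 0L) stop("no non-constant covariates remain", call. = FALSE)
  if (standardize) X <- scale(X)

  make_fit <- function(Xi) {
    eng <- cox_engine(time, event, Xi)
    structure(list(coefficients = stats::setNames(eng$beta, colnames(Xi)),
                   se = stats::setNames(eng$se, colnames(Xi)),
                   var = eng$vcov, loglik = eng$loglik, iter = eng$iter,
                   converged = eng$converged, failed = eng$failed,
                   score_norm = eng$score_norm, n = eng$n,
                   nevent = eng$nevent, mode = mode,
                   standardized = standardize, pathway_id = pathway_id,
                   dropped = drop_cols),
              class = "cox_fit")
  }
  if (mode == "multivariate") {
    make_fit(X)
  } else {
    fits <- lapply(colnames(X), function(g) make_fit(X[, g, drop = FALSE]))
    names(fits) <- colnames(X)
    structure(fits, class = "cox_fit_list")
  }
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_fit <- function(object, ...) object$var

#' @export
confint.cox_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se,
              object$coefficients + z * object$se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit%s: %d covariates, n = %d (%d events), %s in %d iter>\n",
              if (!is.na(x$pathway_id)) paste0(" [", x$pathway_id, "]") else "",
              length(x$coefficients), x$n, x$nevent,
              if (x$failed) "FAILED" else "converged", x$iter))
  if (!x$failed) print(round(rbind(beta = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @export
summary.cox_fit <- function(object, ...) {
  print(object)
  if (!object$failed) print(wald_test(object))
  invisible(object)
}

#' Wald tests for a Cox fit
#'
#' `W = beta / SE(beta)`, two-sided p-value from the standard normal.  A
#' failed fit emits no tests (zero-row result, with a warning).
#'
#' @param fit a `cox_fit` or `cox_fit_list`.
#' @return data.frame with columns `gene`, `beta`, `se`, `wald`, `p`.
#' @export
wald_test <- function(fit) {
  if (inherits(fit, "cox_fit_list")) {
    return(do.call(rbind, lapply(unname(fit), wald_test)))
  }
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$failed) {
    warning("fit did not converge; no Wald tests emitted", call. = FALSE)
    return(data.frame(gene = character(), beta = numeric(), se = numeric(),
                      wald = numeric(), p = numeric()))
  }
  W <- fit$coefficients / fit$se
  data.frame(gene = names(fit$coefficients),
             beta = unname(fit$coefficients), se = unname(fit$se),
             wald = unname(W), p = unname(2 * stats::pnorm(-abs(W))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene survival records with hazard ratios
#'
#' Extends the Wald table with `hr = exp(beta)` and the 95% CI
#' `exp(beta +/- 1.96 se)` (log-symmetric about the estimate), plus a
#' significance flag at `alpha`.
#'
#' @param fit a `cox_fit` or `cox_fit_list`.
#' @param alpha significance threshold on the Wald p-value (default 0.01).
#' @return data.frame with columns `gene`, `beta`, `se`, `wald`, `p`, `hr`,
#'   `ci_low`, `ci_high`, `significant`.
#' @export
gene_survival_records <- function(fit, alpha = 0.01) {
  w <- wald_test(fit)
  w$hr <- exp(w$beta)
  w$ci_low <- exp(w$beta - 1.96 * w$se)
  w$ci_high <- exp(w$beta + 1.96 * w$se)
  w$significant <- w$p < alpha
  w
}

#' Select significant genes
#'
#' @param records data.frame from [gene_survival_records()] (possibly
#'   row-bound over pathways).
#' @param alpha threshold (default 0.01); rows with `p < alpha` are kept,
#'   sorted by p.  An empty result is allowed.
#' @return the filtered, sorted data.frame (the forest-plot data).
#' @export
select_significant_genes <- function(records, alpha = 0.01) {
  out <- records[records$p < alpha, , drop = FALSE]
  out[order(out$p), , drop = FALSE]
}

#' Cox survival screen over significant pathways
#'
#' Fits one Cox model per significant pathway over that pathway's genes in
#' the chosen omics layer (expression by default), emits per-gene records,
#' and combines them into one table.  By default the labelled cohort of the
#' harmonized dataset is used; passing raw `omics_data` + `clinical` runs
#' on every sample with a valid time (censoring is handled natively, so the
#' early-censored class-label exclusions may be retained here).
#'
#' @param dataset a `harmonized_dataset` (must carry `clinical` unless
#'   `clinical` is given).
#' @param significant a `pathway_report`, or a character vector of pathway
#'   ids.
#' @param pathways a [pathway_collection()] providing gene membership.
#' @param omics layer used for covariate values (default `"EXP"`).
#' @param mode `"multivariate"` per pathway (default) or `"univariate"`.
#' @param alpha significance threshold (default 0.01).
#' @param omics_data optional raw [omics_matrix()] overriding the dataset's
#'   layer (wider cohort).
#' @param clinical optional [clinical_table()] overriding the dataset's.
#' @return object of class `pathway_survival`: list with `records` (one
#'   data.frame per pathway), `combined`, `significant`
#'   (filtered combined table), `alpha`, `omics`, `mode`, `n`, `nevent`.
#' @export
run_pathway_survival <- function(dataset, significant, pathways,
                                 omics = "EXP",
                                 mode = c("multivariate", "univariate"),
                                 alpha = 0.01, omics_data = NULL,
                                 clinical = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(pathways, "pathway_collection"))
  pw_ids <- if (inherits(significant, "pathway_report")) {
    unique(unlist(significant$pathway_sets, use.names = FALSE))
  } else as.character(significant)
  missing_pw <- setdiff(pw_ids, names(pathways$pathways))
  if (length(missing_pw)) {
    stop("unknown pathway id(s): ", paste(missing_pw, collapse = ", "),
         call. = FALSE)
  }
  om <- omics_data %||% dataset$omics[[omics]]
  if (is.null(om)) stop("omics layer '", omics, "' not found", call. = FALSE)
  clin <- clinical %||% dataset$clinical
  if (is.null(clin)) stop("no clinical table available", call. = FALSE)
  common <- intersect(rownames(om$values), clin$sample_id)
  if (length(common) < 10L) stop("fewer than 10 samples with both omics and clinical data", call. = FALSE)
  clin <- clin[match(common, clin$sample_id), ]
  vals <- om$values[common, , drop = FALSE]

  recs <- list()
  for (pw in pw_ids) {
    genes <- intersect(pathways$pathways[[pw]], colnames(vals))
    if (!length(genes)) {
      warning("pathway '", pw, "' has no genes in the omics layer; skipped",
              call. = FALSE)
      next
    }
    fit <- fit_coxph(clin$time, clin$event, vals[, genes, drop = FALSE],
                     mode = mode, pathway_id = pw)
    r <- gene_survival_records(fit, alpha)
    if (nrow(r)) {
      r <- cbind(pathway_id = pw, r, stringsAsFactors = FALSE)
      recs[[pw]] <- r
    }
  }
  combined <- if (length(recs)) do.call(rbind, c(recs, make.row.names = FALSE))
              else data.frame()
  structure(list(records = recs, combined = combined,
                 significant = if (nrow(combined))
                   select_significant_genes(combined, alpha) else combined,
                 alpha = alpha, omics = om$omics_name, mode = mode,
                 n = length(common), nevent = sum(clin$event)),
            class = "pathway_survival")
}

#' @export
print.pathway_survival <- function(x, ...) {
  cat(sprintf("<pathway_survival: %d pathways, %s layer, %s mode, n = %d (%d events)>\n",
              length(x$records), x$omics, x$mode, x$n, x$nevent))
  cat(sprintf("%d / %d gene records significant at p < %g\n",
              if (nrow(x$combined)) sum(x$combined$significant) else 0L,
              nrow(x$combined), x$alpha))
  if (nrow(x$significant)) print(utils::head(x$significant, 10L))
  invisible(x)
}

#' Write the combined gene-survival table as TSV (forest-plot data)
#' @param x a `pathway_survival`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(x, path) {
  utils::write.table(x$combined, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
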