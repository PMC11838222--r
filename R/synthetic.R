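## synthetic_data: multi-omics cohorts with planted discriminative pathways
## and survival times with known log-hazard coefficients, so every
## downstream stage can be tested against ground truth.

#' Configuration for the synthetic multi-omics generator
#'
#' Defaults emulate a two-class TCGA-like cohort: 150 labelled samples
#' (60 long-term, 90 non-long-term survivors) plus 10 early-censored samples,
#' three omics layers, 146 pathways of 10-40 genes partitioning the gene
#' universe, and two planted discriminative pathways whose genes are shifted
#' by `delta` standard deviations in the non-LTS class on the expression
#' layer.
#'
#' @param n_per_class named integer vector `c(LTS = , "non-LTS" = )`.
#' @param n_excluded number of extra samples censored before the class
#'   threshold (these exercise the exclusion rule downstream).
#' @param omics_names character vector of layer names (its length sets the
#'   number of omics layers).
#' @param n_pathways number of pathways.
#' @param genes_per_pathway integer range `c(min, max)`; each pathway's size
#'   is drawn uniformly from it.
#' @param planted data.frame with columns `pathway` (index), `omics` (index
#'   into `omics_names`) and `delta` (class mean shift in units of
#'   `noise_sd`).  `NULL` plants nothing.
#' @param noise_sd background standard deviation of gene values.
#' @param survival_betas named numeric vector of true log-hazard
#'   coefficients, names being gene ids (use `"auto"` to place
#'   `c(0.8, -0.5, 0.6)` on the first three genes of the first planted
#'   pathway; `NULL` for none).
#' @param baseline_rate exponential baseline hazard (events per year).
#' @param censoring_rate fraction of long-term survivors whose death time is
#'   replaced by a censoring time beyond the threshold.
#' @param threshold class threshold in years (default 2).
#' @param bounded character vector of omics names squashed through the
#'   normal CDF to a bounded (0,1) scale, mimicking methylation beta values.
#' @param overlap_genes number of genes additionally shared between
#'   consecutive pathways (0 = pathways partition the gene universe).
#' @param seed mandatory integer seed; all randomness is reproducible.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class = c("LTS" = 60L, "non-LTS" = 90L),
                             n_excluded = 10L,
                             omics_names = c("CNV", "EXP", "MET"),
                             n_pathways = 146L,
                             genes_per_pathway = c(10L, 40L),
                             planted = data.frame(pathway = c(10L, 80L),
                                                  omics = c(2L, 2L),
                                                  delta = c(2, 2)),
                             noise_sd = 1,
                             survival_betas = "auto",
                             baseline_rate = 0.5,
                             censoring_rate = 0.2,
                             threshold = 2,
                             bounded = NULL,
                             overlap_genes = 0L,
                             seed) {
  if (missing(seed)) stop("`seed` is mandatory for the synthetic generator", call. = FALSE)
  stopifnot(length(n_per_class) == 2L, all(n_per_class >= 3L),
            n_pathways >= 1L, length(genes_per_pathway) == 2L,
            genes_per_pathway[1L] >= 1L,
            genes_per_pathway[1L] <= genes_per_pathway[2L],
            noise_sd > 0, baseline_rate > 0,
            censoring_rate >= 0, censoring_rate < 1, threshold > 0)
  if (is.null(names(n_per_class))) names(n_per_class) <- c("LTS", "non-LTS")
  if (!is.null(planted) && nrow(planted)) {
    stopifnot(all(c("pathway", "omics", "delta") %in% names(planted)))
    if (any(planted$pathway < 1L | planted$pathway > n_pathways)) {
      stop("planted pathway index out of range 1..", n_pathways, call. = FALSE)
    }
    if (any(planted$omics < 1L | planted$omics > length(omics_names))) {
      stop("planted omics index out of range 1..", length(omics_names), call. = FALSE)
    }
    stopifnot(all(is.finite(planted$delta)))
  }
  structure(list(n_per_class = n_per_class, n_excluded = as.integer(n_excluded),
                 omics_names = omics_names, n_pathways = as.integer(n_pathways),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 planted = planted, noise_sd = noise_sd,
                 survival_betas = survival_betas, baseline_rate = baseline_rate,
                 censoring_rate = censoring_rate, threshold = threshold,
                 bounded = bounded, overlap_genes = as.integer(overlap_genes),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic multi-omics cohort with planted signal
#'
#' Background gene values are `Normal(0, noise_sd)`.  For every planted
#' `(pathway, omics, delta)` triple, genes of that pathway in that layer are
#' shifted by `+delta * noise_sd` for non-LTS samples.  Survival times come
#' from an exponential proportional-hazards model with rate
#' `baseline_rate * exp(sum(beta * x))` over the designated coefficient
#' genes (expression-layer values), truncated to the class side of the
#' threshold so that the label rule reconstructs the planted classes
#' exactly; early-censored "excluded" samples are drawn uniformly below the
#' threshold with no event.  Everything is deterministic given the seed.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `omics` (list of [omics_matrix()]),
#'   `pathways` ([pathway_collection()]), `clinical` ([clinical_table()]),
#'   and `truth` (planted classes, pathway/omics indices, true betas).
#' @export
generate_multiomics <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n1 <- config$n_per_class[[1L]]; n2 <- config$n_per_class[[2L]]
    n_lab <- n1 + n2
    n_tot <- n_lab + config$n_excluded
    classes <- c(rep(names(config$n_per_class)[1L], n1),
                 rep(names(config$n_per_class)[2L], n2),
                 rep("excluded", config$n_excluded))
    sample_ids <- sprintf("S%04d", seq_len(n_tot))

    ## pathway gene lists partition the universe (optional overlap shared
    ## with the next pathway for stress tests)
    size_choices <- seq.int(config$genes_per_pathway[1L], config$genes_per_pathway[2L])
    sizes <- if (length(size_choices) == 1L) {
      rep(size_choices, config$n_pathways)
    } else {
      sample(size_choices, config$n_pathways, replace = TRUE)
    }
    gene_ids <- sprintf("G%05d", seq_len(sum(sizes)))
    stops <- cumsum(sizes)
    starts <- stops - sizes + 1L
    pw <- lapply(seq_len(config$n_pathways), function(p) gene_ids[starts[p]:stops[p]])
    names(pw) <- sprintf("PW%03d", seq_len(config$n_pathways))
    if (config$overlap_genes > 0L && config$n_pathways > 1L) {
      for (p in seq_len(config$n_pathways - 1L)) {
        extra <- utils::head(pw[[p + 1L]], config$overlap_genes)
        pw[[p]] <- unique(c(pw[[p]], extra))
      }
    }
    pathways <- pathway_collection(pw)

    n_genes <- length(gene_ids)
    is_c2 <- classes == names(config$n_per_class)[2L]
    omics <- vector("list", length(config$omics_names))
    names(omics) <- config$omics_names
    for (o in seq_along(config$omics_names)) {
      m <- matrix(stats::rnorm(n_tot * n_genes, 0, config$noise_sd),
                  nrow = n_tot, ncol = n_genes,
                  dimnames = list(sample_ids, gene_ids))
      if (!is.null(config$planted) && nrow(config$planted)) {
        here <- config$planted[config$planted$omics == o, , drop = FALSE]
        for (r in seq_len(nrow(here))) {
          genes <- pw[[here$pathway[r]]]
          m[is_c2, genes] <- m[is_c2, genes] + here$delta[r] * config$noise_sd
        }
      }
      if (config$omics_names[o] %in% (config$bounded %||% character())) {
        m[] <- stats::pnorm(m / config$noise_sd)
      }
      omics[[o]] <- omics_matrix(m, config$omics_names[o])
    }

    ## true log-hazard coefficients on expression-layer genes
    betas <- config$survival_betas
    if (identical(betas, "auto")) {
      anchor <- if (!is.null(config$planted) && nrow(config$planted)) {
        pw[[config$planted$pathway[1L]]]
      } else gene_ids
      betas <- stats::setNames(c(0.8, -0.5, 0.6), utils::head(anchor, 3L))
    }
    expr_layer <- if ("EXP" %in% names(omics)) "EXP" else names(omics)[min(2L, length(omics))]
    lp <- rep(0, n_tot)
    if (!is.null(betas) && length(betas)) {
      xv <- omics[[expr_layer]]$values[, names(betas), drop = FALSE]
      xv <- scale(xv)
      lp <- drop(xv %*% betas)
    }
    rate <- config$baseline_rate * exp(lp)
    thr <- config$threshold
    time <- numeric(n_tot); event <- integer(n_tot)
    u <- stats::runif(n_tot)
    ## non-LTS: exponential truncated to (0, thr], death observed
    i2 <- which(is_c2)
    Fthr <- 1 - exp(-rate[i2] * thr)
    time[i2] <- -log(1 - u[i2] * Fthr) / rate[i2]
    event[i2] <- 1L
    ## LTS: memoryless continuation past thr; a fraction censored beyond thr
    i1 <- which(classes == names(config$n_per_class)[1L])
    time[i1] <- thr - log(1 - u[i1]) / rate[i1]
    event[i1] <- 1L
    if (config$censoring_rate > 0 && length(i1)) {
      n_cens <- round(config$censoring_rate * length(i1))
      cens <- sample(i1, n_cens)
      time[cens] <- thr + stats::runif(n_cens) * (time[cens] - thr)
      event[cens] <- 0L
    }
    ## excluded: censored before the threshold
    i0 <- which(classes == "excluded")
    if (length(i0)) {
      time[i0] <- stats::runif(length(i0), 0.05 * thr, thr)
      event[i0] <- 0L
    }
    clinical <- clinical_table(sample_ids, time, event)

    list(omics = omics, pathways = pathways, clinical = clinical,
         truth = list(class = stats::setNames(classes, sample_ids),
                      planted = config$planted,
                      planted_pathways = if (!is.null(config$planted))
                        names(pw)[config$planted$pathway] else character(),
                      betas = betas, expr_layer = expr_layer,
                      config = config))
  })
}

#' Generate survival data from an exponential proportional-hazards model
#'
#' Standard-normal covariates, death times with hazard
#' `baseline_rate * exp(X %*% betas)`, and a fixed fraction of samples
#' censored uniformly on `(0, t_death)` so the realized censoring fraction
#' equals `censoring_rate` (up to rounding).  Used to calibrate and verify
#' the Cox stage against known coefficients.
#'
#' @param n number of samples (>= 10).
#' @param betas numeric vector of true log-hazard coefficients; its length
#'   sets the number of covariates, names (optional) the gene ids.
#' @param baseline_rate constant baseline hazard (default 0.2).
#' @param censoring_rate fraction of samples censored (default 0).
#' @param seed integer seed.
#' @return list with `clinical` (a [clinical_table()]) and `covariates`
#'   (n x p numeric matrix).
#' @export
generate_survival_data <- function(n, betas, baseline_rate = 0.2,
                                   censoring_rate = 0, seed) {
  stopifnot(n >= 10L, censoring_rate >= 0, censoring_rate < 1)
  with_seed(seed, {
    p <- length(betas)
    ids <- sprintf("S%05d", seq_len(n))
    gn <- names(betas) %||% sprintf("G%03d", seq_len(p))
    x <- matrix(stats::rnorm(n * p), n, p, dimnames = list(ids, gn))
    rate <- baseline_rate * exp(drop(x %*% betas))
    time <- stats::rexp(n, rate)
    event <- rep(1L, n)
    if (censoring_rate > 0) {
      cens <- sample(n, round(censoring_rate * n))
      time[cens] <- stats::runif(length(cens)) * time[cens]
      event[cens] <- 0L
    }
    list(clinical = clinical_table(ids, time, event), covariates = x)
  })
}

#' Write a synthetic cohort to disk in the formats the readers accept
#'
#' One TSV per omics layer, a GMT for the pathways and a TSV clinical table;
#' doubles as the round-trip fixture generator for the I/O tests.
#'
#' @param cohort result of [generate_multiomics()].
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (o in names(cohort$omics)) {
    p <- file.path(dir, paste0(o, ".tsv"))
    write_omics_matrix(cohort$omics[[o]], p)
    paths[[o]] <- p
  }
  paths$gmt <- file.path(dir, "pathways.gmt")
  write_gene_sets(cohort$pathways, paths$gmt)
  paths$clinical <- file.path(dir, "clinical.tsv")
  write_clinical_table(cohort$clinical, paths$clinical)
  invisible(paths)
}
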