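## Pipeline orchestration: a declarative run configuration (YAML-loadable),
## staged execution with per-stage seeds derived from one master seed,
## reproducibility metadata (config hash stamped into every output), and
## the principal-component sweep experiment.

run_config_keys <- list(
  top = c("omics", "orientation", "gmt", "exclusions", "clinical",
          "time_unit", "id_col", "time_col", "event_col", "threshold",
          "n_pcs", "mode", "k", "cnn", "shap", "cox", "top_k", "seed",
          "out_dir"),
  cnn = c("filters", "kernel", "pool", "dense", "dropout", "augment_sd",
          "weight_decay", "mixup_alpha", "lr", "epochs", "batch_size",
          "validation_split"),
  shap = c("n_baselines", "n_path_samples", "noise_sd"),
  cox = c("omics", "mode", "alpha", "cohort"))

#' Build a validated run configuration
#'
#' Unknown keys raise a validation error before any computation, so typos
#' in a config file fail fast.
#'
#' @param ... configuration fields; see the package vignette for the full
#'   schema.  `seed` is the master seed from which every stage derives its
#'   own stream.
#' @return list of class `run_config` with all defaults filled in and a
#'   `hash` attribute.
#' @export
run_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.list(user[[1L]]) && is.null(names(user))) {
    user <- user[[1L]]
  }
  unknown <- setdiff(names(user), run_config_keys$top)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (blk in c("cnn", "shap", "cox")) {
    if (!is.null(user[[blk]])) {
      bad <- setdiff(names(user[[blk]]), c(run_config_keys[[blk]], "seed"))
      if (length(bad)) {
        stop("unknown config key(s) in '", blk, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  cfg <- list(
    omics = user$omics, orientation = user$orientation %||% "samples-as-rows",
    gmt = user$gmt, exclusions = user$exclusions,
    clinical = user$clinical, time_unit = user$time_unit %||% "years",
    id_col = user$id_col %||% "sample_id",
    time_col = user$time_col %||% "time",
    event_col = user$event_col %||% "event",
    threshold = user$threshold %||% 2,
    n_pcs = as.integer(user$n_pcs %||% 2L),
    mode = match.arg(user$mode %||% "fold-safe",
                     c("fold-safe", "own-class")),
    k = as.integer(user$k %||% 5L),
    cnn = user$cnn %||% list(),
    shap = user$shap %||% list(),
    cox = modifyList(list(omics = "EXP", mode = "multivariate", alpha = 0.01,
                          cohort = "labeled"), user$cox %||% list()),
    top_k = as.integer(user$top_k %||% 10L),
    seed = as.integer(user$seed %||% 1L),
    out_dir = user$out_dir)
  cfg <- structure(cfg, class = "run_config")
  attr(cfg, "hash") <- config_hash(unclass(cfg))
  cfg
}

#' Load a run configuration from YAML
#' @param path YAML file path.
#' @return a validated [run_config()].
#' @export
load_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

cfg_cnn <- function(cfg, seed) {
  args <- cfg$cnn
  if (!is.null(args$pool)) args$pool <- lapply(args$pool, unlist)
  args$seed <- seed
  do.call(cnn_config, args)
}

cfg_shap <- function(cfg, seed) {
  args <- cfg$shap
  args$seed <- seed
  do.call(gradient_shap_config, args)
}

stamp <- function(path, hash) {
  ## prepend a reproducibility header to a text output
  txt <- readLines(path)
  writeLines(c(paste0("# config_hash: ", hash), txt), path)
}

#' Run the full pipeline
#'
#' Stages: ingest (read + harmonize + label), cross-validated
#' classification, final model + gradient-SHAP pathway report, and the Cox
#' survival screen over the significant pathways.  Each stage draws its
#' seed from the master seed; outputs (when `out_dir` is set) are TSV/JSON
#' files stamped with the configuration hash, plus per-stage RDS state that
#' allows resuming.
#'
#' @param config a [run_config()].
#' @param cohort optional in-memory cohort (as returned by
#'   [generate_multiomics()]); when supplied the file paths in `config` are
#'   ignored and the cohort's omics/pathways/clinical are used directly.
#' @param resume reuse existing stage state found in `out_dir` (default
#'   FALSE).
#' @param verbose log stage progress (default TRUE).
#' @return object of class `pipeline_run` with elements `dataset`, `cv`,
#'   `model`, `attribution` (the pathway report), `survival`, `config`,
#'   `hash`.
#' @export
run_pipeline <- function(config, cohort = NULL, resume = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  hash <- attr(config, "hash")
  out_dir <- config$out_dir
  state_dir <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    state_dir <- file.path(out_dir, "state")
    dir.create(state_dir, showWarnings = FALSE)
  }
  logf <- if (!is.null(out_dir)) file.path(out_dir, "run.log") else NULL
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    if (verbose) message("[pathwaycnn] ", msg)
    if (!is.null(logf)) cat(msg, "\n", file = logf, append = TRUE)
  }
  staged <- function(name, expr) {
    f <- if (!is.null(state_dir)) file.path(state_dir, paste0(name, ".rds"))
    if (resume && !is.null(f) && file.exists(f)) {
      st <- readRDS(f)
      if (identical(st$hash, hash)) { say("stage ", name, ": resumed"); return(st$value) }
    }
    say("stage ", name, ": running")
    value <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    if (!is.null(f)) saveRDS(list(hash = hash, value = value), f)
    value
  }

  ## -- ingest ---------------------------------------------------------------
  ingest <- staged("ingest", {
    if (!is.null(cohort)) {
      omics <- cohort$omics; pathways <- cohort$pathways; clinical <- cohort$clinical
    } else {
      if (is.null(config$omics) || is.null(config$gmt) || is.null(config$clinical)) {
        stop("config must provide omics, gmt and clinical paths")
      }
      omics <- lapply(names(config$omics), function(nm) {
        read_omics_matrix(config$omics[[nm]], nm, orientation = config$orientation)
      })
      excl <- if (!is.null(config$exclusions)) readLines(config$exclusions) else character()
      pathways <- read_gene_sets(config$gmt, exclusions = trimws(excl))
      clinical <- read_clinical_table(config$clinical, id_col = config$id_col,
                                      time_col = config$time_col,
                                      event_col = config$event_col,
                                      time_unit = config$time_unit)
    }
    labels <- assign_survival_labels(clinical, config$threshold)
    dataset <- harmonize(omics, labels, clinical)
    list(dataset = dataset, pathways = pathways, clinical = clinical,
         omics = omics)
  })
  dataset <- ingest$dataset
  pathways <- ingest$pathways

  ## -- cross-validation -----------------------------------------------------
  cv <- staged("cv", {
    cross_validate(dataset, pathways, n_pcs = config$n_pcs, k = config$k,
                   mode = config$mode,
                   cnn = cfg_cnn(config, derive_seed(config$seed, "cnn")),
                   seed = derive_seed(config$seed, "cv"))
  })
  say(sprintf("pooled CV: acc %.3f auc %.3f",
              cv$pooled$accuracy, cv$pooled$auc))

  ## -- final model + attribution -------------------------------------------
  ## The interpreted model is trained on the configured embedding mode: in
  ## fold-safe mode all samples act as the training set (cross-fitted), so
  ## the explained model is the one whose features generalize.
  expl <- staged("explain", {
    stack <- if (config$mode == "own-class") {
      build_image_stack(dataset, pathways, config$n_pcs,
                        mode = "own-class")
    } else {
      build_image_stack(dataset, pathways, config$n_pcs, mode = "fold-safe",
                        train_ids = dataset$samples,
                        seed = derive_seed(config$seed, "embed-final"))
    }
    y <- dataset$labels$class[match(dataset$samples, dataset$labels$sample_id)]
    fit <- train_cnn(NULL, stack, y,
                     cfg_cnn(config, derive_seed(config$seed, "final")))
    maps <- cohort_attributions(fit, stack, y,
                                cfg_shap(config, derive_seed(config$seed, "shap")))
    scores <- aggregate_class_attributions(maps, as.character(y))
    report <- pathway_set_analysis(scores, k = config$top_k)
    list(model = fit, stack = stack, scores = scores, report = report)
  })

  ## -- survival -------------------------------------------------------------
  surv <- staged("cox", {
    use_all <- identical(config$cox$cohort, "all")
    om <- NULL; cl <- NULL
    if (use_all && !is.null(ingest$omics)) {
      nm <- vapply(ingest$omics, `[[`, character(1), "omics_name")
      om <- ingest$omics[[match(config$cox$omics, nm)]]
      cl <- ingest$clinical
    }
    run_pathway_survival(dataset, expl$report, pathways,
                         omics = config$cox$omics, mode = config$cox$mode,
                         alpha = config$cox$alpha,
                         omics_data = om, clinical = cl)
  })

  ## -- outputs --------------------------------------------------------------
  if (!is.null(out_dir)) {
    mfile <- file.path(out_dir, "cv_metrics.tsv")
    per <- do.call(rbind, lapply(cv$folds, function(f) {
      cbind(fold = f$fold, as.data.frame(f$metrics))
    }))
    per <- rbind(per, cbind(fold = "pooled", as.data.frame(cv$pooled)))
    utils::write.table(per, mfile, sep = "\t", quote = FALSE, row.names = FALSE)
    stamp(mfile, hash)
    jsonlite::write_json(
      list(config_hash = hash, mode = cv$mode, k = cv$k,
           pooled = as.data.frame(cv$pooled)),
      file.path(out_dir, "cv_metrics.json"), auto_unbox = TRUE, digits = NA)
    pfile <- file.path(out_dir, "pathway_report.tsv")
    write_pathway_report(expl$report, pfile); stamp(pfile, hash)
    sfile <- file.path(out_dir, "gene_survival.tsv")
    write_survival_table(surv, sfile); stamp(sfile, hash)
    yaml::write_yaml(c(unclass(config), list(hash = hash)),
                     file.path(out_dir, "config.yaml"))
    say("outputs written to ", out_dir)
  }

  structure(list(dataset = dataset, pathways = pathways, cv = cv,
                 model = expl$model, scores = expl$scores,
                 attribution = expl$report, survival = surv,
                 config = config, hash = hash),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run %s>\n", substr(x$hash, 1, 8)))
  print(x$dataset)
  print(x$cv)
  print(x$attribution)
  print(x$survival)
  invisible(x)
}

#' @export
summary.pipeline_run <- function(object, ...) {
  print(object)
  summary(object$cv)
  invisible(object)
}

#' Sweep the number of principal components
#'
#' Runs a full cross-validation per candidate PC count and tabulates the
#' pooled AUC, reporting the smallest count achieving the maximum (the
#' image width grows as `n_omics * n_pcs`, so fewer components are cheaper).
#'
#' @param dataset a `harmonized_dataset`.
#' @param pathways a [pathway_collection()].
#' @param pc_values integer vector of candidate PC counts (default 1:4).
#' @param k,mode,cnn,seed passed to [cross_validate()].
#' @return data.frame `(n_pcs, auc, accuracy, f1, image_cols)` sorted by
#'   `n_pcs`, with attribute `"best"` = the argmax row's `n_pcs`.
#' @export
sweep_n_pcs <- function(dataset, pathways, pc_values = 1:4, k = 5L,
                        mode = "fold-safe", cnn = cnn_config(), seed = 1L) {
  stopifnot(length(pc_values) >= 1L)
  rows <- lapply(sort(unique(as.integer(pc_values))), function(npc) {
    cv <- cross_validate(dataset, pathways, n_pcs = npc, k = k, mode = mode,
                         cnn = cnn, seed = seed)
    data.frame(n_pcs = npc, auc = cv$pooled$auc,
               accuracy = cv$pooled$accuracy, f1 = cv$pooled$f1,
               image_cols = length(dataset$omics) * npc *
                 (if (mode == "fold-safe") 2L else 1L))
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- out$n_pcs[which.max(out$auc)]
  out
}
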