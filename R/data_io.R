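## data_io: reading and validating omics matrices, GMT gene sets and clinical
## tables; harmonization to common samples/genes; survival-class labelling.

#' Construct an omics matrix object
#'
#' A thin S3 wrapper around a numeric samples x genes matrix carrying the
#' omics layer name.  Sample identifiers live in `rownames`, gene symbols in
#' `colnames`; both must be unique.
#'
#' @param values numeric matrix, samples in rows, genes in columns, with
#'   dimnames set.
#' @param omics_name layer label, e.g. `"CNV"`, `"EXP"`, `"MET"`.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, omics_name) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("omics matrix needs sample rownames and gene colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample ids in omics matrix '", omics_name, "'", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate gene ids in omics matrix '", omics_name, "'", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("non-finite values remain in omics matrix '", omics_name, "'", call. = FALSE)
  }
  structure(list(omics_name = omics_name, values = values), class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix '%s': %d samples x %d genes>\n",
              x$omics_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

## Canonical gene-id normalization: exact match after upper-case + trim.
norm_gene_id <- function(x) toupper(trimws(x))
norm_sample_id <- function(x) trimws(x)

#' Read an omics matrix from TSV/CSV
#'
#' Reads a delimited numeric matrix with a header row and an identifier first
#' column.  The delimiter (tab or comma) is auto-detected from the header
#' line.  Regardless of the file orientation the result is samples x genes.
#'
#' Cleaning policy, applied in order: duplicate gene columns are collapsed by
#' their mean; rows then columns with more than `max_missing` missing values
#' are dropped; remaining missing cells are imputed with the per-gene median.
#' Counts of dropped/imputed entries are reported via
#' `options(pathwaycnn.verbose = TRUE)`.
#'
#' @param path file path.
#' @param omics_name layer label stored in the result.
#' @param orientation `"samples-as-rows"` (default) or `"genes-as-rows"`.
#' @param max_missing maximum tolerated fraction of missing values in a row
#'   or column before it is dropped (default 0.2).
#' @return an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, omics_name,
                              orientation = c("samples-as-rows", "genes-as-rows"),
                              max_missing = 0.2) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          na.strings = c("NA", "", "NaN", "null"))
  ids <- norm_sample_id(as.character(df[[1L]]))
  body <- df[, -1L, drop = FALSE]
  names(body) <- names(df)[-1L]   # data.frame subsetting mangles duplicates
  bad <- which(!vapply(body, is.numeric, logical(1)))
  if (length(bad)) {
    col <- names(body)[bad[1L]]
    row <- which(is.na(suppressWarnings(as.numeric(body[[bad[1L]]]))) &
                   !is.na(body[[bad[1L]]]))[1L]
    stop(sprintf("non-numeric cell in '%s' at column '%s', data row %s",
                 path, col, row %||% "?"), call. = FALSE)
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "genes-as-rows") m <- t(m)
  rownames(m) <- norm_sample_id(rownames(m))
  colnames(m) <- norm_gene_id(colnames(m))

  ## collapse duplicated gene columns by mean
  if (anyDuplicated(colnames(m))) {
    genes <- colnames(m)
    uniq <- unique(genes)
    ndup <- length(genes) - length(uniq)
    m <- vapply(uniq, function(g) {
      cols <- m[, genes == g, drop = FALSE]
      rowMeans(cols, na.rm = FALSE)
    }, numeric(nrow(m)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(ids, uniq))
    colnames(m) <- uniq
    pcn_log("collapsed ", ndup, " duplicate gene column(s) by mean in ", omics_name)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate sample ids in ", path, call. = FALSE)
  }

  ## drop rows/cols exceeding the missingness bound, then median-impute
  miss_row <- rowMeans(is.na(m))
  if (any(miss_row > max_missing)) {
    pcn_log("dropping ", sum(miss_row > max_missing), " sample row(s) with >",
            max_missing * 100, "% missing")
    m <- m[miss_row <= max_missing, , drop = FALSE]
  }
  miss_col <- colMeans(is.na(m))
  if (any(miss_col > max_missing)) {
    pcn_log("dropping ", sum(miss_col > max_missing), " gene column(s) with >",
            max_missing * 100, "% missing")
    m <- m[, miss_col <= max_missing, drop = FALSE]
  }
  if (nrow(m) == 0L || ncol(m) == 0L) {
    stop("no samples or genes remain in '", path, "' after missingness filter",
         call. = FALSE)
  }
  if (anyNA(m)) {
    n_imp <- sum(is.na(m))
    med <- apply(m, 2L, stats::median, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- med[idx[, 2L]]
    pcn_log("imputed ", n_imp, " missing cell(s) by per-gene median in ", omics_name)
  }
  omics_matrix(m, omics_name)
}

#' Write an omics matrix as TSV (samples as rows)
#'
#' Values are written with full double precision (`%.17g`) so that a
#' write/read round trip reproduces them bit-exactly.
#'
#' @param x an [omics_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  m <- x$values
  lines <- c(
    paste(c("sample_id", colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Construct a pathway collection
#'
#' @param pathways named list of character gene vectors, in display (image
#'   row) order.  Names are pathway ids; gene lists must be non-empty.
#' @param exclusions character vector of pathway ids that were removed
#'   upstream (kept for provenance).
#' @return object of class `pathway_collection`.
#' @export
pathway_collection <- function(pathways, exclusions = character()) {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  if (anyDuplicated(names(pathways))) stop("duplicate pathway ids", call. = FALSE)
  if (any(lengths(pathways) == 0L)) stop("empty pathway gene list", call. = FALSE)
  pathways <- lapply(pathways, norm_gene_id)
  structure(list(pathways = pathways, exclusions = exclusions),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  sizes <- lengths(x$pathways)
  cat(sprintf("<pathway_collection: %d pathways, %d-%d genes each, %d excluded upstream>\n",
              length(x$pathways), min(sizes), max(sizes), length(x$exclusions)))
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$pathways)

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `id`, `description`,
#' then one or more genes.  Pathway (row) order is the file order after
#' removing `exclusions`; duplicate genes within a set are dropped keeping
#' the first occurrence.
#'
#' @param path GMT file path.
#' @param exclusions character vector of pathway ids to remove (for example,
#'   disease-specific pathways); ids not present in the file are ignored.
#' @return a [pathway_collection()].
#' @export
read_gene_sets <- function(path, exclusions = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f)]
    if (length(f) < 3L) {
      stop(sprintf("malformed GMT line %d in '%s': need id, description and >=1 gene",
                   i, path), call. = FALSE)
    }
    ids[i] <- f[1L]
    genes <- norm_gene_id(f[-(1:2)])
    sets[[i]] <- genes[!duplicated(genes)]
  }
  if (anyDuplicated(ids)) {
    stop("duplicate pathway ids in '", path, "'", call. = FALSE)
  }
  names(sets) <- ids
  keep <- !(ids %in% exclusions)
  pathway_collection(sets[keep], exclusions = intersect(exclusions, ids))
}

#' Write a pathway collection as a GMT file
#' @param x a [pathway_collection()].
#' @param path output path.
#' @param descriptions optional character vector of descriptions (recycled).
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(x, path, descriptions = "na") {
  stopifnot(inherits(x, "pathway_collection"))
  descriptions <- rep_len(descriptions, length(x$pathways))
  lines <- mapply(function(id, desc, genes) {
    paste(c(id, desc, genes), collapse = "\t")
  }, names(x$pathways), descriptions, x$pathways)
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table
#'
#' Expects columns for sample id, overall survival time and a vital-status /
#' event flag (1 or `"DECEASED"`-like = death observed, 0 or `"LIVING"` =
#' censored).  Times are converted to years.
#'
#' @param path TSV/CSV path (delimiter auto-detected).
#' @param time_col,event_col,id_col column names (defaults `"time"`,
#'   `"event"`, `"sample_id"`).
#' @param time_unit `"years"` or `"days"`; days are divided by 365.25.
#' @return data.frame of class `clinical_table` with columns
#'   `sample_id`, `time` (years), `event` (0/1 integer).
#' @export
read_clinical_table <- function(path, id_col = "sample_id", time_col = "time",
                                event_col = "event",
                                time_unit = c("years", "days")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  for (col in c(id_col, time_col, event_col)) {
    if (!col %in% names(df)) stop("clinical table lacks column '", col, "'", call. = FALSE)
  }
  ev <- df[[event_col]]
  if (is.character(ev)) {
    ev <- ifelse(grepl("^(1|DECEASED|DEAD|EVENT|TRUE)$", toupper(trimws(ev))), 1L, 0L)
  }
  clinical_table(sample_id = norm_sample_id(as.character(df[[id_col]])),
                 time = as.numeric(df[[time_col]]),
                 event = as.integer(ev),
                 time_unit = time_unit)
}

#' Construct a clinical table
#' @param sample_id character vector of ids.
#' @param time numeric survival/follow-up times.
#' @param event 0/1 event indicator (1 = death observed).
#' @param time_unit unit of `time`; `"days"` are converted to years.
#' @return data.frame of class `clinical_table`.
#' @export
clinical_table <- function(sample_id, time, event, time_unit = c("years", "days")) {
  time_unit <- match.arg(time_unit)
  if (time_unit == "days") time <- time / 365.25
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("survival times must be finite and non-negative", call. = FALSE)
  }
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("event flags must be 0/1", call. = FALSE)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in clinical table", call. = FALSE)
  structure(data.frame(sample_id = as.character(sample_id), time = time,
                       event = event, stringsAsFactors = FALSE),
            class = c("clinical_table", "data.frame"))
}

#' Write a clinical table as TSV
#' @param x a [clinical_table()] (times in years).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(x, path) {
  lines <- c("sample_id\ttime\tevent",
             sprintf("%s\t%.17g\t%d", x$sample_id, x$time, x$event))
  writeLines(lines, path)
  invisible(path)
}

#' Assign long-term / non-long-term survivor labels
#'
#' Three-way partition of a cohort around a survival threshold (default
#' 2 years): survivors beyond the threshold are `LTS`; observed deaths at or
#' before it are `non-LTS`; samples censored at or before it carry too little
#' information and are `excluded` from classification.
#'
#' @param clinical a [clinical_table()].
#' @param threshold threshold in years (default 2).
#' @return data.frame of class `cohort_labels` with columns `sample_id` and
#'   `class` (factor with levels `LTS`, `non-LTS`, `excluded`).
#' @export
assign_survival_labels <- function(clinical, threshold = 2) {
  stopifnot(threshold > 0)
  cls <- ifelse(clinical$time > threshold, "LTS",
                ifelse(clinical$event == 1L, "non-LTS", "excluded"))
  n <- table(factor(cls, levels = c("LTS", "non-LTS", "excluded")))
  pcn_log(sprintf("labels: %d LTS, %d non-LTS, %d excluded",
                  n[["LTS"]], n[["non-LTS"]], n[["excluded"]]))
  if (all(cls == "excluded")) {
    warning("all samples excluded at threshold ", threshold, " years")
  }
  structure(data.frame(sample_id = clinical$sample_id,
                       class = factor(cls, levels = c("LTS", "non-LTS", "excluded")),
                       stringsAsFactors = FALSE),
            class = c("cohort_labels", "data.frame"))
}

#' Harmonize omics layers to common samples and genes
#'
#' Restricts every layer to the intersection of sample ids across layers,
#' further intersected with the non-excluded labelled samples, and to the
#' intersection of gene ids across layers.  All matrices are re-indexed to
#' identical orderings (sample order = first layer's order restricted to the
#' intersection; gene order likewise).
#'
#' @param omics list of [omics_matrix()] objects (>= 2 layers).
#' @param labels a `cohort_labels` data.frame from [assign_survival_labels()].
#' @param clinical optional [clinical_table()]; if given, its rows for the
#'   harmonized samples are stored on the result for the survival stage.
#' @return object of class `harmonized_dataset`: list with `omics` (named
#'   list of aligned `omics_matrix`), `labels`, `clinical`, `samples`, `genes`.
#' @export
harmonize <- function(omics, labels, clinical = NULL) {
  if (inherits(omics, "omics_matrix")) omics <- list(omics)
  if (length(omics) < 2L) stop("need at least 2 omics layers", call. = FALSE)
  names(omics) <- vapply(omics, `[[`, character(1), "omics_name")
  sample_sets <- lapply(omics, function(o) rownames(o$values))
  gene_sets <- lapply(omics, function(o) colnames(o$values))
  common_samples <- Reduce(intersect, sample_sets)
  keep_ids <- labels$sample_id[labels$class != "excluded"]
  common_samples <- common_samples[common_samples %in% keep_ids]
  common_genes <- Reduce(intersect, gene_sets)
  if (length(common_samples) == 0L || length(common_genes) == 0L) {
    counts <- paste(sprintf("%s: %d samples x %d genes", names(omics),
                            lengths(sample_sets), lengths(gene_sets)),
                    collapse = "; ")
    stop("empty sample or gene intersection after harmonization (", counts, ")",
         call. = FALSE)
  }
  aligned <- lapply(omics, function(o) {
    omics_matrix(o$values[common_samples, common_genes, drop = FALSE], o$omics_name)
  })
  lab <- labels[match(common_samples, labels$sample_id), , drop = FALSE]
  lab$class <- droplevels(factor(lab$class, levels = c("LTS", "non-LTS")))
  rownames(lab) <- NULL
  clin <- NULL
  if (!is.null(clinical)) {
    clin <- clinical[clinical$sample_id %in% common_samples, , drop = FALSE]
    rownames(clin) <- NULL
  }
  structure(list(omics = aligned, labels = lab, clinical = clin,
                 samples = common_samples, genes = common_genes),
            class = "harmonized_dataset")
}

#' @export
print.harmonized_dataset <- function(x, ...) {
  cat(sprintf("<harmonized_dataset: %d samples x %d genes, layers: %s>\n",
              length(x$samples), length(x$genes),
              paste(names(x$omics), collapse = ", ")))
  print(table(x$labels$class))
  invisible(x)
}
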