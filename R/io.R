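#' Read a feature-by-sample matrix from a delimited text file
#'
#' Canonical dialect: a header row of sample identifiers and a first column of
#' feature identifiers; any delimiter `utils::read.table` understands. Rows
#' containing missing or non-numeric cells are dropped (`missing_policy =
#' "drop_feature"`, the default) or raise an error; zero-variance rows are
#' always dropped, with a message giving the count, because whitening cannot
#' use them.
#'
#' @param path File path.
#' @param delimiter Field separator, default tab.
#' @param missing_policy `"drop_feature"` or `"error"`.
#' @return An unscaled [omics_matrix()]. Attributes `n_dropped_missing` and
#'   `n_dropped_zero_variance` record the filtering.
#' @export
read_matrix <- function(path, delimiter = "\t",
                        missing_policy = c("drop_feature", "error")) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("input matrix not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("matrix file needs a feature-id column plus samples: ", path, call. = FALSE)
  feature_ids <- as.character(df[[1L]])
  check_unique_ids(feature_ids, "feature")
  check_unique_ids(colnames(df)[-1L], "sample")
  vals <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(
    vapply(vals, function(col) as.numeric(as.character(col)), numeric(nrow(vals)))
  )
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(vals), dimnames = list(NULL, colnames(vals)))
  bad_row <- apply(num, 1L, anyNA)
  if (missing_policy == "error" && any(bad_row)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing or non-numeric cell at feature '%s', sample '%s'",
                 feature_ids[idx[1L]], colnames(num)[idx[2L]]), call. = FALSE)
  }
  n_missing <- sum(bad_row)
  if (n_missing) {
    message(n_missing, " feature(s) with missing values removed")
    num <- num[!bad_row, , drop = FALSE]
    feature_ids <- feature_ids[!bad_row]
  }
  rsd <- apply(num, 1L, stats::sd)
  n_zv <- sum(rsd == 0)
  if (n_zv) {
    message(n_zv, " zero-variance feature(s) removed")
    feature_ids <- feature_ids[rsd != 0]
    num <- num[rsd != 0, , drop = FALSE]
  }
  rownames(num) <- feature_ids
  out <- omics_matrix(num, scaled = FALSE)
  attr(out, "n_dropped_missing") <- n_missing
  attr(out, "n_dropped_zero_variance") <- n_zv
  out
}

#' Write an omics matrix (or any labelled matrix) as TSV
#'
#' @param X Matrix with row and column names.
#' @param path Output path.
#' @param id_column Name of the first (identifier) column in the header.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(X, path, id_column = "feature_id") {
  df <- data.frame(rownames(X), unclass(X)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Broad dialect: one set per line, tab-separated fields
#' `name TAB description TAB member1 TAB member2 ...`. When a universe of
#' feature identifiers is supplied, members are intersected with it and sets
#' left empty are dropped (count reported via a message); otherwise the
#' universe defaults to the union of all members.
#'
#' @param path GMT file path.
#' @param universe Optional character vector of feature identifiers.
#' @return A `gene_set_collection`: list with `sets` (named list of
#'   `list(description, members)`) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("GMT line ", which(nf < 3L)[1L], " has fewer than 3 fields", call. = FALSE)
  }
  names_ <- vapply(fields, `[[`, character(1L), 1L)
  check_unique_ids(names_, "gene-set")
  sets <- lapply(fields, function(f) list(description = f[[2L]],
                                          members = unique(f[-c(1L, 2L)])))
  names(sets) <- names_
  if (is.null(universe)) {
    universe <- sort(unique(unlist(lapply(sets, `[[`, "members"))))
  } else {
    universe <- unique(as.character(universe))
    sets <- lapply(sets, function(s) {
      s$members <- intersect(s$members, universe)
      s
    })
    empty <- vapply(sets, function(s) length(s$members) == 0L, logical(1L))
    if (any(empty)) {
      message(sum(empty), " gene set(s) empty after universe intersection removed")
      sets <- sets[!empty]
    }
  }
  if (!length(sets)) stop("no gene sets retained from ", path, call. = FALSE)
  structure(list(sets = sets, universe = universe), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, universe of %d features\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a sample annotation table
#'
#' One row per sample; the first column holds sample identifiers. The named
#' time/event columns (if present and requested) are parsed as right-censored
#' survival data; every other column becomes a categorical factor.
#'
#' @param path TSV file path.
#' @param time_column,event_column Column names holding survival time and the
#'   0/1 event indicator, or `NULL` for no survival data.
#' @param delimiter Field separator.
#' @return A `sample_annotation`: list with `sample_ids`, `factors` (tibble),
#'   and optional `survival_time` / `survival_event` vectors.
#' @export
read_sample_table <- function(path, time_column = NULL, event_column = NULL,
                              delimiter = "\t") {
  if (!file.exists(path)) stop("sample table not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  sample_annotation(df, id_column = colnames(df)[1L],
                    time_column = time_column, event_column = event_column)
}

#' Build a sample annotation from a data frame
#'
#' @param df Data frame with one row per sample.
#' @param id_column Column holding sample identifiers.
#' @inheritParams read_sample_table
#' @return A `sample_annotation` object.
#' @export
sample_annotation <- function(df, id_column = "sample",
                              time_column = NULL, event_column = NULL) {
  if (!id_column %in% colnames(df)) {
    stop("id column '", id_column, "' not found", call. = FALSE)
  }
  ids <- as.character(df[[id_column]])
  check_unique_ids(ids, "sample")
  if (xor(is.null(time_column), is.null(event_column))) {
    stop("time and event columns must be supplied together", call. = FALSE)
  }
  surv_time <- surv_event <- NULL
  if (!is.null(time_column)) {
    for (cn in c(time_column, event_column)) {
      if (!cn %in% colnames(df)) stop("column '", cn, "' not found", call. = FALSE)
    }
    surv_time <- as.numeric(df[[time_column]])
    surv_event <- df[[event_column]]
    if (!all(surv_event %in% c(0, 1))) {
      bad <- which(!surv_event %in% c(0, 1))[1L]
      stop("event indicator outside {0,1} at row ", bad,
           " (value '", surv_event[bad], "')", call. = FALSE)
    }
    surv_event <- as.integer(surv_event)
    if (anyNA(surv_time) || any(surv_time < 0)) {
      stop("survival times must be nonnegative numbers", call. = FALSE)
    }
    names(surv_time) <- names(surv_event) <- ids
  }
  factor_cols <- setdiff(colnames(df), c(id_column, time_column, event_column))
  factors <- tibble::as_tibble(df[, factor_cols, drop = FALSE])
  factors[] <- lapply(factors, as.character)
  structure(list(sample_ids = ids, factors = factors,
                 survival_time = surv_time, survival_event = surv_event),
            class = "sample_annotation")
}

#' @export
print.sample_annotation <- function(x, ...) {
  cat(sprintf("<sample_annotation> %d samples, factors: %s%s\n",
              length(x$sample_ids),
              if (ncol(x$factors)) paste(colnames(x$factors), collapse = ", ") else "(none)",
              if (!is.null(x$survival_time)) "; survival data present" else ""))
  invisible(x)
}

# Align annotation rows to a vector of sample ids (order-independent match).
align_annotation <- function(ann, sample_ids) {
  idx <- match(sample_ids, ann$sample_ids)
  if (anyNA(idx)) {
    stop("samples missing from annotation: ",
         paste(utils::head(sample_ids[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  out <- ann
  out$sample_ids <- ann$sample_ids[idx]
  out$factors <- ann$factors[idx, , drop = FALSE]
  if (!is.null(ann$survival_time)) {
    out$survival_time <- ann$survival_time[idx]
    out$survival_event <- ann$survival_event[idx]
  }
  out
}

#' Write a consensus decomposition to a directory
#'
#' Writes `S.tsv` (features x components), `M.tsv` (components x samples),
#' `stability.tsv` and `metadata.json` (k, number of runs, seed list, scaling
#' mode). Reading the directory back with [read_decomposition()] reproduces
#' the matrices to within 1e-12.
#'
#' @param dec A [run_consensus()] result.
#' @param dir Output directory (created if needed).
#' @param overwrite Allow writing into a non-empty directory?
#' @return Invisibly, a character vector of written file paths (the manifest).
#' @export
write_decomposition <- function(dec, dir, overwrite = FALSE) {
  stopifnot(inherits(dec, "consensus_ica"))
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite) {
    stop("directory ", dir, " is not empty; use overwrite = TRUE", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("S.tsv", "M.tsv", "stability.tsv", "metadata.json"))
  write_matrix(format_full(dec$S), paths[1L], "feature_id")
  write_matrix(format_full(dec$M), paths[2L], "component")
  utils::write.table(
    data.frame(component = rownames(dec$M), stability = format_full(dec$stability)),
    paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(k = dec$k, n_runs = dec$n_runs, seeds = dec$seeds,
               scaling_mode = dec$scaling_mode, n_features = nrow(dec$S),
               n_samples = ncol(dec$M))
  jsonlite::write_json(meta, paths[4L], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

# 17 significant digits round-trips doubles exactly through text.
format_full <- function(x) {
  y <- format(x, digits = 17L, scientific = TRUE, trim = TRUE)
  dim(y) <- dim(x)
  dimnames(y) <- dimnames(x)
  y
}

#' Read back a decomposition written by [write_decomposition()]
#'
#' @param dir Directory containing `S.tsv`, `M.tsv`, `stability.tsv`,
#'   `metadata.json`.
#' @return A `consensus_ica` object.
#' @export
read_decomposition <- function(dir) {
  req <- file.path(dir, c("S.tsv", "M.tsv", "stability.tsv", "metadata.json"))
  missing <- req[!file.exists(req)]
  if (length(missing)) stop("decomposition files missing: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  read_mat <- function(p) {
    df <- utils::read.table(p, sep = "\t", header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE, quote = "", comment.char = "")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    storage.mode(m) <- "double"
    m
  }
  S <- read_mat(req[1L])
  M <- read_mat(req[2L])
  stab_df <- utils::read.table(req[3L], sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  stability <- stats::setNames(as.numeric(stab_df$stability), stab_df$component)
  meta <- jsonlite::read_json(req[4L], simplifyVector = TRUE)
  new_consensus_ica(S = S, M = M, stability = stability,
                    n_runs = meta$n_runs, seeds = as.integer(meta$seeds),
                    k = meta$k, scaling_mode = meta$scaling_mode)
}
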