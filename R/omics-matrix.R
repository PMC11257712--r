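#' Construct a feature-by-sample omics matrix
#'
#' Light wrapper around a numeric matrix enforcing the orientation convention
#' used throughout the package: features (genes, CpGs, miRNAs, ...) are rows,
#' samples are columns. Feature and sample identifiers must be unique; the
#' `scaled` flag records whether row-centering (and optional row variance
#' rescaling) has been applied, so that downstream steps can refuse
#' double-scaled or unscaled input.
#'
#' @param values Numeric matrix, n features x m samples (n >= 2, m >= 3).
#' @param feature_ids Character vector of unique row identifiers. Defaults to
#'   `rownames(values)`.
#' @param sample_ids Character vector of unique column identifiers. Defaults
#'   to `colnames(values)`.
#' @param scaled Logical; has row-centering already been applied?
#' @return An object of class `omics_matrix`: the numeric matrix with
#'   dimnames set and a `scaled` attribute.
#' @examples
#' x <- omics_matrix(matrix(rnorm(12), 4, 3,
#'   dimnames = list(paste0("g", 1:4), paste0("s", 1:3))))
#' dim(x)
#' @export
omics_matrix <- function(values, feature_ids = rownames(values),
                         sample_ids = colnames(values), scaled = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (features x samples)", call. = FALSE)
  }
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop("feature and sample identifiers are required", call. = FALSE)
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) < 2L || ncol(values) < 3L) {
    stop("need at least 2 features and 3 samples, got ",
         nrow(values), " x ", ncol(values), call. = FALSE)
  }
  check_unique_ids(feature_ids, "feature")
  check_unique_ids(sample_ids, "sample")
  if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyNA(values)) stop("omics matrix contains missing values", call. = FALSE)
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(values, scaled = isTRUE(scaled), class = c("omics_matrix", "matrix", "array"))
}

check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate ", what, " identifiers: ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(ids)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %d features x %d samples%s\n",
              nrow(x), ncol(x), if (is_scaled(x)) " (scaled)" else ""))
  invisible(x)
}

#' Test or read the scaled flag of an omics matrix
#' @param x An `omics_matrix` (a plain matrix is treated as unscaled).
#' @return Logical scalar.
#' @export
is_scaled <- function(x) isTRUE(attr(x, "scaled"))

as_omics_matrix <- function(x, scaled = FALSE) {
  if (inherits(x, "omics_matrix")) return(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("f", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  omics_matrix(x, scaled = scaled)
}

#' Row-center (and optionally variance-rescale) an omics matrix
#'
#' Centering each feature across samples is the minimal preprocessing required
#' before whitening; `center_unit_variance` additionally rescales each row to
#' unit variance so that highly expressed features do not dominate the
#' decomposition. Scaling an already-scaled matrix is an error: double scaling
#' is always a pipeline bug.
#'
#' @param X An unscaled [omics_matrix()] (plain matrices are accepted).
#' @param mode `"center"` (default) or `"center_unit_variance"`.
#' @return A new `omics_matrix` with `scaled = TRUE`; the input is untouched.
#' @examples
#' x <- omics_matrix(matrix(1:12, 4, 3,
#'   dimnames = list(paste0("g", 1:4), paste0("s", 1:3))) + 0)
#' rowMeans(scale_matrix(x))
#' @export
scale_matrix <- function(X, mode = c("center", "center_unit_variance")) {
  mode <- match.arg(mode)
  X <- as_omics_matrix(X)
  if (is_scaled(X)) stop("matrix is already scaled; double scaling is forbidden", call. = FALSE)
  V <- unclass(X)
  attr(V, "scaled") <- NULL
  rsd <- apply(V, 1L, stats::sd)
  if (any(rsd == 0)) {
    stop("constant feature row(s) present (",
         paste(utils::head(rownames(V)[rsd == 0], 5L), collapse = ", "),
         "); drop zero-variance features before scaling", call. = FALSE)
  }
  V <- V - rowMeans(V)
  if (mode == "center_unit_variance") V <- V / rsd
  out <- omics_matrix(V, scaled = TRUE)
  attr(out, "scaling_mode") <- mode
  out
}
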