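#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a consensus decomposition
#'
#' One row per component: stability and, when the data matrix is supplied,
#' the fraction of variance explained.
#'
#' @param x A `consensus_ica` object.
#' @param X Optional omics matrix the decomposition was computed from.
#' @param ... Unused.
#' @return A tibble with columns `component`, `stability` and optionally
#'   `variance_explained`.
#' @export
tidy.consensus_ica <- function(x, X = NULL, ...) {
  out <- tibble::tibble(component = names(x$stability),
                        stability = unname(x$stability))
  if (!is.null(X)) {
    out <- dplyr::left_join(out, variance_explained(x, X), by = "component")
  }
  out
}

#' One-row summary of a consensus decomposition
#'
#' @param x A `consensus_ica` object.
#' @param ... Unused.
#' @return A tibble with `k`, `n_features`, `n_samples`, `n_runs`,
#'   `n_dropped`, `mean_stability`, `min_stability`, `scaling_mode`.
#' @export
glance.consensus_ica <- function(x, ...) {
  tibble::tibble(k = x$k, n_features = nrow(x$S), n_samples = ncol(x$M),
                 n_runs = x$n_runs, n_dropped = x$n_dropped,
                 mean_stability = mean(x$stability),
                 min_stability = min(x$stability),
                 scaling_mode = x$scaling_mode)
}

#' Component weights in long form
#'
#' Joins each sample's component weights with the sample annotation, ready
#' for modelling or plotting.
#'
#' @param x A `consensus_ica` object.
#' @param ann Optional [sample_annotation()].
#' @param ... Unused.
#' @return A tibble with `sample`, `component`, `weight` and any annotation
#'   columns.
#' @export
augment.consensus_ica <- function(x, ann = NULL, ...) {
  out <- tibble::as_tibble(t(x$M), rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "component", values_to = "weight")
  if (!is.null(ann)) {
    ann <- align_annotation(ann, x$sample_ids)
    meta <- dplyr::bind_cols(tibble::tibble(sample = ann$sample_ids), ann$factors)
    if (!is.null(ann$survival_time)) {
      meta$time <- unname(ann$survival_time)
      meta$event <- unname(ann$survival_event)
    }
    out <- dplyr::left_join(out, meta, by = "sample")
  }
  out
}
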