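new_consensus_ica <- function(S, M, stability, n_runs, seeds, k,
                              scaling_mode, n_dropped = 0L) {
  structure(list(S = S, M = M, stability = stability,
                 n_runs = as.integer(n_runs), seeds = as.integer(seeds),
                 k = as.integer(k), scaling_mode = scaling_mode,
                 n_dropped = as.integer(n_dropped),
                 feature_ids = rownames(S), sample_ids = colnames(M)),
            class = "consensus_ica")
}

#' Assemble a consensus decomposition from matrices
#'
#' Low-level constructor, mainly useful for wrapping externally computed or
#' ground-truth factorizations so they can flow through the interpretation,
#' clinical and integration tooling.
#'
#' @param S Numeric n x k source matrix (feature rownames required).
#' @param M Numeric k x m weight matrix (sample colnames required).
#' @param stability Optional length-k stability vector; defaults to `NA`.
#' @param seeds,n_runs,scaling_mode Optional provenance fields.
#' @return A `consensus_ica` object.
#' @export
consensus_decomposition <- function(S, M, stability = NULL, seeds = integer(),
                                    n_runs = 0L, scaling_mode = "center") {
  if (!is.matrix(S) || !is.matrix(M) || ncol(S) != nrow(M)) {
    stop("S (n x k) and M (k x m) with matching k are required", call. = FALSE)
  }
  if (is.null(rownames(S)) || is.null(colnames(M))) {
    stop("S needs feature rownames and M needs sample colnames", call. = FALSE)
  }
  k <- ncol(S)
  comp_ids <- paste0("IC", seq_len(k))
  colnames(S) <- rownames(M) <- comp_ids
  if (is.null(stability)) stability <- rep(NA_real_, k)
  names(stability) <- comp_ids
  new_consensus_ica(S = S, M = M, stability = stability, n_runs = n_runs,
                    seeds = seeds, k = k, scaling_mode = scaling_mode)
}

#' @export
print.consensus_ica <- function(x, ...) {
  cat(sprintf(paste0("<consensus_ica> k = %d components, %d features x %d samples\n",
                     "  %d run(s) averaged (%d dropped), stability %.3f-%.3f\n"),
              x$k, nrow(x$S), ncol(x$M), x$n_runs - x$n_dropped, x$n_dropped,
              min(x$stability), max(x$stability)))
  invisible(x)
}

#' Match the components of two ICA runs
#'
#' Components from independent ICA runs come back in random order and with
#' random sign. This computes the k x k matrix of absolute Pearson
#' correlations between the source (`S`) columns of the two runs and solves
#' the optimal one-to-one assignment maximizing total |r| (Hungarian
#' algorithm on cost 1 - |r|). The sign of each matched correlation gives the
#' flip needed to redirect the matched component.
#'
#' @param reference,other `ica_run` objects (or any lists with an `S` matrix)
#'   sharing feature space and k.
#' @return A list of class `component_alignment`: `permutation` (index into
#'   `other` for each reference component), `signs` (+1/-1 per reference
#'   component), `match_correlations` (matched |r| values).
#' @export
match_components <- function(reference, other) {
  S_ref <- reference$S; S_oth <- other$S
  if (ncol(S_ref) != ncol(S_oth)) {
    stop("component counts differ: ", ncol(S_ref), " vs ", ncol(S_oth), call. = FALSE)
  }
  if (nrow(S_ref) != nrow(S_oth)) {
    stop("feature counts differ between runs", call. = FALSE)
  }
  k <- ncol(S_ref)
  R <- stats::cor(S_ref, S_oth)
  R[is.na(R)] <- 0
  perm <- solve_assignment(1 - abs(R))
  matched_r <- R[cbind(seq_len(k), perm)]
  signs <- ifelse(matched_r < 0, -1, 1)
  structure(list(permutation = perm, signs = signs,
                 match_correlations = abs(matched_r)),
            class = "component_alignment")
}

# Apply an alignment: reorder/flip `other` so its components line up with the
# reference (S columns and M rows jointly, leaving S %*% M unchanged).
apply_alignment <- function(other, alignment) {
  S <- other$S[, alignment$permutation, drop = FALSE]
  M <- other$M[alignment$permutation, , drop = FALSE]
  S <- sweep(S, 2L, alignment$signs, "*")
  M <- sweep(M, 1L, alignment$signs, "*")
  list(S = S, M = M)
}

#' Consensus ICA: average many matched ICA runs
#'
#' The core decomposition routine. The input matrix is scaled (row-centered,
#' optionally variance-rescaled), whitened once to rank k, and decomposed
#' `n_runs` times by fixed-point fastICA from different random
#' initializations (run i uses seed `base_seed + i`). Non-converged runs are
#' dropped. A reference run is chosen as the medoid — the converged run with
#' the highest mean matched |r| to all other runs — and every other run is
#' matched to it by [match_components()], reordered, sign-flipped and
#' averaged elementwise into consensus `S` and `M`. Per-component stability
#' is the mean matched |r| to the reference across the other runs. Finally
#' each component is oriented so its largest-magnitude source value is
#' positive (the matching `M` row is flipped jointly).
#'
#' The result is a pure function of `(X, opts, n_runs, base_seed)`: the
#' worker count only affects wall time.
#'
#' @param X An [omics_matrix()] (or plain matrix), scaled or not; unscaled
#'   input is scaled with `opts$scaling_mode`.
#' @param opts An [ica_options()] object.
#' @param n_runs Number of ICA runs to average (>= 2). Default 30.
#' @param base_seed Integer; run i draws its initialization from seed
#'   `base_seed + i`.
#' @param n_workers Parallel workers for the runs (forked via
#'   [parallel::mclapply()]; 1 = sequential).
#' @return A `consensus_ica` object: `S` (n x k), `M` (k x m), `stability`
#'   (length k in \[0, 1\]), `n_runs`, `seeds`, `k`, `scaling_mode`.
#' @examples
#' truth <- simulate_mixture(n = 200, m = 20, k = 3, noise_sd = 0.05, seed = 7)
#' dec <- run_consensus(truth$X, ica_options(k = 3), n_runs = 8, base_seed = 1)
#' dec$stability
#' @export
run_consensus <- function(X, opts, n_runs = 30L, base_seed = 1L, n_workers = 1L) {
  stopifnot(inherits(opts, "ica_options"))
  n_runs <- as.integer(n_runs)
  if (n_runs < 2L) stop("n_runs must be at least 2", call. = FALSE)
  X <- as_omics_matrix(X, scaled = is_scaled(X))
  if (!is_scaled(X)) X <- scale_matrix(X, opts$scaling_mode)
  wh <- whiten(X, opts$k)
  seeds <- as.integer(base_seed) + seq_len(n_runs)
  run_one <- function(s) fastica_run(wh, opts, seed = s)
  runs <- if (n_workers > 1L) {
    parallel::mclapply(seeds, run_one, mc.cores = n_workers)
  } else {
    lapply(seeds, run_one)
  }
  # runs are collected in run-index order, so worker count cannot change the
  # consensus
  ok <- vapply(runs, function(r) isTRUE(r$converged), logical(1L))
  n_dropped <- sum(!ok)
  if (n_dropped) message(n_dropped, " non-converged run(s) dropped")
  if (n_dropped > n_runs / 2) {
    warning("more than half of the ICA runs failed to converge; ",
            "consider a smaller k or a looser tolerance", call. = FALSE)
  }
  if (sum(ok) == 0L) {
    stop("all ICA runs failed to converge; reduce k or loosen tol", call. = FALSE)
  }
  if (sum(ok) == 1L) {
    stop("only one ICA run converged; nothing to average — ",
         "increase n_runs, reduce k or loosen tol", call. = FALSE)
  }
  runs <- runs[ok]
  R <- length(runs)
  # Medoid reference: highest mean matched |r| against all other runs.
  pair_score <- matrix(1, R, R)
  alignments <- vector("list", R * R)
  for (a in seq_len(R - 1L)) {
    for (b in seq((a + 1L), R)) {
      al <- match_components(runs[[a]], runs[[b]])
      pair_score[a, b] <- pair_score[b, a] <- mean(al$match_correlations)
    }
  }
  ref_score <- (rowSums(pair_score) - 1) / (R - 1L)
  ref <- which.max(ref_score)             # ties: lowest index
  reference <- runs[[ref]]
  S_sum <- reference$S
  M_sum <- reference$M
  stab <- matrix(NA_real_, R - 1L, opts$k)
  others <- setdiff(seq_len(R), ref)
  for (idx in seq_along(others)) {
    al <- match_components(reference, runs[[others[idx]]])
    aligned <- apply_alignment(runs[[others[idx]]], al)
    S_sum <- S_sum + aligned$S
    M_sum <- M_sum + aligned$M
    stab[idx, ] <- al$match_correlations
  }
  S <- S_sum / R
  M <- M_sum / R
  stability <- colMeans(stab)
  # Deterministic orientation: largest |S| entry of each component positive.
  flip <- vapply(seq_len(opts$k), function(j) {
    v <- S[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1L))
  S <- sweep(S, 2L, flip, "*")
  M <- sweep(M, 1L, flip, "*")
  comp_ids <- paste0("IC", seq_len(opts$k))
  dimnames(S) <- list(wh$feature_ids, comp_ids)
  dimnames(M) <- list(comp_ids, wh$sample_ids)
  names(stability) <- comp_ids
  new_consensus_ica(S = S, M = M, stability = stability, n_runs = n_runs,
                    seeds = seeds, k = opts$k,
                    scaling_mode = opts$scaling_mode, n_dropped = n_dropped)
}

#' Recommended upper bound on the number of components
#'
#' Components beyond about one-third of the sample count tend to be unstable
#' and uninterpretable; this returns `floor(m / 3)`.
#'
#' @param m Sample count (>= 3).
#' @return Integer upper bound.
#' @export
suggest_max_components <- function(m) {
  m <- as.integer(m)
  if (is.na(m) || m < 3L) stop("need at least 3 samples", call. = FALSE)
  m %/% 3L
}

#' Fraction of total variance captured by each component
#'
#' For component j the rank-1 contribution is `S[, j] %*% t(M[j, ])`; its
#' squared Frobenius norm over that of the scaled data matrix is the variance
#' fraction. Fractions need not sum to 1 (residual noise) and are reported
#' sorted in decreasing order.
#'
#' @param dec A `consensus_ica` object.
#' @param X The omics matrix the decomposition was computed from (scaled or
#'   not; unscaled input is rescaled with the decomposition's recorded mode).
#' @return A tibble with columns `component`, `variance_explained`, sorted
#'   decreasing.
#' @export
variance_explained <- function(dec, X) {
  stopifnot(inherits(dec, "consensus_ica"))
  X <- as_omics_matrix(X, scaled = is_scaled(X))
  if (!is_scaled(X)) X <- scale_matrix(X, dec$scaling_mode)
  if (!identical(rownames(X), dec$feature_ids) ||
      !identical(colnames(X), dec$sample_ids)) {
    X <- X[dec$feature_ids, dec$sample_ids, drop = FALSE]
  }
  if (nrow(X) != nrow(dec$S) || ncol(X) != ncol(dec$M)) {
    stop("matrix dimensions do not match the decomposition", call. = FALSE)
  }
  total <- sum(unclass(X)^2)
  frac <- vapply(seq_len(dec$k), function(j) {
    sum(dec$S[, j]^2) * sum(dec$M[j, ]^2) / total
  }, numeric(1L))
  tibble::tibble(component = colnames(dec$S), variance_explained = frac) |>
    dplyr::arrange(dplyr::desc(.data$variance_explained))
}

#' Reconstruct the scaled data matrix with selected components removed
#'
#' Technical components (batch effects, platform biases) can be removed by
#' setting their weight rows to zero and reconstructing: the returned matrix
#' is `S %*% M'` where `M'` has the rows in `drop` zeroed. With `drop`
#' empty this is the plain rank-k reconstruction.
#'
#' @param dec A `consensus_ica` object.
#' @param drop Integer indices or component names (`"IC3"`) to remove; may be
#'   empty.
#' @return An [omics_matrix()] (scaled) of the reconstruction.
#' @export
remove_components <- function(dec, drop = integer()) {
  stopifnot(inherits(dec, "consensus_ica"))
  if (is.character(drop)) {
    idx <- match(drop, rownames(dec$M))
    if (anyNA(idx)) stop("unknown component(s): ",
                         paste(drop[is.na(idx)], collapse = ", "), call. = FALSE)
    drop <- idx
  }
  drop <- as.integer(drop)
  if (length(drop) && (any(drop < 1L) || any(drop > dec$k))) {
    stop("component indices must lie in 1..", dec$k, call. = FALSE)
  }
  M2 <- dec$M
  M2[drop, ] <- 0
  omics_matrix(dec$S %*% M2, scaled = TRUE)
}
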