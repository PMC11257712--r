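#' Options for a single ICA run
#'
#' @param k Number of components, `1 <= k <= min(n, m)`.
#' @param nonlinearity Contrast function for the fixed-point update:
#'   `"logcosh"` (tanh, a = 1; default), `"exp"` (Gaussian), or `"cube"`
#'   (kurtosis-based).
#' @param tol Convergence tolerance on the maximum change in direction of the
#'   unmixing vectors, `max_j |1 - |<w_j_new, w_j_old>||`. Default 1e-6.
#' @param max_iter Maximum fixed-point iterations. Default 1000.
#' @param scaling_mode Row scaling applied before whitening: `"center"`
#'   (default) or `"center_unit_variance"`.
#' @return A list of class `ica_options`.
#' @export
ica_options <- function(k, nonlinearity = c("logcosh", "exp", "cube"),
                        tol = 1e-6, max_iter = 1000L,
                        scaling_mode = c("center", "center_unit_variance")) {
  nonlinearity <- match.arg(nonlinearity)
  scaling_mode <- match.arg(scaling_mode)
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (!is.numeric(tol) || tol <= 0) stop("tol must be positive", call. = FALSE)
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("max_iter must be at least 1", call. = FALSE)
  structure(list(k = k, nonlinearity = nonlinearity, tol = tol,
                 max_iter = max_iter, scaling_mode = scaling_mode),
            class = "ica_options")
}

#' Whiten a scaled omics matrix to rank k
#'
#' Computes the thin SVD `X = U D V'` of the row-centered matrix and returns
#' the rank-k whitened representation: `Z = K %*% X` is k x m with
#' `Z %*% t(Z) / m = I` (the scaled sample-space scores), where
#' `K = sqrt(m) * D_k^{-1} U_k'`. The object also carries the feature-space
#' scores `U_k` and singular values needed by the fixed-point iteration and
#' for mapping unmixed components back to the original feature/sample spaces.
#'
#' @param X A scaled [omics_matrix()].
#' @param k Target rank, `k <= min(n - 1, m - 1)` and at most the numerical
#'   rank of `X`.
#' @return A list of class `whitened_omics` with elements `Z` (k x m), `K`
#'   (k x n), `singular_values` (length k), `U` (n x k), `X` (the scaled
#'   input), `feature_ids`, `sample_ids`.
#' @export
whiten <- function(X, k) {
  X <- as_omics_matrix(X, scaled = is_scaled(X))
  if (!is_scaled(X)) stop("whitening requires a scaled matrix; call scale_matrix() first",
                          call. = FALSE)
  n <- nrow(X); m <- ncol(X)
  k <- as.integer(k)
  if (k < 1L || k > min(n - 1L, m - 1L)) {
    stop("k must satisfy 1 <= k <= min(n - 1, m - 1) = ", min(n - 1L, m - 1L),
         call. = FALSE)
  }
  V <- unclass(X); attr(V, "scaled") <- NULL; attr(V, "scaling_mode") <- NULL
  sv <- svd(V, nu = k, nv = k)
  d <- sv$d
  rank_eff <- sum(d > max(n, m) * d[1L] * .Machine$double.eps * 10)
  if (k > rank_eff) {
    stop("requested k = ", k, " exceeds effective rank ", rank_eff, call. = FALSE)
  }
  dk <- d[seq_len(k)]
  K <- sqrt(m) * (t(sv$u) / dk)            # k x n
  Z <- sqrt(m) * t(sv$v)                   # k x m, Z = K %*% X
  dimnames(Z) <- list(paste0("IC", seq_len(k)), colnames(X))
  structure(list(Z = Z, K = K, singular_values = dk, U = sv$u,
                 X = X, feature_ids = rownames(X), sample_ids = colnames(X)),
            class = "whitened_omics")
}

# Contrast functions: g and its derivative, applied elementwise.
ica_contrast <- function(nonlinearity) {
  switch(nonlinearity,
    logcosh = list(g = function(u) tanh(u),
                   dg = function(u) 1 - tanh(u)^2),
    exp     = list(g = function(u) u * exp(-u^2 / 2),
                   dg = function(u) (1 - u^2) * exp(-u^2 / 2)),
    cube    = list(g = function(u) u^3,
                   dg = function(u) 3 * u^2))
}

# Symmetric decorrelation: W <- (W W')^{-1/2} W.
sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% (t(e$vectors) / sqrt(vals)) %*% W
}

#' One fastICA run on a whitened matrix
#'
#' Symmetric (parallel) fixed-point iteration with the chosen contrast and
#' symmetric decorrelation at every step, starting from a random orthonormal
#' unmixing matrix drawn from the given seed. Independence is maximized over
#' the feature axis — sources are signals across features, matching the
#' `X = S M` model in which each column of `S` holds a sparse, super-Gaussian
#' signal over the n features. The result is mapped back to the original
#' spaces: `S` (n x k, unit-variance columns) and `M` (k x m) such that
#' `S %*% M` equals the rank-k projection of the scaled input.
#'
#' @param wh A [whiten()] result.
#' @param opts An [ica_options()] object (its `k` must match the whitening
#'   rank).
#' @param seed Integer seed controlling the random initialization; the run is
#'   a pure function of `(wh, opts, seed)`.
#' @return A list of class `ica_run`: `S`, `M`, `W` (k x k rotation), `seed`,
#'   `converged`, `iterations`.
#' @export
fastica_run <- function(wh, opts, seed) {
  stopifnot(inherits(wh, "whitened_omics"), inherits(opts, "ica_options"))
  k <- length(wh$singular_values)
  if (opts$k != k) stop("opts$k = ", opts$k, " does not match whitening rank ", k,
                        call. = FALSE)
  n <- nrow(wh$U)
  # Feature-space whitened scores, k x n observations with G G'/n = I.
  G <- sqrt(n) * t(wh$U)
  ct <- ica_contrast(opts$nonlinearity)
  W <- withr::with_seed(seed,
    matrix(stats::rnorm(k * k), k, k))
  W <- sym_decorrelate(W)
  converged <- FALSE
  iter <- 0L
  while (iter < opts$max_iter) {
    iter <- iter + 1L
    U <- W %*% G                           # k x n projections
    gU <- ct$g(U)
    W_new <- gU %*% t(G) / n - rowMeans(ct$dg(U)) * W
    W_new <- sym_decorrelate(W_new)
    crit <- max(abs(1 - abs(rowSums(W_new * W))))
    W <- W_new
    if (crit < opts$tol) { converged <- TRUE; break }
  }
  A <- W %*% G                             # k x n unmixed sources, ~unit variance
  S <- t(A)
  csd <- apply(S, 2L, stats::sd)
  S <- sweep(S, 2L, csd, "/")              # exact unit sample variance
  # Least-squares weights: S columns are orthogonal (scaled rotation of U),
  # so M = (S'S)^{-1} S'X reconstructs the rank-k projection exactly.
  StS <- crossprod(S)
  M <- solve(StS, crossprod(S, unclass(wh$X)))
  dimnames(S) <- list(wh$feature_ids, paste0("IC", seq_len(k)))
  dimnames(M) <- list(paste0("IC", seq_len(k)), wh$sample_ids)
  structure(list(S = S, M = M, W = W, seed = as.integer(seed),
                 converged = converged, iterations = iter),
            class = "ica_run")
}

#' @export
print.ica_run <- function(x, ...) {
  cat(sprintf("<ica_run> k = %d, seed = %d, %s after %d iteration(s)\n",
              ncol(x$S), x$seed,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}
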