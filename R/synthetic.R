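#' Simulate a sparse super-Gaussian mixture with known ground truth
#'
#' Generates `X = S_true %*% M_true + noise`, the generative model that
#' consensus ICA assumes: k mutually independent, non-Gaussian source
#' signals over n features, mixed into m samples. Sources are iid per
#' feature — `"laplace"` (heavy-tailed, excess kurtosis 3; default) or
#' `"sparse_spikes"` (a small fraction of features carry large values, the
#' rest sit near zero) — and each source column is standardized to mean 0,
#' variance 1. The mixing matrix is Gaussian, redrawn until its condition
#' number is at most 100 so recovery failures reflect the method, not an
#' ill-posed mixture. Gaussian noise of standard deviation `noise_sd` is
#' added. Everything is a pure function of `seed`.
#'
#' @param n,m,k Features, samples, true source count (`k <= min(n, m) / 2`).
#' @param source_model `"laplace"` or `"sparse_spikes"`.
#' @param noise_sd Noise standard deviation (>= 0).
#' @param spike_fraction For `"sparse_spikes"`: expected fraction of spike
#'   features per source. Default 0.02.
#' @param seed Integer seed.
#' @return A list of class `synthetic_truth`: `X` ([omics_matrix()]),
#'   `S_true` (n x k), `M_true` (k x m), `noise` (the drawn residual),
#'   `source_model`, `seed`; later generator stages add `batch_labels`,
#'   `planted_sets`, `survival`.
#' @export
simulate_mixture <- function(n, m, k, source_model = c("laplace", "sparse_spikes"),
                             noise_sd = 0.1, spike_fraction = 0.02, seed = 1L) {
  source_model <- match.arg(source_model)
  n <- as.integer(n); m <- as.integer(m); k <- as.integer(k)
  if (k < 1L || k > min(n, m) / 2) {
    stop("k must satisfy 1 <= k <= min(n, m)/2", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  out <- withr::with_seed(seed, {
    S <- switch(source_model,
      laplace = matrix(rlaplace(n * k), n, k),
      sparse_spikes = {
        spikes <- matrix(stats::runif(n * k) < spike_fraction, n, k)
        base <- matrix(stats::rnorm(n * k, sd = 0.05), n, k)
        amp <- matrix(sample(c(-1, 1), n * k, replace = TRUE) *
                        (4 + abs(stats::rnorm(n * k))), n, k)
        base + spikes * amp
      })
    S <- scale(S)[, , drop = FALSE]          # columns: mean 0, sd 1
    attr(S, "scaled:center") <- attr(S, "scaled:scale") <- NULL
    M <- draw_mixing(k, m, max_condition = 100)
    E <- matrix(stats::rnorm(n * m, sd = noise_sd), n, m)
    list(S = S, M = M, E = E,
         n_spikes = if (source_model == "sparse_spikes")
           colSums(matrix(abs(S) > 1, n, k)) else NULL)
  })
  feature_ids <- sprintf("g%04d", seq_len(n))
  sample_ids <- sprintf("s%03d", seq_len(m))
  dimnames(out$S) <- list(feature_ids, paste0("src", seq_len(k)))
  dimnames(out$M) <- list(paste0("src", seq_len(k)), sample_ids)
  X <- out$S %*% out$M + out$E
  dimnames(out$E) <- dimnames(X)
  structure(list(X = omics_matrix(X), S_true = out$S, M_true = out$M,
                 noise = out$E, source_model = source_model,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 batch_labels = NULL, planted_sets = NULL, survival = NULL),
            class = "synthetic_truth")
}

# Standard Laplace(0, 1/sqrt(2)) variates via inverse CDF: unit variance.
rlaplace <- function(n) {
  u <- stats::runif(n) - 0.5
  -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
}

draw_mixing <- function(k, m, max_condition) {
  for (i in 1:100) {
    M <- matrix(stats::rnorm(k * m), k, m)
    if (k == 1L || kappa(M, exact = TRUE) <= max_condition) return(M)
  }
  stop("failed to draw a well-conditioned mixing matrix", call. = FALSE)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d x %d, %d source(s), model '%s'%s%s%s\n",
              nrow(x$X), ncol(x$X), ncol(x$S_true), x$source_model,
              if (!is.null(x$batch_labels)) ", batch effect" else "",
              if (!is.null(x$survival)) ", survival" else "",
              if (!is.null(x$planted_sets)) ", planted sets" else ""))
  invisible(x)
}

#' Inject a known batch effect into a synthetic mixture
#'
#' Appends one honest extra rank-1 term to the data: a heavy-tailed
#' (Laplace) feature-shift vector (sd `shift_sd`) times a batch-indicator
#' weight row (batch b gets a fixed centered offset, scaled to unit variance
#' across samples, so `shift_sd` alone sets the effect size). The shift is
#' heavy-tailed for the same reason real batch effects are: a subset of
#' features reacts strongly to the platform while most barely move — which
#' also makes the batch term a bona fide independent component that the
#' decomposition can isolate. The injected term is recorded as an
#' additional true source, so the isolate-and-remove workflow can be
#' validated exactly: decompose with `k = k_true + 1`, find the component
#' whose weights associate with batch, zero it, reconstruct.
#'
#' @param truth A [simulate_mixture()] result.
#' @param n_batches Number of batches (>= 2), assigned round-robin.
#' @param shift_sd Standard deviation of the per-feature shift; 0 leaves `X`
#'   unchanged.
#' @param seed Integer seed.
#' @return The updated `synthetic_truth` with `batch_labels` set and the
#'   batch term appended to `S_true` / `M_true`.
#' @export
add_batch_effect <- function(truth, n_batches = 2L, shift_sd = 1, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n_batches <- as.integer(n_batches)
  if (n_batches < 2L) stop("need at least 2 batches", call. = FALSE)
  n <- nrow(truth$X); m <- ncol(truth$X)
  batch <- rep(paste0("batch", seq_len(n_batches)), length.out = m)
  drawn <- list(v = withr::with_seed(seed, shift_sd * rlaplace(n)))
  offsets <- seq_len(n_batches) - (n_batches + 1) / 2
  w <- offsets[match(batch, paste0("batch", seq_len(n_batches)))]
  if (stats::sd(w) > 0) w <- w / stats::sd(w)
  shift <- outer(drawn$v, w)
  X <- unclass(truth$X) + shift
  out <- truth
  out$X <- omics_matrix(X)
  out$batch_labels <- stats::setNames(batch, colnames(truth$X))
  if (shift_sd > 0 && stats::sd(drawn$v) > 0) {
    # store as a standardized source column and matching weight row
    s_new <- (drawn$v - mean(drawn$v)) / stats::sd(drawn$v)
    m_new <- w * stats::sd(drawn$v)      # plus mean(v)*w absorbed into noise-free offset
    out$S_true <- cbind(truth$S_true, batch = s_new)
    out$M_true <- rbind(truth$M_true, batch = m_new)
    out$noise <- out$noise + outer(rep(mean(drawn$v), n), w)
  }
  out
}

#' Attach survival outcomes driven by one component's weights
#'
#' Event times are exponential with per-sample rate
#' `lambda_i = lambda0 * exp(beta * M_true[driving_component, i])`;
#' censoring times are uniform on `(0, c_max)` with `c_max` tuned so the
#' realized censoring fraction is within 5 points of `censor_rate`.
#'
#' @param truth A [simulate_mixture()] result.
#' @param driving_component Index of the true source whose weights drive the
#'   hazard.
#' @param beta Log-hazard coefficient.
#' @param censor_rate Target censoring fraction in \[0, 0.9\]; 0 disables
#'   censoring.
#' @param lambda0 Baseline hazard rate. Default 0.1.
#' @param seed Integer seed.
#' @return The updated `synthetic_truth` with `survival = list(time, event,
#'   beta, driving_component)`.
#' @export
simulate_survival <- function(truth, driving_component, beta = 1,
                              censor_rate = 0.2, lambda0 = 0.1, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  kk <- nrow(truth$M_true)
  if (driving_component < 1L || driving_component > kk) {
    stop("driving_component must lie in 1..", kk, call. = FALSE)
  }
  if (censor_rate < 0 || censor_rate > 0.9) {
    stop("censor_rate must lie in [0, 0.9]", call. = FALSE)
  }
  w <- truth$M_true[driving_component, ]
  m <- length(w)
  drawn <- withr::with_seed(seed, {
    rate <- lambda0 * exp(beta * w)
    t_event <- stats::rexp(m, rate = rate)
    u <- stats::runif(m)
    list(t_event = t_event, u = u)
  })
  if (censor_rate == 0) {
    time <- drawn$t_event
    event <- rep(1L, m)
  } else {
    censor_frac <- function(cmax) mean(drawn$u * cmax < drawn$t_event)
    lo <- 1e-6; hi <- max(drawn$t_event) * 100
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (censor_frac(mid) > censor_rate) lo <- mid else hi <- mid
    }
    cens <- drawn$u * ((lo + hi) / 2)
    event <- as.integer(drawn$t_event <= cens)
    time <- pmin(drawn$t_event, cens)
  }
  out <- truth
  out$survival <- list(time = stats::setNames(time, colnames(truth$X)),
                       event = stats::setNames(event, colnames(truth$X)),
                       beta = beta, driving_component = as.integer(driving_component))
  out
}

#' Plant a gene set in a component's tail (plus a random decoy)
#'
#' Records a named set made of the `set_size` strongest features of the
#' chosen tail of a true source, along with a size-matched random decoy set
#' drawn from the remaining features. Over-representation analysis should
#' rank the planted set first for that component and direction, and leave
#' the decoy unremarkable.
#'
#' @param truth A [simulate_mixture()] result.
#' @param component True-source index whose tail is planted.
#' @param direction `"positive"` or `"negative"`.
#' @param set_size Number of tail features to take.
#' @param seed Integer seed (decoy draw).
#' @return The updated `synthetic_truth`; `planted_sets` gains entries
#'   `planted_ICx_<direction>` and `decoy_ICx_<direction>`.
#' @export
plant_gene_sets <- function(truth, component, direction = c("positive", "negative"),
                            set_size = 20L, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  direction <- match.arg(direction)
  s <- truth$S_true[, component]
  ord <- if (direction == "positive") order(s, decreasing = TRUE) else order(s)
  tail_vals <- if (direction == "positive") s[ord] else -s[ord]
  n_tail <- sum(tail_vals > 2)             # features clearly in the tail (|z| > 2)
  if (set_size > n_tail) {
    stop("component ", component, " has only ", n_tail,
         " usable ", direction, " tail features (need ", set_size, ")", call. = FALSE)
  }
  members <- rownames(truth$S_true)[ord[seq_len(set_size)]]
  decoy <- withr::with_seed(seed,
    sample(setdiff(rownames(truth$S_true), members), set_size))
  sets <- truth$planted_sets %||% list()
  tag <- paste0("IC", component, "_", direction)
  sets[[paste0("planted_", tag)]] <- members
  sets[[paste0("decoy_", tag)]] <- decoy
  out <- truth
  out$planted_sets <- sets
  out
}

#' Convert planted sets to a gene-set collection
#'
#' @param truth A `synthetic_truth` with `planted_sets`.
#' @param extra_random Number of additional random background sets to add.
#' @param set_size Size of each background set.
#' @param seed Integer seed for the background sets.
#' @return A `gene_set_collection` whose universe is the mixture's features.
#' @export
planted_collection <- function(truth, extra_random = 20L, set_size = 20L, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (is.null(truth$planted_sets)) stop("no planted sets; call plant_gene_sets()", call. = FALSE)
  universe <- rownames(truth$S_true)
  sets <- lapply(truth$planted_sets, function(mem) {
    list(description = "planted", members = mem)
  })
  if (extra_random > 0L) {
    bg <- withr::with_seed(seed, lapply(seq_len(extra_random), function(i)
      list(description = "background", members = sample(universe, set_size))))
    names(bg) <- sprintf("random_%02d", seq_len(extra_random))
    sets <- c(sets, bg)
  }
  structure(list(sets = sets, universe = universe), class = "gene_set_collection")
}

#' Annotation table of a synthetic truth
#'
#' Collects batch labels and survival outcomes into a [sample_annotation()]
#' for the clinical module.
#'
#' @param truth A `synthetic_truth`.
#' @return A `sample_annotation`.
#' @export
truth_annotation <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  df <- data.frame(sample = colnames(truth$X), stringsAsFactors = FALSE)
  if (!is.null(truth$batch_labels)) df$batch <- unname(truth$batch_labels)
  tc <- ec <- NULL
  if (!is.null(truth$survival)) {
    df$time <- unname(truth$survival$time)
    df$event <- unname(truth$survival$event)
    tc <- "time"; ec <- "event"
  }
  sample_annotation(df, id_column = "sample", time_column = tc, event_column = ec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
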