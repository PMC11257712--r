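# Shared fixture builders. Everything is generated in code; no stored data.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small labelled matrix with reproducible integer-ish values.
tiny_matrix <- function(n = 3, m = 4, seed = 42) {
  withr::with_seed(seed, {
    v <- matrix(sample(1:50, n * m, replace = TRUE), n, m)
  })
  dimnames(v) <- list(paste0("g", seq_len(n)), paste0("s", seq_len(m)))
  storage.mode(v) <- "double"
  v
}

write_matrix_file <- function(values, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  df <- data.frame(feature_id = rownames(values), values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_gmt_file <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".gmt", .local_envir = env)
  writeLines(lines, path)
  path
}

# Exhaustive-permutation assignment oracle: maximize total |r| over all k!
# permutations (k <= 7).
brute_force_assignment <- function(absR) {
  k <- nrow(absR)
  perms <- all_permutations(k)
  totals <- vapply(perms, function(p) sum(absR[cbind(seq_len(k), p)]), numeric(1))
  list(best_total = max(totals), best_perm = perms[[which.max(totals)]])
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- vector("list", factorial(k))
  i <- 0L
  for (p in sub) {
    for (pos in 0:(k - 1L)) {
      i <- i + 1L
      out[[i]] <- append(p, k, after = pos)
    }
  }
  out
}

# Upper-tail hypergeometric by direct enumeration of the probability mass,
# independent of phyper: P(X >= ov) with universe N, set K, selection s.
enum_hyper_upper <- function(ov, N, K, s) {
  js <- max(0L, s - (N - K)):min(K, s)
  mass <- choose(K, js) * choose(N - K, s - js) / choose(N, s)
  sum(mass[js >= ov])
}

# Exact Cox partial log-likelihood for untied right-censored data.
cox_partial_loglik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- time >= time[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

# Between-group fraction of total sum of squares of a reconstruction.
batch_variance_fraction <- function(X, groups) {
  X <- unclass(X)
  gm <- rowMeans(X)
  ssb <- 0
  for (lev in unique(groups)) {
    idx <- groups == lev
    ssb <- ssb + sum(idx) * sum((rowMeans(X[, idx, drop = FALSE]) - gm)^2)
  }
  ssb / sum((X - gm)^2)
}

# Two-modality pair with one shared weight row (the planted cross-omics
# signal); returns both truths.
shared_signal_pair <- function(n = 300, m = 60, k = 3, noise_sd = 0.1, seed = 1) {
  a <- simulate_mixture(n = n, m = m, k = k, noise_sd = noise_sd, seed = seed)
  b <- simulate_mixture(n = n, m = m, k = k, noise_sd = noise_sd, seed = seed + 50000)
  b$M_true[1, ] <- a$M_true[1, ]
  X <- b$S_true %*% b$M_true + b$noise
  b$X <- omics_matrix(X)
  list(a = a, b = b)
}
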