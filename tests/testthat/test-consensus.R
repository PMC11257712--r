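make_run <- function(S, M = NULL) {
  if (is.null(M)) M <- matrix(0, ncol(S), 5,
                              dimnames = list(colnames(S), paste0("s", 1:5)))
  structure(list(S = S, M = M, converged = TRUE), class = "ica_run")
}

test_that("match_components undoes a constructed permutation and sign flip", {
  set.seed(1)
  S <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(paste0("g", 1:50), paste0("IC", 1:3)))
  perm <- c(2, 3, 1)                       # other column j = reference column perm[j]
  S_other <- S[, perm]
  S_other[, 1] <- -S_other[, 1]            # negate other's first column (= ref 2)
  al <- match_components(make_run(S), make_run(S_other))
  # reference component j must map to the other column holding it
  expect_identical(al$permutation, order(perm))
  expect_equal(al$signs, c(1, -1, 1))
  expect_equal(al$match_correlations, rep(1, 3), tolerance = 1e-12)

  id <- match_components(make_run(S), make_run(S))
  expect_identical(id$permutation, 1:3)
  expect_equal(id$signs, rep(1, 3))

  expect_error(match_components(make_run(S), make_run(S[, 1:2])), "counts differ")
})

test_that("assignment equals the exhaustive-permutation optimum (k <= 6)", {
  set.seed(7)
  for (trial in 1:25) {
    k <- sample(2:6, 1)
    S_a <- matrix(rnorm(40 * k), 40, k)
    S_b <- matrix(rnorm(40 * k), 40, k)
    rownames(S_a) <- rownames(S_b) <- paste0("g", 1:40)
    al <- match_components(make_run(S_a), make_run(S_b))
    absR <- abs(cor(S_a, S_b))
    oracle <- brute_force_assignment(absR)
    expect_equal(sum(al$match_correlations), oracle$best_total, tolerance = 1e-12)
  }
})

test_that("consensus of runs at the same optimum equals a single run up to alignment", {
  truth <- simulate_mixture(n = 150, m = 20, k = 2, noise_sd = 0, seed = 6)
  dec <- run_consensus(truth$X, ica_options(k = 2, tol = 1e-13, max_iter = 10000),
                       n_runs = 2, base_seed = 40)
  wh <- whiten(scale_matrix(truth$X), 2)
  single <- fastica_run(wh, ica_options(k = 2, tol = 1e-13, max_iter = 10000), seed = 41)
  al <- match_components(dec, single)
  aligned <- cicada:::apply_alignment(single, al)
  expect_lt(max(abs(dec$S - aligned$S)), 1e-6)
  expect_lt(max(abs(dec$M - aligned$M)), 1e-6)
})

test_that("consensus recovers planted sources with high stability", {
  truth <- simulate_mixture(n = 600, m = 40, k = 4, noise_sd = 0.1, seed = 10)
  dec <- run_consensus(truth$X, ica_options(k = 4), n_runs = 12, base_seed = 3)
  R <- abs(cor(dec$S, truth$S_true))
  al <- brute_force_assignment(R)
  expect_true(all(R[cbind(seq_len(4), al$best_perm)] >= 0.9))
  expect_true(all(dec$stability >= 0 & dec$stability <= 1))
  expect_true(all(dec$stability >= 0.9))
  # sign convention: strongest source entry of every component is positive
  peaks <- vapply(1:4, function(j) dec$S[which.max(abs(dec$S[, j])), j], numeric(1))
  expect_true(all(peaks > 0))
})

test_that("noise-free identifiable mixtures give stabilities >= 0.99", {
  truth <- simulate_mixture(n = 300, m = 24, k = 3, noise_sd = 0, seed = 12)
  dec <- run_consensus(truth$X, ica_options(k = 3), n_runs = 8, base_seed = 5)
  expect_true(all(dec$stability >= 0.99))
})

test_that("the consensus is a pure function of (X, opts, n_runs, base_seed)", {
  truth <- simulate_mixture(n = 200, m = 21, k = 3, noise_sd = 0.1, seed = 13)
  d1 <- run_consensus(truth$X, ica_options(k = 3), n_runs = 6, base_seed = 7, n_workers = 1)
  d2 <- run_consensus(truth$X, ica_options(k = 3), n_runs = 6, base_seed = 7, n_workers = 2)
  expect_identical(d1$S, d2$S)
  expect_identical(d1$M, d2$M)
  expect_identical(d1$stability, d2$stability)
})

test_that("component-count guidance is floor(m / 3)", {
  expect_identical(suggest_max_components(300), 100L)
  expect_identical(suggest_max_components(3), 1L)
  expect_identical(suggest_max_components(10), 3L)
  expect_error(suggest_max_components(2), "at least 3")
})

test_that("variance_explained matches direct norm computations", {
  # exact rank-1 data: single component explains everything
  set.seed(3)
  s <- matrix(rnorm(40), 40, 1, dimnames = list(paste0("g", 1:40), NULL))
  w <- matrix(rnorm(10), 1, 10, dimnames = list(NULL, paste0("s", 1:10)))
  dec1 <- consensus_decomposition(s, w)
  X1 <- omics_matrix(s %*% w, scaled = TRUE)
  ve1 <- variance_explained(dec1, X1)
  expect_equal(ve1$variance_explained, 1, tolerance = 1e-8)

  # two orthogonal equal-norm components split 50/50
  S <- cbind(c(rep(1, 20), rep(-1, 20)), c(rep(1, 10), rep(-1, 10), rep(1, 10), rep(-1, 10)))
  rownames(S) <- paste0("g", 1:40)
  M <- rbind(c(1, -1, 1, -1, 1, -1), c(1, 1, -1, -1, 1, 1))
  colnames(M) <- paste0("s", 1:6)
  stopifnot(sum(S[, 1] * S[, 2]) == 0, sum(M[1, ] * M[2, ]) == 0)
  dec2 <- consensus_decomposition(S, M)
  X2 <- omics_matrix(S %*% M, scaled = TRUE)
  ve2 <- variance_explained(dec2, X2)
  expect_equal(sort(ve2$variance_explained), c(0.5, 0.5), tolerance = 1e-6)

  # noisy data leaves a residual
  truth <- simulate_mixture(n = 200, m = 20, k = 2, noise_sd = 1, seed = 4)
  dec3 <- run_consensus(truth$X, ica_options(k = 2), n_runs = 4, base_seed = 2)
  ve3 <- variance_explained(dec3, truth$X)
  expect_lt(sum(ve3$variance_explained), 1)
})

test_that("remove_components zeroes weight rows before reconstruction", {
  truth <- simulate_mixture(n = 100, m = 15, k = 3, noise_sd = 0.1, seed = 5)
  dec <- run_consensus(truth$X, ica_options(k = 3), n_runs = 4, base_seed = 9)
  full <- remove_components(dec, integer())
  expect_equal(unclass(full)[, ], dec$S %*% dec$M, ignore_attr = TRUE)
  none <- remove_components(dec, 1:3)
  expect_true(all(none == 0))
  partial <- remove_components(dec, "IC2")
  manual <- dec$S[, -2] %*% dec$M[-2, ]
  expect_lt(max(abs(unclass(partial) - manual)), 1e-12)
  expect_error(remove_components(dec, 5), "1..3")
  expect_error(remove_components(dec, "IC9"), "unknown component")
})
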