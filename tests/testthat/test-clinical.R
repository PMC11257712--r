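weights_decomposition <- function(M) {
  S <- matrix(rnorm(20 * nrow(M)), 20, nrow(M),
              dimnames = list(paste0("g", 1:20), NULL))
  consensus_decomposition(S, M)
}

annotation_of <- function(ids, ...) {
  df <- data.frame(sample = ids, ...)
  tc <- if ("time" %in% names(df)) "time" else NULL
  ec <- if ("event" %in% names(df)) "event" else NULL
  sample_annotation(df, id_column = "sample", time_column = tc, event_column = ec)
}

test_that("ANOVA F and p match a hand sum-of-squares oracle within 1e-10", {
  set.seed(51)
  m <- 18
  ids <- paste0("s", 1:m)
  g <- rep(c("a", "b", "c"), each = 6)
  M <- matrix(rnorm(4 * m), 4, m, dimnames = list(NULL, ids))
  dec <- weights_decomposition(M)
  got <- anova_weights(dec, annotation_of(ids, group = g), "group")
  for (j in 1:4) {
    w <- M[j, ]
    grand <- mean(w)
    ssb <- sum(tapply(w, g, function(v) length(v) * (mean(v) - grand)^2))
    ssw <- sum((w - ave(w, g))^2)
    f_oracle <- (ssb / 2) / (ssw / (m - 3))
    p_oracle <- pf(f_oracle, 2, m - 3, lower.tail = FALSE)
    expect_equal(got$statistic[j], f_oracle, tolerance = 1e-10)
    expect_equal(got$p_value[j], p_oracle, tolerance = 1e-10)
  }
  expect_equal(got$q_value, p.adjust(got$p_value, "BH"))
})

test_that("degenerate ANOVA cases follow the stated contracts", {
  ids <- paste0("s", 1:6)
  g <- rep(c("a", "b"), each = 3)
  # identical groups: zero between-group variance
  M <- rbind(c(1, 2, 3, 1, 2, 3))
  colnames(M) <- ids
  dec <- weights_decomposition(M)
  got <- anova_weights(dec, annotation_of(ids, group = g), "group")
  expect_identical(got$statistic, 0)
  expect_identical(got$p_value, 1)

  # perfect separation: zero within-group variance
  M2 <- rbind(c(0, 0, 0, 1, 1, 1))
  colnames(M2) <- ids
  got2 <- anova_weights(weights_decomposition(M2), annotation_of(ids, group = g), "group")
  expect_true(got2$degenerate)
  expect_identical(got2$p_value, .Machine$double.xmin)
  expect_identical(got2$statistic, Inf)
})

test_that("ANOVA is invariant to shifting and scaling the weights", {
  set.seed(52)
  ids <- paste0("s", 1:15)
  g <- rep(c("a", "b", "c"), each = 5)
  w <- rnorm(15)
  M0 <- rbind(w)
  colnames(M0) <- ids
  base <- anova_weights(weights_decomposition(M0), annotation_of(ids, group = g), "group")
  for (trans in list(w + 100, w * -3.7, (w + 5) * 0.01)) {
    Mt <- rbind(trans); colnames(Mt) <- ids
    got <- anova_weights(weights_decomposition(Mt), annotation_of(ids, group = g), "group")
    expect_equal(got$statistic, base$statistic, tolerance = 1e-9)
    expect_equal(got$p_value, base$p_value, tolerance = 1e-9)
  }
})

test_that("sparse factor levels are dropped with a warning; too few levels error", {
  ids <- paste0("s", 1:7)
  g <- c("a", "a", "a", "b", "b", "b", "c")   # level c has 1 sample
  M <- matrix(rnorm(2 * 7), 2, 7, dimnames = list(NULL, ids))
  dec <- weights_decomposition(M)
  expect_warning(got <- anova_weights(dec, annotation_of(ids, group = g), "group"),
                 "dropped: c")
  expect_identical(unique(got$n_groups), 2L)

  g2 <- c(rep("a", 6), "b")
  expect_error(suppressWarnings(
    anova_weights(dec, annotation_of(ids, group = g2), "group")),
    "fewer than 2 usable levels")
})

test_that("Cox beta matches a grid-search partial-likelihood oracle within 1e-4", {
  ids <- paste0("s", 1:8)
  time <- c(2, 5, 1, 7, 9, 3, 8, 6)
  event <- c(1, 1, 1, 1, 1, 1, 1, 1)
  x <- 1:8
  M <- rbind(x); colnames(M) <- ids
  dec <- weights_decomposition(M)
  got <- cox_weights(dec, annotation_of(ids, time = time, event = event))
  oracle <- optimize(function(b) -cox_partial_loglik(b, time, event, x),
                     interval = c(-5, 5), tol = 1e-10)$minimum
  expect_equal(got$beta, oracle, tolerance = 1e-4)
  expect_equal(got$hr, exp(got$beta), tolerance = 1e-12)
})

test_that("a constant covariate carries no survival information", {
  ids <- paste0("s", 1:6)
  M <- rbind(rep(2.5, 6)); colnames(M) <- ids
  dec <- weights_decomposition(M)
  got <- cox_weights(dec, annotation_of(ids, time = c(1, 4, 2, 6, 3, 5),
                                        event = c(1, 0, 1, 1, 0, 1)))
  expect_identical(got$beta, 0)
  expect_identical(got$hr, 1)
  expect_identical(got$p_value, 1)
  expect_error(cox_weights(dec, annotation_of(ids, time = 1:6, event = rep(0, 6))),
               "no events")
})

test_that("Cox beta shifts and scales correctly with the covariate", {
  set.seed(53)
  ids <- paste0("s", 1:40)
  truth <- simulate_mixture(n = 50, m = 40, k = 2, noise_sd = 0.1, seed = 54)
  truth <- simulate_survival(truth, 1, beta = 0.8, censor_rate = 0.2, seed = 55)
  w <- truth$M_true[1, ]
  fit_beta <- function(wvec) {
    M <- rbind(wvec); colnames(M) <- colnames(truth$X)
    cox_weights(weights_decomposition(M), truth_annotation(truth))$beta
  }
  b0 <- fit_beta(w)
  expect_equal(fit_beta(w + 10), b0, tolerance = 1e-6)
  expect_equal(fit_beta(w * 4), b0 / 4, tolerance = 1e-6)
})

test_that("the driving component attains the smallest Cox p-value", {
  truth <- simulate_mixture(n = 400, m = 80, k = 4, noise_sd = 0.1, seed = 61)
  truth <- simulate_survival(truth, driving_component = 2, beta = 1,
                             censor_rate = 0.2, seed = 62)
  dec <- run_consensus(truth$X, ica_options(k = 4), n_runs = 8, base_seed = 63)
  got <- cox_weights(dec, truth_annotation(truth))
  best <- got$component[which.min(got$p_value)]
  # identify which estimated component carries true source 2
  R <- abs(cor(dec$M[, colnames(truth$X)] |> t(), truth$M_true[2, ]))
  expect_identical(best, rownames(dec$M)[which.max(R)])
})
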