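spiked_decomposition <- function(n = 1000, spike = 10, seed = 21) {
  set.seed(seed)
  s <- c(spike, rnorm(n - 1, sd = 0.1))
  S <- cbind(s, rnorm(n))
  rownames(S) <- paste0("g", seq_len(n))
  M <- matrix(rnorm(2 * 6), 2, 6, dimnames = list(NULL, paste0("s", 1:6)))
  consensus_decomposition(S, M)
}

test_that("top_features finds a single planted spike by direct z computation", {
  dec <- spiked_decomposition()
  tf <- top_features(dec, 1, z_threshold = 3)
  pos <- tf[tf$direction == "positive", ]
  expect_identical(pos$feature, "g1")
  s <- dec$S[, 1]
  expect_equal(pos$z, (s[["g1"]] - mean(s)) / sd(s), tolerance = 1e-12)
  expect_true(all(abs(tf$z) >= 3))
  expect_error(top_features(dec, 1, z_threshold = -1), "positive")
})

test_that("top_features respects symmetry and empty-result contracts", {
  vals <- c(seq(0.5, 5, by = 0.5), -seq(0.5, 5, by = 0.5), rep(0, 30))
  S <- cbind(vals, rev(vals))
  rownames(S) <- paste0("g", seq_along(vals))
  M <- matrix(rnorm(2 * 5), 2, 5, dimnames = list(NULL, paste0("s", 1:5)))
  dec <- consensus_decomposition(S, M)
  tf <- top_features(dec, 1, z_threshold = 1.5)
  expect_identical(sum(tf$direction == "positive"), sum(tf$direction == "negative"))
  expect_identical(intersect(tf$feature[tf$direction == "positive"],
                             tf$feature[tf$direction == "negative"]), character(0))

  tf_empty <- top_features(dec, 1, z_threshold = 50)
  expect_identical(nrow(tf_empty), 0L)
})

test_that("hypergeometric p matches exhaustive enumeration for all N <= 12", {
  for (N in 4:12) {
    universe <- paste0("g", seq_len(N))
    for (K in 1:(N - 1)) {
      for (s in 1:(N - 1)) {
        members <- universe[seq_len(K)]
        selected <- universe[seq_len(s)]
        gsc <- structure(list(sets = list(SET = list(description = "", members = members)),
                              universe = universe),
                         class = "gene_set_collection")
        got <- overrepresentation(selected, gsc)
        ov <- length(intersect(selected, members))
        expect_equal(got$p_value, enum_hyper_upper(ov, N, K, s), tolerance = 1e-12)
      }
    }
  }
})

test_that("the fully-overlapping N=10, K=5, s=5 selection gives p = 1/252", {
  universe <- paste0("g", 1:10)
  gsc <- structure(list(sets = list(SET = list(description = "", members = universe[1:5])),
                        universe = universe),
                   class = "gene_set_collection")
  got <- overrepresentation(universe[1:5], gsc)
  expect_equal(got$p_value, 1 / choose(10, 5), tolerance = 1e-12)
  expect_identical(got$overlap, 5L)

  # zero overlap is never significant: P(X >= 0) = 1
  got0 <- overrepresentation(universe[6:10], gsc)
  expect_equal(got0$p_value, 1)
})

test_that("q-values follow the Benjamini-Hochberg step-up transform", {
  # two sets engineered to give distinct p-values; check q by the hand rule
  universe <- paste0("g", 1:20)
  gsc <- structure(list(sets = list(
    A = list(description = "", members = universe[1:5]),
    B = list(description = "", members = universe[c(1:3, 11:12)])),
    universe = universe), class = "gene_set_collection")
  got <- overrepresentation(universe[1:5], gsc)
  p <- sort(got$p_value)
  # hand rule for 2 hypotheses: q(1) = min(2*p1, p2), q(2) = p2
  expect_equal(sort(got$q_value), sort(c(min(2 * p[1], p[2]), p[2])), tolerance = 1e-12)
  # single-set family: q equals p
  gsc1 <- structure(list(sets = gsc$sets["A"], universe = universe),
                    class = "gene_set_collection")
  one <- overrepresentation(universe[1:5], gsc1)
  expect_identical(one$q_value, one$p_value)
})

test_that("annotate_component ranks a planted set first in its direction only", {
  truth <- simulate_mixture(n = 800, m = 30, k = 3, source_model = "laplace",
                            noise_sd = 0.05, seed = 31)
  truth <- plant_gene_sets(truth, component = 2, direction = "positive",
                           set_size = 15, seed = 32)
  gsc <- planted_collection(truth, extra_random = 15, set_size = 15, seed = 33)
  dec <- consensus_decomposition(truth$S_true, truth$M_true)
  res <- annotate_component(dec, 2, gsc, z_threshold = 2)
  pos <- res[res$direction == "positive", ]
  expect_identical(pos$set[1], "planted_IC2_positive")
  neg <- res[res$direction == "negative", ]
  if (nrow(neg)) expect_false(identical(neg$set[1], "planted_IC2_positive"))
})

test_that("one-sided and empty directions are handled without error", {
  set.seed(41)
  s <- c(rnorm(500, sd = 0.05), rep(-8, 3))   # only negative outliers
  S <- cbind(s, rnorm(503, sd = 1))
  rownames(S) <- paste0("g", seq_along(s))
  M <- matrix(rnorm(2 * 5), 2, 5, dimnames = list(NULL, paste0("s", 1:5)))
  dec <- consensus_decomposition(S, M)
  gsc <- structure(list(sets = list(TAIL = list(description = "", members = paste0("g", 501:503))),
                        universe = rownames(S)), class = "gene_set_collection")
  expect_message(res <- annotate_component(dec, 1, gsc, z_threshold = 4),
                 "no positive features")
  expect_identical(nrow(res[res$direction == "positive", ]), 0L)
  expect_gt(nrow(res[res$direction == "negative", ]), 0)
  expect_error(overrepresentation(character(), gsc), "empty selection")
})

test_that("a planted tail set attains the minimum p across seeds", {
  hits <- 0L
  n_seeds <- 20L
  for (seed in seq_len(n_seeds)) {
    truth <- simulate_mixture(n = 1000, m = 24, k = 2, noise_sd = 0.05,
                              seed = 100 + seed)
    truth <- plant_gene_sets(truth, component = 1, direction = "positive",
                             set_size = 10, seed = 200 + seed)
    gsc <- planted_collection(truth, extra_random = 10, set_size = 10,
                              seed = 300 + seed)
    dec <- consensus_decomposition(truth$S_true, truth$M_true)
    res <- annotate_component(dec, 1, gsc, z_threshold = 2)
    pos <- res[res$direction == "positive", ]
    if (nrow(pos) && pos$set[1] == "planted_IC1_positive") hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})
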