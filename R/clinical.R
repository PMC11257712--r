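#' One-way ANOVA of component weights across a factor
#'
#' Tests, for every component, whether its weight-matrix row differs across
#' the levels of one experimental factor: classical fixed-effects one-way
#' ANOVA, `F` = between-group mean square / within-group mean square with
#' `(g - 1, m - g)` degrees of freedom. Levels with fewer than 2 samples are
#' dropped with a warning; at least 2 usable levels are required. P-values
#' are Benjamini-Hochberg adjusted across the k components (one family per
#' factor).
#'
#' Perfect separation (zero within-group variance with nonzero between-group
#' variance) makes F unbounded; such components are reported with the
#' smallest representable positive p-value and `degenerate = TRUE`.
#'
#' @param dec A `consensus_ica` object.
#' @param ann A [sample_annotation()] covering the decomposition's samples.
#' @param factor Name of the factor column to test.
#' @return A tibble with one row per component: `component`, `factor`,
#'   `n_groups`, `statistic` (F), `p_value`, `q_value`, `degenerate`.
#' @export
anova_weights <- function(dec, ann, factor) {
  stopifnot(inherits(dec, "consensus_ica"), inherits(ann, "sample_annotation"))
  if (!factor %in% colnames(ann$factors)) {
    stop("factor '", factor, "' not found in annotation", call. = FALSE)
  }
  ann <- align_annotation(ann, dec$sample_ids)
  labels <- ann$factors[[factor]]
  counts <- table(labels)
  small <- names(counts)[counts < 2L]
  keep <- !labels %in% small
  if (length(small)) {
    warning("factor '", factor, "' level(s) with < 2 samples dropped: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  labels <- labels[keep]
  g <- length(unique(labels))
  if (g < 2L) stop("factor '", factor, "' has fewer than 2 usable levels", call. = FALSE)
  rows <- purrr::map_dfr(seq_len(dec$k), function(j) {
    w <- dec$M[j, keep]
    ssq <- anova_ss(w, labels)
    if (ssq$ssw == 0 && ssq$ssb > 0) {
      return(tibble::tibble(component = rownames(dec$M)[j], factor = factor,
                            n_groups = g, statistic = Inf,
                            p_value = .Machine$double.xmin, degenerate = TRUE))
    }
    ht <- stats::oneway.test(w ~ labels, var.equal = TRUE)
    f <- unname(ht$statistic)
    p <- unname(ht$p.value)
    if (ssq$ssb == 0) { f <- 0; p <- 1 }
    tibble::tibble(component = rownames(dec$M)[j], factor = factor,
                   n_groups = g, statistic = f, p_value = p,
                   degenerate = FALSE)
  })
  rows$q_value <- stats::p.adjust(rows$p_value, method = "BH")
  dplyr::relocate(rows, "q_value", .after = "p_value")
}

anova_ss <- function(x, g) {
  gm <- mean(x)
  means <- tapply(x, g, mean)
  ns <- tapply(x, g, length)
  list(ssb = sum(ns * (means - gm)^2),
       ssw = sum((x - means[g])^2))
}

#' Univariate Cox regression of survival on component weights
#'
#' Fits, for every component, a proportional-hazards model with the
#' component's weight row as the single covariate
#' (`survival::coxph`, Efron tie handling). Reports the log-hazard
#' coefficient, hazard ratio, standard error (from the observed
#' information), Wald z and p, with Benjamini-Hochberg adjustment across the
#' k components. A constant covariate carries no information and is reported
#' as `beta = 0, hr = 1, p = 1`; monotone-likelihood divergence is caught and
#' flagged rather than raised.
#'
#' @param dec A `consensus_ica` object.
#' @param ann A [sample_annotation()] with survival data (`event = 1` means
#'   the event occurred; right censoring only) and at least one event.
#' @return A tibble with one row per component: `component`, `beta`, `hr`,
#'   `se`, `z`, `p_value`, `q_value`, `n`, `n_events`, `diverged`.
#' @export
cox_weights <- function(dec, ann) {
  stopifnot(inherits(dec, "consensus_ica"), inherits(ann, "sample_annotation"))
  if (is.null(ann$survival_time)) {
    stop("annotation has no survival data", call. = FALSE)
  }
  ann <- align_annotation(ann, dec$sample_ids)
  time <- ann$survival_time
  event <- ann$survival_event
  if (sum(event) == 0L) stop("no events observed; Cox regression undefined", call. = FALSE)
  surv <- survival::Surv(time, event)
  rows <- purrr::map_dfr(seq_len(dec$k), function(j) {
    w <- dec$M[j, ]
    base <- tibble::tibble(component = rownames(dec$M)[j],
                           beta = 0, hr = 1, se = NA_real_, z = NA_real_,
                           p_value = 1, n = length(w),
                           n_events = sum(event), diverged = FALSE)
    if (stats::sd(w) == 0) return(base)
    diverged <- FALSE
    fit <- withCallingHandlers(
      survival::coxph(surv ~ w, ties = "efron"),
      warning = function(wn) {
        if (grepl("infinite|converge|singular", conditionMessage(wn))) {
          diverged <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    sm <- summary(fit)$coefficients
    base$beta <- sm[1L, "coef"]
    base$hr <- sm[1L, "exp(coef)"]
    base$se <- sm[1L, "se(coef)"]
    base$z <- sm[1L, "z"]
    base$p_value <- sm[1L, "Pr(>|z|)"]
    base$diverged <- diverged
    base
  })
  rows$q_value <- stats::p.adjust(rows$p_value, method = "BH")
  dplyr::relocate(rows, "q_value", .after = "p_value")
}
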