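#' Top contributing features of a component, by direction
#'
#' A component's source column is z-scored (its mean subtracted, divided by
#' its standard deviation); features with `z >= z_threshold` form the
#' positive tail (sorted by decreasing z) and features with
#' `z <= -z_threshold` the negative tail (sorted by increasing z). The two
#' directions are annotated separately downstream because usually only one
#' carries the biological signal.
#'
#' @param dec A `consensus_ica` object.
#' @param component Component index (or name such as `"IC2"`).
#' @param z_threshold Positive |z| cutoff; default 3.
#' @return A tibble of class `top_features` with columns `component`,
#'   `feature`, `z`, `direction` (`"positive"`/`"negative"`); attribute
#'   `z_threshold` records the cutoff. Empty tibble (no error) when no
#'   feature passes.
#' @export
top_features <- function(dec, component, z_threshold = 3) {
  stopifnot(inherits(dec, "consensus_ica"))
  if (!is.numeric(z_threshold) || z_threshold <= 0) {
    stop("z_threshold must be positive", call. = FALSE)
  }
  j <- resolve_component(dec, component)
  s <- dec$S[, j]
  z <- (s - mean(s)) / stats::sd(s)
  pos <- sort(z[z >= z_threshold], decreasing = TRUE)
  neg <- sort(z[z <= -z_threshold], decreasing = FALSE)
  out <- tibble::tibble(
    component = colnames(dec$S)[j],
    feature = c(names(pos), names(neg)),
    z = c(unname(pos), unname(neg)),
    direction = rep(c("positive", "negative"), c(length(pos), length(neg))))
  attr(out, "z_threshold") <- z_threshold
  class(out) <- c("top_features", class(out))
  out
}

resolve_component <- function(dec, component) {
  if (is.character(component)) {
    j <- match(component, colnames(dec$S))
    if (is.na(j)) stop("unknown component '", component, "'", call. = FALSE)
    return(j)
  }
  j <- as.integer(component)
  if (is.na(j) || j < 1L || j > dec$k) {
    stop("component index must lie in 1..", dec$k, call. = FALSE)
  }
  j
}

#' Hypergeometric over-representation analysis of a feature selection
#'
#' For every gene set, tests whether the selected features overlap the set
#' more than expected by chance: the p-value is the upper-tail
#' hypergeometric probability `P(overlap >= observed)` with universe size N,
#' set size K and selection size s, followed by Benjamini-Hochberg adjustment
#' across all sets in the collection. Selected features outside the universe
#' are dropped (count reported via a message).
#'
#' @param selected Character vector of selected feature identifiers.
#' @param collection A [read_gmt()] gene-set collection.
#' @return A tibble with one row per set: `set`, `overlap`, `set_size`,
#'   `selection_size`, `universe_size`, `p_value`, `q_value`, sorted by
#'   ascending p (ties by set name).
#' @export
overrepresentation <- function(selected, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  selected <- unique(as.character(selected))
  if (!length(selected)) stop("empty selection: nothing to annotate", call. = FALSE)
  outside <- setdiff(selected, collection$universe)
  if (length(outside)) {
    message(length(outside), " selected feature(s) outside the universe dropped")
    selected <- setdiff(selected, outside)
  }
  if (!length(selected)) stop("no selected features remain inside the universe", call. = FALSE)
  N <- length(collection$universe)
  s <- length(selected)
  rows <- purrr::map_dfr(names(collection$sets), function(nm) {
    members <- collection$sets[[nm]]$members
    K <- length(members)
    ov <- length(intersect(selected, members))
    # P(X >= ov) for X ~ Hypergeometric(N, K, s)
    p <- stats::phyper(ov - 1L, K, N - K, s, lower.tail = FALSE)
    tibble::tibble(set = nm, overlap = ov, set_size = K,
                   selection_size = s, universe_size = N, p_value = p)
  })
  rows$q_value <- stats::p.adjust(rows$p_value, method = "BH")
  dplyr::arrange(rows, .data$p_value, .data$set)
}

#' Annotate one component by over-representation, per direction
#'
#' Extracts the top positive and top negative features of the component and
#' runs [overrepresentation()] independently for each direction. A direction
#' with no features past the threshold yields an empty result (with a note),
#' not an error.
#'
#' @inheritParams top_features
#' @param collection A [read_gmt()] gene-set collection.
#' @return A tibble combining both directions, with columns `component`,
#'   `direction` plus the [overrepresentation()] columns; zero rows for an
#'   empty direction.
#' @export
annotate_component <- function(dec, component, collection, z_threshold = 3) {
  tf <- top_features(dec, component, z_threshold)
  comp_id <- colnames(dec$S)[resolve_component(dec, component)]
  one_direction <- function(dir) {
    sel <- tf$feature[tf$direction == dir]
    sel <- intersect(sel, collection$universe)
    if (!length(sel)) {
      message("component ", comp_id, ": no ", dir,
              " features past |z| >= ", z_threshold)
      return(tibble::tibble(set = character(), overlap = integer(),
                            set_size = integer(), selection_size = integer(),
                            universe_size = integer(), p_value = numeric(),
                            q_value = numeric()))
    }
    overrepresentation(sel, collection)
  }
  dplyr::bind_rows(
    dplyr::mutate(one_direction("positive"), component = comp_id,
                  direction = "positive", .before = 1L),
    dplyr::mutate(one_direction("negative"), component = comp_id,
                  direction = "negative", .before = 1L))
}
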