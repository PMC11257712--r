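#' Correlate component weights across two decompositions
#'
#' Multi-omics linking: for decompositions of two modalities measured on
#' (partly) shared samples, computes the Pearson correlation between every
#' pair of weight rows, restricted to the shared samples (matched by
#' identifier, order-independent), with two-sided p-values from the t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param dec_a,dec_b `consensus_ica` objects sharing at least 3 sample ids.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A tibble with columns `component_a`, `component_b`, `r`,
#'   `p_value`, `n_shared`; attribute `r_matrix` holds the k_a x k_b
#'   correlation matrix.
#' @export
correlate_weights <- function(dec_a, dec_b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(dec_a, "consensus_ica"), inherits(dec_b, "consensus_ica"))
  shared <- intersect(dec_a$sample_ids, dec_b$sample_ids)
  if (length(shared) < 3L) {
    stop("need at least 3 shared samples, found ", length(shared), call. = FALSE)
  }
  A <- dec_a$M[, shared, drop = FALSE]
  B <- dec_b$M[, shared, drop = FALSE]
  R <- stats::cor(t(A), t(B), method = method)
  nobs <- length(shared)
  tstat <- R * sqrt((nobs - 2) / pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * stats::pt(abs(tstat), df = nobs - 2, lower.tail = FALSE)
  P[abs(R) >= 1] <- 0
  out <- tidyr::expand_grid(component_a = rownames(A), component_b = rownames(B)) |>
    dplyr::mutate(
      r = as.vector(t(R)),
      p_value = as.vector(t(P)),
      n_shared = nobs)
  attr(out, "r_matrix") <- R
  out
}

#' Build a graph of correlated components across modalities
#'
#' Takes the pairwise weight-correlation tables of two or more modalities and
#' connects components whose absolute correlation passes `r_threshold` and
#' whose Benjamini-Hochberg q-value (adjusted across all tested pairs in all
#' supplied tables) passes `q_threshold`. Clusters are the connected
#' components of the resulting undirected graph; nodes and clusters are
#' ordered deterministically (by modality name, then component), so the
#' result does not depend on the order in which pairs are supplied.
#'
#' @param correlations Named list of [correlate_weights()] tibbles; names
#'   are `"modA|modB"` pairs (any separator), or supply `modalities` — a list
#'   of 2-element character vectors naming each table's modalities.
#' @param modalities Optional list of length-2 character vectors, one per
#'   correlation table.
#' @param r_threshold Minimum |r| for an edge, in \[0, 1\]. Default 0.5.
#' @param q_threshold Maximum BH q for an edge, in \[0, 1\]. Default 0.05.
#' @return A list of class `component_graph`: `nodes` (tibble: `modality`,
#'   `component`, `cluster`), `edges` (tibble: `from_modality`,
#'   `from_component`, `to_modality`, `to_component`, `r`, `p_value`,
#'   `q_value`), and the `igraph` object in `$graph`.
#' @export
build_component_graph <- function(correlations, modalities = NULL,
                                  r_threshold = 0.5, q_threshold = 0.05) {
  if (r_threshold < 0 || r_threshold > 1 || q_threshold < 0 || q_threshold > 1) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  if (is.data.frame(correlations)) correlations <- list(correlations)
  if (is.null(modalities)) {
    if (is.null(names(correlations)) || any(!nzchar(names(correlations)))) {
      stop("supply `modalities` or name the correlation list 'modA|modB'", call. = FALSE)
    }
    modalities <- strsplit(names(correlations), "[|/_:-]")
    if (any(lengths(modalities) != 2L)) {
      stop("list names must encode exactly two modality names", call. = FALSE)
    }
  }
  all_pairs <- purrr::map2_dfr(correlations, modalities, function(tab, mods) {
    tibble::tibble(
      from_modality = mods[[1L]], from_component = tab$component_a,
      to_modality = mods[[2L]], to_component = tab$component_b,
      r = tab$r, p_value = tab$p_value)
  })
  mod_names <- sort(unique(c(all_pairs$from_modality, all_pairs$to_modality)))
  if (length(mod_names) < 2L) stop("need at least 2 modalities", call. = FALSE)
  all_pairs$q_value <- stats::p.adjust(all_pairs$p_value, method = "BH")
  edges <- all_pairs |>
    dplyr::filter(abs(.data$r) >= r_threshold, .data$q_value <= q_threshold) |>
    dplyr::arrange(.data$from_modality, .data$from_component,
                   .data$to_modality, .data$to_component)
  node_ids <- sort(unique(c(
    paste(all_pairs$from_modality, all_pairs$from_component, sep = "."),
    paste(all_pairs$to_modality, all_pairs$to_component, sep = "."))))
  g <- igraph::make_empty_graph(n = length(node_ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = node_ids)
  if (nrow(edges)) {
    ev <- rbind(paste(edges$from_modality, edges$from_component, sep = "."),
                paste(edges$to_modality, edges$to_component, sep = "."))
    g <- igraph::add_edges(g, as.vector(ev))
    g <- igraph::set_edge_attr(g, "r", value = edges$r)
  }
  comp <- igraph::components(g)
  # relabel clusters by their lexicographically smallest member for stability
  first_member <- tapply(node_ids, comp$membership, min)
  relabel <- match(first_member, sort(first_member))
  cluster <- relabel[comp$membership]
  nodes <- tibble::tibble(
    modality = sub("\\..*$", "", node_ids),
    component = sub("^[^.]*\\.", "", node_ids),
    cluster = as.integer(cluster))
  structure(list(nodes = nodes, edges = edges, graph = g,
                 r_threshold = r_threshold, q_threshold = q_threshold),
            class = "component_graph")
}

#' @export
print.component_graph <- function(x, ...) {
  nontrivial <- sum(table(x$nodes$cluster) > 1L)
  cat(sprintf("<component_graph> %d nodes, %d edges, %d multi-node cluster(s)\n",
              nrow(x$nodes), nrow(x$edges), nontrivial))
  invisible(x)
}

#' Export a component graph as edge-list TSV and GraphML
#'
#' @param graph A [build_component_graph()] result.
#' @param edge_path Path for the edge-list TSV.
#' @param graphml_path Optional path for a GraphML file.
#' @return Invisibly, the written paths.
#' @export
write_component_graph <- function(graph, edge_path, graphml_path = NULL) {
  stopifnot(inherits(graph, "component_graph"))
  utils::write.table(as.data.frame(graph$edges), edge_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  written <- edge_path
  if (!is.null(graphml_path)) {
    igraph::write_graph(graph$graph, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  invisible(written)
}
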