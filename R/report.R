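#' Generate an HTML report describing each component
#'
#' Writes a static, self-contained HTML report with one section per
#' component, ordered by variance explained (when the data matrix is
#' available): stability, variance explained, top positive and negative
#' features, the top enriched gene sets per direction, factor associations
#' and the Cox survival row. Sections whose inputs were not supplied render
#' as "not computed". The output is deterministic: identical inputs give a
#' byte-identical file.
#'
#' @param dec A `consensus_ica` object.
#' @param path Output file path (`.html`).
#' @param X Optional omics matrix (enables variance-explained ordering).
#' @param enrichment Optional tibble from [annotate_component()] calls
#'   (rows for any number of components).
#' @param anova Optional tibble from [anova_weights()] (any number of
#'   factors, row-bound).
#' @param cox Optional tibble from [cox_weights()].
#' @param z_threshold Threshold used for the top-feature listing. Default 3.
#' @param max_rows Rows shown per table section. Default 10.
#' @return `path`, invisibly.
#' @export
generate_report <- function(dec, path, X = NULL, enrichment = NULL,
                            anova = NULL, cox = NULL, z_threshold = 3,
                            max_rows = 10L) {
  stopifnot(inherits(dec, "consensus_ica"))
  comp_order <- names(dec$stability)
  varexp <- NULL
  if (!is.null(X)) {
    varexp <- variance_explained(dec, X)
    comp_order <- varexp$component
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  html_table <- function(df) {
    if (is.null(df) || !nrow(df)) return("<p><em>not computed</em></p>")
    df <- utils::head(df, max_rows)
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(v) signif(v, 4L))
    cells <- vapply(seq_len(nrow(df)), function(i) {
      paste0("<tr>", paste0("<td>", esc(as.character(unlist(df[i, ]))),
                            "</td>", collapse = ""), "</tr>")
    }, character(1L))
    paste0("<table><thead><tr>",
           paste0("<th>", esc(colnames(df)), "</th>", collapse = ""),
           "</tr></thead><tbody>", paste(cells, collapse = "\n"),
           "</tbody></table>")
  }
  sections <- vapply(comp_order, function(cid) {
    j <- match(cid, names(dec$stability))
    tf <- top_features(dec, cid, z_threshold)
    ve_line <- if (!is.null(varexp)) {
      sprintf("<li>variance explained: %.2f%%</li>",
              100 * varexp$variance_explained[varexp$component == cid])
    } else ""
    enr <- if (!is.null(enrichment)) {
      pos <- dplyr::filter(enrichment, .data$component == cid,
                           .data$direction == "positive")
      neg <- dplyr::filter(enrichment, .data$component == cid,
                           .data$direction == "negative")
      paste0("<h3>Enriched sets (positive)</h3>",
             html_table(dplyr::select(pos, -"component", -"direction")),
             "<h3>Enriched sets (negative)</h3>",
             html_table(dplyr::select(neg, -"component", -"direction")))
    } else "<h3>Enrichment</h3><p><em>not computed</em></p>"
    anv <- if (!is.null(anova)) {
      html_table(dplyr::filter(anova, .data$component == cid))
    } else "<p><em>not computed</em></p>"
    cx <- if (!is.null(cox)) {
      html_table(dplyr::filter(cox, .data$component == cid))
    } else "<p><em>not computed</em></p>"
    paste0(
      "<section><h2>", esc(cid), "</h2><ul>",
      sprintf("<li>stability: %.4f</li>", dec$stability[[j]]), ve_line,
      "</ul><h3>Top features</h3>",
      html_table(tf), enr,
      "<h3>Factor associations</h3>", anv,
      "<h3>Survival (Cox)</h3>", cx,
      "</section>")
  }, character(1L))
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
    "<title>Consensus ICA report</title><style>",
    "body{font-family:sans-serif;max-width:60em;margin:2em auto;}",
    "table{border-collapse:collapse;margin:0.5em 0;}",
    "td,th{border:1px solid #999;padding:2px 8px;font-size:90%;}",
    "section{border-top:2px solid #444;margin-top:1.5em;}",
    "</style></head><body>\n<h1>Consensus ICA report</h1>\n",
    sprintf("<p>%d components, %d features, %d samples; %d run(s) averaged.</p>\n",
            dec$k, nrow(dec$S), ncol(dec$M), dec$n_runs - dec$n_dropped),
    paste(sections, collapse = "\n"),
    "\n</body></html>\n")
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}
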