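#' Write a directed edge list
#'
#' Serializes a network edge table (`from`, `to`, `support`, `sign`) as TSV,
#' GraphML, or Graphviz DOT. The three formats carry identical edge content;
#' TSV round-trips byte-identically through [read_edge_list()].
#'
#' @param edges Edge tibble with columns `from`, `to`, `support` (fraction in
#'   `[0, 1]`), `sign` (`POS`, `NEG`, or `NA`). Self-edges are rejected.
#' @param path Output path.
#' @param format One of `"tsv"`, `"graphml"`, `"dot"`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path, format = c("tsv", "graphml", "dot")) {
  format <- match.arg(format)
  edges <- validate_edge_list(edges)
  if (format == "tsv") {
    readr::write_tsv(edges[c("from", "to", "support", "sign")], path)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(
      from = edges$from, to = edges$to,
      support = edges$support,
      sign = ifelse(is.na(edges$sign), "NA", edges$sign),
      stringsAsFactors = FALSE
    ),
    directed = TRUE
  )
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Read a TSV edge list
#'
#' @param path Path to a TSV written by [write_edge_list()].
#' @return Edge tibble with `from`, `to`, `support`, `sign`.
#' @export
read_edge_list <- function(path) {
  edges <- readr::read_tsv(path, col_types = readr::cols(
    from = readr::col_character(), to = readr::col_character(),
    support = readr::col_double(), sign = readr::col_character()
  ), progress = FALSE)
  validate_edge_list(edges)
}

validate_edge_list <- function(edges) {
  req <- c("from", "to", "support", "sign")
  if (!all(req %in% names(edges))) {
    abort("edge list must have columns from, to, support, sign")
  }
  if (any(edges$from == edges$to)) abort("self-edges are not allowed")
  if (any(edges$support < 0 | edges$support > 1)) {
    abort("edge support must lie in [0, 1]")
  }
  ok <- is.na(edges$sign) | edges$sign %in% c("POS", "NEG")
  if (!all(ok)) abort("edge sign must be POS, NEG or NA")
  as_tibble(edges)[req]
}

empty_edge_list <- function() {
  tibble(from = character(0), to = character(0),
         support = numeric(0), sign = character(0))
}
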