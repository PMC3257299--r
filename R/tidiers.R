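#' Tidy and summarize fitted objects
#'
#' broom-style methods: `tidy()` returns a per-element tibble, `glance()` a
#' one-row summary.
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @name hairnet-tidiers
NULL

#' @rdname hairnet-tidiers
#' @export
tidy.sam_result <- function(x, ...) {
  as_tibble(unclass(x)[intersect(c("gene_id", "d", "s", "fc", "q"), names(x))])
}

#' @rdname hairnet-tidiers
#' @export
glance.sam_result <- function(x, ...) {
  extra <- attr(x, "extra")
  tibble(
    n_genes = nrow(x),
    n1 = length(attr(x, "class1")),
    n2 = length(attr(x, "class2")),
    s0 = attr(x, "s0"),
    n_permutations = if (!is.null(extra$n_perm)) extra$n_perm else NA_integer_,
    n_q05 = if ("q" %in% names(x)) sum(x$q < 0.05) else NA_integer_
  )
}

#' @rdname hairnet-tidiers
#' @export
tidy.bn_topk <- function(x, ...) {
  tibble(
    rank = seq_along(x$scores),
    score = x$scores,
    n_edges = vapply(x$structures, nrow, integer(1))
  )
}

#' @rdname hairnet-tidiers
#' @export
glance.bn_topk <- function(x, ...) {
  tibble(n_structures = length(x$scores), best_score = max(x$scores),
         worst_kept = min(x$scores), n_nodes = nrow(x$nodes))
}

#' @rdname hairnet-tidiers
#' @export
tidy.consensus_network <- function(x, ...) as_tibble(unclass(x))

#' @rdname hairnet-tidiers
#' @export
glance.consensus_network <- function(x, ...) {
  tibble(n_edges = nrow(x), f = attr(x, "f"),
         n_structures = attr(x, "n_structures"))
}

#' @rdname hairnet-tidiers
#' @export
tidy.regulatory_clusters <- function(x, ...) {
  as_tibble(unclass(x)) %>%
    dplyr::group_by(.data$cluster_id, .data$collapsed_zone) %>%
    dplyr::summarise(n_genes = dplyr::n(),
                     robust = any(.data$robust),
                     genes = paste(sort(.data$gene_id), collapse = ","),
                     .groups = "drop")
}

#' @rdname hairnet-tidiers
#' @export
glance.regulatory_clusters <- function(x, ...) {
  tibble(n_clusters = dplyr::n_distinct(x$cluster_id), n_genes = nrow(x),
         n_robust = sum(x$robust))
}

#' @rdname hairnet-tidiers
#' @export
glance.screen_result <- function(x, ...) {
  tibble(n_stage1 = nrow(x$stage1), n_core = nrow(x$core),
         n_hair = sum(x$core$class == "HAIR"),
         n_nonhair = sum(x$core$class == "NONHAIR"))
}

#' Plot a SAM result
#'
#' Observed d statistics against fold change, highlighting genes passing the
#' q threshold (when q-values are present).
#'
#' @param object A `sam_result`.
#' @param q_max Highlight threshold (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sam_result <- function(object, q_max = 0.05, ...) {
  df <- tidy(object)
  df$significant <- if ("q" %in% names(df)) df$q < q_max else FALSE
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$fc), y = .data$d,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (class 2 / class 1)",
                  y = "SAM d statistic", colour = sprintf("q < %g", q_max)) +
    ggplot2::theme_minimal()
}

#' Plot a consensus network
#'
#' Force-directed layout of the consensus edges; edge width encodes support,
#' colour encodes sign.
#'
#' @param object A `consensus_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.consensus_network <- function(object, ...) {
  if (!nrow(object)) abort("empty consensus network")
  g <- igraph::graph_from_data_frame(object[c("from", "to")], directed = TRUE)
  set.seed(1L)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble(node = igraph::V(g)$name, x = lay[, 1], y = lay[, 2])
  edges <- as_tibble(unclass(object)) %>%
    dplyr::left_join(nodes, by = c(from = "node")) %>%
    dplyr::rename(x0 = "x", y0 = "y") %>%
    dplyr::left_join(nodes, by = c(to = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y,
                   linewidth = .data$support,
                   colour = ifelse(is.na(.data$sign), "NA", .data$sign)),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
                        size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 1.5)) +
    ggplot2::scale_colour_manual(values = c(POS = "steelblue", NEG = "firebrick",
                                            `NA` = "grey50"), name = "sign") +
    ggplot2::theme_void()
}

#' Plot section profiles grouped by assigned zone
#'
#' Heatmap of z-scored longitudinal profiles with genes ordered by zone and
#' peak section.
#'
#' @param sections Section-profile tibble (`gene_id` + 24 columns).
#' @param zones A `zone_assignment` for the same genes.
#' @return A ggplot.
#' @export
plot_zone_profiles <- function(sections, zones) {
  m <- as.matrix(sections[setdiff(names(sections), "gene_id")])
  rownames(m) <- sections$gene_id
  z <- t(scale(t(m)))
  ord <- zones$gene_id[order(zones$zone, zones$peak_section)]
  df <- as_tibble(z, rownames = "gene_id") %>%
    tidyr::pivot_longer(-"gene_id", names_to = "section", values_to = "z") %>%
    dplyr::mutate(gene_id = factor(.data$gene_id, levels = rev(ord)),
                  section = factor(.data$section,
                                   levels = setdiff(names(sections), "gene_id")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$section, y = .data$gene_id,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "root section (developmental order)", y = NULL,
                  fill = "z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' Plot an MDS embedding of samples
#'
#' @param coords Output of [classical_mds()].
#' @param samples Optional sample tibble supplying a `line_id` to colour by.
#' @return A ggplot.
#' @export
plot_mds <- function(coords, samples = NULL) {
  df <- coords
  if (!is.null(samples)) {
    df <- dplyr::left_join(df, samples[c("sample_id", "line_id")],
                           by = "sample_id")
  } else {
    df$line_id <- "sample"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$MDS1, y = .data$MDS2,
                                   colour = .data$line_id)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(colour = "line") +
    ggplot2::theme_minimal()
}
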