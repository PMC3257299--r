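#' Assign genes to developmental zones from section profiles
#'
#' Each gene's 24-column longitudinal profile (two roots, sections 1-12 each,
#' in developmental order) is z-score standardized and clustered by
#' average-linkage hierarchical clustering on correlation distance
#' (1 - Pearson). The tree is cut into `n_zones` clusters, which are then
#' relabeled 1..n_zones by ascending median peak section, so the zone label
#' is a permutation-invariant function of the data. The peak section is the
#' argmax of the per-root-averaged 12-section profile (ties resolved to the
#' earlier section).
#'
#' @param sections Tibble: `gene_id` plus 24 ordered numeric columns.
#' @param n_zones Number of zones (default 6).
#' @return A `zone_assignment` tibble: `gene_id`, `zone`, `collapsed`
#'   (`EARLY`/`MID`/`LATE`), `peak_section`.
#' @export
assign_zones <- function(sections, n_zones = 6L) {
  if (!"gene_id" %in% names(sections)) abort("sections needs a gene_id column")
  m <- as.matrix(sections[setdiff(names(sections), "gene_id")])
  if (ncol(m) != 24L) abort("expected 24 ordered section columns (two roots x 12)")
  rownames(m) <- sections$gene_id
  if (nrow(unique(m)) < n_zones) {
    abort(sprintf("n_zones = %d exceeds the %d distinct profiles",
                  n_zones, nrow(unique(m))))
  }
  z <- t(scale(t(m)))
  cc <- suppressWarnings(cor(t(z)))
  cc[!is.finite(cc)] <- 0
  hc <- hclust(stats::as.dist(1 - cc), method = "average")
  cl <- cutree(hc, k = n_zones)
  avg <- (m[, 1:12, drop = FALSE] + m[, 13:24, drop = FALSE]) / 2
  peak <- apply(avg, 1L, which.max)  # which.max takes the earlier tie
  med_peak <- tapply(peak, cl, median)
  relabel <- integer(n_zones)
  relabel[order(med_peak, as.integer(names(med_peak)))] <- seq_len(n_zones)
  zone <- relabel[cl]
  collapse_zones(tibble(
    gene_id = sections$gene_id,
    zone = as.integer(zone),
    collapsed = NA_character_,
    peak_section = as.integer(peak)
  ))
}

#' Collapse six zones to early / mid / late
#'
#' Applies the fixed 2-to-1 map: zones 1-2 -> `EARLY`, 3-4 -> `MID`,
#' 5-6 -> `LATE`. Idempotent.
#'
#' @param zones A `zone_assignment` tibble (or any tibble with `zone`).
#' @return The tibble with the `collapsed` column populated.
#' @export
collapse_zones <- function(zones) {
  if (!"zone" %in% names(zones)) abort("zones needs a zone column")
  if (!all(zones$zone %in% 1:6)) abort("zone labels must lie in 1..6")
  zones$collapsed <- c("EARLY", "EARLY", "MID", "MID", "LATE", "LATE")[zones$zone]
  cls <- class(zones)
  if (!"zone_assignment" %in% cls) {
    class(zones) <- c("zone_assignment", cls)
  }
  zones
}
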