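#' Primary q-value screen across two sites
#'
#' Selects genes with a significant hairy-versus-hairless difference
#' (q below `q_max`) in at least one of the two site comparisons.
#'
#' @param sam_site_a,sam_site_b `sam_result` tibbles (with `q`) for the two
#'   profiling sites, over the same gene universe.
#' @param q_max FDR q-value threshold (default 0.01).
#' @return Tibble of passing genes: `gene_id`, `q_site_a`, `q_site_b`.
#' @export
primary_screen <- function(sam_site_a, sam_site_b, q_max = 0.01) {
  for (s in list(sam_site_a, sam_site_b)) {
    if (!all(c("gene_id", "q") %in% names(s))) {
      abort("inputs must be SAM results carrying q-values")
    }
  }
  only_a <- setdiff(sam_site_a$gene_id, sam_site_b$gene_id)
  only_b <- setdiff(sam_site_b$gene_id, sam_site_a$gene_id)
  if (length(only_a) || length(only_b)) {
    abort(sprintf(
      "gene universes differ; only in site A: [%s]; only in site B: [%s]",
      paste(only_a, collapse = ", "), paste(only_b, collapse = ", ")
    ))
  }
  tibble(gene_id = sam_site_a$gene_id,
         q_site_a = sam_site_a$q,
         q_site_b = sam_site_b$q[match(sam_site_a$gene_id, sam_site_b$gene_id)]) %>%
    dplyr::filter(.data$q_site_a < q_max | .data$q_site_b < q_max)
}

#' Build the six-comparison fold-change table
#'
#' One column per (hairy line, site) pair: the linear expression ratio of
#' that hairy line over the hairless line, computed within site.
#'
#' @param expr Expression tibble.
#' @param samples Sample tibble (with `line_id`).
#' @param hairy_lines Character vector of hairy line ids (three in the
#'   default design).
#' @param hairless_line Hairless line id.
#' @param sites Sites over which each comparison is made (default both).
#' @return Tibble: `gene_id` plus one ratio column `<line>.<site>` per
#'   comparison.
#' @export
fc_table <- function(expr, samples, hairy_lines, hairless_line,
                     sites = c("SITE_A", "SITE_B")) {
  out <- tibble(gene_id = expr$gene_id)
  for (site in sites) {
    ref <- samples$sample_id[samples$line_id == hairless_line &
                               samples$site == site & samples$treatment == "NONE"]
    if (length(ref) < 2L) {
      abort(sprintf("hairless line '%s' has < 2 samples at %s", hairless_line, site))
    }
    for (ln in hairy_lines) {
      ids <- samples$sample_id[samples$line_id == ln & samples$site == site &
                                 samples$treatment == "NONE"]
      if (length(ids) < 2L) {
        abort(sprintf("hairy line '%s' has < 2 samples at %s", ln, site))
      }
      out[[paste(ln, site, sep = ".")]] <- fold_change(expr, ref, ids)$fc
    }
  }
  out
}

#' Select core genes by the six-comparison fold-change filter
#'
#' A candidate gene is a `HAIR` gene if all six hairy-over-hairless ratios
#' are at least `fc_min`, a `NONHAIR` gene if all six are at most
#' `1 / fc_min` (same direction in every individual comparison at both
#' sites); any mixed gene is excluded. Exactly-threshold ratios pass.
#'
#' @param candidates Character vector of candidate gene ids (or a tibble with
#'   a `gene_id` column, e.g. the output of [primary_screen()]).
#' @param fc_table Tibble `gene_id` plus the six linear ratio columns,
#'   oriented hairy over hairless, covering all candidates.
#' @param fc_min Fold-change threshold (default 2.0).
#' @return Gene-set tibble: `gene_id`, `class` (`HAIR`/`NONHAIR`).
#' @export
select_core_genes <- function(candidates, fc_table, fc_min = 2.0) {
  if (is.data.frame(candidates)) candidates <- candidates$gene_id
  missing <- setdiff(candidates, fc_table$gene_id)
  if (length(missing)) {
    abort(sprintf("candidate gene(s) missing from the fold-change table: %s",
                  paste(missing, collapse = ", ")))
  }
  fc <- fc_table[match(candidates, fc_table$gene_id), ]
  ratios <- as.matrix(fc[setdiff(names(fc), "gene_id")])
  if (anyNA(ratios)) {
    bad <- candidates[rowSums(is.na(ratios)) > 0][1]
    abort(sprintf("missing comparison for candidate gene '%s'", bad))
  }
  if (any(ratios <= 0)) abort("fold-change ratios must be positive")
  hair <- rowSums(ratios >= fc_min) == ncol(ratios)
  nonhair <- rowSums(ratios <= 1 / fc_min) == ncol(ratios)
  stopifnot(!any(hair & nonhair))  # mutually exclusive by construction
  validate_gene_set(tibble(
    gene_id = c(candidates[hair], candidates[nonhair]),
    class = c(rep("HAIR", sum(hair)), rep("NONHAIR", sum(nonhair)))
  ))
}
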