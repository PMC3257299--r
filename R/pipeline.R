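#' Hairy-versus-hairless SAM comparison at one site
#'
#' Pools the three hairy lines into one class (the "multi-way" arrangement)
#' against the hairless line at a given profiling site and runs
#' [estimate_fdr()].
#'
#' @param expr Expression tibble.
#' @param samples Sample tibble with `line_id` and `site`.
#' @param site `SITE_A` or `SITE_B`.
#' @param hairy_lines,hairless_line Line ids (defaults match
#'   [default_design()]).
#' @param config A [sam_config()].
#' @return A `sam_result` with q-values (class 1 hairless, class 2 hairy, so
#'   fold changes are hairy over hairless).
#' @export
site_sam <- function(expr, samples, site,
                     hairy_lines = c("hairy_wm", "hairy_ge", "hairy_t"),
                     hairless_line = "hairless_ct",
                     config = sam_config()) {
  sel <- samples$site == site & samples$treatment == "NONE"
  class1 <- samples$sample_id[sel & samples$line_id == hairless_line]
  class2 <- samples$sample_id[sel & samples$line_id %in% hairy_lines]
  estimate_fdr(expr, class1, class2, config)
}

#' Run the two-stage core-gene screen on a study
#'
#' Site-wise hairy-versus-hairless SAM, the q-value primary screen
#' (significant in at least one site), the six-comparison fold-change table,
#' and the all-six two-fold same-direction core filter.
#'
#' @param study A `simulated_study` (or any list with `expression` and
#'   `samples` in the default-design layout).
#' @param q_max Primary-screen q threshold (default 0.01).
#' @param fc_min Core-filter fold-change threshold (default 2).
#' @param config A [sam_config()].
#' @return A `screen_result`: list with `stage1` (tibble), `core` (gene-set
#'   tibble), `fc_table`, `sam_site_a`, `sam_site_b`.
#' @export
screen_study <- function(study, q_max = 0.01, fc_min = 2.0,
                         config = sam_config()) {
  expr <- study$expression
  samples <- study$samples
  sam_a <- site_sam(expr, samples, "SITE_A", config = config)
  sam_b <- site_sam(expr, samples, "SITE_B", config = config)
  stage1 <- primary_screen(sam_a, sam_b, q_max = q_max)
  fc <- fc_table(expr, samples,
                 hairy_lines = c("hairy_wm", "hairy_ge", "hairy_t"),
                 hairless_line = "hairless_ct")
  core <- select_core_genes(stage1$gene_id, fc, fc_min = fc_min)
  structure(list(stage1 = stage1, core = core, fc_table = fc,
                 sam_site_a = sam_a, sam_site_b = sam_b),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "<screen_result> stage 1: %d genes; core: %d (%d HAIR + %d NONHAIR)\n",
    nrow(x$stage1), nrow(x$core), sum(x$core$class == "HAIR"),
    sum(x$core$class == "NONHAIR")
  ))
  invisible(x)
}

#' Per-perturbation SAM comparisons of a study
#'
#' One mutant-versus-wild-type comparison per knockout line (at the site
#' where the extra lines were profiled), plus hormone-transfer comparisons
#' (IAA versus MS and ACC versus MS within the hormone background) when the
#' study has one.
#'
#' @param study A `simulated_study`.
#' @param lines Line ids to compare against wild type; defaults to every
#'   learning knockout line profiled at `SITE_A`.
#' @param config A [sam_config()].
#' @return Named list of `sam_result`s; hormone comparisons are named
#'   `IAA` and `ACC`.
#' @export
perturbation_sams <- function(study, lines = NULL, config = sam_config()) {
  samples <- study$samples
  expr <- study$expression
  if (is.null(lines)) {
    lines <- setdiff(unique(samples$line_id[samples$learning &
                                              samples$site == "SITE_A"]), "WT")
  }
  wt <- samples$sample_id[samples$line_id == "WT" & samples$site == "SITE_A"]
  out <- lapply(setNames(lines, lines), function(ln) {
    ids <- samples$sample_id[samples$line_id == ln & samples$site == "SITE_A" &
                               samples$treatment == "NONE"]
    estimate_fdr(expr, wt, ids, config)
  })
  if (any(samples$treatment %in% c("IAA", "ACC"))) {
    ms <- samples$sample_id[samples$treatment == "MS"]
    for (tr in c("IAA", "ACC")) {
      ids <- samples$sample_id[samples$treatment == tr]
      if (length(ids) >= 2L && length(ms) >= 2L) {
        out[[tr]] <- estimate_fdr(expr, ms, ids, config)
      }
    }
  }
  out
}

#' Compare a learned consensus network to the ground truth
#'
#' Recall is the fraction of true edges present (with matching direction) in
#' the consensus; false edges are consensus edges absent from the truth
#' (reversed edges count as false).
#'
#' @param consensus A `consensus_network`.
#' @param truth A `synthetic_truth`.
#' @param learnable_only Drop truth edges from hormone nodes (inactive
#'   throughout an observational learning set) before scoring. Default TRUE.
#' @return One-row tibble: `n_true`, `n_consensus`, `n_recovered`, `recall`,
#'   `n_false`, `false_rate`.
#' @export
edge_recovery <- function(consensus, truth, learnable_only = TRUE) {
  hormones <- truth$nodes$node_id[truth$nodes$kind == "HORMONE"]
  te <- truth$edges
  if (learnable_only) te <- te[!te$from %in% hormones, ]
  tkey <- paste(te$from, te$to)
  ckey <- paste(consensus$from, consensus$to)
  tibble(
    n_true = length(tkey),
    n_consensus = length(ckey),
    n_recovered = sum(tkey %in% ckey),
    recall = sum(tkey %in% ckey) / length(tkey),
    n_false = sum(!ckey %in% tkey),
    false_rate = if (length(ckey)) sum(!ckey %in% tkey) / length(ckey) else 0
  )
}
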