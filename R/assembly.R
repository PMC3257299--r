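#' Perturbation response signatures
#'
#' Classifies every gene's response to every perturbation comparison
#' (perturbation versus reference) as `UP` (fold change at least `fc_min`
#' and q below `q_max`), `DOWN` (fold change at most `1 / fc_min`, same q
#' gate), or `NONE`. Hormone perturbations are gated at their own, stricter
#' FDR threshold.
#'
#' @param sam_results Named list of `sam_result` tibbles (with `fc` and `q`),
#'   one per perturbation, all over the same gene universe.
#' @param fc_min Fold-change threshold (default 2).
#' @param q_max q-value threshold (default 0.05).
#' @param hormone_perturbations Names within `sam_results` treated as hormone
#'   comparisons.
#' @param hormone_fc_min,hormone_q_max Thresholds for hormone comparisons
#'   (defaults 2 and 0.005, i.e. 0.5% FDR).
#' @return A `perturbation_signature` tibble in long form: `gene_id`,
#'   `perturbation`, `response`.
#' @export
perturbation_signature <- function(sam_results, fc_min = 2.0, q_max = 0.05,
                                   hormone_perturbations = character(0),
                                   hormone_fc_min = 2.0,
                                   hormone_q_max = 0.005) {
  if (!length(sam_results) || is.null(names(sam_results))) {
    abort("sam_results must be a named list of SAM results")
  }
  universe <- sort(sam_results[[1]]$gene_id)
  for (nm in names(sam_results)) {
    if (!identical(sort(sam_results[[nm]]$gene_id), universe)) {
      abort(sprintf("gene universe of '%s' differs from the first result", nm))
    }
  }
  out <- purrr::imap_dfr(sam_results, function(s, nm) {
    hormone <- nm %in% hormone_perturbations
    fmin <- if (hormone) hormone_fc_min else fc_min
    qmax <- if (hormone) hormone_q_max else q_max
    response <- dplyr::case_when(
      s$q < qmax & s$fc >= fmin ~ "UP",
      s$q < qmax & s$fc <= 1 / fmin ~ "DOWN",
      TRUE ~ "NONE"
    )
    tibble(gene_id = s$gene_id, perturbation = nm, response = response)
  })
  structure(out, class = c("perturbation_signature", class(out)),
            fc_min = fc_min, q_max = q_max,
            hormone_fc_min = hormone_fc_min, hormone_q_max = hormone_q_max)
}

#' Assemble regulatory clusters
#'
#' Partitions genes by their exact perturbation-response signature (the
#' response tuple over all perturbations, i.e. the gene's transcriptional
#' regulatory position) and their collapsed temporal zone. Genes with a
#' non-`NONE` response in at least `min_affected` members of the
#' downstream-mutant panel are flagged robust.
#'
#' @param sig A `perturbation_signature` (long tibble).
#' @param zones A `zone_assignment` covering the same genes.
#' @param downstream_panel Character vector of perturbation ids forming the
#'   downstream-mutant panel (nine mutants in the original design).
#' @param min_affected Robustness threshold (default 6).
#' @return A `regulatory_clusters` tibble: `gene_id`, `cluster_id`,
#'   `collapsed_zone`, `robust`, `signature` (the signature key string).
#' @export
build_clusters <- function(sig, zones, downstream_panel = character(0),
                           min_affected = 6L) {
  genes <- unique(sig$gene_id)
  no_zone <- setdiff(genes, zones$gene_id)
  if (length(no_zone)) {
    abort(sprintf("gene(s) missing a zone assignment: %s",
                  paste(no_zone, collapse = ", ")))
  }
  wide <- sig %>%
    dplyr::arrange(.data$perturbation) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      signature = paste(.data$perturbation, .data$response,
                        sep = "=", collapse = "|"),
      n_panel_affected = sum(.data$response != "NONE" &
                               .data$perturbation %in% downstream_panel),
      .groups = "drop"
    )
  out <- wide %>%
    dplyr::left_join(zones[c("gene_id", "collapsed")], by = "gene_id") %>%
    dplyr::rename(collapsed_zone = "collapsed") %>%
    dplyr::mutate(robust = .data$n_panel_affected >= min_affected,
                  key = paste(.data$signature, .data$collapsed_zone, sep = "@"))
  keys <- sort(unique(out$key))
  cluster_ids <- setNames(
    paste0("C", formatC(seq_along(keys), width = 2, flag = "0")), keys
  )
  out$cluster_id <- unname(cluster_ids[out$key])
  res <- out[c("gene_id", "cluster_id", "collapsed_zone", "robust", "signature")]
  structure(res, class = c("regulatory_clusters", class(res)),
            downstream_panel = downstream_panel, min_affected = min_affected)
}

#' Gene-set overrepresentation by Fisher's exact test
#'
#' One-sided (overrepresentation) Fisher's exact p-value per annotation term
#' from the 2x2 table of selected / unselected versus annotated /
#' unannotated, with annotation sets intersected with the universe. Raw
#' p-values are reported (sorted ascending) together with a
#' Benjamini-Hochberg column.
#'
#' @param selected Character vector of selected genes (subset of `universe`).
#' @param universe Character vector, the gene universe.
#' @param annotations Named list of character vectors (term -> genes), or a
#'   long tibble with `term` and `gene_id` columns.
#' @return Tibble: `term`, `n_term`, `n_selected`, `overlap`, `p_value`,
#'   `p_bh`.
#' @export
fisher_enrichment <- function(selected, universe, annotations) {
  if (!length(universe)) abort("empty gene universe")
  universe <- unique(universe)
  selected <- unique(selected)
  if (length(setdiff(selected, universe))) {
    abort("selected genes must be a subset of the universe")
  }
  if (is.data.frame(annotations)) {
    annotations <- split(annotations$gene_id, annotations$term)
  }
  res <- purrr::imap_dfr(annotations, function(genes, term) {
    ann <- intersect(genes, universe)
    k <- length(intersect(ann, selected))
    tab <- matrix(c(
      k, length(selected) - k,
      length(ann) - k, length(universe) - length(selected) - length(ann) + k
    ), nrow = 2)
    tibble(term = term, n_term = length(ann), n_selected = length(selected),
           overlap = k,
           p_value = fisher.test(tab, alternative = "greater")$p.value)
  })
  res %>%
    dplyr::mutate(p_bh = stats::p.adjust(.data$p_value, method = "BH")) %>%
    dplyr::arrange(.data$p_value)
}

#' Classical (Torgerson) multidimensional scaling of samples
#'
#' Embeds samples by classical MDS on Euclidean sample-sample distances over
#' a gene subset: double-centered Gram matrix, top-`dim` eigenvectors scaled
#' by the square root of their eigenvalues. Deterministic up to sign and
#' rotation.
#'
#' @param expr Expression tibble.
#' @param genes Optional character vector restricting the gene rows (e.g. the
#'   core gene set).
#' @param dim Embedding dimension (default 2).
#' @return Tibble: `sample_id`, `MDS1`, ..., `MDS<dim>`.
#' @export
classical_mds <- function(expr, genes = NULL, dim = 2L) {
  validate_expression(expr)
  if (!is.null(genes)) {
    missing <- setdiff(genes, expr$gene_id)
    if (length(missing)) {
      abort(sprintf("gene(s) not in matrix: %s", paste(missing, collapse = ", ")))
    }
    expr <- expr[expr$gene_id %in% genes, ]
  }
  x <- t(expr_matrix(expr))
  if (nrow(x) < dim + 1L) abort("need at least dim + 1 samples")
  d <- dist(x)
  fit <- cmdscale(d, k = min(dim, nrow(x) - 1L), eig = TRUE)
  n_pos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  if (dim > n_pos) {
    abort(sprintf("dim = %d exceeds the %d positive eigenvalues", dim, n_pos))
  }
  coords <- fit$points[, seq_len(dim), drop = FALSE]
  out <- as_tibble(coords, .name_repair = "minimal")
  names(out) <- paste0("MDS", seq_len(dim))
  dplyr::bind_cols(tibble(sample_id = rownames(x)), out)
}

#' Scan promoters for an IUPAC consensus motif
#'
#' Scans both strands of the window-proximal subsequence of each promoter
#' (the last `window` nucleotides, i.e. those closest to the translation
#' start, promoters being given 5' to 3' and ending at the start codon).
#' Matches are reported 1-based relative to the translation start (upstream
#' positions negative); reverse-strand matches are reported by their
#' plus-strand start.
#'
#' @param promoters A `Biostrings::DNAStringSet` or path to a FASTA file of
#'   upstream sequences.
#' @param consensus IUPAC consensus string (e.g. `"WHHDTGNNN..."`).
#' @param window Number of nucleotides upstream of the translation start to
#'   scan (default 1000).
#' @return Tibble: `gene_id`, `n_matches`, `positions` (list column of
#'   integer plus-strand start offsets), `strands` (list column).
#' @export
rhe_scan <- function(promoters, consensus, window = 1000L) {
  if (is.character(promoters) && length(promoters) == 1L) {
    promoters <- Biostrings::readDNAStringSet(promoters)
  }
  letters_ok <- names(Biostrings::IUPAC_CODE_MAP)
  cons_chars <- strsplit(toupper(consensus), "")[[1]]
  if (!length(cons_chars) || !all(cons_chars %in% letters_ok)) {
    abort(sprintf("consensus contains non-IUPAC character(s): %s",
                  paste(setdiff(cons_chars, letters_ok), collapse = ", ")))
  }
  pat <- Biostrings::DNAString(paste(cons_chars, collapse = ""))
  rc <- Biostrings::reverseComplement(pat)
  ids <- names(promoters)
  if (is.null(ids)) ids <- paste0("seq", seq_along(promoters))
  res <- purrr::map2_dfr(as.list(promoters), ids, function(seq, id) {
    L <- length(seq)
    sub <- Biostrings::subseq(seq, start = max(1L, L - window + 1L), end = L)
    Ls <- length(sub)
    fw <- Biostrings::start(Biostrings::matchPattern(pat, sub, fixed = FALSE))
    rv <- Biostrings::start(Biostrings::matchPattern(rc, sub, fixed = FALSE))
    pos <- c(fw, rv) - Ls - 1L  # upstream offsets, -Ls .. -1
    strand <- c(rep("+", length(fw)), rep("-", length(rv)))
    ord <- order(pos, strand)
    tibble(gene_id = id, n_matches = length(pos),
           positions = list(as.integer(pos[ord])),
           strands = list(strand[ord]))
  })
  res
}
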