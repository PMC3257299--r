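#' SAM configuration
#'
#' Settings for the significance-analysis-of-microarrays statistic and its
#' permutation false-discovery-rate estimate.
#'
#' @param s0_mode How the exchangeability ("fudge") factor s0 is chosen:
#'   `"tusher_cv_min"` picks, among percentile candidates of the per-gene
#'   scatter s, the value minimizing the coefficient of variation of
#'   `mad(d)` across s-quantile windows; `"fixed_percentile"` uses the
#'   `s0_percentile` quantile of s directly.
#' @param s0_percentile Quantile of s used by `"fixed_percentile"` (and the
#'   fallback when the CV search degenerates). In `[0, 1]`.
#' @param n_permutations Number of label permutations, or `"exhaustive"` to
#'   enumerate all splits. When the number of available splits is at most
#'   `n_permutations`, enumeration is used anyway; the default of 500 makes
#'   desk-scale class sizes (3 vs 3, 3 vs 9, 6 vs 6 balanced) exhaustive.
#' @param balanced Use balanced label reassignments (each permuted class
#'   drawing half its members from each original class) when both class
#'   sizes are even; otherwise all label splits are used.
#' @param pi0 Either the fixed value 1 (conservative default) or
#'   `"estimate"` for the median-based plug-in estimator
#'   `min(1, #\{|d| below the permutation median scatter\} / (G/2))`.
#' @param seed Integer seed for Monte-Carlo permutations.
#' @return A `sam_config` list.
#' @export
sam_config <- function(s0_mode = c("tusher_cv_min", "fixed_percentile"),
                       s0_percentile = 0.5,
                       n_permutations = 500L,
                       balanced = TRUE,
                       pi0 = 1,
                       seed = 1L) {
  s0_mode <- match.arg(s0_mode)
  if (s0_percentile < 0 || s0_percentile > 1) abort("s0_percentile must be in [0, 1]")
  if (!identical(n_permutations, "exhaustive")) {
    n_permutations <- as.integer(n_permutations)
    if (is.na(n_permutations) || n_permutations < 1L) {
      abort("n_permutations must be >= 1 or \"exhaustive\"")
    }
  }
  structure(list(s0_mode = s0_mode, s0_percentile = s0_percentile,
                 n_permutations = n_permutations, balanced = balanced,
                 pi0 = pi0, seed = as.integer(seed)),
            class = "sam_config")
}

check_classes <- function(expr, class1, class2) {
  ids <- sample_cols(expr)
  bad <- setdiff(c(class1, class2), ids)
  if (length(bad)) {
    abort(sprintf("sample id(s) not in expression matrix: %s",
                  paste(bad, collapse = ", ")))
  }
  if (length(intersect(class1, class2))) {
    abort(sprintf("classes overlap: %s",
                  paste(intersect(class1, class2), collapse = ", ")))
  }
  if (length(class1) < 2L || length(class2) < 2L) {
    abort("each class needs at least 2 samples")
  }
  invisible(TRUE)
}

# d, s, fc for one class assignment; x is the genes x samples matrix
sam_stat <- function(x, idx1, idx2, s0) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(x[, idx1, drop = FALSE])
  m2 <- rowMeans(x[, idx2, drop = FALSE])
  ss1 <- rowSums((x[, idx1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, idx2, drop = FALSE] - m2)^2)
  s <- sqrt(((1 / n1 + 1 / n2) / (n1 + n2 - 2)) * (ss1 + ss2))
  list(d = (m2 - m1) / (s + s0), s = s, diff = m2 - m1)
}

# Tusher-style s0: candidate percentiles of s, minimize CV of window MADs of d
choose_s0 <- function(diff, s, cfg) {
  if (cfg$s0_mode == "fixed_percentile") {
    return(unname(quantile(s, cfg$s0_percentile)))
  }
  cand <- unique(unname(quantile(s, seq(0, 1, by = 0.05))))
  qs <- unique(unname(quantile(s, seq(0, 1, by = 0.01))))
  windows <- cut(s, breaks = unique(c(-Inf, qs, Inf)))
  cvs <- vapply(cand, function(a) {
    d <- diff / (s + a)
    v <- tapply(d, windows, mad)
    v <- v[is.finite(v) & !is.na(v)]
    if (length(v) < 2L || mean(v) == 0) return(Inf)
    sd(v) / mean(v)
  }, numeric(1))
  if (all(!is.finite(cvs))) return(unname(quantile(s, cfg$s0_percentile)))
  cand[which.min(cvs)]
}

new_sam_result <- function(tab, cfg, class1, class2, s0, extra = list()) {
  structure(tab, class = c("sam_result", class(tab)),
            config = cfg, class1 = class1, class2 = class2, s0 = s0,
            extra = extra)
}

#' SAM scores for a two-class comparison
#'
#' Computes, per gene, the SAM moderated difference statistic
#' `d = (mean2 - mean1) / (s + s0)` with the two-sample pooled scatter
#' `s = sqrt(((1/n1 + 1/n2) / (n1 + n2 - 2)) * (SS1 + SS2))`, and the
#' linear-scale fold change `fc = 2^(mean2 - mean1)` (class 2 over class 1).
#' Multi-genotype classes are supported by pooling their sample ids (the
#' "multi-way" arrangement: one hairless class against the pooled hairy
#' lines).
#'
#' @param expr Expression tibble (log2 values).
#' @param class1,class2 Disjoint character vectors of sample ids, each of
#'   size >= 2.
#' @param config A [sam_config()].
#' @param s0 Optional fixed s0 overriding the configured selection rule
#'   (e.g. `0` for the raw pooled statistic).
#' @return A `sam_result` tibble: `gene_id`, `d`, `s`, `fc`.
#' @export
sam_scores <- function(expr, class1, class2, config = sam_config(), s0 = NULL) {
  validate_expression(expr)
  check_classes(expr, class1, class2)
  x <- expr_matrix(expr)
  raw <- sam_stat(x, match(class1, colnames(x)), match(class2, colnames(x)), 0)
  if (is.null(s0)) s0 <- choose_s0(raw$diff, raw$s, config)
  st <- list(d = raw$diff / (raw$s + s0), s = raw$s)
  new_sam_result(
    tibble(gene_id = expr$gene_id, d = unname(st$d), s = unname(st$s),
           fc = unname(2^raw$diff)),
    config, class1, class2, s0
  )
}

#' Per-gene linear fold change between two classes
#'
#' `2^(mean2 - mean1)`, i.e. the linear-scale expression ratio of class 2
#' over class 1 (the orientation used for hairy-over-hairless ratios).
#'
#' @inheritParams sam_scores
#' @return Tibble: `gene_id`, `fc`.
#' @export
fold_change <- function(expr, class1, class2) {
  validate_expression(expr)
  check_classes(expr, class1, class2)
  x <- expr_matrix(expr)
  m1 <- rowMeans(x[, class1, drop = FALSE])
  m2 <- rowMeans(x[, class2, drop = FALSE])
  tibble(gene_id = expr$gene_id, fc = unname(2^(m2 - m1)))
}

# all (or sampled) splits of the pooled samples into pseudo-classes; returns a
# list of integer index vectors (positions of pseudo-class1 within the pool)
permutation_splits <- function(n1, n2, cfg) {
  n <- n1 + n2
  balanced_ok <- cfg$balanced && n1 %% 2L == 0L && n2 %% 2L == 0L &&
    n2 >= n1 / 2L && n1 >= n1 / 2L
  if (balanced_ok) {
    h <- n1 %/% 2L
    total <- choose(n1, h) * choose(n2, h)
    exhaustive <- identical(cfg$n_permutations, "exhaustive") ||
      total <= cfg$n_permutations
    if (exhaustive) {
      a <- combn(seq_len(n1), h, simplify = FALSE)
      b <- combn(n1 + seq_len(n2), h, simplify = FALSE)
      return(unlist(lapply(a, function(i) lapply(b, function(j) c(i, j))),
                    recursive = FALSE))
    }
    return(lapply(seq_len(cfg$n_permutations), function(k) {
      c(sample(seq_len(n1), h), sample(n1 + seq_len(n2), h))
    }))
  }
  total <- choose(n, n1)
  exhaustive <- identical(cfg$n_permutations, "exhaustive") ||
    total <= cfg$n_permutations
  if (exhaustive) return(combn(n, n1, simplify = FALSE))
  lapply(seq_len(cfg$n_permutations), function(k) sample(n, n1))
}

#' SAM with permutation-based FDR q-values
#'
#' Extends [sam_scores()] with a permutation estimate of the false discovery
#' rate. Class labels are reassigned over the pooled samples (balanced
#' reassignments when both class sizes are even; exhaustive enumeration when
#' the number of splits is within the configured budget), d is recomputed for
#' each split with the same s0, and for each cutoff `c = |d(i)|` the FDR is
#' estimated as `pi0 * median_b #\{|d*_b| >= c\} / #\{|d| >= c\}`. The
#' q-value of gene i is the minimum estimated FDR over all cutoffs at which
#' the gene is called (`c <= |d(i)|`), clipped to `[0, 1]`; q is therefore
#' monotone non-increasing in `|d|`.
#'
#' @inheritParams sam_scores
#' @return A `sam_result` tibble: `gene_id`, `d`, `s`, `fc`, `q`.
#' @export
estimate_fdr <- function(expr, class1, class2, config = sam_config(), s0 = NULL) {
  res <- sam_scores(expr, class1, class2, config, s0)
  s0 <- attr(res, "s0")
  x <- expr_matrix(expr)
  pool <- c(class1, class2)
  n1 <- length(class1)
  set.seed(config$seed)
  splits <- permutation_splits(n1, length(class2), config)
  if (!length(splits)) abort("no permutations possible for these class sizes")
  xp <- x[, pool, drop = FALSE]
  dperm <- vapply(splits, function(i1) {
    sam_stat(xp, i1, setdiff(seq_along(pool), i1), s0)$d
  }, numeric(nrow(xp)))
  res$q <- sam_qvalues(res$d, dperm, config$pi0)
  attr(res, "extra") <- list(n_perm = length(splits))
  res
}

sam_qvalues <- function(d, dperm, pi0 = 1) {
  absd <- abs(d)
  abspm <- abs(dperm)
  B <- ncol(dperm)
  G <- length(d)
  if (identical(pi0, "estimate")) {
    qlim <- quantile(abspm, 0.5)
    pi0 <- min(1, sum(absd <= qlim) / (0.5 * G))
  }
  ord <- order(absd, decreasing = TRUE)
  cuts <- absd[ord]
  # per-permutation exceedance counts at each cutoff, then the median
  med_false <- vapply(seq_along(cuts), function(k) {
    median(colSums(abspm >= cuts[k]))
  }, numeric(1))
  n_called <- seq_along(cuts)  # #{|d| >= cutoff} in sorted order
  fdr <- pmin(1, pi0 * med_false / n_called)
  q_sorted <- rev(cummin(rev(fdr)))  # min over less-stringent cutoffs
  q <- numeric(G)
  q[ord] <- q_sorted
  q
}
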