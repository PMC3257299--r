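# Shared fixtures and independent oracles used across the suite.

# small expression tibble: genes x samples matrix -> tidy table
make_expr <- function(m, genes = sprintf("g%02d", seq_len(nrow(m))),
                      samples = sprintf("s%02d", seq_len(ncol(m)))) {
  colnames(m) <- samples
  dplyr::bind_cols(tibble::tibble(gene_id = genes),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

# wrap a raw state matrix as a discrete_dataset (FREE gene nodes by default)
make_dataset <- function(states, arity = NULL, clamped = NULL, nodes = NULL) {
  ids <- rownames(states)
  if (is.null(nodes)) {
    nodes <- hairnet::node_specs(ids, gene_arity = if (is.null(arity)) max(states) + 1L else arity)
  }
  if (is.null(clamped)) {
    clamped <- matrix(FALSE, nrow(states), ncol(states), dimnames = dimnames(states))
  }
  structure(list(nodes = nodes, states = states, clamped = clamped,
                 sample_ids = colnames(states)),
            class = "discrete_dataset")
}

# brute-force SAM d statistic (independent of the package implementation)
oracle_d <- function(x1, x2, s0 = 0) {
  n1 <- length(x1); n2 <- length(x2)
  sp <- sqrt(((1 / n1 + 1 / n2) / (n1 + n2 - 2)) *
               (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)))
  (mean(x2) - mean(x1)) / (sp + s0)
}

# brute-force exhaustive-permutation q-values for a genes x samples matrix,
# written as plain loops; pi0 = 1, all label splits of size n1
oracle_sam_q <- function(m, idx1, idx2, s0) {
  pool <- c(idx1, idx2)
  n1 <- length(idx1)
  d_obs <- apply(m, 1L, function(v) oracle_d(v[idx1], v[idx2], s0))
  splits <- utils::combn(length(pool), n1, simplify = FALSE)
  dperm <- sapply(splits, function(i1) {
    apply(m[, pool, drop = FALSE], 1L, function(v) {
      oracle_d(v[i1], v[-i1], s0)
    })
  })
  ord <- order(abs(d_obs), decreasing = TRUE)
  fdr <- numeric(length(d_obs))
  for (k in seq_along(ord)) {
    cutoff <- abs(d_obs)[ord[k]]
    counts <- apply(abs(dperm), 2L, function(col) sum(col >= cutoff))
    fdr[k] <- min(1, stats::median(counts) / k)
  }
  q_sorted <- rev(cummin(rev(fdr)))
  q <- numeric(length(d_obs))
  q[ord] <- q_sorted
  q
}

# enumerate all DAGs on n labelled nodes (543 for n = 4, 25 for n = 3) as
# two-column edge data frames
enumerate_dags <- function(n) {
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  m <- nrow(pairs)
  out <- list()
  for (code in 0:(2^m - 1)) {
    sel <- which(bitwAnd(code, 2^(0:(m - 1))) > 0)
    e <- pairs[sel, , drop = FALSE]
    g <- igraph::make_graph(rbind(e$from, e$to), n = n, directed = TRUE)
    if (igraph::is_dag(g)) out[[length(out) + 1L]] <- e
  }
  out
}

# best score over an enumerated DAG space via the package's scorer
oracle_best_score <- function(dags, dd) {
  ids <- rownames(dd$states)
  max(vapply(dags, function(e) {
    edges <- tibble::tibble(from = ids[e$from], to = ids[e$to])
    hairnet::score_network(edges, dd)
  }, numeric(1)))
}

# default study shared by the heavier pipeline tests (computed once per run)
cached_study <- local({
  env <- new.env()
  function() {
    if (is.null(env$study)) {
      truth <- hairnet::default_truth(seed = 1)
      env$study <- hairnet::simulate_dataset(truth)
    }
    env$study
  }
})

study_nodes <- function() {
  hairnet::node_specs(sprintf("G%02d", 1:15), c("IAA", "ACC"),
                      c("HAIR_LENGTH", "BRANCHING"))
}

delta_profiles <- function() {
  # six triplets of noise-free profiles peaking at sections 1,3,5,7,9,11
  peaks <- rep(c(1, 3, 5, 7, 9, 11), each = 3)
  m <- t(vapply(seq_along(peaks), function(i) {
    prof <- exp(-(1:12 - peaks[i])^2 / 2) + 0.001 * i  # distinct rows
    rep(prof, 2)
  }, numeric(24)))
  make_expr(m, genes = sprintf("gene%02d", seq_along(peaks)),
            samples = c(sprintf("r1_s%02d", 1:12), sprintf("r2_s%02d", 1:12)))
}
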