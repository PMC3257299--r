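#' Node specifications for network learning
#'
#' Builds the node table for the discrete Bayesian network: genes carry three
#' expression states (low / medium / high), hormone nodes two states and are
#' constrained to be parents only (`ROOT_ONLY`), the hair-length phenotype
#' four states and the branching phenotype two states, both constrained to be
#' children only (`LEAF_ONLY`).
#'
#' @param genes Character vector of gene node ids.
#' @param hormones Character vector of hormone node ids (matched against the
#'   sample sheet's `treatment`).
#' @param phenotypes Character vector of phenotype node ids; an id containing
#'   `"LENGTH"` gets arity 4, others arity 2.
#' @param gene_arity States per gene node (default 3).
#' @return Tibble: `node_id`, `kind`, `arity`, `role`.
#' @export
node_specs <- function(genes, hormones = character(0),
                       phenotypes = character(0), gene_arity = 3L) {
  ph_arity <- ifelse(grepl("LENGTH", phenotypes), 4L, 2L)
  tibble(
    node_id = c(genes, hormones, phenotypes),
    kind = c(rep("GENE", length(genes)), rep("HORMONE", length(hormones)),
             rep("PHENOTYPE", length(phenotypes))),
    arity = c(rep(as.integer(gene_arity), length(genes)),
              rep(2L, length(hormones)), ph_arity),
    role = c(rep("FREE", length(genes)), rep("ROOT_ONLY", length(hormones)),
             rep("LEAF_ONLY", length(phenotypes)))
  )
}

# equal-frequency binning; ties broken by stable rank (earlier samples take
# the lower state); a constant vector collapses to state 0
equal_freq_states <- function(x, arity) {
  if (length(unique(x)) == 1L) return(list(states = rep(0L, length(x)), constant = TRUE))
  r <- rank(x, ties.method = "first")
  list(states = as.integer(floor((r - 1) * arity / length(x))), constant = FALSE)
}

#' Discretize a study into the network learner's input
#'
#' Gene expression is discretized per gene by equal-frequency binning across
#' all samples into the node's arity; hormone node states come from the
#' treatment metadata (active when the sample's treatment names the node);
#' phenotype values are equal-frequency binned (hair length into 4 states,
#' branching into 2). The clamped mask marks, per sample, the genes knocked
#' out in that sample's genotype; clamped cells are forced to state 0.
#'
#' @param expr Expression tibble.
#' @param samples Sample tibble (`sample_id`, `genotype`, `treatment`, ...).
#' @param nodes Node table from [node_specs()].
#' @param phenotypes Optional tibble `sample_id`, `hair_length_um`,
#'   `branching_frac` (required when phenotype nodes are declared).
#' @return A `discrete_dataset`: list with `nodes`, `states` (nodes x
#'   samples, 0-based), `clamped` (same shape), `sample_ids`.
#' @export
discretize_dataset <- function(expr, samples, nodes, phenotypes = NULL) {
  validate_expression(expr)
  validate_samples(samples)
  gene_nodes <- nodes$node_id[nodes$kind == "GENE"]
  missing <- setdiff(gene_nodes, expr$gene_id)
  if (length(missing)) {
    abort(sprintf("gene node(s) missing from expression matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  ids <- samples$sample_id
  x <- expr_matrix(expr)[, ids, drop = FALSE]
  n <- nrow(nodes)
  states <- matrix(0L, n, length(ids), dimnames = list(nodes$node_id, ids))
  clamped <- matrix(FALSE, n, length(ids), dimnames = dimnames(states))
  constant <- character(0)
  for (g in gene_nodes) {
    eb <- equal_freq_states(x[g, ], nodes$arity[nodes$node_id == g])
    if (eb$constant) constant <- c(constant, g)
    states[g, ] <- eb$states
  }
  if (length(constant)) {
    warn(sprintf("constant gene(s) discretized to a single state: %s",
                 paste(constant, collapse = ", ")))
  }
  for (h in nodes$node_id[nodes$kind == "HORMONE"]) {
    states[h, ] <- as.integer(samples$treatment == h)
  }
  ph <- nodes$node_id[nodes$kind == "PHENOTYPE"]
  if (length(ph)) {
    if (is.null(phenotypes)) abort("phenotype nodes declared but no phenotype values given")
    pv <- phenotypes[match(ids, phenotypes$sample_id), ]
    for (p in ph) {
      col <- if (grepl("LENGTH", p)) "hair_length_um" else "branching_frac"
      states[p, ] <- equal_freq_states(pv[[col]],
                                       nodes$arity[nodes$node_id == p])$states
    }
  }
  for (i in seq_along(ids)) {
    ko <- intersect(samples$genotype[[i]], nodes$node_id)
    if (length(ko)) {
      clamped[ko, i] <- TRUE
      states[ko, i] <- 0L
    }
  }
  structure(list(nodes = nodes, states = states, clamped = clamped,
                 sample_ids = ids),
            class = "discrete_dataset")
}

#' @export
print.discrete_dataset <- function(x, ...) {
  cat(sprintf("<discrete_dataset> %d nodes x %d samples (%d clamped cells)\n",
              nrow(x$states), ncol(x$states), sum(x$clamped)))
  invisible(x)
}

#' Scoring configuration
#'
#' @param ess Equivalent sample size of the BDeu prior (dimensionless,
#'   default 1).
#' @param max_in_degree Maximum number of parents per node (default 4).
#' @param structure_prior Structure prior; only `"UNIFORM"` is implemented.
#' @return A `score_config` list.
#' @export
score_config <- function(ess = 1.0, max_in_degree = 4L,
                         structure_prior = "UNIFORM") {
  if (ess <= 0) abort("ess must be positive")
  if (max_in_degree < 0L) abort("max_in_degree must be >= 0")
  structure_prior <- match.arg(structure_prior, "UNIFORM")
  structure(list(ess = ess, max_in_degree = as.integer(max_in_degree),
                 structure_prior = structure_prior), class = "score_config")
}

#' Search configuration
#'
#' @param strategy `"greedy"`, `"sa"`, or `"greedy_plus_sa"` (greedy descent
#'   to a local optimum, a simulated-annealing walk, then a final greedy
#'   polish).
#' @param restarts Number of random restarts (the first start is the empty
#'   graph).
#' @param sa_initial_temp Initial temperature; `NA` self-scales from the
#'   spread of 100 random-move score deltas.
#' @param sa_cooling Geometric cooling factor in (0, 1).
#' @param moves_per_temp Proposed moves per temperature.
#' @param n_temps Number of temperature steps.
#' @param top_k Capacity of the top-scoring structure list.
#' @param seed Integer seed.
#' @return A `search_config` list.
#' @export
search_config <- function(strategy = c("greedy_plus_sa", "greedy", "sa"),
                          restarts = 10L, sa_initial_temp = NA_real_,
                          sa_cooling = 0.95, moves_per_temp = 100L,
                          n_temps = 60L, top_k = 1000L, seed = 1L) {
  strategy <- match.arg(strategy)
  if (top_k < 1L) abort("top_k must be >= 1")
  if (sa_cooling <= 0 || sa_cooling >= 1) abort("sa_cooling must be in (0, 1)")
  structure(list(strategy = strategy, restarts = as.integer(restarts),
                 sa_initial_temp = sa_initial_temp, sa_cooling = sa_cooling,
                 moves_per_temp = as.integer(moves_per_temp),
                 n_temps = as.integer(n_temps), top_k = as.integer(top_k),
                 seed = as.integer(seed)), class = "search_config")
}

#' BDeu family score of one node given a parent set
#'
#' Log marginal likelihood of the node's conditional multinomial under a
#' symmetric Dirichlet prior with hyperparameters `ess / (q * r)` per cell
#' (q parent configurations, r node states), computed only over samples in
#' which the node is not clamped by a knockout.
#'
#' @param node Node id.
#' @param parents Character vector of parent node ids (possibly empty).
#' @param data A `discrete_dataset`.
#' @param config A [score_config()].
#' @return Log score (a single real).
#' @export
bdeu_family_score <- function(node, parents, data, config = score_config()) {
  idx <- match(node, rownames(data$states))
  if (is.na(idx)) abort(sprintf("unknown node '%s'", node))
  pidx <- match(parents, rownames(data$states))
  if (anyNA(pidx)) abort("unknown parent node")
  if (node %in% parents) abort("a node cannot be its own parent")
  if (length(parents) > config$max_in_degree) {
    abort(sprintf("parent set exceeds max in-degree %d", config$max_in_degree))
  }
  cpp_family_score(data$states, data$clamped, data$nodes$arity,
                   idx, pidx, config$ess)
}

dag_edge_matrix <- function(dag) {
  if (is.data.frame(dag)) {
    as.matrix(dag[c("from", "to")])
  } else if (is.matrix(dag)) {
    `colnames<-`(dag[, 1:2, drop = FALSE], c("from", "to"))
  } else {
    abort("dag must be a data frame or matrix with from/to columns")
  }
}

check_dag <- function(edges, nodes, config) {
  if (nrow(edges)) {
    bad <- setdiff(c(edges[, 1], edges[, 2]), nodes$node_id)
    if (length(bad)) abort(sprintf("unknown node(s): %s", paste(bad, collapse = ", ")))
    g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = TRUE,
                                       vertices = nodes$node_id)
    if (!igraph::is_dag(g)) abort("structure contains a directed cycle")
    role <- setNames(nodes$role, nodes$node_id)
    if (any(role[edges[, 1]] == "LEAF_ONLY")) {
      abort("a LEAF_ONLY (phenotype) node cannot be a parent")
    }
    if (any(role[edges[, 2]] == "ROOT_ONLY")) {
      abort("a ROOT_ONLY (hormone) node cannot be a child")
    }
    indeg <- table(edges[, 2])
    if (any(indeg > config$max_in_degree)) {
      abort(sprintf("in-degree exceeds max %d", config$max_in_degree))
    }
  }
  invisible(TRUE)
}

#' Total BDeu score of a structure
#'
#' Sum of [bdeu_family_score()] over all nodes; the score is exactly
#' decomposable into its family terms.
#'
#' @param dag Edge table (`from`, `to`) or two-column matrix; must be acyclic
#'   and role-consistent.
#' @param data A `discrete_dataset`.
#' @param config A [score_config()].
#' @return Total log score.
#' @export
score_network <- function(dag, data, config = score_config()) {
  edges <- dag_edge_matrix(dag)
  check_dag(edges, data$nodes, config)
  sum(vapply(data$nodes$node_id, function(v) {
    bdeu_family_score(v, edges[edges[, 2] == v, 1], data, config)
  }, numeric(1)))
}

#' Learn high-scoring network structures
#'
#' Hill-climbing over add / delete / reverse edge moves (rejecting cycles,
#' role violations and in-degree overflow), with optional simulated-annealing
#' walks accepting worsening moves with Metropolis probability under
#' geometric cooling. Every structure evaluated during the search is offered
#' to a capacity-bounded, deduplicated list of the top-scoring structures.
#' Deterministic given the seed.
#'
#' @param data A `discrete_dataset`.
#' @param score_cfg A [score_config()].
#' @param search_cfg A [search_config()].
#' @return A `bn_topk` object: list with `scores` (decreasing), `structures`
#'   (list of edge tibbles), `nodes`, and the two configs.
#' @export
learn_structures <- function(data, score_cfg = score_config(),
                             search_cfg = search_config()) {
  if (!nrow(data$states)) abort("zero nodes")
  role_code <- c(FREE = 0L, ROOT_ONLY = 1L, LEAF_ONLY = 2L)[data$nodes$role]
  set.seed(search_cfg$seed)
  res <- cpp_learn(
    data$states, data$clamped, data$nodes$arity, unname(role_code),
    score_cfg$ess, score_cfg$max_in_degree, search_cfg$strategy,
    search_cfg$restarts,
    ifelse(is.na(search_cfg$sa_initial_temp), -1, search_cfg$sa_initial_temp),
    search_cfg$sa_cooling, search_cfg$moves_per_temp, search_cfg$n_temps,
    search_cfg$top_k
  )
  ids <- data$nodes$node_id
  structures <- lapply(res$structures, function(m) {
    tibble(from = ids[m[, 1]], to = ids[m[, 2]])
  })
  structure(list(scores = res$scores, structures = structures,
                 nodes = data$nodes, score_config = score_cfg,
                 search_config = search_cfg),
            class = "bn_topk")
}

#' @export
print.bn_topk <- function(x, ...) {
  cat(sprintf("<bn_topk> %d structures; best score %.4f; worst kept %.4f\n",
              length(x$scores), max(x$scores), min(x$scores)))
  invisible(x)
}

#' Consensus network over the top-scoring structures
#'
#' A directed edge enters the consensus when it appears in at least a
#' fraction `f` of the retained top-scoring structures; its support fraction
#' is recorded. Edge signs are annotated from the Spearman correlation of the
#' two nodes' states over unclamped samples when a dataset is supplied.
#' Cycles in the consensus union are permitted (it is a composite of DAGs,
#' not itself a DAG) but reported via a message.
#'
#' @param topk A `bn_topk` from [learn_structures()].
#' @param f Support threshold in (0, 1] (default 0.40).
#' @param data Optional `discrete_dataset` used to annotate edge signs.
#' @return A `consensus_network` edge tibble (`from`, `to`, `support`,
#'   `sign`) with attributes `f` and `n_structures`.
#' @export
consensus_network <- function(topk, f = 0.40, data = NULL) {
  if (!inherits(topk, "bn_topk") || !length(topk$structures)) {
    abort("topk must be a nonempty bn_topk")
  }
  if (f <= 0 || f > 1) abort("f must be in (0, 1]")
  k <- length(topk$structures)
  all_edges <- dplyr::bind_rows(topk$structures)
  if (nrow(all_edges)) {
    counts <- all_edges %>%
      dplyr::count(.data$from, .data$to, name = "n_support") %>%
      dplyr::mutate(support = .data$n_support / k) %>%
      dplyr::filter(.data$support + 1e-12 >= f) %>%
      dplyr::arrange(dplyr::desc(.data$support), .data$from, .data$to)
  } else {
    counts <- tibble(from = character(0), to = character(0),
                     n_support = integer(0), support = numeric(0))
  }
  sign <- rep(NA_character_, nrow(counts))
  if (!is.null(data) && nrow(counts)) {
    for (i in seq_len(nrow(counts))) {
      u <- data$states[counts$from[i], ]
      v <- data$states[counts$to[i], ]
      keep <- !data$clamped[counts$from[i], ] & !data$clamped[counts$to[i], ]
      if (sum(keep) > 2L) {
        r <- suppressWarnings(cor(u[keep], v[keep], method = "spearman"))
        if (is.finite(r) && abs(r) > 1e-8) sign[i] <- if (r > 0) "POS" else "NEG"
      }
    }
  }
  out <- tibble(from = counts$from, to = counts$to,
                support = counts$support, sign = sign)
  if (nrow(out)) {
    g <- igraph::graph_from_data_frame(out[c("from", "to")], directed = TRUE)
    if (!igraph::is_dag(g)) {
      message("consensus union contains directed cycles (composite network)")
    }
  }
  structure(out, class = c("consensus_network", class(out)),
            f = f, n_structures = k)
}
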