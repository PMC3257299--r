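#' Generate a random ground-truth regulatory network
#'
#' Samples a directed acyclic graph over gene, hormone, and phenotype nodes
#' together with everything needed to simulate expression data from it:
#' conditional probability tables (CPTs), a states-to-log2-expression map,
#' noise and site-batch parameters, knockout-line definitions, and a
#' developmental zone per gene. Hormone nodes never receive edges and
#' phenotype nodes never emit them; each phenotype node gets one designated
#' "driver" gene parent (taken out of the `n_edges` budget).
#'
#' @param n_genes Number of gene nodes (ids `G01`, `G02`, ...).
#' @param n_edges Total edge budget (phenotype driver edges first, remainder
#'   gene-to-gene). Must be feasible for an acyclic graph.
#' @param n_hormones Number of hormone nodes (first two named `IAA`, `ACC`).
#' @param n_phenotypes Number of phenotype nodes (first two named
#'   `HAIR_LENGTH`, 4 states, and `BRANCHING`, 2 states).
#' @param seed Integer seed; identical seeds give identical truths.
#' @param dirichlet_alpha Concentration of the symmetric Dirichlet from which
#'   CPT rows are drawn.
#' @param n_background Number of background (chip-only) genes outside the
#'   network; they receive independent marginal states and a zone, so the
#'   expression table resembles a chip on which most genes are not part of
#'   the pathway.
#' @return A `synthetic_truth` object: a list with `nodes`, `edges` (with
#'   regulatory `sign`), `cpts`, `state_means`, `state_sd`, `site_shift`,
#'   `knockout_lines`, `zone_of`, `drivers`, `hormone_model`,
#'   `phenotype_model`, and `seed`.
#' @export
generate_truth <- function(n_genes, n_edges, n_hormones = 2L, n_phenotypes = 2L,
                           seed = 1L, dirichlet_alpha = 1, n_background = 0L) {
  if (n_genes < 1L) abort("need at least one gene node")
  max_gg <- n_genes * (n_genes - 1L) / 2L
  n_driver <- min(n_phenotypes, n_edges)
  if (n_edges - n_driver > max_gg) {
    abort(sprintf("edge count %d infeasible: at most %d gene-gene edges plus %d driver edges",
                  n_edges, max_gg, n_phenotypes))
  }
  if (n_driver > 0L && n_driver < n_phenotypes) {
    abort("edge budget must cover either all phenotype driver edges or none")
  }
  set.seed(seed)
  genes <- sprintf("G%02d", seq_len(n_genes))
  hormones <- head(c("IAA", "ACC", sprintf("H%02d", seq_len(max(0L, n_hormones)))), n_hormones)
  phen_names <- head(c("HAIR_LENGTH", "BRANCHING",
                       sprintf("P%02d", seq_len(max(0L, n_phenotypes)))), n_phenotypes)
  phen_arity <- ifelse(phen_names == "HAIR_LENGTH", 4L, 2L)

  ord <- sample(genes)  # topological order
  edges <- tibble(from = character(0), to = character(0), sign = integer(0))
  if (n_driver > 0L) {
    drivers <- head(rev(ord), n_phenotypes)  # late genes drive phenotypes
    edges <- dplyr::bind_rows(edges, tibble(
      from = drivers, to = phen_names, sign = -1L
    ))
  } else {
    drivers <- character(0)
  }
  n_gg <- n_edges - n_driver
  if (n_gg > 0L) {
    pairs <- which(upper.tri(matrix(0, n_genes, n_genes)), arr.ind = TRUE)
    pick <- pairs[sample(nrow(pairs), n_gg), , drop = FALSE]
    edges <- dplyr::bind_rows(tibble(
      from = ord[pick[, "row"]], to = ord[pick[, "col"]],
      sign = sample(c(1L, -1L), n_gg, replace = TRUE)
    ), edges)
  }

  nodes <- tibble(
    node_id = c(genes, hormones, phen_names),
    kind = c(rep("GENE", n_genes), rep("HORMONE", length(hormones)),
             rep("PHENOTYPE", length(phen_names))),
    arity = c(rep(3L, n_genes), rep(2L, length(hormones)), phen_arity),
    role = c(rep("FREE", n_genes), rep("ROOT_ONLY", length(hormones)),
             rep("LEAF_ONLY", length(phen_names)))
  )

  cpts <- lapply(setNames(genes, genes), function(g) {
    pa <- edges$from[edges$to == g & edges$from %in% genes]
    q <- prod(c(1L, nodes$arity[match(pa, nodes$node_id)]))
    probs <- matrix(stats::rgamma(q * 3L, shape = dirichlet_alpha), nrow = q)
    probs <- probs / rowSums(probs)
    list(parents = pa, probs = probs)
  })

  drv <- list(
    hair_length = edges$from[edges$to == "HAIR_LENGTH"][1],
    branching = edges$from[edges$to == "BRANCHING"][1]
  )

  background <- if (n_background > 0L) sprintf("N%03d", seq_len(n_background)) else character(0)
  all_genes <- c(genes, background)
  structure(list(
    nodes = nodes,
    edges = edges,
    cpts = cpts,
    background_genes = background,
    background_levels = setNames(
      sample.int(3L, length(background), replace = TRUE,
                 prob = c(0.2, 0.3, 0.5)) - 1L, background),
    state_means = matrix(c(6, 9, 12), nrow = length(all_genes), ncol = 3,
                         byrow = TRUE, dimnames = list(all_genes, NULL)),
    state_sd = 0.5,
    site_shift = 0.3,
    knockout_lines = setNames(as.list(genes), paste0("ko_", genes)),
    zone_of = setNames(sample(rep(1:6, length.out = length(all_genes))), all_genes),
    drivers = drv,
    hormone_model = NULL,
    phenotype_model = default_phenotype_model(),
    seed = seed
  ), class = "synthetic_truth")
}

default_phenotype_model <- function() {
  list(length_baseline = 400, length_slope = 120, length_sd = 12,
       branch_floor = 0.06, branch_range = 0.24, branch_sd = 0.02)
}

#' The default ground truth behind the simulated study
#'
#' A hand-wired 15-gene network emulating the root-epidermis fate pathway:
#' upstream activators (`G05`, `G04` -> `G03` -> `G01`) and lateral
#' inhibitors (`G06` repressing `G01`) converge on the fate hub `G01`, which
#' activates a non-hair branch (`G12`, `G13`) and represses a hair-morphogenesis
#' cascade (`G08` -> `G09` -> `G14`, `G08` -> `G10`); `G11 -> G15` is an
#' independent decoy module. `G14` drives the hair-length phenotype and `G10`
#' the branching phenotype, both inversely. The four foundational knockout
#' lines clamp `{G01,G02}`, `{G03,G04}`, `{G05}`, `{G06,G07}` (7 foundational
#' knocked-out genes); thirteen further single-knockout lines cover every gene
#' except the redundant partners `G02` and `G07`. The hormone model rescues
#' the hair cascade (`G09`, `G10`, `G14`) in the `G08`-knockout background.
#'
#' In addition to the 15 network genes, the chip carries `n_background`
#' pathway-independent background genes (`N001`, ...) with marginal state
#' distributions, for 208 genes in all by default.
#'
#' @param seed Integer seed stored in the truth (used by the simulators and
#'   for the background-gene zone draw).
#' @param n_background Number of background genes (default 193).
#' @return A `synthetic_truth` object.
#' @export
default_truth <- function(seed = 1L, n_background = 193L,
                          fidelity_sat = 0.96, fidelity_mid = 0.85) {
  genes <- sprintf("G%02d", 1:15)
  edges <- tibble(
    from = c("G05", "G03", "G06", "G01", "G01", "G01",
             "G08", "G08", "G09", "G11", "G14", "G10"),
    to   = c("G03", "G01", "G01", "G12", "G13", "G08",
             "G09", "G10", "G14", "G15", "HAIR_LENGTH", "BRANCHING"),
    sign = c(1L, 1L, -1L, 1L, 1L, -1L, 1L, 1L, 1L, 1L, -1L, -1L)
  )
  nodes <- tibble(
    node_id = c(genes, "IAA", "ACC", "HAIR_LENGTH", "BRANCHING"),
    kind = c(rep("GENE", 15), "HORMONE", "HORMONE", "PHENOTYPE", "PHENOTYPE"),
    arity = c(rep(3L, 15), 2L, 2L, 4L, 2L),
    role = c(rep("FREE", 15), "ROOT_ONLY", "ROOT_ONLY", "LEAF_ONLY", "LEAF_ONLY")
  )
  # stochastic deviations reach adjacent states only: biological replicate
  # noise perturbs expression by one level, never a low-to-high jump.
  # Saturated targets (full activation/repression) are canalized and less
  # noisy than intermediate ones.
  state_row <- function(tgt) {
    fidelity <- if (tgt == 1L) fidelity_mid else fidelity_sat
    p <- c(0, 0, 0)
    adj <- intersect(tgt + c(-1L, 1L), 0:2)
    p[tgt + 1L] <- fidelity
    p[adj + 1L] <- (1 - fidelity) / length(adj)
    p
  }
  # regulators are ON in unperturbed tissue, with sparse one-level off-states
  root_probs <- matrix(state_row(2L), nrow = 1)
  # G03's activators are jointly required co-factors (AND); elsewhere parent
  # contributions average (the fate hub integrates activation and inhibition)
  combine_rule <- c(G03 = "min")
  cpts <- lapply(setNames(genes, genes), function(g) {
    sel <- edges$to == g
    pa <- edges$from[sel]
    sg <- edges$sign[sel]
    if (!length(pa)) return(list(parents = character(0), probs = root_probs))
    ar <- rep(3L, length(pa))
    q <- prod(ar)
    comb <- if (!is.na(combine_rule[g])) combine_rule[[g]] else "mean"
    probs <- matrix(0, nrow = q, ncol = 3)
    for (j in seq_len(q)) {
      cfg <- config_states(j - 1L, ar)
      eff <- ifelse(sg > 0, cfg, 2L - cfg)
      tgt <- if (comb == "min") min(eff) else floor(mean(eff) + 0.5)
      probs[j, ] <- state_row(tgt)
    }
    list(parents = pa, probs = probs)
  })
  singles <- setdiff(genes, c("G02", "G07"))
  ko <- c(
    list(hairy_wm = c("G01", "G02"), hairy_ge = c("G03", "G04"),
         hairy_t = "G05", hairless_ct = c("G06", "G07")),
    setNames(as.list(singles), paste0("ko_", singles))
  )
  zones <- c(G05 = 1L, G06 = 1L, G04 = 2L, G07 = 2L, G03 = 2L, G02 = 3L,
             G01 = 3L, G12 = 3L, G13 = 4L, G08 = 4L, G09 = 5L, G10 = 5L,
             G11 = 5L, G14 = 6L, G15 = 6L)
  set.seed(seed)
  background <- if (n_background > 0L) sprintf("N%03d", seq_len(n_background)) else character(0)
  bg_zones <- setNames(sample(rep(1:6, length.out = length(background))), background)
  bg_levels <- setNames(
    sample.int(3L, length(background), replace = TRUE,
               prob = c(0.2, 0.3, 0.5)) - 1L, background)
  all_genes <- c(genes, background)
  structure(list(
    nodes = nodes,
    edges = edges,
    cpts = cpts,
    background_genes = background,
    background_levels = bg_levels,
    state_means = matrix(c(6, 9, 12), nrow = length(all_genes), ncol = 3,
                         byrow = TRUE, dimnames = list(all_genes, NULL)),
    state_sd = 0.5,
    site_shift = 0.3,
    knockout_lines = ko,
    zone_of = c(zones[genes], bg_zones),
    drivers = list(hair_length = "G14", branching = "G10"),
    hormone_model = list(background = "G08",
                         targets = c("G09", "G10", "G14"), prob = 0.9),
    phenotype_model = default_phenotype_model(),
    seed = seed
  ), class = "synthetic_truth")
}

# decode a 0-based mixed-radix parent-configuration index (first parent fastest)
config_states <- function(j, arities) {
  out <- integer(length(arities))
  for (i in seq_along(arities)) {
    out[i] <- j %% arities[i]
    j <- j %/% arities[i]
  }
  out
}

truth_gene_ids <- function(truth) truth$nodes$node_id[truth$nodes$kind == "GENE"]

truth_topo_order <- function(truth) {
  genes <- truth_gene_ids(truth)
  gg <- truth$edges[truth$edges$from %in% genes & truth$edges$to %in% genes, ]
  g <- igraph::graph_from_data_frame(gg[c("from", "to")], directed = TRUE,
                                     vertices = genes)
  if (!igraph::is_dag(g)) abort("truth graph contains a cycle")
  names(igraph::topo_sort(g, mode = "out"))
}

#' Draw gene states ancestrally from a truth network
#'
#' Knocked-out genes are clamped to state 0 and excluded from ancestral
#' sampling (intervention semantics); all other genes are drawn from their
#' CPT given sampled parent states. When the truth carries a hormone model
#' and the genotype matches its designated background, an active hormone
#' treatment overrides the target genes to their top state with the model's
#' probability.
#'
#' @param truth A `synthetic_truth`.
#' @param n Number of independent samples to draw.
#' @param genotype Character vector of knocked-out genes (empty = wild type).
#' @param treatment One of `NONE`, `MS`, `IAA`, `ACC`.
#' @return Integer matrix (genes x n) of 0-based states, with a `clamped`
#'   attribute (logical matrix of the same shape).
#' @export
simulate_states <- function(truth, n, genotype = character(0),
                            treatment = "NONE") {
  genes <- truth_gene_ids(truth)
  # genotype entries that are not truth nodes are external knockouts: legal,
  # but without effect on the simulated states
  ord <- truth_topo_order(truth)
  states <- matrix(0L, nrow = length(genes), ncol = n,
                   dimnames = list(genes, NULL))
  clamped <- matrix(FALSE, nrow = length(genes), ncol = n,
                    dimnames = list(genes, NULL))
  for (g in ord) {
    if (g %in% genotype) {
      clamped[g, ] <- TRUE
      next  # stays 0: clamp, not a draw
    }
    cpt <- truth$cpts[[g]]
    if (!length(cpt$parents)) {
      p <- cpt$probs[1L, ]
      states[g, ] <- sample.int(length(p), n, replace = TRUE, prob = p) - 1L
    } else {
      ar <- rep(3L, length(cpt$parents))
      idx <- rep(1L, n)
      mult <- 1L
      for (i in seq_along(cpt$parents)) {
        idx <- idx + states[cpt$parents[i], ] * mult
        mult <- mult * ar[i]
      }
      for (j in unique(idx)) {
        cols <- which(idx == j)
        p <- cpt$probs[j, ]
        states[g, cols] <- sample.int(length(p), length(cols),
                                      replace = TRUE, prob = p) - 1L
      }
    }
  }
  hm <- truth$hormone_model
  if (!is.null(hm) && treatment %in% c("IAA", "ACC") &&
      setequal(genotype, hm$background)) {
    for (g in intersect(hm$targets, genes)) {
      hit <- runif(n) < hm$prob
      states[g, hit] <- 2L
    }
  }
  attr(states, "clamped") <- clamped
  states
}

#' Build the default study design
#'
#' Expands a truth's knockout lines into the sample layout of the learning
#' study: the four foundational lines profiled at both sites in triplicate
#' (24 arrays), fourteen further lines (wild type + thirteen single
#' knockouts) at one site in triplicate (42 arrays; 66 learning samples in
#' all), plus a hormone-transfer block (the hormone-model background genotype
#' under MS, IAA and ACC, in triplicate) excluded from network learning.
#'
#' @param truth A `synthetic_truth` whose `knockout_lines` include the four
#'   foundational lines (`hairy_wm`, `hairy_ge`, `hairy_t`, `hairless_ct`).
#' @return A design tibble with one row per sample: `sample_id`, `line_id`,
#'   `genotype` (list column), `site`, `replicate`, `treatment`, `learning`.
#' @export
default_design <- function(truth) {
  foundational <- c("hairy_wm", "hairy_ge", "hairy_t", "hairless_ct")
  if (!all(foundational %in% names(truth$knockout_lines))) {
    abort("truth lacks the four foundational knockout lines")
  }
  extras <- c("WT", setdiff(names(truth$knockout_lines), foundational))
  rows <- list()
  for (ln in foundational) {
    for (site in c("SITE_A", "SITE_B")) {
      for (r in 1:3) {
        rows[[length(rows) + 1L]] <- tibble(
          line_id = ln, genotype = list(truth$knockout_lines[[ln]]),
          site = site, replicate = r, treatment = "NONE", learning = TRUE
        )
      }
    }
  }
  for (ln in extras) {
    geno <- if (ln == "WT") character(0) else truth$knockout_lines[[ln]]
    for (r in 1:3) {
      rows[[length(rows) + 1L]] <- tibble(
        line_id = ln, genotype = list(geno), site = "SITE_A",
        replicate = r, treatment = "NONE", learning = TRUE
      )
    }
  }
  if (!is.null(truth$hormone_model)) {
    for (tr in c("MS", "IAA", "ACC")) {
      for (r in 1:3) {
        rows[[length(rows) + 1L]] <- tibble(
          line_id = "hormone_bg", genotype = list(truth$hormone_model$background),
          site = "SITE_A", replicate = r, treatment = tr, learning = FALSE
        )
      }
    }
  }
  design <- dplyr::bind_rows(rows)
  design$sample_id <- sprintf(
    "%s_%s_r%d%s", design$line_id, sub("SITE_", "", design$site),
    design$replicate,
    ifelse(design$treatment == "NONE", "", paste0("_", design$treatment))
  )
  design[c("sample_id", "line_id", "genotype", "site", "replicate",
           "treatment", "learning")]
}

#' Bookkeeping counts of a study design
#'
#' @param design Design tibble from [default_design()].
#' @return One-row tibble: total samples, learning samples, foundational
#'   arrays (both-site lines), distinct lines, knockout lines, and distinct
#'   knocked-out genes.
#' @export
design_counts <- function(design) {
  per_line <- design %>%
    dplyr::filter(.data$learning) %>%
    dplyr::group_by(.data$line_id) %>%
    dplyr::summarise(n_sites = dplyr::n_distinct(.data$site),
                     n = dplyr::n(), .groups = "drop")
  ko_lines <- design %>%
    dplyr::filter(.data$learning) %>%
    dplyr::distinct(.data$line_id, .keep_all = TRUE)
  tibble(
    n_samples = nrow(design),
    n_learning = sum(design$learning),
    n_foundational_arrays = sum(per_line$n[per_line$n_sites == 2L]),
    n_lines = nrow(per_line),
    n_knockout_lines = sum(lengths(ko_lines$genotype) > 0L),
    n_knockout_genes = dplyr::n_distinct(unlist(ko_lines$genotype))
  )
}

#' Simulate a full study from a ground-truth network
#'
#' Draws, per sample of the design, node states ancestrally from the truth's
#' CPTs (knocked-out nodes clamped to state 0, hormone treatments applied),
#' maps states to log2 expression (`state_mean + site_shift + N(0, state_sd)`),
#' generates per-line phenotype values from the designated driver genes
#' (inversely: higher driver state, shorter hairs / less branching), and
#' simulates longitudinal-section profiles from the truth's zone map.
#'
#' @param truth A `synthetic_truth`.
#' @param design Design tibble (default [default_design()]).
#' @param seed Integer seed; defaults to the truth's seed. Identical seeds
#'   give identical studies.
#' @return A `simulated_study`: list with `expression` (tibble), `samples`
#'   (sample sheet tibble incl. `line_id` and `learning`), `phenotypes`
#'   (per sample: `hair_length_um`, `branching_frac`), `sections`
#'   (genes x 24 profile tibble), `states`, `clamped`, and `truth`.
#' @export
simulate_dataset <- function(truth, design = default_design(truth),
                             seed = truth$seed, resid_coupling = 0.7) {
  unknown <- setdiff(unlist(design$genotype), truth$nodes$node_id)
  ext_flagged <- attr(design, "external_ok", exact = TRUE)
  if (length(unknown) && is.null(ext_flagged)) {
    abort(sprintf("design references unknown node(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  if (any(design$replicate < 1L)) abort("replicate counts must be >= 1")
  set.seed(seed)
  genes <- truth_gene_ids(truth)
  background <- truth$background_genes
  all_genes <- c(genes, background)
  n <- nrow(design)
  states <- matrix(0L, length(genes), n, dimnames = list(genes, design$sample_id))
  clamped <- matrix(FALSE, length(genes), n, dimnames = dimnames(states))
  for (i in seq_len(n)) {
    st <- simulate_states(truth, 1L, genotype = design$genotype[[i]],
                          treatment = design$treatment[i])
    states[, i] <- st[, 1L]
    clamped[, i] <- attr(st, "clamped")[, 1L]
  }
  all_states <- states
  if (length(background)) {
    # background genes sit at a fixed per-gene expression level (clean nulls)
    bg <- matrix(truth$background_levels[background], length(background), n,
                 dimnames = list(background, design$sample_id))
    all_states <- rbind(states, bg)
  }
  # Within-state fluctuations transmit dose-dependently along regulatory
  # edges (children inherit a share of their parents' expression residual,
  # sign-flipped under repression); each gene's marginal noise SD stays at
  # state_sd. Background genes fluctuate independently.
  beta <- resid_coupling
  eps <- matrix(rnorm(length(all_genes) * n, 0, truth$state_sd),
                length(all_genes), n, dimnames = list(all_genes, NULL))
  noise <- eps
  for (g in truth_topo_order(truth)) {
    sel <- truth$edges$to == g & truth$edges$from %in% genes
    pa <- truth$edges$from[sel]
    if (!length(pa)) next
    sg <- truth$edges$sign[sel]
    inp <- colMeans(noise[pa, , drop = FALSE] * sg)
    noise[g, ] <- (eps[g, ] + beta * inp) / sqrt(1 + beta^2 / length(pa))
  }
  shift <- ifelse(design$site == "SITE_B", truth$site_shift, 0)
  vals <- truth$state_means[cbind(rep(seq_along(all_genes), n),
                                  as.vector(all_states) + 1L)]
  vals <- matrix(vals, length(all_genes), n) + noise +
    matrix(shift, length(all_genes), n, byrow = TRUE)
  expression <- dplyr::bind_cols(
    tibble(gene_id = all_genes),
    as_tibble(`colnames<-`(vals, design$sample_id), .name_repair = "minimal")
  )

  # phenotypes are measured per replicate and track the driver gene's actual
  # state in that sample: hair length decreases linearly with the driver
  # state (inverse, dose-dependent); branching is a threshold response,
  # active whenever the driver is below full expression
  pm <- truth$phenotype_model
  d_len <- states[truth$drivers$hair_length, ]
  d_br <- states[truth$drivers$branching, ]
  phenotypes <- tibble(
    sample_id = design$sample_id,
    line_id = design$line_id,
    hair_length_um = pm$length_baseline - pm$length_slope * d_len +
      rnorm(n, 0, pm$length_sd),
    branching_frac = pmin(1, pmax(0, pm$branch_floor +
                                    pm$branch_range * (d_br <= 1L) +
                                    rnorm(n, 0, pm$branch_sd)))
  )

  samples <- design[c("sample_id", "genotype", "site", "replicate",
                      "treatment", "line_id", "learning")]
  sections <- simulate_section_profiles(truth, seed = (seed + 10007L) %% .Machine$integer.max)

  structure(list(
    expression = expression,
    samples = samples,
    phenotypes = phenotypes,
    sections = sections,
    states = states,
    clamped = clamped,
    truth = truth
  ), class = "simulated_study")
}

#' Simulate longitudinal-section expression profiles
#'
#' Each gene receives a unimodal profile over 24 ordered columns (two roots,
#' sections 1-12 each, concatenated in developmental order) peaking in the
#' two-section band of its developmental zone (zone z spans sections
#' 2z-1..2z), plus Gaussian measurement noise.
#'
#' @param truth A `synthetic_truth` with `zone_of` defined for every gene.
#' @param seed Integer seed.
#' @param noise_sd Per-measurement noise SD (log2 units).
#' @param amplitude Peak height above baseline (log2 units).
#' @param base Baseline log2 expression.
#' @param width Gaussian peak width in section units.
#' @return Tibble: `gene_id` plus 24 numeric columns `r1_s01..r1_s12`,
#'   `r2_s01..r2_s12`.
#' @export
simulate_section_profiles <- function(truth, seed = truth$seed,
                                      noise_sd = 0.15, amplitude = 4,
                                      base = 5, width = 1.2) {
  genes <- c(truth_gene_ids(truth), truth$background_genes)
  if (!all(genes %in% names(truth$zone_of))) {
    abort("zone_of must be defined for every gene")
  }
  set.seed(seed)
  secs <- 1:12
  prof <- t(vapply(genes, function(g) {
    center <- 2 * truth$zone_of[[g]] - 0.5
    shape <- base + amplitude * exp(-(secs - center)^2 / (2 * width^2))
    rep(shape, 2) + rnorm(24, 0, noise_sd)
  }, numeric(24)))
  colnames(prof) <- c(sprintf("r1_s%02d", secs), sprintf("r2_s%02d", secs))
  dplyr::bind_cols(tibble(gene_id = genes),
                   as_tibble(prof, .name_repair = "minimal"))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d genes, %d hormones, %d phenotypes; %d edges; seed %d\n",
    sum(x$nodes$kind == "GENE"), sum(x$nodes$kind == "HORMONE"),
    sum(x$nodes$kind == "PHENOTYPE"), nrow(x$edges), x$seed
  ))
  invisible(x)
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study> %d genes x %d samples (%d learning), %d lines\n",
    nrow(x$expression), nrow(x$samples), sum(x$samples$learning),
    dplyr::n_distinct(x$samples$line_id)
  ))
  invisible(x)
}
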