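test_that("generate_truth is deterministic and respects edge budgets", {
  t1 <- generate_truth(n_genes = 10, n_edges = 12, seed = 7)
  t2 <- generate_truth(n_genes = 10, n_edges = 12, seed = 7)
  expect_identical(t1, t2)  # determinism contract

  t0 <- generate_truth(n_genes = 6, n_edges = 0, seed = 3)
  expect_equal(nrow(t0$edges), 0L)  # all nodes parentless
  expect_true(all(vapply(t0$cpts, function(c) length(c$parents) == 0, logical(1))))

  expect_error(generate_truth(n_genes = 4, n_edges = 50, seed = 1), "infeasible")
})

test_that("generated truths are acyclic with role-consistent special nodes", {
  for (seed in c(7, 19, 101)) {
    tr <- generate_truth(n_genes = 15, n_edges = 20, seed = seed)
    g <- igraph::graph_from_data_frame(tr$edges[c("from", "to")],
                                       directed = TRUE,
                                       vertices = tr$nodes$node_id)
    expect_true(igraph::is_dag(g))  # cycle-detection oracle
    phen <- tr$nodes$node_id[tr$nodes$kind == "PHENOTYPE"]
    horm <- tr$nodes$node_id[tr$nodes$kind == "HORMONE"]
    expect_false(any(tr$edges$from %in% phen))  # phenotypes are sinks
    expect_false(any(tr$edges$to %in% horm))    # hormones are sources
    # CPT rows are distributions
    for (cpt in tr$cpts) expect_equal(rowSums(cpt$probs), rep(1, nrow(cpt$probs)),
                                      tolerance = 1e-12)
  }
})

test_that("same seed reproduces the full simulated study byte for byte", {
  tr <- default_truth(seed = 5, n_background = 10)
  s1 <- simulate_dataset(tr)
  s2 <- simulate_dataset(tr)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$sections, s2$sections)
})

test_that("zero noise collapses expression onto the state means", {
  tr <- default_truth(seed = 2, n_background = 5)
  tr$state_sd <- 0
  tr$site_shift <- 0
  study <- simulate_dataset(tr)
  x <- expr_matrix(study$expression)
  means <- tr$state_means
  states <- rbind(study$states,
                  matrix(tr$background_levels, length(tr$background_genes),
                         ncol(x), dimnames = list(tr$background_genes, NULL)))
  expected <- matrix(means[cbind(rep(seq_len(nrow(x)), ncol(x)),
                                 as.vector(states) + 1L)], nrow(x), ncol(x))
  expect_equal(unname(x), expected, tolerance = 1e-12)
})

test_that("knocked-out nodes are clamped to state zero in every sample", {
  study <- cached_study()
  sm <- study$samples
  for (i in seq_len(nrow(sm))) {
    ko <- intersect(sm$genotype[[i]], rownames(study$states))
    if (length(ko)) {
      expect_true(all(study$states[ko, sm$sample_id[i]] == 0L))
      expect_true(all(study$clamped[ko, sm$sample_id[i]]))
    }
  }
  # clamped state frequency is exactly 100% state 0 in the knockout's line
  g5 <- sm$sample_id[vapply(sm$genotype, function(g) "G05" %in% g, logical(1))]
  expect_true(all(study$states["G05", g5] == 0L))
})

test_that("root-node state frequencies match the CPT at large n", {
  tr <- default_truth(seed = 9, n_background = 0)
  set.seed(31)
  st <- simulate_states(tr, 10000)
  for (g in c("G05", "G06", "G11")) {  # parentless regulators
    freq <- tabulate(st[g, ] + 1L, nbins = 3) / 10000
    expect_true(all(abs(freq - tr$cpts[[g]]$probs[1, ]) < 0.02))
  }
})

test_that("the default design reproduces the learning-study bookkeeping", {
  tr <- default_truth(seed = 1)
  design <- default_design(tr)
  counts <- design_counts(design)
  expect_equal(counts$n_learning, 66L)       # published learning-sample count
  expect_equal(counts$n_samples, 75L)        # + hormone-transfer block
  expect_equal(counts$n_foundational_arrays, 24L)
  expect_equal(counts$n_lines, 18L)          # WT + 17 knockout lines
  expect_equal(counts$n_knockout_lines, 17L)
  foundational_genes <- unique(unlist(tr$knockout_lines[
    c("hairy_wm", "hairy_ge", "hairy_t", "hairless_ct")]))
  expect_equal(length(foundational_genes), 7L)
  expect_error(simulate_dataset(tr, dplyr::mutate(design, genotype = list("NOPE"))),
               "unknown node")
})

test_that("section profiles peak inside the zone band and sort by zone", {
  tr <- default_truth(seed = 4, n_background = 0)
  prof <- simulate_section_profiles(tr, seed = 8, noise_sd = 0)
  m <- as.matrix(prof[-1])
  peaks <- apply(m[, 1:12], 1, which.max)
  zones <- tr$zone_of[prof$gene_id]
  expect_true(all(peaks >= 2 * zones - 1 & peaks <= 2 * zones))
  # all six bands recoverable by argmax sort
  expect_equal(sort(unique(ceiling(peaks / 2))), 1:6)
  expect_identical(prof, simulate_section_profiles(tr, seed = 8, noise_sd = 0))
})

test_that("hormone treatment rescues the hair genes in the mutant background", {
  tr <- default_truth(seed = 6, n_background = 0)
  set.seed(12)
  st <- simulate_states(tr, 400, genotype = "G08", treatment = "IAA")
  # targets overridden upward with the configured probability
  for (g in tr$hormone_model$targets) {
    expect_gt(mean(st[g, ] == 2L), 0.8)
  }
  # no override outside the designated background
  set.seed(12)
  st_wt <- simulate_states(tr, 400, genotype = character(0), treatment = "IAA")
  expect_lt(mean(st_wt["G14", ] == 2L), 0.5)
})
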