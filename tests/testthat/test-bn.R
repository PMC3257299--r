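test_that("equal-frequency discretization follows the rank-tertile oracle", {
  expr <- make_expr(matrix(c(9:1, rep(5, 9)), nrow = 2, byrow = TRUE),
                    samples = paste0("s", 1:9))
  samples <- tibble::tibble(sample_id = paste0("s", 1:9),
                            genotype = rep(list(character(0)), 9),
                            site = "SITE_A", replicate = 1:9, treatment = "NONE")
  nodes <- node_specs(c("g01", "g02"))
  expect_warning(dd <- discretize_dataset(expr, samples, nodes), "constant")
  # values 9..1 -> ranks reversed -> states (2,2,2,1,1,1,0,0,0)
  expect_equal(unname(dd$states["g01", ]), c(2L, 2L, 2L, 1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(unname(dd$states["g02", ]), rep(0L, 9))  # constant gene
})

test_that("knockouts fill the clamp mask and force state zero", {
  expr <- make_expr(matrix(rnorm(18, 8), nrow = 2), genes = c("g01", "g02"),
                    samples = paste0("s", 1:9))
  samples <- tibble::tibble(sample_id = paste0("s", 1:9),
                            genotype = c(rep(list("g02"), 3),
                                         rep(list(character(0)), 6)),
                            site = "SITE_A", replicate = 1:9, treatment = "NONE")
  dd <- discretize_dataset(expr, samples, node_specs(c("g01", "g02")))
  expect_true(all(dd$clamped["g02", 1:3]))
  expect_true(all(dd$states["g02", 1:3] == 0L))
  expect_false(any(dd$clamped["g01", ]))
  expect_error(discretize_dataset(expr, samples, node_specs(c("g01", "g03"))),
               "g03")
})

test_that("the BDeu family score equals its closed-form Gamma-ratio values", {
  dd <- make_dataset(matrix(c(0L, 0L, 1L, 1L), 1,
                            dimnames = list("X", paste0("s", 1:4))), arity = 2)
  # Gamma(1)/Gamma(5) * (Gamma(2.5)/Gamma(0.5))^2 = 3/128
  expect_equal(bdeu_family_score("X", character(0), dd), log(3 / 128),
               tolerance = 1e-9)
  dd1 <- make_dataset(matrix(0L, 1, 1, dimnames = list("X", "s1")), arity = 2)
  expect_equal(bdeu_family_score("X", character(0), dd1), -log(2),
               tolerance = 1e-12)  # uniform predictive on one observation
  expect_error(bdeu_family_score("X", "X", dd), "own parent")
})

test_that("a node clamped everywhere scores identically for all parent sets", {
  st <- rbind(X = c(0L, 1L, 2L, 1L, 0L, 2L), Y = c(0L, 0L, 1L, 1L, 2L, 2L))
  colnames(st) <- paste0("s", 1:6)
  cl <- rbind(X = rep(TRUE, 6), Y = rep(FALSE, 6))
  dimnames(cl) <- dimnames(st)
  dd <- make_dataset(st, arity = 3, clamped = cl)
  s_empty <- bdeu_family_score("X", character(0), dd)
  expect_equal(bdeu_family_score("X", "Y", dd), s_empty, tolerance = 1e-12)
  expect_equal(s_empty, 0)  # empty-data score
  # hence adding an edge into X never changes a network's total score
  base <- score_network(tibble::tibble(from = character(0), to = character(0)), dd)
  withY <- score_network(tibble::tibble(from = "Y", to = "X"), dd)
  expect_equal(withY, base, tolerance = 1e-12)
})

test_that("network scores decompose exactly into family scores", {
  set.seed(13)
  st <- matrix(sample(0:2, 30, TRUE), 3, 10,
               dimnames = list(c("A", "B", "C"), paste0("s", 1:10)))
  dd <- make_dataset(st, arity = 3)
  empty <- score_network(tibble::tibble(from = character(0), to = character(0)), dd)
  expect_equal(empty, sum(vapply(c("A", "B", "C"), bdeu_family_score,
                                 numeric(1), parents = character(0), data = dd)),
               tolerance = 1e-12)
  dag <- tibble::tibble(from = c("A", "A"), to = c("B", "C"))
  expect_equal(score_network(dag, dd),
               bdeu_family_score("A", character(0), dd) +
                 bdeu_family_score("B", "A", dd) +
                 bdeu_family_score("C", "A", dd), tolerance = 1e-12)
  expect_error(score_network(tibble::tibble(from = c("A", "B"), to = c("B", "A")), dd),
               "cycle")
})

test_that("interventions orient edges; observational data is score-equivalent", {
  set.seed(7)
  n <- 200
  x <- sample(0:2, n, TRUE)
  clampx <- rep(c(TRUE, FALSE), c(50, 150))
  x[clampx] <- 0L
  y <- ifelse(runif(n) < 0.9, x, sample(0:2, n, TRUE))
  st <- rbind(X = x, Y = as.integer(y))
  colnames(st) <- paste0("s", 1:n)
  cl <- rbind(X = clampx, Y = rep(FALSE, n))
  dimnames(cl) <- dimnames(st)
  dd <- make_dataset(st, arity = 3, clamped = cl)
  xy <- score_network(tibble::tibble(from = "X", to = "Y"), dd)
  yx <- score_network(tibble::tibble(from = "Y", to = "X"), dd)
  expect_gt(xy - yx, 5)  # clamping breaks the equivalence in favour of X -> Y
  ddo <- dd
  ddo$clamped[] <- FALSE
  xyo <- score_network(tibble::tibble(from = "X", to = "Y"), ddo)
  yxo <- score_network(tibble::tibble(from = "Y", to = "X"), ddo)
  expect_equal(xyo, yxo, tolerance = 1e-8)  # BDeu score equivalence
})

test_that("search recovers the exhaustive optimum on a 3-node space", {
  set.seed(17)
  n <- 60
  a <- sample(0:1, n, TRUE)
  b <- ifelse(runif(n) < 0.85, a, 1L - a)
  c_ <- sample(0:1, n, TRUE)
  st <- rbind(A = a, B = as.integer(b), C = c_)
  colnames(st) <- paste0("s", 1:n)
  dd <- make_dataset(st, arity = 2)
  dags <- enumerate_dags(3)
  expect_length(dags, 25L)
  best <- oracle_best_score(dags, dd)
  topk <- learn_structures(dd, score_config(),
                           search_config(restarts = 10, top_k = 5, seed = 2))
  expect_equal(max(topk$scores), best, tolerance = 1e-9)
})

test_that("role constraints hold in every returned structure", {
  set.seed(23)
  st <- rbind(G = sample(0:2, 40, TRUE), H = sample(0:1, 40, TRUE),
              P = sample(0:1, 40, TRUE))
  colnames(st) <- paste0("s", 1:40)
  nodes <- tibble::tibble(node_id = c("G", "H", "P"),
                          kind = c("GENE", "HORMONE", "PHENOTYPE"),
                          arity = c(3L, 2L, 2L),
                          role = c("FREE", "ROOT_ONLY", "LEAF_ONLY"))
  dd <- make_dataset(st, nodes = nodes)
  topk <- learn_structures(dd, score_config(),
                           search_config(restarts = 10, top_k = 200, seed = 3))
  for (s in topk$structures) {
    expect_false("P" %in% s$from)  # phenotype never a source
    expect_false("H" %in% s$to)    # hormone never a target
  }
  expect_error(score_network(tibble::tibble(from = "P", to = "G"), dd), "LEAF_ONLY")
  expect_error(score_network(tibble::tibble(from = "G", to = "H"), dd), "ROOT_ONLY")
})

test_that("repeated runs with one seed are identical and deduplicated", {
  set.seed(29)
  st <- matrix(sample(0:1, 4 * 30, TRUE), 4, 30,
               dimnames = list(paste0("V", 1:4), paste0("s", 1:30)))
  dd <- make_dataset(st, arity = 2)
  t1 <- learn_structures(dd, score_config(), search_config(restarts = 5, top_k = 50, seed = 4))
  t2 <- learn_structures(dd, score_config(), search_config(restarts = 5, top_k = 50, seed = 4))
  expect_identical(t1$scores, t2$scores)
  expect_identical(t1$structures, t2$structures)
  keys <- vapply(t1$structures, function(s) {
    paste(sort(paste(s$from, s$to)), collapse = ";")
  }, character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(diff(t1$scores) <= 1e-12))  # sorted best-first
})

test_that("consensus support counting, limits and monotonicity behave", {
  structures <- list(
    tibble::tibble(from = c("A", "B"), to = c("B", "C")),
    tibble::tibble(from = "A", to = "B"),
    tibble::tibble(from = c("A", "B"), to = c("B", "C")),
    tibble::tibble(from = c("A", "A"), to = c("B", "C")),
    tibble::tibble(from = "B", to = "C")
  )
  topk <- structure(list(scores = rep(0, 5), structures = structures,
                         nodes = node_specs(c("A", "B", "C"))),
                    class = "bn_topk")
  cons <- consensus_network(topk, f = 0.40)
  # B->C appears in 3/5, A->B in 4/5, A->C in 1/5
  expect_equal(cons$support[cons$from == "B" & cons$to == "C"], 0.6)
  expect_false(any(cons$from == "A" & cons$to == "C"))
  # an edge in exactly 2 of 5 structures has support 0.40 and is included
  topk$structures[[4]] <- tibble::tibble(from = "X", to = "Y")
  topk$structures[[5]] <- tibble::tibble(from = "X", to = "Y")
  cons2 <- consensus_network(topk, f = 0.40)
  expect_equal(cons2$support[cons2$from == "X"], 0.4)
  # f = 1 is the intersection; f above every support is empty, not an error
  cons_all <- consensus_network(topk, f = 1)
  expect_equal(nrow(cons_all), 0L)
  expect_equal(nrow(consensus_network(topk, f = 0.99)), 0L)
  # monotone: smaller f keeps a superset of edges
  e30 <- with(consensus_network(topk, f = 0.30), paste(from, to))
  e60 <- with(consensus_network(topk, f = 0.60), paste(from, to))
  expect_true(all(e60 %in% e30))
  expect_error(consensus_network(structure(list(structures = list()),
                                           class = "bn_topk")), "nonempty")
})
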