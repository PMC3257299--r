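sig_result <- function(genes, fc, q) {
  structure(tibble::tibble(gene_id = genes, d = 0, s = 1, fc = fc, q = q),
            class = c("sam_result", "tbl_df", "tbl", "data.frame"))
}

test_that("perturbation responses follow the fold-change and q gates", {
  genes <- paste0("g", 1:4)
  res <- list(mutA = sig_result(genes, fc = c(3.0, 3.0, 0.4, 1.1),
                                q = c(0.01, 0.2, 0.001, 0.001)))
  sig <- perturbation_signature(res)
  resp <- setNames(sig$response, sig$gene_id)
  expect_equal(unname(resp[c("g1", "g2", "g3", "g4")]),
               c("UP", "NONE", "DOWN", "NONE"))
  # hormone comparisons use the stricter 0.5% FDR gate
  res2 <- list(IAA = sig_result(genes, fc = rep(3, 4),
                                q = c(0.004, 0.04, 0.2, 0.0001)))
  sig2 <- perturbation_signature(res2, hormone_perturbations = "IAA")
  resp2 <- setNames(sig2$response, sig2$gene_id)
  expect_equal(unname(resp2[c("g1", "g2", "g4")]), c("UP", "NONE", "UP"))
  expect_error(perturbation_signature(list(a = sig_result(genes, 1, 1),
                                           b = sig_result(paste0("x", 1:4), 1, 1))),
               "universe")
})

test_that("tightening thresholds never converts NONE to a response", {
  set.seed(8)
  genes <- paste0("g", 1:50)
  res <- list(p = sig_result(genes, fc = 2^runif(50, -3, 3), q = runif(50, 0, 0.1)))
  loose <- perturbation_signature(res, fc_min = 2, q_max = 0.05)
  tight <- perturbation_signature(res, fc_min = 3, q_max = 0.01)
  none_loose <- loose$gene_id[loose$response == "NONE"]
  none_tight <- tight$gene_id[tight$response == "NONE"]
  expect_true(all(none_loose %in% none_tight))
})

test_that("clusters partition genes by exact signature and collapsed zone", {
  sig <- structure(tibble::tibble(
    gene_id = rep(c("a", "b", "c", "d"), each = 2),
    perturbation = rep(c("p1", "p2"), 4),
    response = c("UP", "NONE", "UP", "NONE", "UP", "NONE", "DOWN", "UP")
  ), class = c("perturbation_signature", "tbl_df", "tbl", "data.frame"))
  zones <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                          zone = c(1L, 2L, 5L, 3L),
                          collapsed = NA_character_, peak_section = 1L)
  zones <- collapse_zones(zones)
  cl <- build_clusters(sig, zones)
  ids <- setNames(cl$cluster_id, cl$gene_id)
  expect_equal(ids[["a"]], ids[["b"]])   # same signature, both EARLY
  expect_false(ids[["a"]] == ids[["c"]]) # same signature, EARLY vs LATE
  expect_false(ids[["a"]] == ids[["d"]]) # different signature
  # exact partition of the universe
  expect_setequal(cl$gene_id, c("a", "b", "c", "d"))
  expect_error(build_clusters(sig, zones[1:2, ]), "missing a zone")
})

test_that("the robust flag requires responses in six of nine panel mutants", {
  panel <- paste0("m", 1:9)
  make_sig <- function(n_hit) {
    structure(tibble::tibble(
      gene_id = "g",
      perturbation = panel,
      response = c(rep("UP", n_hit), rep("NONE", 9 - n_hit))
    ), class = c("perturbation_signature", "tbl_df", "tbl", "data.frame"))
  }
  zones <- collapse_zones(tibble::tibble(gene_id = "g", zone = 5L,
                                         collapsed = NA_character_,
                                         peak_section = 9L))
  expect_true(build_clusters(make_sig(6), zones, downstream_panel = panel)$robust)
  expect_false(build_clusters(make_sig(5), zones, downstream_panel = panel)$robust)
})

test_that("genes sharing a truth parent and zone co-cluster on the study", {
  study <- cached_study()
  sams <- perturbation_sams(study, lines = "ko_G01",
                            config = sam_config(seed = 2))
  sig <- perturbation_signature(sams, hormone_perturbations = c("IAA", "ACC"))
  zones <- assign_zones(study$sections)
  cl <- build_clusters(sig, zones)
  ids <- setNames(cl$cluster_id, cl$gene_id)
  # G12 and G13 share the parent G01 in truth and the MID collapsed zone
  expect_equal(ids[["G12"]], ids[["G13"]])
})

test_that("Fisher enrichment equals the hypergeometric tail", {
  universe <- paste0("u", 1:20)
  term <- list(T1 = universe[1:5], T2 = universe)
  selected <- c(universe[1:4], "u10")
  res <- fisher_enrichment(selected, universe, term)
  # P(X >= 4) with 5 draws, 5 annotated of 20 = 76/15504
  expect_equal(res$p_value[res$term == "T1"], 76 / 15504, tolerance = 1e-9)
  oracle <- sum(stats::dhyper(4:5, 5, 15, 5))
  expect_equal(res$p_value[res$term == "T1"], oracle, tolerance = 1e-12)
  # a term covering the whole universe is never enriched
  expect_equal(res$p_value[res$term == "T2"], 1, tolerance = 1e-12)
  # selecting the whole universe is never enriched either
  res_all <- fisher_enrichment(universe, universe, term)
  expect_true(all(res_all$p_value == 1))
  expect_error(fisher_enrichment("u1", character(0), term), "empty")
})

test_that("enrichment matches an independent tail computation on random tables", {
  set.seed(14)
  for (i in 1:100) {
    N <- sample(10:60, 1)
    universe <- paste0("g", seq_len(N))
    k_term <- sample(1:N, 1)
    n_sel <- sample(1:N, 1)
    term <- sample(universe, k_term)
    selected <- sample(universe, n_sel)
    p <- fisher_enrichment(selected, universe, list(t = term))$p_value
    ov <- length(intersect(term, selected))
    oracle <- sum(stats::dhyper(ov:min(k_term, n_sel), k_term, N - k_term, n_sel))
    expect_equal(p, oracle, tolerance = 1e-9)
  }
})

test_that("classical MDS reproduces planar configurations exactly", {
  # samples at mutual distances 3, 4, 5 (right triangle): two genes as axes
  expr <- make_expr(matrix(c(0, 3, 3, 0, 0, 4), nrow = 2, byrow = TRUE),
                    samples = c("A", "B", "C"))
  xy <- classical_mds(expr, dim = 2)
  d <- dist(as.matrix(xy[-1]))
  expect_equal(sort(as.numeric(d)), c(3, 4, 5), tolerance = 1e-9)
  # duplicated sample lands on coincident coordinates
  expr2 <- make_expr(matrix(c(0, 3, 3, 3, 0, 0, 4, 4), nrow = 2, byrow = TRUE),
                     samples = c("A", "B", "C", "C2"))
  xy2 <- classical_mds(expr2, dim = 2)
  expect_equal(unlist(xy2[xy2$sample_id == "C", -1]),
               unlist(xy2[xy2$sample_id == "C2", -1]), tolerance = 1e-9)
  # translation invariance of the embedded shape
  shifted <- expr
  shifted[-1] <- shifted[-1] + 11
  xy3 <- classical_mds(shifted, dim = 2)
  expect_equal(as.numeric(dist(as.matrix(xy3[-1]))), as.numeric(d),
               tolerance = 1e-9)
  expect_error(classical_mds(expr, dim = 3), "eigenvalues|samples")
})

test_that("the promoter scan reports planted motifs at exact offsets", {
  seqs <- Biostrings::DNAStringSet(c(
    gene1 = paste0(strrep("A", 40), "TTGACC", strrep("A", 54)),  # ends -59..-54
    gene2 = strrep("C", 80)
  ))
  hits <- rhe_scan(seqs, "TTGACC", window = 100)
  expect_equal(hits$n_matches[hits$gene_id == "gene1"], 1L)
  expect_equal(hits$positions[hits$gene_id == "gene1"][[1]], -60L)
  expect_equal(hits$n_matches[hits$gene_id == "gene2"], 0L)
  # reverse-strand matches are reported by their plus-strand start
  rc <- Biostrings::DNAStringSet(c(
    g = paste0(strrep("A", 10), "GGTCAA", strrep("A", 4))  # revcomp of TTGACC
  ))
  h2 <- rhe_scan(rc, "TTGACC", window = 20)
  expect_equal(h2$n_matches, 1L)
  expect_equal(h2$strands[[1]], "-")
  expect_equal(h2$positions[[1]], -10L)
  # degenerate consensus "N" matches every position on both strands
  one <- Biostrings::DNAStringSet(c(g = strrep("ACGT", 5)))
  expect_equal(rhe_scan(one, "N", window = 20)$n_matches, 40L)
  # IUPAC ambiguity codes work; invalid characters are rejected
  amb <- rhe_scan(seqs, "TTRACC", window = 100)  # R = A/G
  expect_equal(amb$n_matches[amb$gene_id == "gene1"], 1L)
  expect_error(rhe_scan(seqs, "TTGAXC"), "IUPAC")
})

test_that("scans honour the window and read from FASTA files", {
  seqs <- Biostrings::DNAStringSet(c(
    g = paste0("TTGACC", strrep("A", 100))  # motif outside a 50-nt window
  ))
  expect_equal(rhe_scan(seqs, "TTGACC", window = 50)$n_matches, 0L)
  fa <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(seqs, fa)
  expect_equal(rhe_scan(fa, "TTGACC", window = 200)$n_matches, 1L)
})
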