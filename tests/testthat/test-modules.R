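test_that("disease gene lists load with comments, blanks and duplicates handled", {
  f <- write_lines_tmp(c("# header", "A", "", "B", "B", "C"))
  expect_message(g <- load_disease_genes(f), "1 duplicate")
  expect_equal(g, c("A", "B", "C"))

  expect_equal(load_disease_genes(write_lines_tmp("X")), "X")
  expect_error(load_disease_genes(write_lines_tmp(c("# only", "", "#c"))),
               "empty")
})

test_that("candidate modules are the disease-gene connected components", {
  ctn <- make_net(c("a", "b", "c", "e"), c("b", "c", "d", "f"))
  cand <- candidate_modules(ctn, c("a", "c", "d", "f"), min_module_size = 2)
  expect_equal(cand$t, 4L)
  expect_length(cand$modules, 1L)
  expect_equal(cand$modules[[1]]$genes, c("c", "d"))
  expect_equal(cand$modules[[1]]$size, 2L)
  expect_equal(nrow(cand$modules[[1]]$edges), 1L)

  # min_module_size = 1 also reports the singletons
  cand1 <- candidate_modules(ctn, c("a", "c", "d", "f"), min_module_size = 1)
  expect_length(cand1$modules, 3L)
  expect_equal(vapply(cand1$modules, `[[`, 0L, "size"), c(2L, 1L, 1L))

  # no disease genes in the network: empty result with warning, not an error
  expect_warning(none <- candidate_modules(ctn, c("zz", "yy")), "no disease")
  expect_equal(none$t, 0L)
  expect_length(none$modules, 0L)

  # disease set covering a connected network: one module of size |V|
  tri <- make_net(c("a", "a", "b"), c("b", "c", "c"))
  all_in <- candidate_modules(tri, c("a", "b", "c"))
  expect_length(all_in$modules, 1L)
  expect_equal(all_in$modules[[1]]$size, 3L)
})

test_that("permutation null is exact in the degenerate draws and reproducible", {
  tri <- make_net(c("a", "a", "b"), c("b", "c", "c"))
  # t = |V|: no randomness, S_rand is the largest component size
  expect_true(all(permutation_null(tri, 3, 50, seed = 1)$s_rand == 3L))
  # t = 1: always 1
  expect_true(all(permutation_null(tri, 1, 50, seed = 1)$s_rand == 1L))
  # triangle with t = 2: every pair is adjacent, so S_rand = 2 always
  expect_true(all(permutation_null(tri, 2, 200, seed = 1)$s_rand == 2L))

  # identical seeds reproduce; different seeds differ; caller RNG untouched
  sim <- simulate_network(n_vertices = 60, n_edges = 120, module_size = 0,
                          n_disease_genes = 5, seed = 5)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  n1 <- permutation_null(sim$net, 10, 200, seed = 7)
  expect_identical(runif(1), before)
  n2 <- permutation_null(sim$net, 10, 200, seed = 7)
  n3 <- permutation_null(sim$net, 10, 200, seed = 8)
  expect_identical(n1$s_rand, n2$s_rand)
  expect_false(identical(n1$s_rand, n3$s_rand))

  expect_error(permutation_null(tri, 4, 10, 1), "between 1 and")
  expect_error(permutation_null(tri, 0, 10, 1), "between 1 and")
})

test_that("sampled largest-component sizes agree with igraph on random draws", {
  sim <- simulate_network(n_vertices = 40, n_edges = 90, module_size = 0,
                          n_disease_genes = 5, seed = 13)
  null <- permutation_null(sim$net, 8, 50, seed = 21)
  # replay the identical draws and compare against the igraph route
  replay <- ctsnet:::with_seed(21, {
    vapply(seq_len(50), function(i) {
      vs <- sim$net$vertices[sample.int(40, 8)]
      oracle_lcc(sim$net, vs)
    }, numeric(1))
  })
  expect_equal(as.numeric(null$s_rand), replay)
})

test_that("permutation p-values use a strict tail count", {
  null <- structure(list(t = 5L, s_rand = c(rep(2L, 60), rep(6L, 37),
                                            rep(5L, 3)),
                         n_perm = 100L, seed = 1L),
                    class = "permutation_null")
  expect_equal(permutation_pvalue(5, null), 0.37)
  expect_equal(permutation_pvalue(6, null), 0)       # s_obs >= max
  # ties do not count under the strict inequality
  tie_null <- structure(list(t = 2L, s_rand = rep(4L, 10), n_perm = 10L,
                             seed = 1L), class = "permutation_null")
  expect_equal(permutation_pvalue(4, tie_null), 0)
  # pseudocount estimator never returns 0
  expect_equal(permutation_pvalue(4, tie_null, pseudocount = TRUE), 1 / 11)
  expect_equal(permutation_pvalue(3, tie_null, pseudocount = TRUE), 1)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.05, 4)), rep(0.05, 4))
  for (seed in 1:20) {
    p <- withr::with_seed(seed, runif(sample(1:30, 1))^2)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("identify_modules reports pooled-FDR candidates reproducibly", {
  es <- simulate_expression(n_genes = 300, k = 3, cells_per_type = 30,
                            seed = 31)
  planted <- es$truth$planted_markers$ct1[1:6]
  ns <- simulate_network(n_edges = 700, n_disease_genes = 15, seed = 31,
                         genes = es$expr$genes, planted_genes = planted)
  scores <- suppressMessages(compute_score(compute_specificity(
    mean_by_cell_type(cpm_normalize(es$expr), es$ann))))
  ctns <- lapply(setNames(nm = scores$types), function(ty)
    extract_cell_type_network(ns$net, scores, ty, 0))
  rep1 <- suppressMessages(identify_modules(ctns, ns$disease_genes,
                                            n_perm = 200, seed = 5))
  rep2 <- suppressMessages(identify_modules(ctns, ns$disease_genes,
                                            n_perm = 200, seed = 5))
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))

  expect_true(all(c("cell_type", "module_id", "size", "t", "p_perm", "q_fdr",
                    "significant", "genes") %in% names(rep1)))
  if (nrow(rep1)) {
    # every p is a multiple of 1/n_perm; q >= p; significance is q < cutoff
    expect_true(all(abs(rep1$p_perm * 200 - round(rep1$p_perm * 200)) < 1e-9))
    expect_true(all(rep1$q_fdr >= rep1$p_perm - 1e-12))
    expect_identical(rep1$significant, rep1$q_fdr < 0.1)
    # within a network (shared null), larger modules cannot have larger p
    for (ty in unique(rep1$cell_type)) {
      sub <- rep1[rep1$cell_type == ty, ]
      sub <- sub[order(-sub$size), ]
      expect_true(all(diff(sub$p_perm) >= 0))
    }
  }
  # per-cell-type FDR scope runs and preserves the p-values
  rep3 <- suppressMessages(identify_modules(ctns, ns$disease_genes,
                                            n_perm = 200, seed = 5,
                                            fdr_scope = "per-cell-type"))
  expect_equal(rep3$p_perm, rep1$p_perm)

  # an empty disease list hitting no vertices yields an empty, writable report
  rep0 <- suppressMessages(identify_modules(ctns, c("none1", "none2"),
                                            n_perm = 10, seed = 1))
  expect_equal(nrow(rep0), 0L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_module_report(rep0, f)
  expect_true(file.exists(f))
})

test_that("module reports round-trip to TSV with parameter sidecars", {
  net <- make_net(c("a", "b", "c"), c("b", "c", "d"))
  net$cell_type <- "X"
  class(net) <- c("cell_type_network", class(net))
  rep <- suppressMessages(identify_modules(list(X = net), c("a", "b", "c", "d"),
                                           n_perm = 100, seed = 3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_module_report(rep, f, edges = TRUE)
  back <- utils::read.table(f, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(back$size, rep$size)
  expect_equal(back$genes, rep$genes)
  params <- jsonlite::read_json(paste0(f, ".params.json"))
  expect_equal(params$n_perm, 100L)
  expect_equal(params$seed, 3L)
  edge_file <- paste0(f, ".", rep$module_id[1], ".edges.tsv")
  expect_true(file.exists(edge_file))
  expect_equal(nrow(utils::read.table(edge_file)), 3L)
})
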