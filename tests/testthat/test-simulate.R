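# Rate-matrix construction and the phylogenetic sequence simulator.

test_that("rate matrices have zero row sums, unit stationary rate, and GY94 sparsity", {
  cfg <- model_config("codon", length = 10, kappa = 2, omega_bg = 0.5)
  rm <- build_rate_matrix(cfg)
  expect_lt(max(abs(rowSums(rm$Q))), 1e-10)
  expect_equal(-sum(rm$pi * diag(rm$Q)), 1, tolerance = 1e-12)
  # codons differing at two positions never exchange directly
  expect_equal(rm$Q["AAA", "AGG"], 0)
  expect_equal(rm$Q["TTT", "TCC"], 0)
  # protein mode with uniform pi: all off-diagonal rates equal
  prm <- build_rate_matrix(model_config("protein", length = 10))
  off <- prm$Q[row(prm$Q) != col(prm$Q)]
  expect_equal(max(off) - min(off), 0, tolerance = 1e-14)
  expect_error(model_config("protein", pi = rep(0.1, 20)),
               class = "diveconv_model_error")
})

test_that("transition kernels are row-stochastic and converge to pi", {
  cfg <- model_config("codon", length = 10, kappa = 3, omega_bg = 0.3)
  rm <- build_rate_matrix(cfg)
  for (t in c(0, 0.01, 0.3, 2)) {
    P <- transition_kernel(rm, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
    expect_true(all(P >= 0))
  }
  # long-time limit: every row approaches the stationary distribution
  Pinf <- transition_kernel(rm, 500)
  expect_lt(max(abs(sweep(Pinf, 2, rm$pi, "-"))), 1e-8)
  expect_error(transition_kernel(rm, -1),
               class = "diveconv_branch_length_error")
})

test_that("zero-length branches copy the parent state exactly", {
  tree <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  g <- simulate_gene(tree, model_config("protein", length = 80), seed = 3)
  m <- as.matrix(g$alignment)
  for (i in 2:4) expect_identical(m[i, ], m[1, ])
})

test_that("simulation is deterministic given the seed and varies across seeds", {
  tree <- waterfowl_tree()
  cfg <- model_config("codon", length = 60)
  a <- simulate_gene(tree, cfg, seed = 7)$alignment
  b <- simulate_gene(tree, cfg, seed = 7)$alignment
  c_ <- simulate_gene(tree, cfg, seed = 8)$alignment
  expect_identical(a$seqs, b$seqs)
  expect_false(identical(a$seqs, c_$seqs))
})

test_that("tip residue frequencies match the stationary distribution on a star tree", {
  # long branches decorrelate tips from the root; chi-square GoF at
  # alpha = 0.01 against the configured uniform pi
  star <- ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:5", 1:10), collapse = ","), ");"))
  g <- simulate_gene(star, model_config("protein", length = 1500), seed = 12)
  counts <- table(factor(unlist(strsplit(g$alignment$seqs, "")),
                         levels = c("A", "C", "D", "E", "F", "G", "H", "I",
                                    "K", "L", "M", "N", "P", "Q", "R", "S",
                                    "T", "V", "W", "Y")))
  gof <- stats::chisq.test(as.vector(counts), p = rep(1 / 20, 20))
  expect_gt(gof$p.value, 0.01)
})

test_that("planted columns impose the convergence pattern and plant 0 is a no-op", {
  part <- waterfowl_partition()
  tree <- waterfowl_tree()
  g <- simulate_gene(tree, model_config("protein", length = 120), seed = 2)
  pl <- plant_convergent_sites(g$alignment, part, 5, seed = 9)
  expect_equal(nrow(pl$truth), 5L)
  expect_true(all(pl$truth$bg_residue != pl$truth$fg_residue))
  m <- as.matrix(pl$alignment)
  for (k in seq_len(5)) {
    col <- m[, pl$truth$column[k]]
    expect_true(all(col[part$background] == pl$truth$bg_residue[k]))
    expect_true(all(col[part$foreground] == pl$truth$fg_residue[k]))
  }
  same <- plant_convergent_sites(g$alignment, part, 0, seed = 9)
  expect_identical(same$alignment$seqs, g$alignment$seqs)
  expect_error(plant_convergent_sites(g$alignment, part, 121, seed = 1),
               class = "diveconv_range_error")
})

test_that("codon-mode planting writes sense codons encoding the planted residues", {
  part <- waterfowl_partition()
  tree <- waterfowl_tree()
  g <- simulate_gene(tree, model_config("codon", length = 40,
                                        foreground = part$foreground),
                     seed = 2)
  pl <- plant_convergent_sites(g$alignment, part, 3, seed = 5)
  prot <- translate_alignment(pl$alignment)
  m <- as.matrix(prot)
  for (k in 1:3) {
    col <- m[, pl$truth$column[k]]
    expect_true(all(col[part$background] == pl$truth$bg_residue[k]))
    expect_true(all(col[part$foreground] == pl$truth$fg_residue[k]))
  }
})

test_that("datasets are reproducible, stably identified, and distinct across genes", {
  tree <- waterfowl_tree()
  cfg <- model_config("protein", length = 40)
  d1 <- simulate_dataset(tree, cfg, 5, seed = 33)
  d2 <- simulate_dataset(tree, cfg, 5, seed = 33)
  expect_identical(names(d1), sprintf("g%04d", 1:5))
  expect_identical(lapply(d1, function(g) g$alignment$seqs),
                   lapply(d2, function(g) g$alignment$seqs))
  seqs <- vapply(d1, function(g) paste(g$alignment$seqs, collapse = ""), "")
  expect_equal(anyDuplicated(seqs), 0L)
})
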