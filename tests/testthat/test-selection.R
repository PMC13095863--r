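# Ancestral reconstruction, substitution counting, class omega, the
# permutation null, and the LRT/FDR machinery.

test_that("Fitch reconstruction handles the stated base cases and tie-breaks", {
  tree2 <- ape::read.tree(text = "(a:0.1,b:0.1);")
  aln2 <- toy_alignment(c(a = "AAA", b = "AAG"), "g2",
                        seq_type = "nucleotide")
  anc <- fitch_ancestral_codons(aln2, tree2)
  expect_equal(unname(anc["node3", 1]), "AAA")  # lexicographic tie-break

  tree4 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  same <- toy_alignment(c(a = "ATG", b = "ATG", c = "ATG", d = "ATG"),
                        "g4", seq_type = "nucleotide")
  anc4 <- fitch_ancestral_codons(same, tree4)
  expect_true(all(anc4 == "ATG"))

  gapped <- toy_alignment(c(a = "AT-", b = "ATG", c = "ATG", d = "ATG"),
                          "g4", seq_type = "nucleotide")
  expect_error(fitch_ancestral_codons(gapped, tree4),
               class = "diveconv_gap_error")
})

test_that("Fitch change counts match the exhaustive minimisation oracle on small trees", {
  trees <- list(
    ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);"),
    ape::read.tree(text = "(((a:1,b:1):1,c:1):1,(d:1,e:1):1);"),
    ape::read.tree(text = "((a:1,(b:1,c:1):1):1,((d:1,e:1):1,f:1):1);"))
  codon_states <- c("AAA", "AAG", "AAC")
  set.seed(31)
  for (tree in trees) {
    tips <- tree$tip.label
    for (rep in 1:15) {
      tip_states <- setNames(sample(codon_states, length(tips),
                                    replace = TRUE), tips)
      aln <- toy_alignment(as.list(tip_states), "g",
                           seq_type = "nucleotide")
      anc <- fitch_ancestral_codons(aln, tree)
      idx <- attr(anc, "index")
      changes <- sum(idx[tree$edge[, 1]] != idx[tree$edge[, 2]])
      expect_equal(changes, oracle_parsimony_score(tree, tip_states))
    }
  }
})

test_that("site counting matches hand enumeration of single-nt neighbours", {
  tt <- ng_site_counts("TTT")
  expect_equal(unname(tt["S"]), 1 / 3)
  expect_equal(unname(tt["N"]), 8 / 3)
  atg <- ng_site_counts("ATG")
  expect_equal(unname(atg["S"]), 0)
  # conservation: N + S = 3 * codons - stop-excluded fraction
  set.seed(5)
  codons <- sample(sense_codons(), 30, replace = TRUE)
  ns <- ng_site_counts(codons)
  stops_excluded <- sum(vapply(codons, function(cd) {
    nb <- 0L
    sp <- strsplit(cd, "")[[1]]
    for (pos in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), sp[pos])) {
      alt <- sp
      alt[pos] <- nt
      if (paste(alt, collapse = "") %in% c("TAA", "TAG", "TGA")) nb <- nb + 1L
    }
    nb
  }, integer(1))) / 3
  expect_equal(unname(ns["N"] + ns["S"]), 3 * 30 - stops_excluded)
  expect_error(ng_site_counts("TAA"),
               class = "diveconv_internal_stop_error")
})

test_that("pathway counting conserves path length and classifies steps correctly", {
  expect_equal(count_branch_changes("AAA", "AAA"), c(nd = 0, sd = 0))
  expect_equal(count_branch_changes("TTT", "TTC"), c(nd = 0, sd = 1))
  # Phe->Leu two-position change: both stop-free pathways give one
  # synonymous and one nonsynonymous step
  expect_equal(count_branch_changes("TTT", "CTC"), c(nd = 1, sd = 1))
  # pathway length conservation over random pairs
  set.seed(13)
  for (rep in 1:50) {
    pair <- sample(sense_codons(), 2)
    k <- sum(strsplit(pair[1], "")[[1]] != strsplit(pair[2], "")[[1]])
    expect_equal(unname(sum(count_branch_changes(pair[1], pair[2]))), k)
  }
})

test_that("class omegas are undefined on invariant data and recover simulated regimes", {
  tree <- toy_tree5()
  part <- toy_partition(2, 3)
  invariant <- toy_alignment(setNames(rep(strrep("ATGCTT", 10), 5),
                                      tree$tip.label),
                             "inv", seq_type = "nucleotide")
  om <- omega_by_class(invariant, tree, part)
  expect_equal(om$foreground$Nd + om$foreground$Sd, 0)
  expect_true(is.na(om$foreground$omega))
  expect_true(is.na(om$background$omega))

  # omega-homogeneous simulation: both classes near 1
  wtree <- waterfowl_tree()
  wpart <- waterfowl_partition()
  cfg <- model_config("codon", length = 2000, omega_bg = 1, omega_fg = 1,
                      foreground = wpart$foreground)
  g <- simulate_gene(wtree, cfg, seed = 101)
  om1 <- omega_by_class(g$alignment, wtree, wpart)
  expect_lt(abs(om1$foreground$omega - 1), 0.25)
  expect_lt(abs(om1$background$omega - 1), 0.25)
  # N + S within rounding of 3 * codon count
  expect_equal(om1$foreground$N + om1$foreground$S, 3 * 2000,
               tolerance = 0.05)
})

test_that("permutation p is deterministic, bounded below, and flags undefined genes", {
  wtree <- waterfowl_tree()
  wpart <- waterfowl_partition()
  cfg <- model_config("codon", length = 300, omega_bg = 0.2, omega_fg = 2,
                      foreground = wpart$foreground)
  g <- simulate_gene(wtree, cfg, seed = 55)
  r1 <- permutation_test(g$alignment, wtree, wpart, n_perm = 99, seed = 4)
  r2 <- permutation_test(g$alignment, wtree, wpart, n_perm = 99, seed = 4)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 100)

  tree <- toy_tree5()
  part <- toy_partition(2, 3)
  invariant <- toy_alignment(setNames(rep(strrep("ATGCTT", 30), 5),
                                      tree$tip.label),
                             "inv", seq_type = "nucleotide")
  expect_warning(r <- permutation_test(invariant, tree, part, n_perm = 9,
                                       seed = 1))
  expect_true(r$undefined)
  expect_equal(r$p, 1)

  # foreground spanning every tip leaves no permutation space
  all_fg <- taxon_partition(tree$tip.label, "unsampled_outgroup")
  expect_error(permutation_test(invariant, tree, all_fg, n_perm = 99),
               class = "diveconv_partition_error")
})

test_that("LRT p-values follow the chi-square null with the stated clamp", {
  expect_equal(lrt_pvalue(-100, -100 + 3.841459 / 2), 0.05,
               tolerance = 1e-3)
  expect_equal(lrt_pvalue(-50, -50), 1)
  expect_equal(lrt_pvalue(-50, -60), 1)  # lnL1 < lnL0 clamps to 0
  expect_equal(lrt_pvalue(0, 3.841459 / 2, mixture = TRUE), 0.025,
               tolerance = 1e-3)
  expect_error(lrt_pvalue(NaN, 1), class = "diveconv_range_error")
  tab <- lrt_test(data.frame(gene_id = c("a", "b"),
                             lnL0 = c(-100, -100),
                             lnL1 = c(-90, -99.5)))
  expect_true(tab$flagged[1])
  expect_false(tab$flagged[2])
})

test_that("BH q-values match the hand step-up oracle and are monotone", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(17)
  for (rep in 1:10) {
    p <- runif(sample(3:20, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), class = "diveconv_range_error")
})
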