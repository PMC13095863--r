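# The convergence screen: column classifier, per-gene scan, gene-set
# screen, and their invariants.

test_that("classify_column implements the shared-substitution criterion", {
  part <- waterfowl_partition()
  col_all <- function(bg, fg) {
    setNames(c(rep(fg, 8), rep(bg, 17)),
             c(part$foreground, part$background))
  }
  expect_equal(classify_column(col_all("L", "M"), part, screen_policy()),
               c(bg = "L", fg = "M"))
  expect_null(classify_column(col_all("L", "L"), part, screen_policy()))

  # one discordant foreground taxon vetoes
  col <- col_all("L", "M")
  col[part$foreground[1]] <- "L"
  expect_null(classify_column(col, part, screen_policy()))

  # any gap under strict policy vetoes
  col <- col_all("L", "M")
  col[part$background[3]] <- "-"
  expect_null(classify_column(col, part, screen_policy()))
  # ... but tolerate-1 recovers the call
  expect_equal(classify_column(col, part, screen_policy(max_missing = 1)),
               c(bg = "L", fg = "M"))

  expect_error(classify_column(c(col_all("L", "M"), zz = "A"), part,
                               screen_policy()),
               class = "diveconv_unknown_taxon_error")
})

test_that("classifier agrees with the literal brute-force predicate on all small columns", {
  # reduced 4-letter alphabet over a 2 fg / 4 bg partition; smaller than
  # the acceptance enumeration but exercised as a fast regression
  part <- toy_partition(2, 4)
  taxa <- c(part$foreground, part$background)
  alphabet <- c("A", "C", "D", "-")
  grid <- expand.grid(rep(list(alphabet), 6), stringsAsFactors = FALSE)
  pol <- screen_policy()
  mismatches <- 0L
  for (r in seq_len(nrow(grid))) {
    column <- setNames(unlist(grid[r, ]), taxa)
    got <- classify_column(column, part, pol)
    want <- oracle_classify_strict(column, part)
    if (!identical(got, want)) mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("swapping foreground and background mirrors every call", {
  part <- toy_partition(2, 3)
  swapped <- taxon_partition(part$background, part$foreground)
  taxa <- c(part$foreground, part$background)
  set.seed(21)
  for (rep in 1:200) {
    column <- setNames(sample(c("A", "L", "M", "-"), 5, replace = TRUE), taxa)
    a <- classify_column(column, part, screen_policy())
    b <- classify_column(column, swapped, screen_policy())
    if (is.null(a)) {
      expect_null(b)
    } else {
      expect_equal(unname(b), unname(rev(a)))
    }
  }
})

test_that("adding a taxon to either side can only remove strict calls", {
  base <- toy_partition(2, 3)
  taxa <- c(base$foreground, base$background)
  grown_fg <- taxon_partition(c(base$foreground, "d3"), base$background)
  grown_bg <- taxon_partition(base$foreground, c(base$background, "n4"))
  set.seed(22)
  for (rep in 1:200) {
    column <- setNames(sample(c("A", "L", "M"), 5, replace = TRUE), taxa)
    extra <- sample(c("A", "L", "M"), 1)
    before <- classify_column(column, base, screen_policy())
    after_fg <- classify_column(c(column, d3 = extra), grown_fg,
                                screen_policy())
    after_bg <- classify_column(c(column, n4 = extra), grown_bg,
                                screen_policy())
    if (is.null(before)) {
      expect_null(after_fg)
      expect_null(after_bg)
    }
  }
})

test_that("scan_alignment reports qualifying columns in order with reference positions", {
  part <- toy_partition(2, 3)
  # columns: invariant A | bg L / fg M | invariant G | bg T / fg S
  rows <- c(d1 = "AMGS", d2 = "AMGS", n1 = "ALGT", n2 = "ALGT", n3 = "ALGT")
  aln <- toy_alignment(rows, "toy")
  sites <- scan_alignment(aln, part, screen_policy(), ref_taxon = "n1")
  expect_equal(sites$column, c(2L, 4L))
  expect_equal(sites$bg_residue, c("L", "T"))
  expect_equal(sites$fg_residue, c("M", "S"))
  expect_equal(sites$ref_position, c(2L, 4L))
})

test_that("the screen recovers every planted site with no unverified extras", {
  tree <- waterfowl_tree()
  part <- waterfowl_partition()
  dataset <- simulate_dataset(tree, model_config("protein", length = 150),
                              6, seed = 77, partition = part, n_planted = 3)
  pol <- screen_policy()
  for (g in dataset) {
    sites <- scan_alignment(g$alignment, part, pol)
    planted <- g$truth$planted
    found <- paste(sites$column, sites$bg_residue, sites$fg_residue)
    expect_true(all(paste(planted$column, planted$bg_residue,
                          planted$fg_residue) %in% found))
    # every extra call verifies against the brute-force predicate
    m <- as.matrix(g$alignment)
    for (i in seq_len(nrow(sites))) {
      want <- oracle_classify_strict(
        setNames(m[, sites$column[i]], rownames(m)), part)
      expect_equal(unname(want),
                   c(sites$bg_residue[i], sites$fg_residue[i]))
    }
  }
})

test_that("screen_genes aggregates deterministically and rejects duplicates", {
  alns <- convergence_example_alignments(n_decoys = 2)
  part <- waterfowl_partition()
  res <- screen_genes(alns, part, screen_policy(),
                      ref_taxon = "Anas_platyrhynchos")
  expect_equal(nrow(res$genes), 11L)
  expect_identical(res$genes$gene_id, sort(res$genes$gene_id))
  expect_error(screen_genes(c(alns, alns[1]), part, screen_policy()),
               class = "diveconv_duplicate_gene_error")
  expect_warning(empty <- screen_genes(list(), part, screen_policy()),
                 "empty")
  expect_equal(nrow(empty$sites), 0L)
})

test_that("codon alignments are translated before screening", {
  part <- toy_partition(2, 3)
  # bg codon CTT (L), fg codon ATG (M) at codon 2 of 3
  bg <- paste0("GCT", "CTT", "GGT")
  fg <- paste0("GCT", "ATG", "GGT")
  rows <- c(d1 = fg, d2 = fg, n1 = bg, n2 = bg, n3 = bg)
  aln <- toy_alignment(rows, "cod", seq_type = "nucleotide")
  sites <- scan_alignment(aln, part, screen_policy())
  expect_equal(sites$column, 2L)
  expect_equal(sites$bg_residue, "L")
  expect_equal(sites$fg_residue, "M")
})
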