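# Fixtures and independent brute-force oracles used across the suite.

toy_partition <- function(n_fg = 2, n_bg = 3) {
  taxon_partition(paste0("d", seq_len(n_fg)), paste0("n", seq_len(n_bg)))
}

toy_alignment <- function(rows, gene_id = "toy",
                          seq_type = "protein") {
  gene_alignment(gene_id, unlist(rows), seq_type = seq_type)
}

# literal reading of the convergence criterion: one residue consistent
# across all background taxa, a different residue in all foreground
# taxa; any gap/ambiguity/absence vetoes (strict)
oracle_classify_strict <- function(column, partition) {
  taxa <- c(partition$foreground, partition$background)
  if (!all(taxa %in% names(column))) return(NULL)
  bg <- unname(column[partition$background])
  fg <- unname(column[partition$foreground])
  std <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (!all(bg %in% std) || !all(fg %in% std)) return(NULL)
  if (length(unique(bg)) != 1 || length(unique(fg)) != 1) return(NULL)
  if (bg[1] == fg[1]) return(NULL)
  c(bg = bg[1], fg = fg[1])
}

# exhaustive small-parsimony oracle: minimum total changes over all
# labelings of internal nodes, restricted to states seen at the tips
oracle_parsimony_score <- function(tree, tip_states) {
  states <- unique(tip_states)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edges <- tree$edge
  grid <- expand.grid(rep(list(states), nnode), stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- c(tip_states[tree$tip.label], unlist(grid[r, ]))
    changes <- sum(lab[edges[, 1]] != lab[edges[, 2]])
    best <- min(best, changes)
  }
  best
}

# hand Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# hypergeometric upper tail by direct binomial-coefficient enumeration
oracle_hyper <- function(k, K, n, M) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(M - K, n - kk)) / choose(M, n)
}

# small fixed 5-taxon tree for selection-scan unit tests
toy_tree5 <- function() {
  ape::read.tree(text = "((d1:0.05,d2:0.05):0.02,((n1:0.04,n2:0.04):0.02,n3:0.06):0.02);")
}
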