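# Phylogenetic sequence simulator: protein mode (uniform-exchangeability
# reversible model) for screen testing, codon mode (GY94-style, with
# branch-specific dN/dS on foreground terminal branches) for the
# selection scan. Sampling uses exact transition kernels exp(Q t)
# obtained by eigendecomposition of the detailed-balance-symmetrised
# generator, so branch evolution is exact rather than event-driven.

#' Configure the sequence-evolution model
#'
#' @param mode `"protein"` (20 states) or `"codon"` (61 sense codons of
#'   the standard code; stop codons are excluded from the state space).
#' @param length Gene length: sites (protein) or codons (codon mode).
#' @param pi Stationary frequencies (length 20 or 61, summing to 1);
#'   default uniform.
#' @param kappa Transition/transversion rate ratio (codon mode); the
#'   default 1 keeps exchangeabilities uniform so counting-based
#'   expectations stay unbiased.
#' @param omega_bg Background dN/dS (codon mode).
#' @param omega_fg Foreground dN/dS, applied on the terminal branches of
#'   `foreground` tips (codon mode).
#' @param foreground Character vector of foreground tip names (codon
#'   mode; may be empty for a single-class model).
#' @return An object of class `model_config`.
#' @export
model_config <- function(mode = c("protein", "codon"), length = 300L,
                         pi = NULL, kappa = 1, omega_bg = 1, omega_fg = omega_bg,
                         foreground = character(0)) {
  mode <- match.arg(mode)
  nstate <- if (mode == "protein") 20L else 61L
  if (is.null(pi)) pi <- rep(1 / nstate, nstate)
  dc_assert(length(pi) == nstate,
            sprintf("pi must have length %d in %s mode", nstate, mode),
            "diveconv_model_error")
  dc_assert(all(is.finite(pi)) && all(pi >= 0) && abs(sum(pi) - 1) <= 1e-9,
            "pi must be non-negative and sum to 1 (within 1e-9)",
            "diveconv_model_error")
  for (v in c(kappa = kappa, omega_bg = omega_bg, omega_fg = omega_fg)) {
    dc_assert(is.finite(v) && v > 0,
              "kappa and omega values must be finite and positive",
              "diveconv_model_error")
  }
  dc_assert(is.numeric(length) && length >= 1,
            "gene length must be >= 1", "diveconv_model_error")
  structure(list(mode = mode, length = as.integer(length), pi = pi,
                 kappa = kappa, omega_bg = omega_bg, omega_fg = omega_fg,
                 foreground = as.character(foreground)),
            class = "model_config")
}

is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

#' Build the substitution rate matrix Q
#'
#' Protein mode: uniform exchangeabilities, `q_ij = pi_j`. Codon mode:
#' GY94-style, `q_ij = 0` unless codons differ at exactly one
#' nucleotide, multiplied by `kappa` for transitions and by `omega` for
#' nonsynonymous changes. Rows sum to zero and the matrix is rescaled so
#' the expected substitution rate at stationarity is 1 per site
#' (per codon in codon mode).
#'
#' @param config A [model_config()].
#' @param omega Which codon-mode omega to use: `"background"` or
#'   `"foreground"`.
#' @return A list with the scaled generator `Q`, state labels, `pi`, and
#'   the eigendecomposition used for transition kernels.
#' @export
build_rate_matrix <- function(config, omega = c("background", "foreground")) {
  omega <- match.arg(omega)
  pi <- config$pi
  if (config$mode == "protein") {
    states <- AMINO_ACIDS
    Q <- matrix(pi, 20, 20, byrow = TRUE)
  } else {
    states <- sense_codons()
    w <- if (omega == "foreground") config$omega_fg else config$omega_bg
    code <- genetic_code()
    n <- length(states)
    split_cd <- strsplit(states, "")
    Q <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        diff_pos <- which(split_cd[[i]] != split_cd[[j]])
        if (length(diff_pos) != 1L) next
        r <- pi[j]
        if (is_transition(split_cd[[i]][diff_pos], split_cd[[j]][diff_pos])) {
          r <- r * config$kappa
        }
        if (code[states[i]] != code[states[j]]) r <- r * w
        Q[i, j] <- r
      }
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  dc_assert(rate > 0, "degenerate rate matrix (zero total rate)",
            "diveconv_model_error")
  Q <- Q / rate
  dimnames(Q) <- list(states, states)
  # detailed balance holds (symmetric exchangeabilities), so the
  # generator similarity-transforms to a symmetric matrix
  sq <- sqrt(pi)
  B <- sweep(sweep(Q, 1, sq, "*"), 2, sq, "/")
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(Q = Q, states = states, pi = pi,
                 values = eig$values,
                 vectors = eig$vectors, sqrt_pi = sq),
            class = "rate_matrix")
}

#' Transition probability kernel over a branch
#'
#' Computes `exp(Q t)` from the cached eigendecomposition; rows sum to 1
#' and negative round-off is clamped.
#'
#' @param rm A `rate_matrix` from [build_rate_matrix()].
#' @param t Branch length (expected substitutions per site), `t >= 0`.
#' @return Row-stochastic transition matrix.
#' @export
transition_kernel <- function(rm, t) {
  dc_assert(is.finite(t) && t >= 0, "branch length must be >= 0",
            "diveconv_branch_length_error")
  n <- length(rm$states)
  if (t == 0) {
    P <- diag(n)
    dimnames(P) <- list(rm$states, rm$states)
    return(P)
  }
  V <- rm$vectors
  M <- V %*% (exp(rm$values * t) * t(V))
  P <- sweep(sweep(M, 1, rm$sqrt_pi, "/"), 2, rm$sqrt_pi, "*")
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(rm$states, rm$states)
  P
}

# kernels for every edge of the tree, honouring foreground terminal
# branches in codon mode; cached per (config, tree) by the caller
edge_kernels <- function(tree, config) {
  rm_bg <- build_rate_matrix(config, "background")
  rm_fg <- NULL
  fg_edges <- rep(FALSE, nrow(tree$edge))
  if (config$mode == "codon" && length(config$foreground) > 0L) {
    unknown <- setdiff(config$foreground, tree$tip.label)
    if (length(unknown)) {
      dc_abort(sprintf("foreground tips not in tree: %s",
                       paste(unknown, collapse = ", ")),
               "diveconv_unknown_taxon_error")
    }
    fg_tip_idx <- match(config$foreground, tree$tip.label)
    fg_edges <- tree$edge[, 2] %in% fg_tip_idx
    rm_fg <- build_rate_matrix(config, "foreground")
  }
  kernels <- vector("list", nrow(tree$edge))
  # distinct (class, length) pairs only
  key <- paste(ifelse(fg_edges, "fg", "bg"), tree$edge.length)
  for (k in unique(key)) {
    idx <- which(key == k)
    rm <- if (fg_edges[idx[1]]) rm_fg else rm_bg
    P <- transition_kernel(rm, tree$edge.length[idx[1]])
    for (i in idx) kernels[[i]] <- P
  }
  list(kernels = kernels, rm = rm_bg, fg_edges = fg_edges)
}

#' Simulate one gene along a phylogeny
#'
#' The root sequence is drawn from the stationary frequencies; each
#' branch then evolves all sites independently through the exact
#' transition kernel for its length (with the foreground omega on
#' foreground terminal branches in codon mode). Deterministic given
#' `seed`.
#'
#' @param tree An [ape::phylo] with non-negative branch lengths.
#' @param config A [model_config()].
#' @param gene_id Gene identifier for the resulting alignment.
#' @param seed Integer seed.
#' @return A list with elements `alignment` (a [gene_alignment()]) and
#'   `truth` (list: gene_id, planted sites — empty here —, omega used
#'   per branch class, seed).
#' @export
simulate_gene <- function(tree, config, gene_id = "g0001", seed = 1L) {
  tree <- validate_phylogeny(tree)
  ek <- edge_kernels(tree, config)
  states <- ek$rm$states
  nstate <- length(states)
  L <- config$length
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  edge_order <- rev(seq_len(nrow(po$edge)))          # preorder over edges
  # map reordered edges back to original edge indices for kernel lookup
  orig_idx <- match(paste(po$edge[, 1], po$edge[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  node_states <- matrix(NA_integer_, nnode, L)
  node_states[root, ] <- sample.int(nstate, L, replace = TRUE, prob = ek$rm$pi)
  for (e in edge_order) {
    parent <- po$edge[e, 1]
    child <- po$edge[e, 2]
    t <- po$edge.length[e]
    ps <- node_states[parent, ]
    if (t == 0) {                                    # exact t -> 0 identity
      node_states[child, ] <- ps
      next
    }
    P <- ek$kernels[[orig_idx[e]]]
    cs <- integer(L)
    for (s in unique(ps)) {
      i <- which(ps == s)
      cs[i] <- sample.int(nstate, length(i), replace = TRUE, prob = P[s, ])
    }
    node_states[child, ] <- cs
  }
  tip_rows <- vapply(seq_len(ntip), function(i) {
    paste(states[node_states[i, ]], collapse = "")
  }, "")
  aln <- gene_alignment(gene_id, setNames(tip_rows, tree$tip.label),
                        seq_type = if (config$mode == "protein")
                          "protein" else "nucleotide")
  truth <- list(gene_id = gene_id,
                planted = empty_planted(),
                omega_fg = if (config$mode == "codon") config$omega_fg else NA_real_,
                omega_bg = if (config$mode == "codon") config$omega_bg else NA_real_,
                seed = as.integer(seed))
  list(alignment = aln, truth = truth)
}

empty_planted <- function() {
  data.frame(column = integer(0), bg_residue = character(0),
             fg_residue = character(0), stringsAsFactors = FALSE)
}

#' Plant convergent columns into an alignment
#'
#' Overwrites `n_sites` distinct columns so that every background taxon
#' carries one standard residue X and every foreground taxon a different
#' residue Y — the exact pattern the convergence screen looks for. On
#' codon alignments the whole codon column is overwritten with the
#' lexicographically smallest sense codon of each residue.
#'
#' @param aln A [gene_alignment()] containing all partition taxa.
#' @param partition A [taxon_partition()].
#' @param n_sites Number of columns to plant.
#' @param seed Integer seed.
#' @return A list with the modified `alignment` and a `truth` data frame
#'   of planted `(column, bg_residue, fg_residue)`.
#' @export
plant_convergent_sites <- function(aln, partition, n_sites, seed = 1L) {
  n_sites <- as.integer(n_sites)
  dc_assert(n_sites >= 0L, "n_sites must be >= 0", "diveconv_range_error")
  ncol_res <- if (aln$seq_type == "protein") alignment_length(aln)
              else alignment_length(aln) %/% 3L
  dc_assert(n_sites <= ncol_res,
            sprintf("n_sites %d exceeds %d residue columns", n_sites, ncol_res),
            "diveconv_range_error")
  missing <- setdiff(partition_taxa(partition), aln$taxa)
  if (length(missing)) {
    dc_abort(sprintf("partition taxa absent from alignment: %s",
                     paste(missing, collapse = ", ")),
             "diveconv_unknown_taxon_error")
  }
  if (n_sites == 0L) {
    return(list(alignment = aln, truth = empty_planted()))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  cols <- sort(sample.int(ncol_res, n_sites))
  bg_res <- character(n_sites)
  fg_res <- character(n_sites)
  m <- as.matrix(aln)
  bg_i <- match(partition$background, aln$taxa)
  fg_i <- match(partition$foreground, aln$taxa)
  aa_codon <- canonical_codons()
  for (k in seq_len(n_sites)) {
    pair <- sample(AMINO_ACIDS, 2L)
    bg_res[k] <- pair[1]
    fg_res[k] <- pair[2]
    if (aln$seq_type == "protein") {
      m[bg_i, cols[k]] <- pair[1]
      m[fg_i, cols[k]] <- pair[2]
    } else {
      nt_cols <- (cols[k] - 1L) * 3L + 1:3
      m[bg_i, nt_cols] <- matrix(strsplit(aa_codon[pair[1]], "")[[1]],
                                 length(bg_i), 3, byrow = TRUE)
      m[fg_i, nt_cols] <- matrix(strsplit(aa_codon[pair[2]], "")[[1]],
                                 length(fg_i), 3, byrow = TRUE)
    }
  }
  seqs <- setNames(apply(m, 1, paste, collapse = ""), aln$taxa)
  out <- gene_alignment(aln$gene_id, seqs, seq_type = aln$seq_type,
                        codon_aligned = aln$codon_aligned)
  truth <- data.frame(column = cols, bg_residue = bg_res, fg_residue = fg_res,
                      stringsAsFactors = FALSE)
  list(alignment = out, truth = truth)
}

# lexicographically smallest sense codon per amino acid
canonical_codons <- function() {
  if (is.null(.dc_cache$canon)) {
    code <- genetic_code()
    sense <- sense_codons()
    .dc_cache$canon <- vapply(split(sense, code[sense]), min, "")
  }
  .dc_cache$canon
}

#' Simulate a dataset of genes
#'
#' Per-gene seeds are derived deterministically from the master seed and
#' the gene id, so the dataset is byte-identical across runs. Gene ids
#' are `g0001..gNNNN`.
#'
#' @param tree An [ape::phylo].
#' @param config A [model_config()] or a list of them, one per gene.
#' @param n_genes Number of genes (`>= 1`).
#' @param seed Master seed.
#' @param partition Optional [taxon_partition()]; required when
#'   `n_planted > 0`.
#' @param n_planted Number of convergent columns to plant per gene.
#' @return A list of per-gene lists `(alignment, truth)`; each `truth`
#'   carries the planted sites, omegas used and the per-gene seed.
#' @export
simulate_dataset <- function(tree, config, n_genes, seed = 1L,
                             partition = NULL, n_planted = 0L) {
  n_genes <- as.integer(n_genes)
  dc_assert(n_genes >= 1L, "n_genes must be >= 1", "diveconv_range_error")
  configs <- if (inherits(config, "model_config")) {
    rep(list(config), n_genes)
  } else {
    dc_assert(length(config) == n_genes,
              "config list length must equal n_genes", "diveconv_model_error")
    config
  }
  if (n_planted > 0L) {
    dc_assert(!is.null(partition),
              "planting requires a taxon partition", "diveconv_partition_error")
  }
  out <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    gid <- sprintf("g%04d", i)
    g <- simulate_gene(tree, configs[[i]], gene_id = gid,
                       seed = derive_seed(seed, gid))
    if (n_planted > 0L) {
      pl <- plant_convergent_sites(g$alignment, partition, n_planted,
                                   seed = derive_seed(seed, gid, "plant"))
      g$alignment <- pl$alignment
      g$truth$planted <- pl$truth
    }
    out[[i]] <- g
  }
  names(out) <- vapply(out, function(g) g$alignment$gene_id, "")
  out
}

#' Write simulator ground truth to TSV
#'
#' One row per planted site (or one row with NA column for genes without
#' planted sites), recording the omegas and seed actually used.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(dataset, path) {
  rows <- lapply(dataset, function(g) {
    tr <- g$truth
    if (nrow(tr$planted) == 0L) {
      data.frame(gene_id = tr$gene_id, column = NA_integer_,
                 bg_residue = NA_character_, fg_residue = NA_character_,
                 omega_fg = tr$omega_fg, omega_bg = tr$omega_bg,
                 seed = tr$seed, stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = tr$gene_id, tr$planted,
                 omega_fg = tr$omega_fg, omega_bg = tr$omega_bg,
                 seed = tr$seed, stringsAsFactors = FALSE)
    }
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
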