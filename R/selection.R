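# Counting-based foreground-vs-background selection scan. This is an
# explicitly-labelled desk-scale stand-in for full branch-site codon
# maximum likelihood: ancestral codons by Fitch small parsimony,
# nonsynonymous/synonymous substitutions by stop-free minimal-pathway
# counting, omega per branch class, and a tip-relabelling permutation
# null. lrt_pvalue()/bh_fdr() apply the chi-square + FDR decision rule
# to externally computed likelihood pairs (e.g. from codeml).

#' Fitch parsimony ancestral codon reconstruction
#'
#' Small parsimony treating each codon column as one 61-state character:
#' bottom-up intersection/union of child state sets, then top-down
#' resolution preferring the parent's assigned state, with
#' lexicographic tie-breaks (on codon strings) at the root and wherever
#' the parent's state is not available. Deterministic.
#'
#' @param aln Gapless codon-aligned nucleotide [gene_alignment()] whose
#'   taxa equal the tree's tips.
#' @param tree An [ape::phylo].
#' @return Character matrix of codon assignments, rows =
#'   `c(tips, internal nodes)` in ape node order (rownames are tip
#'   labels then `node<k>`), columns = codon positions. The integer
#'   state matrix is attached as attribute `"index"`.
#' @export
fitch_ancestral_codons <- function(aln, tree) {
  tree <- validate_phylogeny(tree)
  dc_assert(setequal(aln$taxa, tree$tip.label) &&
              length(aln$taxa) == length(tree$tip.label),
            "alignment taxa and tree tips differ",
            "diveconv_unknown_taxon_error")
  if (any(grepl("-", aln$seqs, fixed = TRUE))) {
    dc_abort(sprintf("gene %s: gapped alignment; run QC first", aln$gene_id),
             "diveconv_gap_error")
  }
  cm <- codon_matrix(aln)[tree$tip.label, , drop = FALSE]
  tip_states <- matrix(codon_index(cm), nrow(cm), ncol(cm))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  L <- ncol(tip_states)
  anc <- matrix(NA_integer_, nnode, L)
  anc[seq_len(ntip), ] <- tip_states

  # children of each internal node, in postorder-completion order
  internal_order <- unique(po$edge[, 1])
  children <- split(po$edge[, 2], po$edge[, 1])

  memo <- new.env(parent = emptyenv())
  for (col in seq_len(L)) {
    key <- paste(tip_states[, col], collapse = ",")
    cached <- memo[[key]]
    if (!is.null(cached)) {
      anc[(ntip + 1L):nnode, col] <- cached
      next
    }
    sets <- vector("list", nnode)
    for (i in seq_len(ntip)) sets[[i]] <- tip_states[i, col]
    for (nd in internal_order) {
      kids <- children[[as.character(nd)]]
      s <- sets[[kids[1]]]
      for (k in kids[-1]) {
        inter <- intersect(s, sets[[k]])
        s <- if (length(inter)) inter else union(s, sets[[k]])
      }
      sets[[nd]] <- s
    }
    assign <- integer(nnode)
    assign[seq_len(ntip)] <- tip_states[, col]
    assign[root] <- min(sets[[root]])           # lexicographic tie-break
    for (e in rev(seq_len(nrow(po$edge)))) {    # preorder
      parent <- po$edge[e, 1]
      child <- po$edge[e, 2]
      if (child <= ntip) next
      s <- sets[[child]]
      assign[child] <- if (assign[parent] %in% s) assign[parent] else min(s)
    }
    internal <- assign[(ntip + 1L):nnode]
    memo[[key]] <- internal
    anc[(ntip + 1L):nnode, col] <- internal
  }
  out <- matrix(sense_codons()[anc], nnode, L)
  rownames(out) <- c(tree$tip.label,
                     paste0("node", (ntip + 1L):nnode))
  attr(out, "index") <- anc
  out
}

# per-edge substitution counts and site counts, shared by
# omega_by_class and the permutation test
edge_count_table <- function(aln, tree, anc = NULL) {
  if (is.null(anc)) anc <- fitch_ancestral_codons(aln, tree)
  idx <- attr(anc, "index")
  pair <- codon_pair_tables()
  site <- codon_site_table()
  codons <- sense_codons()
  node_N <- rowSums(matrix(site$N[codons[idx]], nrow(idx), ncol(idx)))
  node_S <- rowSums(matrix(site$S[codons[idx]], nrow(idx), ncol(idx)))
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  nd <- sd <- numeric(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    p <- idx[edges[e, 1], ]
    c_ <- idx[edges[e, 2], ]
    changed <- which(p != c_)
    if (length(changed)) {
      nd[e] <- sum(pair$nd[cbind(p[changed], c_[changed])])
      sd[e] <- sum(pair$sd[cbind(p[changed], c_[changed])])
    }
  }
  data.frame(parent = edges[, 1], child = edges[, 2],
             tip_label = ifelse(edges[, 2] <= ntip,
                                tree$tip.label[edges[, 2]], NA_character_),
             length = tree$edge.length,
             nd = nd, sd = sd,
             N = (node_N[edges[, 1]] + node_N[edges[, 2]]) / 2,
             S = (node_S[edges[, 1]] + node_S[edges[, 2]]) / 2,
             stringsAsFactors = FALSE)
}

summarize_class <- function(ec, in_class, class) {
  sub <- ec[in_class, , drop = FALSE]
  Nd <- sum(sub$nd)
  Sd <- sum(sub$sd)
  N <- mean(sub$N)
  S <- mean(sub$S)
  omega <- if (Sd > 0 && N > 0) (Nd / N) / (Sd / S) else NA_real_
  list(class = class, Nd = Nd, Sd = Sd, N = N, S = S,
       total_length = sum(sub$length), omega = omega)
}

class_omegas <- function(ec, fg_tips) {
  fg_edge <- !is.na(ec$tip_label) & ec$tip_label %in% fg_tips
  list(foreground = summarize_class(ec, fg_edge, "foreground"),
       background = summarize_class(ec, !fg_edge, "background"))
}

#' Branch-class dN/dS summaries
#'
#' Foreground class = terminal branches of foreground tips; background
#' class = all other branches. Substitutions are accumulated from the
#' Fitch reconstruction with stop-free pathway counting; expected site
#' counts N and S are the mean of the endpoint sequences' counts per
#' branch, averaged over the class. `omega = (Nd/N)/(Sd/S)`, undefined
#' (`NA`) when `Sd = 0`.
#'
#' @param aln Gapless codon [gene_alignment()].
#' @param tree An [ape::phylo] whose tips equal the alignment taxa.
#' @param partition A [taxon_partition()]; taxa must match the tips.
#' @param anc Optional precomputed [fitch_ancestral_codons()] result.
#' @return List with `foreground` and `background` summaries (`Nd`,
#'   `Sd`, `N`, `S`, `total_length`, `omega`).
#' @export
omega_by_class <- function(aln, tree, partition, anc = NULL) {
  dc_assert(setequal(partition_taxa(partition), tree$tip.label),
            "partition taxa and tree tips differ",
            "diveconv_partition_error")
  ec <- edge_count_table(aln, tree, anc)
  class_omegas(ec, partition$foreground)
}

#' Permutation test of elevated foreground omega
#'
#' Statistic `Delta = log(omega_fg / omega_bg)`. The null is built by
#' relabelling random same-size tip subsets as foreground and
#' recomputing Delta from the same per-branch substitution counts;
#' `p = (1 + #\{Delta_perm >= Delta_obs\}) / (1 + n_perm)`. Genes whose
#' observed omega is undefined (synonymous count 0 in either class)
#' report `p = 1` with `undefined = TRUE`.
#'
#' @param aln Gapless codon [gene_alignment()].
#' @param tree An [ape::phylo].
#' @param partition A [taxon_partition()].
#' @param n_perm Number of permutations (>= 99 recommended).
#' @param seed Integer seed (deterministic result).
#' @return List: `gene_id`, `omega_fg`, `omega_bg`, `delta`, `p`,
#'   `n_perm`, `undefined`.
#' @export
permutation_test <- function(aln, tree, partition, n_perm = 999L, seed = 1L) {
  n_perm <- as.integer(n_perm)
  dc_assert(n_perm >= 1L, "n_perm must be >= 1", "diveconv_range_error")
  if (n_perm < 99L) {
    warning("n_perm < 99 gives a coarse permutation p-value", call. = FALSE)
  }
  tips <- tree$tip.label
  n_fg <- length(partition$foreground)
  if (n_fg >= length(tips)) {
    dc_abort("foreground size equals tip count: no permutation space",
             "diveconv_partition_error")
  }
  ec <- edge_count_table(aln, tree)
  obs <- class_omegas(ec, partition$foreground)
  res <- list(gene_id = aln$gene_id,
              omega_fg = obs$foreground$omega,
              omega_bg = obs$background$omega,
              delta = NA_real_, p = 1, n_perm = n_perm, undefined = TRUE)
  if (is.na(obs$foreground$omega) || is.na(obs$background$omega) ||
      obs$background$omega == 0) {
    return(res)
  }
  delta_obs <- log(obs$foreground$omega / obs$background$omega)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    fg_perm <- sample(tips, n_fg)
    perm <- class_omegas(ec, fg_perm)
    if (is.na(perm$foreground$omega) || is.na(perm$background$omega) ||
        perm$background$omega == 0) next
    delta_perm <- log(perm$foreground$omega / perm$background$omega)
    if (delta_perm >= delta_obs) exceed <- exceed + 1L
  }
  res$delta <- delta_obs
  res$p <- (1 + exceed) / (1 + n_perm)
  res$undefined <- FALSE
  res
}

#' Selection scan over a gene set
#'
#' Runs [permutation_test()] per gene, applies Benjamini-Hochberg
#' correction across genes, and flags genes with `q < fdr`. Genes with
#' undefined omega are never flagged.
#'
#' @param alignments List of gapless codon [gene_alignment()] objects.
#' @param tree An [ape::phylo].
#' @param partition A [taxon_partition()].
#' @param n_perm Permutations per gene.
#' @param seed Master seed; per-gene seeds are derived from it.
#' @param fdr FDR threshold for flagging.
#' @return Data frame: `gene_id`, `omega_fg`, `omega_bg`, `delta`,
#'   `p`, `q`, `flagged`, `undefined`.
#' @export
selection_scan <- function(alignments, tree, partition, n_perm = 999L,
                           seed = 1L, fdr = 0.05) {
  rows <- lapply(alignments, function(aln) {
    r <- permutation_test(aln, tree, partition, n_perm = n_perm,
                          seed = derive_seed(seed, aln$gene_id, "perm"))
    data.frame(gene_id = r$gene_id, omega_fg = r$omega_fg,
               omega_bg = r$omega_bg, delta = r$delta, p = r$p,
               undefined = r$undefined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- bh_fdr(out$p)
  out$flagged <- !out$undefined & out$q < fdr
  out[order(out$gene_id), c("gene_id", "omega_fg", "omega_bg", "delta",
                            "p", "q", "flagged", "undefined")]
}

#' Likelihood-ratio test p-value
#'
#' Upper-tail chi-square probability of `2 (lnL1 - lnL0)`, clamped at 0
#' when the alternative likelihood is below the null. With
#' `mixture = TRUE` the null is the 50:50 point-mass/chi-square(1)
#' mixture sometimes used for boundary hypotheses.
#'
#' @param lnL0,lnL1 Null and alternative log-likelihoods (vectorised).
#' @param df Degrees of freedom (default 1).
#' @param mixture Use the 50:50 mixture null (forces `df = 1`).
#' @return P-value(s) in `(0, 1]`.
#' @examples
#' lrt_pvalue(0, 3.841459 / 2)  # ~0.05
#' @export
lrt_pvalue <- function(lnL0, lnL1, df = 1L, mixture = FALSE) {
  dc_assert(all(is.finite(lnL0)) && all(is.finite(lnL1)),
            "log-likelihoods must be finite", "diveconv_range_error")
  dc_assert(df >= 1, "df must be >= 1", "diveconv_range_error")
  stat <- pmax(0, 2 * (lnL1 - lnL0))
  if (mixture) {
    ifelse(stat == 0, 1, 0.5 * pchisq(stat, 1, lower.tail = FALSE))
  } else {
    ifelse(stat == 0, 1, pchisq(stat, df, lower.tail = FALSE))
  }
}

#' Apply the LRT + FDR decision rule to a likelihood table
#'
#' Consumes externally computed per-gene log-likelihood pairs (e.g. from
#' branch-site model fits), computes `2 delta lnL`, chi-square p-values,
#' Benjamini-Hochberg q-values, and flags genes with `q < fdr` —
#' the classification rule for positively selected genes.
#'
#' @param lnl Data frame with columns `gene_id`, `lnL0`, `lnL1`.
#' @param df Chi-square degrees of freedom.
#' @param mixture Use the 50:50 mixture null.
#' @param fdr FDR threshold.
#' @return The input with `statistic`, `df`, `p`, `q`, `flagged` added.
#' @export
lrt_test <- function(lnl, df = 1L, mixture = FALSE, fdr = 0.05) {
  dc_assert(all(c("gene_id", "lnL0", "lnL1") %in% names(lnl)),
            "lnl needs columns gene_id, lnL0, lnL1", "diveconv_format_error")
  lnl$statistic <- pmax(0, 2 * (lnl$lnL1 - lnl$lnL0))
  lnl$df <- df
  lnl$p <- lrt_pvalue(lnl$lnL0, lnl$lnL1, df = df, mixture = mixture)
  lnl$q <- bh_fdr(lnl$p)
  lnl$flagged <- lnl$q < fdr
  lnl
}

#' Benjamini-Hochberg step-up q-values
#'
#' Order-preserving with the input; q-values are monotone non-decreasing
#' in sorted p.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(pvalues) {
  dc_assert(is.numeric(pvalues) && all(is.finite(pvalues)) &&
              all(pvalues >= 0) && all(pvalues <= 1),
            "p-values must lie in [0, 1]", "diveconv_range_error")
  p.adjust(pvalues, method = "BH")
}
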