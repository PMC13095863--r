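# The convergence screen: classify alignment columns as shared
# (convergent) amino-acid substitutions of the foreground lineages —
# every background taxon carries one standard residue, every foreground
# taxon a different one — aggregate calls per gene, and report
# positions in a user-named reference taxon.

#' Screening policy for gaps, ambiguity and missing taxa
#'
#' The strict default (the criterion as stated: residues must be
#' consistent across all background taxa and different in all foreground
#' taxa) vetoes a column whenever any taxon is absent or carries `"-"`,
#' `"*"` or (by default) `"X"`. `max_missing = k` relaxes this to
#' tolerate up to `k` missing/ambiguous taxa per column, calling on the
#' remaining taxa; every relaxation is an explicit, logged deviation
#' from the strict criterion.
#'
#' @param max_missing Maximum taxa absent/ambiguous per column
#'   (0 = strict).
#' @param treat_X_as_missing Treat `"X"` as missing (default `TRUE`).
#' @param require_all_taxa_present Require every partition taxon in the
#'   alignment (default `TRUE`).
#' @return An object of class `screen_policy`.
#' @export
screen_policy <- function(max_missing = 0L, treat_X_as_missing = TRUE,
                          require_all_taxa_present = TRUE) {
  max_missing <- as.integer(max_missing)
  dc_assert(max_missing >= 0L, "max_missing must be >= 0",
            "diveconv_range_error")
  structure(list(max_missing = max_missing,
                 treat_X_as_missing = isTRUE(treat_X_as_missing),
                 require_all_taxa_present = isTRUE(require_all_taxa_present)),
            class = "screen_policy")
}

#' Classify one alignment column
#'
#' Returns a call `(bg_residue, fg_residue)` iff (i) every background
#' taxon carries the same standard residue X, (ii) every foreground
#' taxon carries the same standard residue Y, (iii) X != Y, and (iv) the
#' policy's missing-data conditions hold. Under the strict policy any
#' gap, stop, ambiguous residue or absent taxon anywhere in the column
#' vetoes the call.
#'
#' @param column Named character vector, taxon -> single residue.
#' @param partition A [taxon_partition()].
#' @param policy A [screen_policy()].
#' @return `NULL` (no call) or named character vector
#'   `c(bg = X, fg = Y)`.
#' @examples
#' part <- taxon_partition(c("d1", "d2"), c("n1", "n2", "n3"))
#' classify_column(c(d1 = "M", d2 = "M", n1 = "L", n2 = "L", n3 = "L"),
#'                 part, screen_policy())
#' @export
classify_column <- function(column, partition, policy = screen_policy()) {
  unknown <- setdiff(names(column), partition_taxa(partition))
  if (length(unknown)) {
    dc_abort(sprintf("column references taxa outside the partition: %s",
                     paste(unknown, collapse = ", ")),
             "diveconv_unknown_taxon_error")
  }
  missing_chars <- c("-", "*")
  if (policy$treat_X_as_missing) missing_chars <- c(missing_chars, "X")
  side_residues <- function(taxa) {
    obs <- column[taxa[taxa %in% names(column)]]
    n_absent <- sum(!taxa %in% names(column))
    res <- obs[!obs %in% missing_chars]
    # a non-standard residue that is not policy-missing blocks the call
    list(res = res, veto = any(!is_standard_residue(res)),
         n_missing = n_absent + sum(obs %in% missing_chars))
  }
  bg <- side_residues(partition$background)
  fg <- side_residues(partition$foreground)
  if (bg$veto || fg$veto) return(NULL)
  if (bg$n_missing + fg$n_missing > policy$max_missing) return(NULL)
  if (length(bg$res) == 0L || length(fg$res) == 0L) return(NULL)
  x <- unique(unname(bg$res))
  y <- unique(unname(fg$res))
  if (length(x) != 1L || length(y) != 1L || x == y) return(NULL)
  c(bg = x, fg = y)
}

#' Scan a protein alignment for convergent sites
#'
#' Applies [classify_column()] to every column and reports qualifying
#' columns in ascending order, each with its position in the ungapped
#' reference sequence (`NA` when the reference is gapped there or no
#' reference is named). Codon-aligned nucleotide input is translated
#' first.
#'
#' @param aln A protein (or codon-aligned nucleotide) [gene_alignment()].
#' @param partition A [taxon_partition()].
#' @param policy A [screen_policy()].
#' @param ref_taxon Optional reference taxon for position reporting.
#' @return Data frame of convergent sites: `gene_id`, `column`,
#'   `ref_position`, `bg_residue`, `fg_residue`.
#' @export
scan_alignment <- function(aln, partition, policy = screen_policy(),
                           ref_taxon = NULL) {
  if (aln$seq_type == "nucleotide") aln <- translate_alignment(aln)
  absent <- setdiff(partition_taxa(partition), aln$taxa)
  if (policy$require_all_taxa_present && length(absent)) {
    dc_abort(sprintf("gene %s: partition taxa missing from alignment: %s",
                     aln$gene_id, paste(absent, collapse = ", ")),
             "diveconv_unknown_taxon_error")
  }
  if (!is.null(ref_taxon)) {
    dc_assert(ref_taxon %in% aln$taxa,
              sprintf("reference taxon '%s' absent from gene %s",
                      ref_taxon, aln$gene_id),
              "diveconv_unknown_taxon_error")
  }
  m <- as.matrix(aln)
  keep <- rownames(m) %in% partition_taxa(partition)
  m <- m[keep, , drop = FALSE]
  hits <- empty_sites()
  for (j in seq_len(ncol(m))) {
    call <- classify_column(setNames(m[, j], rownames(m)), partition, policy)
    if (is.null(call)) next
    ref_pos <- if (is.null(ref_taxon)) NA_integer_
               else map_column_to_reference(aln, j, ref_taxon)
    hits <- rbind(hits, data.frame(
      gene_id = aln$gene_id, column = j, ref_position = ref_pos,
      bg_residue = unname(call["bg"]), fg_residue = unname(call["fg"]),
      stringsAsFactors = FALSE))
  }
  hits
}

empty_sites <- function() {
  data.frame(gene_id = character(0), column = integer(0),
             ref_position = integer(0), bg_residue = character(0),
             fg_residue = character(0), stringsAsFactors = FALSE)
}

#' Screen a gene set for convergent substitutions
#'
#' Runs [scan_alignment()] over a collection of alignments and returns
#' the full site list plus the per-gene summary of genes carrying at
#' least one convergent site, in deterministic `(gene_id, column)`
#' order.
#'
#' @param alignments List of [gene_alignment()] objects with unique
#'   gene ids.
#' @param partition A [taxon_partition()].
#' @param policy A [screen_policy()].
#' @param ref_taxon Optional reference taxon for position reporting.
#' @return A list: `sites` (data frame of all convergent sites) and
#'   `genes` (data frame `gene_id`, `n_sites` for flagged genes).
#' @export
screen_genes <- function(alignments, partition, policy = screen_policy(),
                         ref_taxon = NULL) {
  if (length(alignments) == 0L) {
    warning("empty alignment collection: empty screen result", call. = FALSE)
    return(list(sites = empty_sites(),
                genes = data.frame(gene_id = character(0),
                                   n_sites = integer(0))))
  }
  ids <- vapply(alignments, function(a) a$gene_id, "")
  if (anyDuplicated(ids)) {
    dc_abort(sprintf("duplicate gene id(s): %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "diveconv_duplicate_gene_error")
  }
  sites <- do.call(rbind, lapply(alignments, scan_alignment,
                                 partition = partition, policy = policy,
                                 ref_taxon = ref_taxon))
  sites <- sites[order(sites$gene_id, sites$column), , drop = FALSE]
  rownames(sites) <- NULL
  counts <- table(sites$gene_id)
  genes <- data.frame(gene_id = as.character(names(counts) %||% character(0)),
                      n_sites = as.integer(counts),
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  list(sites = sites, genes = genes)
}
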