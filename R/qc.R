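# Alignment-level and pairwise quality control: the length/gap
# exclusion rule applied to codon alignments before the selection scan,
# and the identity/coverage filter used when extracting CDS from
# aligned regions.

#' Quality-control one codon alignment
#'
#' Applies the exclusion rules used to prepare codon alignments for
#' selection testing: alignments shorter than `min_length_nt` (150 nt by
#' default) and/or alignments containing gaps are excluded. Frame
#' violations (length not a codon multiple) and internal stop codons
#' are always fatal. The length/gap pair can be combined as independent
#' criteria (`rule = "or"`, the default) or jointly (`rule = "and"`);
#' both reasons are always recorded so either reading can be recovered
#' from the report.
#'
#' @param aln A nucleotide [gene_alignment()].
#' @param min_length_nt Minimum aligned length in nucleotides.
#' @param rule `"or"` (either criterion excludes) or `"and"` (only both
#'   together exclude).
#' @return A one-row data frame: `gene_id`, `passed`, `reasons`
#'   (comma-separated), `length_nt`, `gap_count`.
#' @examples
#' aln <- gene_alignment("toy", c(a = strrep("ATG", 50), b = strrep("ATG", 50)),
#'                       "nucleotide")
#' qc_gene_alignment(aln)$passed  # TRUE: 150 nt, gapless
#' @export
qc_gene_alignment <- function(aln, min_length_nt = 150L,
                              rule = c("or", "and")) {
  rule <- match.arg(rule)
  dc_assert(inherits(aln, "gene_alignment"), "not a gene_alignment",
            "diveconv_format_error")
  if (aln$seq_type != "nucleotide") {
    dc_abort("QC expects a nucleotide codon alignment (got protein)",
             "diveconv_mode_error")
  }
  len <- alignment_length(aln)
  gap_count <- sum(vapply(aln$seqs,
                          function(s) lengths(regmatches(s, gregexpr("-", s, fixed = TRUE))),
                          integer(1)))
  reasons <- character(0)
  too_short <- len < min_length_nt
  has_gaps <- gap_count > 0L
  if (too_short) reasons <- c(reasons, "too_short")
  if (has_gaps) reasons <- c(reasons, "contains_gaps")
  if (len %% 3L != 0L) reasons <- c(reasons, "not_codon_multiple")
  internal_stop <- FALSE
  if (len %% 3L == 0L) {
    for (s in aln$seqs) {
      ok <- tryCatch({translate_cds(s); TRUE},
                     diveconv_internal_stop_error = function(e) FALSE)
      if (!ok) {
        internal_stop <- TRUE
        break
      }
    }
  }
  if (internal_stop) reasons <- c(reasons, "internal_stop")
  exclusionary <- reasons
  if (rule == "and" && xor(too_short, has_gaps)) {
    # under the joint reading, length and gaps only exclude together
    exclusionary <- setdiff(exclusionary, c("too_short", "contains_gaps"))
  }
  passed <- length(exclusionary) == 0L
  data.frame(gene_id = aln$gene_id, passed = passed,
             reasons = paste(if (passed) character(0) else exclusionary,
                             collapse = ","),
             length_nt = len, gap_count = gap_count,
             stringsAsFactors = FALSE)
}

#' Quality-control a set of alignments
#'
#' @param alignments List of nucleotide [gene_alignment()] objects.
#' @param ... Passed to [qc_gene_alignment()].
#' @return Data frame, one row per gene.
#' @export
qc_genes <- function(alignments, ...) {
  do.call(rbind, lapply(alignments, qc_gene_alignment, ...))
}

#' Pairwise identity/coverage filter for aligned CDS extraction
#'
#' Mirrors the reference-based CDS extraction filter: a query region is
#' kept when its identity to the reference is at least `min_identity`
#' (70%) and it covers at least `min_coverage` (50%) of the full-length
#' reference. Identity is computed over columns where both rows are
#' non-gap; coverage is the fraction of the ungapped reference CDS
#' present in the aligned region.
#'
#' @param query_aligned,ref_aligned Equal-length aligned rows.
#' @param ref_full_length Full ungapped reference CDS length.
#' @param min_identity,min_coverage Inclusive thresholds.
#' @return A list: `identity`, `coverage`, `passed`.
#' @export
identity_coverage_filter <- function(query_aligned, ref_aligned,
                                     ref_full_length,
                                     min_identity = 0.70,
                                     min_coverage = 0.50) {
  q <- strsplit(toupper(query_aligned), "")[[1]]
  r <- strsplit(toupper(ref_aligned), "")[[1]]
  dc_assert(length(q) == length(r), "aligned rows differ in length",
            "diveconv_shape_error")
  dc_assert(ref_full_length >= 1, "ref_full_length must be >= 1",
            "diveconv_range_error")
  comparable <- q != "-" & r != "-"
  if (!any(comparable)) {
    dc_abort("no comparable (gapless) columns: identity undefined",
             "diveconv_undefined_identity_error")
  }
  identity <- sum(q[comparable] == r[comparable]) / sum(comparable)
  coverage <- sum(r != "-") / ref_full_length
  list(identity = identity, coverage = coverage,
       passed = identity >= min_identity && coverage >= min_coverage)
}

#' Translate a codon alignment to protein
#'
#' Row-wise [translate_cds()]; the alignment keeps its taxa and gene id.
#' Genes failing translation (internal stops) raise their error rather
#' than being silently dropped.
#'
#' @param aln A codon-aligned nucleotide [gene_alignment()].
#' @return A protein [gene_alignment()].
#' @export
translate_alignment <- function(aln) {
  dc_assert(aln$seq_type == "nucleotide" && aln$codon_aligned,
            "translation expects a codon-aligned nucleotide alignment",
            "diveconv_mode_error")
  prot <- vapply(aln$seqs, translate_cds, "")
  widths <- nchar(prot)
  # a terminal stop dropped in some rows but not others would de-align
  if (length(unique(widths)) != 1L) {
    dc_abort(sprintf("gene %s: rows translate to unequal lengths",
                     aln$gene_id), "diveconv_shape_error")
  }
  gene_alignment(aln$gene_id, setNames(prot, aln$taxa), "protein")
}
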