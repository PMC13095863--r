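# Gene alignment container and FASTA input/output.

#' Construct a gene alignment
#'
#' A `gene_alignment` holds one gene's multiple sequence alignment: an
#' ordered set of taxa and equal-length aligned rows, either nucleotide
#' (codon) or protein. Gap character is `"-"`; `"."` in input is
#' normalised to `"-"` on read. Coordinates are 1-based throughout.
#'
#' @param gene_id Single gene identifier.
#' @param seqs Named character vector of aligned rows (names = taxa).
#' @param seq_type `"protein"` or `"nucleotide"`.
#' @param codon_aligned For nucleotide alignments, whether rows are
#'   codon-aligned (length then must be divisible by 3). Default `TRUE`
#'   for nucleotide input.
#' @return An object of class `gene_alignment`.
#' @examples
#' aln <- gene_alignment("toy", c(a = "MKL", b = "MRL"), "protein")
#' alignment_length(aln)
#' @export
gene_alignment <- function(gene_id, seqs, seq_type = c("protein", "nucleotide"),
                           codon_aligned = NULL) {
  seq_type <- match.arg(seq_type)
  dc_assert(is.character(gene_id) && length(gene_id) == 1L && nzchar(gene_id),
            "gene_id must be a single non-empty string", "diveconv_format_error")
  dc_assert(is.character(seqs) && length(seqs) >= 1L,
            "alignment must contain at least one sequence",
            "diveconv_format_error")
  taxa <- names(seqs)
  dc_assert(!is.null(taxa) && all(nzchar(taxa)),
            "all sequences must be named by taxon", "diveconv_format_error")
  if (anyDuplicated(taxa)) {
    dc_abort(sprintf("duplicate taxon name(s): %s",
                     paste(unique(taxa[duplicated(taxa)]), collapse = ", ")),
             "diveconv_duplicate_taxon_error")
  }
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    dc_abort(sprintf("ragged alignment: row lengths %s",
                     paste(sort(unique(widths)), collapse = ", ")),
             "diveconv_shape_error")
  }
  if (is.null(codon_aligned)) codon_aligned <- seq_type == "nucleotide"
  if (seq_type == "nucleotide" && codon_aligned && widths[1] %% 3L != 0L) {
    dc_abort(sprintf("codon alignment length %d not divisible by 3", widths[1]),
             "diveconv_frame_error")
  }
  structure(list(gene_id = gene_id, taxa = taxa, seqs = unname(seqs),
                 seq_type = seq_type,
                 codon_aligned = isTRUE(codon_aligned) && seq_type == "nucleotide"),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s: %d taxa x %d %s columns%s\n",
              x$gene_id, length(x$taxa), alignment_length(x),
              x$seq_type, if (x$codon_aligned) " (codon-aligned)" else ""))
  invisible(x)
}

#' Alignment length (columns)
#' @param aln A `gene_alignment`.
#' @return Integer number of alignment columns.
#' @export
alignment_length <- function(aln) {
  if (length(aln$seqs) == 0L) return(0L)
  nchar(aln$seqs[[1]])
}

#' Alignment as a character matrix
#'
#' @param x A `gene_alignment`.
#' @param ... Unused.
#' @return Character matrix, taxa in rows (rownames), columns = alignment
#'   columns.
#' @export
as.matrix.gene_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$taxa
  m
}

# taxa x n_codon matrix of 3-letter codon strings
codon_matrix <- function(aln) {
  dc_assert(aln$seq_type == "nucleotide" && aln$codon_aligned,
            "codon matrix requires a codon-aligned nucleotide alignment",
            "diveconv_mode_error")
  n <- alignment_length(aln) %/% 3L
  m <- matrix("", length(aln$taxa), n, dimnames = list(aln$taxa, NULL))
  starts <- seq.int(1L, by = 3L, length.out = n)
  for (i in seq_along(aln$taxa)) {
    m[i, ] <- substring(aln$seqs[[i]], starts, starts + 2L)
  }
  m
}

#' Read one gene's alignment from FASTA
#'
#' Rows are returned in file order; `"."` gaps are normalised to `"-"`
#' and sequences are upper-cased. Sequence type is guessed from the
#' alphabet unless given.
#'
#' @param path Path to a FASTA file.
#' @param gene_id Gene identifier; defaults to the file name without
#'   extension.
#' @param seq_type `"protein"`, `"nucleotide"`, or `NULL` to guess
#'   (alphabet within `{A,C,G,T,N,-}` means nucleotide).
#' @return A [gene_alignment()].
#' @export
read_alignment_fasta <- function(path, gene_id = NULL, seq_type = NULL) {
  dc_assert(file.exists(path), sprintf("no such file: %s", path),
            "diveconv_io_error")
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    dc_abort(sprintf("cannot parse FASTA %s: %s",
                                     path, conditionMessage(e)),
                             "diveconv_format_error")
                  })
  if (length(set) == 0L) {
    dc_abort(sprintf("empty FASTA file: %s", path), "diveconv_format_error")
  }
  seqs <- as.character(set)
  # headers: take the first whitespace-delimited token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  if (is.null(seq_type)) {
    chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
    seq_type <- if (all(chars %in% c("A", "C", "G", "T", "N", "-")))
      "nucleotide" else "protein"
  }
  gene_alignment(gene_id %||% sub("\\.[^.]*$", "", basename(path)),
                 seqs, seq_type = seq_type,
                 codon_aligned = if (seq_type == "nucleotide")
                   nchar(seqs[[1]]) %% 3L == 0L else FALSE)
}

#' Write an alignment to FASTA
#'
#' @param aln A `gene_alignment`.
#' @param path Output file path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$taxa)) {
    writeLines(paste0(">", aln$taxa[i]), con)
    s <- aln$seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Map an alignment column to an ungapped reference position
#'
#' Reports the 1-based position of alignment column `column` in the
#' ungapped sequence of `ref_taxon` (the count of non-gap reference
#' characters in columns `1..column`). Returns `NA` when the reference
#' itself is gapped at that column.
#'
#' @param aln A `gene_alignment`.
#' @param column 1-based alignment column index.
#' @param ref_taxon Reference taxon name (must be present in `aln`).
#' @return Integer reference position, or `NA_integer_` if the reference
#'   carries a gap at `column`.
#' @examples
#' aln <- gene_alignment("toy", c(r = "M-KL", q = "MAKL"), "protein")
#' map_column_to_reference(aln, 3, "r")  # 2
#' map_column_to_reference(aln, 2, "r")  # NA: gap in reference
#' @export
map_column_to_reference <- function(aln, column, ref_taxon) {
  i <- match(ref_taxon, aln$taxa)
  dc_assert(!is.na(i), sprintf("taxon '%s' absent from alignment", ref_taxon),
            "diveconv_unknown_taxon_error")
  L <- alignment_length(aln)
  dc_assert(is.numeric(column) && length(column) == 1L &&
              column >= 1 && column <= L,
            sprintf("column %s out of range 1..%d", toString(column), L),
            "diveconv_range_error")
  column <- as.integer(column)
  chars <- strsplit(aln$seqs[[i]], "", fixed = TRUE)[[1]]
  if (chars[column] == "-") return(NA_integer_)
  sum(chars[seq_len(column)] != "-")
}
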