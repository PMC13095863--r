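# Phylogeny and taxon-partition input, plus the TSV side tables
# (domain intervals, gene -> term assignments, externally computed
# likelihood pairs).

#' Read a species phylogeny from Newick
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants
#' the downstream scans rely on: unique tip labels and finite,
#' non-negative branch lengths. Trees without branch lengths are
#' accepted with a warning and all lengths set to 0.
#'
#' @param path Path to a file containing a single Newick tree.
#' @return An [ape::phylo] object.
#' @export
read_tree_newick <- function(path) {
  dc_assert(file.exists(path), sprintf("no such file: %s", path),
            "diveconv_io_error")
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    dc_abort(sprintf("unbalanced parentheses in Newick file %s", path),
             "diveconv_parse_error")
  }
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = txt)),
    error = function(e) dc_abort(sprintf("cannot parse Newick %s: %s",
                                         path, conditionMessage(e)),
                                 "diveconv_parse_error"))
  if (is.null(tree) || inherits(tree, "multiPhylo")) {
    dc_abort(sprintf("expected a single Newick tree in %s", path),
             "diveconv_parse_error")
  }
  validate_phylogeny(tree)
}

validate_phylogeny <- function(tree) {
  dc_assert(inherits(tree, "phylo"), "not a phylo object",
            "diveconv_parse_error")
  if (anyDuplicated(tree$tip.label)) {
    dc_abort("duplicate tip labels in tree", "diveconv_duplicate_taxon_error")
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0",
            call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    dc_abort("non-finite branch length in tree", "diveconv_branch_length_error")
  }
  if (any(tree$edge.length < 0)) {
    dc_abort("negative branch length in tree", "diveconv_branch_length_error")
  }
  tree
}

#' Construct a foreground/background taxon partition
#'
#' The bipartition that defines the convergence screen and the selection
#' scan: foreground taxa (here, diving species — their terminal branches
#' are the foreground branch class) versus all remaining background
#' taxa. Sides must be disjoint and non-empty.
#'
#' @param foreground,background Character vectors of taxon names.
#' @return An object of class `taxon_partition`.
#' @export
taxon_partition <- function(foreground, background) {
  foreground <- as.character(foreground)
  background <- as.character(background)
  dc_assert(length(foreground) > 0L, "foreground side is empty",
            "diveconv_partition_error")
  dc_assert(length(background) > 0L, "background side is empty",
            "diveconv_partition_error")
  both <- c(foreground, background)
  if (anyDuplicated(both)) {
    dc_abort(sprintf("taxon in both classes or repeated: %s",
                     paste(unique(both[duplicated(both)]), collapse = ", ")),
             "diveconv_duplicate_taxon_error")
  }
  structure(list(foreground = foreground, background = background),
            class = "taxon_partition")
}

#' @export
print.taxon_partition <- function(x, ...) {
  cat(sprintf("<taxon_partition> %d foreground / %d background taxa\n",
              length(x$foreground), length(x$background)))
  invisible(x)
}

partition_taxa <- function(partition) {
  c(partition$foreground, partition$background)
}

#' Read a taxon partition from TSV
#'
#' Expects a header line and two columns `taxon` and `class`, with class
#' values `foreground` or `background`.
#'
#' @param path Path to the TSV file.
#' @return A [taxon_partition()].
#' @export
read_partition <- function(path) {
  dc_assert(file.exists(path), sprintf("no such file: %s", path),
            "diveconv_io_error")
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", strip.white = TRUE)
  dc_assert(all(c("taxon", "class") %in% names(tab)),
            "partition TSV needs columns 'taxon' and 'class'",
            "diveconv_format_error")
  bad <- setdiff(unique(tab$class), c("foreground", "background"))
  if (length(bad)) {
    dc_abort(sprintf("unknown class label(s): %s", paste(bad, collapse = ", ")),
             "diveconv_format_error")
  }
  taxon_partition(tab$taxon[tab$class == "foreground"],
                  tab$taxon[tab$class == "background"])
}

#' Write a taxon partition to TSV
#' @param partition A [taxon_partition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  tab <- data.frame(
    taxon = c(partition$foreground, partition$background),
    class = rep(c("foreground", "background"),
                c(length(partition$foreground), length(partition$background))),
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read protein-domain intervals from TSV
#'
#' Columns `gene_id`, `domain_name`, `start`, `end`; coordinates are
#' 1-based inclusive protein positions in the same reference used for
#' site reporting.
#'
#' @param path Path to the TSV file.
#' @return A data frame of domain intervals.
#' @export
read_domain_intervals <- function(path) {
  dc_assert(file.exists(path), sprintf("no such file: %s", path),
            "diveconv_io_error")
  tab <- read.delim(path, header = TRUE, sep = "\t", strip.white = TRUE)
  dc_assert(all(c("gene_id", "domain_name", "start", "end") %in% names(tab)),
            "domain TSV needs gene_id, domain_name, start, end",
            "diveconv_format_error")
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  dc_assert(all(tab$start >= 1L) && all(tab$start <= tab$end),
            "domain intervals must satisfy 1 <= start <= end",
            "diveconv_range_error")
  tab
}

#' Read gene-to-term assignments from TSV
#'
#' Columns `gene_id`, `term_id` and optionally `term_name`; duplicate
#' (gene, term) pairs are rejected.
#'
#' @param path Path to the TSV file.
#' @return A data frame of term assignments.
#' @export
read_term_assignments <- function(path) {
  dc_assert(file.exists(path), sprintf("no such file: %s", path),
            "diveconv_io_error")
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", strip.white = TRUE)
  dc_assert(all(c("gene_id", "term_id") %in% names(tab)),
            "term TSV needs gene_id and term_id", "diveconv_format_error")
  if (!"term_name" %in% names(tab)) tab$term_name <- tab$term_id
  if (anyDuplicated(tab[c("gene_id", "term_id")])) {
    dc_abort("duplicate (gene_id, term_id) pair in term assignments",
             "diveconv_format_error")
  }
  tab
}
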