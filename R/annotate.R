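# Domain-interval overlap for convergent sites and hypergeometric term
# enrichment. Domain intervals and gene->term assignments are user
# inputs (protein coordinates of the same reference taxon used for site
# reporting); no database lookup happens here.

#' Overlap convergent sites with protein-domain intervals
#'
#' Labels each site with every domain interval of the same gene whose
#' 1-based inclusive `[start, end]` contains the site's reference
#' position. Sites lacking a reference position are skipped with a
#' warning.
#'
#' @param sites Data frame of convergent sites (from [scan_alignment()]
#'   or [screen_genes()]`$sites`) carrying `ref_position`.
#' @param domains Data frame of domain intervals (`gene_id`,
#'   `domain_name`, `start`, `end`).
#' @return Data frame: one row per (site, covering domain), plus one row
#'   with `domain_name = NA` for sites covered by no domain;
#'   `within_domain` flags coverage. Attribute `"genes"` holds the
#'   per-gene within/outside partition.
#' @export
overlap_sites_domains <- function(sites, domains) {
  dc_assert(all(c("gene_id", "ref_position") %in% names(sites)),
            "sites need gene_id and ref_position", "diveconv_format_error")
  dc_assert(all(c("gene_id", "domain_name", "start", "end") %in% names(domains)),
            "domains need gene_id, domain_name, start, end",
            "diveconv_format_error")
  dc_assert(all(domains$start >= 1L) && all(domains$start <= domains$end),
            "domain intervals must satisfy 1 <= start <= end",
            "diveconv_range_error")
  skipped <- is.na(sites$ref_position)
  if (any(skipped)) {
    warning(sprintf("%d site(s) lack a reference position and were skipped",
                    sum(skipped)), call. = FALSE)
    sites <- sites[!skipped, , drop = FALSE]
  }
  out <- NULL
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, , drop = FALSE]
    d <- domains[domains$gene_id == s$gene_id &
                   domains$start <= s$ref_position &
                   domains$end >= s$ref_position, , drop = FALSE]
    if (nrow(d) == 0L) {
      row <- cbind(s, domain_name = NA_character_,
                   domain_start = NA_integer_, domain_end = NA_integer_,
                   within_domain = FALSE)
      out <- rbind(out, row)
    } else {
      d <- d[order(d$domain_name), , drop = FALSE]
      for (j in seq_len(nrow(d))) {
        row <- cbind(s, domain_name = d$domain_name[j],
                     domain_start = d$start[j], domain_end = d$end[j],
                     within_domain = TRUE)
        out <- rbind(out, row)
      }
    }
  }
  if (is.null(out)) {
    out <- cbind(sites[0, , drop = FALSE], domain_name = character(0),
                 domain_start = integer(0), domain_end = integer(0),
                 within_domain = logical(0))
  }
  rownames(out) <- NULL
  gene_ids <- unique(sites$gene_id)
  within <- vapply(gene_ids, function(g) {
    any(out$within_domain[out$gene_id == g])
  }, logical(1))
  attr(out, "genes") <- data.frame(gene_id = gene_ids,
                                   within_domain = unname(within),
                                   stringsAsFactors = FALSE)
  out
}

#' Upper-tail hypergeometric p-value
#'
#' `P[X >= k]` for `X ~ Hypergeometric(M, K, n)`: drawing `n` genes
#' from a universe of `M` of which `K` carry the term.
#'
#' @param k Flagged genes carrying the term.
#' @param K Universe genes carrying the term.
#' @param n Number of flagged genes.
#' @param M Universe size.
#' @return P-value in `(0, 1]`.
#' @examples
#' hypergeom_pvalue(5, 5, 5, 10)  # 1/252
#' @export
hypergeom_pvalue <- function(k, K, n, M) {
  dc_assert(k >= 0 && K >= 0 && n >= 0 && M >= 1 &&
              k <= min(K, n) && K <= M && n <= M,
            "inconsistent hypergeometric counts", "diveconv_range_error")
  phyper(k - 1, K, M - K, n, lower.tail = FALSE)
}

#' Hypergeometric term over-representation test
#'
#' One-sided enrichment of each term among flagged genes relative to a
#' user-supplied universe, with Benjamini-Hochberg correction across the
#' tested terms. Only terms carried by at least one flagged gene are
#' tested; rows are sorted by p then term id.
#'
#' @param flagged Character vector of flagged gene ids (must be a subset
#'   of `universe`).
#' @param assignments Data frame of gene->term assignments (`gene_id`,
#'   `term_id`, optional `term_name`; unique pairs).
#' @param universe Character vector of all analysed gene ids.
#' @return Data frame: `term_id`, `term_name`, `k`, `K`, `n`, `M`, `p`,
#'   `q`.
#' @export
enrich_terms <- function(flagged, assignments, universe) {
  flagged <- unique(as.character(flagged))
  universe <- unique(as.character(universe))
  outside <- setdiff(flagged, universe)
  if (length(outside)) {
    dc_abort(sprintf("flagged gene(s) absent from universe: %s",
                     paste(outside, collapse = ", ")),
             "diveconv_partition_error")
  }
  dc_assert(all(c("gene_id", "term_id") %in% names(assignments)),
            "assignments need gene_id and term_id", "diveconv_format_error")
  if (!"term_name" %in% names(assignments)) {
    assignments$term_name <- assignments$term_id
  }
  if (anyDuplicated(assignments[c("gene_id", "term_id")])) {
    dc_abort("duplicate (gene_id, term_id) assignment",
             "diveconv_format_error")
  }
  assignments <- assignments[assignments$gene_id %in% universe, , drop = FALSE]
  empty <- data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      M = integer(0), p = numeric(0), q = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(flagged) == 0L || nrow(assignments) == 0L) return(empty)
  M <- length(universe)
  n <- length(flagged)
  terms <- unique(assignments$term_id[assignments$gene_id %in% flagged])
  if (length(terms) == 0L) return(empty)
  rows <- lapply(sort(terms), function(tid) {
    sub <- assignments[assignments$term_id == tid, , drop = FALSE]
    K <- length(unique(sub$gene_id))
    k <- length(unique(sub$gene_id[sub$gene_id %in% flagged]))
    data.frame(term_id = tid, term_name = sub$term_name[1],
               k = k, K = K, n = n, M = M,
               p = hypergeom_pvalue(k, K, n, M),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
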