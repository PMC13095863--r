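# Standard genetic code, CDS translation, and the Nei-Gojobori-style
# counting primitives (expected synonymous/nonsynonymous site counts per
# codon, substitution counts per codon pair averaged over minimal
# stop-free mutational pathways). All codon work uses the 61 sense
# codons of the standard code; stop codons are excluded from every state
# space and pathway.

.dc_cache <- new.env(parent = emptyenv())

genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  setNames(as.character(code), names(code))
}

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense codons in lexicographic
#'   order (the order used for state indexing and tie-breaking).
#' @export
sense_codons <- function() {
  if (is.null(.dc_cache$sense)) {
    code <- genetic_code()
    .dc_cache$sense <- sort(names(code)[code != "*"])
  }
  .dc_cache$sense
}

codon_aa <- function(codons) {
  unname(genetic_code()[codons])
}

codon_index <- function(codons) {
  i <- match(codons, sense_codons())
  if (anyNA(i)) {
    bad <- unique(codons[is.na(i)])
    dc_abort(sprintf("stop or invalid codon(s): %s",
                     paste(bad, collapse = ", ")),
             "diveconv_internal_stop_error")
  }
  i
}

#' Translate a coding sequence to protein
#'
#' Standard genetic code. Codons containing `N` or `-` translate to
#' `"X"`; a terminal stop codon is dropped; an internal stop is an
#' error, as is a length not divisible by 3.
#'
#' @param seq A single nucleotide string over `{A,C,G,T,N,-}`.
#' @return The translated protein string.
#' @examples
#' translate_cds("ATGAAA")   # "MK"
#' translate_cds("ATGNNA")   # "MX"
#' translate_cds("ATGAAATAA")  # "MK": terminal stop dropped
#' @export
translate_cds <- function(seq) {
  dc_assert(is.character(seq) && length(seq) == 1L,
            "seq must be a single string", "diveconv_format_error")
  seq <- toupper(gsub(".", "-", seq, fixed = TRUE))
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    dc_abort(sprintf("sequence length %d not divisible by 3", n),
             "diveconv_frame_error")
  }
  if (n == 0L) return("")
  bad <- setdiff(unique(strsplit(seq, "")[[1]]),
                 c("A", "C", "G", "T", "N", "-"))
  dc_assert(length(bad) == 0L,
            sprintf("invalid nucleotide character(s): %s",
                    paste(bad, collapse = ", ")),
            "diveconv_format_error")
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  code <- genetic_code()
  aa <- ifelse(grepl("[N-]", codons), "X", code[codons])
  if (length(aa) > 1L && aa[length(aa)] == "*" && !is.na(aa[length(aa)])) {
    aa <- aa[-length(aa)]
  } else if (length(aa) == 1L && identical(aa[[1]], "*")) {
    aa <- character(0)
  }
  if (any(aa == "*", na.rm = TRUE)) {
    dc_abort(sprintf("internal stop codon at codon %d",
                     which(aa == "*")[1]),
             "diveconv_internal_stop_error")
  }
  paste(aa, collapse = "")
}

# per-codon expected site counts: each of the 3 positions contributes
# (synonymous single-nt changes)/3 to S and (nonsynonymous)/3 to N;
# changes into stop codons are excluded from the numerators, so
# N + S = 3 - (stop neighbours)/3 per codon.
codon_site_table <- function() {
  if (!is.null(.dc_cache$site_tab)) return(.dc_cache$site_tab)
  codons <- sense_codons()
  code <- genetic_code()
  nts <- c("A", "C", "G", "T")
  N <- S <- numeric(length(codons))
  for (i in seq_along(codons)) {
    cd <- strsplit(codons[i], "")[[1]]
    aa <- code[codons[i]]
    for (pos in 1:3) {
      for (nt in setdiff(nts, cd[pos])) {
        alt <- cd
        alt[pos] <- nt
        alt_cd <- paste(alt, collapse = "")
        alt_aa <- code[alt_cd]
        if (alt_aa == "*") next
        if (alt_aa == aa) S[i] <- S[i] + 1 / 3 else N[i] <- N[i] + 1 / 3
      }
    }
  }
  .dc_cache$site_tab <- list(N = setNames(N, codons), S = setNames(S, codons))
  .dc_cache$site_tab
}

#' Expected nonsynonymous and synonymous site counts of a codon sequence
#'
#' Nei-Gojobori-style counting: for every codon, each of its three
#' positions contributes the fraction (out of 3 possible changes) of
#' single-nucleotide changes that are nonsynonymous to N and synonymous
#' to S; changes creating stop codons are excluded, so `N + S` equals
#' three times the codon count minus the stop-excluded fraction.
#'
#' @param seq Either one gapless codon nucleotide string or a character
#'   vector of codons.
#' @return Named numeric vector `c(N = ..., S = ...)`.
#' @examples
#' ng_site_counts("TTT")  # S = 1/3, N = 8/3
#' @export
ng_site_counts <- function(seq) {
  codons <- as_codons(seq)
  idx <- codon_index(codons)
  tab <- codon_site_table()
  c(N = sum(tab$N[idx]), S = sum(tab$S[idx]))
}

as_codons <- function(seq) {
  if (length(seq) == 1L && nchar(seq[[1]]) > 3L) {
    n <- nchar(seq)
    if (n %% 3L != 0L) {
      dc_abort(sprintf("sequence length %d not divisible by 3", n),
               "diveconv_frame_error")
    }
    starts <- seq.int(1L, n, by = 3L)
    substring(toupper(seq), starts, starts + 2L)
  } else {
    toupper(seq)
  }
}

# 61 x 61 lookup tables of fractional (nd, sd) substitution counts per
# ordered codon pair, averaged over minimal mutational pathways that
# avoid stop codons. When every minimal pathway crosses a stop (rare),
# fall back to all minimal pathways with steps into/out of stops
# counted as nonsynonymous.
codon_pair_tables <- function() {
  if (!is.null(.dc_cache$pair_tab)) return(.dc_cache$pair_tab)
  codons <- sense_codons()
  code <- genetic_code()
  n <- length(codons)
  nd <- sd <- matrix(0, n, n, dimnames = list(codons, codons))
  split_cd <- strsplit(codons, "")
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      diff_pos <- which(split_cd[[i]] != split_cd[[j]])
      k <- length(diff_pos)
      paths <- path_step_counts(split_cd[[i]], split_cd[[j]], diff_pos, code)
      nd[i, j] <- nd[j, i] <- paths["nd"]
      sd[i, j] <- sd[j, i] <- paths["sd"]
    }
  }
  .dc_cache$pair_tab <- list(nd = nd, sd = sd)
  .dc_cache$pair_tab
}

# average (nd, sd) over orderings of the differing positions
path_step_counts <- function(from, to, diff_pos, code) {
  orders <- perms(diff_pos)
  tally <- function(skip_stops) {
    res <- NULL
    for (ord in orders) {
      cur <- from
      ndp <- sdp <- 0
      ok <- TRUE
      for (pos in ord) {
        nxt <- cur
        nxt[pos] <- to[pos]
        aa_cur <- code[paste(cur, collapse = "")]
        aa_nxt <- code[paste(nxt, collapse = "")]
        if (skip_stops && (aa_cur == "*" || aa_nxt == "*")) {
          ok <- FALSE
          break
        }
        if (aa_cur == "*" || aa_nxt == "*" || aa_cur != aa_nxt) {
          ndp <- ndp + 1
        } else {
          sdp <- sdp + 1
        }
        cur <- nxt
      }
      if (ok) res <- rbind(res, c(nd = ndp, sd = sdp))
    }
    res
  }
  res <- tally(skip_stops = TRUE)
  if (is.null(res)) res <- tally(skip_stops = FALSE)
  colMeans(res)
}

perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Fractional substitution counts between two codons
#'
#' For codons differing at k positions, nd (nonsynonymous) and sd
#' (synonymous) step counts are averaged over all minimal
#' single-nucleotide pathways that avoid stop codons; `nd + sd = k`.
#'
#' @param parent,child Sense codon strings.
#' @return Named numeric vector `c(nd = ..., sd = ...)`.
#' @examples
#' count_branch_changes("TTT", "TTC")  # one synonymous step
#' @export
count_branch_changes <- function(parent, child) {
  i <- codon_index(toupper(parent))
  j <- codon_index(toupper(child))
  tab <- codon_pair_tables()
  c(nd = tab$nd[i, j], sd = tab$sd[i, j])
}
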