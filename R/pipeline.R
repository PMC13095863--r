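# End-to-end pipeline: QC -> translate -> convergence screen ->
# selection scan -> (optional) domain annotation -> (optional) term
# enrichment, with a JSON manifest; plus a one-command synthetic demo
# dataset generator.

#' Assemble a pipeline configuration
#'
#' Paths plus the thresholds of the published workflow (minimum aligned
#' length 150 nt, identity 0.70 / coverage 0.50 for pairwise filtering,
#' FDR 0.05) and the screening/permutation policy. Every value can also
#' be supplied in a JSON config file consumed by the command-line
#' wrapper.
#'
#' @param alignments_dir Directory of per-gene FASTA codon alignments.
#' @param tree Path to the Newick species tree.
#' @param partition Path to the taxon partition TSV.
#' @param out_dir Output directory (created if absent).
#' @param ref_taxon Reference taxon for site positions (default: first
#'   background taxon).
#' @param domains,terms Optional paths to domain-interval and
#'   gene-to-term TSVs.
#' @param min_len_nt,fdr,n_perm,qc_rule,max_missing,seed Stage
#'   parameters; see the stage functions.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alignments_dir, tree, partition, out_dir,
                            ref_taxon = NULL, domains = NULL, terms = NULL,
                            min_len_nt = 150L, fdr = 0.05, n_perm = 999L,
                            qc_rule = "or", max_missing = 0L, seed = 1L) {
  dc_assert(fdr > 0 && fdr < 1, "fdr must lie in (0, 1)",
            "diveconv_range_error")
  dc_assert(min_len_nt >= 1, "min_len_nt must be >= 1",
            "diveconv_range_error")
  structure(list(alignments_dir = alignments_dir, tree = tree,
                 partition = partition, out_dir = out_dir,
                 ref_taxon = ref_taxon, domains = domains, terms = terms,
                 min_len_nt = as.integer(min_len_nt), fdr = fdr,
                 n_perm = as.integer(n_perm), qc_rule = qc_rule,
                 max_missing = as.integer(max_missing),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

read_alignment_dir <- function(dir) {
  dc_assert(dir.exists(dir), sprintf("no such directory: %s", dir),
            "diveconv_io_error")
  paths <- sort(list.files(dir, pattern = "\\.(fa|fasta|fna)$",
                           full.names = TRUE))
  dc_assert(length(paths) > 0L,
            sprintf("no FASTA files in %s", dir), "diveconv_io_error")
  alns <- lapply(paths, read_alignment_fasta)
  names(alns) <- vapply(alns, function(a) a$gene_id, "")
  alns
}

#' Run the full analysis pipeline
#'
#' Stages: read inputs, QC the codon alignments, translate passing
#' genes, screen for convergent substitutions, run the
#' counting/permutation selection scan, then (when domain or term
#' tables are supplied) annotate sites against domains and test term
#' enrichment of the selection-flagged genes against the QC-passing
#' universe. All stage tables are written as TSV under `out_dir`
#' together with `manifest.json` (seed, input digests, per-stage
#' counts). Deterministic given identical inputs and seed.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  for (p in c(config$tree, config$partition, config$domains, config$terms)) {
    dc_assert(is.null(p) || file.exists(p),
              sprintf("input file not found: %s", p), "diveconv_io_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tree <- read_tree_newick(config$tree)
  partition <- read_partition(config$partition)
  ref_taxon <- config$ref_taxon %||% partition$background[1]
  alns <- read_alignment_dir(config$alignments_dir)

  qc <- qc_genes(alns, min_length_nt = config$min_len_nt,
                 rule = config$qc_rule)
  rownames(qc) <- NULL
  write_tsv <- function(x, name) {
    write.table(x, file.path(config$out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write_tsv(qc, "qc_report.tsv")
  passing <- alns[qc$gene_id[qc$passed]]

  proteins <- lapply(passing, translate_alignment)
  screen <- screen_genes(proteins, partition,
                         screen_policy(max_missing = config$max_missing),
                         ref_taxon = ref_taxon)
  write_tsv(screen$sites, "convergent_sites.tsv")
  write_tsv(screen$genes, "convergent_genes.tsv")

  sel <- selection_scan(passing, tree, partition, n_perm = config$n_perm,
                        seed = config$seed, fdr = config$fdr)
  write_tsv(sel, "selection_results.tsv")

  n_annotated <- NA_integer_
  if (!is.null(config$domains)) {
    domains <- read_domain_intervals(config$domains)
    annotated <- overlap_sites_domains(screen$sites, domains)
    write_tsv(annotated, "annotated_sites.tsv")
    n_annotated <- sum(annotated$within_domain)
  }
  n_terms <- NA_integer_
  if (!is.null(config$terms)) {
    assignments <- read_term_assignments(config$terms)
    flagged <- sel$gene_id[sel$flagged]
    enrichment <- enrich_terms(flagged, assignments,
                               universe = qc$gene_id[qc$passed])
    write_tsv(enrichment, "enrichment.tsv")
    n_terms <- nrow(enrichment)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("diveconv")),
    seed = config$seed,
    inputs = list(
      tree = unname(tools::md5sum(config$tree)),
      partition = unname(tools::md5sum(config$partition)),
      n_alignments = length(alns)),
    counts = list(
      genes_in = length(alns),
      genes_passing_qc = sum(qc$passed),
      convergent_genes = nrow(screen$genes),
      convergent_sites = nrow(screen$sites),
      selection_flagged = sum(sel$flagged),
      annotated_within_domain = n_annotated,
      enriched_terms_tested = n_terms))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(manifest)
}

#' Generate the synthetic demo dataset
#'
#' Emits a ready-to-run input set under `out_dir`: the fixed 25-taxon
#' tree, the 8-vs-17 diving partition, simulated codon gene alignments
#' (`n_planted` neutral genes with 3 planted convergent columns each,
#' `n_selected` genes with elevated foreground omega, `n_neutral` plain
#' neutral genes), the simulator ground truth, and a JSON pipeline
#' config pointing at it all.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param n_planted,n_selected,n_neutral Gene counts per class
#'   (defaults 10/10/40).
#' @param n_codons Codons per gene (default 300).
#' @param omega_fg Foreground omega of the selected class (default 2).
#' @param omega_bg Background omega (default 0.2 for the selected
#'   class; neutral classes evolve at omega 1 throughout).
#' @param n_sites_planted Convergent columns planted per planted gene.
#' @return Path to the written config JSON, invisibly.
#' @export
make_demo <- function(out_dir, seed = 1L, n_planted = 10L, n_selected = 10L,
                      n_neutral = 40L, n_codons = 300L, omega_fg = 2,
                      omega_bg = 0.2, n_sites_planted = 3L) {
  dir.create(file.path(out_dir, "genes"), recursive = TRUE,
             showWarnings = FALSE)
  tree <- waterfowl_tree()
  partition <- waterfowl_partition()
  ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
  write_partition(partition, file.path(out_dir, "partition.tsv"))

  neutral_cfg <- model_config("codon", length = n_codons, omega_bg = 1,
                              omega_fg = 1, foreground = partition$foreground)
  selected_cfg <- model_config("codon", length = n_codons,
                               omega_bg = omega_bg, omega_fg = omega_fg,
                               foreground = partition$foreground)
  n_genes <- n_planted + n_selected + n_neutral
  configs <- c(rep(list(neutral_cfg), n_planted),
               rep(list(selected_cfg), n_selected),
               rep(list(neutral_cfg), n_neutral))
  dataset <- simulate_dataset(tree, configs, n_genes, seed = seed)
  # plant convergent columns into the first class
  for (i in seq_len(n_planted)) {
    g <- dataset[[i]]
    pl <- plant_convergent_sites(g$alignment, partition, n_sites_planted,
                                 seed = derive_seed(seed, g$truth$gene_id,
                                                    "plant"))
    dataset[[i]]$alignment <- pl$alignment
    dataset[[i]]$truth$planted <- pl$truth
  }
  for (g in dataset) {
    write_alignment_fasta(g$alignment,
                          file.path(out_dir, "genes",
                                    paste0(g$alignment$gene_id, ".fasta")))
  }
  write_truth_tsv(dataset, file.path(out_dir, "truth.tsv"))

  cfg <- list(alignments_dir = file.path(out_dir, "genes"),
              tree = file.path(out_dir, "tree.nwk"),
              partition = file.path(out_dir, "partition.tsv"),
              out_dir = file.path(out_dir, "results"),
              ref_taxon = "Anas_platyrhynchos",
              min_len_nt = 150L, fdr = 0.05, n_perm = 199L,
              qc_rule = "or", max_missing = 0L, seed = as.integer(seed))
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(cfg_path)
}

#' Load a pipeline configuration from JSON
#'
#' @param path Path to a config JSON as written by [make_demo()].
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  dc_assert(file.exists(path), sprintf("no such file: %s", path),
            "diveconv_io_error")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}
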