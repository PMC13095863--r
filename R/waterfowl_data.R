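# Built-in study system: the 25 Anseriformes species analysed for
# diving adaptation, a fixed reference phylogeny for simulation and
# demos, the 8-vs-17 diving/non-diving taxon partition, and the
# published set of convergent amino-acid substitutions used as the
# package's worked example.

#' The 25 Anseriformes species and their foraging strategies
#'
#' @return Data frame with `species` (underscored binomial) and
#'   `foraging` (`Dabbling`, `Diving`, `Walking`). Diving species are
#'   the foreground of the built-in partition.
#' @export
waterfowl_species <- function() {
  data.frame(
    species = c(
      "Aix_galericulata", "Anas_bernieri", "Anas_platyrhynchos",
      "Asarcornis_scutulata", "Lophonetta_specularioides",
      "Mareca_falcata", "Mareca_strepera", "Sibirionetta_formosa",
      "Spatula_versicolor", "Speculanas_specularis", "Tadorna_tadorna",
      "Cygnus_olor",
      "Bucephala_clangula", "Clangula_hyemalis", "Melanitta_perspicillata",
      "Mergus_serrator", "Nettapus_auritus", "Somateria_mollissima",
      "Heteronetta_atricapilla", "Oxyura_jamaicensis",
      "Alopochen_aegyptiaca", "Anser_anser", "Anser_cygnoides",
      "Anser_indicus", "Branta_ruficollis"),
    foraging = c(rep("Dabbling", 12), rep("Diving", 8), rep("Walking", 5)),
    stringsAsFactors = FALSE)
}

#' Built-in diving/non-diving taxon partition
#'
#' Eight diving species as foreground, the 17 dabbling/walking species
#' as background.
#'
#' @return A [taxon_partition()].
#' @export
waterfowl_partition <- function() {
  sp <- waterfowl_species()
  taxon_partition(sp$species[sp$foraging == "Diving"],
                  sp$species[sp$foraging != "Diving"])
}

#' Fixed 25-taxon reference phylogeny
#'
#' A fixed rooted tree over the 25 species with branch lengths in
#' expected substitutions per codon, used by the simulator and the demo
#' pipeline. Diving lineages sit in two separate clades (sea ducks, and
#' stifftails plus the pygmy goose), mirroring the repeated independent
#' origins of diving in the order; the topology is a fixed package
#' convention, not an inference. All terminal branches share one length
#' (0.05), so under an omega-homogeneous model the foreground and
#' background terminal-branch classes are statistically
#' indistinguishable — the exchangeability that the tip-relabelling
#' permutation null of [permutation_test()] relies on; internal branch
#' lengths vary.
#'
#' @return An [ape::phylo] with 25 tips.
#' @export
waterfowl_tree <- function() {
  nwk <- paste0(
    "(((((Anser_anser:0.05,Anser_cygnoides:0.05):0.012,",
    "Anser_indicus:0.05):0.015,Branta_ruficollis:0.05):0.018,",
    "(Alopochen_aegyptiaca:0.05,Tadorna_tadorna:0.05):0.015):0.020,",
    "((Cygnus_olor:0.05,",
    "((Oxyura_jamaicensis:0.05,Heteronetta_atricapilla:0.05):0.025,",
    "Nettapus_auritus:0.05):0.018):0.012,",
    "(((Bucephala_clangula:0.05,Mergus_serrator:0.05):0.015,",
    "(Melanitta_perspicillata:0.05,",
    "(Clangula_hyemalis:0.05,Somateria_mollissima:0.05):0.010):0.012):0.025,",
    "((((Anas_platyrhynchos:0.05,Anas_bernieri:0.05):0.010,",
    "(Mareca_falcata:0.05,Mareca_strepera:0.05):0.012):0.008,",
    "((Spatula_versicolor:0.05,Sibirionetta_formosa:0.05):0.008,",
    "(Speculanas_specularis:0.05,Lophonetta_specularioides:0.05):0.010):0.008):0.012,",
    "(Aix_galericulata:0.05,Asarcornis_scutulata:0.05):0.010):0.020):0.015):0.018);")
  ape::read.tree(text = nwk)
}

#' Published convergent substitutions in diving waterfowl
#'
#' The 11 genes reported to carry an amino-acid substitution shared by
#' all eight diving species and absent from all 17 non-diving species,
#' with the protein position and the residues on each side.
#'
#' @return Data frame: `gene_id`, `position`, `bg_residue` (non-diving),
#'   `fg_residue` (diving).
#' @export
diving_site_table <- function() {
  data.frame(
    gene_id = c("ARNT2", "CHST9", "CRACDL", "GPR34", "KIF11", "PKD1",
                "PLB1", "PLEKHG1", "SH3TC1", "SLIT3", "THADA"),
    position = c(176L, 246L, 492L, 152L, 975L, 194L, 209L, 1144L,
                 1286L, 1067L, 144L),
    bg_residue = c("V", "G", "P", "V", "V", "T", "L", "A", "T", "H", "S"),
    fg_residue = c("I", "S", "S", "I", "M", "A", "M", "V", "I", "R", "P"),
    stringsAsFactors = FALSE)
}

#' Encode the published substitution table as toy alignments
#'
#' Builds one gapless 25-taxon protein alignment per gene of
#' [diving_site_table()]: at the stated position the eight diving
#' (foreground) taxa carry the diving residue and the 17 non-diving
#' (background) taxa the non-diving residue; every other column is
#' invariant. Optionally adds fully invariant decoy genes containing no
#' qualifying column. Because the alignments are gapless, alignment
#' columns equal reference positions in any taxon.
#'
#' @param n_decoys Number of invariant decoy genes to append.
#' @param flank Number of invariant columns after the substitution
#'   position.
#' @return Named list of [gene_alignment()] objects.
#' @export
convergence_example_alignments <- function(n_decoys = 4L, flank = 10L) {
  part <- waterfowl_partition()
  taxa <- partition_taxa(part)
  tab <- diving_site_table()
  filler <- function(len) {
    # invariant columns cycle through the residue alphabet
    paste(AMINO_ACIDS[(seq_len(len) - 1L) %% 20L + 1L], collapse = "")
  }
  build <- function(gene_id, position, bg, fg) {
    len <- position + flank
    base <- filler(len)
    rows <- setNames(rep(base, length(taxa)), taxa)
    substr(rows[part$background], position, position) <- bg
    substr(rows[part$foreground], position, position) <- fg
    gene_alignment(gene_id, rows, "protein")
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    build(tab$gene_id[i], tab$position[i], tab$bg_residue[i],
          tab$fg_residue[i])
  })
  names(out) <- tab$gene_id
  for (d in seq_len(n_decoys)) {
    gid <- sprintf("DECOY%d", d)
    rows <- setNames(rep(filler(120L), length(taxa)), taxa)
    out[[gid]] <- gene_alignment(gid, rows, "protein")
  }
  out
}
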