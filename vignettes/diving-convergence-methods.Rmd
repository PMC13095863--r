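---
title: "Methods: convergence screening and selection scanning in diving waterfowl"
author: "diveconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convergence screening and selection scanning in diving waterfowl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diveconv)
```

# The scientific problem

Diving waterfowl face hypoxia and hydrostatic pressure that surface-feeding
relatives never experience. Because diving evolved repeatedly within
Anseriformes, the order offers an internal control: eight diving species can
be contrasted against seventeen non-diving relatives within one clade.
`diveconv` implements the two genomic contrasts used for this design:

1. **A convergence screen.** An alignment column is a *shared amino-acid
   substitution* of the diving lineages when one residue is consistent across
   all seventeen non-diving (background) species and a different residue is
   carried by all eight diving (foreground) species.
2. **A foreground-vs-background selection scan.** Per gene, the ratio
   $\omega = d_N/d_S$ of nonsynonymous to synonymous substitution rates is
   contrasted between the terminal branches of the diving tips (foreground
   branch class) and all remaining branches (background class); $\omega > 1$
   on the foreground suggests positive selection associated with diving.

The screen is exact and combinatorial; the scan is a counting-based
approximation whose decision machinery (likelihood-ratio test, chi-square
p-values, Benjamini–Hochberg FDR at $q < 0.05$) can also be applied to
likelihood pairs computed externally with full branch-site codon models.

# The convergence screen

`classify_column()` implements the criterion literally. For a column
$c : \text{taxon} \to \text{residue}$ and a partition $(F, B)$, a call
$(X, Y)$ is returned iff

* $c(b) = X$ for every $b \in B$, with $X$ one of the 20 standard residues,
* $c(f) = Y$ for every $f \in F$, with $Y$ standard,
* $X \neq Y$, and
* the missing-data policy is satisfied.

Under the **strict** default policy any gap (`-`), stop (`*`), ambiguous
residue (`X`, treated as missing by default) or absent taxon anywhere in the
column vetoes the call. This matches the single-copy-ortholog setting where
every species is expected to be present. `screen_policy(max_missing = k)`
tolerates up to `k` missing taxa per column and calls on the remainder; this
is an explicit relaxation, off by default, and any non-standard residue that
is not policy-missing still vetoes. Scanning is column-independent, so the
screen is exactly reproducible and is tested against a brute-force predicate
by exhaustive enumeration of all $4^6$ columns of a 6-taxon toy system.

Positions are reported both as alignment columns and as 1-based ungapped
positions in a user-named reference taxon (`map_column_to_reference()`);
inclusive 1-based coordinates are used everywhere. Codon alignments are
translated before screening (`translate_cds()`: standard code, codons with
`N` or `-` become `X`, a terminal stop is dropped, an internal stop is an
error).

# The counting-based selection scan

A full branch-site codon maximum-likelihood fit is out of scope by design;
the scan is an explicitly labelled counting stand-in.

1. **Ancestral codons** are reconstructed by Fitch small parsimony treating
   each codon column as one 61-state character (stop codons are excluded
   from the state space). Ties are resolved deterministically: the top-down
   pass prefers the parent's state, otherwise the lexicographically smallest
   codon; the root takes the smallest member of its state set.
2. **Substitutions per branch** are counted from the reconstruction:
   for a codon pair differing at $k$ positions, nonsynonymous ($n_d$) and
   synonymous ($s_d$) step counts are averaged over all $k!$ minimal
   single-nucleotide pathways that avoid stop codons, so $n_d + s_d = k$.
   If every minimal pathway crosses a stop (a rare corner the classical
   counting method leaves undefined), the average is taken over all minimal
   pathways with steps into or out of stops classified nonsynonymous.
3. **Expected site counts** follow Nei–Gojobori-style counting: each codon
   position contributes (synonymous single-nucleotide changes)/3 to $S$ and
   (nonsynonymous changes)/3 to $N$, with changes into stop codons excluded
   from the numerators; hence $N + S$ equals three times the codon count
   minus the stop-excluded fraction.
4. **Class summaries.** The foreground class is the set of terminal branches
   of foreground tips; the background class is every other branch. Within a
   class, $N_d, S_d$ are summed over branches, $N, S$ are the mean per-branch
   site counts (each branch's $N$ being the mean of its endpoint sequences'
   counts), and
   $\hat\omega = (N_d/N) \,/\, (S_d/S)$, undefined when $S_d = 0$.
5. **Permutation null.** The statistic is
   $\Delta = \log(\hat\omega_{fg}/\hat\omega_{bg})$. Random same-size tip
   subsets are relabelled as foreground and $\Delta$ recomputed from the same
   per-branch counts;
   $p = (1 + \#\{\Delta_{perm} \ge \Delta_{obs}\})/(1 + n_{perm})$.
   Genes with undefined $\hat\omega$ report $p = 1$ and are flagged
   `undefined`, never significant. BH correction across genes and the
   $q < 0.05$ rule give the flagged set.

Counting is unbiased for $\omega$ only at low divergence and when the
generating process weighs all single-nucleotide exchanges equally. No
multiple-hit correction is applied (desk-scale divergences are small), and
unweighted site counting would be biased if transitions were favoured —
which motivates the simulator default $\kappa = 1$ below. On the built-in
tree (terminal branches of 0.05 substitutions/codon), 2,000-codon genes
simulated at $\omega_{bg} = 0.2$, $\omega_{fg} = 2.0$ are recovered with the
correct ordering in at least 95/100 replicates and class medians within
25% of truth (this is recomputed by the test suite, not quoted here).

# The simulator and its stated world

`simulate_gene()` evolves sites independently along the tree using the exact
transition kernel $P(t) = e^{Qt}$, computed by eigendecomposition of the
detailed-balance-symmetrised generator; no event-driven simulation is used.
Defaults define the package's reference world:

* **Tree**: a fixed 25-taxon phylogeny over the study species
  (`waterfowl_tree()`), with the eight diving species in two separate clades
  (diving evolved repeatedly). Terminal branch lengths are all 0.05
  substitutions/codon; internal lengths vary (0.008–0.025). Equal terminal
  lengths make the two terminal-branch classes statistically
  indistinguishable under an $\omega$-homogeneous model — the
  exchangeability that the tip-relabelling permutation null requires for
  type-I calibration. An earlier draft with heterogeneous terminal lengths
  made the permutation test measurably conservative, which is the expected
  behaviour when relabelling is not a symmetry of the null, not a defect of
  the counting machinery.
* **Model**: uniform stationary frequencies and uniform exchangeabilities
  ($\kappa = 1$) by default, in both protein (20 states) and codon (61
  sense codons, GY94-style sparsity: only single-nucleotide exchanges) modes.
  Uniform defaults keep analytic expectations checkable and keep unweighted
  counting unbiased; $\kappa$, $\pi$, and the two $\omega$ values are
  configurable (`model_config()`).
* **Branch classes**: in codon mode the foreground $\omega$ applies on the
  terminal branches of the configured foreground tips only, mirroring the
  foreground definition of the scan.
* **Seeds**: one master seed; per-gene streams are derived by a stable
  string hash of (seed, gene id) kept below $2^{31}$, so datasets are
  byte-identical across runs. Simulation within a gene is sequential in a
  fixed traversal order, so no per-branch streams are needed.
* **Planted convergence**: `plant_convergent_sites()` overwrites whole
  columns with a background residue X and a foreground residue Y
  ($X \neq Y$, drawn from the 20 standard residues); on codon alignments the
  lexicographically smallest sense codon of each residue is written. Planted
  columns satisfy the screen's criterion by construction, which is what
  makes sensitivity-1 recovery a meaningful end-to-end check of the
  plumbing rather than of the criterion itself.

What the generator does **not** emulate: insertions/deletions, rate
heterogeneity across sites, site-class mixtures of the true branch-site
model, alignment error, and non-uniform codon usage. A green simulation test
therefore establishes correctness of the implemented computations on clean
data, not robustness to real-data artefacts.

# Quality control

`qc_gene_alignment()` applies the published preparation rules for codon
alignments: exclusion when shorter than 150 nt and/or when containing gaps.
The source sentence is ambiguous between an AND and an OR reading; the
default is OR (both criteria exclude independently), matching the
conventional preparation of gapless input for codon-model fitting, and both
reasons are always recorded so the AND reading (`rule = "and"`) is
recoverable from the same report. Frame violations and internal stop codons
are always exclusionary. `identity_coverage_filter()` implements the
pairwise CDS-extraction thresholds (identity $\ge$ 0.70 over columns where
both rows are non-gap; coverage $\ge$ 0.50 of the full ungapped reference
length, both inclusive); the denominators are the package's choice since the
source states thresholds but not definitions.

# Annotation and enrichment

`overlap_sites_domains()` intersects convergent-site reference positions
with user-supplied 1-based inclusive domain intervals (domain databases are
not queried); both endpoints are within the domain. `enrich_terms()` applies
a one-sided hypergeometric over-representation test per term with BH
correction. The enrichment statistic is a reconstruction — the original
analysis names no method — and the background universe must be supplied
explicitly (the QC-passing gene set in the pipeline), since the original
choice of universe is unstated.

# Numerical and design choices

* Chi-square LRT p-values default to `df = 1`; the 50:50 point-mass/$\chi^2_1$
  mixture for boundary null hypotheses is available via `mixture = TRUE`.
  The statistic $2(\ln L_1 - \ln L_0)$ is clamped at 0, giving $p = 1$.
* $\hat\omega$ with $S_d = 0$ is reported as `NA`, not $\infty$, and such
  genes are never flagged.
* BH q-values are computed with `stats::p.adjust` and verified in the test
  suite against a hand step-up implementation; the hypergeometric upper tail
  uses `stats::phyper` and is verified against binomial-coefficient
  enumeration.
* All output tables are sorted lexicographically by (gene, column) or
  (p, term), so reruns diff cleanly; the pipeline writes a JSON manifest
  with input digests and per-stage counts.
* Configuration files are JSON rather than YAML (no YAML parser is part of
  the package's dependency footprint).

# Known limitations

The scan's counting approximation degrades with divergence (multiple hits,
parsimony reconstruction error both bias $\hat\omega$ toward 1) and its
permutation null assumes terminal branches are exchangeable under the null;
on real trees with strongly heterogeneous tip branch lengths the test will
be conservative or anticonservative accordingly, and externally computed
branch-site likelihoods fed through `lrt_test()` are the better instrument.
The screen itself is intentionally strict: a single discordant or missing
taxon suppresses a site, so its sensitivity on real (gappy) orthologs
depends on upstream alignment quality, which is why the QC stage precedes
it.
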