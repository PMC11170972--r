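---
title: "Methods: comparative genomics of cultivated genome collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of cultivated genome collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`panlachno` reimplements, as one tested pipeline, the comparative-genomics
workflow commonly applied to large cultivated collections of gut bacterial
genomes (our motivating system is the family *Lachnospiraceae*, an abundant,
strictly anaerobic clade of the mammalian intestine and a leading source of
next-generation probiotic candidates). This vignette describes the models and
procedures, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## Species delineation by average nucleotide identity

ANI between a query and a reference genome is estimated the way fragment
mappers define it: the query is cut into consecutive windows
(`fragment_length = 1000` bp), each window is placed on the reference by
shared 16-mer seeding with best-diagonal voting followed by ungapped
columnwise comparison, and ANI is 100 times the mean identity over windows
whose identity reaches `min_fragment_identity = 0.80`. An estimate whose
mapped fraction falls below `min_mapped_fraction = 0.2` is flagged
unreliable. Directional estimates are symmetrized by their mean — fragment
ANI is inherently asymmetric and a single orientation is not canonically
preferred — and unreliable pairs are imputed as 0 ANI (distance 1.0) so the
downstream linkage stays well defined, mirroring dereplication practice.

Species are delineated by complete-linkage hierarchical clustering of
`(100 - ANI)/100` distances, cut at height 0.05: genomes sharing at least
95% ANI are the same species, the conventional prokaryotic species boundary.
The cut is inclusive at exactly 95.00 ANI. Cluster ids are deterministic
(size-descending, ties broken by the lexicographically smallest member).
Habitat specificity of the resulting clusters is summarized as the
percentage of single-habitat clusters plus a Pearson chi-squared test
(without continuity correction) of the cluster-by-habitat table; on small
tables the null distribution of its p value is discrete, which is why the
test suite checks calibration rather than exact uniformity.

## 16S rRNA novelty gating and OTU clustering

Full-length 16S identity is computed from a global (Needleman–Wunsch)
alignment with match +2, mismatch −3, gap open −5, gap extend −2 (a gap of
length $L$ costs $5 + 2(L-1)$), as matches divided by alignment columns.
Global rather than local alignment is deliberate: full-length 16S comparison
is the intended semantics and is reproducible without HSP heuristics; near
the thresholds this may differ slightly from a local-alignment identity, so
the scoring constants are part of the package contract. Queries are gated at
the conventional demarcations — at least 98.7% identity to a reference means
a known species, $[94.5, 98.7)$ a potentially novel species, below 94.5% a
potentially novel genus — with boundaries inclusive on the "known" side.
Novel sequences are grouped by greedy centroid OTU clustering (sort by
length, first sequence founds an OTU, each next sequence joins the
earliest-founded centroid it matches at the threshold).

## Pan-genome structure

One greedy incremental clustering engine stands behind the three catalog
constructions used in this field, exposed as presets: `gene_catalog`
(nucleotide, identity 0.95, coverage 0.90 of the shorter sequence),
`protein_catalog` (amino acid, identity 0.95, coverage 0.80 of the
representative) and `pangenome` (nucleotide, identity 0.90). Sequences are
processed longest-first; each joins the earliest-founded representative it
matches, with candidate representatives prefiltered by shared k-mers
(k = 12 nt / 5 aa, at least 2 shared), which at the identities of interest
loses nothing while keeping the scan linear. Paralog splitting and synteny
refinement (as done by Roary) are not reproduced; one-genome-many-member
families are allowed.

Families are partitioned by prevalence into core (at least 0.99 of genomes),
soft-core [0.95, 0.99), shell [0.15, 0.95) and cloud (below 0.15) — the
Roary bounds, exposed as configuration. Accumulation curves average the
families-seen (pan) and families-shared (core) counts over seeded random
genome orderings. Between-genome Jaccard distances are computed with
`vegan::vegdist(binary = TRUE)`; lineage divergence within versus between
phylogenetic branches is summarized by both medians (percent scale) and a
two-sided Wilcoxon rank-sum test, exact when both pair sets have at most 10
elements and the tie-corrected normal approximation otherwise.

## SCFA pathway screens and sporulation signature

Pathway models are lists of routes; a route is an ordered list of steps and
each step a set of acceptable enzyme labels (OR within a step). Butyrate
production from acetyl-CoA has two routes sharing Thl, Hbd, Cro and Bcd and
ending either in the butyryl-CoA:acetate CoA-transferase (But) or in
phosphate butyryltransferase plus butyrate kinase (Ptb, Buk). Propionate
production from propionyl-CoA has three routes: the one-step CoA-transferase
(Pct), the one-step CoA-ligase (ACSS1_2 or ACSS3 or Acd), and the two-step
phosphotransferase/kinase route (Pta or PduL, then AckA or TdcD). A route is
complete iff every step has a present enzyme; a pathway iff any route is.

Enzyme presence is called by Smith–Waterman local alignment (BLOSUM62, gap
open 11 / extend 1, undetermined residues scoring 0) of each proteome member
against a reference enzyme set, requiring identity at least 0.60, coverage
of the reference enzyme at least 0.50, and a raw score of at least 50. The
score floor stands in for the usual e-value cutoff: at these protein lengths
the identity and coverage conditions dominate, and a raw floor is
reproducible without database-size-dependent statistics. Coverage is taken
over the reference (subject) sequence; per label the best-scoring passing
query is kept. The sporulation screen is an exact, case-insensitive
gene-name match of annotations against a signature list supplied as
configuration (66 names in the motivating application), with the absence of
the master regulator *spo0A* flagged specially. Niche structure of the
binary sporulation profiles is visualized by classical-scaling PCoA
(`stats::cmdscale` with a deterministic axis-sign convention).

## SNP calling, effects, and trees

SNPs of a genome against a designated reference are called by
anchor-and-compare: unique 21-mers shared by both sequences vote for a
dominant diagonal; the anchored span is compared columnwise. This is exact
for substitution-only divergence, which is the regime the generator produces
(below); indel-containing segments fall off the diagonal and are simply not
compared. Coding effects are annotated by recomputing the affected codon
with the alternate base under bacterial translation table 11, with start
codons {ATG, GTG, TTG}: stop_gained, stop_lost and start_lost are HIGH
impact, missense MODERATE, synonymous LOW, intergenic MODIFIER. A variant in
codon 1 that destroys the start codon is classified start_lost even when the
encoded amino acid is unchanged. Translation is literal (no
initiator-codon-to-methionine coercion), a convention the homology screens
are insensitive to.

Pairwise SNP distances (differing called sites over jointly compared sites)
feed a neighbor-joining tree (`ape::nj`, negative branch lengths clamped to
0). The original analyses report clades "divided based on genetic distance"
without a stated rule; here clade assignment is an average-linkage cut at a
user-chosen `k` or height, recorded in the output. Per-gene variant density
is binned (default 50 bp) by effect class, with the fraction of genomes
carrying a premature stop reported overall and per clade.

## Differential abundance and co-occurrence

Genome-by-sample count tables are filtered by the presence rule: all-zero
samples and genomes are dropped, a genome is present in a sample when its
relative abundance reaches 0.001%, and genomes present in at least 10% of
samples (inclusive) are retained. The test is a native exact negative
binomial test: size factors by median-of-ratios (library-size fallback),
per-genome dispersions by the method of moments on normalized counts pooled
within groups, shrunk 50% toward a lowess mean-dispersion trend, and a
two-sided exact test on group total counts (the sum of $n$ i.i.d.
NB($\mu,\phi$) draws is NB($n\mu,\phi/n$); conditioning on the overall
total, the conditional probabilities not exceeding that of the observed
split are summed). This is deliberately a documented exact-style NB test,
not a clone of any particular package's empirical-Bayes machinery; its
contract is simulation calibration (type-I error near nominal under the
null), which the test suite checks. Fold-changes come from normalized group
means with a prior count of 0.5, capped at ±20. Markers require
BH-adjusted p below 0.01 and |log2FC| strictly above 1, with a roll-up to
distinct species clusters per direction. Co-occurrence networks use Pearson
correlation (Spearman by flag) on log10(relative abundance + 1e-6), p values
from the t-transform of r, BH over all pairs, and edges at |r| > 0.3 and
adjusted p < 0.01. Whether the original analyses correlated counts,
relative abundances or transforms is not stated; these defaults are the
package's documented choice, not a claim about the source analyses.

One caveat worth knowing: when a large fraction of genomes is differentially
abundant in one direction, median-of-ratios size factors absorb part of the
effect (the classic composition bias, shared by all global-scaling
normalizations). At a 5% DE fraction the planted log2FC of 2 is recovered
essentially unbiased; at 20% one-directional DE the estimate shrinks by
roughly 0.3.

## The synthetic collection generator

The generator is first-class, tested code that defines the study conditions
for every downstream stage. A shared root genome (i.i.d. uniform ACGT, one
contig, default 100 kb) carries all gene families, placed non-overlapping on
the forward strand (a configurable fraction on the reverse strand) with
short random spacers. Species ancestors are independent mutated copies of
the root at the between-species rate (default 0.15, so pairwise
between-species divergence is about twice that — recorded empirically, not
assumed); strains are mutated copies of their ancestor at the within-species
rate (default 0.01). Mutation is substitution-only — the number of
substituted sites is Binomial(length, rate) and replacements are uniform
over the other three bases — so ANI and SNP truth are exactly columnwise.
Indels, codon models, recombination and HGT are deliberately not simulated;
passing tests therefore demonstrate correctness of the procedures on the
no-indel regime, not robustness to structural variation in real assemblies.

Accessory families are dropped per genome (Bernoulli retention by default;
an exact per-family presence count is available for noise-free prevalence
constructions). By default a lost family is omitted from the annotation and
protein output while its chromosomal span is retained, keeping
nucleotide-level truth exactly columnwise (and the within/between ANI gap
intact); a scramble mode additionally replaces the span with random
sequence when sequence-level loss is wanted. Pathway enzymes and 16S genes
are planted per genome at an exact configured identity to synthetic
references (substituting exactly `round((1-t) * length)` positions), so the
homology and novelty layers have sharp planted truth. Emitted proteins are
translations of the emitted genome, a consistency the tests verify.

All randomness is governed by one integer seed (per-stage seeds derived by a
fixed affine counter scheme, kept below $2^{31}$); a fixed seed yields
byte-identical FASTA/GFF3/TSV output.

## Problem sizes and numerical choices

The test and acceptance workloads use: 40 ANI pairs of 100 kb at
divergences 0.005–0.05; a 5-species × 6-strain collection for partition
recovery; a 20-strain single-species collection with 500 core and 300
two-genome accessory families (430 kb genomes, within-species divergence
0.005 for that construction so that member-to-representative identity sits
about 7 standard deviations above the 0.95 catalog cutoff and the planted
counts are recovered without chance splits); exhaustive codon-substitution
enumeration for the effect classifier; SNP calling at divergences
0.001–0.05; and NB simulations with 2000 genomes at 20+20 samples (null,
dispersion 0.2) and 30+30 samples (100 genomes planted at log2FC = 2 among
1900 nulls). These sizes were chosen so each property is measured with
comfortable statistical margin on a single CPU.

Other numerical conventions: gap costs are open + (L−1)·extend; alignment
ties in the 16S best-hit scan break to the lexicographically smaller
reference id; greedy clustering orders by length descending then id;
`cutree` boundaries are inclusive; chi-squared tests are uncorrected;
Wilcoxon is exact only for small samples; BH is the step-up procedure of
`stats::p.adjust`. Internal coordinates are 1-based inclusive throughout
(the native R and GFF3 convention), converted only when emitting VCF-style
records, which are already 1-based.

## Known limitations

- No indel handling in ANI, SNP calling or effect annotation (frameshifts
  are out of scope); real draft assemblies with structural variation need
  the usual external aligners.
- Greedy clustering is order-dependent by construction (as are the tools it
  mirrors); the deterministic ordering makes runs reproducible but a
  different ordering rule could split borderline families differently.
- The exact NB test conditions on rounded normalized totals; with very
  small library-size differences this rounding is negligible, but extreme
  size-factor spread would warrant quantile-adjusted pseudo-counts.
- The clade rule for SNP trees and the correlation transform for
  co-occurrence are package choices where the field's practice is
  heterogeneous; both are recorded in outputs.
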