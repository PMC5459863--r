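---
title: "Methods: aquaporin family annotation and expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aquaporin family annotation and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqpscan)
```

## Scope and model

Plant aquaporins (major intrinsic proteins, MIPs) are six-helix membrane
channels whose substrate range is encoded by a handful of conserved sequence
features: two NPA-type half-helix motifs in loops B and E, the spacing
between them, the four-residue aromatic/arginine (ar/R) selectivity filter at
positions H2, H5, LE1 and LE2, a fifth contributing Loop-C residue, and the
five Froger positions that separate glycerol-transporting from
water-selective channels. `aqpscan` turns the manual genome-wide
characterization workflow for this family — candidate screening, motif and
filter annotation, subfamily classification and naming, substrate prediction,
and the standard RNA-seq summaries — into tested, deterministic code.

The package ships a transcribed 120-row feature table for *Brassica napus*
(`load_bnapus_table()`) that anchors the conventions (motif positions are 1-based
indices of the motif's N residue; the NPA–NPA distance equals
`le_pos - lb_pos - 3`, a relation that holds for every complete row of the
table and is enforced by `validate_bnapus_fixture()`).

## Sequence-level computations

**Transmembrane segments.** External topology servers are replaced by a
self-contained Kyte–Doolittle scanner: a centered window (default 19) is
averaged, residues with window mean ≥ 1.6 seed runs, runs separated by fewer
than 3 residues merge, and merged runs shorter than 15 residues are dropped.
Windows are truncated at the termini (the mean is taken over the available
residues) so that helices abutting a sequence end remain detectable; `X`
residues are excluded from window means. A segment's reported
`mean_hydropathy` is the mean over its qualifying residues, so it is at least
the threshold by construction.

**Physicochemistry.** Molecular weight uses average residue masses plus one
water; `X` counts as the mean residue mass and flags the value approximate.
The isoelectric point is found by bisection on the monotone
Henderson–Hasselbalch net-charge function with an EMBOSS-style pKa set
(recorded in the result's `pka` attribute, since published family averages do
not state which server constants produced them; no numeric reconciliation is
attempted). Bisection runs to at most 60 iterations and stops only when both
the pH bracket is below 0.01 and the residual net charge is below 0.01.

**Motifs and spacing.** `scan_npa_candidates()` reports every N-P-x
occurrence with x in {A, S, V, L, C, T, G} — the variants observed in the
family, configurable. `select_motif_pair()` admits ordered pairs with
spacing in a window (default [85, 150], spanning the family's printed range
92–143) and picks the pair closest to the subfamily-expected spacing when one
is known, falling back to the leftmost loop-B motif. Absence of a qualifying
pair is a value, not an error: such proteins are flagged `needs_review`,
mirroring the family workflow in which single- or missing-motif proteins are
examined manually.

**Guided extraction.** Filter and Froger residues are read off a global
affine-gap alignment (Needleman–Wunsch/Gotoh, BLOSUM62, gap open 10 / extend
1, a gap of length *k* costing `open + (k-1)·extend`) against the
best-scoring annotated reference. Traceback ties break deterministically
(diagonal, then up, then left). Reference positions aligned to a gap yield
the undefined marker `-`, which lowers the confidence tier of any downstream
specificity call. An alignment identity below 30% raises a `low_identity`
extraction-quality flag.

## Screening, classification, naming, specificity

Screening keeps proteins of length 150–450 with at least 5 predicted
membrane segments (6 expected; 5 tolerates prediction error) and at least
one NPA-variant motif; every exclusion carries machine-readable reason
codes. Classification adopts the subfamily/group of the best-scoring
reference, with a threshold of 40% of that reference's self-alignment
score — a reproducible stand-in for tool-specific bit-score cutoffs.
Genome letters come from chromosome prefixes; scaffold-only genes take the
genome of their best-scoring progenitor reference with a `_random` suffix.
Paralog letters a, b, c are assigned within (genome, group) sets ordered by
chromosome then start coordinate, with scaffold genes last and gene-id
lexicographic order as the stable tie-break — the authors' own ordering on
unanchored scaffolds is not recoverable, so this convention may differ from
theirs there.

Substrate specificity is data, not code: `inst/extdata/specificity_rules.tsv`
maps filter patterns (pipe-separated alternatives per position) and an
optional required spacing to (substrate, tier) pairs. The F-H-T-R filter
predicts water; tonoplast-type filters add urea and hydrogen peroxide at
tier 2; W-[VI]-A-R (NIP-I) predicts glycerol; A-[IV]-[GA]-R (NIP-II)
predicts boric acid; and silicic acid is predicted only for G-S-G-R at
exactly 108-residue spacing, reflecting the coupling of filter and spacing
in silicon-permeable channels. One known ambiguity: the TIP4 filter
A-I-A-R matches the NIP-II pattern, and such proteins receive the NIP-II
substrates — the two groups genuinely share the filter, and classification
(not the filter alone) distinguishes them.

The quality-control tree uses neighbor joining (via `ape`) on
`1 - fractional identity` distances; the full maximum-likelihood,
bootstrapped phylogeny of the original workflow is out of scope.

## Expression analyses

RPKM is `1e9 · count / (length_bp · sample_total)`; pass true library sizes
when the matrix covers only a gene subset. Thresholds follow the family
literature verbatim and their strictness follows the printed wording: a gene
is *expressed* iff it exceeds 2 RPKM in at least one library (strict >); a
DEG satisfies |log2 fold change| > 2 (strict) with the larger condition mean
≥ 2 RPKM (non-strict), with a pseudo-count of 1 guarding zeros (the source
workflow is silent on zeros; the pseudo-count is configurable). Pearson
p-values use the t transform with n − 2 degrees of freedom, two-sided;
replicates are treated as independent samples. Dosage dependence requires
both p < 0.01 and r > 0, since dependence is reported as positive
correlation with genome composition. Co-expression edges keep correlations
at or beyond the 5th/95th percentile of each bait's own correlation
distribution; the percentile convention (linear interpolation, `quantile`
type 7) is recorded in the output because the original tool does not state
it, and a global-null option is exposed without asserting which the authors
used. Hierarchical clustering is average linkage on `1 - r`.

## Synthetic data: what it emulates and what it does not

The generator defines the study conditions for every stochastic test.

*Sequences.* Each of 16 groups (PIP1–2, TIP1–5, NIP1–7, SIP1–2) has a
template with the group's motif variants, representative loop-B position and
spacing, filter residues, Loop-C residue (F for TIP1/TIP3, H for TIP2/TIP4,
Y for TIP5, F elsewhere) and subfamily-level Froger residues. Six 21-residue
membrane blocks drawn from {I, L, V, F} are planted around the motifs with
loops of at least 15 residues so that adjacent helices do not merge under
the default scanner. Background positions draw from a Swiss-Prot-like
natural residue frequency table — chosen over a uniform table so that
template masses land in realistic bands (a ~245-residue tonoplast template
weighs 23–29 kDa) — and decoys draw from the same distribution so that
their difficulty is not artificially lowered. A- and C-progenitor variants
diverge at 3% of unprotected sites; cohort members mutate at 5% (rates
configurable up to 20%), with motif, filter, Loop-C and Froger columns never
mutated. Decoys cover fragments (length 80), single-motif proteins (all
other N-P-x occurrences disrupted so exactly one motif remains) and
membrane-less proteins. Gene models carry group-typical intron counts
(3 for PIPs, 2 for TIPs and SIP2, 4 for NIPs, 11 for SIP1). Not emulated:
indels, signal peptides, splice variants, paralog cross-similarity beyond
the shared template — so passing recovery tests demonstrate correctness of
the extraction machinery, not performance on diverged real proteomes.

*Expression.* Baselines are lognormal (meanlog `log 20`, sdlog 0.8, RPKM
units); effects are multiplicative; noise is lognormal with σ = 0.2; counts
are Poisson around RPKM-implied means given planted gene lengths
(1–3 kb) and library sizes (~5 × 10⁶). The dosage design profiles
genotypes AA, CC, AC, AAC, CCA, CCAA (A-genome fractions 1, 0, 0.5, 0.66,
0.33, 0.5) with two biological replicates — the full parent-plus-progeny
panel of the underlying experiment; 30% of genes are dosage-dependent with
expression `b(1 + 3a)`, a slope calibrated so that per-gene detection power
at p < 0.01 is about 0.9 under the default noise. The drought design plants
eight DEGs at log2 fold change 3 and eight at 1.5 (baselines floored at
5 RPKM so that calls are limited by the rule, not by count noise); the
seed-development design plants rising (TIP3-like) and falling (PIP1-like)
trajectories over 2, 4, 6 and 8 weeks after pollination. Co-expression
modules of six genes share a latent factor with loading
`σ·sqrt(r/(1−r))` targeting within-module r ≈ 0.95. Not emulated:
overdispersion beyond Poisson, mapping bias, batch structure.

## Problem sizes and numerical choices

Test problem sizes are chosen to exercise every code path at desk scale:
alignment oracles run exhaustively over all sequence pairs up to length 3 of
a 4-letter alphabet (7,056 pairs) plus 300 random longer pairs against an
independent affine-gap implementation; motif scanning is cross-checked on
1,000 random sequences; classification and filter recovery run 200 seeded
trials at 5% mutation; expression recovery uses 120-gene matrices. The
species-scale totals of the original study (380 family members across seven
genomes, 104 expressed, 16 drought DEGs) require the public genomes and
RNA-seq archives and are deliberately not reproduced; the fixture and
property suites cover the corresponding logic instead.

Tie-breaks and degenerate inputs are deterministic throughout: alignment
traceback prefers diagonal, classification ties resolve by identity then
reference name, clustering ties by gene index, zero-variance genes are
flagged rather than propagated as NaN, and every generator is bit-exact
reproducible for a fixed seed.

## Worked example

```{r example}
spec <- sequence_sim_spec(groups = c("PIP1", "NIP5", "TIP2"),
                          count_per_group = 2)
profile <- simulate_reference_profile(spec, seed = 1)
cohort <- simulate_aqp_sequences(spec, profile, seed = 1)
res <- annotate_proteome(cohort$proteins, profile, cohort$gene_models,
                         cohort$progenitors)
build_feature_table(res$annotations)[, c("name", "npa_lb", "npa_le",
                                         "h2", "h5", "le1", "le2",
                                         "distance", "substrates")]
```

## Known limitations

Classification assumes the reference profile spans the query's group; novel
groups surface only as `low_identity`/`unclassified` flags. The screening
thresholds encode the published exclusion criteria qualitatively (the
original count of excluded proteins cannot be reproduced without the
original proteome). Specificity rules are evidence-class heuristics, not
transport measurements. The per-bait percentile null makes co-expression
edge sets bait-dependent; the global option changes results and neither is
canonical.
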