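# aqpscan

Annotation and expression analysis of plant aquaporin (MIP) gene families,
with *Brassica napus* (canola) and its Brassicaceae relatives as the model
system.

Aquaporins are six-transmembrane channels whose substrate selectivity is
written in a few conserved sequence features: the dual NPA motifs of loops B
and E (with variants N-P-[S/V/L/C/T/G]), the residue spacing between them,
the aromatic/arginine (ar/R) selectivity filter at positions H2–H5–LE1–LE2
plus a fifth Loop-C residue, and the five Froger positions P1–P5.
Genome-wide studies of the family annotate these features by hand across
hundreds of proteins; `aqpscan` implements that workflow as a reproducible
pipeline:

- **Screening** of candidate proteomes (length, hydropathy-predicted
  transmembrane segments, motif presence) with machine-readable exclusion
  reasons.
- **Feature extraction**: NPA-motif scanning, loop-B/loop-E pair selection,
  NPA–NPA spacing (`le_pos − lb_pos − 3`), and ar/R-filter / Froger-residue
  read-off through global affine-gap alignment (Needleman–Wunsch/Gotoh,
  BLOSUM62) against annotated references.
- **Classification and nomenclature**: subfamily/group assignment by
  reference similarity, genome letters from chromosome prefixes (progenitor
  similarity with a `_random` suffix for scaffold-only genes), and paralog
  letters by chromosome-then-position order, yielding names such as
  `BnaANIP5-1a`.
- **Substrate-specificity rules** as editable data, including the
  silicic-acid rule that requires the G-S-G-R filter at exactly 108-residue
  spacing.
- **Expression analyses**: RPKM normalization, the strict >2 RPKM
  expressed-gene rule, threshold DEG calls (|log2FC| > 2, mean ≥ 2 RPKM),
  percentile-thresholded (5/95) co-expression networks, average-linkage
  clustering, and allopolyploid genome-dosage dependency tests
  (Pearson r vs A-genome fraction, p < 0.01, r > 0).
- **Synthetic-data generators** that plant all of the above with
  machine-readable truth, for end-to-end validation.

The package ships the transcribed 120-row *B. napus* feature table
(`load_bnapus_table()`) as its reference fixture, and a thin command-line wrapper
(`inst/scripts/aqpscan-cli.R`) with subcommands `scan`, `classify`, `expr`,
`dosage`, `simulate` and `validate-fixture`.

## Worked example

```r
library(aqpscan)

spec    <- sequence_sim_spec(groups = c("PIP1", "NIP5", "TIP2"),
                             count_per_group = 2)
profile <- simulate_reference_profile(spec, seed = 1)
cohort  <- simulate_aqp_sequences(spec, profile, seed = 1)
res     <- annotate_proteome(cohort$proteins, profile,
                             cohort$gene_models, cohort$progenitors)
build_feature_table(res$annotations)[, c("name", "npa_lb", "npa_le", "h2",
                                         "h5", "le1", "le2", "distance",
                                         "lc", "substrates")]
```

```
          name   npa_lb   npa_le h2 h5 le1 le2 distance lc substrates
1  BnaANIP5-1a NPS(134) NPV(245)  A  I   G   R      108  F boric_acid
2  BnaANIP5-1b NPS(134) NPV(245)  A  I   G   R      108  F boric_acid
3  BnaAPIP1-1a NPA(114) NPA(235)  F  H   T   R      118  F      water
4  BnaAPIP1-1b NPA(114) NPA(235)  F  H   T   R      118  F      water
5  BnaATIP2-1a  NPA(83) NPA(197)  H  I   G   R      111  H      water
...
```

Each row is one annotated protein: the loop-B and loop-E motif variants with
the 1-based position of their N residue, the four ar/R filter residues, the
NPA–NPA distance (108 is the conserved NIP5 spacing; 118 the PIP spacing),
the Loop-C residue (H for TIP2-type proteins) and the tier-1 substrate
prediction (the A-I-G-R NIP-II filter predicts boric acid, F-H-T-R water).
Unnamed rows are screened-in proteins flagged `needs_review` (for example
single-motif decoys), mirroring the manual-curation step of the family
workflow. The fixture check

```r
validate_bnapus_fixture()$ok
#> TRUE
```

confirms the spacing identity on all 113 complete fixture rows, with the one
partial-motif row (`BnaCNIP4-1c`) reported as exempt.

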