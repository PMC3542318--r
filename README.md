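# aprvote

Consensus prediction of aggregation-prone regions (APRs) in protein
sequences.

Short peptide stretches — often around six residues — can nucleate the
aggregation of a whole protein into cross-β amyloid fibrils, the structures
behind amyloidoses (Alzheimer's, Parkinson's, prion diseases, type II
diabetes) and a major nuisance in biotechnology (inclusion bodies) and
biotherapeutics (antibody aggregation). Many predictors of such
amyloidogenic determinants exist, each with its own physics and biases.
`aprvote` combines eleven of them under a per-residue majority vote: a
residue is a consensus hit when at least

```
floor(n / 2)
```

of the *n* participating methods flag it (5 of 11 when all methods run;
clamped to 1 when n = 1). Consensus predictions of this form outperform each
subordinate method on per-residue benchmarks, and the vote histogram lets a
researcher distinguish a 10-of-11 region from a marginal 5-of-11 one.

## What is included

* **Five native predictors**, computed from packaged data files with
  checksums verified at load:
  * `pattern` — six-position amyloidogenic sequence pattern (allowed /
    forbidden residue sets per position; its defining peptide is STVIIE);
  * `apd` — five-residue sliding mean of an expected-packing-density scale,
    hits above 21.4;
  * `bsc` — β-strand contiguity by sliding averages: windows of 4–20
    residues with mean Chou–Fasman β-propensity ≥ 1.2 add their mean to
    every covered residue's cumulative score *y*; hits where *y* > 20;
  * `aggrescan` — sliding mean of an in-vivo aggregation-propensity scale
    (window 5/7/9/11 by protein length), hits above −0.02;
  * `waltz` — hexapeptide PSSM scoring (window score = sum of six
    position-residue entries, scaled 0–100), hits ≥ 79.0 (strict setting
    92.0). The packaged matrix is a documented synthetic stand-in; see the
    vignette.
* **Six threshold adapters** for externally computed per-residue score
  tables (`tango` > 5.00% β-aggregation, `hce` energy < −27.00, `pafig`
  reliability index ≥ 7, `netcssp` HβP = P(β)/P(α) > 1 and P(β) > 6,
  `secstr` and `amylmut` as binary tracks).
* **Consensus machinery**: vote histogram, floor(n/2) threshold (methods
  that cannot run are excluded from n), merged consensus regions, and a
  substitution scan (`T28G`-style notation) reporting regions lost/gained —
  the workflow used to engineer more soluble proteins.
* **Benchmark protocol**: per-residue TP/TN/FP/FN against annotated regions;
  Sensitivity = TP/(TP+FN), Specificity = TN/(TN+FP),
  Q = (Sens+Spec)/2, MCC = (TP·TN − FP·FN)/√((TN+FN)(TN+FP)(TP+FN)(TP+FP));
  pooled and per-protein tables with an equal-weight macro-MCC; DSSP-based
  surface / semi-surface / buried classification of predicted peptides
  (mean ACC ≥ 20 Å² / 10–20 Å² / below).
* **Deterministic fixtures**: seeded synthetic sequences with planted
  motifs and exact annotations, so the whole pipeline is testable offline.
* **CLI**: `predict`, `benchmark`, `mutate` subcommands (`exec/aprvote`).

## Worked example

```r
library(aprvote)
seq <- protein_sequence("demo", paste0(strrep("D", 20), "STVIIE", strrep("E", 20)))
cons <- vote(run_all(seq))   # five native methods
cons
#> <consensus_result> demo: 5 methods, threshold 2
#>   regions: [21-26]
consensus_table(seq, cons)[20:28, ]
#>    residue aa votes   hit
#> 20      20  D     1 FALSE
#> 21      21  S     4  TRUE
#> 22      22  T     4  TRUE
#> 23      23  V     4  TRUE
#> 24      24  I     4  TRUE
#> 25      25  I     4  TRUE
#> 26      26  E     3  TRUE
#> 27      27  E     1 FALSE
#> 28      28  E     0 FALSE
```

The planted STVIIE peptide in a polar background is flagged by 3–4 of the 5
native methods, well past the floor(5/2) = 2 vote threshold, giving the
consensus region 21–26. A single proline substitution in its core knocks the
region out — the solubility-engineering use case:

```r
substitution_scan(seq, "V23P")$regions_lost
#>   start end
#> 1    21  26
```

The metric formulas reproduce published per-residue benchmark rows from
their confusion counts:

```r
metrics(confusion_counts_record(494, 5553, 1020, 764))
#> <metric_set> Sens 39.27% Spec 84.48% Q 61.88% MCC 0.22
```

## Command line

```sh
Rscript exec/aprvote predict --input seqs.fasta --out results --format txt,tsv,gff3
Rscript exec/aprvote benchmark --input seqs.fasta --regions regions.tsv --out results
Rscript exec/aprvote mutate --input one.fasta --mutations T28G,I201E --out results
```

External score tables (one `<method>.tsv` per adapter: columns
`sequence_id`, `index`, then the method's score columns) are picked up from
`--scores DIR`; adapters without a table are reported `external_missing` and
excluded from the vote count n.

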