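---
title: "Consensus prediction of aggregation-prone regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus prediction of aggregation-prone regions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aprvote)
```

## The model

Protein aggregation into cross-β amyloid fibrils is nucleated by short
aggregation-prone segments, typically around six residues long. Individual
predictors of such segments rest on very different models — sequence
patterns from saturation mutagenesis, sliding averages of physicochemical
scales, position-specific scoring matrices, trained classifiers, energy
models — and disagree substantially on any one protein. `aprvote` treats
each method as one voter over residues: method *m* produces a boolean hit
vector, the vote histogram counts how many of the *n* participating methods
flag each residue, and a residue is a **consensus hit** when its vote count
reaches

$$t(n) = \max(1, \lfloor n/2 \rfloor).$$

With all eleven methods that is 5 of 11. The floor rule is an empirical
balance point between sensitivity (low thresholds) and specificity (high
thresholds); the threshold is exposed (`threshold_override` in `vote()`,
`--threshold` on the CLI) precisely because that trade-off is the user's to
make. Ties at exactly the threshold are hits ("at least" semantics). The
clamp at 1 covers the degenerate single-method case, where a literal floor
of 0 would flag every residue.

**Participation rule.** n counts only methods that actually produced output
(status `"ok"`). A method skipped because the sequence is shorter than its
minimum supported length (`pattern`/`waltz`/`pafig` 6, `netcssp` 7,
`amylmut` 20, `apd` 5 — its window length), or an adapter with no external
score table, is excluded from n rather than counted as a silent "no" vote.
This changes the threshold on short sequences — e.g. a 5-residue input run
with all eleven tokens participates with n = 3 natives only, t = 1 — so the
reports always print both n and t.

## Component methods

Five methods are computed natively from packaged data files (checksummed at
load); six consume externally computed per-residue score tables through a
generic threshold adapter, because their scoring engines (statistical
mechanics, neural networks, SVMs, structure threading) are separate
published programs that this package does not re-derive.

Shared window semantics for the native methods: only full-length windows
are scored (no truncated edge windows — the simplest defensible reading,
and configurable per method), and a residue is a hit when **any** qualifying
window covers it (union semantics, matching the region-style output of the
original tools). Reported per-residue scores are the maximum over covering
windows (cumulative for `bsc`, match counts for `pattern`). Non-standard
residues (X, B, Z, U, O) are accepted on input but carry no propensity
value: any window containing one is disqualified, and such positions can
never be hits.

| token | rule | cut-off | boundary |
|---|---|---|---|
| `pattern` | 6-position allowed/forbidden sets | match | — |
| `apd` | window-5 mean of packing-density scale | 21.4 | strict > |
| `bsc` | cumulative y over windows 4–20 with mean β-propensity ≥ 1.2 | 20 | y strict >, propensity ≥ |
| `aggrescan` | window mean of in-vivo propensity scale, window 5/7/9/11 for length ≤75/≤175/≤300/>300 | −0.02 | strict > |
| `waltz` | hexapeptide PSSM sum, scaled 0–100 | 79.0 (strict setting 92.0) | ≥ |
| `tango` | external β-aggregation % | 5.00 | strict > |
| `hce` | external conformational energy | −27.00 | strict < |
| `pafig` | external reliability index | 7 | ≥ |
| `netcssp` | external P(β), P(α); HβP = P(β)/P(α) | HβP > 1 and P(β) > 6 | strict > |
| `secstr` | external conformational-switch track | ≥ 1 | binary |
| `amylmut` | external hit track | ≥ 1 | binary |

Boundary semantics transcribe the published wording of each cut-off
literally: "above"/"below" are strict, the others inclusive. The adapter
tests pin the boundaries exactly (5.00 is not a Tango hit, 5.01 is; −27.00
is not an energy hit, −27.01 is; HβP exactly 1 is not a NetCSSP hit). All
cut-offs live in `inst/extdata/method_registry.tsv`, not in code.

Two adapters needed a contract of this package's own: the
conformational-switch and mutational-landscape methods publish no numeric
per-residue threshold (their servers emit flagged regions), so their score
tables are binary `switch`/`hit` columns thresholded at ≥ 1.

**Sliding-average procedure for `bsc`.** Window lengths default to 4–20;
every window whose mean β-propensity reaches 1.2 contributes its mean to
the cumulative score y of each residue it covers, and y > 20 marks a hit.
The original sliding-averages algorithm additionally ranked windows and
summed only the top-scoring ones; this implementation sums *all* qualifying
windows — with the 1.2 propensity gate the two differ only in rare
edge cases, and the window range is exposed in the method config for users
who want to restrict it.

**Aggrescan hot spots.** The original definition of a hot spot (≥ 5
consecutive residues over the threshold, prolines excluded) is simplified
here to the shared union-of-qualifying-windows rule with the −0.02 cut-off;
the window-length-vs-protein-length table is stored in the registry.

## Packaged data provenance

Numeric tables are shipped as versioned TSVs under `inst/extdata/`, each
carrying its citation in comment lines and an md5 checksum verified at
load (`data_manifest.tsv`).

* `scale_beta_propensity.tsv` — Chou–Fasman β-sheet propensities
  (transcribed from the 1978 publication).
* `scale_aggrescan_a3v.tsv` — the in-vivo aggregation-propensity scale
  (transcribed from the 2007 publication).
* `pattern_amyloidogenic_hexapeptide.tsv` — the six-position pattern from
  saturation scanning mutagenesis of the de novo amyloid peptide STVIIE.
* `scale_packing_density_synthetic.tsv` — **synthetic stand-in**: the
  original expected-contacts-within-8-Å table was not available in this
  build environment, so the shipped values reproduce the published ordering
  (branched hydrophobics and aromatics 22–23.3, above the 21.4 cut-off;
  polar, charged, P and G 16.9–20.5, below it).
* `pssm_waltz_ph7_synthetic.tsv` — **synthetic stand-in**: the original
  pH-7 hexapeptide matrix is not redistributable here. The packaged profile
  is built deterministically (`data-raw/build_waltz_pssm.R`) as a
  pseudocount-smoothed log-odds profile over 14 experimentally established
  amyloid-forming hexapeptides (STVIIE; GNNQQN/NNQQNY from the yeast prion;
  KLVFFA, MVGGVV, GGVVIA, AIIGLM from Aβ; VQIVYK from tau; NFGAIL, FGAILS,
  SSTNVG from IAPP; VEALYL, LYQLEN from insulin; SNQNNF from PrP), affine
  scaled per position so the achievable window score spans exactly 0–100 —
  which is what makes the 79.0 (high-sensitivity) and 92.0 (strict)
  cut-offs meaningful on this matrix.

Because two of the five tables are stand-ins, **no test asserts a
hand-typed propensity or matrix value**: every native predictor is checked
against an independent brute-force window-enumeration oracle that reads the
same packaged file, so the tests establish that the windowing, thresholding
and union logic are correct for whatever table is installed. Swapping in a
faithful transcription of either original table requires editing only the
TSV and its checksum line.

## Evaluation protocol

Per-residue confusion counts against annotated regions (residue inside an
annotated interval and predicted → TP, and so on), then

* Sensitivity = TP/(TP+FN), Specificity = TN/(TN+FP) (percentages),
* Q = (Sensitivity + Specificity)/2,
* MCC = (TP·TN − FP·FN)/√((TN+FN)(TN+FP)(TP+FN)(TP+FP)).

Counts pool over proteins by element-wise summation; the per-protein MCC
table is additionally macro-averaged with equal weight per protein, which
corrects the size bias of pooled counts (large, sparsely annotated proteins
otherwise dominate). Any metric with a zero denominator reports 0 and sets
a `degenerate` flag (the standard MCC convention when a marginal is zero).
Full precision is kept internally; reports round to two decimals, and the
regression tests compare at ±0.005. One source quirk is handled explicitly:
in the reference benchmark rows used as a regression fixture, two printed
MCC entries are truncations rather than roundings of the exact formula
values (0.12509 printed 0.12; 0.16526 printed 0.16), so the regression
accepts agreement at printed precision under either convention. The exact
values computed by this package are the formula values.

Surface exposure of a predicted peptide aggregates per-residue DSSP ACC
values (Å², probe radius 1.4 Å): mean ≥ 20 Å² → surface (about two water
molecules per residue), mean in [10, 20) → semi-surface, else buried. The
published cut-offs are per-residue while the label applies to a whole
peptide; the mean is this package's documented aggregation choice, with a
strict `mode = "all"` (every residue must clear the bound) available. The
"between 10–20" band is read half-open so the three classes partition.

## The synthetic fixture generator

`generate_fixture()` emulates the one property of real benchmark data the
pipeline needs: sequences whose annotated positive class is exactly known.
Defaults (chosen once): 10 sequences of 120 residues, 2 planted motifs per
sequence cycling through STVIIE, GNNQQNY and NNQQNY — the classic de novo
and yeast-prion amyloid peptides — in a background drawn from a
polar/charged-biased alphabet (D, E, K, R, S, T, G, N, Q, H, P, A) that
excludes every residue scoring high on the packaged scales, a minimum gap
of 3 between plantings so annotation intervals never merge, and full
determinism from a single seed.

What a green fixture test does establish: the planted STVIIE windows are
recovered by the pattern method and by the consensus, coordinates flow
1-based-inclusively through FASTA/TSV/GFF3 round trips, and consensus
sensitivity on planted regions exceeds the background positive rate. What
it does **not** establish: any claim about real amyloid biology — the
Q/N-rich motifs are deliberately *not* recoverable by the pattern method
(position 4 of the pattern forbids Q), background residues have no
aggregation physics, and fixture performance numbers say nothing about
performance on real proteomes.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive in every external format; internal
  vectors are ordinary R vectors, so no conversion exists to get wrong.
* `read_score_table()` uses `NA` as the "no score" sentinel; threshold
  comparisons against `NA` are defined false, so unscored positions can
  never be hits.
* A direct call to `run_amyloidogenic_pattern()` on a sequence shorter than
  six residues returns status `"ok"` with zero hits (there is simply no
  window); under `run_all()` the registry minimum length (6) applies and the
  method is reported `skipped_too_short`, keeping it out of the vote count.
* `vote()` refuses mixed sequence ids and a participant set of zero.
* Mutations validate the stated wild-type letter against the sequence and
  fail naming the position; non-overlapping substitutions commute. Adapter
  methods without score tables for *both* the original and the mutant are
  dropped from both runs symmetrically, so before/after deltas always
  compare the same method set.
* Fixture generation restores the caller's RNG state; identical specs give
  byte-identical outputs.

## Known limitations

* Two packaged tables are synthetic stand-ins (above); absolute `apd` and
  `waltz` scores are therefore not comparable to the original servers',
  although their threshold behaviour and all pipeline logic are.
* The six adapter methods require the user to run the external programs;
  this package applies only their published cut-offs.
* No signal-peptide trimming: sequences are taken as given, and annotation
  coordinates must already be in mature-protein numbering.
* DSSP parsing covers the classic fixed-column format only (single chain or
  an explicit chain selector; insertion codes rejected); accessibility is
  consumed, never computed.
* The 33-protein reference benchmark itself is not reproducible offline —
  it needs the curated sequence set and the six external methods' original
  score files — so the test suite covers the metric formulas on its printed
  confusion counts plus oracle/property tests, not the full table.
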