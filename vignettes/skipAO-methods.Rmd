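---
title: "Methods: efficacy models and descriptor definitions in skipAO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: efficacy models and descriptor definitions in skipAO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skipAO)
```

# Scope and model

`skipAO` predicts exon-skipping efficacy of splice-switching antisense
oligonucleotides (AOs) from computable target-site descriptors, screens every
placement of an oligo across an exon, and provides the statistical machinery
to refit the predictive models on compiled efficacy datasets.

## Coordinates and sequence handling

An exon is handled as an `ExonContext`: the exon sequence plus upstream
(acceptor-side) and downstream (donor-side) intronic flanks, plus the exon's
Malueka splice category. Coordinates are 0-based and half-open internally;
the distance from acceptor (DfA) of a target site is the 0-based offset of
its 5'-most base, so the acceptor-adjacent site has DfA = 0 — matching the
convention in which prospective oligos are labelled by "position 0".
Enumeration is exonic-only: `dfa + length <= exon_length`. Targets crossing
into the introns are not generated, because the efficacy formulas were
derived on exonic sites only and are not valid for intronic positions. `N`
bases are tolerated in flanks but rejected inside any target or energy
window, since the thermodynamic parameters are undefined for them.

AOs are exact reverse complements of their target (no wobble in the
complementarity check; wobble pairs are allowed *inside* the folding models).
All thermodynamics use RNA:RNA parameters regardless of backbone chemistry;
chemistry-specific parameter sets for PMO or 2'-O-methyl backbones do not
exist publicly, which is a known limitation — absolute energies are therefore
best interpreted comparatively across sites.

## Binding-energy descriptors

The descriptor panel contains five energies per site (kcal/mol, 37 °C):

* `dg_target` — nearest-neighbor energy of the bare, fully paired
  oligo:target duplex (duplex initiation + stacking terms + terminal AU/GU
  penalties);
* `dg50`, `dg100`, `dg200` — binding energy of the oligo to the target
  embedded in 50/100/200 bases of genomic context on each side, drawing from
  the intronic flanks where the window crosses an exon boundary and clipping
  silently (recorded in a `clipped` flag) at the ends of available sequence;
* `dg_et10` — context running from the first exon base to 10 bases downstream
  of the target's 3' end, a proxy for co-transcriptional folding of the
  already-transcribed upstream exon portion.

Binding energy is defined symmetrically as
`dG(complex) − dG(region) − dG(oligo)` — the standard cofold binding free
energy. Whether the original calculations subtracted the oligo monomer term
is not documented; the symmetric definition is adopted as the default because
it is the standard output of cofold-style tools, and a
`targetOnlyReference = TRUE` switch subtracts only the region term for
calibration against previously tabulated dG50 columns. When validating a
refit against an external dG50 column, correlation rather than equality is
the appropriate check, since the exact folding program and mode behind any
given table is rarely recoverable.

Two backends implement `foldEnergy`/`cofoldEnergy`:

* `ViennaRNABackend()` — shells out to `RNAfold`/`RNAcofold` (full Turner
  2004 parameters, dangles configurable). This is the production backend;
  published coefficients belong to full-parameter energy scales.
* `SimpleNNBackend()` — an exact dynamic-programming engine over a
  deliberately simplified model: pseudoknot-free structures, Watson-Crick +
  wobble pairs, minimum hairpin loop of 3 bases, and *stacking terms only*
  (the published Turner 2004 stack table, bundled as plain text at
  `inst/extdata/stack_rna_turner2004.tsv`); loops and isolated pairs carry
  zero energy. Bimolecular complexes are folded as the concatenation of the
  two strands with a nick: pairs across the nick are exempt from the hairpin
  minimum and stacks spanning the nick are not scored, and no bimolecular
  initiation term is applied.

The simplified model exists so that every number the engine produces can be
verified independently: `enumerateStructuresOracle()` lists *all* structures
of sequences up to 50 total bases under the same model, and the test-suite
asserts that engine minimum free energies equal enumerated minima exactly and
that engine unpaired probabilities equal Boltzmann-weighted enumeration to
1e-9. The enumeration's own completeness is cross-checked against an
independent memoized structure count. Because the engine and oracle share the
model but not the algorithm, agreement is informative.

Absolute predictions shift between backends; a model fitted on one backend's
energy scale should only be applied to energies from the same backend.

## Accessibility descriptors

Per-base unpaired probabilities of the pre-mRNA around the target come from
`RNAplfold` (`-W window -u 1`) for the production backend, or from the exact
partition function of the simplified model with pairing spans capped at the
window length for the internal backend. The folding window defaults to 150
bases — the scale at which local secondary-structure prediction is most
reliable — and the profiled region is the target plus available context
(±45 bases by default for the internal backend, whose per-base computation is
quartic in region length; keep internal-backend regions to a few hundred
bases).

Five aggregations summarize a profile over a target of length ≥ 15:
the summed probability over the whole target; the same normalized by length;
the sums over the last 15 and last 8 bases; and the maximum 8-base contiguous
window sum. "Last N bases" counts inwards from the target's **3' end on the
pre-mRNA sense strand** by default. The siRNA literature from which the
"3'-end accessibility" idea derives concerns the guide strand, which would
correspond to the opposite end; since the convention is genuinely ambiguous,
`endConvention = "oligo"` flips it.

## Sequence-motif and GC descriptors

Neighborhood-inference (NI) scores estimate splice-factor binding propensity
per hexamer. The score table is an external resource supplied as two-column
text (all 4096 DNA hexamers); the cumulative NI score of a target is the sum
over its `L − 5` overlapping hexamers, and the per-base score divides by `L`.
Hexamers are evaluated on the DNA sense sequence of the target. Synthetic
tables (`synthHexamerTable()`) stand in for the external resource in tests
and are labelled as synthetic.

GC architecture captures exon-definition signals of GC-rich exons inside
GC-poor introns (the DMD situation): exon GC%, GC% of the 150 bases
immediately upstream of the acceptor, their difference (ΔGC), ΔGC with the
target bases excluded (modelling a blocking effect of the bound oligo), and
the change caused by that exclusion. Flanks shorter than 150 bases are used
in full and flagged.

## The efficacy models

The PMO model is a least-squares formula on DfA, dG50 and the Malueka
category, plus a DfA × dG50 interaction:

```
skip% = −44.177 − 0.253·DfA − 2.435·dG50 + (A: −11.4 | C: +11.4)
        + 0.02·(DfA − 80.197)·(dG50 + 37.467)
```

The interaction is read as a **centered** product. The alternative literal
reading, `DfA × (−80.197) × (dG50 + 37.467) × 0.02`, would contribute
hundreds of percentage points at typical inputs and dwarf every other term,
whereas 80.197 and −37.467 are evidently the sample means of DfA and dG50 —
exactly what a centered-interaction fit reports. The literal reading remains
available as `strictLiteral = TRUE` for audit. Categories other than A and C
(B, unannotated) contribute no offset. Predictions are returned unclamped —
the linear model is unbounded — with `clampSkip()` as a display helper.

Two consequences of the coefficients are enforced as invariants in the
test-suite: predictions strictly increase as dG50 becomes more negative for
every DfA ≤ 200 (since −2.435 + 0.02·(DfA − 80.197) < 0 there), and
predictions decrease with DfA whenever dG50 < −24.817.

The 2'-O-methyl model is a logistic classifier on dG50, distance from the
acceptor, their centered cross-term, and an oligo-length indicator. Its
published coefficients are not transcribed anywhere recoverable, so the
package treats them as configuration: `omeGoodProbability()` refuses to run
without explicit coefficients (no silent defaults), and a refit on a compiled
or synthetic dataset can be exported to the same flat key-value config format
(`writeModelConfig()`/`readModelConfig()`). Distance defaults to DfA, with
ACP (acceptor-to-midpoint distance) selectable — the two behave near
interchangeably because they differ by `(length − 1)/2`, which varies little
within a study. The oligo-length indicator is "> 22 nt"; a length of exactly
22 is unassigned by that phrasing and is resolved here as *short* (the
indicator is `length >= 23`), the strict reading of "> 22".

Good/bad classification is strict: a value exactly at the threshold is
"bad", following the "> x%" phrasing of the per-study stratifications
(Aartsma-Rus 25, Dwi Pramono 27.5, Harding 30, Popplewell 30, Wilton 30).

## Model derivation

`fitLeastSquares()` is ordinary least squares with interactions centered at
sample means (or supplied constants; centering constants are stored with the
fit and convertible with `recenterCoefficients()`, which is how refits are
compared coefficient-by-coefficient against generating values). R² is
`1 − SSE/SST`; RMSE uses denominator `n − p` with `p` counting the intercept,
the regression root-mean-square-error convention of the major statistics
packages. The Malueka term expands to offset indicators for A and C with B
and unannotated as the zero reference — the same structure as the published
formula.

`fitBinaryLogistic()` is maximum-likelihood logistic regression (the binary
case of the ordinal model; genuinely graded responses go through
`fitOrdinalLogistic()`, a proportional-odds fit). Complete separation is
detected from the fitted probabilities, reported as a warning, and the fit
falls back to a lightly ridge-penalized IRLS (λ = 0.01, intercept
unpenalized) so that coefficients stay finite; classification at probability
0.5 is unaffected in the separable direction. Confusion matrices are
in-sample at 0.5, with rows = observed and columns = predicted.

`stepwiseKfold()` is forward selection: starting from the intercept, it adds
the candidate minimizing the BIC of the enlarged fit and stops when no
candidate improves BIC. K defaults to 5 with a fixed fold-assignment seed
(20150327), both configurable; K is a convention choice at this dataset scale
(n ≈ 66 gives folds of ~13) and the fixed seed makes paths reproducible. For
each accepted step the in-sample R² and the K-fold R² (mean over folds of
`1 − SSE/SST` on the held-out fold) are recorded; a `criterion = "kfold"`
mode instead stops when held-out R² stops improving, since the two criteria
answer slightly different questions (parsimony vs. predictivity). Equivalence
with any original stepwise run is asserted at the level of selected terms and
fit statistics, not intermediate steps.

Records whose only efficacy information cannot decide the good/bad label at
the study threshold (e.g. an unstratified "> 5%" grade against a 25%
threshold) are flagged by the loader (`grade_only_gt5`) and excluded from
classification by way of their `NA` label. Wilton-study rows carry a
`wilton_omitted` flag for the cross-chemistry analyses. The loader reports
per-study counts and does not attempt to reconcile totals beyond that.

## The per-position screen

`screenExon()` evaluates every exonic placement: f50 region → dG50 → formula
(PMO) or good-probability (2OMe). The prediction series is smoothed with a
centered moving average whose window defaults to `ceiling(length/2)` — 15 for
30-mers, 13 for 25-mers, 10 for 20-mers — so the smoothed value sits at the
midpoint of each target site. For a 25-mer the exact midpoint window would be
12.5 bases, which is not realizable; rounding up to 13 is the documented
resolution. Positions where the full window does not fit are `NA`, and for
even windows the extra base falls on the acceptor side. Ranking sorts by
prediction descending with deterministic tie-breaks (smaller DfA, then
lexicographic oligo sequence). Outputs are three tab-separated files
(sequences, energies, consolidated report) whose headers carry the package
version, model id, backend id and window; numerics are serialized at full
precision (`%.17g`) so reports reload losslessly. Per-window dG50 values are
cached by (sequence window, backend, parameter set) within a session, making
re-screens incremental. An optional report column rescales predictions to a
supplied mean observed skip for cross-study display; stored predictions are
never normalized.

## Synthetic fixtures

The generators in `synthSpec()`/`synthExonSet()`/`synthEfficacyDataset()`
define the study conditions for all self-contained validation:

* exon GC 44% and upstream-intron GC 32% (the DMD averages), long flanks
  (200 bases), internal exon lengths of 120–200 bases;
* efficacy values drawn as `formula(true descriptors) + Normal(0, 21.1)`,
  the published residual scale of the PMO fit; simulated values are *not*
  truncated to [0, 100] by default because truncation would bias
  parameter-recovery checks (a `truncate` switch exists for realism demos);
* dataset size n = 66 (the PMO study's scale), oligo lengths 25–30;
* Malueka categories allocated by largest-remainder quota over the mix
  weights (default 0.4/0.2/0.4), guaranteeing that both offset-carrying
  categories appear so refits stay full-rank;
* loader-branch switches append grade-only and Wilton-style rows.

Everything is a pure function of `seed` + spec. Base composition is i.i.d.
per region, so the fixtures reproduce the *statistical* structure the models
consume (GC architecture, energy and distance ranges) but none of the
biology: no splice-site motifs, no ESE landscapes, no intron phase, no
correlated base composition. Passing recovery tests therefore demonstrate
that the fitting machinery is correct and well-conditioned at the study's
scale and noise level — not that the model is true of real exons; that
evidence can only come from refits on compiled experimental tables.

## Numerical choices and degenerate inputs

* Temperature fixed at 37 °C (kT = 0.0019872041 × 310.15 kcal/mol), one
  constant shared by engine and oracle.
* Engine-vs-oracle equality asserted at 1e-12 (MFE) and 1e-9 (probabilities);
  formula evaluations at 1e-12 under term reordering.
* Empty flanks, clipped windows, single-placement enumerations, whole-exon
  targets (GC-ignoring-target undefined), constant responses, rank-deficient
  designs and empty confusion matrices all have explicit, tested behavior —
  either a defined value or a named error, never a silent default.
* Screens shorter than the moving-average window yield all-`NA` smoothing
  rather than an error; direct calls to `movingAverage()` with an oversized
  window do error, since there the window is an explicit argument.

## Known limitations

* No chemistry-specific thermodynamics (PMO/2OMe backbones are scored with
  RNA:RNA parameters).
* The co-transcriptional folding engagement scores (L1/L3) and external
  splicing-factor matrix scores are importable columns, not computations.
* The simplified internal model ignores loop entropies; its energies are for
  testing and relative screening, not for quantitative comparison with
  full-parameter tools.
* The 2OMe model ships unfitted by design; its published coefficients must be
  transcribed into a config by users who have them, or refit from data.
* Internal-backend accessibility is exact but quartic in region length;
  production accessibility should use the windowed external backend.
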