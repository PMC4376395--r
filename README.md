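# skipAO

In-silico pre-screening of exon-skipping antisense oligonucleotides.

Splice-switching antisense oligonucleotides (AOs) induce skipping of a target
exon from a pre-mRNA — the most mature therapeutic application being
restoration of the dystrophin reading frame in Duchenne muscular dystrophy
(DMD). Designing an AO means choosing, among the hundreds of possible target
positions on an exon, the handful worth taking into the lab. `skipAO`
implements a quantitative pre-screen for that choice: it computes target-site
descriptors at every position of an exon and converts them into a predicted
skipping efficacy, for phosphorodiamidate morpholino (PMO) and
2'-O-methyl (2OMe) chemistries. It is aimed at researchers designing
exon-skipping AOs and at methodologists who want to refit or extend the
underlying models on compiled efficacy data.

## The model

Two descriptors dominate predicted efficacy:

* **dG50** — the free energy of binding of the AO to its target site embedded
  in 50 bases of flanking sequence, computed as the standard cofold binding
  energy `dG(complex) − dG(region) − dG(oligo)` (kcal/mol, RNA:RNA
  parameters, 37 °C);
* **DfA** — the distance in bases of the target's 5'-most base from the
  splice acceptor (0-based; DfA = 0 is the acceptor-adjacent placement).

For 30-mer PMOs the least-squares efficacy formula is

```
predicted skip (%) = −44.177 − 0.253·DfA − 2.435·dG50
                     + (Malueka A: −11.4 | C: +11.4)
                     + 0.02·(DfA − 80.197)·(dG50 + 37.467)
```

where the Malueka category is a splice-characteristic class (A/B/C) of the
exon and the last term is a centered DfA × dG50 interaction (80.197 and
−37.467 are the dataset means at which it vanishes). For 2OMe oligos a
logistic model on dG50, distance, their cross-term and an oligo-length
category (> 22 nt) yields the probability of "good" (above-threshold)
skipping; its coefficients are supplied by config or refit.

Beyond the formulas, the package computes the full descriptor panel
(duplex and flanked-region binding energies; five target-site accessibility
scores from per-base unpaired probabilities; hexamer neighborhood-inference
splice-factor scores; exon/intron GC architecture) and ships the complete
model-derivation machinery: forward stepwise selection with K-fold
cross-validation, least squares with centered interactions, binary/ordinal
logistic classification with confusion matrices, and leave-one-exon-out
refits.

Thermodynamics run on a pluggable backend: `ViennaRNABackend()` shells out to
`RNAfold`/`RNAcofold`/`RNAplfold` (full Turner parameters; use for production
screens), while the built-in `SimpleNNBackend()` is an exact
dynamic-programming engine over a simplified stacking-only nearest-neighbor
model, paired with an exhaustive structure-enumeration oracle so every energy
and probability it reports is independently verifiable in the test-suite.

## Worked example

Screen every 30-mer placement on a DMD-like synthetic exon:

```r
library(skipAO)

spec <- synthSpec(seed = 42, nExons = 1, exonLenRange = c(148L, 148L))
ctx  <- synthExonSet(spec)[[1]]
ctx
#> ExonContext 'synthExon1': exon 148 nt (GC 52.0%), flanks 200/200 nt, Malueka A

prof <- screenExon(ctx, oligoLength = 30, backend = SimpleNNBackend())
prof
#> ScreenProfile 'synthExon1': 119 positions, 30-mer PMO, window 15 [turner2004-stack-subset]

rankCandidates(prof, topN = 3)[, c("rank", "dfa", "dg50", "prediction", "oligo_seq")]
#>  rank dfa  dg50 prediction                      oligo_seq
#>     1  57 -36.6   18.72076 TTTCCCATCTAATCTATTTTCGTTGCCGCA
#>     2  54 -36.0   17.65238 CCCATCTAATCTATTTTCGTTGCCGCATTC
#>     3  56 -36.0   17.20506 TTCCCATCTAATCTATTTTCGTTGCCGCAT
```

The screen enumerates all 148 − 30 + 1 = 119 exonic placements, computes each
site's dG50 and applies the PMO formula; `prediction` is the predicted
percentage of transcript skipped (here modest values — this random exon binds
its AOs weakly), `dfa` the acceptor distance of each site, and the ranking
surfaces the most promising positions for in vitro testing. A 15-base moving
average (`prof@movingAvg`) smooths the profile to the midpoint of each target
site, and `writeScreenOutputs(prof, "out", ctx = ctx)` emits the per-position
sequences, energies and consolidated report files. The same screen is
available from a shell via
`Rscript $(Rscript -e 'cat(system.file("scripts/screen_exons.R", package="skipAO"))') --fasta exons.fa --exon ID --length 30 --out out`.

For real exons, supply a FASTA of exon sequences with fixed-length intronic
flanks to `loadExonRecords()` (with an optional two-column Malueka annotation
sidecar), and prefer `ViennaRNABackend()`: the published coefficients were
derived on full-parameter energies, so predictions from the simplified
backend are on a shifted scale.

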