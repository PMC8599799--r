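---
title: "Reactivity scoring, footprint prediction and polyA-site calling with footprintr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reactivity scoring, footprint prediction and polyA-site calling with footprintr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the model behind
each stage, the parameters that matter, what the synthetic generator does
and does not emulate, and the numerical conventions chosen where more than
one reasonable definition exists.

## 1. From RT stops to reactivity

Structure-probing chemistries modify RNA at positions whose local
environment permits the reaction: an acylation probe reacts with flexible
2'-hydroxyls (the "flexibility" reagent), a photo-activated nicotinoyl
azide reacts with solvent-exposed purine C8 atoms (the "accessibility"
reagent).  Reverse transcription terminates one nucleotide 3' of an
adduct, so a read whose 5' end maps at position $p$ records a stop at
$p - 1$; reads at $p = 0$ carry no information and are dropped
(`stops_from_read_ends()`).

Given a probe-treated library (stops $T_i$) and a no-probe control (stops
$B_i$, base density $D_i$), with library-size factor
$f = N_{treatment} / N_{control}$, the raw enrichment score is

$$ s_i \;=\; \frac{\max(T_i - \alpha f B_i,\; 0)}{\max(f D_i,\; \varepsilon)} $$

* $\alpha$ (default 0.25, dimensionless in $[0,1]$) subtracts the part of
  the treatment stops expected from spontaneous termination, estimated by
  the control.
* $\varepsilon$ (default 1, in scaled-count units) floors the denominator
  so zero-coverage positions do not blow up; coverage filters
  ($T_i < T_{min}$ or $f D_i < t_{min}$, both default 0 i.e. switched
  off, matching probing pipelines run with the filters disabled) report
  `NA` ("null") instead of a number.
* Raw scores are floored at zero because reactivity is non-negative by
  definition.

Normalization (`normalize_profile()`) divides each transcript's raw scores
by the mean of its positive scores lying between the 90th and 99th
percentile, then clamps to $[0,1]$.  The percentile-slice mean is a
winsorized scale estimate: it ignores the extreme top 1% (ligation/PCR
artifacts) and the bulk of weak positions.  The exact internals of
published scoring pipelines vary between versions; the slice definition
used here is therefore an explicit, config-exposed choice
(`scoring_params(winsor_lo, winsor_hi)`), not a ground truth, and the test
suite pins it against an independent sort-based oracle.  Degenerate inputs
pass through unchanged: an all-`NA` or all-zero transcript normalizes to
itself.

**VTD** is the in-cell profile minus the in-vitro profile, position-wise,
`NA`-propagating.  Negative VTD at a position means less reactive inside
cells — the signature of protein protection.  `hexamer_vtd()` averages VTD
over all complete (fully non-`NA`) hexamer occurrences, and
`metaprofile()` aligns profiles at anchor positions with truncation at
transcript ends.

## 2. Binding-site prediction

Positive sites are motif occurrences overlapping a peak (at least one
motif base inside the half-open peak interval); peaks without the motif
are dropped and counted.  Negatives are occurrences of the *same* motif
whose full span is peak-disjoint, sampled without replacement to match the
number of positives.  Windows of motif $\pm 5$ nt (15 positions for the
5-mer motifs typical of RBP catalogs) are extracted per reagent; any
window containing an `NA` or leaving the transcript is discarded, and in
the combined design a site must survive in *every* reagent.

Design choices where the convention was genuinely open:

* **Multiple occurrences in one peak** are all kept as distinct positives
  (a first-per-peak option exists); deduplication is by
  (transcript, start) so overlapping peaks cannot duplicate rows.
* **Label purity is asymmetric**: positives need one overlapping base,
  negatives need full-span disjointness (with an optional buffer).
* **Degenerate IUPAC letters** are not supported; motifs are exact
  strings.
* Peaks must already be in transcript coordinates; projecting
  genome-space peak calls onto transcripts is out of scope and its
  convention is the caller's responsibility.
* The "at least three A/G residues" motif filter used for probe-visible
  RBP catalogs is interpreted on the motif string itself.

The classifier harness (`evaluate_design()`) follows standard libSVM
practice: a stratified random half-split (stratification prevents
degenerate single-class halves on small site sets), per-column min-max
scaling to $[0,1]$ learned on the training half only (test values clamped;
constant columns map to 0), exhaustive grid search over $(C, \gamma)$ by
stratified 5-fold cross-validation maximizing mean held-out AUC (ties
break toward the smallest $C$, then $\gamma$ — the least complex model),
refit on the training half, ROC on the test half.  AUC is computed as the
Mann–Whitney rank statistic with half-credit ties, which is exactly the
trapezoidal area under the tie-grouped ROC curve.  The cross-validation
objective is AUC rather than accuracy so that model selection optimizes
the same surface the evaluation reports.  Because published headline
phrases like "predicts X% of binding sites" are not operationally defined,
the package reports AUC and, via `sensitivity_at_specificity()`, the
sensitivity at 90% specificity, and does not claim equivalence between the
two.

## 3. PolyA-site calling and classification

`call_pas_sites()` scans a 3'-end read pileup for positions with at least
`min_reads` (default 5) reads, merges qualifying positions within
`cluster_distance` (default 10 nt) into clusters, and reports each cluster
at its modal position with ties resolved toward the 3' end (cleavage is
heterogeneous; the 3'-most mode is a deterministic convention).  Sites are
anchored to the canonical AAUAAA signal whose 3' end lies 10–40 nt
upstream of the cleavage position (`d_min`/`d_max`; the canonical
signal-to-cleavage spacing), choosing the closest candidate.  The zero
point for metaprofiles and windows is `signal_start + 2`, the uridine.

Activity labels come from read depth among anchored sites: counts at or
above the 0.75 quantile are `active`, at or below the 0.25 quantile
`inactive`, and the middle band stays `unassigned` and is excluded from
training — sharper labels at the cost of discarding ambiguous sites.  When
all counts are equal the quantiles coincide and everything is labeled
active; the convention is documented rather than special-cased.  No
internal-priming (genomic A-stretch) filter is applied; a config hook is
the natural place for one when consuming real libraries.

Classifier positives are the signal positions of active sites; negatives
are AAUAAA occurrences not assigned to any called site, defined
operationally from the package's own calls rather than from an external
annotation (an annotation-based negative set would differ; the operational
definition keeps the experiment self-contained).  Windows are signal
$\pm 20$ nt, width 46 per reagent, with the same discard rules as above.

## 4. What the generator emulates — and what it does not

`simulation_params()` defines a complete synthetic experiment whose ground
truth exercises every stage.  Defaults are the package's reference study
conditions:

| knob | default | meaning |
|---|---|---|
| `n_transcripts`, `length_range` | 250, 500–1500 nt | transcriptome size |
| `coverage` | 200 | mean per-position base density |
| `phi` | 50 | NB size; mild overdispersion of counts |
| `beta0`, `beta1` | 0.02, 0.2 | background and modification stop rates |
| `delta` | 0.5 | footprint suppression of in-cell reactivity |
| `channel_balance` | 0.5 | P(footprint acts on the accessibility channel) |
| `bound/unbound_per_transcript` | 2, 2 | planted motif instances |
| `pas_reads_active/inactive` | 50, 8 | read depth at used/unused signals |

Mechanics worth knowing when interpreting tests:

* **Baselines** are moving averages (window 5) of uniform noise, rescaled
  per transcript to $[0,1]$ — realistic local correlation without a
  folding engine.
* **Every motif occurrence** gets its baseline blended toward 0.85
  (weight 0.7) in both conditions and channels: motifs are bindable
  *because* they are accessible and flexible.  Without this
  sequence-intrinsic component, between-site baseline heterogeneity
  dominates the windows and no classifier can see the footprint.
* **Footprints** multiply in-cell reactivity by $(1 - \delta \cdot w)$
  over the motif plus 2-nt shoulders ($w = 0.5$ at shoulders), on one
  channel per site chosen by a Bernoulli(`channel_balance`) draw.  The
  per-site channel assignment is what makes the two reagents
  complementary: each single reagent sees only half the footprints, the
  combined design sees all of them.
* **PolyA signals** additionally receive the signal-recognition
  signature on the accessibility channel — high at the two leading
  adenosines, low over the UAAA — as a weak sequence-intrinsic part at
  every planted signal (both conditions) plus a strong protein part at
  active signals in cells only.  The protein part scales with the same
  footprint dial $\delta$ (full strength from $\delta = 0.5$), so
  $\delta = 0$ means *no* protein effect anywhere, in-cell truth equals
  in-vitro truth, and the classifiers must fall to chance.
* **Counts** are negative-binomial at every stage (density, treatment
  stops at rate $\beta_0 + \beta_1 \cdot r_i \cdot b_i$, control stops at
  $\beta_0$), where $b_i$ is the reagent's base preference — strong A/G
  for the accessibility probe, mild A/U for the flexibility probe.  The
  overdispersion default $\phi = 50$ reflects the mildly super-Poisson
  behavior of position-level stop counts in enrichment-based libraries;
  $\phi$ is exposed so null calibrations can be stress-tested at heavier
  dispersion.
* **Determinism**: every stage derives its own seed stream from the
  master seed, so any stage can be re-run in isolation byte-identically.

The generator does **not** emulate: thermodynamic RNA folding (baselines
are stochastic, not structure-derived), read-level sequences or alignment
artifacts, transcript-abundance variation (coverage is homogeneous),
internal priming in polyA-seq, or nonspecific peak-calling noise beyond
boundary jitter.  Passing tests therefore demonstrate that the pipeline
recovers the signals it models, at realistic depth and noise — not that
real libraries contain those signals at the same strength.

## 5. Problem sizes and numerical conventions

The test suite runs the full classification experiments at the generator's
default scale (about 500 sites per class at coverage 200) for the
calibration and signal-recovery properties, and at reduced scale (40–120
transcripts) for structural and determinism properties; hyperparameter
grids in tests are small ($C \in \{1, 10\}$, $\gamma \in \{0.03, 0.3\}$)
because the AUC surface at these feature dimensions is flat over wider
grids, while `model_config()` defaults to the conventional wide libSVM
grids.  Remaining conventions: percentile slices use type-7 quantiles;
ROC ties are grouped (half credit); PAS cluster mode ties resolve 3';
hexamers containing N are skipped; an empty negative pool warns and
returns what exists rather than failing.

## 6. Known limitations

* Reactivity is scored per transcript; very short or almost fully
  `NA` transcripts normalize against few positions and are best filtered
  upstream (e.g. with `filter_rbp_targets()` at ≥ 5 RPKM).
* The combined design requires each site to survive window extraction in
  every reagent, which biases the shared site set toward well-covered
  regions.
* The SVM harness is deliberately the only learner: the scientific
  comparison is between *feature designs* (reagents), not learners.
* Genome-to-transcript projection of peaks, alignment, and
  differential polyA-usage testing are out of scope.
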