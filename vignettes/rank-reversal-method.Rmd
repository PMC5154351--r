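---
title: "Individual-level differential expression from rank reversals: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-level differential expression from rank reversals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reodiff)
```

## The model

Within one expression profile, the ordering of two features is invariant to
any monotone per-sample transformation — library-size scaling, quantile
normalization, log transforms all preserve it.  `reodiff` exploits this for
per-patient differential-expression calls in three assumptions:

1. **Stability in health.** For many miRNA pairs (A, B), the ordering
   expr(A) < expr(B) holds in almost every normal sample of a tissue.  We
   require support strictly above 95% of normals, with ties (equal values,
   common in zero-inflated counts) counted against stability.
2. **Reversal under deregulation.** If A becomes up-regulated in a subset
   of tumors, orderings of A against partners lying between A's normal and
   deregulated levels flip in exactly those patients.  A two-sided Fisher
   exact test on the keep/flip contingency of normals versus tumors, with
   BH FDR control at 0.1 across all stable pairs and the requirement that
   the tumor flip fraction exceed the normal one, finds these reversal
   pairs.
3. **Constant partners.** A reversal of (A, B) is ambiguous — A may have
   risen or B fallen.  Each pair is attributed to the member whose implied
   direction matches its group-level deregulation direction, and partners
   are then ranked by coefficient of variation so that the references
   actually used are the most nearly constant miRNAs available.

A patient-level call for miRNA A is a majority vote: A is called in its
direction iff strictly more than half of its (at most k = 3) panel pairs
show the tumor-state ordering in that sample.  Ties never vote.  With a
panel of two, both pairs must agree; a single-pair panel calls on its one
ordering, the minimal configuration the approach admits (a configurable
`min_panel` floor is available).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `stability` | 0.95 | minimal fraction of normals supporting a stable ordering (strict inequality) |
| `fdr` | 0.1 | BH threshold for reversal pairs |
| `k` | 3 | panel size cap; 5 and 7 behave similarly on real cohorts |
| `direction_alpha` | 0.05 | significance level for a group-level deregulation direction |
| `cv_scale` | `"raw"` | scale on which partner CV is computed |
| `min_panel` | 1 | minimal panel size to keep a miRNA callable |

Two of these encode design decisions that were genuinely open:

**Direction significance.**  The group-level direction is the sign of the
tumor-minus-normal mean difference, but we declare a direction only when the
per-miRNA Welch test is significant (`direction_alpha = 0.05`, `NULL`
restores the raw sign rule).  A "deregulation direction" presupposes
deregulation: with the raw-sign rule, every unperturbed miRNA acquires a
coin-flip direction from noise, and any strongly deregulated miRNA donates
its reversal pairs to every stably co-ordered neutral miRNA whose noise sign
happens to match — on synthetic cohorts this collapses end-to-end
specificity from ~0.98 to ~0.73.  The significance rule removes those
donated panels while leaving genuinely deregulated miRNAs (whose group shift
is large) untouched.

**CV scale.**  The partner coefficient of variation is computed on the raw
scale (log2 matrices are exponentiated first).  On log-scale values CV =
sd/mean depends on the arbitrary location of the log scale — it decreases
mechanically with expression level, so ranking by it systematically prefers
the highest-expressed partner in a window, which is also the partner with
the weakest ordering margin.  On the raw scale CV measures relative
variability and is comparable across expression levels.  `cv_scale =
"native"` restores the as-stored behaviour.

Other conventions: ties count as flips in the Fisher table and as
non-votes in calling (conservative in every direction); equal CVs break
lexicographically by partner id for reproducibility; a partner with zero
mean gets CV = +Inf and sorts last; exact ±0.1 copy-number log2 ratios are
neutral (strict inequalities); the CNA–expression consistency test is
one-sided in the direction named by the alteration.

## What the synthetic cohorts emulate — and what they do not

`generate_cohort()` builds a normal/tumor pair with the structure the
method assumes: per-miRNA baselines 0.05 log2-units apart (a ~10-unit
dynamic range for 200 miRNAs, comparable to sequencing profiles), per-miRNA
noise sd drawn uniformly from 0.5–1.5 times the nominal 0.5 (real profiles
mix tight and noisy features, which is exactly what the CV ranking
exploits; a constant absolute noise would make CV a deterministic function
of expression level), and deregulation of ±4 log2 units planted in a random
half of the tumors for each of 40 DE miRNAs.  Normals are never perturbed.
Deregulation is planted only on miRNAs with at least three potential
reference partners inside the shift window: down-regulating a
floor-expression miRNA is biologically not meaningful and structurally
undetectable by any within-sample rank method, a limitation shared with the
method itself (only miRNAs with stable reference partners are callable).

The generator's empirical stable-pair yield is checked against a
closed-form Gaussian order-statistics prediction (`expected_stable_fraction`,
agreement within 2%).

What the generator does **not** model: zero inflation and the resulting tie
mass of real count data, cross-platform probe effects, correlated miRNA
modules, and library-size artefacts.  Green tests therefore certify the
algorithmic contract and its statistical calibration, not performance on
any particular real cohort.

For the spike-in protocol, `make_spike_design()` reproduces the published
recipe: each disease sample receives a fixed number of up and down spikes
(4:1 ratio), each spiked miRNA is perturbed in a fixed number of samples
(exactly where the margins are consistent, within ±1 by randomized
balanced quotas where they are not), and the spike magnitude is the
miRNA's maximum absolute backbone value.  Two deliberate design choices:

* **Per-miRNA spike direction.**  Spike directions are constant per miRNA
  (an up pool and a down pool sized 4:1).  With per-cell random directions,
  a direction-specific majority-vote caller can never exceed sensitivity
  ≈ 0.8 on a 4:1 mix — incompatible with the ~0.93 the protocol is known to
  reach — whereas per-miRNA assignment is consistent with the protocol's
  description and with those results.
* **Subset spiking.**  Only a subset of profiled miRNAs is spiked
  (`spiked_mirnas = 60` of 200 in the shipped configurations, mirroring a
  study that perturbed its ~290 callable miRNAs out of ~1000 profiled).
  The unspiked majority supplies constant reference partners; spiking
  everything leaves no constant partner for any panel, which is not the
  situation the protocol describes.

Desk-scale problem sizes used by the tests and the acceptance script: the
default cohort (200 miRNAs, 60/60 samples), spike-in backbones of 84 and
120 samples with per-miRNA counts 14 and 20 at 20 replicates (60 × 14 =
10 × 84 and 60 × 20 = 10 × 120 keep both margins exact), and five seeds
for the exclusivity screen.  These sizes keep every protocol property
measurable (planted sensitivity/specificity, the specificity trend between
the two spike configurations, planted-pair recovery) at interactive run
times.

## The linked multi-omics layer

`generate_linked_omics()` plants one mutually exclusive miRNA–target pair on
top of a cohort: the target gene is deleted (log2 ratio −0.5) in tumors
disjoint from the miRNA's up-regulated subset, its expression drops in both
event groups, and a module of co-regulated genes places both DEG lists into
the same two planted pathways.  Distractor interactions are engineered to
fail specific stages robustly: a target without copy-number events, a
target deleted exactly in its miRNA's deregulated patients (maximal
co-occurrence), a target mildly induced rather than repressed in the miRNA
group (consistency failure), a target whose pathway footprint is disjoint
(overlap failure), and a single-database record removed by the interaction
filter.  The screen itself follows the published four stages with raw
P < 0.05 inside each stage (no multiplicity correction, as specified; a BH
option exists), "only with" groups excluding double-event patients, and a
sample universe of patients carrying both call and copy-number data.

## Numerical notes and degenerate inputs

* Fisher two-sided p-values use the point-probability rule (sum of tables
  as or more extreme by probability, with a 1e-7 relative slack), matching
  the dominant convention; degenerate margins give p = 1.
* Hypergeometric tails include the observed point mass on both sides.
* Welch is the default t-test (a pooled-variance switch exists); constant
  data are handled explicitly (equal means → p = 1, unequal → p = 0).
* Quantile normalization assigns tied values the mean of the reference
  values they span; a single-sample matrix is a warning no-op.
* A log-rank test with no events returns p = 1; an empty survival group
  yields no p, with the reason recorded.
* Missing expression cells are rejected at load: rank comparisons are
  undefined for missing data, and imputation policy is left upstream.

## Known limitations

Calls exist only for miRNAs with at least one direction-consistent reversal
pair — miRNAs near the extremes of the expression range may be uncallable
in the relevant direction.  Power to detect a deregulated patient falls
when the shift is small relative to the gap to the panel partners.  The
method trains on a sizeable normal cohort; very small normal sets make the
95% stability support unreliable.  Cross-platform identifier harmonization
and probe mapping are out of scope, as are Cox modelling (group
construction and the log-rank test are provided; hazard ratios belong to
dedicated survival tooling) and any data download clients.
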