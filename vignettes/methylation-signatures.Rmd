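---
title: "Calling organ-specific methylation signatures, DMRs and iPSC epigenetic memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling organ-specific methylation signatures, DMRs and iPSC epigenetic memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methtrail)
```

## The model

`methtrail` works on *beta values*: per-CpG, per-sample methylation
fractions in [0, 1] from the Illumina 450K array. Its central primitive
is not a statistical test but a deterministic threshold rule tailored to
isogenic designs, where every sample shares one genome and a handful of
samples per group is the norm. A CpG is *relatively hypermethylated* in
the group of interest when its beta exceeds the beta of **every**
comparison sample by more than a cutoff, and *relatively
hypomethylated* when it falls below every comparison sample by more than
the cutoff:

$$\min_{o' \neq o} \left(\beta_o - \beta_{o'}\right) > c
  \quad\text{(hyper)},\qquad
  \max_{o' \neq o} \left(\beta_o - \beta_{o'}\right) < -c
  \quad\text{(hypo)},\qquad c = 0.2 .$$

The universal quantifier is what makes the call *specific*: a single
comparison sample within the cutoff vetoes the call. Three points follow
directly from the definition and are enforced in code:

* the inequalities are strict — a pairwise difference of exactly 0.2 is
  not a call;
* "below 0.2" for hypomethylation is read as a *signed* difference below
  −0.2; a literal reading (difference < +0.2) would include zero and
  contradict the word "hypomethylated";
* hyper and hypo calls for one group are disjoint at any positive cutoff.

The same rule is applied at three comparison scopes:

| scope | group of interest | comparison set |
|---|---|---|
| organ-specific | one organ of an isogenic set | every other organ of that set |
| pluripotency barcode | all hiPSC clones | all fetal organs of origin |
| triplet memory | one organ + its two hiPSC clones | all members of the other triplets |

When a group has replicate samples the replicate mean is compared
(the isogenic sets have one sample per organ; the mean covers the
general case). Each call carries `min_pairwise_delta`, the pairwise
difference of smallest magnitude — the margin by which the call
survives.

For the barcode the comparison scope is genuinely ambiguous in the
field: "clones compared to the organs of origin" can mean every clone
against every organ, or each clone against its own organ only. The
all-pairs reading is the default; `scope = "own_organ"` in
`call_pluripotency_barcode()` gives the other.

### Missing values

Missingness propagates: group means are computed without `na.rm`, and a
probe whose comparison requires an undefined group mean is *not
evaluable* — it produces no call and is counted in the
`n_not_evaluable` attribute rather than silently treated as a negative.

## DMRs: the consecutive-CpG rule

A differentially methylated region is defined combinatorially, not by
smoothing: at least `min_core = 3` consecutive CpGs sharing the feature
(hyper- or hypomethylation for one group), with at most
`max_gap_bp = 1000` between *every* pair of adjacent probes in the
region and at most `max_interrupt = 3` probes inside the region that
lack the feature. Three reading decisions deserve a note:

* **"Consecutive" is evaluated on the ladder of all measured probes.**
  Interrupting probes are real array probes lying between core probes;
  this is the only reading under which "not more than three CpGs that
  did not have the common feature" is meaningful.
* **The gap cap applies to every adjacent pair**, core or interrupting —
  no exemption is stated, so none is implemented.
* **The interruption budget is a per-region total**, not a per-gap run.

`call_dmrs()` scans each chromosome left to right: from the first
unconsumed feature probe it extends as far as the gap partition and the
interruption budget allow, trims the end back to the last feature probe
(regions start and end on cores), emits the region if it holds enough
cores, and resumes after it. `dmr_oracle()` is the verification path: it
enumerates *all* candidate windows with core endpoints, filters by the
three rules, and resolves overlaps by earliest start (ties: the longest
window). The two are proven equal on thousands of random instances in
the test suite; the oracle refuses inputs above 10,000 probes because it
is quadratic by design.

A property worth knowing when tuning parameters: the number of DMRs is
monotone in `min_core` (raising it can only suppress regions) but **not**
in `max_gap_bp` or `max_interrupt` — tightening either can *split* one
long region into two valid shorter ones and so increase the count.
(Cores c1–c3, two interrupting probes, cores c4–c6: one region at
budget 3, two regions at budget 1.) What tightening does guarantee is
that every region called under the stricter setting is still a valid
window under the laxer one; the tests assert exactly that.

Interrupting probes may in principle carry the *opposite* feature (a
hypomethylated CpG inside a hypermethylated region); the rule as stated
treats them as mere non-feature probes, and the `opposite_interrupt`
flag reports when it happens.

DMR boundaries are reported at core-probe positions, unpadded; BED
output is 0-based half-open with `end` = last core position.

## Annotation conventions

Every probe receives exactly one genic and one CGI-centric category —
the partition property is asserted on every generated manifest.

**Genic.** The nearest TSS (minimum absolute genomic distance; ties
broken by lexicographically smallest gene id, for determinism) selects
the reference gene; the signed, strand-aware distance `d` (upstream
negative) then selects the window: DP for d ∈ [−10000, −1500), PP for
d ∈ [−1500, +500], GB for d ∈ (+500, L] where L is the gene length, DS
for d ∈ (L, L + 5000], IG otherwise. The half-open boundary conventions
are the package's choice (the window edges are stated in the kb
vocabulary, not at base resolution); they are documented here and
applied consistently. A position inside gene A's body but within
1.5 kb of gene B's TSS belongs to B's promoter — nearest-TSS-first
resolves all window overlaps between neighbouring genes, including
DS-vs-DP conflicts. Probes on chromosomes without any gene model are IG
with a logged message.

**CGI-centric.** Overlapping islands are merged first (edge distances
are otherwise ambiguous). A probe inside a merged island is CGI; within
`shore_width` of an island edge, SHO; within `shore_width +
shelf_width`, SHE; otherwise NC. The widths are not fixed by the
definition of the categories themselves; the defaults of 2 kb shores
and 2 kb shelves follow the UCSC/Irizarry convention universally used
with this array, and both are exposed as arguments. Distances are in
bases from the probe to the closest island boundary, boundaries
inclusive (a probe exactly 2000 bp out is still shore).

## Probe-level QC

The three probe filters are read as a two-stage rule — the only reading
under which all three thresholds are non-redundant: bead count < 3 or
detection p > 0.01 mask the individual *cell*; the success rate (the
fraction of non-missing cells per probe, threshold 95%) then decides
probe death. The success-rate denominator is all samples of the input
matrix; whether batch-wise denominators were used upstream is not
determinable from the rule itself, so the simplest convention is taken
and stated. Filtering is idempotent and monotone in all thresholds, and
both properties are tested.

SNP-overlapping probes come in as an exclusion list (mapping ambiguity
and SNP content are manifest properties, not something to recompute
here); sex-chromosome probes are dropped except in isogenic analyses
(`exclude_sex_chromosomes = FALSE`), where all samples share one
genome and sex probes are informative.

## Enrichment

Odds ratios come from the 2×2 table of call-set membership × category
membership, with OR = (a·d)/(b·c). The significance test is a plain
chi-squared without continuity correction (Yates and Fisher variants
are options). When a table cell is zero the Haldane–Anscombe correction
(+0.5 on all cells) is applied to the OR only — the raw table keeps the
test honest — and the row is flagged. The universe is the QC-surviving
probe set of the analysis that produced the calls, not the full array:
calls are only possible among evaluable probes, and using the full
array would bias every OR by the QC structure. Raw p-values are the
primary output (a Bonferroni column is provided); with 4–15 categories
per annotation the correction rarely changes conclusions.

## The synthetic-data generator

The generators produce the three study layouts with planted truth:

* **Isogenic organ sets** (default 14 organs, one sample each): a
  shared baseline per probe, organ-specific CpGs planted at a beta
  shift of 0.4 — singles on the sparse background ladder and runs of
  3–8 consecutive probes inside dense clusters, so planted DMRs satisfy
  the gap rule by construction and planted singles can never abut them
  (clusters are isolated by > 1 kb on both sides).
* **Triplet studies**: six organs × (one organ sample + two hiPSC
  clones); barcode CpGs shifted in all twelve clones, memory CpGs (18
  hyper + 6 hypo by default) shifted only in the designated brain
  triplet.
* **DEG tables**: disjoint organ-unique DEG sets (FDR < 0.01,
  |logFC| > 1) plus sub-threshold decoys and one deliberately shared
  gene; coupled promoter/gene-body delta betas of magnitude 0.3 with
  the biological sign structure (up-DEGs lose promoter methylation and
  gain gene-body methylation; down-DEGs the opposite).

Noise is *logit-normal*: Gaussian with sd σ (default 0.05) added on the
logit of the beta value. This respects the [0, 1] support without
clipping artefacts and reproduces the characteristic heteroscedasticity
of array betas — variance is largest at intermediate methylation and
compressed near 0 and 1. Baselines are drawn from a two-component
logit-normal mixture with modes near 0.1 and 0.9, mimicking the bimodal
beta distributions of somatic tissues. Planted baselines are drawn from
ranges such that the ±0.4 shift stays inside [0, 1] exactly, so at
σ = 0 every planted pairwise delta equals the effect size precisely and
every closure test is exact.

What the generator does **not** emulate: probe-type (Infinium I/II)
chemistry differences, background/dye effects, batch structure,
cell-composition heterogeneity within an organ, spatial correlation of
noise along the ladder, and genuine biological inter-individual
variation. Passing the recovery tests therefore demonstrates the
correctness of the calling logic under the stated noise model, not the
field performance of the thresholds on raw arrays — the upstream
normalization those thresholds assume is out of scope by design.

At the study conditions (effect 0.4, σ = 0.05) the planted effect is
eight noise standard deviations on the logit scale, so sensitivity near
1 and a false-call rate near 0 are the *expected* behaviour, and the
acceptance thresholds (≥ 0.95, ≤ 0.01) are comfortable rather than
tight. The deterministic seed policy derives every generator's stream
from one base seed with small fixed offsets, so studies are reproducible
individually and jointly.

## Numerical and engineering choices

* Betas are squeezed into [10⁻⁶, 1 − 10⁻⁶] before logit transforms.
* Beta matrices are written at 17 significant digits, so a write/read
  round trip reproduces values and the missing-value mask exactly.
* Coordinates: 1-based positions in manifests (array convention),
  0-based half-open in all BED I/O; conversions live in the I/O layer
  only.
* All tie-breaks (nearest-TSS gene, DMR-to-gene mapping, majority genic
  category of a DMR) are lexicographic or enum-ordered and therefore
  deterministic; DMR gene ties are additionally flagged.
* `run_pipeline()` writes every inter-stage contract to disk and a run
  manifest with input checksums and a config hash but no timestamps, so
  identical inputs give byte-identical output trees.

Problem sizes in the test suite were chosen to exercise each property at
meaningful scale while keeping a full run in the low minutes: 1000
random ladders (≤ 300 probes) for DMR-oracle equivalence, 200 random
matrices (≤ 120 × 20) for signature-oracle equivalence, a
20,000-probe × 14-organ isogenic set for recovery, and 100 random gene
sets for the annotation oracle.

## Known limitations

* The threshold rule has no error model: with one sample per organ
  there is no within-group variance to exploit, which is exactly why
  the isogenic design and the conservative universal quantifier are
  used. Replicated designs wanting inference should look to
  regression-based DMR callers instead.
* Nearest-TSS annotation is gene-level; alternative TSSs and isoforms
  are not modelled.
* The DMR rule's region count is not monotone in the gap/interruption
  parameters (see above) — compare parameterisations by inspecting the
  regions, not by counting them.
* The enrichment chi-squared is asymptotic; for very sparse categories
  use `method = "fisher"`.
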