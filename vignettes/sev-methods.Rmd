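---
title: "Detecting stochastic epigenetic variants: model, parameters and design choices"
author: "sevscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stochastic epigenetic variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevscan)
```

## The problem

In clinically heterogeneous disorders, methylation lesions need not recur
at the same locus across patients: each affected individual may carry a
private epimutation. A case-vs-control group test then has essentially no
power, because averaging over cases dilutes any single individual's signal
to nothing. The single-case strategy implemented here inverts the design:
the controls define, probe by probe, a *normal methylation range*, and each
sample — case or control — is screened individually for values far outside
it.

## The outlier model

For probe $j$, let $Q_1$ and $Q_3$ be the first and third quartiles of the
control beta-values and $\mathrm{IQR} = Q_3 - Q_1$. The reference range is
the pair of Tukey fences

$$\mathrm{lower}_j = Q_1 - k\,\mathrm{IQR}, \qquad
  \mathrm{upper}_j = Q_3 + k\,\mathrm{IQR},$$

with $k = 3$ — the classical "extreme outlier" multiplier, far stricter
than the $k = 1.5$ whisker convention. A sample's beta strictly outside the
fences is a **stochastic epigenetic variant (SEV)**, hyper- or
hypo-methylated according to which fence it violates (equivalently, which
side of the control median it falls on). Because the rule is quartile-based
it is insensitive to outliers *within* the control panel itself, and it
adapts per probe: noisy probes get wide fences, stable probes tight ones.

Numerical conventions, all configurable:

* **Quartile algorithm**: linear interpolation between order statistics
  (`stats::quantile` type 7, the R default). The worked example in
  `?reference_ranges` — controls $\{0.10, 0.12, 0.14, 0.16, 0.18\}$ giving
  fences $[0, 0.28]$ — assumes this convention.
* **Strict comparison**: a value exactly on a fence is *not* an outlier
  ("falling outside" is read strictly).
* **Degenerate spread**: if $\mathrm{IQR} = 0$ the fences collapse onto the
  quartiles and any deviation is an SEV — faithful to the formula. An
  optional `min_halfwidth` can pad such fences for pathological synthetic
  inputs; the default is 0.
* **Saturation**: fences may extend past $[0,1]$; a probe with
  $\mathrm{upper} \ge 1$ and $\mathrm{lower} \le 0$ can never fire, and
  `sev_saturation()` reports that blind fraction.
* **In-sample reference**: one range is computed from *all* controls, and
  the controls are then screened against it like cases (no leave-one-out).
  This matches the procedure this package models. The cost is a small
  asymmetry — a control partly masks its own outliers in the fences it
  helped estimate — which is negligible at the ~48-control design point
  (see *Calibration* below) but grows quickly for small panels. A
  leave-one-out variant was deliberately not made the default, to keep the
  single published reference range.

## The enrichment scan

SEVs occur as technical or biological noise in every sample. The scan
separates clustered, regional deregulation from that background. Walking
the post-QC probe universe in manifest order (chromosome, position), a
window of $n = 11$ consecutive probes is tested at every admissible centre:
with $x$ = the sample's SEVs in the window, $K$ = its genome-wide SEV
count, $N$ = universe size, the window p-value is the exact hypergeometric
tail $P(X \ge x)$. The *central* probe of a significant window
($p < \alpha$) is retained **iff it is itself an SEV**; everything else is
discarded.

Design choices:

* $\alpha = 0.05$ by default (configurable); the threshold is recorded in
  the scan output.
* Windows never span chromosomes, and a centre must have the full
  $(n-1)/2$ flanks on each side — constant window size keeps the test
  identical across centres; truncated edge windows are not tested.
* $K$ and $N$ are genome-wide, matching the scan statistic's universe to
  the burden the sample actually carries.
* Hyper- and hypo-methylated SEVs are pooled for $x$ and $K$; direction is
  re-attached to retained probes afterwards. `per_direction = TRUE` runs
  the two strata separately.
* No multiple-testing correction is applied across windows: specificity
  comes from the central-SEV requirement, the control subtraction and the
  single-variant-locus exclusion downstream.

A consequence worth knowing: when a sample's total burden $K$ is small,
even an isolated SEV can pass ($P(X \ge 1) \approx nK/N$). Such singletons
are removed later anyway — a retained locus must hold at least two
variants — so the scan's permissiveness at tiny $K$ does not reach the
final locus tables.

## From retained SEVs to gene loci

Retained SEVs of cases are first cleansed of anything also retained in any
control (probe-level set difference, the strictest reading; a gene-level
alternative is available). The survivors are annotated to manifest genes —
composite annotations like `"SIX3;SIX2"` stay verbatim as one locus key —
and grouped per (sample, gene); intergenic probes are dropped with a
logged count, and single-variant groups are excluded. Loci are directional
when their SEVs agree and `mixed` otherwise; the shared-gene tables are
strictly directional and omit mixed loci.

Burden comparisons use `count ~ group + sex + age` — the minimal reading
of "adjusted for gender and age": sex as a two-level factor, age linear.
The count family is Poisson with log link; because SEV counts are often
overdispersed, the fit automatically switches to quasi-Poisson when the
Pearson $\chi^2/\mathrm{df}$ exceeds 2, and the result records which
family was used. Clinical prevalences are reported as $100\,n/N$ rounded
to the nearest integer, except below 10% where one decimal is kept; the
published table this convention mirrors is itself inconsistent in two
cells (one truncation, one extra decimal), so those two are only
reproducible to ±0.5.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not the raw array physics:

* **Bimodal baselines**: per-probe means from a 0.4 / 0.4 / 0.2 mixture at
  modes 0.85 / 0.10 / 0.50 (jitter sd 0.04) — the classic two-peaked
  beta-value histogram of 450K blood data.
* **Technical noise**: additive Gaussian, sd 0.03, clipped to $[0,1]$.
* **Isolated extreme outliers**: each cell independently becomes an
  outlier with probability $10^{-3}$, displaced by Uniform(0.15, 0.45) in
  a random direction — identical in cases and controls, so an uninjected
  cohort is an exact null for the burden test.
* **QC layers**: detection p-values below 0.01 except a $5\times10^{-4}$
  failure fraction; bead counts $\ge 3$ except a $5\times10^{-4}$ low
  fraction.
* **Demographics**: log-normal ages with medians 6 (cases) and 12.9
  (controls) years; random sex.

`inject_epivariants()` plants truth: contiguous same-gene runs and
isolated intergenic probes, displaced to *fence ± shift* computed from the
control columns — so injected events are SEVs by construction, and their
magnitude is defined relative to the decision boundary rather than as an
absolute delta. Targets are only placed where the fence leaves room for
the shift inside $[0,1]$, and isolated targets are intergenic so they can
never legitimately appear in a gene locus. All randomness flows from one
integer seed through a single generator, with the caller's RNG state left
untouched.

What the generator does **not** emulate: batch and position effects, probe
type (Infinium I/II) chemistry differences, cell-composition variation,
correlated noise along the genome, and realistic linkage between
neighbouring probes' baselines. Passing the recovery and calibration tests
therefore demonstrates the pipeline's internal correctness and its
behaviour under idealized noise — not performance on raw clinical arrays,
where normalization quality and confounder structure dominate.

## Calibration and validation experiments

Three seeded experiments ship as package functions and are exercised by
the test suite and the acceptance script:

* `region_recovery_sim()` — cohorts of 2,000 probes, 8 cases / 24
  controls, one injected 4-probe region at shift 0.15 plus two intergenic
  singletons; records whether the region returns as a correctly-directed
  locus and whether any singleton contaminates a locus. The pilot run of
  100 cohorts recovered ≥ 9 in 10 regions with zero singleton
  contamination, which fixed the package's documented sensitivity floor
  (90%) at these settings.
* `burden_null_rejection_rate()` / `burden_power()` — the GLM alone on
  simulated counts: type-I error at nominal $\alpha$ and power at a
  3× mean-ratio pilot effect (20 vs 20 samples, means 30 vs 10).
* `sev_chain_null_rejection_rate()` — the full generation → fences →
  detection → burden chain on uninjected cohorts (2,000 probes, 16 cases,
  48 controls). The 48-control reference matches the design point this
  analysis is built around; with much smaller panels the in-sample masking
  asymmetry described above inflates the null rejection rate severely
  (pilots with a 16-control reference rejected in essentially every
  cohort), which is the quantitative reason the reference panel should not
  be small.

Problem sizes in the shipped tests and acceptance script (20,000-probe
showcase cohort, 100–200 simulation replicates, enumeration lattice
$N \le 150$ exhaustive plus seeded coverage to $N = 500$) were chosen to
exercise every code path at full cohort dimensions while keeping a routine
check fast on a laptop.

## Known limitations

* Gene annotation comes from the manifest's gene string; no external
  annotation service is consulted, so multi-gene probes produce composite
  locus keys rather than being resolved.
* The group-level module (`site_diff_meth()`) is a deliberately minimal
  Welch / moderated-t surface for volcano-style filtering; it fits no
  surrogate variables and is not a substitute for a full group pipeline.
* The enrichment scan's universe is the post-QC probe set; probes removed
  by QC do not occupy window slots, so window "width" in base pairs varies
  with local probe density and QC loss.
* With no multiple-testing correction across windows, retained-SEV counts
  scale with per-sample burden; cross-sample comparisons should use the
  burden GLM rather than raw retained counts.
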