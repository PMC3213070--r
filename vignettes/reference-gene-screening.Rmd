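---
title: "Screening reference genes in qPCR time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening reference genes in qPCR time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refscreen)
```

## The problem

Relative quantification by qPCR divides every target gene's signal by that
of a reference ("housekeeping") gene assumed constant across samples. In
acute inflammation that assumption is fragile: classic references such as
GAPDH are transcriptionally responsive to hypoxia and innate-immune
signaling, so normalizing against them can *manufacture* differential
expression in genes that never moved, and mask genes that did. `refscreen`
implements a complete evaluation workflow for this situation on a genes
&times; samples Ct matrix from a time-course experiment:

1. pre-analytic processing (missing-value handling, gene filtering, the
   41&nbsp;&minus;&nbsp;Ct transform),
2. per-gene differential-regulation testing under declared normalization
   conditions,
3. two independent stability screens (MAD/p plane and geNorm M), and
4. quantification of the artifacts a chosen reference would introduce.

Because microfluidic array studies of this kind rarely deposit raw Ct
matrices, the package carries a synthetic-data generator with known ground
truth; every claim the test suite makes is a claim about planted truth
recovery.

## The data scale

Ct is the PCR cycle at which a gene's fluorescence crosses threshold: lower
Ct means more transcript, one cycle is a 2-fold abundance step at the
conventional 100% amplification efficiency (the package fixes efficiency at
2; no efficiency correction is attempted). All analysis happens on

$$x = 41 - \mathrm{Ct},$$

a log2-like scale on which *higher* values mean *higher* expression.
Undetected reactions assigned the maximum cycle number Ct&nbsp;=&nbsp;40 map
to $x = 1$ rather than 0 — a pseudocount (Laplace correction) that keeps
ratios defined. The transform is an affine reflection, so robust spread
statistics (MAD) are identical on the Ct and x scales, and group-mean
differences on x are log2 fold changes: $\mathrm{FC}(g,t) =
2^{\bar x_{g,t} - \bar x_{g,t_0}}$.

## Pre-analytic rules

Missing wells are classified before anything else:

* **biological** — the gene is undetected in *every* replicate of a
  contiguous run of time points touching the first or last time point
  (expression plausibly absent at the beginning or end of the response);
  these cells are assigned Ct&nbsp;40.
* **technical** — every other missing cell; imputed with the mean Ct of the
  gene's detected replicates at the *same* time point (never across time
  points, which would flatten kinetics).

Genes with `max_unexplained` (default 2) or more technical missing cells are
removed; biological cells never count toward removal. The published
procedure used expert judgment for this distinction, so the automatic rule
is overridable per cell through a sidecar annotation file
(`read_missing_overrides()`).

The classify &rarr; impute &rarr; filter &rarr; transform order makes the
"two or more *unexplained*" count literal. A technical cell with no detected
replicate at its time point is unrecoverable; inside the pipeline such genes
are necessarily caught by the filter (an all-replicate technical run is
already &ge;&nbsp;2 cells), and `impute_and_flag()` called directly raises
an error.

One further QC step vets suspect genes (e.g. an rRNA control with
array-specific detection failures): the Pearson correlation of the gene's Ct
with the per-sample mean Ct over all *other* genes. A gene tracking global
template quantity correlates positively; an artifact gene sits near zero and
is excluded below `qc_r_min` (default 0.5). The focal gene is excluded from
the mean to avoid self-correlation bias. This replaces a PCA-based batch
check with an equivalent, directly testable statistic.

## Testing and normalization

Per gene, time points are treated as independent groups: classical one-way
fixed-effects ANOVA (and, as a distribution-free companion, Kruskal–Wallis
with tie correction) across all groups including baseline; the ANOVA
p-values are Benjamini–Hochberg adjusted **within one normalization
condition** (one family per condition, so regulated counts are comparable
across conditions). A gene is *regulated* when its maximal two-directional
fold change $\max(\mathrm{FC}, 1/\mathrm{FC})$ reaches 1.5 **and** its
adjusted p is below 0.05. The time point of greatest change (greatest in
either direction; ties resolved toward the earlier point) also receives a
two-sided pooled-variance t-test against baseline (Welch available via
`var_equal = FALSE`; group sizes of 3–4 make pooling the sensible default).

A `norm_scheme()` is `none`, a single reference, or the geometric mean of
several references. On the x scale the geometric mean of linear abundances
is the arithmetic mean of x, which is what gets subtracted per sample; a
re-centering constant (the across-sample mean of the subtracted signal) is
added back so values stay positive, and cancels from every fold change and
test statistic. A literal geometric mean *of the Ct numbers themselves* is a
different (and numerically eccentric) operation; it is available behind
`literal_ct_geomean = TRUE` for fidelity experiments — with a single
reference the two coincide exactly, with several they differ.

Normalization is a per-sample shift: differences between genes within one
sample are untouched, so within-sample rank order is preserved, and
normalizing against a perfectly stable noise-free reference changes no fold
change at all. Conversely, normalizing against a *drifting* reference
imprints the mirror image of the drift on every flat gene — the mechanism by
which an unstable reference manufactures spurious "regulated" calls.
`compare_schemes()` quantifies this with exact Venn-region set algebra over
the per-condition regulated sets, and `focal_gene_trajectories()` exposes it
for a single gene, flagging direction discordance (up under one condition,
down or flat under another).

## Stability screening

Candidates are the genes *not* regulated in the non-normalized condition
(adjusted p &ge; 0.05). Two screens run on them:

* **MAD screen** — raw median absolute deviation of each candidate's x
  values across all samples, sorted ascending. The MAD is reported *without*
  the 1.4826 consistency factor: the convention in this literature treats
  the scaling factor as something one would multiply by to *obtain* an SD
  estimate, so printed MADs are unscaled cycles.
* **geNorm** — authored from scratch: for candidate $i$,
  $M_i = \mathrm{mean}_{j \ne i}\, \mathrm{SD}_s\!\left(x_{is} -
  x_{js}\right)$ with the $n-1$ SD denominator (the statistic's published
  convention). Ranking is by stepwise exclusion: recompute M on the current
  set, drop the highest-M gene with the current worst rank, repeat; the
  final two genes are indistinguishable by construction (in a two-gene set
  both M values equal the SD of the pairwise difference) and share rank 1.
  Reported M values are the full-candidate-set values, with stepwise ranks a
  separate column. Candidates with more than `missing_tolerance` (default 2,
  aligned with the pre-analytic filter) imputed or Ct40-assigned cells are
  excluded before ranking, with the reason recorded.

The conventional cutoff M&nbsp;&lt;&nbsp;0.5 (strict) marks potentially
useful references. The geNorm pairwise-variation statistic for choosing the
*number* of references is not computed; the effect of adding references is
assessed empirically by comparing regulated sets across geometric-mean
schemes instead.

Implementation note: M is computed through the covariance identity
$\mathrm{Var}(x_i - x_j) = \mathrm{Var}(x_i) + \mathrm{Var}(x_j) -
2\,\mathrm{Cov}(x_i, x_j)$, which makes stepwise ranking of ~80 candidates
instantaneous; the test suite checks it to 1e-10 against a brute-force
oracle that materializes every pairwise difference vector.

## What the simulator emulates

`simulate_ct()` draws
$$\mathrm{Ct}(g,s) = \mathrm{baseline}(g) - \mathrm{traj}(g, t(s))
- \mathrm{array}(s) + \varepsilon_{gs}, \qquad
\varepsilon_{gs} \sim N(0, \sigma_g^2),$$

with trajectories *subtracted* (positive log2 fold change lowers Ct, as real
template kinetics do), an optional shared per-array shift, and censoring
above a per-gene detection threshold. The default design is 7 time points
(0, 1, 4, 9, 18, 27, 50 h) with replicates (3, 4, 4, 3, 3, 3, 3) — 23
samples, the layout of the murine air-pouch urate-crystal experiment the
package emulates.

The default 96-gene truth mix (`study_archetypes()`):

| archetype | n | parameters | emulates |
|---|---|---|---|
| stable | 3 | flat, $\sigma$ = 0.25 cycles | validated reference candidates |
| spike | 1 | $2^{7.70}$ (~208-fold) burst at 4 h, $\sigma$ = 0.4 | an IL-1&beta;-like cytokine burst |
| drift | 1 | $2^{1.49}$ (~2.8-fold) rise peaking at 18 h, $\sigma$ = 0.3 | a GAPDH-like unstable reference |
| batch artifact | 1 | flat, $\sigma$ = 2.0 | an rRNA control with array-specific failures |
| dropout | 2 | baseline Ct 39.8, censored at 40, $\sigma$ = 0.5 | low expressors at the detection limit |
| null | 88 | flat, $\sigma$ spread 0.7–1.5 | expressed but unregulated genes |

Eight null genes additionally receive two planted single-replicate interior
missing cells each in the default configuration, so a bare run exercises the
filter: 96 genes &rarr; 8 planted + 2 dropout genes removed, the batch gene
QC-excluded &rarr; 85 retained, mirroring the quality funnel of the
emulated study.

Two noise choices deserve justification, since no noise model was published
for such arrays. First, a single gene's array-specific shifts are
statistically identical to iid per-cell noise (each gene &times; sample cell
is observed once), so the batch-artifact archetype is simply a large
$\sigma$; the *shared* array effect is the separate `array_effect_sd`
mechanism, default 0. Second, null genes carry heterogeneous biological
noise at 0.7–1.5 cycles (1.6–2.8-fold animal-to-animal variation). This was
fixed by a design-time power analysis: reference candidates must sit near
the technical noise floor while expressed genes in inflamed tissue vary
substantially more — consistent with real screens of this kind, where even
the *best* candidates show raw MADs near 0.3 cycles, i.e. nothing on a real
array is quieter than the planted 0.25-cycle floor. With a lower biological
floor (0.4–0.6 cycles) the minimum-of-~80 order statistic of null MADs
routinely undercuts the planted stable genes at n&nbsp;=&nbsp;23 and *no*
screen could meet a 90% top-3 recovery property — not a deficiency of the
statistics but of the separation; the chosen floor reflects the regime the
method is designed for.

What the simulator does **not** model: amplification-efficiency variation,
probe chemistry, melt/amplification curves, inter-plate calibrators,
correlated noise between genes (beyond the shared array effect), and
non-Gaussian heavy-tailed replicate noise. Passing tests therefore
demonstrate correctness of the *procedure* and its behavior under the
stated generative model, not performance guarantees on any particular real
data set.

## Worked example

```{r example}
fit <- refgene_screen(
  n_genes = 96, seed = 17,
  technical_missing = setNames(rep(2L, 8), sprintf("null_%02d", 1:8)),
  qc_genes = "batch_1",
  schemes = list(norm_scheme("none"),
                 norm_scheme("single", "drift_1"),
                 norm_scheme("single", "stable_1")),
  focal_gene = "stable_3")
summary(fit)
```

```{r plots, fig.width = 6, fig.height = 4}
plot(fit, which = "screen")
plot(fit, which = "trajectories")
```

The drifting reference inflates the regulated count with genes unique to
that condition, and the flat focal gene acquires an apparent
down-regulation mirroring the reference's rise — the classic normalization
artifact, flagged as direction discordance.

## Numerical and design choices

* Degenerate inputs are signalled, not silently absorbed: zero within-group
  variance with equal means (undefined F), all-tied values (undefined
  Kruskal–Wallis H), zero variance in both t-test groups, zero-variance
  correlation inputs, an empty post-filter table.
* Zero within-group variance with *unequal* means yields p = 0 (infinite
  F), so noise-free planted effects are maximally significant.
* Ties in the time of greatest change go to the earlier time point; ties in
  stepwise exclusion go to the candidate listed first. Both are
  deterministic.
* All simulation runs restore the caller's RNG state; identical seeds give
  byte-identical output bundles (`write_screen()` emits no timestamps).
* Test-suite problem sizes are the package's own choices for a fast,
  reproducible default run: 100-seed recovery/artifact ensembles, a
  500-seed global-null ensemble, 100 random oracle instances at up to 10
  genes &times; 23 samples; the acceptance script uses 50-seed ensembles
  for rates and 100 seeds for the global null.

## Limitations

* Time points are independent groups; no autocorrelation or mixed-effects
  modeling of the time course.
* BH families are per normalization condition by design; comparing counts
  across conditions therefore compares equally-sized families, but a
  different family choice would change absolute counts.
* The MAD/geNorm screens inherit the candidate set from the testing step: a
  gene regulated under the non-normalized condition can never become a
  candidate, even if a better normalization would have revealed it as
  stable.
* NormFinder/BestKeeper-style model-based stability statistics and
  efficiency-corrected &Delta;&Delta;Ct variants are out of scope.
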