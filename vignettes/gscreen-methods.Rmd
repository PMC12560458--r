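---
title: "Methods: drug sensitivity scoring and resistance profiling in gscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug sensitivity scoring and resistance profiling in gscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gscreen)
```

This vignette documents the statistical models, the parameters that matter,
the numerical choices, and the design decisions behind `gscreen`, in the
order the pipeline runs them. It also describes what the synthetic-cohort
generator does and does not emulate, and therefore what a passing test suite
does and does not demonstrate about real screens.

## 1. From raw wells to percent inhibition

Each plate carries drug wells (one well per dose, five ten-fold doses per
drug by default) and shared control wells: DMSO as the negative control
(full viability) and benzethonium chloride as the positive control (full
kill), 16 wells each by default. Raw luminescence is mapped to percent
inhibition by linear interpolation between the control means:

$$\mathrm{inh} = 100 \cdot \frac{\bar{L}_{neg} - L}{\bar{L}_{neg} - \bar{L}_{pos}}.$$

Inhibition is clipped to $[-25, 100]$. The lower clip admits mild growth
stimulation (a real phenomenon in viability screens) without letting a few
stimulated wells dominate the least-squares fit; the upper clip removes
super-maximal artifacts. A plate whose negative-control mean does not exceed
its positive-control mean is reported as an error naming the sample — there
is no sensible inhibition scale on such a plate.

## 2. Four-parameter logistic fit

Per drug and culture, inhibition versus $x = \log_{10}(\text{concentration})$
is fit with

$$y(x) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}{1 + 10^{\,s\,(m - x)}}$$

by bounded Levenberg–Marquardt (`minpack.lm::nls.lm`), with box constraints
$\mathrm{bottom} \in [-25, 25]$, $\mathrm{top} \in [-25, 120]$,
$s \in (0, 10]$, and $m$ within 2 log10 units of the tested range. The
bounds keep the asymptotes on the inhibition scale, force a non-negative
slope (sensitivity increases with dose; bell-shaped series are flagged by
their residuals, not chased), and stop the midpoint from wandering far
outside the tested range where it is unidentified. The optimizer is started
from four deterministic initializations (half-maximum crossing or grid
midpoint for $m$; shallow and steep slopes) and the best residual sum of
squares is kept, so the fit is reproducible without randomness. Convergence
accepts the relative-reduction, parameter-step and gradient stopping rules
of the algorithm; series that still fail — in practice almost exclusively
flat, truly inactive series where the midpoint and slope mean nothing — are
flagged and scored DSS = 0 rather than missing, which keeps responder
counts conservative. Replicate wells at the same dose, if present, are
averaged before fitting. Fewer than two distinct doses is an error.

## 3. Drug Sensitivity Score

The fitted curve is reduced to the area of drug activity above an
activity floor $t = 10$% across the tested range $[x_1, x_2]$ only — no
extrapolation beyond tested concentrations:

$$\mathrm{DSS} = \frac{100 \int_{x_1}^{x_2} \max(0,\ \hat{y}(x) - t)\,dx}
{(100 - t)(x_2 - x_1)},
\qquad \hat{y} = \min(\max(y, 0), 100).$$

A flat inactive curve scores 0, full inhibition across the range scores 100,
and a curve pinned exactly at the floor scores 0. The integral is evaluated
exactly: the 4PL is monotone in $x$, so its crossings with $t$, 0 and 100
are solved in closed form and each sub-interval is either constant (clipped)
or an exact logistic segment with antiderivative
$F(x) = \mathrm{bottom}\cdot x + \frac{\mathrm{top}-\mathrm{bottom}}{s \ln 10}
\ln(1 + 10^{\,s(x-m)})$. The tests verify this piecewise closed form against
a $10^5$-point trapezoid rule to $10^{-6}$. The score is invariant to
rescaling all concentrations (only $x$-offsets change) and monotone under
pointwise increases of the response. A second variant (`dss2`), dividing
additionally by $\log_{10}(\mathrm{top})$, is available behind
`dss_params(variant = )` for compatibility with the alternative score
family; it is off by default.

## 4. Resistance classification

Cultures are ranked by their responder count — the number of drugs with
DSS ≥ 10, the conventional floor for a moderate-to-high response; the
comparison is inclusive and ties in the ranking are broken by lexicographic
sample id so results are deterministic. Before clustering, the matrix is
restricted to drugs screened in every culture (no imputation), and each
drug's row is centered on its cohort mean. Centering, rather than division
by the mean, is the chosen reading of "normalizing against the cohort
average": division is unstable for drugs with near-zero mean DSS, and
centering is the conventional pre-clustering transform; the alternative
reading would change only the clustering input, not the machinery.

Cultures are clustered by Ward.D2 linkage on Euclidean distances between
culture columns and the tree is cut at $k = 2$. The cluster with the lower
mean responder count is labeled *resistant* — a deterministic restatement of
labeling ranked screens by inspection. Group separation in responder counts
is tested with an unpaired two-tailed Welch t-test, computed by closed form
so that degenerate inputs (both groups constant) return $t = 0$, $p = 1$
instead of an error.

## 5. Multiscale bootstrap cluster stability

For each scale $r \in \{0.5, 0.6, \dots, 1.4\}$ and $B$ replicates
(default 10000), drugs (rows) are resampled with replacement to size
$\mathrm{round}(r \cdot n_{drugs})$ — features are the replicated units, as
is conventional for expression-like matrices — the cultures are reclustered,
and the fraction of replicates in which a reference cluster reappears as a
clade is its per-scale bootstrap probability $BP_r$. The scale curve

$$\Phi^{-1}(1 - BP_r) = v\sqrt{r} + c/\sqrt{r}$$

is fit by weighted least squares (binomial variance weights), giving the
approximately unbiased value $AU = 1 - \Phi(v - c)$ and the naive $BP$ at
scale 1. Degenerate profiles are handled explicitly rather than pushed
through the fit: a cluster present in every replicate gives $AU = BP = 1$; a
cluster never reproduced gives $AU = 0$ with a warning; and a profile that
is *constant* across scales carries no information about scale dependence,
so the curvature term is taken as $c = 0$ and $AU$ equals the bootstrap
probability at scale 1. The last rule is a deliberate design choice: a
constant profile is outside the two-parameter scale model (the generic
least-squares fit would return a spurious curvature), and zero measured
scale dependence is most faithfully read as "no curvature evidence".
Resampling is seeded through the single classification seed, so stability
values are reproducible.

## 6. Expression scores

Counts are normalized to $\log_2(\mathrm{CPM} + 1)$. The scores downstream
are rank-based, so they depend only weakly on the variance stabilizer; the
normalization mode is recorded on the matrix so provenance survives I/O.

**Stemness set score.** Per gene, values are rank-transformed across samples
(average ranks on ties) and standardized to mean 0, sd 1. The group score of
a panel (the 34-gene stemness panel, in the reference design) is the sum
over panel genes of the group-mean z-score; a `score_fun = "mean"` switch
divides by the panel size for users who prefer a per-gene scale. The sum
convention is the default because it reproduces the familiar magnitude of
roughly ±10–25 for a 34-gene panel over a one-digit cohort; since z-rows are
centered, the size-weighted group scores cancel gene-by-gene, making the
score a signed contrast. The group difference is tested by Welch's t on
per-sample panel means.

**ssGSEA.** Per sample, genes are ordered by decreasing expression (ties
broken by gene symbol) with rank values $N, \dots, 1$; the enrichment score
is the summed difference between the in-set CDF weighted by
$\text{rank}^{\alpha}$ and the unweighted out-of-set ECDF, normalized by the
number of out-of-set genes. $\alpha = 0.75$ follows the original
single-sample enrichment convention; at $\alpha = 0$ the score depends on
ranks alone and is invariant to monotone transforms of a sample's values.
Subtype calls take the larger of the PN and MES enrichment scores; exact
ties are labeled ambiguous with a warning rather than broken arbitrarily.

**Over-representation.** Overlap of a differentially expressed gene list
(consumed as input — the package does not fit differential expression) with
each gene set is tested by the hypergeometric upper tail
$P(X \ge k)$ with BH adjustment across sets. Tests verify exact agreement
with combinatorial enumeration for all universes up to $N = 12$.

## 7. Methylation

**Input and filtering.** Per-site 5mC records are consumed at the bedMethyl
level (tab-separated, modification code in column 4, valid coverage in
column 10, percent modified in column 11; only code `m` records are used).
Records below 5 reads of valid coverage are dropped (inclusive boundary:
coverage 5 is kept). The depth-5 floor is interpreted as a per-site filter —
the conservative operational reading of a sequencing depth floor; setting
`min_site_coverage = 0` recovers the mean-genome-coverage reading in which
no per-site filtering occurs.

**Island aggregation.** The methylation of an island is the unweighted mean
of the percent values of all CpG sites whose 0-based position falls in the
half-open island interval $[\mathrm{start}, \mathrm{end})$, both strands
pooled. An optional `combine_strands` switch first merges plus/minus records
of the same CpG dinucleotide by coverage-weighted average. Aggregation is
invariant to record order and to splitting records across files, and is
tested against a brute-force per-site scan.

**MGMT status.** The MGMT promoter interval is stored as printed in clinical
coordinates — chr10:129,466,685–129,467,446, 1-based inclusive, hg38 — and
converted internally to the 0-based site convention (a site with 0-based
start $p$ is inside iff $\mathrm{start}-1 \le p \le \mathrm{end}-1$); both
boundary sites are unit-tested. A sample is called methylated when the mean
over region sites strictly exceeds 22%; exactly 22% is unmethylated. Zero
sites in the region yield status "undetermined" rather than a call.

**Differential methylation and linkage.** Per island, the groups are
compared with the classical equal-variance two-sample t-test (Welch
selectable by config); islands with $p < 0.05$ (raw — deliberately no
multiplicity correction, matching the screening character of the analysis;
a BH column is emitted for information) are called differentially
methylated, with direction recorded as hyper/hypo in the resistant group.
An island is *linked* to its associated gene when methylation and expression
changes have opposite signs,
$\mathrm{sign}(\Delta\text{meth}) \cdot \mathrm{sign}(\Delta\text{expr}) < 0$
(a zero expression change is not linked), the classical signature of
promoter-methylation silencing; the per-island Spearman correlation across
samples is reported alongside. The island→gene map is a user-supplied input:
how islands should be assigned to genes (nearest TSS, within 2 kb, curated)
is a question for the annotation, not this package.

## 8. The synthetic-cohort generator

The generator plants a known two-group structure in all three modalities so
every estimator above can be checked against ground truth:

* **Screens.** 4 sensitive + 5 resistant cultures, 329 drugs, 5-dose
  ten-fold series with a randomized per-drug anchor concentration, 16 + 16
  control wells. A drug is active in a group with probability 0.25
  (sensitive) or 0.08 (resistant); active curves have top asymptotes of
  60–100% with mild per-sample jitter, inactive drugs have top = 0 exactly.
  Well noise is multiplicative lognormal with CV 0.1 (mean 1), so CV = 0
  reproduces the true curves exactly. An optional `missing_fraction` drops
  whole drug × sample series to emulate incomplete panel overlap.
* **Expression.** Negative-binomial counts (dispersion 0.1; the Poisson
  limit at 0). A 34-gene stemness panel is shifted up by $2^{1}$ in
  resistant cultures; PN and MES panels (28 + 27 genes) are
  baseline-expression-matched and shifted up in the sensitive and resistant
  group respectively — matching matters because the subtype call compares
  raw enrichment scores, and unmatched panel baselines would encode panel
  composition, not the planted subtype.
* **Methylome.** 500 islands (5–100 CpG sites each) on a synthetic
  chromosome, non-overlapping, island means uniform in 15–55%; per-site
  fractions are Beta draws around the island mean with precision 50
  (infinite precision collapses sites onto the mean exactly). 5% of islands
  carry a planted ±30 percentage-point group difference. Coverage is
  1 + negative-binomial (mean 15), so some sites genuinely fall below the
  depth-5 filter. A 98-site MGMT-like promoter is placed at the real hg38
  coordinates with planted per-sample means of 30% (methylated) or 10%
  (unmethylated).

These noise models — lognormal for luminescence, negative-binomial for
counts, Beta for methylation fractions — are the standard minimal choices
for each modality. All values above were chosen once as realistic for this
assay class and are not tuned. Every draw flows from the single cohort seed
through fixed per-stage offsets, so identical configuration and seed give
byte-identical output files.

**What the generator does not emulate:** plate-position effects and batch
structure, drug–drug mechanism correlations, per-sample library-size and
purity variation, spatially correlated methylation, read-level basecalling
error, and any mutational signal. Passing tests therefore demonstrate
correctness of the estimators under clean, planted structure — not
robustness to every artifact of real screens.

## 9. Problem sizes and numerical tolerances

The test suite runs cohorts at the design scale (9 cultures × 329 drugs)
where the check is about end-to-end behavior, and smaller panels (25–300
drugs, 150–2000 islands) where the check is statistical: 50 seeded cohorts
for cluster-label recovery, 2000 islands for type-I calibration (flagged
fraction within 3 binomial standard errors of 0.05) and for power at the
planted 30-point difference (≥ 90% detection at 4 vs 5 samples), and
$B = 2000$ bootstrap replicates for stability checks. Closed-form DSS is
held to $10^{-6}$ against the trapezoid oracle; noiseless end-to-end
recovery to $10^{-4}$ on parameters and DSS; exact identities (z-row
centering, per-drug zero means) to $10^{-12}$. Matrix I/O writes 6
significant digits, and `write → read → write` is byte-stable.

## 10. Known limitations

* The fit assumes a monotone sigmoid; bell-shaped dose responses surface
  only as poor fits (high RSS or non-convergence scored 0), they are not
  modeled.
* The DSS variant implemented integrates the clipped response above the
  floor and normalizes by the full window; other score families differ in
  asymptote handling, so absolute values are comparable only within one
  variant.
* The stemness score's sum convention scales with panel size; use the mean
  switch when comparing panels of different sizes.
* AU values from the multiscale fit are asymptotic approximations; at small
  drug panels the per-scale BP estimates are noisy and AU inherits that
  noise.
* Island-level t-tests treat island means as approximately normal, which is
  reasonable for ≥ 5 sites but coarse for tiny islands at extreme
  methylation.
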