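---
title: "Methods: TF activity from paired tumor/normal multi-omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TF activity from paired tumor/normal multi-omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfacts)
```

# The model

`tfacts` treats a transcription factor's activity as a latent quantity that
is observable only through its consequences: the coordinated expression of
its target genes, and the phosphorylation state of proteins in its
pathways. The pipeline composes seven stages, each with an explicit
statistical contract.

## Regulon inference

Regulons are inferred from **normal-tissue** samples only, on
variance-stabilized expression. For a candidate TF–gene pair the statistic
is the Pearson correlation $r$ with the exact two-sided test
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of freedom. An edge is
retained when

* $p \le$ `p_threshold` (default $10^{-8}$) on the full data, **and**
* the edge reaches `p_threshold` in at least `min_support` (default 0.5)
  of `n_bootstraps` (default 1000) resamples of the samples, drawn with
  replacement.

The target's mode is $\mathrm{sign}(r)$: $+1$ activated, $-1$ repressed.
TFs retaining fewer than `min_targets` (default 20) edges are excluded
before any super-enhancer filtering — the exclusion applies to the
inferred regulon, not the direct subset. The bootstrap-support fraction is
recorded per edge so stricter post-hoc filters remain possible. Assumptions:
samples are exchangeable (no batch structure), and coexpression in normal
tissue is an adequate proxy for regulation; the SE filter exists precisely
because the second assumption is weak on its own.

Zero-variance genes are removed from the candidate pool before
correlation; a zero-variance TF is skipped with a warning rather than an
error, so one degenerate TF cannot abort a batch.

## Direct targets

A TF's direct-target set is the union of regulated-gene sets over all
super-enhancer records listing the TF among its bound factors, in the
tissue requested at read time (tissue labels are the only
case-insensitive identifiers in the package). Binding is taken as given by
the SE table; no motif scanning or distance arithmetic is performed, so no
genome-coordinate convention is needed. Filtering a regulon intersects its
target set with the direct set and never alters surviving edges; it is
idempotent by construction.

## Master regulator analysis

The differential signature is a **paired** statistic: per gene, the paired
t over tumor-minus-NAT patient differences, mapped through the t CDF
(df $= n-1$) onto the standard normal quantile scale. The enrichment score
of a regulon with $m$ usable targets is

$$\mathrm{NES} = \frac{1}{\sqrt{m}} \sum_{t} \mathrm{mode}_t \, z_t,$$

with a two-sided normal p-value. Under the null (targets exchangeable with
background genes) the NES is asymptotically standard normal; the test
suite checks this against a permutation oracle and a KS test. Modes are
used unweighted — bootstrap support does not weight the NES — because sign
semantics, not edge confidence, define the score. The 0.05 screen is
applied per TF without multiplicity correction; it is a screen, not an
inferential endpoint.

## Activity scores

Counts are normalized with a simplified variance-stabilizing transform
("vst-simple"): per-sample size factors by the median-of-ratios method
(genes with a zero anywhere are excluded from size-factor estimation,
since their geometric mean vanishes), then $\log_2(x/s_j + 1)$. This keeps
the two properties downstream stages need — library-size removal and
variance compression — with a closed form that is easy to audit. Size
factors are estimated jointly across all $2N$ samples so tumor and NAT
columns share a scale.

The per-sample activity score is the plain signed sum
$\sum_{+} x_{t,s} - \sum_{-} x_{t,s}$ over direct targets. It is linear in
the expression matrix, negates under a global mode flip, and is left
unstandardized because the survival stages split it at its median, which
is invariant to monotone transforms anyway. Inside `score_structure()`
TF rows are standardized before PCA by default (a flag disables this);
the TF×TF correlation matrix is computed on tumor samples only.

## Phosphosite selection

For each TF, eligible predictors are phosphosites detected in **all**
patients whose protein shares at least one pathway with the TF. The
response is the TF's tumor activity score per patient. The data are split
80/20, stratified by response quartile, and on the training set an L1 path
of 100 log-spaced lambdas from $\lambda_{\max}$ (the smallest lambda with
an all-zero solution) down to $10^{-3}\lambda_{\max}$ is fit with glmnet;
lambda is chosen by seeded 5-fold cross-validation. Predictors enter
unstandardized (log2 fold changes already share a scale); a flag enables
standardization.

The default selection rule is the **1-SE rule** (largest lambda within one
standard error of the CV-MSE minimum). The choice is deliberate: the model
is a feature-selection device, and with a pure-noise response the CV-MSE
minimizer admits spurious predictors in roughly half of runs, while the
1-SE rule mostly returns the empty model — the behavior a no-signal TF
should produce. `lambda_rule = "min"` restores the plain CV minimum.

Three outcomes are possible and all are first-class: `fitted`,
`no_predictors` (empty eligible set — no pathway-sharing complete sites),
and `all_zero` (no nonzero coefficient at the chosen lambda). The 20%
holdout R² is logged but nothing downstream consumes it.

Phosphorylation scores use coefficient **signs only**: per patient,
$P^+$ is the sum of fold changes over positive-coefficient sites and
$P^-$ over negative-coefficient sites. A reference 13-site coefficient set
for ERG ships in `inst/extdata/` as a worked fixture
(`erg_coefficient_table()`).

## Survival stratification

Median splits assign ties at the median to `"low"` — an arbitrary but
fixed rule that keeps splits deterministic (with an even patient count the
median is the midpoint of the middle two values). The only test is the
log-rank test over Kaplan–Meier strata; no Cox models are fit. The
worst-prognosis side of each split is **derived** from the data as the
group with the smaller restricted-mean survival, never hardcoded, because
on synthetic cohorts the direction depends on planted signs. Combined
strata count, per patient, the TFs on whose worst side they fall.
Quadrants split transcriptomic activity (x) and $P^+$ (y) at their
medians; the labeling follows reading order so that concordant patients
land in Q2 (high/high) and Q4 (low/low) and discordant patients in Q1
(low/high) and Q3 (high/low).

## Kinase activity

The "ksea-z" statistic compares a kinase's $m$ observed substrate fold
changes with the patient's full site background:
$z = (\bar{x}_{\text{sub}} - \bar{x}_{\text{bg}})\sqrt{m}/s_{\text{bg}}$.
It is exactly invariant to shifting all of a patient's sites by a constant
or scaling them by a positive factor. At least 10 observed sites are
required for a stable background. FDR control is Benjamini–Hochberg
across kinases **within each patient** (per-patient significant-kinase
counts are the quantity of interest); a `scope = "global"` flag applies BH
across the whole matrix instead.

# The synthetic cohort generator

`generate_cohort()` plants everything downstream stages look for, at the
scale of a 100-patient paired cohort:

* latent activity $a \sim N(0,1)$ in NAT and $N(1.5, 1)$ in tumor
  (`tumor_activity_shift`), per TF and patient;
* target counts negative-binomial (dispersion 0.1) around
  $\exp(\text{baseline} + \text{mode}\cdot\beta\, a)$ with $\beta = 1$;
  each TF's own gene tracks its activity the same way;
* 20 TFs × 50 targets (30% repressive) of 2000 genes; 40% of each target
  set receives super-enhancer support in tissue `"lung"`;
* five true phosphosites per TF with fold change
  $w \cdot (a_{\text{tumor}} - a_{\text{NAT}}) + \varepsilon$
  ($|w| \in [0.8, 1.5]$, signed, at least two positive), plus 200 decoy
  sites of pure noise; each TF shares one pathway with its true-site
  proteins, and decoy proteins are spread over those same pathways so that
  they are *eligible but uninformative* predictors;
* one planted kinase per TF mapped to that TF's positively-weighted true
  sites (a kinase's own substrates move with its activity), plus decoy
  kinases on decoy sites;
* survival exponential with log hazard $0.7 \times$ the **first** TF's
  tumor activity — a single designated prognostic TF makes power checks
  well-defined; censoring draws `event ~ Bernoulli(1 − censor_rate)` and
  gives censored patients a uniform fraction of their event time.

What the generator does **not** emulate: real-data marginal count
distributions, batch effects, missing-phosphosite patterns beyond the
complete/incomplete flag, correlated TF programs, or non-proportional
hazards. Passing tests therefore demonstrate internal correctness and
calibration of the statistics, not robustness to those real-data
features.

# Numerical choices

* Degenerate signature genes: differences with zero variance up to
  floating-point jitter (sd $\le 10^{-10}|\bar d|$) and nonzero mean are
  capped at $z = \pm 8$; all-zero differences give $z = 0$. The cap keeps
  one constant-shift gene from dominating a regulon score.
* Extreme t-to-z mapping is done in log space
  (`qnorm(pt(log.p = TRUE), log.p = TRUE)`) so far-tail z-scores do not
  saturate.
* `edge_pvalue()` returns exactly 0 at $|r| = 1$ rather than overflowing
  the t statistic.
* With a single eligible predictor, a zero column pads the design matrix
  (glmnet requires two columns); the pad can never be selected.
* Empty predictions in `truth_eval()` report precision as `NA`, not 0 —
  an empty set is not wrong, it is uninformative.

# Problem sizes in the test suite

Unit and property tests run on reduced cohorts (e.g. 60 patients, 300
genes, 4 TFs, 100 bootstraps) chosen so each check still exercises the
statistical behavior it targets; the acceptance-style checks use the full
standard cohort (100 patients, 2000 genes, 20 TFs, 1000 bootstraps),
10-seed LASSO sweeps, 50-replicate no-model rates, 100-replicate power and
1000-replicate null-calibration simulations. These sizes are the package's
validation design; the same generators accept larger values.

# Known limitations

* The coexpression + bootstrap regulon stage is a transparent stand-in for
  more elaborate network-inference machinery (mutual information, DPI
  pruning); it recovers planted linear regulons well but has no claim to
  optimality on real data.
* "vst-simple" is not a dispersion-fitted variance-stabilizing transform;
  for genes with very low counts its variance stabilization is coarser.
* The NES treats targets as independent given the signature; correlated
  targets inflate its variance, which the SE filter mitigates only in
  part.
* Kinase activity is substrate-mean scoring; no network propagation or
  sequence-motif information is used.
* Survival analysis is strictly two-or-more-group log-rank; no covariate
  adjustment.
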