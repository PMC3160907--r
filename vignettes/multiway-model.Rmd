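---
title: "The multivariate multi-way model for HDL lipidomic drug response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multivariate multi-way model for HDL lipidomic drug response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdlmultiway)
```

## Why a multi-way latent factor model

UPLC-MS lipidomics of HDL particles yields hundreds of peaks per sample,
while an intervention study of this kind has only a few dozen patients.
Lipids do not vary independently — species sharing class, chain length and
regulation move together — so the data support far fewer effective degrees
of freedom than peaks. The multivariate multi-way model exploits this: it
clusters lipids into similarly behaving groups and estimates ANOVA-type
covariate effects on one latent factor per cluster, with clustering and
effect estimation performed jointly in a single hierarchical Bayesian
model. Working at the cluster level is the defence against multiple
testing, and the full posterior propagates the uncertainty that a
small-sample study cannot avoid.

The design has three patient groups — fenofibrate-treated patients who end
up in the lowest quartile of homocysteine (Hcy), fenofibrate-treated
patients in the highest quartile, and placebo patients Hcy-matched to the
low group — with paired before/after samples. Two features make it
non-standard. First, the *high-Hcy placebo* cell is structurally missing:
placebo does not raise Hcy, so no such patients exist; the group coding
makes the cell unrepresentable rather than merely empty. Second, the
repeated measures require a per-patient term so that before/after changes
are judged against each patient's own baseline.

## The generative model

For lipid $d$ assigned to cluster $z_d$ with loading $v_d > 0$, in sample
$s$ of patient $j$ at time $t$:

$$x_{ds} = v_d\, x^{\mathrm{lat}}_{z_d, s} + \varepsilon_{ds},
  \qquad \varepsilon_{ds} \sim N(0, \Lambda_d)$$

$$x^{\mathrm{lat}}_{ks} = \alpha^{\mathrm{pat}}_{jk}
  + f_s\,\beta^F_k + p_s\,\beta^P_k + i_s\,\beta^I_k + \eta_{ks},
  \qquad \eta_{ks} \sim N(0, 1)$$

The projection matrix has exactly one nonzero entry per row (lipid), so the
cluster assignment *is* the sparsity pattern and the loading its value;
$\Lambda$ is the diagonal matrix of residual variances. The design
indicators $(f_s, p_s, i_s)$ per (group, time) cell are:

| cell | f | p | i |
| --- | --- | --- | --- |
| any group, before | 0 | 0 | 0 |
| low-Hcy fenofibrate, after | 1 | 0 | 0 |
| high-Hcy fenofibrate, after | 1 | 0 | 1 |
| placebo, after | 0 | 1 | 0 |

So $\beta^F$ is the fenofibrate effect shared by both treated groups,
$\beta^P$ the placebo effect, and $\beta^I$ the *additional* shift in
fenofibrate-treated high-Hcy patients. The patient effect
$\alpha^{\mathrm{pat}}_{jk}$ is identical in a patient's before and after
samples; before-treatment cells contain nothing else, so baseline group
differences are absorbed by the patient effects and no separate baseline
Hcy main effect is needed. A placebo patient sampled only at close-out
still contributes: their single sample gives a proper, more strongly shrunk
patient-effect conditional.

## Priors and identifiability

All priors are conjugate and weak, and all are configurable through
`model_config()`:

* effects: $\beta \sim N(0, 10^2)$ per cluster and effect;
* loadings: positive half-Gaussian $|N(0,1)|$;
* residual variances: $\Lambda_d \sim \mathrm{InvGamma}(2, 1)$;
* patient effects: $\alpha \sim N(0, \sigma^2_{\mathrm{pat}})$ with
  $\sigma^2_{\mathrm{pat}} \sim \mathrm{InvGamma}(2, 1)$;
* cluster probabilities: $\pi \sim \mathrm{Dirichlet}(1, \ldots, 1)$.

Two constraints pin the scale and sign of the latent space: the latent
noise variance is fixed at 1, and loadings are constrained positive. With
positive loadings, "positive effect" reads unambiguously as upregulation of
the cluster's lipids.

The grand mean is handled by centering. Because the model defines the
intercept as the *before-treatment* average, model fits center each lipid
on its before-treatment samples (`standardize(..., center = "before")`);
the scale is the full-sample standard deviation. Centering on all samples
instead would fold part of the treatment effect into the location — a
common shift that the shrunken patient effects only partially absorb — and
bias the effect estimates toward zero; we measured exactly this bias before
adopting before-treatment centering, which removed it. `standardize()`
defaults to full-sample centering (`center = "all"`) for generic use; the
model pipeline always passes the design and uses `center = "before"`.
Concentrations are logged before centering (`log_z`), since they are
positive and right-skewed; zeros receive a half-minimum pseudo-count, and
zero-variance lipids are excluded with a warning.

## Gibbs sampler

All full conditionals are conjugate. One sweep updates, in fixed order:
cluster assignments $z$ (categorical, proportional to $\pi_k$ times the
Gaussian likelihood of the lipid's profile under factor $k$'s current
trajectory), loadings (positive-truncated Gaussian) and residual variances
(inverse gamma), latent factors (Gaussian, pooling the prior trajectory
with the loaded lipid profiles), patient effects (Gaussian shrinkage over
the patient's samples) and their variance (inverse gamma), the three
effects (joint trivariate Gaussian per cluster — the placebo effect is
informed only by placebo after-treatment samples and the interaction only
by high-Hcy after-treatment samples, via the design indicators), and
finally $\pi$ (Dirichlet). Any fixed order gives a valid Gibbs kernel;
fixing it makes chains bit-reproducible under a seed. The defaults are 2000
burn-in plus 2000 retained sweeps; initialization uses a seeded k-means
partition (10 restarts — single-restart k-means occasionally starts the
chain in a merged-cluster mode that Gibbs is slow to escape), unit
loadings, unit variances and zero effects.

Empty clusters are allowed to persist; they simply attract no lipids, which
is how a requested 25 clusters can yield fewer non-empty ones. Cluster
labels are exchangeable, so retained draws are aligned to the
maximum-a-posteriori partition (the retained draw with the highest joint
log density) by greedy maximum-overlap matching before summarizing.

## Effect classification

An effect is called when its posterior mass sits clear of zero:
*significant* if the equal-tailed 95% credible interval excludes 0, *almost
significant* if the 90% interval excludes 0 but the 95% does not. The 95/90
pair is a documented convention of this package (configurable in
`classify_effect()`); the distinction mirrors the two-tier highlighting
used in effect box plots. The (F, I) sign pair then has a direct group
reading (`interpret_combination()`): for example, positive fenofibrate with
negative interaction means only the low-Hcy group is upregulated.

## Choosing the number of clusters

`select_num_clusters()` holds out a fraction of patients (stratified by
group), fits each candidate K on the rest, and scores held-out patients by
posterior predictive density. A held-out patient's before/after pair is
scored *jointly*: integrating the shared patient effect gives each cluster
block the covariance $\Lambda + (\sigma^2_{\mathrm{pat}} + 1)vv^\top$
within a sample and $\sigma^2_{\mathrm{pat}} v v^\top$ across the pair,
evaluated by the Woodbury identity. Joint scoring matters: scoring samples
marginally discards the pairing information, and with it any measurable
benefit of the repeated-measures term.

The held-out score rises steeply until K reaches the number of clusters the
data support and then plateaus — surplus clusters simply stay empty, so
candidates above the true K score identically up to Monte-Carlo noise.
An argmax over a noisy plateau is arbitrary, so ties are resolved by the
one-standard-error parsimony rule: the smallest K whose mean per-patient
score lies within one standard error (over held-out patients) of the best
candidate. On synthetic data with five true clusters this selects K = 5
from the grid {1, 5, 10} reliably; on flat stretches of a real grid such as
20–25 it prefers the lower end.

## The synthetic study generator

`generate_study()` draws data exactly from the generative form above, with
the study's dimensions as defaults: 17/16/14 patients in the three groups,
615 peaks of which 249 carry parseable lipid names, paired samples, and
optionally a baseline-free placebo arm. Loadings are drawn
$|N(0,1)| + 0.5$ so clusters have unambiguous sign; unidentified peaks get
retention times uniform on [60, 840] s so the normalization dispatch rules
are exercised; residual sd defaults to 0.5 and the patient-effect sd to 1.
Because a peak table must hold nonnegative values, the Gaussian field is
generated on the log scale and stored exponentiated (lognormal
concentrations); `standardize(log_z)` recovers the Gaussian field exactly.
`as_raw_intensities()` converts a concentration table into a raw-intensity
view — per-sample lognormal drift factors plus spiked standard rows — whose
normalization reproduces the concentrations, which is precisely the
instrument-drift invariance the internal standards exist to provide.
Scaled-down tests use `generator_config_small()` (60 lipids, 5 clusters,
10/10/10 patients); the recovery checks in the test suite run 20 replicates
at 17/16/14 patients with 500 + 500 sweeps and K = 10, sizes chosen so the
whole suite completes in a few minutes while leaving the per-replicate
posterior informative.

What the generator does *not* emulate: MS noise physics, retention-time
drift, isotope patterns, missing peaks, or heavy-tailed residuals. Passing
recovery tests therefore demonstrates correctness of the inference under
the model's own assumptions, not robustness to real-data artefacts.
Similarly, `clinical_covariate_fixture()` reproduces only the marginal
per-cell summaries of the clinical variables (independent Gaussians), not
their correlation structure; it exists to exercise the
one-factor-per-variable analysis path.

## Internal-standard normalization

Raw intensities are converted to concentrations by dividing each peak by
the intensity of its assigned internal standard in the same sample and
multiplying by the standard's spiked concentration. The assignment rules:
monoacyl lipids except cholesteryl esters → `PC(17:0/0:0)`; diacyl lipids
except ethanolamine phospholipids → `PC(17:0/17:0)`; ceramides →
`Cer(d18:1/17:0)`; diacyl ethanolamine phospholipids → `PE(17:0/17:0)`; TG
and cholesteryl esters → `TG(17:0/17:0/17:0)`; unidentified peaks by
retention time, `[0, 300)` s / `[300, 410]` s / `(410, ∞)` s to the three
standards in that order. Interval closure at the boundaries follows the
open/closed wording of the rule set ("below 300 s", "between 300 and
410 s", "higher") and is pinned by tests.

Three mappings are package decisions where the rule set is silent:
sphingomyelins (two-chain choline sphingolipids, for which no dedicated
standard is spiked) follow the diacyl-PC rule; ether and plasmalogen PE
species follow the ethanolamine rule; free cholesterol follows the
TG/sterol-ester rule. Spiked concentrations default to 1.0 per standard and
are configuration (`default_standard_map()`, YAML via
`read_standard_map()`), since only a range is known for the actual spike
levels. No drift correction, batch correction or imputation is performed
beyond the log-transform pseudo-count.

## Numerical choices and degenerate inputs

* Positive-truncated normal draws use the inverse-CDF method with an
  exponential-proposal rejection fallback for deep-tail cases.
* A sweep aborts with a state dump if non-finite values appear; fits under
  the missing placebo-baseline layout are explicitly tested to stay finite.
* Identical lipid profiles receive identical cluster-assignment
  conditionals (exchangeability), and the joint log density is invariant to
  relabeling clusters; both are tested.
* `K = 1` makes the assignment update a no-op; `K > D` is rejected.
* Constant lipids are excluded before fitting; their ids are reported.
* The conjugate reduction (one lipid, one cluster, fixed loading and
  variances) is compared against the exact multivariate normal posterior in
  the test suite, using batch-means Monte-Carlo standard errors.

## Known limitations

* One factor per lipid: a lipid influenced by two processes is forced into
  one cluster.
* The latent noise and residual scales are set by convention (unit latent
  noise, standardized lipids); effect magnitudes are therefore in
  standardized units and not directly comparable across datasets with
  different residual structure.
* Effect information per cluster is limited by the number of *patients*,
  not lipids — cluster-level latent noise is shared across a cluster's
  lipids, so adding lipids sharpens the factor, not the treatment
  contrast.
* Label alignment by greedy overlap matching is adequate for the
  well-separated regimes tested here; heavily label-switching chains would
  warrant a relabeling algorithm with optimality guarantees.
* The clinical-variable path (`one_factor_per_variable`) estimates one
  factor per variable and is exercised on synthetic fixtures only.
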