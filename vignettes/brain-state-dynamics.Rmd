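---
title: "Modelling whole-brain state dynamics with Gaussian hidden Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling whole-brain state dynamics with Gaussian hidden Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainstates)
```

## The model

`brainstates` treats a cohort of parcellated resting-state fMRI recordings as
realizations of a single K-state hidden Markov model with multivariate-normal
observations. Each subject contributes a $T \times R$ matrix of region
time series; all subjects are stacked (in manifest order) into one
$\sum_s T_s \times R$ matrix, z-scored, and modelled jointly. The latent chain
has an initial distribution $\pi$, a row-stochastic transition matrix $A$, and
per-state emission parameters $(\mu_k, \Sigma_k)$. In the neuroimaging reading,
$\mu_k$ is the state's *averaged functional activity* and the correlation
matrix derived from $\Sigma_k$ its *functional connectivity*. Because the
stacked subjects are unrelated people, the chain restarts from $\pi$ at every
subject boundary; transitions are never counted across subjects.

From a decoded cohort the package computes the standard temporal statistics,
per subject:

* **Fractional occupancy (FO)** — the mean posterior probability of a state
  over the subject's timepoints: the proportion of scan time spent there.
  FO vectors sum to one by construction.
* **Averaged lifetime (ALT)** — the mean length of maximal constant runs of a
  state in the Viterbi path, in timepoints (seconds via the TR, default 2 s).
  For a Markov chain the population analogue is the geometric mean dwell
  $1/(1 - A_{kk})$, which the package exposes as `expected_dwell()` and uses
  to validate ALT on simulated chains.
* **Switching rate (SR)** — the fraction of consecutive timepoint pairs at
  which the decoded state changes.
* **Per-subject transition matrices** — row-normalized Viterbi bigram counts.

FO is computed from the soft posteriors while ALT, SR and transition matrices
come from the hard Viterbi path. This split is deliberate: FO is a time
proportion, which the smoothed posterior estimates most directly, whereas
lifetimes and switches are visit-level constructs that need an actual state
assignment. (Either convention could be defended for FO; the identity
`FO(one-hot gamma) == FO(path)` is tested so the two views agree whenever the
posterior is degenerate.)

## Variational inference and why it is the default

Model inversion is variational Bayes with conjugate priors: symmetric
Dirichlet priors on $\pi$ and on each row of $A$, and Gaussian–Wishart priors
on $(\mu_k, \Lambda_k)$. Each cycle alternates a forward–backward E-step
(run in compiled code over the whole concatenation, restarting at subject
boundaries) with closed-form posterior updates, and tracks the variational
free energy. The objective is monotone across cycles up to numerical slack,
which the test suite asserts on every fit it makes.

The variational treatment is not a luxury here: the package selects the
number of states by sweeping K and counting *occupied* states, and that rule
only works if surplus states actually die. Under maximum-likelihood or MAP
EM, two components that split one true state both keep responsibility mass
indefinitely; under the free-energy penalty the weaker duplicate drains and
collapses onto its prior (its occupancy falls below any sensible floor, and
it is flagged `prior_dominated` in the fit metadata). Watching fitted traces
shows the pruning transient passes through a long plateau of small relative
objective gains (around $10^{-5}$) before accelerating as the state empties;
the convergence tolerance therefore defaults to a relative change of
$10^{-7}$ with a 500-cycle cap, so fits are not stopped in the middle of that
plateau.

Key tunables, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `alpha_trans` | 0.1 | Dirichlet pseudo-count per transition entry; values below 1 favour sparse state use and sharpen pruning while leaving the posterior mean essentially the empirical rates at realistic data sizes |
| `beta0` | 0.01 | prior precision scale on state means; vague, so a one-state fit reproduces the sample moments |
| `nu0_extra` | 1 | Wishart degrees of freedom above $R + 1$; the prior scale matrix matches the per-column data variance |
| `tol` | 1e-7 | relative free-energy change at which a fit is declared converged |
| `max_cycles` | 500 | cycle cap per restart |
| `n_restarts` | 5 | independent k-means-seeded initializations; the best objective wins |

Restarts are seeded `seed + i - 1`; every random draw in the package flows
from an explicit seed and global RNG state is restored afterwards, so all
results are bit-reproducible.

## Model-order selection

Following common practice for this model family, the state count is chosen by
fitting every K in a range (e.g. 5–12 for whole-brain data; the packaged
simulations use 4–8) several times with different initializations, recording
the free energy and the cohort-mean FO of every state. A state counts as
occupied when its cohort-mean FO reaches 0.01 — strict enough to kill
prior-dominated empty states, loose enough to keep genuinely transient ones.
The working model is taken at the smallest K from which increasing K adds no
occupied states; among that K's repetitions the lowest free energy wins, with
ties resolved to the earliest repetition. When no plateau exists in the range
the best model at the largest K is returned with an explicit warning. Within
a sweep each fit defaults to a single restart, because the sweep's
repetitions already are the independent initializations.

## The synthetic cohort generator

`cohort_spec()` / `simulate_cohort()` generate the ground-truth cohorts used
throughout the tests: two groups of subjects whose time series are emitted by
per-state multivariate normals under a Markov chain. The case group differs
from controls *only* in the target state's self-transition probability,
raised by `delta` with the row's off-diagonal mass renormalized
proportionally — this isolates the induced FO/ALT difference in one state,
mirroring the empirical picture of a single over-occupied state in patients.
A severity score is generated for case subjects only (as a self-rated
symptom scale would be), as a linear function of the subject's *realized*
target-state occupancy plus Gaussian noise, which makes the
severity-correlation stage testable with a known effect. Initial
distributions default to the chain's stationary law so short records carry no
burn-in transient, and age/sex are drawn independently of the dynamics.

Default study conditions, chosen once and used by the validation battery:

* 6 states over 20 regions, 232 timepoints per subject (the retained length
  of a TR = 2 s acquisition), 60 + 60 subjects;
* control self-transition 0.45, i.e. a mean dwell of about 1.8 timepoints
  (3.6 s) — fast, transient states;
* case increment `delta = +0.15` on state 6;
* severity = 40 × FO(target) + N(0, 6), a scale straddling the default
  severity split of 7.

The stickiness default was fixed by an operating-characteristic calculation
done before the validation battery was frozen. The FO vector is
compositional: raising the target state's occupancy by $\Delta$ necessarily
lowers every other state's by about $\Delta/(K-1)$, so group differences
"leak" into non-target states at one fifth of the target amplitude. Power
for the target state saturates for any stickiness in [0.4, 0.6] under the
default design, so the binding constraint is specificity; at stickiness 0.45
the measured non-target flag rate (Bonferroni level, 150 simulated cohorts)
was 0.12, comfortably below the 0.2 bound the battery asserts, while target
power stayed at 1.0. One consequence worth stating plainly: the non-target
"false" positives are not artifacts — they are real, small, compositionally
induced group differences, which is exactly why their rate is bounded rather
than required to equal the nominal level.

What the generator deliberately does **not** emulate: hemodynamic
autocorrelation, motion and scanner artifacts, site effects, spatial
structure in the noise, or any voxel-level process. Passing the battery
therefore shows the estimator and inference chain are correct for
Markov-switching Gaussian data, not that real fMRI obeys that model.

## The statistical battery

`run_group_analysis()` reproduces the group-inference chain used in
dynamic-state case-control studies:

1. each temporal feature (per-state FO and ALT, and SR) is rank-based
   inverse-normal transformed with the Blom offset,
   $\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$, ties averaged, missing values
   passed through;
2. a fixed-effect linear model of the transformed feature on group plus age
   (centered) and sex gives the two-group t (or the partial group F with
   three groups);
3. Bonferroni correction divides the threshold by the number of states,
   separately per feature family (K-state FO family, K-state ALT family, SR
   alone) — the correction is per feature, not pooled across features;
4. Tukey post-hoc contrasts (via estimated marginal means on the same model)
   compare control, asymptomatic and symptomatic groups, the latter two split
   at a configurable severity threshold (default 7, "above" = symptomatic);
5. Cohen's d with a percentile bootstrap CI (2000 paired resamples by
   default) quantifies each two-group contrast; and
6. Pearson correlations relate case-subject severity to each state's FO and
   ALT.

Degenerate inputs follow explicit conventions, each tested: a feature that is
identical across subjects yields t = 0, p = 1; unvisited states propagate as
missing and are deleted pairwise with a logged count; collinear designs stop
with an error naming the offending columns; a zero pooled SD stops the
bootstrap. With exactly two groups the Tukey-adjusted p equals the
unadjusted pairwise p (the studentized-range identity $q = \sqrt{2}\,|t|$),
which the suite checks against `ptukey` directly.

## Numerical choices

* Forward–backward uses per-timepoint scaling (not log-space), accumulating
  the log evidence from the normalizers; posteriors are renormalized rowwise
  to cancel drift. The implementation is checked to $10^{-8}$ against
  exhaustive enumeration over all $K^T$ paths on 200 random toy instances.
* Covariance updates inherit positive definiteness from the Wishart scale
  accumulation; if floating-point loss ever breaks a Cholesky, a diagonal
  floor of $10^{-6}$ times the mean column variance is added.
* Standardization is global per-column by default (stack, then z-score),
  matching the stated order of operations for concatenated cohorts;
  `per_subject` mode (z-score within each subject, then stack) is available
  because both conventions circulate for this model class. Zero-variance
  channels are an error naming the column.
* Row ranges are half-open and 0-based internally; user-facing states and
  regions are 1-based.
* State labels are arbitrary, so every comparison across runs or against a
  ground truth goes through `match_states()`, an exact assignment over state
  mean correlations for $K \le 8$ (covariance Frobenius distance breaks
  ties) and greedy beyond.
* Parameter-recovery scores map the truth means into the standardized data
  space through the recorded center/scale before correlating; correlation is
  not invariant to per-column rescaling, so comparing across spaces would
  understate recovery.

## Problem sizes used in the validation battery

The packaged battery runs at desk scale: bookkeeping on 812 × 232 × 111
(dimensions only), decoding oracles at $K \le 3$, $T \le 8$, parameter
recovery on 120 subjects × 200 timepoints × 12 regions, order selection on
ten replicates of 40 × 150 × 10, and inference operating characteristics on
60 null and 20 perturbed cohorts at the default study conditions. These
sizes keep the whole battery to a few minutes while leaving each check
well-powered; all of them are the package's own choices, stated here so they
can be scaled up.

## Known limitations

* The observation model is order-0 Gaussian: no autoregressive emissions,
  time-delay embedding, or stochastic mini-batch inference.
* Free energies are comparable across runs and K within one dataset and
  configuration, not across datasets or priors.
* The greedy matching for $K > 8$ is not guaranteed optimal.
* The severity threshold convention is `> threshold` = symptomatic, matching
  the usual clinical split; scores exactly at the threshold are
  asymptomatic.
* No reading of imaging formats: inputs are delimited text matrices plus a
  manifest and a parcellation CSV, with nuisance regression and denoising
  assumed done upstream.
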