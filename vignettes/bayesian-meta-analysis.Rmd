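---
title: "Bayesian and frequentist meta-analysis of binary outcomes with binmeta"
author: "binmeta authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian and frequentist meta-analysis of binary outcomes with binmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

A meta-analysis of a binary outcome combines $k$ independent 2×2
tables: study $i$ observes $r_{Ti}$ events among $n_{Ti}$ treated
patients and $r_{Ci}$ events among $n_{Ci}$ controls. The conventional
frequentist analysis converts each table to a log odds ratio
$y_i = \log(a_i d_i / b_i c_i)$ with sampling variance
$v_i = 1/a_i + 1/b_i + 1/c_i + 1/d_i$ and fits the normal–normal
random-effects model $y_i \sim N(\theta, v_i + \tau^2)$. Two of its
assumptions are fragile: the $v_i$ are treated as known constants even
though they are functions of random counts, and zero cells make $y_i$
and $v_i$ undefined, forcing ad hoc continuity corrections and the
outright exclusion of double-zero studies.

`binmeta` implements both this conventional route and an exact-
likelihood Bayesian alternative, so the two can be compared on the same
data — which is exactly where the interesting disagreements live: few
studies, rare events, many zero cells.

## The hierarchical model

The Bayesian route models the counts directly:

$$r_{Ci} \sim \mathrm{Bin}(n_{Ci}, \pi_{Ci}), \qquad
  r_{Ti} \sim \mathrm{Bin}(n_{Ti}, \pi_{Ti}),$$
$$\mathrm{logit}(\pi_{Ci}) = \mu_i, \qquad
  \mathrm{logit}(\pi_{Ti}) = \mu_i + \delta_i, \qquad
  \delta_i \sim N(\theta, \tau^2).$$

The $\mu_i$ are study-specific baseline logits, treated as unknown
fixed effects with vague $N(0, 100^2)$ priors (we deliberately do not
model them as exchangeable random effects; that is a separate,
debated assumption). $\theta$ is the overall log OR, also with an
$N(0, 100^2)$ prior, and $\tau$ is the between-study heterogeneity
standard deviation. Results are reported as the posterior median and
central 95% credible interval of $e^\theta$ and of $\tau$. Quantiles
commute with monotone transforms, so summarizing $\exp(\theta)$ draws
or exponentiating $\theta$ quantiles gives the same interval (up to
quantile-interpolation arithmetic); the package exponentiates the
$\theta$ quantiles.

Because the likelihood is the exact binomial, studies with zero cells
pose no difficulty: a double-zero study is simply strong evidence of a
low baseline rate, and it still informs $\mu_i$ (and, through the
hierarchy, everything else). No continuity correction is applied on the
Bayesian route.

## Heterogeneity priors

The prior on $\tau$ (or $\tau^2$) is the critical modelling choice,
especially for small $k$ or rare events. Four families are provided,
each on the scale conventional for it:

| family | scale | hyper-parameters | defaults in the 12-prior grid |
|---|---|---|---|
| inverse-gamma IG($\alpha,\beta$) | $\tau^2$ | shape, scale | $\alpha=\beta \in \{0.001, 0.01, 0.1\}$ |
| uniform U($0,c$) | $\tau$ | upper bound | $c \in \{2, 10, 100\}$ |
| half-normal HN($0,\sigma^2$) | $\tau$ | variance of the folded normal | $\sigma^2 \in \{0.1, 1, 2\}$ |
| log-normal LN($\mu,\sigma^2$) | $\tau^2$ | $\log\tau^2 \sim N(\mu,\sigma^2)$ | Turner catalogue |

The log-normal entries are the evidence-based informative priors of
Turner and colleagues, fitted to a large corpus of Cochrane
meta-analyses and indexed by treatment-comparison type
(pharmacological vs. placebo, pharmacological vs. pharmacological,
non-pharmacological) and outcome type (all-cause mortality,
semi-objective, subjective). Outcome classification can be genuinely
ambiguous, so `default_prior_grid()` includes all three outcome keys
for the chosen comparison rather than guessing one. `U(0, 2)` is a
reasonable weak default for log ORs, which rarely exceed ±2;
IG priors with tiny shape are close to flat on $\log \tau^2$ and are
*not* non-informative — IG(0.001, 0.001) places roughly half its mass
beyond the range of double-precision numbers, which is why the package
evaluates such densities on the log scale (`prior_density(log_x =
TRUE)`) when normalization or far-tail behavior matters.

Prior sensitivity analysis — rerunning with all 12 priors via
`run_analysis()` — is the recommended practice whenever data are
sparse.

## The sampler

`run_mcmc()` uses a hand-written adaptive Metropolis-within-Gibbs
scheme. Per iteration:

1. **$\mu$ sweep.** Given everything else, the $\mu_i$ are mutually
   independent, so all $k$ receive simultaneous random-walk proposals
   with componentwise accept/reject.
2. **$\delta$ sweep.** Likewise for the $\delta_i$ (treatment-arm
   likelihood plus the $N(\theta, \tau^2)$ term).
3. **$\theta$.** Exact conjugate normal Gibbs draw given
   $(\delta, \tau)$.
4. **Translation move.** A single random-walk shift applied jointly to
   $\theta$ and all $\delta_i$. When $\tau$ is small the hierarchy
   glues $\delta$ to $\theta$ and steps 2–3 move the common location
   only in $O(\tau)$ increments; the joint shift restores mixing (it
   is what makes the near-degenerate-$\tau$ posterior reproduce the
   common-effect estimate rather than wherever the chain started).
5. **$\tau$.** With an inverse-gamma prior, an exact conjugate Gibbs
   draw of $\tau^2$; with any other prior, random-walk Metropolis on
   $\log \tau$ with the Jacobian correction. The two update types are
   cross-validated against each other in the test suite (they must
   produce indistinguishable posteriors under an IG prior).

Proposal scales adapt by Robbins–Monro (step $\min(0.25, t^{-1/2})$)
toward 44% acceptance — the standard target for one-dimensional
random-walk Metropolis — during the burn-in only, and are frozen
afterwards so the retained draws come from a fixed kernel with the
correct invariant distribution. Sampling on $\log \tau$ (or
$\tau^2 > 0$) excludes the $\tau = 0$ boundary by convention;
`log_posterior()` returns $-\infty$ there.

Initialization uses empirical logits with a 0.5 stabilizer
($\mu_i$ at the control-arm logit, $\delta_i$ at the empirical log OR,
0 for double-zero studies, $\theta$ at their mean, $\tau$ at 0.1),
jittered by ±50% per chain so chains start overdispersed. Chain $j$
uses seed `seed + j − 1`; identical seed and configuration reproduce
the draw sequences bit for bit.

Defaults follow common long-run practice for this model: 3 chains,
50,000 burn-in iterations, 200,000 sampling iterations, thinning rate 2
(read as "retain every 2nd draw"). The test suite and the acceptance
script use a scaled-down configuration — 3 chains × (2,000 burn-in +
10,000 iterations, thin 2), i.e. 15,000 retained draws — which is
ample for the summary quantiles these checks compare; the handful of
heavier self-validation runs use 2 chains × 50,000 iterations with
thinning 10.

## Convergence diagnostics

The workflow treats diagnostics as a gate, not an afterthought.
`build_report()` monitors $\theta$ and $\tau$ with:

- rank-normalized split-$\hat R$ (chains split in half so within-chain
  drift registers as between-chain variance; ranks make the statistic
  robust to heavy tails), with the convention $\hat R = \infty$ for
  chains stuck at distinct constants;
- effective sample size via Geyer's initial monotone positive sequence
  on the combined split-chain autocorrelations;
- a kernel-density mode count on the pooled $\theta$ draws, with a
  topographic-prominence filter (a mode counts only if it rises above
  its deepest separating valley by 10% of the peak density) so that
  wiggles and heavy tails are not misread as multimodality.

Verdicts: **converged** iff $\max \hat R \le 1.05$, $\min \mathrm{ESS}
\ge 400$, and $\theta$ unimodal; **failed** iff any $\hat R > 1.2$ (or
non-finite), any ESS < 100, or $\theta$ multimodal; **suspect**
otherwise. The thresholds are package defaults (configurable via
`diagnostic_thresholds()`): 1.05/400 reflect widely used reporting
practice, and the failed tier is set where experience says summaries
are no longer trustworthy. A failed verdict suppresses the posterior
summaries as NA in `run_analysis()` tables and attaches remedies in
priority order (more iterations; re-examine the prior; consider
subgroup analyses; treat results as unreliable). Raw draws remain
exportable via `draws_table()` regardless of verdict.

## Sparse-data policies

For the frequentist route, `apply_sparse_policy()` implements the
standard rules: studies with zero cells in both arms are excluded
(their log OR is not estimable); studies with zero cells in a single
arm receive a continuity correction. The correction adds 0.5 to **all
four** cells of the affected study (the Gart convention) by default;
`all_cells = FALSE` switches to correcting only the zero cells, since
conventions differ across software and the choice is consequential
only in extreme sparsity. Arms with $r = n$ (a zero *non-event* cell)
trigger the same policy as zero-event arms by symmetry. In Bayesian
mode the function is the identity: the exact likelihood needs none of
this.

## The frequentist engine

$\tau^2$ estimators: the DerSimonian–Laird moment estimator
$\max\{0, (Q - (k-1)) / (\sum w_i - \sum w_i^2 / \sum w_i)\}$ with
$w_i = 1/v_i$; and ML/REML, maximizing the profiled marginal
(restricted) log-likelihood over $\tau^2 \in [0, 100]$ by Brent's
bounded scalar optimization (relative tolerance $10^{-10}$), with the
boundary value 0 always compared against the interior optimum so the
estimate is properly truncated. The optimizer is validated against a
dense grid search (step $10^{-4}$) and against `metafor` as an
independent implementation.

Pooling uses inverse-variance weights $w_i^* = 1/(v_i + \hat\tau^2)$
and the Wald interval $\hat\theta \pm 1.959964 (\sum w_i^*)^{-1/2}$ —
deliberately the plain z-interval, matching conventional practice, not
Knapp–Hartung.

The Q-profile interval for $\tau$ inverts
$Q_{\mathrm{gen}}(\tau^2) = \sum (y_i - \hat\theta(\tau^2))^2 /
(v_i + \tau^2)$, which is continuous and decreasing in $\tau^2$,
against $\chi^2_{k-1}$ quantiles; roots are bracketed by geometric
expansion from $[0, 1]$ and solved to $10^{-8}$ on $\tau^2$. A bound
whose equation has no non-negative root is truncated to 0. One
degenerate case deserves note: when all $y_i$ are equal,
$Q_{\mathrm{gen}} \equiv 0$ and *both* bounds truncate, so the
interval is $[0, 0]$ — the "empty set" metafor reports in the same
situation, and the behavior seen in heavily-truncated real analyses.

## The synthetic-data generator

`simulate_meta()` draws from exactly the hierarchical model above:
$\mu_i \sim N(\texttt{baseline\_mean}, \texttt{baseline\_sd}^2)$,
$\delta_i \sim N(\theta, \tau^2)$, per-arm sizes uniform on `n_range`
(balanced arms by default; an `imbalance` ratio is available), binomial
counts. It returns the realized latent truth alongside the data so
recovery tests need no re-derivation.

`scenario_presets()` fixes five regimes chosen to span the situations
that stress meta-analytic methods, with parameters chosen once to
mirror realistic published meta-analyses of each shape:

- **large_cohort** — $k = 13$, 2,000–30,000 per arm, uncommon outcome
  (baseline logit −5.5), OR 4.4, $\tau = 0.45$: abundant information,
  all methods should roughly agree.
- **no_heterogeneity** — $k = 8$, $\tau = 0$, OR 1.16, common outcome:
  frequentist estimators truncate $\hat\tau$ to 0 (the moment/ML
  estimate falls at the boundary in most replicates), while Bayesian
  posteriors keep $\tau$ uncertainty and give wider intervals.
- **rare_event** — $k = 13$, baseline logit −5 ($\approx 0.7\%$),
  100–500 per arm, OR 4: zero control arms are common, double-zero
  studies occur, and the Bayesian and frequentist sparse-data paths
  diverge.
- **all_zero_control** — $k = 15$, baseline logit −9, 150–350 per arm,
  true log OR 2.6: around 7,000 patients and a handful of events, with
  every control arm empty in most replicates; MCMC convergence
  typically fails, which is the point of the regime.
- **moderate** — $k = 25$, OR 0.82, $\tau = 0.22$: a well-behaved
  middle ground.

Regime-defining features are probabilistic, so a given replicate may
not realize them (a rare-event replicate may happen to contain no
double-zero study). `simulate_meta_where()` therefore scans seeds
deterministically and returns the first replicate satisfying the
regime's defining condition — the in-silico analogue of choosing a
real dataset as an example *because* it exhibits the phenomenon. Tests
that assert regime phenomena condition on the regime being realized;
they do not tune parameters.

What the generator does **not** emulate: publication bias or selective
reporting, non-binomial overdispersion within arms, correlated or
multi-arm trials, covariate-driven heterogeneity, and non-normal
random-effects distributions. Passing recovery tests therefore show
the machinery is self-consistent under the model's own assumptions,
not that the model is adequate for any particular real dataset.

## Numerical choices and edge cases

- Binomial log-likelihoods are computed as $r\eta - n\log(1+e^\eta)$
  with a stable `log1p`-based `log1pexp`; no probabilities are formed.
- `optimize()` never evaluates interval endpoints, so the boundary
  $\tau^2 = 0$ is checked explicitly in ML/REML.
- ESS is capped at the total draw count; $\hat R$ of identical
  constant chains is 1, of distinct constant chains $\infty$.
- Multimodality needs ≥ 500 pooled draws; below that the check is
  skipped (flag `FALSE`, mode count `NA`) rather than guessed.
- The KS comparison between Gibbs and Metropolis $\tau$ updates
  subsamples the thinned draws once more, since autocorrelation makes
  two-sample tests anti-conservative.
- Degenerate inputs fail loudly and early: empty datasets, $r > n$,
  duplicate study labels, all-double-zero frequentist analyses, zero
  cells reaching `log_or()` directly.

## Limitations

Only odds ratios are supported (no risk ratios, risk differences, or
continuous outcomes); baseline risks are fixed effects, not random;
there is no meta-regression, no Knapp–Hartung adjustment, no
Paule–Mandel or Sidik–Jonkman estimator, and no automated subgroup
discovery. The sampler is a random-walk scheme: adequate for this
model's dimensionality, but convergence must be checked — which is
precisely what the built-in diagnostics are for — and extremely sparse
data can defeat it, in which case the package reports NA rather than a
number.
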