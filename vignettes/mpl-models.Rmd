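---
title: "Pattern-searching reinforcement learning models of probability matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-searching reinforcement learning models of probability matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mplearn)
```

## The scientific problem

In a binary probability learning task a participant repeatedly predicts
which of two outcomes will occur; one option (coded 1, the *majority*
option) is correct with fixed probability $p > 0.5$, independently across
trials. The optimal strategy is to always predict the majority option
(*maximising*, expected accuracy $p$), yet people typically *match
probabilities*, predicting each option roughly as often as it occurs
(expected accuracy $p^2 + (1-p)^2$, i.e. 58% at $p = 0.7$). This package
implements a family of reinforcement-learning choice models that make the
candidate causes of this suboptimality measurable: pattern search,
exploration, recency and forgetting.

## The MPL model

The Markov pattern learning (MPL) agent assumes the outcome sequence is a
Markov chain of order $k$ and learns, by reinforcement, the expected
utility $E_j^\eta(t)$ of predicting $j \in \{0, 1\}$ after each history
$\eta$ of the previous $k$ outcomes. Choices follow a softmax (Boltzmann)
rule in the utility difference of the realized history,

$$p_1(t) = \frac{1}{1 + e^{-\theta\,[E_1^\eta(t) - E_0^\eta(t)]}},$$

and after the outcome $x(t)$ is observed, both options are credited
fictively ($u_j = 1$ if $x(t) = j$, else 0) and the whole table decays at
two rates:

$$E_j^\eta(t+1) = \begin{cases}
A\rho\,E_j^\eta(t) + u_j(t) & \text{realized history } \eta,\\
A\,E_j^\eta(t) & \text{otherwise.}
\end{cases}$$

The four parameters and their interpretations:

* $k \in \{0, \dots, 5\}$ — working-memory usage in pattern search. The
  cap of 5 matches estimates of human working-memory capacity; an agent
  with $k = 5$ can still learn much longer patterns (e.g. the length-12
  pattern 001010001100, which is generated by an order-5 Markov chain).
* $A \in [0, 1]$ — forgetting: spontaneous decay of *all* knowledge.
* $\rho \in [0, 1]$ — recency: down-weighting of old reinforcement on the
  history the agent just learned about. With $k = 0$ the two rates are
  confounded and only $A\rho$ is identified; the MPL model with $k = 0$,
  $\rho = 1$ is exactly the PVL decay-reinforcement model.
* $\theta \ge 0$ — exploration–exploitation: $\theta = 0$ is random
  choice, $\theta = \infty$ (an explicit flag, not a large float) is a
  greedy argmax with ties at 0.5.

Two boundary conventions reproduce the published worked example exactly:
before a full history of $k$ outcomes exists, the choice probability uses
the all-zero utilities (hence 0.5) and no reinforcement is applied — only
the global $A$-decay, a no-op on a zero table. The learning win-stay/
lose-shift (WSLS) baseline instead tracks a stay-after-win probability
$p_w(t)$ and a shift-after-loss probability $p_l(t)$, each with its own
learning rate; its first trial is also fixed at 0.5.

```{r table1}
mpl_probs(mpl_agent(k = 1, A = 0.9, rho = 0.9, theta = 0.3),
          gen_repeating("01", 8))$probs
```

## Hierarchical population model

Individual task records carry little information about $(k, A, \rho)$
when $\theta$ is small, so cohort-level inference uses a hierarchical
model: per participant $i$,

$$y_i \sim \mathrm{MPL}(x_i, k_i, A_i, \rho_i, \theta_i), \qquad
k_i \sim \mathrm{Categorical}(q),$$
$$(\mathrm{logit}\,A_i,\ \mathrm{logit}\,\rho_i,\ \log\theta_i) \sim
t_4(\mu, \Sigma = \tau\,\Omega\,\tau),$$

with $\mu \sim N(0, 10^4)$ componentwise ($N(0, 25)$ for the
four-parameter WSLS model), $\tau \sim \mathrm{Half\text{-}Normal}(0,1)$,
$\Omega \sim \mathrm{LKJ}(1)$ and $q \sim
\mathrm{Dirichlet}(0.001, \dots, 0.001)$ (prior mean $P(k) = 1/6$). The
Student-$t$ with $\nu = 4$ gives robustness to outlying participants.

### Sampler

No general-purpose probabilistic-programming sampler in this package's
dependency set can express the replayed MPL likelihood, so the package
ships its own Metropolis-within-Gibbs scheme:

* The discrete $k_i$ is never sampled into the likelihood: each
  participant's likelihood is the log-sum-exp mixture
  $\log \sum_k q_k L_{ik}$ over $k = 0..k_{\max}$, computed from six
  sequential replays in compiled code. Posterior $P(k_i = k)$ falls out of
  the normalized mixture terms at each draw.
* Per-participant transformed parameters use a Haario-style
  adaptive-covariance random walk (proposal covariance tracks
  $2.38^2/d$ times the chain's sample covariance during warmup, with a
  global scale tuned towards ~0.3 acceptance in batches of 50).
* $q$ is refreshed by a conjugate Dirichlet–Gibbs step after sampling a
  latent $k_i$ from each participant's mixture responsibilities.
* $\mu$, $\log\tau$ and the off-diagonals of $\Omega$ use tuned
  scalar random walks (proposals leaving the positive-definite cone are
  rejected; the LKJ(1) prior is flat there).

Individual flat-prior fits (the parameter-recovery analysis: $k$ uniform
on $\{0..5\}$, $A, \rho \sim U[0,1]$, $\theta \sim U[0,5]$) mix a 50%
adaptive random walk with 50% independence proposals drawn from the flat
prior itself. The independence kernel matters: near-deterministic agents
(large $\theta$, $A\rho \approx 1$) produce ridge- and plateau-shaped
posteriors in which a pure random walk stalls. Even so, such fits can
retain split-$\hat R$ above 1.1; the non-convergence policy throughout is
to *flag* the result (`converged = FALSE`) and never to discard or
silently rerun it. Convergence is assessed by split-chain $\hat R \le
1.1$ for every stored parameter.

### Identifiability metrics

`kl_prior_posterior()` reports the Kullback–Leibler divergence from prior
to posterior per parameter, in nats. For $k$ this is the exact categorical
divergence; a posterior that puts 0.75 on one $k$ value scores 0.827 nats
and a point mass scores $\ln 6 \approx 1.79$. For continuous parameters
the estimator is a fixed 50-bin histogram on the prior's support with
add-one smoothing (the source analysis does not state its estimator; this
one is simple, positive, and has bias of roughly $(B-1)/2n$ nats on an
exactly flat posterior, about 0.01 at 3,000 draws). `hdi()` returns the
narrowest interval containing the requested mass, taking the lowest
window among numerical ties.

## Model comparison

`twelve_fold_cv()` scores out-of-sample predictive accuracy: fit the
hierarchical model with one fold of participants held out, then estimate
each held-out participant's sequence probability by averaging
$\prod_t p_{y(t)}(t \mid x, \phi^s)$ over $S$ parameter sets $\phi^s$,
each generated from one posterior hyperparameter draw (a fresh $k$ from
$q$, fresh continuous parameters from the $t_4$ law). The score is
$-2\sum_i \log \Pr(y_i \mid x_i)$, computed with log-sum-exp; lower is
better. WAIC and PSIS-LOO are deliberately out of scope here (they are
unreliable for these models), as are AIC/BIC.

## Behavioural statistics

* `mean_response()` — frequency of majority-option choice, per trial and
  per participant.
* `cross_correlation()` — windowed mean of $[2x(t-1)-1][2y(t)-1]$;
  $(c+1)/2$ is exactly the fraction of predictions equal to the previous
  outcome, so $c = 1$ identifies strict win-stay/lose-shift.
* `recency_group()` / `fit_recency_model()` — the nonmonotonic recency
  analysis: trials grouped by lag since the most recent minority outcome
  (lags pooled at "6+"; trials before the first observed 0 are excluded,
  as their lag is undefined), with a beta-binomial hierarchy per lag
  ($s_i^n \sim \mathrm{Bin}(c_i^n, \pi_i^n)$, $\pi_i^n \sim
  \mathrm{Beta}(a_n, b_n)$, Half-Cauchy(0, 100) priors) whose
  participant-level probabilities are marginalized analytically.
* `counterfactual_experiment()` — population simulations with one
  behaviour switched off (`k := 0`, `rho := 1`, or `theta := Inf`). The
  override replaces only the drawn parameter; the joint draw of the
  others is untouched. Forgetting $A$ is never overridden except in the
  `"optimal"` scenario, because forgetting is not under strategic
  control.

A modelling subtlety surfaced by simulation: for greedy agents with
$k = 3$ the nonmonotonic recency signature under the most-recent-0
grouping is a *stall below the neighbour trend* at lag $k+1$, not an
absolute decrease (with 3,000 simulated agents the lag-1..5 response
rates in the first 100 trials are approximately 0.75, 0.78, 0.81, 0.81,
0.92). Tests therefore assert that the lag-4 rate falls below the linear
interpolation of lags 3 and 5.

## Synthetic data as study conditions

The generators encode the study design: 300-trial Bernoulli(0.7) outcome
sequences; recovery agents with flat-prior parameters; cohorts drawn from
the hierarchical law. `example_population()` fixes a plausible population
for this task, centred on published cohort-level estimates (medians
$A = 0.99$, $\rho = 0.96$, $\theta = 0.23$; $q \approx (0.15, 0.39,
0.45)$ over $k = 0, 1, 2$) with scales chosen so that about half the
simulated participants have $\theta \in [0.15, 0.37]$ and correlations
reflecting the reported negative association of $\theta$ with $A$ and
$\rho$. Simulating this population reproduces the published predictions
well: last-100-trial mean response near 0.76, cross-correlation near
0.28, and counterfactual means near 0.82 (no pattern search), 0.89 (no
recency) and 0.94–0.97 (no exploration).

What the synthetic data do *not* emulate: expectation matching (the
early-task cognitive bias that produces the observed dip three-to-four
trials after a minority outcome in real first-100-trial data), reaction
times, block structure and motivational effects. Passing tests therefore
show that the algorithms are faithful to the models, not that the models
capture every feature of human data.

## Problem sizes and numerical choices

Examples and tests run at desk scale by design: hierarchical fits use one
or two chains of a few thousand iterations (production-quality posteriors
for a real cohort warrant one to two orders of magnitude more, e.g. two
chains of 70,000 draws for posterior-predictive work); the recovery
analysis uses 200 agents with two chains of 1,250 iterations each rather
than 10,000 agents with four chains of 3,500; cross-validation of a
24-participant cohort uses four folds with $S = 200$ rather than twelve
folds with $S = 1000$. Expected utilities are bounded by $1/(1 - A\rho)$
when $A\rho < 1$, and softmax log-probabilities are computed in
log1p-exp-safe form, so no further overflow handling is needed. All
randomness flows through R's RNG (a single seed reproduces any dataset or
fit bit-for-bit; MCMC results are reproducible distributionally across
seeds).

## Known limitations

* The hierarchical sampler is a random-walk scheme: it needs long chains
  for tight hyperparameter posteriors, and correlation-matrix and scale
  parameters mix slowest. The `converged` flag and per-parameter
  split-$\hat R$ should always be checked.
* With $k = 0$ only the product $A\rho$ is identified; with $\theta$
  near zero nothing about $k$, $A$ or $\rho$ is identified from a single
  record — by design the recovery analysis quantifies exactly this.
* The cohort CV assumes exchangeable participants and uses fold-specific
  hyperparameter draws for held-out prediction.
* One shared $(A, \rho, \theta)$ triple is fitted per participant across
  the mixture components of $k$ (the mixture is over $k$ only), matching
  the individual-level mixture formulation.
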