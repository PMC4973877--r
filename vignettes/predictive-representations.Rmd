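---
title: "Predictive representations of oddball sequences: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive representations of oddball sequences: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predrep)
```

predrep asks a simple question about sensory neurons: when a neuron's
spike count fluctuates from trial to trial in an oddball experiment, how
much of that fluctuation tracks the *surprise* of each stimulus, and what
does the answer reveal about the memory the neuron's circuit keeps about the
recent stimulus sequence?  This vignette lays out the statistical model, the
optimisation problem, the numerical choices, and the limits of what the
package's synthetic validation can show.

## The oddball world

An oddball block is a sequence of two pure tones (`low`, `high`) delivered
at a fixed rate.  Within a block the high tone occurs with a fixed
probability $p$, tones are drawn independently, and different blocks use
different $p$ (10%, 30%, 50%, 70%, 90%).  The subject does not know $p$.
We model this with a Bernoulli world under a uniform prior on $p$: the joint
distribution of the last $N$ tones (*past*) and the next tone (*future*) is
obtained by integrating $p$ out.  Because tones are exchangeable given $p$,
the number $k$ of high tones among the last $N$ is a minimal sufficient
statistic, and the model collapses to closed form:

$$P_N(k, \mathrm{high}) = \frac{k+1}{(N+1)(N+2)}, \qquad
  P_N(k, \mathrm{low}) = \frac{N-k+1}{(N+1)(N+2)},$$

so the marginal over $k$ is uniform, and the predictive probability of the
high tone is the rule of succession $(k+1)/(N+2)$ — never 0 or 1, so the
surprise of any outcome is finite.  `oddball_world()` exposes the memory
length $N$ and (as a hook) general Beta priors; the uniform prior is the
reference analysis throughout, and changing it alters exact values but not
the qualitative structure.

```{r closed-form}
iq <- info_quantities(joint_suffstat(oddball_world(10)))
unlist(iq)
```

## Reduced representations and the Information Bottleneck

A *reduced representation* is a (possibly stochastic) summary $m$ of the
past, given by an encoder $P(m\mid k)$, with predictions carried by a
decoder $P(\mathrm{future}\mid m)$.  Two information quantities grade any
such summary, both in bits: its **complexity** $I(k;m)$ (how much detail
about the past it keeps; at most $\log_2(N+1)$) and its **predictive
power** $I(m;\mathrm{future})$ (at most $I(k;\mathrm{future})$, by data
processing).  The optimal frontier — maximal power at each complexity — is
the Information Bottleneck (IB) problem, solved by minimising
$I(k;m) - \beta\, I(m;\mathrm{future})$ over encoders, where $\beta \ge 0$
sweeps the tradeoff.  Fixed points satisfy three self-consistent equations
(exponentiated-KL encoder update, marginal update, Bayes decoder update),
which `ib_fixed_point()` iterates to a per-row total-variation residual
below $10^{-10}$ (default; non-convergence is flagged on the result, never
silently accepted).

The solver runs on the sufficient-statistic alphabet $k \in \{0..N\}$, not
on the $2^N$ sequences: any encoder over full pasts that depends on the past
only through $k$ has the same information coordinates, and optimal solutions
factor through the sufficient statistic.  This is what makes $N = 50$
tractable.  The full-sequence joint exists (`sequence_joint()`, $N \le 20$)
as an oracle for entropies of the full past and marginalisation checks.
The number of representation states defaults to $N + 1$; more states cannot
improve the frontier.

### Numerical strategy of the beta sweep

`sweep_beta()` traces one tradeoff curve with deterministic annealing:
$\beta$ ascends a geometric grid (factor 1.25 from 0.8), each solution
warm-starts the next after a small fixed sinusoidal perturbation that lets
clusters split.  Three facts of this problem shaped the implementation:

* **Critical slowing.**  Near a cluster-split transition the fixed-point
  map's contraction rate approaches 1.  The C++ core therefore wraps the
  plain iteration in SQUAREM-style extrapolation (two map evaluations give
  a step length; the extrapolated point is projected back onto the row
  simplices; a safeguarded map evaluation keeps every accepted iterate a
  genuine map image), which cuts the iteration count by roughly an order of
  magnitude while preserving determinism.
* **Hysteresis.**  A warm-started iterate can stick to a branch with merged
  states well past that branch's critical $\beta$.  Every $\beta$ is
  therefore additionally solved from a fresh near-uniform init (where the
  first transitions live) and from the identity encoder (where the top of
  the curve lives), and the fixed point with the lowest Lagrangian wins.
* **First-order gaps.**  At some transitions no single fixed point exists at
  intermediate complexity: as $\beta$ crosses the critical value the
  solution jumps (about 0.18 bits at $N = 10$).  The frontier is still
  attained there, by time-sharing: concatenating the state spaces of the
  two bracketing solutions with weights $(1-t, t)$ yields a valid encoder
  whose complexity and power interpolate *exactly* linearly, staying on the
  concave envelope.  Residual gaps are filled with such mixtures, so every
  curve spans $[0, \log_2(N+1)]$ with no gap above 0.1 bits.

Exploration solves use a capped iteration budget ($10^4$); the
representations finally selected (those nearest a uniform grid of 200
complexity targets) are re-polished at a larger budget ($2 \times 10^4$).
A handful of near-critical points remain flagged unconverged at residuals
around $10^{-6}$, which perturbs their information coordinates by far less
than the curve resolution.  The whole sweep uses no random numbers, so
banks are reproducible bit-for-bit.

```{r curve, eval = FALSE}
cv4 <- sweep_beta(joint_suffstat(oddball_world(4)))
power_at_complexity(cv4, 1.0)                       # ~0.134 bits
effective_states(curve_at_complexity(cv4, 1.0))     # 3
```

`effective_states()` counts states after merging numerical duplicates.  Two
states are duplicates only when both their decoders *and* their input
posteriors $P(k\mid m)$ agree to within $10^{-6}$ total variation: decoder
agreement alone is not enough, since distinct pasts can make identical
predictions (the full-past representation at $N=4$ has 16 states although
sequences sharing a count share a decoder).

`build_bank()` assembles the default analysis grid: $N = 1..50$, 200
representations per curve, 10,000 in total.

## Prediction errors

Given a representation and an observed tone, the prediction error in state
$m$ is the surprise $-\log_2 P(\mathrm{tone}\mid m)$.  Because the state is
latent, each trial carries a *set* of errors with weights $P(m\mid k)$;
`trace_sequence()` walks a tone sequence and emits those weights and errors
for every retained trial, plus the expected error
$E = -\sum_m P(m\mid k)\log_2 P(\mathrm{tone}\mid m)$.  Averaged over the
stationary joint of $(k, \mathrm{tone})$, the expected error equals
$H(\mathrm{future}) - I(m;\mathrm{future})$ — an identity the test suite
verifies to $10^{-9}$ for every bank member with $N \le 10$ — so maximising
predictive power and minimising expected surprise are the same thing.

Two conventions follow the experimental design: blocks are independent
recordings, so pasts never cross block boundaries; and the first 50 trials
of every block are discarded (burn-in) so that each analysed trial has a
fully defined past for every $N \le 50$.  A 400-trial block therefore
contributes 350 trials, and the three-block main design 1050.

## Fitting spike counts

For one neuron and one test frequency, the trials whose tone equals that
frequency enter a linear regression of spike count on prediction error.
The latent state makes the predictor a weighted set: each trial is expanded
into its (error, count) pairs weighted by $P(m \mid k)$, and weighted least
squares is applied to the expansion (`weighted_regression()`), with the
weighted $r^2$ as goodness of fit.  With a deterministic representation
this reduces exactly to ordinary least squares on expected errors — a
reduction the tests check against `lm()`.

`grid_search()` repeats this for all 10,000 bank members and records the
$r^2$ surface, its maximum $r^2_{\max}$, the argmax (ties broken toward the
smallest $N$, then the smallest complexity — the most parsimonious
representation), and the *good set* of representations reaching at least
90% of $r^2_{\max}$.  Internally the regression for a whole curve is
computed from per-$k$ sufficient statistics (counts, response sums and
squares per past-count value), making one grid pass essentially
instantaneous; the expanded-set equivalence is covered by tests.

Because $r^2_{\max}$ is a maximum over thousands of correlated fits, its
significance is assessed by permutation (`permutation_test()`): the tone
sequence is randomly permuted *within each block* (preserving each block's
tone probabilities; responses stay attached to their trial slots), the full
grid search is recomputed, and the effect is significant when the observed
$r^2_{\max}$ strictly exceeds all 20 permuted values (nominal
$p < 1/21 \approx 0.048$).  The test suite calibrates this on 200 null
synthetic neurons and requires a false-positive rate at or below 10%.
Whether responses exceed the spontaneous rate at all is judged by a
one-sided Wilcoxon rank-sum test at $\alpha = 0.05$
(`response_significance()`); the choice of a rank-based test is this
package's, made for robustness to non-Gaussian counts.

`population_maps()` aggregates good sets across cases passing an
$r^2_{\max} \ge 0.1$ filter: for each representation, the fraction of cases
whose good set contains it, reported on the native (duration x complexity
index) grid and projected onto binned complexity/power planes.  A projected
cell keeps the *maximum* fraction over the representations it contains, so
a cell reads "good for most cases" whenever some representation at those
coordinates is; the 50% contour is available via `map_contour()`.

## Variance partition and SSA

A small fraction of explained variance can reflect large trial-to-trial
noise rather than model failure.  `noise_variance()` estimates the noise as
the group-size-weighted average of spike-count variances conditioned on the
exact preceding 7 tones *and* the block (at most $2^7 = 128$ contexts per
block); conditioning on the block partially accounts for the more remote
past.  Both an unbiased ($n-1$) and a conservative biased ($n$) estimate
are produced; singleton groups contribute zero to the biased estimate and
are excluded from the unbiased one.  `explainable_fraction()` divides the
predictor variance by total variance minus noise: the unbiased correction
can over-correct (fractions below 0 or above 1 are reported as-is and
flagged), while the conservative correction under-corrects and stays in
$[0,1]$ on well-sampled data.

`ssa_index()` computes the standard per-frequency adaptation contrast
$SI(f) = (d(f) - s(f)) / (d(f) + s(f))$, where $d(f)$ and $s(f)$ are the
mean responses to $f$ when rare (10% block) and common (90% block).  This
formula is the field's convention rather than something the analysis above
fixes; it is computed per frequency, not frequency-averaged.

## The synthetic-data generator

No recordings ship with the package, so every pipeline stage is validated
on synthetic experiments with known ground truth (`experiment_suite()`).
The generator mirrors the experimental design, not the analytic model:
blocks of 400 tones with *fixed counts* per condition (e.g. exactly 40 high
tones at 10%) in random order, while the analysis assumes i.i.d. draws —
this model/experiment mismatch is deliberate and preserved.  Spike counts
follow the affine surprise-coding model $Y = aX + b + \varepsilon$: on each
trial a latent state is *sampled* from $P(m\mid k)$ (not averaged), the
error of that state sets the mean, and Poisson or rounded-Gaussian noise is
added (negative Gaussian draws clip at zero; the clip rate is recorded).
Sampling the latent state makes the generated data genuinely probabilistic
in the state, exercising the analysis-side weighting for real.  Defaults —
$a = 2$ spikes/bit, $b = 3$ spikes, $\sigma = 1$, generating member
$N^* = 10$ at 2 bits — put the signal in the range where recovery is
expected but not trivial.

What passing tests show, and what they do not: the suite demonstrates that
the pipeline recovers generating parameters, calibrates its permutation
test, and keeps conservative explainable fractions in $[0,1]$ *under the
affine generative model with stationary noise*.  Real cortical responses
add slow drifts, bursting, adaptation with its own kinetics, and
non-Poisson dispersion, none of which the generator emulates; population
percentages obtained on synthetic data are therefore qualitative analogues,
not predictions of recording statistics.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds through self-contained RNG
streams, so no package function disturbs the caller's RNG state, and
`run_pipeline()` reruns byte-identically under a fixed configuration.  The
test suite exercises banks of $N \le 20$ with 50 curve points (recovery and
identity properties) and $N \le 8$ with 15 points (the 200-run permutation
calibration); the two reference curves ($N = 4$, $N = 10$; 200 points) are
built in full.  These sizes were chosen so the complete suite runs in a few
minutes while still covering every code path at the default analysis
design.

## Known limitations

* The response model is linear; saturating (sigmoid, threshold-linear)
  relationships between surprise and rate are out of scope.
* The analytic world is i.i.d. given $p$; Markov or otherwise structured
  sequence statistics require a different joint table (the IB machinery
  itself would carry over).
* The noise-variance estimator conditions on a 7-tone context as a proxy
  for the unobservable full history; with few trials per context the
  unbiased variant is statistically unstable, which is why the conservative
  variant is reported alongside it.
* Curve points at first-order transitions are time-sharing mixtures; they
  are exactly on the information frontier but have up to $2(N+1)$ states
  before duplicate merging.
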