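---
title: "Closed-loop Bayesian optimization over combinatorial protein libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop Bayesian optimization over combinatorial protein libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqbo)
```

## The problem

Protein engineering campaigns search a sequence–function landscape: a
mapping from genotype to a measurable phenotype (here, the thermal
tolerance T50 of glycoside hydrolase enzymes — the incubation temperature
at which half of the activity is irreversibly lost in ten minutes). Two
features make this search hard. First, combinatorial DNA assembly gives
access to thousands of sequences from a few dozen gene fragments, far more
than can be tested. Second, a large fraction of recombined sequences are
inactive "holes" — destabilized proteins with no measurable activity —
which yield no quantitative signal at all.

`seqbo` implements an autonomous design–test–learn agent for this setting:
a multi-output Gaussian-process surrogate over the candidate space,
upper-confidence-bound (UCB) acquisition rules that account for the holes,
an exception-handling state machine for noisy laboratory outcomes, and a
simulation harness (synthetic landscape oracle plus benchmark trials) so
the entire closed loop can be exercised and validated without a robot.

## The candidate space: assembly graphs

A Golden Gate library is a set of DNA fragments, each assigned to a
segment position and flanked by 4-bp overhangs. Fragment `u` can precede
fragment `v` exactly when `u`'s right overhang equals `v`'s left overhang
(top strand, 5'→3'; fragments are assumed pre-oriented, so no
reverse-complement matching is attempted). The library is therefore a
layered DAG in which every Start→Stop path is one assemblable gene.
`count_paths()` counts paths by dynamic programming in segment order, and
`enumerate_designs()` materializes them with translated proteins.

```{r space}
frags <- synthetic_fragment_library()
graph <- assembly_graph(frags)
graph
```

The packaged `synthetic_fragment_library()` is a deterministic, fully
synthetic stand-in for a real four-segment GH1 recombination library. It
is engineered to the headline statistics of the library it emulates — 34
fragments in segments of 8/4/9/13, exactly 1,352 Start→Stop paths (the
second junction is only partially compatible and two fragments are dead
ends), a mean pairwise distance of about 116 substitutions with a minimum
of 16 (one engineered near-duplicate fragment pair), and at most a handful
of residues per variable site. Residue identities are random: the library
reproduces the *combinatorial geometry* of such a space, not GH1
biochemistry, so results on it validate the search machinery rather than
any biological claim.

Designs are encoded for the model by one-hot indicators over variable
alignment columns. This realizes Hamming similarity as a dot product:
`x_i · x_j = V − Hamming(i, j)` with `V` the number of variable columns,
which is what makes the linear kernel below a "Hamming kernel".

## The surrogate: a multi-output GP

Two Gaussian processes share the encoding:

* a **classifier** (logistic link, Laplace approximation) trained on all
  consolidated observations, giving `p_active`;
* a **regressor** trained on the active observations' T50 values, giving a
  posterior mean `mu` and predictive standard deviation `sigma`.

Both use the linear kernel `k(x, x′) = σ₀² + x·x′` (default `σ₀ = 1`); the
regressor adds a white-noise term (default variance 1). `sigma` by default
includes the noise term, so `mu ± 1.96 σ` is a 95% *prediction* interval
(a flag restores the latent-function width instead). Hyperparameters can
be re-estimated by maximizing the log marginal likelihood (a single
deterministic L-BFGS-B start from the configured values); the classifier's
kernel stays fixed, since activity labels carry far less information per
observation.

Two modelling choices deserve emphasis:

* **Zero prior mean on the raw °C scale.** The regressor is *not*
  centered. A sequence dissimilar from every observation reverts to
  `mu ≈ 0`, i.e. dissimilarity is presumed deleterious. This pessimism is
  load-bearing: it is what lets the acquisition rules exploit near known
  good sequences instead of wandering, and it is why the expected-UCB
  score re-bases predictions on the pool minimum (see below).
* **Single-class data still fit the classifier.** The Laplace
  approximation is perfectly well defined when only one class has been
  observed; the latent dips toward the observed class near the data and
  reverts to the prior (`p = 0.5`) far away. This matters in the first
  rounds of a campaign: after a run of inactive observations the agent is
  steered *away* from the dead region, whereas a constant-probability
  fallback would make every candidate score identically and reduce the
  agent to scanning designs in index order.

Duplicate measurements of a design are consolidated by averaging T50 and
letting the *latest* record decide the status — an erroneous early call is
outweighed by later data rather than edited away.

## Acquisition rules

Four rules are implemented over the untested pool:

* `random` — uniform draw (the baseline);
* `ucb` — argmax of `mu + z·sigma` (default `z = 1.96`); carries no
  classifier and learns nothing from an inactive observation;
* `ucb_positive` — best UCB among candidates with `p_active > 0.5`; when
  no candidate qualifies it falls back to the largest `p_active`, which
  gathers the activity information the gate is starving on;
* `expected_ucb` — `((mu − min_pool mu) + z·sigma) · p_active`: the
  baseline shift makes the bracket non-negative over the pool, so the
  product is a probability-weighted optimistic gain. A predicted-dead
  candidate scores 0 regardless of its regression posterior.

Ties break to the lowest design index, making selection fully
deterministic given the model.

**Batches** are chosen by fantasy updates: after each pick the regressor is
conditioned on a hypothetical observation equal to the pick's current
posterior mean. The posterior mean field is unchanged but `sigma` deflates
around the pick, pushing later picks elsewhere. Fantasies touch only the
regressor (a fantasy defines a regression target, not an activity label),
the expected-UCB pool minimum is recomputed as the pool shrinks, and all
fantasies are discarded once the batch is assembled.

## The closed loop

`run_campaign()` measures the seed designs (round 0) and then iterates:
fit surrogate → select batch among non-finalized designs → submit to the
executor → update records → log. The executor is either the synthetic
oracle (in-process) or a file-exchange executor that writes request CSVs
and polls for results, so a real laboratory can be attached unchanged.

Laboratory outcomes pass through a small state machine. An `active` result
finalizes the design with its T50. A QC failure (`failed_qc`) re-queues
the design and never counts toward an inactive call. A `no_activity`
result re-queues the design the first time — a lone negative may be an
assembly or expression failure — and only a second `no_activity` finalizes
it as inactive and creates a classifier label (the "test twice" rule).
Erroneous executor data (say, a T50 reported for a dead design) are
ingested as-is; consolidation lets subsequent data outweigh them.

Per-campaign randomness derives from one master seed through deterministic
per-round child seeds, so a campaign replays identically.

## The synthetic oracle

`generate_landscape()` plays the ground truth. Latent stability is
`base_t50` plus one additive effect per chosen fragment plus ten sparse
pairwise fragment-interaction effects, all drawn once per seed; a design
is active iff its latent stability clears the threshold that puts the
inactive fraction at its target (the destabilization reading of landscape
holes — the same latent variable controls activity and T50; an
independent-Bernoulli hole model is available behind a flag).
`measure()` adds Gaussian noise to active designs' T50, returns
`no_activity` for holes, and fails outright with a fixed probability.

Defaults, fixed once as the package's study conditions:

| parameter | default | why |
|---|---|---|
| inactive fraction | 0.64 | composition of the published 518-sequence P450 benchmark (331 inactive) |
| additive effect scale | 4 °C | puts ~2% of designs within 90% of the landscape maximum, a selectivity comparable to the published benchmark's engineering goal |
| epistasis | 10 pairs, 2 °C | half the additive scale: enough ruggedness to separate acquisition rules without burying the additive signal |
| base T50 | 50 °C | typical mesophilic GH1 midpoint |
| measurement noise | 0.8 °C | keeps replicate disagreement under the 1.6 °C reproducibility observed on automated platforms |
| failure probability | 0.09 | the ~9% liquid-handling failure rate of such platforms |

`simulate_assay_plate()` additionally emits raw plate data (per-well
progress curves along a temperature gradient plus fluorescein internal
standards) so the assay-reduction code path — progress-curve slopes, the
20% fluorescein mask, the shifted-sigmoid fit — can be tested end to end:
noiseless plates round-trip the true T50 to well under 0.1 °C.

## Assay reduction

Rates are least-squares slopes of fluorescence versus time. Wells whose
fluorescein internal standard falls strictly below 20% of the run mean are
masked as pipetting failures. The thermal profile is fit with the shifted
sigmoid `rate(T) = b + A / (1 + exp((T − t50)/s))`, initialized at the
half-maximum temperature with `s` a tenth of the assayed range; fits whose
amplitude is indistinguishable from residual noise, or whose midpoint
leaves the assayed range, are flagged `no_sigmoid` (upstream this maps to
a QC failure), and profiles that never clear twice the extract background
are `below_background` (the fold factor is configurable; 2 is our
default). Michaelis–Menten kinetics are fit by nonlinear least squares on
replicate-averaged initial rates; exactly-proportional (sub-saturation)
data leave `kcat` and `Km` unidentifiable separately, in which case the
reported `Km` is pinned far above the assayed range and flagged
unreliable. The qualitative "progress curves look as expected" check is
realized as the amplitude-versus-residual test above — our construction,
as the underlying criterion is not quantitative.

## The benchmark harness

`simulate_trials()` replays the in-silico protocol used to compare
acquisition rules: the first pick is random, subsequent picks follow the
rule, the ground truth answers noise-free, and a trial ends on reaching
90% of the landscape maximum. Every measured design counts as one
evaluation, inactive picks included (an attempt-count view is also logged
by campaigns). Trials use fixed kernel hyperparameters — the configured
`σ₀ = 1`, noise 1 operating point — because tens of thousands of refits
must stay cheap, and per-trial child seeds make results order-independent.
The suite and the acceptance script run 500 trials per method; this is a
deliberate desk-scale choice (the published protocol used 10,000), and
any number is available via `n_trials`.

At these conditions the activity-aware rules need about 14–16 evaluations
on average, at least twofold fewer than random search and about threefold
fewer than plain UCB — reproducing the published finding that classifier
guidance, not UCB itself, is what copes with hole-rich landscapes. One
directional caveat is worth stating plainly: on this synthetic landscape
plain UCB is *worse* than random search (≈46 vs ≈36 mean evaluations),
because UCB pays full exploration cost inside hole-rich regions it never
learns from, while random search benefits from the landscape's ~2.6%
qualifying fraction. Which of the two baselines loses more is
dataset-specific; the robust, reproducible ordering is
`expected_ucb ≈ ucb_positive ≪ {ucb, random}`.

Analytics mirror the published agent-behaviour analyses: Pearson
correlation between two models' predicted landscapes
(`landscape_correlation()`), a sliding-window (default 10 °C) profile of
model uncertainty across the T50 axis (`uncertainty_profile()`),
percentile ranks of each round's chosen designs for the four decision
factors (`choice_percentiles()`, convention: fraction strictly below with
midranks for ties), and classical MDS of the Hamming distance matrix for
trajectory maps (`mds_embed()`).

## What the simulations do and do not show

The oracle emulates the *statistical* structure of a combinatorial
thermostability landscape — additive fragment effects, sparse epistasis,
stability-coupled holes, realistic noise and failure rates — but not
protein physics: no structure, no catalysis, no expression artifacts
beyond the failure model. Passing benchmarks therefore demonstrates that
the agent machinery (modelling, acquisition, exception handling) works as
specified under conditions resembling a real campaign; transfer to any
particular real landscape depends on that landscape being broadly additive
with stability-coupled holes, which is an empirical matter. Reproduction
of the published wet-lab numbers (absolute stabilization gains, specific
T50 values) is out of scope by construction; a documented script
(`inst/scripts/reproduce-p450.R`) reproduces the published cross-validated
accuracy and sample-efficiency figures for users who obtain the deposited
P450 dataset.

## Numerical notes and open choices

* Cholesky-based GP algebra with a 1e-8 jitter; zero-noise fits are
  supported through the jitter alone.
* Classifier inference: Newton iteration to the latent mode (tolerance
  1e-8 on the penalized log-likelihood), predictive probabilities via the
  standard logistic–probit moment-matching approximation.
* A design-by-design Gram matrix can be precomputed once
  (`tcrossprod(encode_space(space))`); every fit and prediction then
  reduces to kernel lookups, which is what keeps 500-trial benchmarks in
  minutes on one core.
* Whether the published agent optimized hyperparameters per round, and
  whether its interval included the noise term, are not stated in our
  sources; both are exposed as flags
  (`optimize_hyperparameters`, `include_noise_in_sigma`), with defaults
  chosen as the more standard practice (optimize; include).
* Whether the 1,352 figure counts DNA paths or distinct proteins is
  ambiguous; we count paths and flag (with a warning) any protein-level
  duplicates.
* Batch fantasies could in principle also update the classifier; we leave
  the classifier fixed within a batch, as a fantasy only defines a
  regression target.

## A worked example

```{r loop}
space <- enumerate_designs(graph)
oracle <- generate_landscape(space, oracle_params())
cam <- run_campaign(space, oracle_executor(oracle),
                    cfg = acq_cfg("expected_ucb", batch_size = 3),
                    rounds = 20, seed = 7)
cam
```

```{r plot, fig.width = 6, fig.height = 4}
plot(cam)
```
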