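---
title: "Opinion amplification dynamics: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opinion amplification dynamics: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soam)
```

## The model

`soam` simulates a population of `n` agents holding continuous opinions on a
single topic, connected by a *directed* social network: an edge `a -> b`
means `b` follows `a`, so `a`'s published opinion can influence `b` but not
the other way around. Opinions start i.i.d. uniform on `[-1, 1]` (−1 a very
negative stance, +1 a very positive one) and are unbounded afterwards.

The update is the classic bounded-confidence averaging rule, with one twist:
agents influence each other through *expressed* opinions, which for some
agents are amplified versions of what they actually believe. A fixed
proportion `pi` of the population carries the amplifier trait; each timestep
an amplifier amplifies with probability `p`, in which case it publishes its
opinion pushed away from zero by an amount `sigma ~ Uniform(0, s)`:

```
SO_i = O_i - sigma_i   if amplifying and O_i <  0
       O_i + sigma_i   if amplifying and O_i >= 0
       O_i             otherwise
```

Every agent then moves, synchronously, to the mean of its own previous
opinion and the expressed opinions of the in-neighbors within its confidence
threshold `epsilon` (boundary inclusive):

```
O_i(t) = ( O_i(t-1) + sum_{j in I_i} SO_j ) / ( 1 + |I_i| )
I_i    = { j in in_neighbors(i) : |O_i(t-1) - SO_j| <= epsilon }
```

Amplification models sensationalism, hype, clickbait and similar
attention-seeking distortions. Its central consequence, which the experiment
grid reproduces, is *extreme polarization*: unlike plain bounded-confidence
dynamics — whose updates are convex combinations and therefore can never
leave the initial opinion hull — amplified expressed opinions drag the
population to values far outside `[-1, 1]`.

A subtlety worth stating: the expressed-opinion vector used for a timestep
is computed once, from the `t-1` opinions, and used both for the confidence
gate and for the average. Agents whose influence set is empty (no
in-neighbors, or all gated out) keep their opinion unchanged — the update
degenerates to `O_i / 1`.

## Parameters

| Parameter | Meaning | Range | Grid default |
|---|---|---|---|
| `n` | population size | >= 2 | 100 |
| `k` | mean links per node | `[0, n-1]` | 5 |
| `epsilon` | confidence threshold (opinion units) | `[0, 1]` | 0.2 / 0.5 / 0.8 |
| `pi` | amplifier proportion | `[0, 1]` | 0 / 0.2 / 0.5 / 0.8 |
| `p` | amplification probability per timestep | `[0, 1]` | 0.2 / 0.5 / 0.8 |
| `s` | amplification strength (opinion units) | `[0, 1]` | 0.2 / 0.5 / 0.8 |
| `t_max` | timesteps | >= 0 | 400 |

The reference experiment grid (`figure_presets()`) runs every condition at
`n = 100`, `k = 5`, `t_max = 400` on a directed Erdős–Rényi network; one run
at that scale takes well under a second, and the replicate sets used
throughout (20 seeds per condition; 100 seeds for the initial-conflict
check) take a few seconds each.

## Networks

`generate_network()` implements four generators:

* **`erdos_renyi`** — each ordered pair of distinct nodes carries an edge
  independently with probability `k/(n-1)`. "Links per node" is interpreted
  as the mean out-degree, which under this construction equals the mean
  in-degree. This is the default and the one the experiment grid uses.
* **`barabasi_albert`** and **`scale_free`** — grown or static power-law
  graphs are undirected objects, so they are built undirected (attachment
  count `m = round(k/2)`; static model with exponent 2.5) and every link is
  replaced by both directed edges. Used for robustness checks only; no
  directed construction is prescribed for them.
* **`complete`** — all ordered pairs; with `pi = 0` the model on a complete
  network reduces exactly to the classic bounded-confidence update (a tested
  invariant).

The network is static over a run, and the whole generated graph is used,
including disconnected fragments. One structural consequence matters for
interpretation: a directed Erdős–Rényi node has in-degree 0 with probability
`(1 - k/(n-1))^(n-1)` (about `e^-k`), and such "leader" agents never update.
At `k = 5` roughly half of all runs contain at least one; when a leader's
opinion is farther than `epsilon` from the emergent consensus, a residual
conflict of order 0.1 persists forever. Seed-averaged end-of-run conflict in
the no-amplification, high-threshold condition is therefore a few hundredths
rather than exactly zero, even though the median run does reach zero — a
property of the directed-network dialect itself, visible in the acceptance
suite.

## Conflict and the other metrics

Population *conflict* at a timestep is the standard deviation of the actual
(not expressed) opinions, with denominator `n` rather than `n - 1` so that
the uniform initialization has expected conflict exactly `1/sqrt(3) ≈
0.577`. Actual opinions are the right substrate: expressed opinions are
strategic noise, while behavior follows true beliefs. `opinion_range()`,
`extremity_fraction()` (share of agents beyond a bound; bound 1 = outside
the initial range) and `count_clusters()` (sorted-gap splitting, default gap
0.1 — a descriptive choice, no canonical value exists) complete the summary.

## Interventions

**Five-strike rule** (`intervention_config(max_amplify = 5)`): each agent
may amplify at most five times in its lifetime. The attempted sixth
amplification is suppressed — that timestep the agent expresses its actual
opinion — and the agent is replaced at the end of the timestep: same node
and edges, fresh uniform opinion on `[-1, 1]`, amplifier trait redrawn with
probability `pi`, strikes reset. Replacement redraws the trait from the
population default rather than inheriting it; the alternative (inherit the
flag) was considered and rejected because a replacement is a *new* user, not
the same user reformed. Population size is constant throughout.

**Balanced dissemination** (`intervention_config(dissemination = TRUE)`):
every other timestep (first injection at `t = 2`), five external opinions
drawn uniformly on `[-1, 1]` are shown to every agent. They pass through the
same confidence gate as neighbor opinions and count in the averaging
denominator — the arithmetic is not otherwise specified anywhere, and
treating institutional messages exactly like ordinary neighbors is the
least-assumption choice. Injection starts at `t = period` so the initial
conflict is untouched.

Both substantially curb extreme polarization at the strong-amplification
settings. A structural caveat the simulations expose: at `epsilon = 0.2` an
agent that has drifted beyond about `|O| = 1.2` is outside the confidence
threshold of *every* message in `[-1, 1]`, so dissemination at the default
rate can prevent early drift but cannot reverse it; a substantial minority
of low-threshold runs still end with opinions beyond 2. Denser messaging
(higher `message_count`, `period = 1`) closes the gap.

## Randomness and reproducibility

A run consumes randomness for four purposes — network construction,
population initialization, per-timestep amplification draws, and
interventions — and each purpose gets an independent named RNG substream
derived from the single master seed. Two consequences are load-bearing and
tested: runs are bit-identical for a fixed seed, and enabling an
intervention does not perturb the base dynamics' draws (a paired
base-vs-intervention comparison at the same seed starts from the identical
population and amplification schedule). Per-timestep draws consume a fixed
amount of the stream regardless of the realized amplification pattern (the
`sigma` vector is drawn full-length and zeroed), so trajectories diverge
only where the model says they should.

Exact-count amplifier assignment (`round(pi * n)` agents, sampled without
replacement) was chosen over per-agent Bernoulli flags: at `n = 100` it
removes a binomial variance term from every cross-condition comparison.

## What the generator does and does not emulate

All inputs are synthetic by design: uniform initial opinions and random
directed graphs are the study conditions themselves, not stand-ins for a
dataset. What passing tests show is that the *mechanism* — amplified
expression under bounded confidence — produces extreme polarization,
conflict growth ordered by `epsilon`, `pi`, `p`, and an interior optimum in
`s` (weak amplification polarizes most, because strongly amplified opinions
fall outside everyone's confidence threshold and lose influence). What they
do not show: real opinion distributions are not uniform, real follower
graphs are not Erdős–Rényi (degree heterogeneity changes how much
dissemination is needed), opinions are not one-dimensional, and `epsilon`,
`pi`, `p`, `s` are not directly measurable for a real platform.

## Numerical choices and degenerate inputs

* Confidence gate boundary inclusive (`<=`), including `epsilon = 0`
  (only exact matches influence).
* Zero actual opinion amplifies in the positive direction (`O >= 0` branch).
* Opinions are never clipped; the dynamics are exact convex/affine averages,
  so no tolerance parameters exist anywhere in the engine.
* `t_max = 0` returns the initial state only; empty opinion vectors are an
  error for every metric.
* Replicate seeds are consecutive integers from `base_seed`; the outcome
  distributions are strongly bimodal under amplification (runs either stay
  near baseline conflict or polarize hard), so seed-averages over 20
  replicates still carry a standard error of roughly 0.1 conflict units —
  single-run figures from the reference grid sit well within that spread,
  but a particular 20-seed mean can land a tenth away from a particular
  single run.

## Known limitations

Homogeneous `epsilon` across agents; no group pressure, external events, or
multidimensional issue spaces; no network rewiring (replaced agents keep
their edges — no rewiring rule is specified anywhere); interventions are
population-blind (no degree-aware targeting). These are boundaries of the
model family, not roadmap items.
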