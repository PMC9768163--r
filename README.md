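# soam

Agent-based simulation of **opinion amplification** on directed social
networks: a bounded-confidence opinion-dynamics model in which some agents
publish amplified versions of their true opinions, for researchers studying
how sensationalism, hype and clickbait-style exaggeration can drive a
population to *extreme polarization* — opinions far outside the initial
range — and how platform-style interventions can curb it.

## The model

`n` agents hold continuous opinions, initialized i.i.d. uniform on
`[-1, 1]`, on a directed network (edge `a -> b`: `b` follows `a`). A
proportion `pi` of agents are *amplifiers*; each timestep an amplifier
amplifies with probability `p`, publishing its opinion pushed away from
zero by `sigma ~ Uniform(0, s)`:

```
SO_i = O_i - sigma_i   if amplifying and O_i <  0
       O_i + sigma_i   if amplifying and O_i >= 0
       O_i             otherwise
```

All agents then update synchronously, averaging their own previous opinion
with the expressed opinions of in-neighbors within the confidence threshold
`epsilon`:

```
O_i(t) = ( O_i(t-1) + sum_{j in I_i} SO_j ) / ( 1 + |I_i| ),
I_i    = { j in in_neighbors(i) : |O_i(t-1) - SO_j| <= epsilon }
```

Population **conflict** at a timestep is the population standard deviation
of the actual opinions (`1/sqrt(3) ≈ 0.577` for the uniform start). Two
interventions are built in: a **five-strike rule** (an agent amplifying
more than five times is replaced by a fresh one) and **balanced
dissemination** (five uniform opinions on `[-1, 1]` shown to everyone every
other timestep, subject to the same confidence gating).

## Worked example

Strong amplification (`epsilon = 0.8`, `pi = 0.5`, `p = 0.5`, `s = 0.5`)
versus the same seed with the five-strike rule:

```r
library(soam)

params <- soam_params(n = 100, k = 5, epsilon = 0.8, pi = 0.5, p = 0.5,
                      s = 0.5, t_max = 400, seed = 1)
traj <- soam_run(params)
traj
#> <soam_trajectory> n=100 t_max=400 eps=0.80 pi=0.50 p=0.50 s=0.50 (erdos_renyi)
#>   final conflict 3.0125, max |opinion| 21.268, 0 replacements
round(traj$conflict[c(1, 101, 401)], 3)   # conflict at t = 0, 100, 400
#> 0.559 0.768 3.013

curbed <- soam_run(params, interventions = intervention_config(max_amplify = 5))
curbed
#> <soam_trajectory> n=100 t_max=400 eps=0.80 pi=0.50 p=0.50 s=0.50 (erdos_renyi)
#>   final conflict 0.1680, max |opinion| 1.162, 101 replacements
```

Without intervention the population, which started inside `[-1, 1]`,
reaches opinions beyond ±21 and conflict five times the initial level —
extreme polarization. With the five-strike rule (101 replacements over the
run) every opinion stays near the initial range.

Replicated experiments and sweeps:

```r
cfg <- figure_presets("fig3c")               # eps sweep under amplification
soam_sweep(attr(cfg, "grid"), cfg)           # seed-averaged conflict table
run_replicates(cfg$model, replicates = 20)   # per-seed summaries
```

A thin CLI wraps the same functions:

```sh
Rscript exec/soam run --preset fig2f --replicates 3 --out out/
Rscript exec/soam sweep --config cfg.yaml
Rscript exec/soam net --kind erdos_renyi --n 100 --k 5 --out net.edgelist
```

See `vignette("soam-model")` for the full model description, parameter
semantics, and design choices.

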