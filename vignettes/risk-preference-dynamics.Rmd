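---
title: "Modelling the evolution of risk preference with riskfix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of risk preference with riskfix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskfix)
```

## The model and its assumptions

`riskfix` simulates competition between two heritable behavioural
strategies in a haploid population of constant size $N$ with
non-overlapping generations. Every generation, each individual accumulates
payoffs over $E$ decision events. A *risk-averse* individual receives a
constant payoff per event (10 in all standard schemes); a *risk-prone*
individual receives $high$ with probability $p$ and $low$ otherwise, drawn
independently per event. Schemes are *mean-matched*:
$p \cdot high + (1-p) \cdot low$ equals the risk-averse payoff, so the
strategies differ only in payoff variance and distribution shape.

Reproduction is a zero-sum lottery: the population is wholly replaced by
$N$ offspring whose parents are drawn independently from a weight vector
computed from the realized payoffs of that generation (a single parent may
produce several offspring). Offspring inherit the parental strategy exactly
— there is no mutation, migration, or environmental change — so the
risk-prone count $k$ is a Markov chain with absorbing states $0$ and $N$,
and every run ends in fixation.

Five payoff-to-fitness mappings are implemented; see
`?selection_scheme`. Proportional and power/sigmoid weighting act on the
payoff *value*; rank-based truncation acts on the payoff *rank*. This
distinction matters: under proportional selection only the *sum* of a
strategy's payoffs affects its expected share of the next generation, so
the outcome is sensitive to payoff variance but not to the distribution's
shape, whereas the non-linear mappings translate each individual's payoff
separately and are therefore sensitive to shape as well.

## Key parameters

| Parameter | Meaning | Units | Typical values |
|---|---|---|---|
| $N$ | population size | individuals | 10–1000 |
| $E$ (`events`) | decision events per lifetime | count | 1–20 |
| $low$, $high$, risk-averse payoff | per-event payoffs | payoff units | 5‑10‑15 baseline |
| $p$ (`p_high`) | chance of the high outcome | probability | 0.1–0.8 |
| $T$ (`threshold`) | top fraction that reproduces (rank truncation) | fraction | 0.1–0.9 |
| $z$ | fitness-function exponent (power) | — | 0.75–1.5 |
| $\xi$ (`steepness`), $\beta$ (`inflection`) | logistic shape (sigmoid) | — / normalized payoff | $\xi = 10$, $\beta = 2/3$ |

Defaults follow the standard study conditions: runs start from a 50/50
population ($\lfloor N/2 \rfloor$ risk-prone when $N$ is odd — the even
sizes used in practice are unaffected), and replicate counts default to
5000 for the scenarios where that is the stated convention and 2000
elsewhere, both overridable.

## What the simulator emulates — and what it does not

The simulated payoff process *is* the data-generating model: two-point
per-event payoffs, independent across events and individuals, with
parenthood decided once per generation. Passing tests therefore show that
the implementation reproduces this idealized process, not that real
populations behave like it. In particular the model omits state-dependent
behaviour (payoff distributions that depend on condition, size, or
experience), frequency- or environment-dependent payoffs, overlapping
generations, mutation between strategies, and any survival component of
fitness; conclusions about, say, foraging risk in a real species need the
mapping from these idealizations to the species' ecology argued
separately.

## Numerical and design choices

**Exchangeability-based engine.** Individuals within a strategy are
exchangeable, so a generation is summarized by the counts of individuals at
each of the at most $E + 2$ distinct accumulated-payoff values, and the
next risk-prone count is Binomial($N$, total risk-prone weight). This makes
a generation $O(E)$ regardless of $N$ without changing the process; the
test suite verifies the equivalence against a naive per-individual
reference implementation for every selection scheme.

**Truncation details.** The eligible count is
$k = \max(1, \mathrm{round}(T \cdot N))$ with half-up rounding (at least
one parent must exist). Ties spanning the cutoff rank are pervasive with
two-point payoffs; they are broken uniformly at random — in the grouped
engine by a hypergeometric draw of boundary slots, in the vector interface
by an iid uniform jitter key. Unbiased tie-breaking is what makes the
symmetric 5‑10‑15 scheme exactly neutral at $T = 0.5$, which the exact
oracle confirms (the martingale $E[k' \mid k] = k$ holds at every interior
state).

**Sigmoid normalization** is recomputed every generation from that
generation's realized maximum payoff, so the best-scoring individual always
sits at normalized payoff 1. Weight depends on the payoff value only, never
on rank.

**Absolute-threshold truncation** can leave an empty parent set (all
payoffs below the cutoff). The population's fate in that case is genuinely
undefined by the model, so the weight function signals a condition of class
`empty_parent_set` and `experiment_config()` exposes a policy: `"error"`
(default) or `"uniform"` fallback for that generation. Neither choice is
canonical; the default refuses to guess.

**The extreme 5‑10‑500 scheme** has no stated high-outcome probability;
the equal-mean constraint implies $p = 5/495 \approx 0.0101$, which is what
`payoff_scheme(5, 500)` solves automatically. Similarly, the "variance not
maintained" sweep fixes $low = 5$ and solves
$high = low + (mean - low)/p$, one natural one-parameter family through the
baseline scheme; other families are possible and would change the numbers
but not the direction of the effect.

**Exact oracle.** For $N \le 12$ and $E = 1$,
`transition_matrix()` enumerates all payoff realizations (mixing over
hypergeometric tie-breaks analytically) and `fixation_probability()` solves
the absorbing-chain system $(I - Q)u = b$ directly. The restriction to a
single event is deliberate: the oracle exists to pin down one generation's
mechanics, which given the payoff vector do not depend on $E$, and
multi-event enumeration grows combinatorially. Multi-event behaviour is
checked by simulation against the naive reference instead.

**Seeding.** Every replicate $r$ runs under `spawn_seed(base_seed, r)`, a
small Lehmer-style integer scramble, so results are bit-reproducible from
`(config, base_seed)`, independent of execution order, and decorrelated
across replicates; all seeds stay below $2^{31} - 1$.

**Tipping points.** `locate_tipping_point()` simulates a parameter grid and
interpolates the 0.5 crossing of the risk-prone fixation proportion
linearly on the logit scale (smooth and approximately linear near 0.5);
when noise produces multiple sign changes the proportions are first made
monotone by isotonic regression, and uncertainty comes from a parametric
bootstrap of the per-cell binomial counts. A grid with no crossing is an
error, not an extrapolation.

**Guard rails.** `max_generations` (default $10^6$) catches configuration
errors only — with valid weights fixation is almost sure, and typical
fixation times are of order $N$ generations from a 50/50 start.

## Problem sizes

The bundled tests and the acceptance script run at the study's own scales:
$N$ up to 1000, 2000–5000 replicates per condition (up to $10^5$ for one
small-$N$ power-selection case whose value lies close to its comparison
band, and $10^4$ per cell for oracle-vs-simulation checks at
$N \in \{2,3,4\}$). The full test suite completes in roughly a minute and a
half on one CPU; the acceptance script in under a minute.

## Known limitations

* The exact oracle is limited to $N \le 12$, $E = 1$.
* Rank-based variants of proportional, power, and sigmoid selection are not
  implemented (only truncation is rank-based), and payoffs with more than
  two risk-prone outcomes per event are out of scope.
* Fixation-time distributions are recorded but not calibrated against any
  external reference.
* The proportion $z$-test is a normal approximation; at very small
  replicate counts use the Wilson interval rather than the $p$-value.
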