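---
title: "Emergent periodicity from aperiodic flashers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emergent periodicity from aperiodic flashers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firesync)
```

## The problem

A lone *Photinus carolinus* firefly produces flash bursts at irregular
intervals: the waiting time between bursts is a broad, heavy-right-tailed
random variable with a hard lower bound — the refractory floor $T_0$ set by
physiology — and a tail reaching many minutes. Swarms of the same animals
flash with a strikingly regular collective period. `firesync` implements a
minimal mechanism for this emergence and the tooling needed to test it:
if each quiet individual independently draws its next interburst interval
(IBI) from a density $b(t)$, and the first one to flash triggers everyone
else, then after each collective burst all clocks reset together and the
next collective interval is the minimum of $N$ independent draws.

## The extreme-value theory

Let $\gamma(t) = \int_t^\infty b(u)\,du$ be the survival function of the
individual waiting time. The collective IBI density for $N$ identical
individuals is

$$P_N(T) = N\,\gamma(T)^{N-1} b(T),$$

and for heterogeneous individuals
$P_N(T) = \sum_i b_i(T) \prod_{j \neq i} \gamma_j(T)$. Moments follow the
survival-function identity
$\langle T_N^m \rangle = m \int_0^\infty \gamma^N(t)\, t^{m-1} dt$, which
`group_moment()` uses directly: it is numerically robust for very large
$N$ because $\gamma = 1$ below $T_0$ exactly, and $\gamma^N$ is evaluated
in log space to avoid underflow. Three qualitative consequences hold for
*any* non-degenerate $b$, and the test suite checks them numerically:

* every moment strictly decreases with $N$;
* the variance never increases with $N$;
* the left-most mode of $P_N$ never moves right as $N$ grows, and is
  floored at $T_0$; as $N \to \infty$ the distribution collapses to a
  point mass at $T_0$.

`min_of_n_oracle()` provides the brute-force check: empirical minima of
$N$ draws from $b$, which must agree with $P_N$ in Kolmogorov–Smirnov
distance at Monte-Carlo resolution.

A caveat worth stating: the *rate* of the large-$N$ collapse depends on
how much mass $b$ has just above $T_0$. For densities that vanish
smoothly at the floor (e.g. a shifted lognormal) the approach is
arbitrarily slow, and a group of $10^4$ can still sit visibly above
$T_0$. The concentration checks therefore use densities with
non-vanishing mass at the floor (shifted exponentials, histogram
envelopes); this is a property of the mathematics, not of the
implementation.

## Densities and the envelope protocol

`ibi_density` objects tabulate $b$ on a uniform grid from 0 with hard
support $[t_{\min}, t_{\max}]$; between grid points the density is
piecewise linear and all integrals are trapezoidal. `build_envelope()`
reproduces the standard protocol for measured intervals:

1. remove intervals below 2.0 s (they are interflash gaps within a burst,
   not interburst intervals);
2. density histogram with 50 uniform bins between the sample extremes
   (right-closed bins, so the maximum is included);
3. natural cubic spline through the (bin centre, height) pairs — natural
   boundary conditions are chosen for stability, and negative spline
   excursions are clipped to zero;
4. evaluation on a 0.1 s grid, zero-padding on $[0, t_{\min})$;
5. renormalisation to unit trapezoid integral (within $10^{-6}$).

Sampling uses inverse transform on the piecewise-linear CDF, the
continuous counterpart of resampling the fine-grained envelope, which
avoids grid-cell artifacts.

Two numerical conventions deserve a note. First, a piecewise-linear
density that is 0 at one grid point and positive at the next necessarily
ramps across that cell, so a sliver of trapezoid mass
($\approx b(t_{\min})\,h/2$) sits below the floor. The full-grid integral
is kept at exactly 1, but the CDF used for sampling and for survival
curves is conditioned on the support, so draws never fall below
$t_{\min}$ and $\gamma(t_{\min}) = 1$ exactly. Without this, the
min-of-$N$ operation amplifies the sliver $N$-fold into a spurious atom
at the floor. Second, the default 0.1 s grid is the protocol constant; for
sharp group densities (the $N = 50$ shifted-exponential tail decays on a
$1/(N\lambda) = 0.1$ s scale) quadrature at 0.1 s is too coarse for
sub-percent closed-form agreement, so oracle comparisons evaluate
parametric densities at 0.01 s. `grid_step` is exposed everywhere.

Because the underlying flash-length measurements are not reproduced here,
`flash_length_density()` is a synthetic stand-in: a shifted lognormal
with floor 0.2 s, median 1.0 s and shape 0.3 — flashes last on the order
of a second. It is configurable and only enters the simulator through the
discharge time.

## The swarm simulator

`simulate_swarm()` advances $N$ agents by forward Euler at
$dt = 0.009$ s for 200000 steps (30 simulated minutes) by default. Agent
$i$ carries a voltage $V_i \in [0,1]$ and a binary state $\epsilon_i$
(1 = charging/quiet, 0 = discharging/flashing). At each step,
synchronously for all agents:

1. a charging agent with $V \ge 1$ starts flashing and resamples its next
   cycle — an interval $T_b$ from $b$ and a flash length $T_d$ from the
   flash-length density, rejected until $T_b > T_d$, giving the charging
   time $T_s = T_b - T_d$; a flashing agent with $V \le 0$ goes quiet;
2. agents with $\epsilon = 0$ are flashing during this step;
3. charging agents gain $dt/T_s$; flashing agents lose $dt/T_d$; $V$ is
   clamped to $[0, 1]$.

Resampling the full cycle at flash *onset* makes the start-to-start
interval of an uncoupled agent exactly the sampled $T_b$ (discharge and
subsequent charge share one draw), so a single uncoupled agent is a
renewal process with interval law $b$ — the $\beta = 0$ limit the theory
requires. Initial voltages are uniform on $[0,1)$ with all agents
charging; the first few collective bursts carry this arbitrary initial
condition, so analyses discard a burn-in (default 5 bursts per run).

### Coupling

Coupling is pulsatile: at the timestep a neighbour $j$ *starts* flashing,
every charging agent $i$ that sees it ($\delta_{ij} = 1$; all-to-all with
zero diagonal by default) receives a voltage donation

$$\Delta V_i = \mathrm{gain} \cdot \beta / N ,$$

while flashing agents ignore their neighbours. This choice was made
deliberately over integrating a sustained coupling term through the
neighbour's whole flash, for a structural reason: with sustained
donations, any coupling strong enough to synchronize the swarm also
re-triggers agents that have just finished flashing (their reset voltage
is pumped back to threshold by the tail of the very burst they
initiated), and the simulation collapses into a single never-ending
burst. Onset pulses are immune by construction — every donation of a
collective burst is delivered while the burst's participants are still
discharging, and discharging agents receive nothing — so a burst always
terminates, and the total donation an agent can receive per burst is
bounded by $\mathrm{gain}\cdot\beta\,(N-1)/N$. In the two limits the
model does what the theory demands: $\beta = 0$ gives independent renewal
processes, and large $\beta$ gives instant triggering, i.e. the
first-to-flash idealisation whose interval law is $P_N$.

The fixed donation gain (default 4) calibrates where the synchronization
transition falls for the default study conditions ($N = 20$, the default
densities): just above $\beta = 0.1$, with full synchrony by
$\beta \approx 0.3$, so the interesting dynamics — and the region where a
KS fit can discriminate neighbouring couplings — lie inside the swept
range $\beta \in [0, 1]$. Below the transition, pooled flash-to-flash
intervals pile up toward zero (superposed independent renewal processes);
above it the collective interval locks onto the minimum-of-$N$ law. The
per-pair scaling $\beta/N$ is retained so that total drive is
size-independent under all-to-all connectivity.

Determinism: the C++ core draws from R's RNG, so a `swarm_config` seed
makes runs bit-identical; replicate $k$ uses `seed + k - 1`.

## Burst analysis

`detect_bursts()` pools flashes over agents, orders them by start time,
and groups them into temporal connected components with a 2 s
start-to-start gap threshold (flash durations are well under the gap, so
the start-vs-end convention is immaterial in practice, but start-to-start
is fixed for reproducibility). The burst time is its first flash start.
Two interval definitions are exposed, because both are in common use and
they answer different questions: `interburst_intervals()` (first flash of
one burst to first flash of the next — the experimental definition, and
the default for fitting) and `flash_to_flash_intervals()` (differences of
all pooled flash starts, zeros retained since simultaneous starts encode
synchrony). Summaries report the highest histogram bin centre as the mode
(0.5 s bins by default — about 24 bins across a 12 s period; ties resolve
to the smallest centre).

## Fitting the coupling strength

`beta_sweep()` simulates `n_trials` replicates per $(\beta, N)$ cell,
pools burn-in-trimmed first-to-first intervals across replicates (pooling
before the test, rather than averaging per-trial statistics, because the
reference distributions are themselves pooled), and computes the
two-sample KS statistic against the per-$N$ reference sample.
`select_best_beta()` takes the argmin per $N$, ties toward smaller
$\beta$. The default grid is $\beta \in [0,1]$ in steps of 0.02 with 10
trials per cell. No significance threshold is imposed on the KS p-value;
the fit is a minimisation, not a hypothesis test. Parameter-recovery
tests (reference generated by the simulator itself at known $\beta^*$,
with 50000-step trials to keep the full 51-point sweep inside a desk-scale
compute budget) recover $\beta^* \in \{0.2, 0.3\}$ within one grid step.

## What the synthetic generators do and do not emulate

The parametric interval models (shifted exponential, shifted lognormal)
reproduce the two features the mechanism actually needs: a hard
refractory floor and a broad right tail. They do not reproduce
multimodality, temperature dependence, behavioural-state switching, or
any correlation between successive intervals of one individual — all
present in real data to some degree. Passing tests therefore demonstrate
the mechanism and the correctness of the machinery, not a fit to any
particular field dataset; fitting real data requires supplying measured
interval samples (the package reads them as one-column `ibi_s` text
files) and proceeds through exactly the same envelope → theory →
simulate → sweep pipeline.

Known limitations, intentionally out of scope: no spatial positions or
distance/occlusion-dependent connectivity (the adjacency matrix is the
hook for that), no perception delays (which would shift the collective
interval right), and single-flash bursts only — within-burst flash trains
are not modelled, which is why intervals below 2 s are cleaned from
inputs rather than simulated.
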