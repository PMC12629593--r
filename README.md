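# firesync

Emergent collective periodicity from intrinsically aperiodic flashers.

Isolated *Photinus carolinus* fireflies flash in bursts separated by wildly
irregular waiting times — anything from a few seconds to many minutes. Put
enough of them together and a crisp collective rhythm appears. `firesync`
implements the extreme-value mechanism behind this: if every individual
draws its next interburst interval (IBI) independently from a broad density
b(t), and the *first* flasher triggers the whole group, then the collective
interval is the **minimum of N draws**,

```
P_N(T) = N [ γ(T) ]^(N-1) b(T),    γ(t) = ∫_t^∞ b(u) du ,
```

whose moments and variance all shrink monotonically with N and which
collapses onto the refractory floor T0 (the shortest physiologically
possible interval) as N → ∞. Periodicity is an emergent group property; no
individual is periodic.

The package is aimed at researchers in collective animal behaviour and
pulse-coupled oscillator dynamics who want to

* turn tables of measured intervals into smooth **envelope densities**
  (histogram → cubic spline through bin centres → fine 0.1 s grid →
  zero-padding below the observed minimum → normalisation);
* evaluate the analytic **first-to-flash theory** (group density, moments,
  variance, mode behaviour) for any input density, homogeneous or
  heterogeneous, with a brute-force Monte-Carlo oracle;
* run a **stochastic pulse-coupled integrate-and-fire swarm**: each agent
  charges a voltage over a randomly resampled cycle and a visible flash
  onset donates `gain·β/N` voltage to every charging neighbour, with the
  coupling strength β tunable from 0 (independent flashers) to the
  instant-trigger idealisation (large β);
* detect collective **bursts** (temporal connected components of flashes
  less than 2 s apart) and extract interval samples;
* **fit β** by sweeping (β, N) and minimising the two-sample
  Kolmogorov–Smirnov distance to reference interval distributions.

Everything is tibble-first: samples, densities, flash series, burst trains
and sweep surfaces are data frames that pipe through dplyr, with
`autoplot()` methods and `tidy()`/`glance()` for sweep results.

## Worked example

```r
library(firesync)

# a synthetic individual: 5 s refractory floor + exponential tail (mean 10 s)
b <- parametric_density(ibi_model("shifted_exponential", t0 = 5, rate = 0.2))
b
#> <ibi_density> shifted_exponential
#>   support [5.000, 97.103] s, grid step 0.1 s, 973 points
#>   mean 9.950 s, sd 5.000 s

# the analytic sharpening of the collective rhythm
std_vs_N(b, c(1, 5, 10, 20))
#> # A tibble: 4 × 2
#>       N  sd_s
#>   <int> <dbl>
#> 1     1 5.00
#> 2     5 0.998
#> 3    10 0.497
#> 4    20 0.243
```

A single flasher is hugely variable (sd 5 s); twenty of them already beat
with a 0.24 s jitter around a period just above the 5 s floor
(`group_mean(b, 20)` is 5.25 s).

```r
# simulate 20 coupled agents for 30 simulated minutes
cfg <- swarm_config(N = 20, beta = 0.3, seed = 1)
flashes <- simulate_swarm(cfg, b, flash_length_density())
ibis <- flashes |> detect_bursts(gap = 2) |> interburst_intervals()
summarize_intervals(ibis, bin_width = 0.5)[c("mode_s", "mean_s", "sd_s")]
#> $mode_s  [1] 5.25
#> $mean_s  [1] 5.46
#> $sd_s    [1] 0.46
```

At β = 0.3 the swarm is synchronized: 330 collective bursts with a modal
interval of 5.25 s, close to the analytic prediction for the
first-to-flash mechanism (mode 5.0 s, mean 5.25 s). Setting `beta = 0`
instead gives desynchronized flashing whose pooled intervals pile up
*below* the floor; large `beta` converges to `group_density(b, 20)`.

Given reference interval samples (measured or simulated), the coupling is
fitted by KS minimisation:

```r
sweep <- beta_sweep(seq(0, 1, 0.02), N_list = 20, reference = ibis,
                    config = cfg, b = b, d = flash_length_density())
glance(sweep)     # best beta per N
autoplot(sweep)   # KS surface
```

A command-line front end over the same functions lives at
`inst/cli/firesync.R` (`synth`, `envelope`, `theory`, `simulate`,
`analyze`, `sweep`), writing delimited-text outputs plus a run manifest.

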