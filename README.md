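# madm1

A multi-population extension of the Anaerobic Digestion Model No. 1 (ADM1)
for studying ammonia inhibition of volatile fatty acid (VFA) degradation in
chemostats. The package is aimed at anaerobic-digestion modellers and
microbial ecologists who want a mechanistic, fully reproducible account of
how a community *recovers* from an ammonium shock through competitive
population replacement — something the single-population ADM1 structure
cannot represent.

## The model

Standard ADM1 applies free-ammonia inhibition only to its single
acetoclastic population. Here, acetoclastic methanogenesis and syntrophic
propionate oxidation are each carried by **two competing populations** that
share yield and maximum uptake rate but differ in half-saturation and
ammonia inhibition constants, e.g. for the acetoclasts

    dX_ac,i/dt = (X_in,ac,i − X_ac,i)/HRT
                 + ( Y_ac · k_m,ac · S_ac/(S_ac + K_S,ac,i) · I_ac,i − k_dec ) · X_ac,i

    I_ac,i = I_pH · I_IN,lim · 1/(1 + S_nh3 / K_I,nh3,i)

and propionate uptake (both populations) additionally keeps its hydrogen
inhibition term while gaining the ammonia term that standard ADM1 lacks.
Defaults: `K_S = 0.34 / 0.15` gCOD/L and `K_I,nh3 = 0.3387 / 0.0052` M for
the tolerant/sensitive acetoclasts, `0.34 / 0.10` gCOD/L and
`0.4887 / 0.0036` M for the propionate oxidizers. The sensitive populations
(higher affinity, low `K_I`) dominate at 52 mM influent ammonium
bicarbonate; when the influent steps to 277 mM on day 21 their growth falls
below dilution + decay, they wash out, VFAs accumulate, and the tolerant
populations take over and restore degradation.

Around that core the package provides: an algebraic acid-base/pH subsystem
(charge-balance root-finding, van 't Hoff-corrected to 37 °C), closed
COD/C/N balances in the Petersen matrix, headspace gas transfer with
overpressure outflow, the experiment's influent schedules (ammonia step,
HCl window, pulse disturbances with feed suspension), the per-acid
degradation-efficiency calculus on one-day mass balances, sequential
bounded least-squares calibration of the eight population parameters, and a
synthetic-observation generator (lognormal concentration noise, Dirichlet
community resampling) for parameter-recovery studies. The right-hand side
is compiled (Rcpp) with a pure-R reference implementation kept as
documentation and cross-check.

## A worked example

```r
library(madm1)

params   <- adm1_params()                      # fitted two-population kinetics
schedule <- experiment_schedule("NH3")         # 277 mM step at day 21 + pulses
sim      <- simulate_reactor(schedule, params) # steady-state init + 79 d run
sim_targets(sim)
#> # A tibble: 1 × 6
#>   peak_ac peak_pro ac_day55 abund_ac1_day55 pro_day62 abund_pro1_day62
#>     <dbl>    <dbl>    <dbl>           <dbl>     <dbl>            <dbl>
#> 1    8.63     2.55    0.488           0.750     0.375            0.117
```

Acetate accumulates to 8.6 gCOD/L and propionate to 2.5 gCOD/L after the
ammonia step, then both recover as the tolerant populations grow in: by
day 55 acetate is back to 0.49 gCOD/L and the tolerant acetoclast holds a
0.75 share of the methanogens; by day 62 propionate is at 0.38 gCOD/L with
the tolerant oxidizer at a 0.12 share of the bacteria. `autoplot(sim)`
draws the VFA, pH/free-ammonia and relative-abundance panels.

The per-acid degradation efficiencies from the same run show the ordering
of inhibition severity (propionate hit hardest, butyrate barely affected):

```r
eff <- degradation_efficiency(vfa_series_from_sim(sim),
                              c(S_ac = 16.74, S_pro = 3.72, S_bu = 16.74),
                              hrt = 5.5)
sapply(eff[eff$time > 21, c("E_pro", "E_ac", "E_bu")], min)
#>    E_pro     E_ac     E_bu
#> 0.279360 0.676486 0.983771
```

The single-population contrast run shows why the extension matters:

```r
classify_trajectory(compare_original_structure(schedule, 0.008))
#> [1] "elevated_no_recovery"
classify_trajectory(compare_original_structure(schedule, 0.0018))
#> [1] "washout_failure"
classify_trajectory(sim)
#> [1] "recovery"
```

Calibration and synthetic-data recovery:

```r
obs  <- generate_observations(params, experiment_schedule("NH3", pulses = FALSE),
                              noise_model(cv = 0.07), seed = 1)
fit  <- fit_sequential(obs, calibration_spec(start = c(K_I_nh3_ac2 = 0.01,
                                                       K_I_nh3_pro2 = 0.01)))
tidy(fit)    # estimates with bounds, broom-style
glance(fit)  # stage SSEs, convergence, seed
```

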