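# fertkin

Kinetics of mammalian fertilization and of the blocks to polyspermy, from
interval-censored single-oocyte observation data.

## The problem

In kinetic-tracking insemination experiments, individual zona-intact mouse
oocytes are observed in rounds while spermatozoa cross the zona pellucida
(ZP), enter the perivitelline space (PVS) and — one of them — fuses with the
oolemma.  Because observation is sequential, event times are interval
censored: a penetration between two rounds is only known to lie in the gap,
and a fusion is dated backwards from the morphological stage (sperm-head
internalisation, second-polar-body extrusion) seen at the next looks.  From
such data one wants the kinetics of three things:

* the **baseline ZP permeability** λ₀ (sperm entering the PVS per oocyte
  per hour before fertilization),
* the **penetration block** — after the first fusion, the entry rate decays
  as λ₀·exp(−t/τ_PB); the cumulative count follows
  *f(t) = A(1 − exp(−t/τ_PB))* with plateau A = λ₀·τ_PB,
* the **fusion block** — sperm already in the PVS lose fusion competence
  with a much shorter time constant τ_FB; extra fusions follow
  *f(t) = a(1 − exp(−t/τ_FB))* with the amplitude *a* fixed at the observed
  number of extra fusions per fertilized oocyte.

`fertkin` provides the chronogram data model and table I/O, the
landmark-based refinement of fusion time windows, a uniform-within-window
Monte Carlo estimator of cumulative event-count curves with bootstrap
confidence bands, the least-squares block-model fits, a mechanistic Monte
Carlo simulator of polyspermy with switchable blocks, and a synthetic-data
generator that reproduces the full observation-censoring process for
end-to-end validation.

## Worked example

Generate a synthetic cohort at the default kinetics (λ₀ = 1.21/h,
τ_PB = 48.3 min, τ_FB = 6.2 min, penetration-to-fusion delay
15.8 ± 5.7 min), censor it through a realistic observation schedule, and
re-estimate the penetration block:

```r
library(fertkin)

p     <- kinetic_params(n_oocytes = 57)          # one study-sized cohort
truth <- generate_truth(p, seed = 2026)          # true event histories
cens  <- censor_truth(truth, seed = 2027)        # what the experiment sees

summary(cens$chronogram)
#> Chronogram summary [synthetic] (57 oocytes)
#> Oocyte fates:
#>              fertilized penetrated_unfertilized            unpenetrated
#>                      55                       1                       1
#> Penetrated sperm per oocyte:
#>  0  1  2  3  4  5  7
#>  1 17 19 14  4  1  1
#> First penetrant outcome (n=55 fertilized oocytes): 70.9% fertilized, 0.0% failed, 29.1% ambiguous
#>   penetrated before first fusion: 58 sperm, 96.6% fused
#>   penetrated after first fusion: 25 sperm, 0.0% fused
#>   penetrated unknown first fusion: 41 sperm, 7.3% fused
#> Dispermic oocytes: 4

fert <- subset_oocytes(cens$chronogram, fate = "fertilized")
cp <- count_curve(fert, "first_fusion", "penetration",
                  n_realizations = 1000, n_boot = 1000, seed = 2028)
fit_penetration_block(cp)
#> Penetration-block fit: A = 0.885 sperm/oocyte (95% CI 0.669-1.124), tau_PB = 41.0 min (95% CI 31.3-55.4)
#>   implied initial rate 1.29 sperm/oocyte/h

fusion_delay_curve(fert, n_realizations = 1000, n_boot = 1000, seed = 2029)
#> Penetration-to-fusion delay: 17.0 min (95% CI 14.9-19.2), between-sperm SD 12.8 min; 59 fused sperm
```

The bootstrap CIs recover the generating values (τ_PB = 48.3 min inside
31.3–55.4; the implied initial rate 1.29/h against a true λ₀ of 1.21/h); a
cohort of 57 oocytes carries exactly this much information.

What-if scenarios of the mechanistic simulator quantify each block's
contribution to polyspermy prevention:

```r
p5 <- kinetic_params(n_oocytes = 5000)
run_scenario(p5, "baseline",        seed = 2030)$polyspermy_fraction  # 0.104
run_scenario(p5, "no_fusion_block", seed = 2030)$polyspermy_fraction  # 0.696
```

Removing the fusion block multiplies polyspermy several-fold — it, not the
slow penetration block, is what keeps fertilization monospermic.

A full pipeline (synthesis → curves → fits → scenarios, with a
reproducibility manifest) runs from one YAML config via `run_pipeline()`;
see `vignettes/fertkin-methods.Rmd` for the models, conventions and
validation caveats.

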