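# gudpeck

Giving-up densities (GUDs) for **every** bird species visiting a
depletable seed tray — not just the last one.

A classical GUD experiment mixes 20 g of seed into a tray of sand,
leaves it out for 24 h, and weighs what remains. That mass is the
quitting decision of the *final* forager only; every earlier visitor
quit at some higher, unobserved seed density. Given video-scored peck
logs, `gudpeck` recovers the rest: it fits the **GUD-Peck model**

    GUD_i = beta0 + beta_P * P_i + beta_d * d_i + alpha_s(i) + e_i

on final-forager trays (`P_i` total pecks on tray *i*, `d_i` the tray's
minimum number of individuals from visit concurrency, `alpha_s` a
species offset for the final forager), then evaluates the fitted model
at the cumulative peck count at the moment each species quit, yielding
a per-species GUD and, with summed foraging-bout times, a consumption
rate in g/h. Around the model sit the event-log primitives (one-minute
bout segmentation, class-wise concurrency minima, quitting points) and
the community comparisons used to contrast residential landscape
designs: MRPP on Bray-Curtis distances, Pielou evenness, ANOVA/ANCOVA
on GUDs, paired bush/open microhabitat t-tests, Wilcoxon and
Kruskal-Wallis rank tests.

Because the field data this analysis style comes from are unpublished,
the package includes a mechanistic optimal-foraging simulator
(Poisson arrivals, shared seed ledger, departure when the expected
yield of the next peck falls below a species threshold) with exact
ground truth; the test suite validates the whole chain against it.

## Worked example

```r
library(gudpeck)

study  <- generate_study(sim_config(), seed = 1)   # 20 yards, 40 trays, 24 h
events <- analyze_events(study)
fit    <- fit_gud_peck_model(training_table(study, events))
print(fit)
```

```
GUD-Peck model (OLS), n = 40
  beta0         13.2284 g
  beta_pecks   -0.002310 g/peck
  beta_density  -0.0208 g/individual
  species offsets (ref ABTO):
    ABTO     0.0000
    CBTH    -1.4625
    HOFI     1.0954
    HOSP    -1.3450
  r^2 = 0.992, obs-vs-pred Pearson r = 0.996
```

Forty trays had a weighed final GUD; four species (Abert's towhee,
curve-billed thrasher, house finch, house sparrow) appeared as final
foragers, so only they get offsets — everything else is flagged
`species_not_in_model` downstream, mirroring how species that are never
the final forager have no GUD-peck anchor. Estimating GUDs for all
visitors and comparing yard types:

```r
est   <- estimate_species_guds(fit, events$quit_points, events$density,
                               study$trials, study$config)
rates <- consumption_rates(fit, events$quit_points, events$foraging_times,
                           events$density, study$trials, study$config)
stats <- yard_comparisons(study, events, est, rates, study$config)
```

prints (via `analysis/05_yard_comparisons.R`):

```
GUD by yard type: F(1,49) = 42.16, P = 4e-08; mesic 4.88 g (SE 0.37), xeric 8.81 g (SE 0.49).
Yard-type x density interaction: t = -0.93, P = 0.36.
Paired bush vs open (mesic): t = -0.10, df = 15, P = 0.92.
Community MRPP: A = 0.0677, P = 0.01 (999 permutations).
Evenness by yard type: F(1,18) = 4.48, P = 0.05.
```

Birds in the simulated mesic yards deplete trays further (lower GUDs)
than in xeric yards — the generator builds that contrast in through
species composition and higher xeric quitting thresholds — while bush
and open trays do not differ (the simulator makes microhabitat
behaviourally neutral).

## The analysis workflow

Numbered drivers under `analysis/` run the chain stage by stage and
write their tables under `results/`:

| script | stage |
|---|---|
| `01_simulate.R` | generate the 20-yard study (`results/data/`) |
| `02_events.R` | bouts, quitting points, densities (`results/events/`) |
| `03_fit_model.R` | fit the GUD-Peck model (`results/model/`) |
| `04_estimate_guds.R` | per-species GUDs and rates (`results/estimates/`) |
| `05_yard_comparisons.R` | yard-type statistics (`results/stats/`) |

`run_pipeline(out_dir, simulate = TRUE)` runs the same chain in one
call and writes a manifest. The methods vignette
(`vignettes/gud-peck-workflow.Rmd`) documents the model, the simulator
defaults and every numerical choice.

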