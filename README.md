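# unicub — uniparental incubation in biparentally incubating shorebirds

Most shorebirds that share incubation do so obligately: the female and
male alternate incubation bouts around the clock, and a clutch attended
by a single parent is usually assumed doomed. Continuous nest-monitoring
(a thermocouple in the nest cup, a second probe recording surface
temperature beside it, and an RFID antenna reading the tags of sitting
parents every 5 s) makes it possible to see what actually happens when
one parent disappears: how often the remaining bird incubates alone, with
what daily rhythm, and whether such clutches can still hatch.

`unicub` implements that analysis as a tested, reusable R pipeline:

1. **Extraction** — per-reading incubation state from the thermal
   signature (nest temperature held above the surface baseline by a
   margin; steep rises/drops mark arrivals and departures), parent
   identity from RFID, maximal parent-labelled incubation bouts, and the
   estimated start of incubation per nest. All records use local solar
   time, `UTC + longitude · 24/360` h.
2. **Phase detection** — a *uniparental incubation phase* on a nest with
   population median bout length *m* is a solo span `[t0, t1]` (one
   parent only) such that, after discarding the first "regular" bout
   `[t0, t0 + m]` (the deserted bird initially just sits its usual
   shift), the remainder is at least `2m` long. Windows confounded by
   hatching are trimmed (6 h before hatch start, 24 h before chicks
   found). Each phase carries its **start fraction**
   `100 · (start − incubation_start) / typical_incubation_period` (%,
   values > 100 are post-expected-hatch starts), duration in days, a
   cause (natural/unknown, post-capture, experimental removal, temporal)
   and a censoring flag.
3. **Attendance** — hourly and daily *nest attendance* (incubation
   constancy): the percentage of readings classified as incubated, per
   incubation type (biparental; uniparental in a biparental species;
   uniparental in an obligate uniparental species), with a 75 %
   type-purity filter per window: a day that is 80 % biparental and 20 %
   uniparental contributes one biparental record computed on the 80 %.
4. **Inference** — lme4 mixed models fitted by maximum likelihood:
   daily attendance ~ day-in-period × type and hourly attendance ~
   (sin, cos of time-of-day) × type with nest and species crossed with a
   2-level type factor as random intercepts and the time covariate as a
   random slope; sex-specific variants; and a binomial model of hatching
   success ~ start fraction + duration + median daily attendance with a
   species random intercept. Uncertainty is summarised by simulation:
   5,000 draws from the multivariate-normal sampling distribution of the
   fit (flat prior), reported as posterior medians with 2.5/97.5
   percentile credible intervals, plus variance-component shares.
5. **Synthetic data** — a generator with a ground-truth ledger
   (log-normal bout alternation, diel ambient sinusoid, exponential
   nest-temperature relaxation, RFID emission, desertion and solo
   circadian rhythms) so every stage is testable against known truth.

## Worked example

```r
library(unicub)

cfg <- sim_config(n_nests = 6, sampling_interval_s = 120,
                  desertion_prob = 1, seed = 11)
sim <- generate_dataset(cfg)
out <- run_pipeline(sim$dataset, truth = sim$truth)

out$phases[, c("nest_id", "sex", "start", "duration_days",
               "start_fraction", "cause", "censored")]
#>    nest_id    sex               start duration_days start_fraction
#> 1:    N001      M 2015-06-12 04:42:00      2.494444       55.97917
#> 2:    N002      M 2015-06-11 22:50:00      1.929167       54.75694
#> 3:    N003      M 2015-06-16 05:14:00      2.023611       76.09028
#> 4:    N004      M 2015-06-15 05:58:00      3.630556       71.24306
#> 5:    N005      M 2015-06-07 14:40:00      4.094444       33.05556
#> 6:    N006      M 2015-06-11 00:06:00      2.055556       50.02083
#>              cause censored
#> 1: natural/unknown    FALSE
#> ...

out$case_stats
#>                         statistic     value     n
#> 1:           median_duration_days  2.275000     6
#> 4:          median_start_fraction 55.368056     6
#> 8:   pct_cases_start_after_period  0.000000     6
```

All six simulated nests lost their (mostly female, by the configured
80/20 rule) partner; the remaining males incubated alone for a median of
2.3 days, with solo phases starting between 33 % and 76 % of the way
through the 20-day incubation period — none after the expected hatch
date, so the >100 %-start filter removes nothing here.

The published headline statistics are recomputed from the packaged
summary-count fixture:

```r
round(contingency_stats(), 1)
#>   t1   t2   t3   t4   t5   t6
#> 27.3 65.5  7.3 80.0 17.1 10.1
```

i.e. 27 % of known-outcome uniparentally incubated nests hatched, 65 %
were deserted, 7 % depredated; the male was the remaining incubator in
80 % of cases; 17 % of all monitored nests had at least one uniparental
case; 10 % of cases began after the typical incubation period.

## Command line

```sh
Rscript inst/exec/unicub simulate --config sim.cfg --seed 3 --out data/
Rscript inst/exec/unicub run-all  --in data/ --out results/
Rscript inst/exec/unicub fit --model daily --in results/ --out results/
Rscript inst/exec/unicub report --out results/
```

## Documentation

The methods vignette (`vignettes/uniparental-incubation.Rmd`) documents
the model and its assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate, the
numerical choices (hysteresis classification, tie-breaks, trims), and
known limitations.
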