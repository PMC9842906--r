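# kitedispersal

Tools for scoring the **departure to natal dispersal** of GPS-tagged
juvenile raptors and for modelling its drivers. The package targets data of
the kind produced by two-season field studies of juvenile red kites
(*Milvus milvus*) carrying solar GPS-GSM transmitters across an elevational
gradient — duty-cycled daylight fixes, a supplementary-feeding experiment,
brood-level covariates — and implements the complete analysis chain from
raw fixes to path analysis as reusable, tested functions, plus a
synthetic-study generator so the whole chain runs and is testable without
any field data.

## What it does

**Departure detection (geofence rule).** A juvenile has departed when it
first stays continuously outside a 2 km radius around its nest for more
than 2 days (both thresholds configurable). Departure age is continuous
days since hatching; the post-fledging dependence period (PFDP) subtracts
an assumed fledging age of 55 days. `threshold_sensitivity()` re-scores
everyone at 1/2/3/5/9-day thresholds; exclusion filters remove birds that
died, lost their transmitter, or started migration before departing.

**Communal roosts.** Night-time positions of tagged non-breeders (the last
fix of each day and the first of the next, since duty-cycled transmitters
record no true night fixes) are scored by revisitation — entry events into
a 50 m disc around each position — and the top 5 % are k-means clustered
into the 10 most used roosts per year. The distance from each nest to the
closest roost is a control covariate.

**Covariates.** Edge-corrected conspecific territory density (count within
2 km, inflated by the inverse of the disc's in-survey area fraction),
hatching date inverted from a feather growth curve, hatching rank from
sibling wing lengths, body-condition residuals, and a scaled, join-checked
analysis table.

**Inference.** The departure-age model is a linear mixed model with a brood
random intercept (REML, lme4):

    departure_age ~ treatment + hatching_date + rank + elevation + sex +
                    roost_distance + year + density + (all two-way
                    interactions, pruned stepwise) + (1 | brood)

with simulated-posterior 95 % credible intervals (2000 multivariate-normal
draws), a parametric-bootstrap likelihood-ratio test of the brood random
effect, companion models for hatching date, territory density and roost
distance, and a path analysis splitting the elevation effect into a direct
path and an indirect path through hatching date (per draw, indirect =
a x b).

**Synthetic studies.** `generate_study()` / `generate_tracks()` simulate
complete studies — stratified feeding experiment, elevational hatching
gradient, duty-cycled trajectories with excursions and abrupt departures,
communal roosts, censoring — at the fitted coefficient structure, with
per-individual ground truth for testing.

## Worked example

```r
library(kitedispersal)

cfg <- run_config(sim = sim_config(n_broods = 30L,
                                   brood_size_dist = c(0.3, 0.5, 0.15, 0.05),
                                   p_fail_pre_departure = 0.1,
                                   p_migrate_pre_departure = 0.04,
                                   p_year_2017 = 0.4),
                  candidate_interactions = list(c("year", "dens_s"),
                                                c("sex", "dens_s")),
                  n_draws = 500L, lrt_sims = 100L, seed = 7L)
run <- run_pipeline(cfg)
run
#> <pipeline_run> seed 7
#>   filter chain: tagged=68, failed=7, migrated=4, censored=0, included=57
#>   retained interactions: (none)

run$manifest$hatch_slope_days_per_100m
#> [1] 3.446341
```

The filter chain reports how many tagged juveniles were excluded before the
analysis set (transmitter failure / death, pre-departure migration,
censoring), mirroring the accounting a field study reports. The
`hatch_slope_days_per_100m` entry is the elevational hatching-date slope
back-transformed to days per 100 m — here 3.45 d/100 m recovered from data
generated at 3.03 d/100 m, one small study's sampling noise. The fitted
model, its credible intervals (`run$cri_departure$intervals`), the
random-effect test (`run$lrt`) and the path analysis (`run$path`) hang off
the returned object.

Detector in isolation:

```r
st  <- generate_study(sim_config(n_broods = 25L, seed = 3))
trk <- generate_tracks(st)
dep <- detect_departures(trk, st$juveniles)
head(dep[dep$status == "departed",
         c("individual_id", "departure_age_days", "pfdp_days")], 3)
#>   individual_id departure_age_days pfdp_days
#> 1       juv_001           96.78036  41.78036
#> 3       juv_003           89.89280  34.89280
#> 4       juv_004           89.10247  34.10247
```

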