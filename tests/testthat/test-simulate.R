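test_that("invalid configurations are rejected", {
  expect_error(sim_config(brood_size_dist = c(0.5, 0.4)), "summing to 1")
  expect_error(sim_config(elevation_range_m = c(1200, 500)), "low < high")
  expect_error(sim_config(hatch_model = list(
    intercept_doy = 132, slope_days_per_100m = 3, year_effect_days = -6,
    density_effect_days = 0, brood_sd_days = -1, resid_sd_days = 1)),
    "standard deviations")
  expect_error(sim_config(fix_interval_h = 0), "fix_interval_h")
  expect_error(sim_config(p_fail_pre_departure = 0.8,
                          p_migrate_pre_departure = 0.4), "fate")
})

test_that("a fixed seed reproduces the study and its tracks exactly", {
  cfg <- small_config(seed = 21)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$juveniles, s2$juveniles)
  expect_identical(s1$roost_truth, s2$roost_truth)
  expect_identical(truth_report(s1), truth_report(s2))
  t1 <- generate_tracks(s1)
  t2 <- generate_tracks(s2)
  expect_identical(t1$fixes, t2$fixes)
})

test_that("the noise-free limit reproduces the linear predictors exactly", {
  cfg <- sim_config(
    n_broods = 60, p_year_2017 = 0.5, seed = 3,
    hatch_model = list(intercept_doy = 132.71, slope_days_per_100m = 3.03,
                       year_effect_days = -5.99, density_effect_days = 0,
                       brood_sd_days = 0, resid_sd_days = 0),
    departure_model = list(intercept = 79.47, feeding = -3.52,
                           hatch_date = -2.14, rank_later = 1.49,
                           rank_singleton = 0.24, elevation = 0.39,
                           sex_male = 3.26, roost_distance = -2.90,
                           year_2017 = 4.57, density = -4.99,
                           year_density = 4.44, sex_density = 3.38,
                           brood_sd = 0, resid_sd = 0))
  st <- generate_study(cfg)
  juv <- st$juveniles
  tr <- truth_report(st)
  # refitting the exact model structure on the pre-snap outcomes leaves no
  # residual and returns the configured coefficients
  d <- juv
  d$y <- tr$departure_age_model
  d$year <- factor(d$year)
  for (v in c("hatch_doy", "elevation_m", "roost_distance_m",
              "territory_density")) {
    d[[paste0(v, "_s")]] <- as.numeric(scale(d[[v]]))
  }
  fit <- lm(y ~ treatment + hatch_doy_s + hatching_rank + elevation_m_s +
              sex + roost_distance_m_s + year + territory_density_s +
              year:territory_density_s + sex:territory_density_s, data = d)
  expect_lt(sigma(fit), 1e-6)
  expect_equal(unname(coef(fit)["treatmentfed"]), -3.52, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["sexM"]), 3.26, tolerance = 1e-6)
  # hatch dates are exactly linear in elevation within a year
  fh <- lm(hatch_doy ~ I(elevation_m / 100) + factor(year), data = d)
  expect_lt(sigma(fh), 1e-6)
  expect_equal(unname(coef(fh)[2]), 3.03, tolerance = 1e-4)
})

test_that("expected juvenile count matches the analytic multinomial mean", {
  cfg <- sim_config(seed = 1)
  analytic <- cfg$n_broods *
    sum(cfg$brood_size_dist * seq_along(cfg$brood_size_dist))
  expect_lt(abs(analytic - 158), 1.0)
  counts <- vapply(1:25, function(i) {
    nrow(generate_study(sim_config(n_nonbreeders_per_year = 0,
                                   seed = 100 + i))$juveniles)
  }, numeric(1))
  mc_se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - analytic), 3 * mc_se + 1e-9)
  # and an exact target count is honoured when requested
  st <- generate_study(sim_config(n_juveniles = 158, seed = 5))
  expect_identical(nrow(st$juveniles), 158L)
  expect_identical(length(unique(st$juveniles$brood_id)), 105L)
})

test_that("feeding treatment is stratified within 100 m elevation bands", {
  st <- generate_study(sim_config(seed = 8))
  juv <- st$juveniles
  broods <- juv[!duplicated(juv$brood_id), ]
  band <- floor(broods$elevation_m / 100)
  for (b in unique(band)) {
    n_fed <- sum(broods$treatment[band == b] == "fed")
    n_ctl <- sum(broods$treatment[band == b] == "control")
    expect_lte(abs(n_fed - n_ctl), 1)
  }
})

test_that("every fix falls inside a duty-cycle window", {
  st <- generate_study(small_config(seed = 31))
  tr <- generate_tracks(st)
  h <- as.numeric(format(tr$fixes$t, "%H")) +
    as.numeric(format(tr$fixes$t, "%M")) / 60
  mo <- as.numeric(format(tr$fixes$t, "%m"))
  in_window <- (mo %in% 2:9 & h >= 3 & h <= 21) |
    (!(mo %in% 2:9) & h >= 5 & h <= 19)
  expect_identical(mean(!in_window), 0)
})

test_that("truth is conserved and departures fall after fledging", {
  st <- generate_study(small_config(seed = 13))
  tr <- truth_report(st)
  expect_identical(nrow(tr), nrow(st$juveniles))
  inc <- tr[tr$fate == "included", ]
  expect_true(all(inc$departure_age_days >
                    st$config$fledging_age_days))
  expect_equal(inc$pfdp_days,
               inc$departure_age_days - st$config$fledging_age_days)
})

test_that("without excursions the first distant fix is the departure fix", {
  cfg <- small_config(seed = 17, excursion_rate_per_day = 0,
                      return_rate_per_day = 0)
  st <- generate_study(cfg)
  tracks <- generate_tracks(st)
  per_id <- split(tracks$fixes, tracks$fixes$id)
  juv <- st$juveniles[st$juveniles$fate == "included", ]
  for (i in seq_len(nrow(juv))) {
    j <- juv[i, ]
    tr <- per_id[[j$individual_id]]
    d <- geodesic_distance_m(tr$lon, tr$lat, j$nest_lon, j$nest_lat)
    first_out <- tr$t[which(d > 2000)[1]]
    expect_identical(first_out, j$departure_t)
  }
})

test_that("fates are realized at the configured frequencies", {
  # pooled over several studies, fate shares approach 64/239 and 17/239
  fates <- unlist(lapply(1:10, function(i)
    generate_study(sim_config(n_nonbreeders_per_year = 0,
                              seed = 300 + i))$juveniles$fate))
  n <- length(fates)
  p_fail <- mean(fates == "failed")
  p_mig <- mean(fates == "migrated")
  expect_lt(abs(p_fail - 64 / 239), 3 * sqrt(64 / 239 * (1 - 64 / 239) / n))
  expect_lt(abs(p_mig - 17 / 239), 3 * sqrt(17 / 239 * (1 - 17 / 239) / n))
})
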