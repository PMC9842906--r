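#' Configuration for a synthetic dispersal study
#'
#' Collects every parameter of the synthetic-study generator. The defaults
#' describe the study conditions the package is designed around: 105 broods
#' (about 158 juveniles) tracked over two seasons across a 524--1129 m
#' elevational gradient, hourly GPS fixes inside two daylight duty cycles
#' (03:00--21:00 UTC February--September, 05:00--19:00 UTC October--January),
#' hatching dates that shift 3.03 days later per 100 m of elevation, and
#' departure ages generated from a linear mixed model with a brood random
#' intercept whose fixed-effect structure matches the departure-age model
#' fitted by the package (feeding treatment, hatching date, hatching rank,
#' elevation, sex, roost distance, year, territory density, and the
#' year x density and sex x density interactions).
#'
#' Continuous covariates enter the departure model in scaled (mean 0, SD 1)
#' units, so its coefficients are in days per SD; the hatching-date model is
#' parameterized in natural units (days per 100 m) and converted at fit time.
#' Variance components are standard deviations in days.
#'
#' @param n_broods Number of broods.
#' @param n_juveniles Optional exact total number of juveniles; brood sizes
#'   are minimally adjusted after sampling to hit this total. `NA` (default)
#'   leaves the sampled total untouched.
#' @param brood_size_dist Probabilities of 1--4 nestlings per brood.
#' @param elevation_range_m Nest elevation bounds, m a.s.l.
#' @param hatch_model List: `intercept_doy` (day of year at mean elevation in
#'   the 2016 reference year), `slope_days_per_100m`, `year_effect_days`
#'   (2017 minus 2016), `density_effect_days` (per SD of territory density),
#'   `brood_sd_days`, `resid_sd_days`.
#' @param departure_model List of fixed-effect coefficients on the scaled
#'   scale (`intercept`, `feeding`, `hatch_date`, `rank_later`,
#'   `rank_singleton`, `elevation`, `sex_male`, `roost_distance`,
#'   `year_2017`, `density`, `year_density`, `sex_density`) plus `brood_sd`
#'   and `resid_sd` in days.
#' @param duty_cycles List of daily recording windows, each
#'   `list(months, start_h, end_h)` in UTC hours.
#' @param fix_interval_h Hours between fixes inside a duty window.
#' @param excursion_rate_per_day Daily probability of a short (<1 day)
#'   pre-departure excursion beyond the natal radius.
#' @param excursion_max_h Maximum excursion duration, hours.
#' @param return_rate_per_day Daily probability (from the fourth day after
#'   departure) of a sub-day return inside the natal radius.
#' @param roost_count_per_year Communal roosts simulated per year.
#' @param roost_min_sep_m Minimum separation between simulated roosts.
#' @param n_nonbreeders_per_year Tagged immature non-breeders (earlier
#'   cohorts) tracked July--September each year; they contribute night
#'   positions to the roost analysis but are not study juveniles.
#' @param p_communal_night Probability that a tracked non-breeder (departed
#'   juvenile or immature) spends a given night at a communal roost rather
#'   than roosting solitarily near its current position.
#' @param solitary_scatter_m Scatter of solitary night spots around the
#'   bird's current daytime position.
#' @param p_fail_pre_departure Probability a juvenile dies or its transmitter
#'   fails before departure (default 64/239).
#' @param p_migrate_pre_departure Probability a juvenile starts migration
#'   before departing (default 17/239).
#' @param p_year_2017 Probability a brood belongs to the second season.
#' @param n_territories_per_year Total conspecific territory centroids per
#'   year (tagged nests plus untagged territories).
#' @param study_center `c(lon, lat)` of the study-area centre.
#' @param study_dims_km Width and height of the rectangular study area (the
#'   defaults enclose roughly 387 km2).
#' @param tagging_age_days Age at which tracking starts.
#' @param fledging_age_days Assumed mean fledging age (55 d).
#' @param density_radius_m Radius of the territory-density count.
#' @param post_departure_days Minimum days of tracking simulated after
#'   departure (also the tracking horizon for failed/migrated birds).
#' @param track_until_monthday Included birds are tracked at least to this
#'   month-day of their hatch year (`"09-30"`, the end of the roosting
#'   season; set to `NA` to truncate at `post_departure_days`).
#' @param seed Integer seed; a fixed seed makes the whole study reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_broods = 105L,
                       n_juveniles = NA_integer_,
                       brood_size_dist = c(0.575, 0.355, 0.06, 0.01),
                       elevation_range_m = c(524, 1129),
                       hatch_model = list(
                         intercept_doy = 132.71,
                         slope_days_per_100m = 3.03,
                         year_effect_days = -5.99,
                         density_effect_days = -0.69,
                         brood_sd_days = 2.3,
                         resid_sd_days = 1.5),
                       departure_model = list(
                         intercept = 79.47,
                         feeding = -3.52,
                         hatch_date = -2.14,
                         rank_later = 1.49,
                         rank_singleton = 0.24,
                         elevation = 0.39,
                         sex_male = 3.26,
                         roost_distance = -2.90,
                         year_2017 = 4.57,
                         density = -4.99,
                         year_density = 4.44,
                         sex_density = 3.38,
                         brood_sd = sqrt(3.20),
                         resid_sd = 8.3),
                       duty_cycles = list(
                         list(months = 2:9, start_h = 3L, end_h = 21L),
                         list(months = c(10L, 11L, 12L, 1L),
                              start_h = 5L, end_h = 19L)),
                       fix_interval_h = 1,
                       excursion_rate_per_day = 0.15,
                       excursion_max_h = 6,
                       return_rate_per_day = 0.03,
                       roost_count_per_year = 10L,
                       roost_min_sep_m = 3000,
                       n_nonbreeders_per_year = 100L,
                       p_communal_night = 0.1,
                       solitary_scatter_m = 500,
                       p_fail_pre_departure = 64 / 239,
                       p_migrate_pre_departure = 17 / 239,
                       p_year_2017 = 0.57,
                       n_territories_per_year = 130L,
                       study_center = c(7.0, 46.8),
                       study_dims_km = c(22, 17.6),
                       tagging_age_days = 39,
                       fledging_age_days = 55,
                       density_radius_m = 2000,
                       post_departure_days = 12,
                       track_until_monthday = "09-30",
                       seed = 1L) {
  cfg <- mget(names(formals()))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$brood_size_dist) - 1) > 1e-8 || any(cfg$brood_size_dist < 0))
    stop("brood_size_dist must be non-negative probabilities summing to 1")
  if (cfg$elevation_range_m[1] >= cfg$elevation_range_m[2])
    stop("elevation_range_m must be (low, high) with low < high")
  sds <- c(cfg$hatch_model$brood_sd_days, cfg$hatch_model$resid_sd_days,
           cfg$departure_model$brood_sd, cfg$departure_model$resid_sd)
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  if (cfg$fix_interval_h <= 0) stop("fix_interval_h must be > 0")
  if (cfg$p_fail_pre_departure < 0 || cfg$p_migrate_pre_departure < 0 ||
      cfg$p_fail_pre_departure + cfg$p_migrate_pre_departure > 1)
    stop("fate probabilities must be >= 0 and sum to <= 1")
  invisible(cfg)
}

duty_window <- function(month, duty_cycles) {
  for (w in duty_cycles) {
    if (month %in% w$months) return(c(w$start_h, w$end_h))
  }
  stop("no duty cycle covers month ", month)
}

# all fix times (POSIXct UTC) for the UTC dates in [date_from, date_to]
duty_fix_times <- function(date_from, date_to, cfg) {
  days <- seq(as.Date(date_from), as.Date(date_to), by = "day")
  months <- as.integer(format(days, "%m"))
  out <- vector("list", length(days))
  for (i in seq_along(days)) {
    w <- duty_window(months[i], cfg$duty_cycles)
    hrs <- seq(w[1], w[2], by = cfg$fix_interval_h)
    out[[i]] <- as.POSIXct(days[i], tz = "UTC") + hrs * 3600
  }
  do.call(c, out)
}

# snap a POSIXct to the nearest duty-cycle fix time
snap_to_duty <- function(t, cfg) {
  out <- t
  for (i in seq_along(t)) {
    grid <- duty_fix_times(as.Date(t[i], tz = "UTC") - 1,
                           as.Date(t[i], tz = "UTC") + 1, cfg)
    out[i] <- grid[which.min(abs(as.numeric(grid) - as.numeric(t[i])))]
  }
  out
}

hatch_datetime <- function(year, hatch_doy) {
  as.POSIXct(paste0(year, "-01-01"), tz = "UTC") + (hatch_doy - 1) * 86400
}

#' Generate a complete synthetic dispersal study
#'
#' Simulates broods (nest locations, elevations, stratified feeding
#' treatment, years), territory centroids and communal roosts, then draws
#' hatching dates and departure ages from the configured generative models
#' and assigns pre-departure fates. Feeding treatment is assigned in a
#' stratified design: within every 100 m elevational band, half of the
#' broods (up to rounding) are supplemented. Each true departure time is
#' realized at the nearest duty-cycle fix time, so the geofence detector can
#' recover it from the simulated trajectory; the pre-snap model draw is kept
#' alongside in the truth table.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_study`: list with `juveniles`
#'   (one row per juvenile, covariates and truth), `territory_centroids`,
#'   `roost_truth`, `study_polygon` (lon/lat ring), `origin`, `scaling`
#'   (mean/SD used for the scaled covariates), `truth` (per-individual
#'   truth table) and `config`.
#' @export
generate_study <- function(config) {
  cfg <- if (inherits(config, "sim_config")) config else
    do.call(sim_config, config)
  set.seed(cfg$seed)
  origin <- cfg$study_center
  w <- cfg$study_dims_km[1] * 500
  h <- cfg$study_dims_km[2] * 500
  poly_xy <- rbind(c(-w, -h), c(w, -h), c(w, h), c(-w, h), c(-w, -h))
  poly_ll <- unproject_local_m(poly_xy[, 1], poly_xy[, 2], origin)

  # broods ------------------------------------------------------------------
  nb <- cfg$n_broods
  sizes <- sample(seq_along(cfg$brood_size_dist), nb, replace = TRUE,
                  prob = cfg$brood_size_dist)
  if (!is.na(cfg$n_juveniles)) {
    while (sum(sizes) > cfg$n_juveniles) {
      i <- sample(which(sizes > 1L), 1L); sizes[i] <- sizes[i] - 1L
    }
    while (sum(sizes) < cfg$n_juveniles) {
      i <- sample(which(sizes < length(cfg$brood_size_dist)), 1L)
      sizes[i] <- sizes[i] + 1L
    }
  }
  nest_x <- runif(nb, -w, w)
  nest_y <- runif(nb, -h, h)
  nest_ll <- unproject_local_m(nest_x, nest_y, origin)
  elev <- runif(nb, cfg$elevation_range_m[1], cfg$elevation_range_m[2])
  year <- ifelse(runif(nb) < cfg$p_year_2017, 2017L, 2016L)

  # stratified feeding treatment per 100 m band
  treatment <- character(nb)
  for (band in unique(floor(elev / 100))) {
    idx <- which(floor(elev / 100) == band)
    n_fed <- floor(length(idx) / 2) + rbinom(1, 1, 0.5) * (length(idx) %% 2)
    fed <- sample(idx, n_fed)
    treatment[fed] <- "fed"
    treatment[setdiff(idx, fed)] <- "control"
  }

  # territory centroids: tagged nests plus untagged territories -------------
  cents <- lapply(sort(unique(year)), function(yr) {
    own <- which(year == yr)
    n_extra <- max(0L, cfg$n_territories_per_year - length(own))
    ex <- cbind(runif(n_extra, -w, w), runif(n_extra, -h, h))
    data.frame(year = yr,
               territory_id = c(paste0("brood_", own),
                                sprintf("terr_%d_%03d", yr, seq_len(n_extra))),
               x = c(nest_x[own], ex[, 1]), y = c(nest_y[own], ex[, 2]))
  })
  cents <- do.call(rbind, cents)
  cll <- unproject_local_m(cents$x, cents$y, origin)
  cents$lon <- cll[, "lon"]; cents$lat <- cll[, "lat"]

  # edge-corrected density per nest (own territory excluded)
  density <- numeric(nb)
  for (i in seq_len(nb)) {
    cc <- cents[cents$year == year[i] &
                  cents$territory_id != paste0("brood_", i), ]
    raw <- sum((cc$x - nest_x[i])^2 + (cc$y - nest_y[i])^2 <=
                 cfg$density_radius_m^2)
    f <- if (dist_to_ring_m(nest_x[i], nest_y[i], poly_xy) >=
             cfg$density_radius_m) 1 else
      disc_area_fraction(c(nest_x[i], nest_y[i]), cfg$density_radius_m,
                         poly_xy)
    density[i] <- raw / f
  }

  # communal roosts per year, minimum separation enforced -------------------
  roosts <- lapply(sort(unique(year)), function(yr) {
    pts <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(pts) < cfg$roost_count_per_year && tries < 2000L) {
      cand <- c(runif(1, -w, w), runif(1, -h, h))
      if (nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >=
          cfg$roost_min_sep_m) {
        pts <- rbind(pts, cand)
      }
      tries <- tries + 1L
    }
    ll <- unproject_local_m(pts[, 1], pts[, 2], origin)
    data.frame(year = yr, roost_id = seq_len(nrow(pts)),
               x = pts[, 1], y = pts[, 2], lon = ll[, 1], lat = ll[, 2])
  })
  roosts <- do.call(rbind, roosts)

  roost_dist <- vapply(seq_len(nb), function(i) {
    rr <- roosts[roosts$year == year[i], ]
    min(sqrt((rr$x - nest_x[i])^2 + (rr$y - nest_y[i])^2))
  }, numeric(1))

  # hatching dates (days per 100 m parameterization) ------------------------
  hm <- cfg$hatch_model
  dens_s_brood <- as.numeric(scale(density))
  brood_re_h <- rnorm(nb, 0, hm$brood_sd_days)
  hatch_brood <- hm$intercept_doy +
    hm$slope_days_per_100m * (elev - mean(elev)) / 100 +
    hm$year_effect_days * (year == 2017L) +
    hm$density_effect_days * dens_s_brood + brood_re_h

  # expand to juveniles ------------------------------------------------------
  brood_of <- rep(seq_len(nb), sizes)
  nj <- length(brood_of)
  hatch_doy <- hatch_brood[brood_of] + rnorm(nj, 0, hm$resid_sd_days)
  sex <- sample(c("F", "M"), nj, replace = TRUE)
  rank <- character(nj)
  for (b in seq_len(nb)) {
    idx <- which(brood_of == b)
    if (length(idx) == 1L) rank[idx] <- "singleton" else {
      rank[idx] <- "later"
      rank[idx[which.min(hatch_doy[idx])]] <- "first"
    }
  }

  # morphometrics consistent with hatch order -------------------------------
  meas_doy <- vapply(seq_len(nb), function(b)
    max(hatch_doy[brood_of == b]) + cfg$tagging_age_days, numeric(1))
  age_meas <- meas_doy[brood_of] - hatch_doy
  curve <- default_growth_curve()
  p8 <- curve$value(age_meas)
  wing <- 6.5 * age_meas + rnorm(nj, 0, 0.5)
  tarsus <- rnorm(nj, 58, 2.5)
  mass <- 20 * tarsus + rnorm(nj, 0, 60)

  # departure ages from the scaled-coefficient mixed model ------------------
  dm <- cfg$departure_model
  sc <- list(
    hatch_doy = c(mean = mean(hatch_doy), sd = sd(hatch_doy)),
    elevation_m = c(mean = mean(elev[brood_of]), sd = sd(elev[brood_of])),
    roost_distance_m = c(mean = mean(roost_dist[brood_of]),
                         sd = sd(roost_dist[brood_of])),
    territory_density = c(mean = mean(density[brood_of]),
                          sd = sd(density[brood_of])))
  zs <- function(x, nm) (x - sc[[nm]]["mean"]) / sc[[nm]]["sd"]
  hatch_s <- zs(hatch_doy, "hatch_doy")
  elev_s <- zs(elev[brood_of], "elevation_m")
  roost_s <- zs(roost_dist[brood_of], "roost_distance_m")
  dens_s <- zs(density[brood_of], "territory_density")
  male <- as.numeric(sex == "M")
  fed <- as.numeric(treatment[brood_of] == "fed")
  y17 <- as.numeric(year[brood_of] == 2017L)
  lp <- dm$intercept + dm$feeding * fed + dm$hatch_date * hatch_s +
    dm$rank_later * (rank == "later") +
    dm$rank_singleton * (rank == "singleton") +
    dm$elevation * elev_s + dm$sex_male * male +
    dm$roost_distance * roost_s + dm$year_2017 * y17 +
    dm$density * dens_s + dm$year_density * y17 * dens_s +
    dm$sex_density * male * dens_s
  brood_re_d <- rnorm(nb, 0, dm$brood_sd)
  age_model <- lp + brood_re_d[brood_of] + rnorm(nj, 0, dm$resid_sd)
  age_model <- pmax(age_model, cfg$fledging_age_days + 0.5)

  hdt <- hatch_datetime(year[brood_of], hatch_doy)
  dep_t <- snap_to_duty(hdt + age_model * 86400, cfg)
  dep_age <- as.numeric(difftime(dep_t, hdt, units = "days"))

  fate_draw <- runif(nj)
  fate <- ifelse(fate_draw < cfg$p_fail_pre_departure, "failed",
                 ifelse(fate_draw < cfg$p_fail_pre_departure +
                          cfg$p_migrate_pre_departure, "migrated", "included"))

  juveniles <- data.frame(
    individual_id = sprintf("juv_%03d", seq_len(nj)),
    brood_id = paste0("brood_", brood_of),
    year = year[brood_of],
    nest_lon = nest_ll[brood_of, "lon"], nest_lat = nest_ll[brood_of, "lat"],
    nest_x = nest_x[brood_of], nest_y = nest_y[brood_of],
    elevation_m = elev[brood_of],
    treatment = factor(treatment[brood_of], levels = c("control", "fed")),
    sex = factor(sex, levels = c("F", "M")),
    hatching_rank = factor(rank, levels = c("first", "later", "singleton")),
    n_siblings = sizes[brood_of] - 1L,
    hatch_doy = hatch_doy,
    hatching_date = as.Date(paste0(year[brood_of], "-01-01")) +
      floor(hatch_doy) - 1L,
    mass_g = mass, tarsus_mm = tarsus, p8_mm = p8, wing_mm = wing,
    territory_density = density[brood_of],
    roost_distance_m = roost_dist[brood_of],
    fate = fate,
    departure_age_days = dep_age,
    stringsAsFactors = FALSE
  )
  juveniles$departure_t <- dep_t

  truth <- data.frame(
    individual_id = juveniles$individual_id,
    brood_id = juveniles$brood_id,
    fate = fate,
    departure_t = dep_t,
    departure_age_days = dep_age,
    departure_age_model = age_model,
    pfdp_days = dep_age - cfg$fledging_age_days,
    stringsAsFactors = FALSE
  )

  structure(list(
    juveniles = juveniles,
    territory_centroids = cents,
    roost_truth = roosts,
    study_polygon = as.data.frame(poly_ll),
    study_polygon_xy = poly_xy,
    origin = origin,
    scaling = sc,
    truth = truth,
    truth_effects = list(hatch_model = hm, departure_model = dm),
    config = cfg
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", nrow(x$juveniles), " juveniles in ",
      length(unique(x$juveniles$brood_id)), " broods, ",
      nrow(x$roost_truth), " roosts, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Per-individual ground truth of a synthetic study
#'
#' @param study A `synthetic_study`.
#' @return Data frame with one row per juvenile: fate, true departure
#'   timestamp and age, the pre-snap model draw and the post-fledging
#'   dependence period.
#' @export
truth_report <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  study$truth
}

#' Build a tagging roster with fixed exclusion counts
#'
#' @param n_tagged Total tagged individuals.
#' @param n_failed Number that died / lost their transmitter before
#'   departure.
#' @param n_migrated Number that started migration before departing.
#' @return Data frame `individual_id`, `fate` with mutually exclusive fates
#'   (`failed`, `migrated`, `included`).
#' @export
generate_exclusion_roster <- function(n_tagged, n_failed, n_migrated) {
  if (any(c(n_tagged, n_failed, n_migrated) < 0))
    stop("counts must be non-negative")
  if (n_failed + n_migrated > n_tagged)
    stop("n_failed + n_migrated exceeds n_tagged")
  data.frame(
    individual_id = sprintf("bird_%03d", seq_len(n_tagged)),
    fate = rep(c("failed", "migrated", "included"),
               c(n_failed, n_migrated, n_tagged - n_failed - n_migrated)),
    stringsAsFactors = FALSE
  )
}
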