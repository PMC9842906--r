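#' Simulate GPS trajectories for a synthetic study
#'
#' Realizes each juvenile's movement as duty-cycled hourly fixes: a bounded
#' nest-centred random walk before departure (with occasional sub-day
#' excursions beyond the natal radius), an abrupt biased walk away from the
#' nest from the true departure time onwards, night-adjacent fixes of
#' departed birds snapped to the year's communal roosts, and rare sub-day
#' returns into the natal radius. Birds that fail before departure get a
#' truncated track; birds that migrate before departing leave on a directed
#' >50 km displacement before any qualifying absence. Deterministic given
#' the study's seed.
#'
#' @param study A `synthetic_study` from [generate_study()].
#' @param config A [sim_config()]; defaults to the study's own.
#' @return A `track_set` covering every juvenile.
#' @export
generate_tracks <- function(study, config = study$config) {
  stopifnot(inherits(study, "synthetic_study"))
  cfg <- config
  set.seed(cfg$seed + 1000L)
  juv <- study$juveniles
  roosts <- study$roost_truth
  # weight nightly roost choice inversely to availability so that roosts
  # sitting near many nests (excluded from those birds' menus) still
  # receive comparable total use across the population
  roosts$avail <- vapply(seq_len(nrow(roosts)), function(r) {
    b <- juv[juv$year == roosts$year[r], ]
    sum(sqrt((b$nest_x - roosts$x[r])^2 + (b$nest_y - roosts$y[r])^2) > 3000)
  }, numeric(1))
  pieces <- vector("list", nrow(juv))
  for (i in seq_len(nrow(juv))) {
    pieces[[i]] <- simulate_one_track(juv[i, ], roosts, cfg)
  }
  # tagged immature non-breeders from earlier cohorts: tracked through the
  # roosting season, they dominate the night-position pool
  imm <- list()
  if (cfg$n_nonbreeders_per_year > 0) {
    poly_xy <- study$study_polygon_xy
    for (yr in sort(unique(juv$year))) {
      for (b in seq_len(cfg$n_nonbreeders_per_year)) {
        imm[[length(imm) + 1L]] <- simulate_nonbreeder_track(
          sprintf("imm_%d_%03d", yr, b), yr, roosts, poly_xy, cfg)
      }
    }
  }
  fixes <- do.call(rbind, c(pieces, imm))
  ll <- unproject_local_m(fixes$px, fixes$py, study$origin)
  fixes$lon <- ll[, "lon"]
  fixes$lat <- ll[, "lat"]
  as_track_set(fixes[, c("id", "t", "lon", "lat")], source = "simulated")
}

simulate_one_track <- function(j, roosts, cfg) {
  hdt <- hatch_datetime(j$year, j$hatch_doy)
  dep_t <- j$departure_t
  t_start <- hdt + cfg$tagging_age_days * 86400
  season_end <- if (is.na(cfg$track_until_monthday)) dep_t else
    as.POSIXct(paste0(j$year, "-", cfg$track_until_monthday, " 23:59:59"),
               tz = "UTC")
  t_end <- switch(j$fate,
    included = max(dep_t + cfg$post_departure_days * 86400, season_end),
    failed   = max(t_start + 86400, dep_t - runif(1, 2, 15) * 86400),
    migrated = dep_t + 4 * 86400)
  migr_t <- if (j$fate == "migrated")
    max(t_start + 86400, dep_t - runif(1, 3, 8) * 86400) else NA

  tt <- duty_fix_times(as.Date(t_start, tz = "UTC"),
                       as.Date(t_end, tz = "UTC"), cfg)
  tt <- tt[tt >= t_start & tt <= t_end]
  n <- length(tt)
  if (n == 0L) {
    return(data.frame(id = character(0), t = as.POSIXct(character(0)),
                      px = numeric(0), py = numeric(0)))
  }

  # nest-centred bounded random walk (AR(1), radius clipped at 1.5 km)
  dx <- as.numeric(stats::filter(rnorm(n, 0, 350), 0.7, "recursive"))
  dy <- as.numeric(stats::filter(rnorm(n, 0, 350), 0.7, "recursive"))
  r <- sqrt(dx^2 + dy^2)
  shrink <- pmin(1, 1500 / pmax(r, 1))
  dx <- dx * shrink; dy <- dy * shrink

  pre <- tt < dep_t & (is.na(migr_t) | tt < migr_t)

  # sub-day excursions beyond the natal radius on pre-departure days
  for (d in unique(as.Date(tt[pre], tz = "UTC"))) {
    if (runif(1) >= cfg$excursion_rate_per_day) next
    day <- as.Date(d, origin = "1970-01-01")
    w <- duty_window(as.integer(format(day, "%m")), cfg$duty_cycles)
    dur <- runif(1, cfg$fix_interval_h, cfg$excursion_max_h)
    s_h <- runif(1, w[1], max(w[1], w[2] - dur))
    hrs <- as.numeric(tt - as.POSIXct(day, tz = "UTC")) / 3600
    sel <- pre & as.Date(tt, tz = "UTC") == day & hrs >= s_h & hrs <= s_h + dur
    if (!any(sel)) next
    ang <- runif(1, 0, 2 * pi)
    dist <- runif(1, 2300, 4000)
    dx[sel] <- dist * cos(ang) + rnorm(sum(sel), 0, 50)
    dy[sel] <- dist * sin(ang) + rnorm(sum(sel), 0, 50)
  }

  # nights before departure are spent at the nest
  dates_all <- as.Date(tt, tz = "UTC")
  for (d in unique(dates_all)) {
    day_idx <- which(dates_all == d)
    for (k in c(day_idx[1], day_idx[length(day_idx)])) {
      if (pre[k]) {
        dx[k] <- rnorm(1, 0, 8); dy[k] <- rnorm(1, 0, 8)
      }
    }
  }

  if (j$fate == "migrated") {
    mig <- tt >= migr_t
    days_m <- as.numeric(difftime(tt[mig], migr_t, units = "days"))
    ang <- runif(1, 0, 2 * pi)
    dist <- 2500 + 45000 * days_m
    dx[mig] <- dist * cos(ang) + rnorm(sum(mig), 0, 200)
    dy[mig] <- dist * sin(ang) + rnorm(sum(mig), 0, 200)
  } else if (j$fate == "included") {
    post <- tt >= dep_t
    days_p <- as.numeric(difftime(tt[post], dep_t, units = "days"))
    ang0 <- runif(1, 0, 2 * pi)
    ang <- ang0 + rnorm(sum(post), 0, 0.03)
    # rapid initial displacement, then regional wandering
    dist <- 2300 + 2500 * pmin(days_p, 10) + 150 * pmax(days_p - 10, 0)
    dx[post] <- dist * cos(ang)
    dy[post] <- dist * sin(ang)

    # rare sub-day returns, only after the qualifying absence is complete
    post_days <- unique(as.Date(tt[post], tz = "UTC"))
    dep_day <- as.Date(dep_t, tz = "UTC")
    for (d in post_days[post_days > dep_day + 3]) {
      if (runif(1) >= cfg$return_rate_per_day) next
      day <- as.Date(d, origin = "1970-01-01")
      w <- duty_window(as.integer(format(day, "%m")), cfg$duty_cycles)
      dur <- runif(1, 1, min(12, w[2] - w[1] - 1))
      s_h <- runif(1, w[1], w[2] - dur)
      hrs <- as.numeric(tt - as.POSIXct(day, tz = "UTC")) / 3600
      sel <- post & as.Date(tt, tz = "UTC") == day &
        hrs >= s_h & hrs <= s_h + dur
      rr <- runif(sum(sel), 0, 1500); aa <- runif(sum(sel), 0, 2 * pi)
      dx[sel] <- rr * cos(aa); dy[sel] <- rr * sin(aa)
    }

    # night-adjacent fixes of departed birds: some nights at a communal
    # roost (re-drawn per night, one spot within the roost wood), the rest
    # solitary near the bird's current position; both fixes of one night
    # share the spot
    rr <- roosts[roosts$year == j$year, ]
    rr <- rr[sqrt((rr$x - j$nest_x)^2 + (rr$y - j$nest_y)^2) > 3000 &
               rr$avail > 0, ]
    rw <- if (nrow(rr)) (1 / rr$avail) / sum(1 / rr$avail) else numeric(0)
    dates <- as.Date(tt, tz = "UTC")
    for (d in unique(dates[post])) {
      day_idx <- which(dates == d)
      last_i <- day_idx[length(day_idx)]
      nxt <- which(dates == d + 1)
      first_i <- if (length(nxt)) nxt[1] else NA_integer_
      night_idx <- c(last_i, first_i)
      night_idx <- night_idx[!is.na(night_idx) & tt[night_idx] >= dep_t]
      if (!length(night_idx)) next
      if (nrow(rr) && runif(1) < cfg$p_communal_night) {
        best <- sample(nrow(rr), 1L, prob = rw)
        spot_x <- rr$x[best] + rnorm(1, 0, 80)
        spot_y <- rr$y[best] + rnorm(1, 0, 80)
      } else {
        k1 <- night_idx[1]
        spot_x <- j$nest_x + dx[k1] + rnorm(1, 0, cfg$solitary_scatter_m)
        spot_y <- j$nest_y + dy[k1] + rnorm(1, 0, cfg$solitary_scatter_m)
        # a solitary night must not re-enter the natal radius
        rad <- sqrt((spot_x - j$nest_x)^2 + (spot_y - j$nest_y)^2)
        if (rad < 2100) {
          sc <- (2100 + runif(1, 0, 300)) / max(rad, 1)
          spot_x <- j$nest_x + (spot_x - j$nest_x) * sc
          spot_y <- j$nest_y + (spot_y - j$nest_y) * sc
        }
      }
      for (k in night_idx) {
        dx[k] <- spot_x - j$nest_x + rnorm(1, 0, 10)
        dy[k] <- spot_y - j$nest_y + rnorm(1, 0, 10)
      }
    }
  }

  data.frame(id = j$individual_id, t = tt,
             px = j$nest_x + dx, py = j$nest_y + dy,
             stringsAsFactors = FALSE)
}

# immature non-breeder: regional wandering with four day fixes, communal or
# solitary nights on the day-boundary fixes
simulate_nonbreeder_track <- function(id, year, roosts, poly_xy, cfg) {
  from <- as.Date(paste0(year, "-07-01"))
  to <- as.Date(paste0(year, "-09-30"))
  tt <- duty_fix_times(from, to, cfg)
  hr <- as.numeric(format(tt, "%H"))
  tt <- tt[hr %in% c(3, 9, 15, 21)]
  days <- as.Date(tt, tz = "UTC")
  udays <- unique(days)
  w <- max(abs(poly_xy[, 1])); h <- max(abs(poly_xy[, 2]))
  cx <- runif(1, -w, w) + cumsum(c(0, rnorm(length(udays) - 1, 0, 300)))
  cy <- runif(1, -h, h) + cumsum(c(0, rnorm(length(udays) - 1, 0, 300)))
  di <- match(days, udays)
  px <- cx[di] + rnorm(length(tt), 0, 800)
  py <- cy[di] + rnorm(length(tt), 0, 800)
  rr <- roosts[roosts$year == year, ]
  for (d in udays) {
    day_idx <- which(days == d)
    last_i <- day_idx[length(day_idx)]
    nxt <- which(days == d + 1)
    first_i <- if (length(nxt)) nxt[1] else NA_integer_
    night_idx <- c(last_i, first_i)
    night_idx <- night_idx[!is.na(night_idx)]
    ci <- di[day_idx[1]]
    if (nrow(rr) && runif(1) < cfg$p_communal_night) {
      best <- sample(nrow(rr), 1L)
      spot_x <- rr$x[best] + rnorm(1, 0, 80)
      spot_y <- rr$y[best] + rnorm(1, 0, 80)
    } else {
      spot_x <- cx[ci] + rnorm(1, 0, cfg$solitary_scatter_m)
      spot_y <- cy[ci] + rnorm(1, 0, cfg$solitary_scatter_m)
    }
    for (k in night_idx) {
      px[k] <- spot_x + rnorm(1, 0, 10)
      py[k] <- spot_y + rnorm(1, 0, 10)
    }
  }
  data.frame(id = id, t = tt, px = px, py = py, stringsAsFactors = FALSE)
}
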