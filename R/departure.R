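#' Parameters of the geofence departure rule
#'
#' Departure to natal dispersal is scored when a juvenile first stays
#' continuously outside a nest-centred radius for longer than a temporal
#' threshold. Defaults: 2 km radius, more than 2 days outside (strictly),
#' with sensitivity thresholds of 1/2/3/5/9 days and an assumed mean
#' fledging age of 55 days for the post-fledging dependence period.
#'
#' @param radius_m Spatial threshold in metres around the nest.
#' @param min_outside_days Temporal threshold in days; a maximal outside-run
#'   qualifies when its duration is strictly greater than this.
#' @param validation_thresholds_days Thresholds for the sensitivity table.
#' @param fledging_age_days Assumed fledging age used for the PFDP.
#' @return A validated list of class `departure_params`.
#' @export
departure_params <- function(radius_m = 2000,
                             min_outside_days = 2,
                             validation_thresholds_days = c(1, 2, 3, 5, 9),
                             fledging_age_days = 55) {
  stopifnot(radius_m > 0, min_outside_days > 0, fledging_age_days > 0,
            all(validation_thresholds_days > 0))
  structure(list(radius_m = radius_m,
                 min_outside_days = min_outside_days,
                 validation_thresholds_days = sort(validation_thresholds_days),
                 fledging_age_days = fledging_age_days),
            class = "departure_params")
}

#' Maximal runs of fixes outside the natal radius
#'
#' A run is a maximal sequence of consecutive fixes all strictly farther
#' than `radius_m` from the nest; a single inside fix terminates it. Run
#' duration is measured fix-to-fix (last fix time minus first fix time), so
#' gaps between fixes -- nights, outages -- count as outside time exactly
#' when both flanking fixes are outside.
#'
#' @param track Data frame of one individual's fixes (`t`, `lon`, `lat`),
#'   time-ordered.
#' @param nest Length-2 numeric `c(lon, lat)`.
#' @param radius_m Radius in metres.
#' @return Data frame with one row per run: `start_t`, `end_t`,
#'   `duration_days`, `n_fixes`.
#' @export
outside_runs <- function(track, nest, radius_m) {
  empty <- data.frame(start_t = as.POSIXct(character(0), tz = "UTC"),
                      end_t = as.POSIXct(character(0), tz = "UTC"),
                      duration_days = numeric(0), n_fixes = integer(0))
  if (is.null(track) || nrow(track) == 0L) return(empty)
  d <- geodesic_distance_m(track$lon, track$lat, nest[1], nest[2])
  out <- d > radius_m
  r <- rle(out)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(empty)
  s <- starts[keep]; e <- ends[keep]
  data.frame(
    start_t = track$t[s],
    end_t = track$t[e],
    duration_days = as.numeric(difftime(track$t[e], track$t[s],
                                        units = "days")),
    n_fixes = e - s + 1L
  )
}

#' Detect departure to natal dispersal for one individual
#'
#' The departure run is the first maximal outside-run whose duration
#' strictly exceeds `min_outside_days`; departure time is anchored at the
#' first fix of that run, and departure age is continuous days since
#' hatching. If no run qualifies before the track ends the individual is
#' censored.
#'
#' @param track One individual's time-ordered fixes (`t`, `lon`, `lat`).
#' @param juvenile One-row data frame (or list) with at least `nest_lon`,
#'   `nest_lat`, `hatching_date` (Date) or `hatch_doy` + `year`, and
#'   optionally `individual_id`.
#' @param params A [departure_params()].
#' @return One-row data frame: `individual_id`, `status` (`departed` or
#'   `censored_no_departure`), `departure_t`, `departure_age_days`,
#'   `pfdp_days`, plus the thresholds used.
#' @export
detect_departure <- function(track, juvenile, params = departure_params()) {
  hdt <- juvenile_hatch_datetime(juvenile)
  id <- if (!is.null(juvenile$individual_id)) juvenile$individual_id
        else NA_character_
  if (nrow(track) > 0 &&
      as.numeric(difftime(track$t[1], hdt, units = "days")) > 365)
    stop("hatching date more than a year before the first fix: ",
         "implausible metadata for ", id)
  runs <- outside_runs(track, c(juvenile$nest_lon, juvenile$nest_lat),
                       params$radius_m)
  hit <- which(runs$duration_days > params$min_outside_days)
  if (length(hit)) {
    dep_t <- runs$start_t[hit[1]]
    age <- as.numeric(difftime(dep_t, hdt, units = "days"))
    data.frame(individual_id = id, status = "departed",
               departure_t = dep_t, departure_age_days = age,
               pfdp_days = age - params$fledging_age_days,
               radius_m = params$radius_m,
               min_outside_days = params$min_outside_days,
               stringsAsFactors = FALSE)
  } else {
    data.frame(individual_id = id, status = "censored_no_departure",
               departure_t = as.POSIXct(NA, tz = "UTC"),
               departure_age_days = NA_real_, pfdp_days = NA_real_,
               radius_m = params$radius_m,
               min_outside_days = params$min_outside_days,
               stringsAsFactors = FALSE)
  }
}

juvenile_hatch_datetime <- function(juvenile) {
  if (!is.null(juvenile$hatch_doy) && !is.null(juvenile$year)) {
    hatch_datetime(juvenile$year, juvenile$hatch_doy)
  } else if (!is.null(juvenile$hatching_date)) {
    as.POSIXct(as.Date(juvenile$hatching_date), tz = "UTC")
  } else {
    stop("juvenile record needs hatching_date or hatch_doy + year")
  }
}

#' Detect departures for every individual in a track set
#'
#' @param tracks A `track_set`.
#' @param juveniles Data frame of juvenile records (one row per individual,
#'   keyed by `individual_id`).
#' @param params A [departure_params()].
#' @return Data frame with one row per juvenile, as [detect_departure()].
#' @export
detect_departures <- function(tracks, juveniles,
                              params = departure_params()) {
  per_id <- split_tracks(tracks)
  out <- lapply(seq_len(nrow(juveniles)), function(i) {
    j <- juveniles[i, ]
    tr <- per_id[[j$individual_id]]
    if (is.null(tr)) tr <- data.frame(t = as.POSIXct(character(0)),
                                      lon = numeric(0), lat = numeric(0))
    detect_departure(tr, j, params)
  })
  do.call(rbind, out)
}

#' Departure-age sensitivity to the temporal threshold
#'
#' Re-scores departure at each validation threshold. Because a longer
#' required absence can only be met by the same or a later run, estimated
#' departure age is non-decreasing in the threshold.
#'
#' @inheritParams detect_departure
#' @return Data frame: `threshold_days`, `status`, `departure_age_days`.
#' @export
threshold_sensitivity <- function(track, juvenile,
                                  params = departure_params()) {
  hdt <- juvenile_hatch_datetime(juvenile)
  runs <- outside_runs(track, c(juvenile$nest_lon, juvenile$nest_lat),
                       params$radius_m)
  out <- lapply(params$validation_thresholds_days, function(thr) {
    hit <- which(runs$duration_days > thr)
    if (length(hit)) {
      age <- as.numeric(difftime(runs$start_t[hit[1]], hdt, units = "days"))
      data.frame(threshold_days = thr, status = "departed",
                 departure_age_days = age)
    } else {
      data.frame(threshold_days = thr, status = "censored_no_departure",
                 departure_age_days = NA_real_)
    }
  })
  do.call(rbind, out)
}

#' Count post-departure full-day returns to the natal radius
#'
#' Number of UTC calendar days strictly after the departure day on which
#' the individual was located at least once and every fix lay inside the
#' natal radius. Partial-day returns do not count.
#'
#' @param track One individual's fixes.
#' @param nest `c(lon, lat)`.
#' @param radius_m Radius in metres.
#' @param departure_t Departure timestamp.
#' @return Integer count.
#' @export
count_full_day_returns <- function(track, nest, radius_m, departure_t) {
  post <- track[track$t > departure_t, , drop = FALSE]
  if (nrow(post) == 0L) return(0L)
  post <- post[as.Date(post$t, tz = "UTC") >
                 as.Date(departure_t, tz = "UTC"), , drop = FALSE]
  if (nrow(post) == 0L) return(0L)
  inside <- geodesic_distance_m(post$lon, post$lat, nest[1], nest[2]) <=
    radius_m
  day <- as.Date(post$t, tz = "UTC")
  sum(vapply(split(inside, day), all, logical(1)))
}

#' Apply the pre-departure exclusion filters
#'
#' Removes individuals that died or lost their transmitter before departure
#' and individuals that started migration before departing, then keeps only
#' scored departures. Counts per category are reported so that the filter
#' chain conserves individuals (tagged = included + failed + migrated +
#' censored).
#'
#' @param roster Data frame `individual_id`, `fate` with fates in
#'   `included`, `failed`, `migrated`.
#' @param results Optional data frame of [detect_departures()] results; when
#'   supplied, only `status == "departed"` rows survive and statuses of
#'   excluded birds are rewritten to `excluded_failed` / `excluded_migrated`.
#' @return List: `analysis_set` (data frame) and `counts` (named integer
#'   vector: tagged, failed, migrated, censored, included).
#' @export
apply_exclusions <- function(roster, results = NULL) {
  stopifnot(all(c("individual_id", "fate") %in% names(roster)))
  bad <- setdiff(unique(roster$fate), c("included", "failed", "migrated"))
  if (length(bad)) stop("unknown fate flag(s): ", paste(bad, collapse = ", "))
  if (is.null(results)) {
    results <- data.frame(individual_id = roster$individual_id,
                          status = rep("departed", nrow(roster)),
                          stringsAsFactors = FALSE)
  }
  m <- merge(roster, results, by = "individual_id", all.x = TRUE)
  m$status[is.na(m$status)] <- "censored_no_departure"
  m$status[m$fate == "failed"] <- "excluded_failed"
  m$status[m$fate == "migrated"] <- "excluded_migrated"
  keep <- m[m$status == "departed", , drop = FALSE]
  counts <- c(tagged = nrow(roster),
              failed = sum(m$status == "excluded_failed"),
              migrated = sum(m$status == "excluded_migrated"),
              censored = sum(m$status == "censored_no_departure"),
              included = nrow(keep))
  list(analysis_set = keep, counts = counts)
}

#' Restrict a track set to post-departure (independent) fixes
#'
#' Keeps, for every individual with a scored departure, only the fixes at or
#' after its departure time. Pre-departure juveniles still roost at the
#' natal site, so communal-roost identification works on the independent
#' portion of the trajectories. Juveniles without a scored departure are
#' dropped; individuals not present in the departure table at all (tagged
#' immature non-breeders from earlier cohorts) are already independent and
#' are kept in full.
#'
#' @param tracks A `track_set`.
#' @param departures Data frame from [detect_departures()] (`individual_id`,
#'   `status`, `departure_t`).
#' @return A `track_set`.
#' @export
post_departure_tracks <- function(tracks, departures) {
  dep <- departures[departures$status == "departed", , drop = FALSE]
  fx <- tracks$fixes
  m <- match(fx$id, dep$individual_id)
  juvenile <- fx$id %in% departures$individual_id
  keep <- (!juvenile) | (!is.na(m) & fx$t >= dep$departure_t[m])
  as_track_set(fx[keep, , drop = FALSE],
               source = paste0(tracks$provenance$source, " [post-departure]"))
}

#' Flag migration before departure from a trajectory
#'
#' Stand-in migration criterion for rosters without field fate flags: the
#' bird reaches a net displacement from the nest beyond `min_km` with no
#' later return inside the natal radius, and does so before its first
#' continuous absence has even lasted the departure threshold -- i.e. the
#' first qualifying absence is already long-distance directed movement
#' rather than settling in the wider natal area.
#'
#' @param track One individual's fixes.
#' @param nest `c(lon, lat)`.
#' @param min_km Displacement threshold (default 50 km).
#' @param params A [departure_params()].
#' @return Logical.
#' @export
flag_migration <- function(track, nest, min_km = 50,
                           params = departure_params()) {
  if (nrow(track) == 0L) return(FALSE)
  d <- geodesic_distance_m(track$lon, track$lat, nest[1], nest[2])
  far <- which(d > min_km * 1000)
  if (!length(far)) return(FALSE)
  first_far <- far[1]
  if (any(d[first_far:length(d)] <= params$radius_m)) return(FALSE)
  runs <- outside_runs(track, nest, params$radius_m)
  qual <- runs[runs$duration_days > params$min_outside_days, , drop = FALSE]
  if (nrow(qual) == 0L) return(TRUE)
  track$t[first_far] <=
    qual$start_t[1] + params$min_outside_days * 86400
}
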