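# shared fixture builders ----------------------------------------------------

# a nest and a local frame for constructed tracks
NEST <- c(7.0, 46.8)

# build a track from times (hours since an origin) and metric offsets from
# the nest; offsets are (east, north) metres
make_track <- function(hours, east_m, north_m, nest = NEST,
                       origin_time = as.POSIXct("2016-07-01 00:00:00",
                                                tz = "UTC"),
                       id = "bird1") {
  ll <- unproject_local_m(east_m, north_m, nest)
  data.frame(id = id, t = origin_time + hours * 3600,
             lon = ll[, "lon"], lat = ll[, "lat"],
             stringsAsFactors = FALSE)
}

# square polygon of half-width `half_m` metres around a lon/lat centre
square_polygon <- function(center = NEST, half_m = 10000) {
  xy <- rbind(c(-half_m, -half_m), c(half_m, -half_m),
              c(half_m, half_m), c(-half_m, half_m), c(-half_m, -half_m))
  ll <- unproject_local_m(xy[, 1], xy[, 2], center)
  as.matrix(ll)
}

# independent haversine distance (spherical earth), used as a geodesic oracle
haversine_m <- function(lon1, lat1, lon2, lat2, r = 6371008.8) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# exhaustive window-scan departure oracle: earliest fix index i such that
# some j >= i has all fixes i..j outside the radius and t_j - t_i > thr days
oracle_departure <- function(track, nest, radius_m, thr_days) {
  d <- geodesic_distance_m(track$lon, track$lat, nest[1], nest[2])
  out <- d > radius_m
  n <- nrow(track)
  for (i in seq_len(n)) {
    if (!out[i]) next
    j <- i
    while (j < n && out[j + 1]) j <- j + 1
    if (as.numeric(difftime(track$t[j], track$t[i], units = "days")) >
        thr_days) {
      return(track$t[i])
    }
  }
  as.POSIXct(NA, tz = "UTC")
}

# brute-force revisit oracle (no spatial hashing)
oracle_revisits <- function(focal, night, radius_m) {
  nt <- !duplicated(night$id)
  vapply(seq_len(nrow(focal)), function(i) {
    inside <- (night$x - focal$x[i])^2 + (night$y - focal$y[i])^2 <=
      radius_m^2
    prev <- c(FALSE, inside[-length(inside)])
    prev[nt] <- FALSE
    sum(inside & !prev)
  }, numeric(1))
}

# small deterministic study for pipeline-level tests
small_config <- function(seed = 42L, ...) {
  sim_config(n_broods = 30L, n_nonbreeders_per_year = 20L,
             p_year_2017 = 0, seed = seed, ...)
}
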