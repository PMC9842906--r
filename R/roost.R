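#' Parameters of the communal-roost pipeline
#'
#' Roosts are located from night-time positions of non-breeders inside the
#' buffered study area: revisitation is scored as entry events into a 50 m
#' disc around each position, the top 5\% most revisited positions are kept
#' (ties at the cutoff included), and k-means groups them into 10 clusters
#' per year. Because the transmitters record only in daylight duty cycles,
#' the default night rule proxies the roost position by the day-boundary
#' fixes: the last fix of each UTC day paired with the first fix of the
#' following day. A fixed clock window (19:00--05:00 UTC) is available as an
#' alternative.
#'
#' @param revisit_radius_m Revisit disc radius (default 50 m).
#' @param top_fraction Fraction of positions kept (default 0.05).
#' @param k_clusters Clusters per year (default 10).
#' @param season_months Months pooled per year (default July--September).
#' @param study_buffer_m Outward buffer on the study polygon (default 10 km).
#' @param night_rule `"day_boundary"` or `"clock_window"`.
#' @param night_window_utc For the clock-window rule: `c(start_h, end_h)`
#'   wrapping midnight.
#' @param seed Seed for the k-means restarts.
#' @return A validated list of class `roost_params`.
#' @export
roost_params <- function(revisit_radius_m = 50,
                         top_fraction = 0.05,
                         k_clusters = 10L,
                         season_months = 7:9,
                         study_buffer_m = 10000,
                         night_rule = c("day_boundary", "clock_window"),
                         night_window_utc = c(19, 5),
                         seed = 1L) {
  stopifnot(top_fraction > 0, top_fraction <= 1, k_clusters >= 1,
            revisit_radius_m > 0, study_buffer_m >= 0)
  structure(list(revisit_radius_m = revisit_radius_m,
                 top_fraction = top_fraction,
                 k_clusters = as.integer(k_clusters),
                 season_months = season_months,
                 study_buffer_m = study_buffer_m,
                 night_rule = match.arg(night_rule),
                 night_window_utc = night_window_utc,
                 seed = as.integer(seed)),
            class = "roost_params")
}

#' Night-time positions inside the buffered study area
#'
#' Selects the fixes that proxy where a bird spent the night, restricted to
#' one calendar year's season and to the study polygon dilated by the
#' buffer. Under the `day_boundary` rule, each tracked night contributes the
#' last fix of the day and the first fix of the following day (both must
#' exist); under `clock_window`, all fixes whose UTC hour falls in the
#' configured night window are retained.
#'
#' @param tracks A `track_set`.
#' @param year Calendar year to pool.
#' @param study_polygon Two-column lon/lat ring.
#' @param origin Projection origin `c(lon, lat)`; defaults to the polygon
#'   centroid.
#' @param params A [roost_params()].
#' @return Data frame `id`, `t`, `lon`, `lat`, `x`, `y` (projected metres),
#'   time-ordered within individuals. Empty result raises a warning.
#' @export
filter_night_positions <- function(tracks, year, study_polygon,
                                   origin = NULL,
                                   params = roost_params()) {
  fx <- tracks$fixes
  if (is.null(origin)) origin <- c(mean(study_polygon[, 1]),
                                   mean(study_polygon[, 2]))
  yr <- as.integer(format(fx$t, "%Y"))
  mo <- as.integer(format(fx$t, "%m"))
  fx <- fx[yr == year & mo %in% params$season_months, , drop = FALSE]
  if (nrow(fx)) {
    if (params$night_rule == "day_boundary") {
      day <- as.Date(fx$t, tz = "UTC")
      key <- paste(fx$id, day)
      ord <- order(fx$id, fx$t)
      fx <- fx[ord, ]; day <- day[ord]; key <- key[ord]
      first_of_day <- !duplicated(key)
      last_of_day <- !duplicated(key, fromLast = TRUE)
      # a night = (last fix of day d, first fix of day d+1), both required
      nxt_key <- paste(fx$id, day + 1)
      prv_key <- paste(fx$id, day - 1)
      has_next <- last_of_day & nxt_key %in% key
      has_prev <- first_of_day & prv_key %in% key
      fx <- fx[has_next | has_prev, , drop = FALSE]
    } else {
      h <- as.numeric(format(fx$t, "%H")) + as.numeric(format(fx$t, "%M")) / 60
      w <- params$night_window_utc
      keep <- if (w[1] > w[2]) h >= w[1] | h <= w[2] else
        h >= w[1] & h <= w[2]
      fx <- fx[keep, , drop = FALSE]
    }
  }
  if (nrow(fx)) {
    # fixes far outside the buffered study area (e.g. migrating birds)
    # cannot be retained; drop them before projecting
    d0 <- geodesic_distance_m(fx$lon, fx$lat, origin[1], origin[2])
    fx <- fx[d0 <= 150e3, , drop = FALSE]
  }
  if (nrow(fx)) {
    xy <- project_local_m(fx$lon, fx$lat, origin)
    poly_xy <- project_local_m(study_polygon[, 1], study_polygon[, 2], origin)
    inside <- point_in_polygon(xy[, 1], xy[, 2], poly_xy) |
      dist_to_ring_m(xy[, 1], xy[, 2], poly_xy) <= params$study_buffer_m
    fx <- fx[inside, , drop = FALSE]
    xy <- xy[inside, , drop = FALSE]
    fx$x <- xy[, 1]; fx$y <- xy[, 2]
  } else {
    fx$x <- numeric(0); fx$y <- numeric(0)
  }
  if (nrow(fx) == 0L) warning("no night positions retained for year ", year)
  rownames(fx) <- NULL
  fx
}

#' Revisitation score of focal positions
#'
#' For each focal point, counts the distinct entry events of the pooled
#' night trajectories into the disc of radius `radius_m` centred on it: an
#' entry is a transition from outside to inside along an individual's
#' time-ordered positions, and a trajectory that starts inside contributes
#' one entry. A bird sitting in the disc all season therefore scores 1, not
#' one per fix.
#'
#' @param focal Data frame with projected `x`, `y` of focal positions.
#' @param night Data frame of pooled night positions (`id`, `x`, `y`),
#'   time-ordered within individuals.
#' @param radius_m Disc radius in metres.
#' @return Integer vector of counts, aligned with `focal`.
#' @export
revisit_counts <- function(focal, night, radius_m) {
  nf <- nrow(focal)
  if (nf == 0L) return(integer(0))
  if (nrow(night) == 0L) return(integer(nf))
  new_track <- !duplicated(night$id)
  nx <- night$x; ny <- night$y
  r2 <- radius_m^2
  # spatial hash with cell size = radius: the 3x3 cell neighbourhood of a
  # focal point contains every fix within the radius
  cell <- function(x, y) paste(floor(x / radius_m), floor(y / radius_m))
  bins <- split(seq_along(nx), cell(nx, ny))
  counts <- integer(nf)
  fcx <- floor(focal$x / radius_m)
  fcy <- floor(focal$y / radius_m)
  off <- expand.grid(dx = -1:1, dy = -1:1)
  for (i in seq_len(nf)) {
    keys <- paste(fcx[i] + off$dx, fcy[i] + off$dy)
    cand <- unlist(bins[keys], use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    ins <- cand[(nx[cand] - focal$x[i])^2 + (ny[cand] - focal$y[i])^2 <= r2]
    if (!length(ins)) next
    # an inside fix opens an entry if it starts a track or follows an
    # outside fix; any inside predecessor is itself within the radius and
    # therefore in the candidate (inside) set
    counts[i] <- sum(new_track[ins] | !((ins - 1L) %in% ins))
  }
  counts
}

#' Select the most revisited positions
#'
#' Keeps at least `ceiling(top_fraction * n)` positions with the highest
#' scores; all positions tied at the cutoff score are included.
#'
#' @param points Data frame of positions.
#' @param counts Aligned revisit scores.
#' @param top_fraction Proportion to keep.
#' @return Subset of `points` (with a `revisits` column appended).
#' @export
select_top_revisited <- function(points, counts, top_fraction = 0.05) {
  stopifnot(nrow(points) == length(counts))
  if (nrow(points) == 0L) return(cbind(points, revisits = integer(0)))
  m <- ceiling(top_fraction * nrow(points))
  cutoff <- sort(counts, decreasing = TRUE)[m]
  out <- points[counts >= cutoff, , drop = FALSE]
  out$revisits <- counts[counts >= cutoff]
  rownames(out) <- NULL
  out
}

#' Cluster selected night positions into roosts
#'
#' Standard k-means (within-cluster sum-of-squares objective) on the
#' projected coordinates, with 25 restarts seeded by k-means++ (distance-
#' proportional seeding); plain random initialization essentially never
#' covers k tight, well-separated clouds, whereas ++ seeding makes the
#' restarts reliable. Centroids are reported back in lon/lat. If fewer
#' points than clusters are available, k is reduced with a warning.
#'
#' @param selected Data frame with `x`, `y` (projected) of selected
#'   positions; a `revisits` column is carried through if present.
#' @param k Number of clusters.
#' @param origin Projection origin used to report centroids in lon/lat.
#' @param seed Seed making the restarts reproducible.
#' @param year Optional year label stored in the result.
#' @return A `roost_set`: list with `year`, `centroids` (data frame
#'   `cluster`, `x`, `y`, `lon`, `lat`, `n_members`), `members` (cluster
#'   index per selected position), `scores`.
#' @export
cluster_roosts <- function(selected, k = 10L, origin, seed = 1L,
                           year = NA_integer_) {
  if (nrow(selected) == 0L) {
    return(structure(list(year = year,
                          centroids = data.frame(), members = integer(0),
                          scores = integer(0)), class = "roost_set"))
  }
  if (nrow(selected) < k) {
    warning("only ", nrow(selected), " positions; reducing k from ", k)
    k <- nrow(selected)
  }
  set.seed(seed)
  xy <- cbind(selected$x, selected$y)
  if (nrow(selected) == k) {
    # each position is its own cluster
    ll <- unproject_local_m(xy[, 1], xy[, 2], origin)
    return(structure(list(
      year = year,
      centroids = data.frame(cluster = seq_len(k), x = xy[, 1], y = xy[, 2],
                             lon = ll[, 1], lat = ll[, 2],
                             n_members = 1L),
      members = seq_len(k),
      scores = if (!is.null(selected$revisits)) selected$revisits
               else rep(NA_integer_, k)), class = "roost_set"))
  }
  km <- NULL
  for (r in seq_len(25L)) {
    cand <- suppressWarnings(
      kmeans(xy, centers = xy[kmeanspp_seeds(xy, k), , drop = FALSE],
             iter.max = 100L))
    if (is.null(km) || cand$tot.withinss < km$tot.withinss) km <- cand
  }
  ll <- unproject_local_m(km$centers[, 1], km$centers[, 2], origin)
  centroids <- data.frame(cluster = seq_len(k),
                          x = km$centers[, 1], y = km$centers[, 2],
                          lon = ll[, "lon"], lat = ll[, "lat"],
                          n_members = as.integer(km$size))
  structure(list(year = year, centroids = centroids,
                 members = km$cluster,
                 scores = if (!is.null(selected$revisits))
                   selected$revisits else rep(NA_integer_, nrow(selected))),
            class = "roost_set")
}

# k-means++ seeding: each new seed drawn with probability proportional to
# its squared distance from the nearest seed chosen so far
kmeanspp_seeds <- function(xy, k) {
  n <- nrow(xy)
  seeds <- sample.int(n, 1L)
  d2 <- (xy[, 1] - xy[seeds, 1])^2 + (xy[, 2] - xy[seeds, 2])^2
  while (length(seeds) < k) {
    if (all(d2 == 0)) {
      nxt <- sample.int(n, 1L)
    } else {
      nxt <- sample.int(n, 1L, prob = d2)
    }
    seeds <- c(seeds, nxt)
    d2 <- pmin(d2, (xy[, 1] - xy[nxt, 1])^2 + (xy[, 2] - xy[nxt, 2])^2)
  }
  seeds
}

#' @export
print.roost_set <- function(x, ...) {
  cat("<roost_set> year ", x$year, ": ", nrow(x$centroids),
      " roosts from ", length(x$members), " positions\n", sep = "")
  invisible(x)
}

#' Distance from a nest to the closest communal roost
#'
#' @param nest `c(lon, lat)`.
#' @param roost_set A `roost_set` for the nest's year.
#' @return Minimum geodesic distance in metres; `NA` with a warning when the
#'   roost set is empty.
#' @export
nearest_roost_distance <- function(nest, roost_set) {
  cen <- roost_set$centroids
  if (is.null(cen) || nrow(cen) == 0L) {
    warning("empty roost set; returning NA")
    return(NA_real_)
  }
  min(geodesic_distance_m(nest[1], nest[2], cen$lon, cen$lat))
}

#' Full roost pipeline for one year
#'
#' Night filter, revisit scoring (focal points are the night positions
#' themselves), top-fraction selection, k-means clustering.
#'
#' @inheritParams filter_night_positions
#' @return A `roost_set`.
#' @export
detect_roosts <- function(tracks, year, study_polygon, origin = NULL,
                          params = roost_params()) {
  if (is.null(origin)) origin <- c(mean(study_polygon[, 1]),
                                   mean(study_polygon[, 2]))
  night <- suppressWarnings(
    filter_night_positions(tracks, year, study_polygon, origin, params))
  counts <- revisit_counts(night, night, params$revisit_radius_m)
  sel <- select_top_revisited(night, counts, params$top_fraction)
  cluster_roosts(sel, k = params$k_clusters, origin = origin,
                 seed = params$seed, year = year)
}
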