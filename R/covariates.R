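#' Edge-corrected conspecific territory density
#'
#' Counts territory centroids within `radius_m` of the nest (the focal
#' pair's own territory excluded by default) and inflates the count
#' proportionally where the disc leaves the surveyed study area: with `f`
#' the fraction of the disc's area inside the polygon, the corrected density
#' is `raw / f`, so an interior nest (`f = 1`) keeps its raw count.
#'
#' @param nest `c(lon, lat)` of the focal nest.
#' @param centroids Data frame of territory centroids with `lon`, `lat` and
#'   optionally `territory_id`.
#' @param radius_m Count radius (default 2 km).
#' @param study_polygon Two-column lon/lat ring of the surveyed area.
#' @param origin Projection origin; defaults to the polygon centroid.
#' @param exclude_id Territory id of the focal nest to exclude (`NULL` keeps
#'   all centroids).
#' @return Scalar corrected count (>= raw count).
#' @export
territory_density <- function(nest, centroids, radius_m = 2000,
                              study_polygon, origin = NULL,
                              exclude_id = NULL) {
  if (is.null(origin)) origin <- c(mean(study_polygon[, 1]),
                                   mean(study_polygon[, 2]))
  cc <- centroids
  if (!is.null(exclude_id) && !is.null(cc$territory_id)) {
    cc <- cc[cc$territory_id != exclude_id, , drop = FALSE]
  }
  raw <- if (nrow(cc)) {
    sum(geodesic_distance_m(cc$lon, cc$lat, nest[1], nest[2]) <= radius_m)
  } else 0L
  poly_xy <- project_local_m(study_polygon[, 1], study_polygon[, 2], origin)
  nest_xy <- project_local_m(nest[1], nest[2], origin)
  f <- if (point_in_polygon(nest_xy[1], nest_xy[2], poly_xy) &&
           dist_to_ring_m(nest_xy[1], nest_xy[2], poly_xy) >= radius_m) 1
  else disc_area_fraction(c(nest_xy[1], nest_xy[2]), radius_m, poly_xy)
  if (f <= 0) stop("nest lies outside the study area (disc fraction 0)")
  raw / f
}

#' Primary-feather growth curve
#'
#' Parametric logistic growth of the eighth primary feather with age,
#' used to invert a feather-length measurement into a nestling age. The
#' defaults are a placeholder calibration; study-specific curves should be
#' supplied via the parameters.
#'
#' @param asymptote_mm Adult feather length.
#' @param midpoint_days Age at half the asymptote.
#' @param rate Logistic growth rate per day.
#' @param age_range_days Support of the curve.
#' @return List of class `growth_curve` with `value(age)` and the domain.
#' @export
growth_curve <- function(asymptote_mm = 340, midpoint_days = 35,
                         rate = 0.10, age_range_days = c(0, 120)) {
  stopifnot(asymptote_mm > 0, rate > 0,
            age_range_days[1] < age_range_days[2])
  value <- function(age) asymptote_mm / (1 + exp(-rate * (age - midpoint_days)))
  structure(list(value = value, age_range_days = age_range_days,
                 asymptote_mm = asymptote_mm, midpoint_days = midpoint_days,
                 rate = rate),
            class = "growth_curve")
}

default_growth_curve <- function() growth_curve()

#' Hatching date from feather length
#'
#' Inverts a strictly increasing age-to-length growth curve at the measured
#' eighth-primary length by monotone root finding (tolerance 0.01 d), then
#' subtracts the recovered age from the measurement date.
#'
#' @param p8_mm Measured feather length(s), mm.
#' @param measurement_date Date(s) of measurement.
#' @param curve A [growth_curve()] (or any list with `value` and
#'   `age_range_days`).
#' @return List: `age_days`, `hatching_date` (Date, fractional ages rounded
#'   to the containing day), `hatch_doy` (continuous day of year).
#' @export
hatch_date_from_feather <- function(p8_mm, measurement_date,
                                    curve = growth_curve()) {
  rng <- curve$age_range_days
  lo <- curve$value(rng[1]); hi <- curve$value(rng[2])
  bad <- p8_mm < lo | p8_mm > hi
  if (any(bad)) {
    stop("feather length outside the curve's range [",
         signif(lo, 4), ", ", signif(hi, 4), "] mm")
  }
  age <- vapply(p8_mm, function(L) {
    uniroot(function(a) curve$value(a) - L, interval = rng,
            tol = 0.001)$root
  }, numeric(1))
  measurement_date <- as.Date(measurement_date)
  hd <- measurement_date - round(age)
  doy <- as.numeric(measurement_date -
                      as.Date(paste0(format(measurement_date, "%Y"),
                                     "-01-01"))) + 1 - age
  list(age_days = age, hatching_date = hd, hatch_doy = doy)
}

#' Hatching rank from sibling wing lengths
#'
#' Within a brood, the nestling with the longest wing is the first hatched
#' and all others are later hatched; a lone nestling is a singleton. Ties in
#' wing length are broken by body mass (heavier = earlier), then by id.
#'
#' @param wing_mm Wing lengths of all siblings in one brood.
#' @param mass_g Optional masses for tie-breaking.
#' @param ids Optional ids for the final tie-break.
#' @return Factor with levels `first`, `later`, `singleton`, aligned with
#'   the input.
#' @export
hatching_rank <- function(wing_mm, mass_g = NULL, ids = NULL) {
  n <- length(wing_mm)
  stopifnot(n >= 1)
  if (n == 1L) {
    return(factor("singleton", levels = c("first", "later", "singleton")))
  }
  if (is.null(mass_g)) mass_g <- rep(0, n)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  o <- order(-wing_mm, -mass_g, ids)
  rank <- rep("later", n)
  rank[o[1]] <- "first"
  factor(rank, levels = c("first", "later", "singleton"))
}

#' Body condition as mass-size residuals
#'
#' Ordinary least-squares regression of body mass on tarsus length over the
#' population; a bird's condition is its residual from that line, so the
#' residuals of the population itself sum to zero.
#'
#' @param mass_g,tarsus_mm Focal bird(s).
#' @param population Data frame with `mass_g`, `tarsus_mm` of the reference
#'   population (>= 3 rows, non-degenerate tarsus).
#' @return Numeric residual(s), grams.
#' @export
body_condition <- function(mass_g, tarsus_mm, population) {
  stopifnot(nrow(population) >= 3)
  if (sd(population$tarsus_mm) == 0)
    stop("zero variance in tarsus length: mass-size line undefined")
  fit <- lm(mass_g ~ tarsus_mm, data = population)
  unname(mass_g - predict(fit, newdata = data.frame(tarsus_mm = tarsus_mm)))
}

#' Assemble and scale the analysis table
#'
#' Joins juvenile metadata with departure results, territory densities and
#' roost distances, restricts to the analysis set (scored departures only),
#' and scales the continuous covariates to mean 0 / SD 1. Scaling metadata
#' is attached so coefficients can be back-transformed to natural units.
#' Unmatched keys are returned in the reject list, never silently dropped.
#'
#' @param juveniles Data frame keyed by `individual_id` with `brood_id`,
#'   `treatment`, `sex`, `hatching_rank`, `year`, `elevation_m`,
#'   `hatch_doy`, `territory_density`, `roost_distance_m` (the last two may
#'   instead be supplied separately).
#' @param departures Data frame from [detect_departures()] /
#'   [apply_exclusions()] with `individual_id`, `status`,
#'   `departure_age_days`.
#' @param densities,roost_distances Optional data frames
#'   (`individual_id`, value) overriding the columns in `juveniles`.
#' @return A `covariate_table`: data frame with the response
#'   `departure_age_days`, scaled continuous covariates (`hatch_s`,
#'   `elev_s`, `roost_s`, `dens_s`), factors, `brood_id`; attributes
#'   `scaling` (mean/SD per variable), `rejects`, `correlation_flags`
#'   (pairs with |r| > 0.7 among fixed-effect columns).
#' @export
assemble_covariates <- function(juveniles, departures,
                                densities = NULL, roost_distances = NULL) {
  juv <- juveniles
  if (!is.null(densities)) {
    juv$territory_density <- NULL
    names(densities) <- c("individual_id", "territory_density")
    juv <- merge(juv, densities, by = "individual_id", all.x = TRUE)
  }
  if (!is.null(roost_distances)) {
    juv$roost_distance_m <- NULL
    names(roost_distances) <- c("individual_id", "roost_distance_m")
    juv <- merge(juv, roost_distances, by = "individual_id", all.x = TRUE)
  }
  dep <- departures[, c("individual_id", "status", "departure_age_days")]
  unmatched <- setdiff(dep$individual_id, juv$individual_id)
  juv$departure_age_days <- NULL  # the scored value comes from `departures`
  juv$status <- NULL
  tab <- merge(juv, dep, by = "individual_id")
  tab <- tab[tab$status == "departed", , drop = FALSE]
  model_cols <- c("departure_age_days", "treatment", "hatch_doy",
                  "hatching_rank", "elevation_m", "sex", "roost_distance_m",
                  "year", "territory_density", "brood_id")
  missing_cols <- setdiff(model_cols, names(tab))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  incomplete <- !complete.cases(tab[, model_cols])
  rejects <- list(unmatched_ids = unmatched,
                  incomplete_ids = tab$individual_id[incomplete])
  tab <- tab[!incomplete, , drop = FALSE]

  scaling <- list()
  zscale <- function(x, nm) {
    scaling[[nm]] <<- c(mean = mean(x), sd = sd(x))
    (x - mean(x)) / sd(x)
  }
  tab$hatch_s <- zscale(tab$hatch_doy, "hatch_doy")
  tab$elev_s <- zscale(tab$elevation_m, "elevation_m")
  tab$roost_s <- zscale(tab$roost_distance_m, "roost_distance_m")
  tab$dens_s <- zscale(tab$territory_density, "territory_density")
  tab$year <- factor(tab$year, levels = sort(unique(tab$year)))
  tab$sex <- factor(tab$sex, levels = c("F", "M"))
  tab$treatment <- factor(tab$treatment, levels = c("control", "fed"))
  tab$hatching_rank <- factor(tab$hatching_rank,
                              levels = c("first", "later", "singleton"))
  rownames(tab) <- NULL

  num <- cbind(fed = as.numeric(tab$treatment == "fed"),
               hatch = tab$hatch_s, elev = tab$elev_s,
               male = as.numeric(tab$sex == "M"), roost = tab$roost_s,
               year = as.numeric(tab$year) - 1, dens = tab$dens_s)
  cm <- suppressWarnings(stats::cor(num))
  flags <- which(abs(cm) > 0.7 & upper.tri(cm), arr.ind = TRUE)
  corr_flags <- if (nrow(flags)) {
    data.frame(var1 = rownames(cm)[flags[, 1]],
               var2 = colnames(cm)[flags[, 2]],
               r = cm[flags])
  } else data.frame(var1 = character(0), var2 = character(0), r = numeric(0))

  structure(tab, scaling = scaling, rejects = rejects,
            correlation_flags = corr_flags,
            class = c("covariate_table", "data.frame"))
}

#' Back-transform a scaled slope to natural units
#'
#' @param coef_scaled Coefficient in response units per SD of the covariate.
#' @param scaling Scaling metadata (attribute `scaling` of the table or the
#'   study's `scaling` list).
#' @param var Covariate name in the metadata.
#' @param per Natural-unit step to express the slope in (e.g. `100` for
#'   days per 100 m of elevation; default 1).
#' @return Slope in response units per `per` natural units.
#' @export
unscale_slope <- function(coef_scaled, scaling, var, per = 1) {
  s <- scaling[[var]]
  if (is.null(s)) stop("no scaling metadata for variable ", var)
  coef_scaled / unname(s["sd"]) * per
}
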