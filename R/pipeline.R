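#' Configuration of an end-to-end pipeline run
#'
#' @param sim A [sim_config()] (or list of arguments for one).
#' @param departure A [departure_params()].
#' @param roost A [roost_params()].
#' @param prune_alpha Retention threshold for interaction pruning.
#' @param candidate_interactions Candidate two-way interactions of the
#'   departure model: `"all"` or a list of character pairs. The default is
#'   every pair among the fixed effects.
#' @param n_draws Posterior simulations for credible intervals.
#' @param lrt_sims Null simulations for the random-effect test.
#' @param use_truth_roosts Use the simulated roost locations directly
#'   instead of re-deriving them from night positions (faster; the roost
#'   pipeline is exercised independently in the test-suite).
#' @param out_dir Optional output directory for per-stage CSVs and the JSON
#'   manifest.
#' @param seed Master seed; stage seeds are derived from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       departure = departure_params(),
                       roost = roost_params(),
                       prune_alpha = 0.05,
                       candidate_interactions = "all",
                       n_draws = 2000L,
                       lrt_sims = 200L,
                       use_truth_roosts = FALSE,
                       out_dir = NULL,
                       seed = 1L) {
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, departure = departure, roost = roost,
                 prune_alpha = prune_alpha,
                 candidate_interactions = candidate_interactions,
                 n_draws = as.integer(n_draws),
                 lrt_sims = as.integer(lrt_sims),
                 use_truth_roosts = use_truth_roosts,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Bundled demonstration configuration
#'
#' A complete study at the default conditions with lighter Monte-Carlo
#' settings, sized to run end-to-end in about a minute.
#'
#' @param seed Master seed.
#' @param out_dir Optional output directory.
#' @return A [run_config()].
#' @export
demo_config <- function(seed = 1L, out_dir = NULL) {
  run_config(sim = sim_config(n_broods = 60L, seed = seed),
             candidate_interactions = list(
               c("year", "dens_s"), c("sex", "dens_s"),
               c("treatment", "elev_s"), c("hatch_s", "elev_s")),
             n_draws = 1000L, lrt_sims = 100L, use_truth_roosts = FALSE,
             out_dir = out_dir, seed = seed)
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Simulate, write and re-ingest trajectories, detect departures, apply the
#' exclusion filters, locate communal roosts, derive covariates, fit the
#' departure-age mixed model with interaction pruning, compute simulated
#' posterior credible intervals, test the brood random effect, fit the
#' hatching-date / density / roost-distance models, and run the path
#' analysis. Each stage is seeded from the master seed, so an identical
#' configuration reproduces the run exactly.
#'
#' @param config A [run_config()] (or a path to a YAML file with its
#'   fields; requires the yaml package).
#' @return List of class `pipeline_run`: stage outputs (`study`, `tracks`,
#'   `departures`, `exclusions`, `roosts`, `covariates`), model fits
#'   (`fit_departure`, `cri_departure`, `lrt`, `fit_hatch`, `fit_density`,
#'   `fit_roost`, `path`) and a `manifest` with seeds, per-stage row counts
#'   and filter accounting.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    raw <- yaml::read_yaml(config)
    config <- do.call(run_config, raw)
  }
  stopifnot(inherits(config, "run_config"))
  stage_counts <- list()

  study <- generate_study(config$sim)
  juv <- study$juveniles
  stage_counts$juveniles <- nrow(juv)

  tracks <- generate_tracks(study)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(config$out_dir, "tracks.csv")
    write_tracks(tracks, p)
    tracks <- read_tracks(p)   # round-trip through the on-disk format
  }
  stage_counts$fixes <- nrow(tracks$fixes)

  departures <- detect_departures(tracks, juv, config$departure)
  roster <- data.frame(individual_id = juv$individual_id, fate = juv$fate,
                       stringsAsFactors = FALSE)
  excl <- apply_exclusions(roster, departures)
  stage_counts$filter <- as.list(excl$counts)

  poly <- as.matrix(study$study_polygon)
  years <- sort(unique(juv$year))
  roosts <- if (config$use_truth_roosts) {
    lapply(setNames(years, years), function(yr) {
      rt <- study$roost_truth[study$roost_truth$year == yr, ]
      structure(list(year = yr,
                     centroids = data.frame(cluster = seq_len(nrow(rt)),
                                            x = rt$x, y = rt$y,
                                            lon = rt$lon, lat = rt$lat,
                                            n_members = NA_integer_),
                     members = integer(0), scores = integer(0)),
                class = "roost_set")
    })
  } else {
    indep <- post_departure_tracks(tracks, departures)
    lapply(setNames(years, years), function(yr)
      detect_roosts(indep, yr, poly, origin = study$origin,
                    params = config$roost))
  }

  roost_dist <- data.frame(
    individual_id = juv$individual_id,
    roost_distance_m = vapply(seq_len(nrow(juv)), function(i)
      nearest_roost_distance(c(juv$nest_lon[i], juv$nest_lat[i]),
                             roosts[[as.character(juv$year[i])]]),
      numeric(1)))

  dens <- data.frame(
    individual_id = juv$individual_id,
    territory_density = vapply(seq_len(nrow(juv)), function(i)
      territory_density(
        c(juv$nest_lon[i], juv$nest_lat[i]),
        study$territory_centroids[
          study$territory_centroids$year == juv$year[i], ],
        radius_m = config$sim$density_radius_m,
        study_polygon = poly, origin = study$origin,
        exclude_id = juv$brood_id[i]),
      numeric(1)))

  tab <- assemble_covariates(juv, excl$analysis_set,
                             densities = dens, roost_distances = roost_dist)
  stage_counts$analysis_rows <- nrow(tab)

  # factors that are constant in this study (e.g. a single season) cannot
  # enter the models
  usable_terms <- function(terms) {
    terms[vapply(terms, function(v)
      !is.factor(tab[[v]]) || length(unique(as.character(tab[[v]]))) > 1,
      logical(1))]
  }
  fixed_terms <- usable_terms(
    c("treatment", "hatch_s", "hatching_rank", "elev_s", "sex",
      "roost_s", "year", "dens_s"))
  cand <- config$candidate_interactions
  if (is.list(cand)) {
    cand <- cand[vapply(cand, function(p) all(p %in% fixed_terms),
                        logical(1))]
  }
  dep_spec <- model_spec(
    "departure_age_days",
    fixed = fixed_terms,
    interactions = cand,
    random = "brood_id")
  pruned <- prune_interactions(dep_spec, tab, alpha = config$prune_alpha)
  fit_dep <- pruned$fit
  cri_dep <- simulate_cri(fit_dep, config$n_draws, seed = config$seed + 11L)
  lrt <- random_effect_lrt(fit_dep, tab, n_null_sims = config$lrt_sims,
                           seed = config$seed + 12L)

  fit_hatch <- fit_model(
    model_spec("hatch_doy", usable_terms(c("elev_s", "year", "dens_s")),
               random = "brood_id"), tab)
  fit_density <- fit_model(
    model_spec("territory_density", usable_terms(c("elev_s", "year"))), tab)
  fit_roostd <- fit_model(
    model_spec("roost_distance_m",
               usable_terms(c("elev_s", "dens_s", "year"))), tab)
  path <- path_analysis(fit_hatch, fit_dep, n_draws = config$n_draws,
                        seed = config$seed + 13L)

  manifest <- list(
    seed = config$seed,
    counts = stage_counts,
    pruning = pruned$trace,
    retained_interactions = pruned$retained,
    departure_coefficients = cri_dep$intervals,
    lrt = lrt[c("statistic", "p_value", "n_null_sims")],
    hatch_slope_days_per_100m = unscale_slope(
      fit_hatch$coefficients$estimate[
        fit_hatch$coefficients$term == "elev_s"],
      attr(tab, "scaling"), "elevation_m", per = 100),
    path_natural = path$natural
  )

  run <- structure(list(study = study, tracks = tracks,
                        departures = departures, exclusions = excl,
                        roosts = roosts, covariates = tab,
                        fit_departure = fit_dep, cri_departure = cri_dep,
                        lrt = lrt, fit_hatch = fit_hatch,
                        fit_density = fit_density, fit_roost = fit_roostd,
                        path = path, manifest = manifest,
                        config = config),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) write_run_outputs(run, config$out_dir)
  run
}

write_run_outputs <- function(run, out_dir) {
  write.csv(run$departures, file.path(out_dir, "departures.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(run$covariates),
            file.path(out_dir, "covariates.csv"), row.names = FALSE)
  write.csv(run$cri_departure$intervals,
            file.path(out_dir, "departure_model.csv"), row.names = FALSE)
  cents <- do.call(rbind, lapply(run$roosts, function(r)
    cbind(year = r$year, r$centroids)))
  write.csv(cents, file.path(out_dir, "roosts.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    man <- run$manifest
    man$file_md5 <- as.list(tools::md5sum(
      list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)))
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> seed ", x$manifest$seed, "\n", sep = "")
  cat("  filter chain:",
      paste(names(x$manifest$counts$filter), unlist(x$manifest$counts$filter),
            sep = "=", collapse = ", "), "\n")
  cat("  retained interactions:",
      if (length(x$manifest$retained_interactions))
        paste(x$manifest$retained_interactions, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
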