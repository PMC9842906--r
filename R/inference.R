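#' Specify a model of the inference chain
#'
#' @param response Response column name.
#' @param fixed Character vector of main-effect terms (column names).
#' @param interactions Candidate two-way interactions: a list of character
#'   pairs, `"all"` for every pair of main effects, or `NULL`.
#' @param random Grouping factor for a random intercept (e.g. `"brood_id"`),
#'   or `NULL` for an ordinary linear model.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(response, fixed, interactions = NULL, random = NULL) {
  if (identical(interactions, "all")) {
    interactions <- utils::combn(fixed, 2, simplify = FALSE)
  }
  if (!is.null(interactions)) {
    ok <- vapply(interactions, function(p) all(p %in% fixed), logical(1))
    if (!all(ok)) stop("interaction terms must reference declared main effects")
  }
  structure(list(response = response, fixed = fixed,
                 interactions = interactions, random = random),
            class = "model_spec")
}

spec_formula <- function(spec, interactions = spec$interactions) {
  rhs <- spec$fixed
  if (length(interactions)) {
    rhs <- c(rhs, vapply(interactions, paste, character(1), collapse = ":"))
  }
  if (is.null(spec$random)) {
    as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
  } else {
    as.formula(paste(spec$response, "~", paste(rhs, collapse = " + "),
                     "+ (1 |", spec$random, ")"))
  }
}

#' Fit a model of the inference chain
#'
#' REML linear mixed model (via lme4) when the spec declares a random
#' intercept, ordinary least squares otherwise. Coefficients stay on the
#' scale of the supplied table (scaled covariates); use [unscale_slope()]
#' to express slopes in natural units.
#'
#' @param spec A [model_spec()].
#' @param table Data frame (typically a `covariate_table`).
#' @return A `model_fit`: list with the fitted `model`, `coefficients`
#'   (term, estimate, se), fixed-effect `vcov`, `spec`, `n_obs`,
#'   `n_groups`, `re_sd`, `resid_sd`, `singular` flag and the table's
#'   scaling metadata.
#' @export
fit_model <- function(spec, table) {
  f <- spec_formula(spec)
  if (is.null(spec$random)) {
    m <- lm(f, data = table)
    beta <- coef(m)
    V <- vcov(m)
    re_sd <- NA_real_
    n_groups <- NA_integer_
    singular <- FALSE
  } else {
    m <- lme4::lmer(f, data = table, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
    beta <- lme4::fixef(m)
    V <- as.matrix(vcov(m))
    vc <- lme4::VarCorr(m)
    re_sd <- attr(vc[[spec$random]], "stddev")[[1]]
    n_groups <- lme4::ngrps(m)[[spec$random]]
    singular <- lme4::isSingular(m)
  }
  structure(list(
    model = m,
    formula = f,
    coefficients = data.frame(term = names(beta),
                              estimate = unname(beta),
                              se = sqrt(diag(V)),
                              row.names = NULL),
    vcov = V,
    spec = spec,
    n_obs = nrow(model.matrix(m)),
    n_groups = n_groups,
    re_sd = re_sd,
    resid_sd = sigma(m),
    singular = singular,
    scaling = attr(table, "scaling")
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit> ", deparse(x$formula), "\n  n = ", x$n_obs, sep = "")
  if (!is.na(x$n_groups)) cat(", groups =", x$n_groups)
  if (isTRUE(x$singular)) cat("  [singular fit]")
  cat("\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

# Wald chi-square test of a (possibly multi-df) model term
term_wald_p <- function(fit, term_label) {
  asgn <- attr(model.matrix(fit$model), "assign")
  labels <- attr(terms(fit$formula), "term.labels")
  labels <- labels[!grepl("\\|", labels)]
  k <- match(term_label, labels)
  if (is.na(k)) stop("term not in model: ", term_label)
  idx <- which(asgn == k)
  b <- fit$coefficients$estimate[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  pchisq(stat, df = length(idx), lower.tail = FALSE)
}

#' Stepwise pruning of non-significant interactions
#'
#' Fits the model with all candidate two-way interactions, then repeatedly
#' removes the least significant interaction (largest Wald chi-square
#' p-value at or above `alpha`) and refits, until every remaining
#' interaction is significant. Main effects are never dropped.
#'
#' @param spec A [model_spec()] with candidate interactions.
#' @param table Data frame.
#' @param alpha Retention threshold (default 0.05).
#' @return List: `fit` (final `model_fit`), `trace` (data frame of dropped
#'   terms and their p-values, in drop order), `retained` (interaction
#'   labels kept).
#' @export
prune_interactions <- function(spec, table, alpha = 0.05) {
  current <- spec$interactions
  trace <- data.frame(step = integer(0), dropped = character(0),
                      p = numeric(0))
  repeat {
    sp <- model_spec(spec$response, spec$fixed, current, spec$random)
    fit <- suppressWarnings(suppressMessages(fit_model(sp, table)))
    if (!length(current)) break
    labs <- vapply(current, paste, character(1), collapse = ":")
    ps <- vapply(labs, function(l) term_wald_p(fit, l), numeric(1))
    worst <- which.max(ps)
    if (ps[worst] < alpha) break
    trace <- rbind(trace, data.frame(step = nrow(trace) + 1L,
                                     dropped = labs[worst],
                                     p = ps[worst]))
    current <- current[-worst]
  }
  list(fit = fit, trace = trace,
       retained = if (length(current))
         vapply(current, paste, character(1), collapse = ":")
       else character(0))
}

#' Simulated-posterior credible intervals
#'
#' Draws fixed-effect vectors from the multivariate normal approximation
#' centred at the estimates with the fitted covariance (the random-effect
#' and residual variances are held at their REML estimates) and reports
#' percentile intervals -- 2000 draws and a 95\% level by default.
#'
#' @param fit A `model_fit`.
#' @param n_draws Number of posterior simulations.
#' @param level Interval level.
#' @param seed Seed; fixed seed gives identical intervals.
#' @return List: `intervals` (term, estimate, lower, upper), `draws`
#'   (n_draws x p matrix), `level`, `n_draws`.
#' @export
simulate_cri <- function(fit, n_draws = 2000L, level = 0.95, seed = 1L) {
  beta <- fit$coefficients$estimate
  V <- (fit$vcov + t(fit$vcov)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("fixed-effect covariance is not positive semi-definite; ",
         "consider projecting to the nearest PD matrix ",
         "(e.g. Matrix::nearPD) before simulating")
  }
  set.seed(seed)
  draws <- MASS::mvrnorm(n_draws, mu = beta, Sigma = V, tol = 1e-6)
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = length(beta))
  colnames(draws) <- fit$coefficients$term
  a <- (1 - level) / 2
  qs <- apply(draws, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  list(intervals = data.frame(term = fit$coefficients$term,
                              estimate = beta,
                              lower = qs[1, ], upper = qs[2, ],
                              row.names = NULL),
       draws = draws, level = level, n_draws = n_draws)
}

#' Parametric-bootstrap likelihood-ratio test of the random intercept
#'
#' Compares the REML log-likelihood of the mixed model to that of the
#' ordinary linear model with the same fixed effects. Because the null
#' hypothesis (zero random-intercept variance) sits on the boundary of the
#' parameter space, the chi-square reference is invalid; the p-value is
#' taken from a simulated null distribution obtained by refitting both
#' models to responses generated under the no-random-effect model.
#'
#' @param fit_mixed A mixed `model_fit`.
#' @param table The data the model was fitted to.
#' @param n_null_sims Null-simulation replicates (warning below 100).
#' @param seed Seed.
#' @return List: `statistic`, `p_value`, `n_null_sims`, `null_stats`.
#' @export
random_effect_lrt <- function(fit_mixed, table, n_null_sims = 200L,
                              seed = 1L) {
  if (is.null(fit_mixed$spec$random)) stop("fit has no random effect")
  if (n_null_sims < 100L) {
    warning("fewer than 100 null simulations; the p-value will be coarse")
  }
  spec0 <- model_spec(fit_mixed$spec$response, fit_mixed$spec$fixed,
                      fit_mixed$spec$interactions, random = NULL)
  f0 <- spec_formula(spec0)
  m0 <- lm(f0, data = table)
  stat_of <- function(mm, m0) {
    max(0, 2 * (as.numeric(logLik(mm)) - as.numeric(logLik(m0, REML = TRUE))))
  }
  obs <- stat_of(fit_mixed$model, m0)
  set.seed(seed)
  mu <- predict(m0)
  s <- sigma(m0)
  tab <- table
  null_stats <- vapply(seq_len(n_null_sims), function(i) {
    y <- mu + rnorm(length(mu), 0, s)
    mm <- suppressWarnings(suppressMessages(
      lme4::refit(fit_mixed$model, newresp = y)))
    tab[[fit_mixed$spec$response]] <- y
    stat_of(mm, lm(f0, data = tab))
  }, numeric(1))
  p <- (1 + sum(null_stats >= obs)) / (1 + n_null_sims)
  list(statistic = obs, p_value = p, n_null_sims = n_null_sims,
       null_stats = null_stats)
}

#' Path analysis of direct and indirect elevation effects
#'
#' Decomposes the effect of elevation on departure age into the direct path
#' (the elevation coefficient of the departure model) and the indirect path
#' through hatching date: `a`, the elevation effect on hatching date, times
#' `b`, the hatching-date effect on departure age. Per joint posterior draw
#' the indirect effect is exactly the product of the two draws (with `a`
#' expressed in SDs of hatching date so the product lands on the departure
#' model's scale); intervals are percentile intervals of the draws. The
#' chain is also reported in natural units: days of hatching delay per
#' 100 m, and days of departure age per 100 m of elevation.
#'
#' @param fit_hatch `model_fit` of the hatching-date model (response in
#'   days, elevation covariate scaled).
#' @param fit_departure `model_fit` of the departure-age model.
#' @param elev_term,hatch_term Coefficient names of elevation and hatching
#'   date in the respective models.
#' @param n_draws,seed Posterior simulation settings.
#' @return A `path_result`: list with the per-path estimates and credible
#'   intervals (`direct`, `indirect`, `total`, `a`, `b`), the natural-unit
#'   chain, and the draw matrices.
#' @export
path_analysis <- function(fit_hatch, fit_departure,
                          elev_term = "elev_s", hatch_term = "hatch_s",
                          n_draws = 2000L, seed = 1L) {
  sc_h <- fit_departure$scaling
  if (is.null(sc_h) || is.null(sc_h$hatch_doy) || is.null(sc_h$elevation_m)) {
    stop("departure fit carries no scaling metadata for hatch_doy / ",
         "elevation_m; path coefficients cannot be aligned")
  }
  sd_hatch <- unname(sc_h$hatch_doy["sd"])
  sd_elev <- unname(sc_h$elevation_m["sd"])
  dr_h <- simulate_cri(fit_hatch, n_draws, seed = seed)$draws
  dr_d <- simulate_cri(fit_departure, n_draws, seed = seed + 1L)$draws
  a_days <- dr_h[, elev_term]          # hatch days per SD elevation
  a_std <- a_days / sd_hatch           # SD hatch per SD elevation
  b <- dr_d[, hatch_term]              # departure days per SD hatch
  direct <- dr_d[, elev_term]
  indirect <- a_std * b
  total <- direct + indirect
  ci <- function(x) quantile(x, c(0.025, 0.975), names = FALSE)
  est <- function(hat, x) c(estimate = hat, lower = ci(x)[1],
                            upper = ci(x)[2])
  a_hat <- fit_hatch$coefficients$estimate[
    fit_hatch$coefficients$term == elev_term]
  b_hat <- fit_departure$coefficients$estimate[
    fit_departure$coefficients$term == hatch_term]
  d_hat <- fit_departure$coefficients$estimate[
    fit_departure$coefficients$term == elev_term]
  structure(list(
    a = est(a_hat, a_days),
    b = est(b_hat, b),
    direct = est(d_hat, direct),
    indirect = est((a_hat / sd_hatch) * b_hat, indirect),
    total = est(d_hat + (a_hat / sd_hatch) * b_hat, total),
    natural = c(
      a_days_per_100m = a_hat / sd_elev * 100,
      indirect_days_per_100m = (a_hat / sd_elev * 100) * (b_hat / sd_hatch),
      direct_days_per_100m = d_hat / sd_elev * 100),
    draws = list(a = a_days, b = b, direct = direct, indirect = indirect,
                 total = total),
    n_draws = n_draws
  ), class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  f <- function(v) sprintf("%6.2f [%6.2f, %6.2f]", v[1], v[2], v[3])
  cat("<path_result> (departure days per SD elevation)\n",
      "  direct:   ", f(x$direct), "\n",
      "  indirect: ", f(x$indirect), " (via hatching date)\n",
      "  total:    ", f(x$total), "\n", sep = "")
  invisible(x)
}

#' Model predictions over a scenario grid
#'
#' Point predictions and simulated-posterior bands for fixed-effect
#' scenarios. Unspecified continuous covariates default to 0 (their scaled
#' mean) and unspecified factors to their reference level.
#'
#' @param fit A `model_fit`.
#' @param scenarios Data frame of predictor values; missing model columns
#'   are filled with defaults.
#' @param n_draws,level,seed Posterior band settings.
#' @return `scenarios` with `predicted`, `lower`, `upper` appended.
#' @export
predict_effects <- function(fit, scenarios, n_draws = 2000L, level = 0.95,
                            seed = 1L) {
  f_fixed <- lme4::nobars(fit$formula)
  mf <- if (inherits(fit$model, "merMod")) fit$model@frame else
    stats::model.frame(fit$model)
  vars <- all.vars(f_fixed)
  xlev <- lapply(mf[vars[vars %in% names(mf)]], function(col)
    if (is.factor(col)) levels(col) else NULL)
  xlev <- xlev[!vapply(xlev, is.null, logical(1))]
  for (v in vars) {
    if (!v %in% names(scenarios)) {
      scenarios[[v]] <- if (v %in% names(xlev))
        factor(xlev[[v]][1], levels = xlev[[v]]) else 0
    } else if (v %in% names(xlev)) {
      bad <- setdiff(unique(as.character(scenarios[[v]])), xlev[[v]])
      if (length(bad)) stop("unknown level(s) for ", v, ": ",
                            paste(bad, collapse = ", "))
      scenarios[[v]] <- factor(as.character(scenarios[[v]]),
                               levels = xlev[[v]])
    }
  }
  X <- model.matrix(delete.response(terms(f_fixed)), scenarios, xlev = xlev)
  beta <- fit$coefficients$estimate
  scenarios$predicted <- drop(X %*% beta)
  draws <- simulate_cri(fit, n_draws, level = level, seed = seed)$draws
  pd <- X %*% t(draws)
  a <- (1 - level) / 2
  scenarios$lower <- apply(pd, 1, quantile, probs = a, names = FALSE)
  scenarios$upper <- apply(pd, 1, quantile, probs = 1 - a, names = FALSE)
  scenarios
}
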