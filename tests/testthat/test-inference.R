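# a small deterministic design shared by several blocks
make_linear_data <- function(n = 200, seed = 1, noise = 0) {
  set.seed(seed)
  d <- data.frame(
    x1 = rnorm(n), x2 = rnorm(n),
    g = factor(sample(c("A", "B"), n, TRUE)),
    brood_id = factor(rep(seq_len(n / 2), each = 2)))
  d$y <- 2 + 3 * d$x1 - 1.5 * d$x2 + 2 * (d$g == "B") + rnorm(n, 0, noise)
  d
}

test_that("fit_model recovers exact coefficients in the noise-free limit", {
  d <- make_linear_data(noise = 0)
  sp <- model_spec("y", c("x1", "x2", "g"))
  fit <- suppressWarnings(fit_model(sp, d))
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(est["x1"]), 3, tolerance = 1e-10)
  expect_equal(unname(est["x2"]), -1.5, tolerance = 1e-10)
  expect_equal(unname(est["gB"]), 2, tolerance = 1e-10)
  # mixed version: zero group variance, fixed effects still exact
  spm <- model_spec("y", c("x1", "x2", "g"), random = "brood_id")
  fitm <- suppressWarnings(suppressMessages(fit_model(spm, d)))
  estm <- setNames(fitm$coefficients$estimate, fitm$coefficients$term)
  expect_equal(unname(estm["x1"]), 3, tolerance = 1e-6)
  expect_identical(fitm$n_obs, nrow(d))
})

test_that("a zero-variance response gives zero slopes and a mean intercept", {
  d <- make_linear_data()
  d$y <- 7.5
  fit <- suppressWarnings(fit_model(model_spec("y", c("x1", "x2")), d))
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(est["(Intercept)"]), 7.5, tolerance = 1e-10)
  expect_equal(unname(est["x1"]), 0, tolerance = 1e-10)
})

test_that("interaction pruning keeps real interactions, drops spurious ones", {
  set.seed(4)
  n <- 300
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- 1 + d$x1 + d$x2 + 2 * d$x1 * d$x2 + rnorm(n, 0, 0.7)
  sp <- model_spec("y", c("x1", "x2", "x3"), interactions = "all")
  out <- prune_interactions(sp, d, alpha = 0.05)
  expect_true("x1:x2" %in% out$retained)
  expect_false(any(c("x1:x3", "x2:x3") %in% out$retained))
  expect_true(all(out$trace$p >= 0.05))
  # zero candidates -> identity with the plain fit
  sp0 <- model_spec("y", c("x1", "x2", "x3"))
  out0 <- prune_interactions(sp0, d)
  expect_identical(out0$retained, character(0))
  expect_equal(out0$fit$coefficients, fit_model(sp0, d)$coefficients)
})

test_that("spurious interaction retention stays near the nominal level", {
  # with no true interactions, each of the 3 candidates should survive
  # pruning at about the alpha = 0.05 rate
  set.seed(9)
  kept <- replicate(80, {
    n <- 120
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    d$y <- 1 + d$x1 + rnorm(n)
    length(prune_interactions(
      model_spec("y", c("x1", "x2", "x3"), interactions = "all"),
      d)$retained)
  })
  # family-wise retention of >= 1 interaction: roughly 1-(1-.05)^3 = 0.14
  expect_lt(mean(kept > 0), 0.30)
  expect_gt(mean(kept > 0), 0.02)
})

test_that("simulated-posterior intervals match the normal closed form", {
  d <- make_linear_data(noise = 1, seed = 11)
  fit <- fit_model(model_spec("y", c("x1", "x2")), d)
  cri <- simulate_cri(fit, n_draws = 4000, seed = 2)
  est <- fit$coefficients$estimate
  se <- fit$coefficients$se
  expect_equal(cri$intervals$lower, est - 1.96 * se, tolerance = 0.05)
  expect_equal(cri$intervals$upper, est + 1.96 * se, tolerance = 0.05)
  # deterministic under the seed
  cri2 <- simulate_cri(fit, n_draws = 4000, seed = 2)
  expect_identical(cri$intervals, cri2$intervals)
  # degenerate covariance collapses to the point estimate
  d0 <- make_linear_data(noise = 0)
  d0$y <- 2 + 3 * d0$x1 - 1.5 * d0$x2
  fit0 <- suppressWarnings(fit_model(model_spec("y", c("x1", "x2")), d0))
  cri0 <- simulate_cri(fit0, n_draws = 500, seed = 1)
  expect_equal(cri0$intervals$lower, cri0$intervals$estimate,
               tolerance = 1e-6)
})

test_that("the random-effect LRT separates null from planted brood variance", {
  set.seed(6)
  nb <- 60
  d <- data.frame(brood_id = factor(rep(seq_len(nb), each = 2)),
                  x1 = rnorm(2 * nb))
  # planted brood SD twice the residual SD
  re <- rnorm(nb, 0, 2)
  d$y <- 1 + 0.5 * d$x1 + re[as.integer(d$brood_id)] + rnorm(2 * nb, 0, 1)
  sp <- model_spec("y", "x1", random = "brood_id")
  fit <- fit_model(sp, d)
  lrt <- random_effect_lrt(fit, d, n_null_sims = 199, seed = 3)
  expect_gte(lrt$statistic, 0)
  expect_lt(lrt$p_value, 0.02)
  expect_true(all(lrt$null_stats >= 0))
  # zero brood variance: small statistic, large p
  d0 <- d
  d0$y <- 1 + 0.5 * d0$x1 + rnorm(2 * nb, 0, 1)
  fit0 <- suppressWarnings(suppressMessages(fit_model(sp, d0)))
  lrt0 <- random_effect_lrt(fit0, d0, n_null_sims = 199, seed = 3)
  expect_gt(lrt0$p_value, 0.1)
  expect_warning(random_effect_lrt(fit0, d0, n_null_sims = 50, seed = 1),
                 "fewer than 100")
})

# linear mediation system with scaling metadata attached; the mediator needs
# its own variation or the two predictors are collinear
make_path_system <- function(n = 400, a_nat = 0.03, b_nat = -0.5,
                             c_nat = 0.01, noise_hatch = 1, noise = 0,
                             seed = 21) {
  set.seed(seed)
  elev <- rnorm(n, 800, 100)
  hatch <- 130 + a_nat * (elev - 800) + rnorm(n, 0, noise_hatch)
  dep <- 80 + b_nat * (hatch - 130) + c_nat * (elev - 800) +
    rnorm(n, 0, noise)
  tab <- data.frame(
    departure_age_days = dep, hatch_doy = hatch, elevation_m = elev,
    elev_s = as.numeric(scale(elev)), hatch_s = as.numeric(scale(hatch)))
  attr(tab, "scaling") <- list(
    hatch_doy = c(mean = mean(hatch), sd = sd(hatch)),
    elevation_m = c(mean = mean(elev), sd = sd(elev)))
  tab
}

test_that("path analysis decomposes the total effect exactly per draw", {
  tab <- make_path_system(noise = 0)
  fit_h <- fit_model(model_spec("hatch_doy", "elev_s"), tab)
  fit_d <- suppressWarnings(fit_model(model_spec("departure_age_days",
                                                 c("hatch_s", "elev_s")),
                                      tab))
  pr <- path_analysis(fit_h, fit_d, n_draws = 500, seed = 7)
  # indirect draws are exactly the per-draw product a_std * b
  sd_hatch <- attr(tab, "scaling")$hatch_doy["sd"]
  expect_equal(pr$draws$indirect,
               (pr$draws$a / sd_hatch) * pr$draws$b, ignore_attr = TRUE)
  expect_equal(pr$draws$total, pr$draws$direct + pr$draws$indirect)
  # direct + indirect equals the total-effect regression exactly (the
  # classic OLS path identity, which holds in-sample for nested OLS fits)
  fit_tot <- fit_model(model_spec("departure_age_days", "elev_s"), tab)
  expect_equal(unname(pr$total["estimate"]),
               fit_tot$coefficients$estimate[2], tolerance = 1e-8)
  # natural-unit chain: a close to the generating 3 d / 100 m
  expect_equal(unname(pr$natural["a_days_per_100m"]), 3, tolerance = 0.1)
  # when b = 0 the indirect interval covers 0
  tab0 <- make_path_system(b_nat = 0, noise = 1, seed = 22)
  f_h0 <- fit_model(model_spec("hatch_doy", "elev_s"), tab0)
  f_d0 <- fit_model(model_spec("departure_age_days",
                               c("hatch_s", "elev_s")), tab0)
  pr0 <- path_analysis(f_h0, f_d0, n_draws = 2000, seed = 8)
  expect_lt(pr0$indirect["lower"], 0)
  expect_gt(pr0$indirect["upper"], 0)
})

test_that("scenario predictions propagate coefficients linearly", {
  st <- generate_study(small_config(seed = 19))
  juv <- st$juveniles
  dep <- data.frame(individual_id = juv$individual_id, status = "departed",
                    departure_age_days = juv$departure_age_days)
  tab <- assemble_covariates(juv, dep)
  sp <- model_spec("departure_age_days",
                   c("treatment", "hatch_s", "elev_s", "sex"),
                   random = "brood_id")
  fit <- suppressWarnings(suppressMessages(fit_model(sp, tab)))
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  # all-defaults scenario = intercept (scaled scale, reference levels)
  p0 <- predict_effects(fit, data.frame(row = 1), n_draws = 300, seed = 1)
  expect_equal(p0$predicted, unname(est["(Intercept)"]), tolerance = 1e-8)
  # fed vs control difference at identical covariates = feeding coefficient
  p <- predict_effects(fit, data.frame(treatment = c("control", "fed")),
                       n_draws = 300, seed = 1)
  expect_equal(diff(p$predicted), unname(est["treatmentfed"]),
               tolerance = 1e-8)
  # monotone decline across hatching date when the coefficient is negative
  grid <- predict_effects(fit, data.frame(hatch_s = seq(-2, 2, 1)),
                          n_draws = 300, seed = 1)
  if (est["hatch_s"] < 0) expect_true(all(diff(grid$predicted) < 0))
  expect_error(predict_effects(fit, data.frame(treatment = "banquet")),
               "unknown level")
  # bands widen away from the data centre and bracket the point estimate
  expect_true(all(grid$lower <= grid$predicted &
                    grid$predicted <= grid$upper))
})
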