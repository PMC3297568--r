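test_that("the cost is a weighted sum of squared normalized residuals", {
  syn0 <- fixture_noiseless()
  gt <- syn0$truth
  data <- syn0$survivor
  # perfect fit
  expect_lt(sepsis_cost(gt$theta_surv, data, g = 1), 1e-10)
  # a single residual of exactly one SD contributes exactly 1
  d1 <- data
  d1$mean[5] <- d1$mean[5] + d1$sd[5]
  expect_equal(sepsis_cost(gt$theta_surv, d1, g = 1), 1, tolerance = 1e-8)
  # hand-summed fixture: known offsets on a 2-observable subset (all seven
  # measurement times kept so the prediction normalization is unchanged)
  d2 <- data[data$observable %in% c("TNF", "IL6"), ]
  set.seed(4)
  offs <- round(stats::runif(14, -0.1, 0.1), 3)
  d2$sd <- rep(c(0.05, 0.1), 7)
  d2$mean <- d2$mean + offs
  expect_equal(sepsis_cost(gt$theta_surv, d2, g = 1), sum((offs / d2$sd)^2),
               tolerance = 1e-6)
  # summation symmetry: shuffling rows leaves the cost unchanged
  set.seed(1)
  d3 <- data[sample.int(nrow(data)), ]
  expect_equal(sepsis_cost(gt$theta_surv, d3, g = 1),
               sepsis_cost(gt$theta_surv, data, g = 1))
  # unknown observables are a configuration error
  d4 <- data
  d4$observable[1] <- "CRP"
  expect_error(sepsis_cost(gt$theta_surv, d4, g = 1), "mapping")
  d5 <- data
  d5$sd[1] <- 0
  expect_error(sepsis_cost(gt$theta_surv, d5, g = 1), "positive")
})

test_that("the Boltzmann target turns cost differences into acceptance", {
  expect_equal(log_target(0, 1), 0)                   # maximal log target
  # acceptance for an uphill move of exactly T is exp(-1)
  expect_equal(exp(log_target(3, 2) - log_target(1, 2)), exp(-1))
  # doubling T halves the log-target difference
  expect_equal(log_target(4, 2) - log_target(2, 2),
               2 * (log_target(4, 4) - log_target(2, 4)))
  expect_error(log_target(1, 0), "positive")
})

test_that("prior draws are log10-uniform within bounds and seeded", {
  b <- prior_bounds()
  draws <- sample_prior(b, n = 500, seed = 3)
  expect_true(all(t(draws) >= b$lo & t(draws) <= b$hi))
  expect_identical(sample_prior(b, seed = 9), sample_prior(b, seed = 9))
  # KS test of one parameter against the uniform CDF on the log10 scale
  b1 <- b[b$name == "tau_pi", ]
  class(b1) <- class(b)
  x <- log10(sample_prior(b1, n = 10000, seed = 5))
  ks <- suppressWarnings(stats::ks.test(x, "punif", log10(b1$lo), log10(b1$hi)))
  expect_gt(ks$p.value, 0.01)
})

test_that("the Metropolis chain respects bounds, seeds and the no-move limit", {
  # quadratic toy cost on two parameters, no ODE involved
  cost_fn <- function(th) sum(log10(th)^2) / 2
  reg <- parameter_registry()[1:2, ]
  reg$prior_lo <- 1e-6; reg$prior_hi <- 1e6
  b <- prior_bounds(ids = 1:2, registry = reg)
  start <- stats::setNames(c(1, 1), b$name)
  ch <- run_chain(cost_fn, start, b, n_steps = 500, sigma = 0.5, seed = 4)
  expect_true(all(t(ch$samples) >= log10(b$lo) & t(ch$samples) <= log10(b$hi)))
  ch2 <- run_chain(cost_fn, start, b, n_steps = 500, sigma = 0.5, seed = 4)
  expect_identical(ch$samples, ch2$samples)
  # vanishing proposal scale: every proposal is accepted
  ch3 <- run_chain(cost_fn, start, b, n_steps = 300, sigma = 1e-12, seed = 1)
  expect_equal(ch3$acceptance_rate, 1)
  expect_error(run_chain(cost_fn, stats::setNames(c(1e9, 1), b$name), b),
               "outside")
})

test_that("thinning and burn-in control the recorded sample count", {
  cost_fn <- function(th) sum(log10(th)^2) / 2
  reg <- parameter_registry()[1:2, ]
  reg$prior_lo <- 1e-6; reg$prior_hi <- 1e6
  b <- prior_bounds(ids = 1:2, registry = reg)
  start <- stats::setNames(c(1, 1), b$name)
  ch <- run_chain(cost_fn, start, b, n_steps = 1000, burn_in = 200, thin = 10,
                  sigma = 0.5, seed = 2)
  expect_equal(nrow(ch$samples), 100)
  expect_equal(length(ch$costs), 100)
})

test_that("Gelman-Rubin separates converged from separated chains", {
  set.seed(8)
  iid <- replicate(5, matrix(rnorm(5000 * 2), ncol = 2), simplify = FALSE)
  rep1 <- gelman_rubin(iid)
  expect_true(all(rep1$psrf < 1.05))
  expect_true(all(rep1$psrf >= 1 - 1e-3))
  sep <- list(matrix(rnorm(1000, 0), ncol = 1),
              matrix(rnorm(1000, 10), ncol = 1))
  expect_gt(gelman_rubin(sep)$psrf, 1.2)
  expect_error(gelman_rubin(iid[1]), "two chains")
  expect_error(gelman_rubin(list(matrix(1, 50, 1), matrix(1, 50, 1))),
               "variance")
  expect_error(gelman_rubin(list(matrix(rnorm(20), ncol = 1),
                                 matrix(rnorm(30), ncol = 1))),
               "equal")
})

test_that("effective sample size shrinks with autocorrelation", {
  set.seed(21)
  x <- rnorm(4000)
  expect_gt(effective_sample_size(x), 2000)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.9), 4000))
  expect_lt(effective_sample_size(ar), 1500)
})

test_that("mapping-parameter fit lowers the summed two-cohort cost", {
  syn <- fixture_cohort()
  base <- default_parameters()
  perturbed <- base
  map_names <- parameter_registry()$name[35:50]
  perturbed[map_names] <- perturbed[map_names] * 1.8
  before <- sepsis_cost(perturbed, syn$survivor, 1) +
    sepsis_cost(perturbed, syn$nonsurvivor, 1)
  fit <- fit_mapping(syn$survivor, syn$nonsurvivor, perturbed, perturbed,
                     maxit = 8)
  expect_named(fit$mapping, map_names)
  expect_lte(fit$value, before)
})

test_that("calibrate_ensemble returns a usable model fit object", {
  syn <- fixture_cohort()
  mask <- c("kappa_pi_b", "tau_prime", "tau_mig", "tau_pi")
  fit <- calibrate_ensemble(syn$nonsurvivor, mask = mask, n_chains = 2,
                            n_steps = 400, burn_in = 400, thin = 4,
                            seed = 6, temperature = 5)
  expect_s3_class(fit, "sepsis_fit")
  expect_equal(ncol(fit$ensemble), 4)
  expect_equal(nrow(fit$ensemble), 2 * 100)
  expect_equal(nrow(fit$psrf), 4)
  th <- coef(fit)
  expect_length(th, 57)
  expect_true(all(th[mask] >= prior_bounds()$lo[match(mask, prior_bounds()$name)]))
  tr <- simulate(fit, times = seq(0, 48, 8))
  expect_s3_class(tr, "sepsis_trajectory")
  expect_length(residuals(fit), nrow(syn$nonsurvivor))
  expect_output(print(fit), "sepsis_fit")
  s <- summary(fit)
  expect_equal(nrow(s), 4)
  # artifact round trip
  dir <- tempfile()
  paths <- write_fit_artifacts(fit, dir)
  expect_true(all(file.exists(file.path(dir, c("chain_01.csv", "chain_02.csv",
                                               "chain_psrf.json")))))
})

test_that("tuning reaches the target acceptance band on a toy target", {
  cost_fn <- function(th) sum(log10(th)^2) / 2
  reg <- parameter_registry()[1:3, ]
  reg$prior_lo <- 1e-6; reg$prior_hi <- 1e6
  b <- prior_bounds(ids = 1:3, registry = reg)
  start <- stats::setNames(rep(1, 3), b$name)
  tn <- tune_chain(cost_fn, start, b, target_acceptance = 0.25,
                   n_tune = 6000, seed = 5)
  ch <- run_chain(cost_fn, tn$start, b, n_steps = 6000, sigma = tn$sigma,
                  temperature = tn$temperature, seed = 6)
  expect_gte(ch$acceptance_rate, 0.20)
  expect_lte(ch$acceptance_rate, 0.30)
  # an unreachable target is reported, not fatal
  tn_bad <- tune_chain(cost_fn, start, b, target_acceptance = 0.99,
                       n_tune = 1200, sigma0 = 20, seed = 7)
  expect_false(tn_bad$reached)
})
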