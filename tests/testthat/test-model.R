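test_that("Hill functions match their closed forms and contracts", {
  K <- 0.37
  expect_equal(hill(0, K), 0)
  expect_equal(hill(K, K), 0.5)
  # hand evaluation of x^n/(x^n + K^n) at x = 100 K
  expect_equal(hill(100 * K, K, 3), 1e6 / (1e6 + 1), tolerance = 1e-12)
  expect_true(all(diff(hill(seq(0, 10, 0.1), K)) >= 0))    # monotone
  expect_equal(hill_norm(1, K), 1)                         # normalized at 1
  expect_equal(hill_norm(0, K), 0)
  # normalized HillCube is the plain Hill rescaled by its value at 1
  x <- c(0.1, 0.4, 0.9)
  expect_equal(hill_norm(x, K), hill(x, K) / hill(1, K), tolerance = 1e-12)
  expect_error(hill(1, -1), "positive")
  expect_error(hill(-1, 1), "negative")
  expect_error(hill(1, 1, n = 0.5), "coefficient")
})

test_that("homeostatic state is an exact fixed point of the derivatives", {
  p <- default_parameters()
  s0 <- homeostatic_state(p)
  d <- sepsis_derivatives(0, s0, p, g = 0)
  expect_true(all(abs(d) < 1e-8 * pmax(abs(s0), 1)))
})

test_that("bacterial derivative matches the hand-computed balance", {
  p <- default_parameters()
  s <- homeostatic_state(p)
  s[c("N_bm", "N_r")] <- 0
  s["B"] <- 1e6
  d <- sepsis_derivatives(0, s, p, g = 0)
  # logistic growth at 0.1/hr toward 1e9, macrophage removal saturated at
  # 0.1/hr x 1e5 for B > B_mac; no neutrophils, no CLP source
  expect_equal(unname(d["B"]), 0.1 * 1e6 * (1 - 1e6 / 1e9) - 0.1 * 1e5,
               tolerance = 1e-12)
})

test_that("full inflammation with full anti-inflammation decays without drive", {
  p <- default_parameters()
  s <- homeostatic_state(p)
  s[c("N_bm", "N_r")] <- 0
  s["PI"] <- 1
  s["AI"] <- 1
  d <- sepsis_derivatives(0, s, p, g = 0)
  expect_lte(unname(d["PI"]), 0)
})

test_that("compiled and reference right-hand sides agree along trajectories", {
  p <- default_parameters()
  for (ha in list(NULL, ha_config())) {
    t1 <- simulate_sepsis(p, g = 1, times = seq(0, 60, 3), ha = ha)
    t2 <- simulate_sepsis(p, g = 1, times = seq(0, 60, 3), ha = ha,
                          compiled = FALSE)
    expect_lt(max(abs(t1$states - t2$states) / pmax(abs(t1$states), 1)), 1e-6)
  }
})

test_that("activation flux sums the three PI-gated transitions", {
  p <- default_parameters()
  s <- homeostatic_state(p)
  s["N_r"] <- 0; s["N_p"] <- 0; s["N_a"] <- 0
  expect_equal(activation_flux(s, p), 0)          # empty source pools
  s["N_r"] <- 1e6; s["N_p"] <- 1e5; s["PI"] <- 0
  expect_equal(activation_flux(s, p), 0)          # PI gates are closed
  s["PI"] <- 0.5
  # term-by-term hand evaluation with the baseline thresholds
  hn <- function(x, K) x^3 * (1 + K^3) / (x^3 + K^3)
  expected <- hn(0.5, 0.70) * 1e6 / 20 + hn(0.5, 0.60) * 1e5 / 15 + 0
  expect_equal(activation_flux(s, p), expected, tolerance = 1e-12)
})

test_that("simulation is stationary at homeostasis and deterministic", {
  p <- default_parameters()
  tr <- simulate_sepsis(p, g = 0, times = seq(0, 200, 10))
  dev <- abs(sweep(tr$states, 2, tr$states[1, ], "-")) /
    pmax(abs(tr$states[1, ]), 1e-9)
  expect_lt(max(dev), 1e-5)   # < 10x the 1e-6 relative solver tolerance
  tr2 <- simulate_sepsis(p, g = 0, times = seq(0, 200, 10))
  expect_identical(tr$states, tr2$states)
})

test_that("bacteria follow the closed-form logistic law without removal", {
  p <- default_parameters()
  p["r_kill"] <- 1e-30     # neutrophil killing disabled
  p["r_mac"] <- 0          # resident macrophage removal disabled
  s0 <- homeostatic_state(p)
  s0["B"] <- 1e4
  times <- seq(0, 120, 4)
  tr <- simulate_sepsis(p, g = 0, times = times, state0 = s0,
                        rtol = 1e-8, atol = c(rep(1e-4, 8), rep(1e-12, 11)))
  K <- 1e9; r <- 0.1; B0 <- 1e4
  closed <- K * B0 * exp(r * times) / (K + B0 * (exp(r * times) - 1))
  expect_lt(max(abs(tr$states[, "B"] - closed) / closed), 1e-4)
})

test_that("bacteria plateau at the carrying capacity when killing is disabled", {
  p <- default_parameters()
  p["r_kill"] <- 1e-30
  tr <- simulate_sepsis(p, g = 1, times = seq(0, 200, 5))
  expect_lt(abs(tr$states[nrow(tr$states), "B"] / 1e9 - 1), 1e-3)
})

test_that("a stronger CLP severity never lowers the early bacterial load", {
  p <- default_parameters()
  times <- seq(0, 6, 0.5)
  b_prev <- rep(0, length(times))
  for (g in c(0.2, 0.5, 0.8, 1)) {
    b <- simulate_sepsis(p, g = g, times = times)$states[, "B"]
    expect_true(all(b >= b_prev - 1e-6 * pmax(b, 1)))
    b_prev <- b
  }
})

test_that("survival classification applies both endpoint criteria", {
  crit <- survival_criteria()   # defaults: horizon 200, B 5e8, PI 0.5
  expect_equal(classify_survival(fake_trajectory(0, 0.1)), "survivor")
  expect_equal(classify_survival(fake_trajectory(0, 0.7)), "non-survivor")
  expect_equal(classify_survival(fake_trajectory(crit$b_crit, 0.1)),
               "non-survivor")
  expect_error(classify_survival(fake_trajectory(0, 0.1, horizon = 100)),
               "before")
  expect_error(survival_criteria(pi_crit = 1.2))
})

test_that("parameter registry has the documented structure", {
  reg <- parameter_registry()
  expect_equal(nrow(reg), 57)
  expect_equal(sum(reg$sampled), 34)
  expect_equal(sum(reg$group == "mapping"), 16)
  expect_equal(sum(reg$group == "constant"), 7)
  expect_true(all(reg$value[1:50] > 0))
  b <- prior_bounds()
  expect_true(all(b$lo < b$hi))
  # bounds cover the baselines
  expect_true(all(reg$value[reg$sampled == 1] >= b$lo &
                    reg$value[reg$sampled == 1] <= b$hi))
  expect_error(prior_bounds(ids = 51), "no prior bounds")
  # round trip through the CSV interface
  tf <- tempfile(fileext = ".csv")
  write_parameter_registry(reg, tf)
  expect_equal(read_parameter_registry(tf)$value, reg$value)
})

test_that("trajectory accessors expose a tidy view", {
  tr <- simulate_sepsis(default_parameters(), g = 0, times = seq(0, 20, 10))
  d <- as.data.frame(tr)
  expect_equal(nrow(d), 3 * 19)
  expect_setequal(unique(d$state), state_names())
  tf <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, tf)
  expect_equal(nrow(utils::read.csv(tf)), 57)
})
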