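test_that("HA removal is a windowed Hill elimination of exactly three targets", {
  ha <- ha_config()
  s <- homeostatic_state(default_parameters())
  expect_equal(ha_removal_rates(s, ha, 19), c(N_a = 0, PI = 0, AI = 0))
  s["N_a"] <- ha$half_na; s["PI"] <- ha$half_pi; s["AI"] <- ha$half_ai
  # half-maximal levels give half the maximal rates inside the window
  r <- ha_removal_rates(s, ha, 20)
  expect_equal(unname(r), c(ha$rate_na, ha$rate_pi, ha$rate_ai) / 2)
  # just outside the window the rates are exactly zero
  expect_equal(unname(ha_removal_rates(s, ha, 17.9)), c(0, 0, 0))
  expect_equal(unname(ha_removal_rates(s, ha, 22)), c(0, 0, 0))
  expect_error(ha_config(rate_pi = -1), ">= 0")
  expect_error(ha_config(t_on = 22, t_off = 18), "t_on < t_off")
})

test_that("a zero-rate device is bit-identical to no treatment", {
  p <- sepsis_ground_truth()$theta_nonsurv
  sham_cfg <- ha_config(rate_na = 0, rate_pi = 0, rate_ai = 0)
  t1 <- simulate_sepsis(p, 1, seq(0, 100, 5))
  t2 <- simulate_sepsis(p, 1, seq(0, 100, 5), ha = sham_cfg)
  expect_identical(t1$states, t2$states)
})

test_that("treatment does not alter the trajectory before the window opens", {
  p <- sepsis_ground_truth()$theta_nonsurv
  times <- seq(0, 60, 2)
  t1 <- simulate_sepsis(p, 1, times)
  t2 <- simulate_sepsis(p, 1, times, ha = ha_config())
  pre <- times <= 18
  dev <- abs(t2$states[pre, ] - t1$states[pre, ]) /
    pmax(abs(t1$states[pre, ]), 1)
  expect_lt(max(dev), 1e-6)   # same solver path up to restart tolerance
  # and does alter it afterwards
  expect_gt(max(abs(t2$states[!pre, "PI"] - t1$states[!pre, "PI"])), 0.1)
})

test_that("stronger PI elimination cannot raise PI at the end of the window", {
  ens <- fixture_ns_ensemble()
  base <- default_parameters()
  times <- c(0, 18, 20, 22)
  set.seed(14)
  for (i in sample.int(nrow(ens), 5)) {
    th <- base
    th[colnames(ens)] <- 10^ens[i, ]
    pi_prev <- Inf
    for (rate in c(0.1, 0.5, 1, 3)) {
      tr <- simulate_sepsis(th, 1, times,
                            ha = ha_config(rate_pi = rate))
      pi_now <- tr$states[4, "PI"]
      expect_lte(pi_now, pi_prev + 1e-9)
      pi_prev <- pi_now
    }
  }
})

test_that("treating an ensemble reports a full outcome partition", {
  ens <- fixture_ns_ensemble()
  rep_ <- treat_ensemble(ens[1:30, ], n_draw = 30, replace = FALSE, seed = 9,
                         times = seq(0, 200, 4))
  expect_s3_class(rep_, "treatment_report")
  ok <- sum(!is.na(rep_$outcomes$treated_outcome))
  expect_equal(rep_$counts[["treated_survivor"]] +
                 rep_$counts[["treated_nonsurvivor"]], ok)
  expect_equal(ok + rep_$failures, 30)
  expect_true(all(rep_$outcomes$sham_outcome[!is.na(rep_$outcomes$sham_outcome)]
                  == "non-survivor"))
  # zero-rate device: treated outcomes equal sham outcomes member by member
  sham_rep <- treat_ensemble(ens[1:15, ],
                             ha = ha_config(rate_na = 0, rate_pi = 0,
                                            rate_ai = 0),
                             n_draw = 15, replace = FALSE, seed = 3,
                             times = seq(0, 200, 4))
  expect_identical(sham_rep$outcomes$sham_outcome,
                   sham_rep$outcomes$treated_outcome)
  # report artifacts
  tf1 <- tempfile(fileext = ".csv"); tf2 <- tempfile(fileext = ".json")
  write_treatment_report(rep_, tf1, tf2)
  agg <- jsonlite::read_json(tf2)
  expect_equal(agg$n_draw, 30)
  expect_error(treat_ensemble(ens[1:5, ], n_draw = 10, replace = FALSE),
               "exceeds")
})

test_that("misdirected elimination can harm a borderline survivor", {
  # high AI elimination with no PI elimination removes the brake on systemic
  # inflammation: at least one synthetic survivor flips to non-survivor
  gt <- sepsis_ground_truth()
  surv <- jittered_ensemble(gt$theta_nonsurv, n = 260, jitter_sd = 0.15,
                            seed = 31, outcome = "survivor")
  expect_gt(nrow(surv), 10)
  ha_bad <- ha_config(rate_pi = 0, rate_na = 0, rate_ai = 1, half_ai = 0.02)
  harmed <- 0
  for (i in seq_len(min(nrow(surv), 40))) {
    th <- default_parameters()
    th[colnames(surv)] <- 10^surv[i, ]
    out <- classify_survival(simulate_sepsis(th, 1, seq(0, 200, 4),
                                             ha = ha_bad))
    if (out == "non-survivor") harmed <- harmed + 1
  }
  expect_gte(harmed, 1)
})
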