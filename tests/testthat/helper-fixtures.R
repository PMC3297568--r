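# shared fixtures, built once per test run

# default noisy synthetic cohort (23 virtual animals)
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(sepsis_ground_truth(), seed = 11)
    cache
  }
})

# noiseless single-phenotype cohort (both cohorts at the survivor truth):
# cohort means equal the max-normalized simulated observables exactly
fixture_noiseless <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gt <- sepsis_ground_truth(noise_sd = 0, jitter_sd = 0)
      gt$theta_nonsurv <- gt$theta_surv
      cache <<- generate_cohort(gt, seed = 1)
    }
    cache
  }
})

# jittered non-survivor ensemble restricted to sham non-survivors
fixture_ns_ensemble <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gt <- sepsis_ground_truth()
      cache <<- jittered_ensemble(gt$theta_nonsurv, n = 260, jitter_sd = 0.15,
                                  seed = 31, outcome = "non-survivor")
    }
    cache
  }
})

# build a trajectory-shaped object with prescribed endpoint values, for
# exercising the survival classifier without a solver run
fake_trajectory <- function(b_end, pi_end, horizon = 200) {
  times <- c(0, horizon)
  states <- matrix(0, 2, 19, dimnames = list(NULL, state_names()))
  states[2, "B"] <- b_end
  states[2, "PI"] <- pi_end
  structure(list(times = times, states = states,
                 params = default_parameters(), g = 1, ha = NULL),
            class = "sepsis_trajectory")
}

# random correlated Gaussian ensemble with a reproducible structure
random_gaussian_ensemble <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  Sigma <- crossprod(A) + diag(p) * 0.5
  L <- chol(Sigma)
  x <- matrix(rnorm(n * p), n) %*% L
  colnames(x) <- paste0("x", seq_len(p))
  x
}
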