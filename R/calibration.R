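#' Weighted least-squares cost of a parameter set against cohort data
#'
#' The cost is the weighted sum of squared residuals over all observables and
#' measurement times, `C = sum(((m - yhat) / sigma)^2)`, where `m` and
#' `sigma` are the cohort mean and standard deviation of the normalized
#' measurement and `yhat` is the model's normalized prediction: the simulated
#' observable state divided by its maximum over the measurement times, with
#' the same detection floor applied by [log_max_normalize()] (so vanishing
#' trajectories predict ~0 rather than a rescaled shape). Integration
#' failure maps to `Inf` (the proposal is rejected by the sampler).
#'
#' @param theta Full named parameter vector (57 entries).
#' @param data Cohort data.frame with columns `observable`, `time_h`,
#'   `mean`, `sd` (one cohort).
#' @param g CLP severity grade.
#' @return Non-negative scalar cost (`Inf` on solver failure).
#' @export
sepsis_cost <- function(theta, data, g = 1) {
  if (any(data$sd <= 0)) stop("data SDs must be positive", call. = FALSE)
  obs <- unique(data$observable)
  bad <- setdiff(obs, observable_names())
  if (length(bad))
    stop("no observation mapping for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  times <- sort(unique(data$time_h))
  tr <- tryCatch(simulate_sepsis(theta, g, c(0, times)),
                 error = function(e) NULL)
  if (is.null(tr)) return(Inf)
  total <- 0
  for (o in obs) {
    y <- tr$states[-1, paste0("O_", o)]
    yhat <- y / max(y, 1e-3)
    sub <- data[data$observable == o, ]
    yh <- yhat[match(sub$time_h, times)]
    total <- total + sum(((sub$mean - yh) / sub$sd)^2)
  }
  total
}

#' Log target density from a cost value
#'
#' The sampling target is a Boltzmann weight with the cost as energy:
#' `log pi = -C / T` up to an additive constant, so a proposal with
#' `C_new >= C_old` is accepted with probability `exp(-(C_new - C_old)/T)`.
#'
#' @param cost_value Non-negative cost.
#' @param temperature Sampling temperature `T > 0`.
#' @return Scalar log target value.
#' @export
log_target <- function(cost_value, temperature) {
  if (temperature <= 0)
    stop("temperature must be positive", call. = FALSE)
  -cost_value / temperature
}

#' Draw parameter sets from the log10-uniform prior
#'
#' @param bounds A [prior_bounds()] object.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return For `n = 1` a named parameter vector (natural scale); otherwise an
#'   `n x p` matrix with one draw per row.
#' @export
sample_prior <- function(bounds, n = 1, seed = NULL) {
  stopifnot(inherits(bounds, "prior_bounds"))
  if (!is.null(seed)) set.seed(seed)
  lo <- log10(bounds$lo); hi <- log10(bounds$hi)
  u <- matrix(stats::runif(n * nrow(bounds)), nrow = n, byrow = TRUE)
  draws <- 10^sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  colnames(draws) <- bounds$name
  if (n == 1) draws[1, ] else draws
}

#' Build a cohort cost function over a masked parameter subset
#'
#' Returns `function(theta_sub)` taking the masked parameters (natural
#' scale, named) and evaluating [sepsis_cost()] with the remaining entries
#' fixed at `base_params`.
#'
#' @param data Cohort data.frame.
#' @param base_params Full baseline parameter vector.
#' @param mask Names of the varied parameters.
#' @param g CLP severity grade.
#' @return A cost closure.
#' @export
make_cost_function <- function(data, base_params = default_parameters(),
                               mask = parameter_registry()$name[sampled_parameter_ids()],
                               g = 1) {
  force(data); force(base_params); force(mask); force(g)
  function(theta_sub) {
    theta <- base_params
    theta[mask] <- theta_sub
    sepsis_cost(theta, data, g)
  }
}

#' Run one Metropolis chain
#'
#' Random-walk Metropolis in log10 parameter space: proposals are
#' componentwise normal around the current point, proposals outside the
#' prior bounds are rejected (preserving the truncated uniform prior), and
#' in-bounds proposals are accepted with probability
#' `min(1, exp(-(C_new - C_old)/T))`.
#'
#' @param cost_fn Cost closure over the masked parameters (natural scale).
#' @param start Named start vector (natural scale) within bounds.
#' @param bounds [prior_bounds()] for the masked parameters.
#' @param n_steps Number of Metropolis proposals after burn-in.
#' @param sigma Proposal sd in log10 space (scalar or per-parameter).
#' @param temperature Sampling temperature.
#' @param burn_in Steps discarded before recording.
#' @param thin Record every `thin`-th post-burn-in step.
#' @param seed Integer seed; fixed seed gives a bit-identical chain.
#' @return An `mcmc_chain`: `samples` (log10 scale, one row per recorded
#'   step), `costs`, `accepted` flags, `acceptance_rate` (post-burn-in
#'   accepted / proposals) and the configuration.
#' @export
run_chain <- function(cost_fn, start, bounds, n_steps = 2000, sigma = 0.05,
                      temperature = 1, burn_in = 0, thin = 1, seed = 1) {
  stopifnot(inherits(bounds, "prior_bounds"), n_steps >= 1, burn_in >= 0,
            thin >= 1, all(sigma > 0), temperature > 0)
  p <- nrow(bounds)
  lo <- log10(bounds$lo); hi <- log10(bounds$hi)
  u <- log10(unname(start[bounds$name]))
  if (any(u < lo | u > hi))
    stop("start point outside prior bounds", call. = FALSE)
  if (length(sigma) == 1) sigma <- rep(sigma, p)
  set.seed(seed)

  cur_cost <- cost_fn(stats::setNames(10^u, bounds$name))
  n_total <- burn_in + n_steps
  n_keep <- n_steps %/% thin
  samples <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, bounds$name))
  costs <- numeric(n_keep)
  accepted <- logical(n_keep)
  acc_post <- 0L
  k <- 0L
  for (s in seq_len(n_total)) {
    prop <- u + stats::rnorm(p, 0, sigma)
    acc <- FALSE
    if (all(prop >= lo & prop <= hi)) {
      new_cost <- cost_fn(stats::setNames(10^prop, bounds$name))
      if (is.finite(new_cost)) {
        d <- (new_cost - cur_cost) / temperature
        if (d <= 0 || stats::runif(1) < exp(-d)) {
          u <- prop; cur_cost <- new_cost; acc <- TRUE
        }
      }
    }
    if (s > burn_in) {
      if (acc) acc_post <- acc_post + 1L
      if ((s - burn_in) %% thin == 0) {
        k <- k + 1L
        samples[k, ] <- u
        costs[k] <- cur_cost
        accepted[k] <- acc
      }
    }
  }
  structure(list(samples = samples, costs = costs, accepted = accepted,
                 acceptance_rate = acc_post / n_steps,
                 config = list(n_steps = n_steps, burn_in = burn_in,
                               thin = thin, sigma = sigma,
                               temperature = temperature, seed = seed)),
            class = "mcmc_chain")
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat("<mcmc_chain>", nrow(x$samples), "recorded samples x",
      ncol(x$samples), "parameters; acceptance",
      sprintf("%.3f", x$acceptance_rate), "\n")
  invisible(x)
}

#' Tune proposal scale (and temperature) toward a target acceptance ratio
#'
#' Stochastic-approximation tuning run during a dedicated burn-in phase.
#' After an initial settle phase, the chain is advanced in batches: a global
#' proposal scale follows a diminishing-gain Robbins-Monro update toward the
#' target acceptance ratio while per-parameter relative scales track the
#' recent sample spread (adaptive diagonal proposal). Finally, acceptance is
#' probed at frozen scales and corrected, and the configuration is frozen so
#' post-freeze samples satisfy the stationarity assumptions. If no
#' temperature is supplied it is set once from the initial cost
#' (`T = max(8, C0 / 25)`) before adaptation.
#'
#' @inheritParams run_chain
#' @param target_acceptance Desired acceptance ratio in (0, 1) (default 0.25).
#' @param n_tune Total tuning proposals.
#' @param batch Batch size between adaptations.
#' @param sigma0 Initial proposal sd (log10 space).
#' @return A frozen configuration: list with `sigma`, `temperature`, `start`
#'   (chain endpoint, natural scale), `acceptance` (last-batch ratio),
#'   `reached` (within 0.05 of target) and the adaptation `history`.
#' @export
tune_chain <- function(cost_fn, start, bounds, target_acceptance = 0.25,
                       n_tune = 8000, batch = 100, sigma0 = 0.05,
                       temperature = NULL, seed = 1) {
  stopifnot(target_acceptance > 0, target_acceptance < 1)
  p <- nrow(bounds)
  lo <- log10(bounds$lo); hi <- log10(bounds$hi)
  u <- log10(unname(start[bounds$name]))
  set.seed(seed)
  cur_cost <- cost_fn(stats::setNames(10^u, bounds$name))
  # the floor keeps the Boltzmann landscape smooth enough that the frozen
  # acceptance ratio is stable while the chain explores basins of varying
  # local roughness
  if (is.null(temperature)) temperature <- max(8, cur_cost / 25)

  advance <- function(n, sig) {
    acc_n <- 0L
    path <- matrix(NA_real_, n, p)
    for (s in seq_len(n)) {
      prop <- u + stats::rnorm(p, 0, sig)
      if (all(prop >= lo & prop <= hi)) {
        new_cost <- cost_fn(stats::setNames(10^prop, bounds$name))
        if (is.finite(new_cost)) {
          d <- (new_cost - cur_cost) / temperature
          if (d <= 0 || stats::runif(1) < exp(-d)) {
            u <<- prop; cur_cost <<- new_cost; acc_n <- acc_n + 1L
          }
        }
      }
      path[s, ] <- u
    }
    list(acc = acc_n, path = path)
  }

  # settle phase: let the chain descend toward the typical set before the
  # acceptance statistics are used for adaptation
  n_settle <- min(500, n_tune %/% 4)
  advance(n_settle, sigma0)

  # stochastic approximation on a global scale factor, with relative
  # per-parameter scales re-estimated from the recent sample spread
  log_sc <- log(sigma0)
  rel <- rep(1, p)
  recent <- NULL
  n_batches <- max(1, (n_tune - n_settle) %/% batch)
  hist_acc <- numeric(n_batches)
  for (b in seq_len(n_batches)) {
    r <- advance(batch, exp(log_sc) * rel)
    acc_rate <- r$acc / batch
    hist_acc[b] <- acc_rate
    log_sc <- log_sc + (1.5 / b^0.7) * (acc_rate - target_acceptance)
    recent <- rbind(recent, r$path)
    if (nrow(recent) > 600) recent <- recent[-seq_len(nrow(recent) - 600), ]
    if (b %% 10 == 0 && nrow(recent) >= 500) {
      sds <- pmax(apply(recent, 2, stats::sd), 1e-3)
      rel <- sds / exp(mean(log(sds)))
    }
  }

  # probe rounds: acceptance keeps drifting while the chain descends during
  # adaptation, so measure it at frozen scales where the chain has settled
  # and apply final corrections before freezing
  sigma <- exp(log_sc) * rel
  tail_acc <- mean(hist_acc[max(1, n_batches - 4):n_batches])
  probe <- min(1500, max(200, n_tune %/% 4))
  for (rnd in 1:5) {
    acc_probe <- advance(probe, sigma)$acc / probe
    tail_acc <- acc_probe
    if (abs(acc_probe - target_acceptance) <= 0.015) break
    sigma <- sigma * exp(1.2 * (acc_probe - target_acceptance))
  }

  list(sigma = sigma, temperature = temperature,
       start = stats::setNames(10^u, bounds$name),
       acceptance = tail_acc,
       reached = abs(tail_acc - target_acceptance) <= 0.05,
       history = hist_acc)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' For each parameter, the PSRF is the square root of the ratio of the
#' pooled-variance estimate to the mean within-chain variance:
#' `W = mean(s_j^2)`, `B/n = var(chain means)`,
#' `Vhat = (n-1)/n * W + B/n`, `PSRF = sqrt(Vhat / W)`.
#' Values near 1 indicate approximate convergence of parallel chains.
#'
#' @param chains List of at least two `mcmc_chain` objects or sample
#'   matrices with equal numbers of rows (>= 10).
#' @return A `psrf_report`: data.frame with columns `parameter`, `psrf`,
#'   plus attributes `n_chains`, `n_samples`.
#' @export
gelman_rubin <- function(chains) {
  mats <- lapply(chains, function(ch) {
    if (inherits(ch, "mcmc_chain")) ch$samples else as.matrix(ch)
  })
  if (length(mats) < 2)
    stop("Gelman-Rubin diagnostics require at least two chains",
         call. = FALSE)
  n <- unique(vapply(mats, nrow, integer(1)))
  if (length(n) != 1)
    stop("chains must have equal post-burn-in lengths", call. = FALSE)
  if (n < 10) stop("chains too short (need >= 10 samples)", call. = FALSE)
  p <- ncol(mats[[1]])
  m <- length(mats)
  psrf <- numeric(p)
  for (j in seq_len(p)) {
    x <- vapply(mats, function(mm) mm[, j], numeric(n))
    W <- mean(apply(x, 2, stats::var))
    if (W <= 0)
      stop("zero within-chain variance for parameter ", j, call. = FALSE)
    Bn <- stats::var(colMeans(x))   # B/n
    vhat <- (n - 1) / n * W + Bn
    psrf[j] <- sqrt(vhat / W)
  }
  nm <- colnames(mats[[1]])
  out <- data.frame(parameter = if (is.null(nm)) paste0("p", seq_len(p)) else nm,
                    psrf = psrf, stringsAsFactors = FALSE)
  attr(out, "n_chains") <- m
  attr(out, "n_samples") <- n
  class(out) <- c("psrf_report", "data.frame")
  out
}

#' Integrated-autocorrelation effective sample size
#'
#' Effective number of independent draws `n / (1 + 2 * sum(rho_k))`, with the
#' autocorrelation sum truncated at the first non-positive term (initial
#' positive sequence). For a matrix, the minimum over columns (conservative).
#'
#' @param x Numeric vector or sample matrix.
#' @return Effective sample size (scalar).
#' @export
effective_sample_size <- function(x) {
  if (is.matrix(x))
    return(min(apply(x, 2, effective_sample_size)))
  n <- length(x)
  if (stats::var(x) == 0) return(1)
  rho <- stats::acf(x, lag.max = min(n - 1, 1000), plot = FALSE)$acf[-1]
  s <- 0
  for (r in rho) {
    if (r <= 0) break
    s <- s + r
  }
  max(1, n / (1 + 2 * s))
}

#' Fit the shared observation-mapping parameters
#'
#' The 16 observation-mapping parameters must be consistent across cohorts;
#' they are estimated once, before MCMC, by minimizing the sum of the two
#' cohorts' costs with a bounded local optimizer (L-BFGS-B on log10 scale),
#' then frozen.
#'
#' @param data_surv,data_nonsurv Cohort data.frames.
#' @param params_surv,params_nonsurv Cohort dynamic parameter vectors into
#'   which candidate mapping values are substituted.
#' @param g CLP severity grade.
#' @param maxit Optimizer iteration cap.
#' @return List with `mapping` (named fitted values), `value` (summed cost),
#'   and `convergence` (optim code).
#' @export
fit_mapping <- function(data_surv, data_nonsurv,
                        params_surv = default_parameters(),
                        params_nonsurv = params_surv, g = 1, maxit = 40) {
  reg <- parameter_registry()
  map_names <- reg$name[reg$group == "mapping"]
  lo <- log10(reg$prior_lo[reg$group == "mapping"])
  hi <- log10(reg$prior_hi[reg$group == "mapping"])
  objective <- function(u) {
    v <- stats::setNames(10^u, map_names)
    ps <- params_surv; pn <- params_nonsurv
    ps[map_names] <- v; pn[map_names] <- v
    sepsis_cost(ps, data_surv, g) + sepsis_cost(pn, data_nonsurv, g)
  }
  fit <- stats::optim(log10(params_surv[map_names]), objective,
                      method = "L-BFGS-B", lower = lo, upper = hi,
                      control = list(maxit = maxit))
  list(mapping = stats::setNames(10^fit$par, map_names), value = fit$value,
       convergence = fit$convergence)
}

#' Calibrate a parameter ensemble to cohort data
#'
#' The package's main fitting function: runs several independently seeded
#' Metropolis chains (optionally tuned during burn-in toward a 0.25
#' acceptance ratio), pools the post-burn-in samples into a parameter
#' ensemble, and computes Gelman-Rubin diagnostics.
#'
#' @param data Cohort data.frame `(observable, time_h, mean, sd)`.
#' @param base_params Full baseline parameter vector; unmasked entries stay
#'   fixed.
#' @param mask Names of the sampled parameters (default: the 34 dynamic
#'   parameters).
#' @param n_chains Number of chains (default 3; the full-scale study preset
#'   is 5).
#' @param n_steps Post-burn-in proposals per chain.
#' @param burn_in Discarded proposals per chain (tuning happens here).
#' @param thin Thinning interval.
#' @param seed Master seed; chain `i` uses `seed + i - 1`.
#' @param g CLP severity grade.
#' @param tune Tune proposal scale during burn-in (default `TRUE`).
#' @param temperature Sampling temperature; `NULL` = set from the initial
#'   cost during tuning.
#' @param sigma0 Initial proposal sd (log10).
#' @param target_acceptance Tuning target.
#' @param start Optional start vector for the masked parameters (natural
#'   scale); default: prior draws per chain.
#' @return A `sepsis_fit` object with `chains`, pooled `ensemble` (log10
#'   samples), `psrf`, the data and settings. Methods: `print`, `summary`,
#'   `coef` (posterior median, natural scale, full 57-vector), `simulate`
#'   (trajectory at the posterior median), `plot` (fit against the data).
#' @export
calibrate_ensemble <- function(data, base_params = default_parameters(),
                               mask = NULL, n_chains = 3, n_steps = 4000,
                               burn_in = 2000, thin = 5, seed = 1, g = 1,
                               tune = TRUE, temperature = NULL, sigma0 = 0.05,
                               target_acceptance = 0.25, start = NULL) {
  reg <- parameter_registry()
  if (is.null(mask)) mask <- reg$name[reg$sampled == 1L]
  bounds <- prior_bounds(reg$id[match(mask, reg$name)], reg)
  cost_fn <- make_cost_function(data, base_params, mask, g)

  chains <- vector("list", n_chains)
  tunings <- vector("list", n_chains)
  for (i in seq_len(n_chains)) {
    chain_seed <- seed + i - 1L
    st <- if (is.null(start)) sample_prior(bounds, seed = chain_seed * 1000L)
          else start[mask]
    if (tune) {
      tn <- tune_chain(cost_fn, st, bounds,
                       target_acceptance = target_acceptance,
                       n_tune = burn_in, sigma0 = sigma0,
                       temperature = temperature, seed = chain_seed)
      chains[[i]] <- run_chain(cost_fn, tn$start, bounds, n_steps = n_steps,
                               sigma = tn$sigma, temperature = tn$temperature,
                               burn_in = 0, thin = thin, seed = chain_seed)
      tunings[[i]] <- tn
    } else {
      chains[[i]] <- run_chain(cost_fn, st, bounds, n_steps = n_steps,
                               sigma = sigma0,
                               temperature = if (is.null(temperature)) 1 else temperature,
                               burn_in = burn_in, thin = thin,
                               seed = chain_seed)
    }
  }
  ensemble <- do.call(rbind, lapply(chains, function(ch) ch$samples))
  psrf <- if (n_chains >= 2) gelman_rubin(chains) else NULL
  structure(list(chains = chains, ensemble = ensemble, tunings = tunings,
                 psrf = psrf, mask = mask, bounds = bounds, data = data,
                 base_params = base_params, g = g, seed = seed,
                 settings = list(n_chains = n_chains, n_steps = n_steps,
                                 burn_in = burn_in, thin = thin,
                                 tune = tune)),
            class = "sepsis_fit")
}

#' @export
print.sepsis_fit <- function(x, ...) {
  cat("<sepsis_fit>", length(x$chains), "chains,",
      nrow(x$ensemble), "pooled samples,", length(x$mask),
      "sampled parameters\n")
  acc <- vapply(x$chains, function(ch) ch$acceptance_rate, numeric(1))
  cat("  acceptance:", paste(sprintf("%.3f", acc), collapse = " "), "\n")
  cat("  min cost  :", sprintf("%.2f", min(vapply(x$chains, function(ch)
    min(ch$costs), numeric(1)))), "\n")
  if (!is.null(x$psrf))
    cat("  max PSRF  :", sprintf("%.3f", max(x$psrf$psrf)), "\n")
  invisible(x)
}

#' @export
coef.sepsis_fit <- function(object, ...) {
  med <- apply(object$ensemble, 2, stats::median)
  theta <- object$base_params
  theta[object$mask] <- 10^med
  theta
}

#' @export
summary.sepsis_fit <- function(object, ...) {
  q <- t(apply(object$ensemble, 2, stats::quantile,
               probs = c(0.05, 0.25, 0.5, 0.75, 0.95)))
  out <- data.frame(parameter = rownames(q), q, check.names = FALSE,
                    row.names = NULL)
  if (!is.null(object$psrf)) out$psrf <- object$psrf$psrf
  cat("Posterior quantiles (log10 scale) of", length(object$mask),
      "sampled parameters,", nrow(object$ensemble), "pooled samples\n")
  out
}

#' @export
simulate.sepsis_fit <- function(object, nsim = 1, seed = NULL,
                                times = seq(0, 200, 2), ...) {
  if (!is.null(seed)) set.seed(seed)
  if (nsim == 1)
    return(simulate_sepsis(coef(object), object$g, times))
  idx <- sample.int(nrow(object$ensemble), nsim, replace = TRUE)
  lapply(idx, function(i) {
    theta <- object$base_params
    theta[object$mask] <- 10^object$ensemble[i, ]
    simulate_sepsis(theta, object$g, times)
  })
}

#' @export
residuals.sepsis_fit <- function(object, ...) {
  theta <- coef(object)
  data <- object$data
  times <- sort(unique(data$time_h))
  tr <- simulate_sepsis(theta, object$g, c(0, times))
  res <- numeric(nrow(data))
  for (o in unique(data$observable)) {
    y <- tr$states[-1, paste0("O_", o)]
    yhat <- y / max(y, 1e-3)
    i <- data$observable == o
    res[i] <- (data$mean[i] - yhat[match(data$time_h[i], times)]) / data$sd[i]
  }
  res
}

#' @export
plot.sepsis_fit <- function(x, ...) {
  data <- x$data
  times <- sort(unique(data$time_h))
  tr <- simulate_sepsis(coef(x), x$g, seq(0, max(times), length.out = 101))
  op <- graphics::par(mfrow = c(2, 4), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (o in observable_names()) {
    y <- tr$states[, paste0("O_", o)]
    yhat <- y / max(y, 1e-3)
    sub <- data[data$observable == o, ]
    ylim <- range(0, 1, sub$mean + sub$sd, sub$mean - sub$sd)
    graphics::plot(tr$times, yhat, type = "l", ylim = ylim, xlab = "time (h)",
                   ylab = o, ...)
    graphics::points(sub$time_h, sub$mean, pch = 16)
    graphics::arrows(sub$time_h, sub$mean - sub$sd, sub$time_h,
                     sub$mean + sub$sd, angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}

#' Write chain samples and a PSRF report
#'
#' Chains are stored as one CSV per chain (log10 samples plus `cost` and
#' `accepted` columns); the PSRF report as JSON.
#'
#' @param fit A `sepsis_fit`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the written paths.
#' @export
write_fit_artifacts <- function(fit, dir, prefix = "chain") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(fit$chains)) {
    ch <- fit$chains[[i]]
    d <- data.frame(ch$samples, cost = ch$costs, accepted = ch$accepted,
                    check.names = FALSE)
    p <- file.path(dir, sprintf("%s_%02d.csv", prefix, i))
    utils::write.csv(d, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(fit$psrf)) {
    p <- file.path(dir, paste0(prefix, "_psrf.json"))
    jsonlite::write_json(list(parameter = fit$psrf$parameter,
                              psrf = fit$psrf$psrf,
                              n_chains = attr(fit$psrf, "n_chains"),
                              n_samples = attr(fit$psrf, "n_samples")),
                         p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
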