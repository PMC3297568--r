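#' Ground truth for the synthetic two-cohort experiment
#'
#' Defines the virtual CLP cohort emulating the rat study design: 23 animals
#' (7 survivors, 16 non-survivors) measured at 18, 22, 48, 72, 120, 144 and
#' 168 h after CLP at severity g = 1. The survivor cohort uses the registry
#' baseline parameters (prompt priming and migration, activation-resistant
#' neutrophils); the non-survivor cohort slows priming, migration and damage
#' resolution, lowers the systemic-activation and migration-impairment
#' thresholds and delays the anti-inflammatory response, reproducing the
#' dysregulated-trafficking phenotype (sustained bacterial load and
#' inflammation, lung neutrophil accumulation).
#'
#' @param noise_sd Lognormal measurement noise sd on the raw scale.
#' @param jitter_sd Inter-animal lognormal parameter jitter sd (log10 space)
#'   applied to the 34 sampled parameters.
#' @param n_animals,n_survivors Cohort sizes.
#' @param sd_floor Floor applied to per-point standard deviations on the
#'   normalized scale (keeps cost weights finite).
#' @return A `ground_truth` list with `theta_surv`, `theta_nonsurv`, `g`,
#'   `times`, cohort sizes and noise settings.
#' @export
sepsis_ground_truth <- function(noise_sd = 0.2, jitter_sd = 0.1,
                                n_animals = 23, n_survivors = 7,
                                sd_floor = 0.05) {
  stopifnot(n_survivors <= n_animals, noise_sd >= 0, jitter_sd >= 0,
            sd_floor > 0)
  theta_s <- default_parameters()
  theta_n <- theta_s
  theta_n[c("tau_prime", "tau_mig", "kappa_act_r", "kappa_act_p",
            "kappa_mig_inh", "kappa_ai_pi", "tau_d", "kappa_pi_b")] <-
    c(15, 8, 0.28, 0.30, 0.48, 0.55, 80, 0.45)
  structure(list(theta_surv = theta_s, theta_nonsurv = theta_n, g = 1,
                 times = c(18, 22, 48, 72, 120, 144, 168),
                 n_animals = n_animals, n_survivors = n_survivors,
                 noise_sd = noise_sd, jitter_sd = jitter_sd,
                 sd_floor = sd_floor),
            class = "ground_truth")
}

# observables whose raw measurements are natural-log transformed before
# max-normalization (the four plasma cytokines)
.CYTOKINES <- c("TNF", "IL1b", "IL6", "IL10")

# dynamic range of the raw cytokine read-out: a unit-interval observable is
# mapped onto three decades of raw concentration before the ln transform
.CYTO_LOG_RANGE <- log(1000)

# assay detection limit as a fraction of each observable's dynamic range:
# signals below this are reported relative to the limit instead of being
# rescaled to peak 1, so vanishing trajectories normalize to ~0
.DETECT <- 1e-3

#' Log/max normalization of raw measurements
#'
#' Cytokine measurements are natural-log transformed and then divided by
#' their maximum across all time points and animals; all other markers are
#' divided by their maximum directly. The maximum element of each observable
#' maps to exactly 1.
#'
#' Given a numeric vector, applies the two-step transform directly
#' (`log_transform = TRUE` for the cytokine branch). Given a raw-measurement
#' data.frame with columns `(animal_id, cohort, observable, time_h, value)`,
#' applies the cytokine branch to TNF/IL-1b/IL-6/IL-10 and the plain branch
#' to the other markers, per observable across all animals and time points,
#' and returns the data.frame with a `value_norm` column. Noisy ln values
#' below zero are clamped to zero so normalized measurements stay in [0, 1].
#'
#' @param raw Numeric vector or raw-measurement data.frame.
#' @param log_transform For the vector form: apply the ln branch.
#' @param floor Detection floor: when the maximum (transformed) value falls
#'   below it, values are divided by the floor instead, so signals below the
#'   assay detection limit normalize to ~0 rather than being rescaled to
#'   peak 1. The data.frame form applies 0.1% of each observable's dynamic
#'   range.
#' @return Normalized vector, or the data.frame with `value_norm` added.
#' @examples
#' log_max_normalize(c(exp(1), exp(2)))   # 0.5, 1
#' @export
log_max_normalize <- function(raw, log_transform = TRUE, floor = 0) {
  if (is.numeric(raw)) {
    x <- raw
    if (log_transform) {
      if (any(x <= 0))
        stop("cytokine measurements must be strictly positive for the ln ",
             "transform", call. = FALSE)
      x <- pmax(log(x), 0)
    }
    mx <- max(x, floor)
    if (mx <= 0) stop("all-zero measurements cannot be max-normalized",
                      call. = FALSE)
    return(x / mx)
  }
  stopifnot(is.data.frame(raw),
            all(c("observable", "value") %in% names(raw)))
  raw$value_norm <- NA_real_
  for (obs in unique(raw$observable)) {
    i <- raw$observable == obs
    cyto <- obs %in% .CYTOKINES
    raw$value_norm[i] <- log_max_normalize(
      raw$value[i], log_transform = cyto,
      floor = if (cyto) .CYTO_LOG_RANGE * .DETECT else .DETECT)
  }
  raw
}

# deterministic raw-scale read-out of a unit-interval observable state
.raw_scale <- function(obs, x) {
  if (obs %in% .CYTOKINES) exp(.CYTO_LOG_RANGE * x) else x
}

#' Generate a synthetic two-cohort data set
#'
#' Simulates per-animal trajectories from cohort-specific ground-truth
#' parameters perturbed by lognormal inter-animal jitter, reads the eight
#' observables at the measurement times, applies multiplicative lognormal
#' measurement noise on the raw scale, transforms via [log_max_normalize()]
#' (maximum pooled across both cohorts, as in a single assay batch), and
#' summarizes each cohort by per-observable, per-time mean and standard
#' deviation (with the configured SD floor).
#'
#' In the noiseless limit (`noise_sd = 0`, `jitter_sd = 0`) the cohort means
#' equal the max-normalized simulated observables and the SDs sit at the
#' floor.
#'
#' @param truth A [sepsis_ground_truth()] object.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `synthetic_cohort` list: `survivor` and `nonsurvivor` cohort
#'   data.frames `(cohort, observable, time_h, mean, sd, n)`, the per-animal
#'   `raw` measurements `(animal_id, cohort, observable, time_h, value,
#'   value_norm)`, and the truth used.
#' @export
generate_cohort <- function(truth = sepsis_ground_truth(), seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (truth$sd_floor <= 0)
    stop("degenerate noise configuration: sd_floor must be > 0", call. = FALSE)
  set.seed(seed)
  obs_names <- observable_names()
  obs_states <- paste0("O_", obs_names)
  tgrid <- c(0, truth$times)
  bounds <- prior_bounds()
  cohorts <- c(rep("survivor", truth$n_survivors),
               rep("nonsurvivor", truth$n_animals - truth$n_survivors))

  rows <- vector("list", truth$n_animals)
  for (a in seq_len(truth$n_animals)) {
    theta <- if (cohorts[a] == "survivor") truth$theta_surv else truth$theta_nonsurv
    if (truth$jitter_sd > 0) {
      u <- log10(theta[bounds$name]) +
        stats::rnorm(nrow(bounds), 0, truth$jitter_sd)
      theta[bounds$name] <- 10^pmin(pmax(u, log10(bounds$lo)), log10(bounds$hi))
    }
    tr <- simulate_sepsis(theta, truth$g, tgrid)
    latent <- tr$states[-1, obs_states, drop = FALSE]
    eps <- matrix(stats::rnorm(length(latent), 0, truth$noise_sd),
                  nrow = nrow(latent))
    vals <- vapply(seq_along(obs_names), function(j) {
      .raw_scale(obs_names[j], latent[, j]) * exp(eps[, j])
    }, numeric(length(truth$times)))
    rows[[a]] <- data.frame(
      animal_id = a, cohort = cohorts[a],
      observable = rep(obs_names, each = length(truth$times)),
      time_h = rep(truth$times, times = length(obs_names)),
      value = as.vector(vals), stringsAsFactors = FALSE)
  }
  raw <- do.call(rbind, rows)
  raw <- log_max_normalize(raw)

  summarize <- function(lbl) {
    sub <- raw[raw$cohort == lbl, ]
    agg_m <- stats::aggregate(value_norm ~ observable + time_h, sub, mean)
    agg_s <- stats::aggregate(value_norm ~ observable + time_h, sub, stats::sd)
    n <- sum(cohorts == lbl)
    out <- data.frame(cohort = lbl, observable = agg_m$observable,
                      time_h = agg_m$time_h, mean = agg_m$value_norm,
                      sd = pmax(ifelse(is.na(agg_s$value_norm), 0,
                                       agg_s$value_norm), truth$sd_floor),
                      n = n, stringsAsFactors = FALSE)
    out[order(out$observable, out$time_h), ]
  }
  structure(list(survivor = summarize("survivor"),
                 nonsurvivor = summarize("nonsurvivor"),
                 raw = raw, truth = truth, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", x$truth$n_animals, "virtual animals (",
      x$truth$n_survivors, "survivors ),",
      length(unique(x$raw$observable)), "observables x",
      length(x$truth$times), "time points\n")
  invisible(x)
}

#' Write / read cohort data CSV
#'
#' Cohort summaries use columns `(cohort, observable, time_h, mean, sd, n)`;
#' raw measurements use `(animal_id, cohort, observable, time_h, value,
#' value_norm)`.
#'
#' @param cohort Cohort data.frame (one or both cohorts stacked).
#' @param path File path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cohort", "observable", "time_h", "mean", "sd")
  if (!all(need %in% names(d)))
    stop("cohort file missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  d
}

#' Jittered parameter ensemble around a ground-truth vector
#'
#' Builds a synthetic parameter ensemble by lognormal jitter (log10 space) of
#' the sampled parameters around a reference vector, clamped to the prior
#' bounds, optionally keeping only members whose untreated simulation yields
#' a given outcome. This is the synthetic stand-in for a posterior cohort
#' ensemble in treatment experiments.
#'
#' @param theta Reference full parameter vector.
#' @param n Number of members to generate (before filtering).
#' @param jitter_sd Jitter sd in log10 space (default 0.15).
#' @param seed Integer seed.
#' @param outcome Optional `"survivor"` / `"non-survivor"` filter on the
#'   untreated (sham) outcome.
#' @param g Severity grade used for the filter simulations.
#' @param criteria [survival_criteria()] for the filter.
#' @return Matrix of log10 parameter samples (columns: the 34 sampled
#'   parameters) with a `sham_outcome` attribute when filtering was applied.
#' @export
jittered_ensemble <- function(theta, n = 150, jitter_sd = 0.15, seed = 1,
                              outcome = NULL, g = 1,
                              criteria = survival_criteria()) {
  bounds <- prior_bounds()
  set.seed(seed)
  ens <- matrix(NA_real_, n, nrow(bounds),
                dimnames = list(NULL, bounds$name))
  for (i in seq_len(n)) {
    u <- log10(theta[bounds$name]) + stats::rnorm(nrow(bounds), 0, jitter_sd)
    ens[i, ] <- pmin(pmax(u, log10(bounds$lo)), log10(bounds$hi))
  }
  if (is.null(outcome)) return(ens)
  times <- seq(0, criteria$horizon, by = 4)
  keep <- logical(n)
  for (i in seq_len(n)) {
    th <- theta
    th[colnames(ens)] <- 10^ens[i, ]
    keep[i] <- tryCatch(
      classify_survival(simulate_sepsis(th, g, times), criteria) == outcome,
      error = function(e) FALSE)
  }
  ens[keep, , drop = FALSE]
}
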