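#' @useDynLib sepsisflow, .registration = TRUE
NULL

#' Names of the 19 model states
#'
#' Bacteria, seven neutrophil pools (bone-marrow reserve, resting, primed,
#' activated, tissue, lung-sequestered, lung), the three unit-interval
#' inflammation/damage states, and the eight observable states.
#' @return Character vector of length 19.
#' @export
state_names <- function() {
  c("B", "N_bm", "N_r", "N_p", "N_a", "N_t", "N_s", "N_l",
    "PI", "AI", "D",
    "O_TNF", "O_IL1b", "O_IL6", "O_IL10", "O_Lsel", "O_HMGB1", "O_CRT", "O_ALT")
}

#' Names of the eight observables
#' @return Character vector of length 8 (order matches the observable states).
#' @export
observable_names <- function() {
  c("TNF", "IL1b", "IL6", "IL10", "Lsel", "HMGB1", "CRT", "ALT")
}

# bone marrow reserve at homeostasis (cells/ml-equivalent); with the printed
# basal release rate 3.22e-6/hr and a resting-neutrophil death time constant
# of 8 hr this sustains ~2.6e6 resting neutrophils/ml in blood
.N_BM0 <- 1e11

#' Homeostatic initial state
#'
#' The self-consistent pre-CLP fixed point: no bacteria, no inflammation or
#' damage, all observables at baseline zero, and the resting blood pool at the
#' balance between basal bone-marrow release and apoptotic death,
#' `N_r = r_release * tau_nr * N_bm`.
#'
#' @param params Named parameter vector ([default_parameters()]).
#' @return Named numeric state vector of length 19; all derivatives vanish at
#'   this state when the severity grade is 0.
#' @export
homeostatic_state <- function(params = default_parameters()) {
  s <- stats::setNames(numeric(19), state_names())
  s["N_bm"] <- .N_BM0
  s["N_r"] <- params[["r_release"]] * params[["tau_nr"]] * .N_BM0
  s
}

# assemble the 68-element parameter block shared by the C and R right-hand
# sides: 57 registry values, severity, and the hemoadsorption block
.parm_block <- function(params, g, ha = NULL) {
  if (length(params) != 57)
    stop("parameter vector must have 57 entries", call. = FALSE)
  if (any(!is.finite(params)))
    stop("non-finite parameter value", call. = FALSE)
  if (any(params[1:50] <= 0))
    stop("rates, thresholds and time constants must be strictly positive",
         call. = FALSE)
  if (g < 0 || g > 1)
    stop("severity grade g must lie in [0, 1]", call. = FALSE)
  if (is.null(ha)) {
    ha_block <- c(0, 0, 1, 0, 1, 0, 1, 0, 0, 3)
  } else {
    ha_block <- c(1, ha$rate_na, ha$half_na, ha$rate_pi, ha$half_pi,
                  ha$rate_ai, ha$half_ai, ha$t_on, ha$t_off, ha$hill_n)
  }
  c(unname(params), g, ha_block)
}

#' Model derivatives (reference implementation)
#'
#' Pure-R right-hand side of the 19-state ODE system; the compiled C version
#' used by the solver must agree with this function (tested). Exposed for
#' unit-level inspection of individual terms.
#'
#' @param t Time (hours).
#' @param state Named state vector of length 19 ([state_names()] order).
#' @param params Named parameter vector of length 57.
#' @param g CLP severity grade in `[0, 1]`.
#' @param ha Optional hemoadsorption configuration ([ha_config()]).
#' @return Named vector of the 19 state derivatives.
#' @export
sepsis_derivatives <- function(t, state, params, g, ha = NULL) {
  if (length(state) != 19)
    stop("state vector must have 19 entries", call. = FALSE)
  if (any(state[1:8] < -1e-6 * max(1, abs(state[1:8]))))
    stop("negative count-valued state", call. = FALSE)
  p <- .parm_block(params, g, ha)
  y <- pmax(unname(state), c(rep(0, 8), rep(-Inf, 11)))

  B <- y[1]; Nbm <- y[2]; Nr <- y[3]; Np <- y[4]; Na <- y[5]
  Nt <- y[6]; Ns <- y[7]; Nl <- y[8]; PI <- y[9]; AI <- y[10]; D <- y[11]
  # regulator levels entering Hill terms are clamped for transient solver
  # undershoot, matching the compiled right-hand side; the linear relaxation
  # terms keep the raw values
  pi_c <- max(PI, 0); ai_c <- max(AI, 0); d_c <- max(D, 0)

  r_grow <- p[51]; r_mac <- p[52]; B_inf <- p[53]; B_mac <- p[54]
  Nt_max <- p[55]; v_bt <- p[56]; v_bl <- p[57]
  Bn <- B / B_inf
  fB <- min(B, B_inf)

  rel   <- (p[8] + p[10] * hill(Bn, p[9])) * Nbm
  prime <- hill(B, p[12]) * Nr / p[13]
  act_r <- hill_norm(pi_c, p[14]) * Nr / p[15]
  act_p <- hill_norm(pi_c, p[17]) * Np / p[18]
  seq_  <- hill_norm(pi_c, p[21]) * Na / p[22]
  mig_t <- hill(B, p[25]) * (1 - hill_norm(pi_c, p[26])) * Np / p[19]
  mig_l <- hill_norm(pi_c, p[28]) * Ns / p[24]
  flux  <- act_r + act_p + seq_

  ha_na <- ha_pi <- ha_ai <- 0
  if (p[59] > 0.5 && t >= p[66] && t < p[67]) {
    n_ha <- p[68]
    ha_na <- p[60] * hill(Na, p[61], n_ha)
    ha_pi <- p[62] * hill(max(PI, 0), p[63], n_ha)
    ha_ai <- p[64] * hill(max(AI, 0), p[65], n_ha)
  }

  d <- numeric(19)
  d[1] <- (p[33] * g + r_grow * B) * (1 - Bn) - p[34] * fB * Nt -
    r_mac * min(B, B_mac)
  d[2] <- -p[10] * hill(Bn, p[9]) * Nbm
  d[3] <- rel - Nr / p[11] - prime - act_r
  d[4] <- prime - Np / p[16] - act_p - mig_t
  d[5] <- act_r + act_p - Na / p[20] - seq_ - ha_na
  d[6] <- v_bt * mig_t * (1 - Nt / Nt_max) - Nt / p[27]
  d[7] <- seq_ - Ns / p[23] - mig_l
  d[8] <- v_bl * mig_l - Nl / p[29]

  act_pi <- 1 - (1 - hill(Bn, p[1])) * (1 - hill_norm(d_c, p[2]))
  inh_pi <- 1 - hill_norm(ai_c, p[3]) * (1 - hill_norm(pi_c, p[6]))
  d[9]  <- (act_pi * inh_pi - PI) / p[4] - ha_pi
  d[10] <- (hill_norm(pi_c, p[5]) - AI) / p[7] - ha_ai
  act_d <- 1 - (1 - hill(Ns / Nt_max, p[30])) * (1 - hill(Nl / Nt_max, p[31]))
  d[11] <- (act_d - D) / p[32]

  d[12] <- (hill_norm(pi_c, p[35]) - y[12]) / p[36]
  d[13] <- (hill_norm(pi_c, p[37]) - y[13]) / p[38]
  d[14] <- (hill_norm(pi_c, p[39]) - y[14]) / p[40]
  d[15] <- (hill_norm(ai_c, p[41]) - y[15]) / p[42]
  d[16] <- (hill(flux / Nt_max, p[43]) - y[16]) / p[44]
  d[17] <- (hill_norm(d_c, p[45]) - y[17]) / p[46]
  d[18] <- (hill_norm(d_c, p[47]) - y[18]) / p[48]
  d[19] <- (hill_norm(d_c, p[49]) - y[19]) / p[50]
  stats::setNames(d, state_names())
}

#' Neutrophil activation flux
#'
#' The summed rate of the three PI-gated neutrophil transitions
#' (resting to activated, primed to activated, activated to sequestered),
#' which drives the L-selectin observable.
#'
#' @inheritParams sepsis_derivatives
#' @return Non-negative flux (cells/ml/hr).
#' @export
activation_flux <- function(state, params) {
  PI <- state[["PI"]]
  hill_norm(PI, params[["kappa_act_r"]]) * max(state[["N_r"]], 0) / params[["tau_act_r"]] +
    hill_norm(PI, params[["kappa_act_p"]]) * max(state[["N_p"]], 0) / params[["tau_act_p"]] +
    hill_norm(PI, params[["kappa_seq"]]) * max(state[["N_a"]], 0) / params[["tau_seq"]]
}

# run the compiled (or reference) solver over one time segment
.ode_segment <- function(y0, times, pv, compiled, rtol, atol) {
  if (compiled) {
    out <- deSolve::ode(y = y0, times = times, func = "sepsis_derivs",
                        parms = pv, dllname = "sepsisflow",
                        initfunc = "sepsis_initmod", method = "lsoda",
                        rtol = rtol, atol = atol)
  } else {
    rhs <- function(t, y, parms) {
      yn <- stats::setNames(y, state_names())
      prm <- stats::setNames(parms[1:57], names(default_parameters()))
      ha <- NULL
      if (parms[59] > 0.5)
        ha <- list(rate_na = parms[60], half_na = parms[61],
                   rate_pi = parms[62], half_pi = parms[63],
                   rate_ai = parms[64], half_ai = parms[65],
                   t_on = parms[66], t_off = parms[67], hill_n = parms[68])
      list(unname(sepsis_derivatives(t, yn, prm, parms[58], ha)))
    }
    out <- deSolve::ode(y = y0, times = times, func = rhs, parms = pv,
                        method = "lsoda", rtol = rtol, atol = atol)
  }
  if (attr(out, "istate")[1] < 0)
    stop("integration failure (lsoda istate ", attr(out, "istate")[1], ")",
         call. = FALSE)
  out
}

#' Simulate the sepsis model
#'
#' Integrates the 19-state system from the homeostatic initial state with a
#' stiff multistep solver (lsoda; relative tolerance `1e-6`, absolute
#' tolerance 1 for the count-valued states and `1e-9` for the unit-interval
#' states). When a hemoadsorption window is configured the solver is restarted
#' exactly at the window boundaries so the discontinuous elimination terms
#' never straddle an internal step.
#'
#' @param params Named parameter vector of length 57.
#' @param g CLP severity grade in `[0, 1]`.
#' @param times Strictly increasing output grid starting at 0 (hours).
#' @param ha Optional [ha_config()]; a configuration with all rates zero is
#'   treated as sham (identical to no treatment).
#' @param state0 Initial state (default [homeostatic_state()]).
#' @param compiled Use the compiled right-hand side (default) or the pure-R
#'   reference.
#' @param rtol,atol Solver tolerances (`atol` may be a vector of length 19).
#' @return A `sepsis_trajectory`: list with `times`, `states`
#'   (length(times) x 19 matrix), and the inputs used (`params`, `g`, `ha`).
#' @examples
#' tr <- simulate_sepsis(default_parameters(), g = 0, times = seq(0, 48, 4))
#' max(abs(tr$states[, "B"]))  # no infection without CLP
#' @export
simulate_sepsis <- function(params, g, times = seq(0, 200, by = 2), ha = NULL,
                            state0 = homeostatic_state(params),
                            compiled = TRUE, rtol = 1e-6,
                            atol = c(rep(1, 8), rep(1e-9, 11))) {
  if (times[1] != 0) stop("time grid must start at 0", call. = FALSE)
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing",
                                  call. = FALSE)
  if (!is.null(ha) && all(c(ha$rate_na, ha$rate_pi, ha$rate_ai) == 0))
    ha <- NULL   # sham: bit-identical to the untreated simulation
  pv <- .parm_block(params, g, ha)
  y0 <- unname(state0)

  t_end <- times[length(times)]
  if (is.null(ha) || ha$t_on >= t_end) {
    out <- .ode_segment(y0, times, pv, compiled, rtol, atol)
    states <- out[, -1, drop = FALSE]
  } else {
    cuts <- sort(unique(c(0, ha$t_on, min(ha$t_off, t_end), t_end)))
    states <- matrix(NA_real_, length(times), 19)
    states[1, ] <- y0
    y <- y0
    for (k in seq_len(length(cuts) - 1)) {
      seg <- sort(unique(c(cuts[k], times[times > cuts[k] & times <= cuts[k + 1]],
                           cuts[k + 1])))
      out <- .ode_segment(y, seg, pv, compiled, rtol, atol)
      y <- unname(out[nrow(out), -1])
      keep <- seg %in% times & seg > cuts[k]
      states[match(seg[keep], times), ] <- out[keep, -1, drop = FALSE]
    }
  }
  colnames(states) <- state_names()

  # negative-undershoot guard: clamp roundoff-scale negatives, flag real ones
  counts <- states[, 1:8, drop = FALSE]
  if (any(counts < -1)) {
    stop("integration produced a negative count-valued state beyond solver ",
         "tolerance (min ", format(min(counts)), ")", call. = FALSE)
  }
  states[, 1:8] <- pmax(counts, 0)
  units <- states[, 9:19, drop = FALSE]
  if (any(units < -1e-6) || any(units > 1 + 1e-6))
    stop("unit-interval state left [0, 1] beyond solver tolerance",
         call. = FALSE)
  states[, 9:19] <- pmin(pmax(units, 0), 1)

  structure(list(times = times, states = states, params = params, g = g,
                 ha = ha),
            class = "sepsis_trajectory")
}

#' @export
print.sepsis_trajectory <- function(x, ...) {
  cat("<sepsis_trajectory>\n")
  cat("  time span : 0 -", max(x$times), "h (", length(x$times), "points )\n")
  cat("  severity g:", x$g, "\n")
  cat("  HA window :",
      if (is.null(x$ha)) "none" else paste0("[", x$ha$t_on, ", ", x$ha$t_off, ") h"),
      "\n")
  fin <- x$states[nrow(x$states), ]
  cat(sprintf("  final     : B = %.3g CFU/ml, PI = %.3f, D = %.3f\n",
              fin[["B"]], fin[["PI"]], fin[["D"]]))
  invisible(x)
}

#' @export
as.data.frame.sepsis_trajectory <- function(x, ...) {
  data.frame(time = rep(x$times, times = 19),
             state = rep(state_names(), each = length(x$times)),
             value = as.vector(x$states),
             stringsAsFactors = FALSE)
}

#' @export
plot.sepsis_trajectory <- function(x, states = c("B", "N_t", "N_s", "N_l", "PI", "D"),
                                   ...) {
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(states)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in states) {
    graphics::plot(x$times, x$states[, s], type = "l", xlab = "time (h)",
                   ylab = s, ...)
  }
  invisible(x)
}

#' Write a trajectory as tidy CSV
#'
#' Columns `(time, state, value)`.
#' @param traj A `sepsis_trajectory`.
#' @param path Output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Survival criteria
#'
#' A simulated animal survives when, at the end of the simulation horizon,
#' the bacterial load is below `b_crit` and systemic inflammation PI is below
#' `pi_crit`.
#'
#' @param horizon Simulation end time (hours).
#' @param b_crit Bacterial threshold (CFU/ml); default 5e8, midway
#'   between the neutrophil-controlled equilibrium and the carrying capacity.
#' @param pi_crit Systemic inflammation threshold in (0, 1).
#' @return A `survival_criteria` list.
#' @export
survival_criteria <- function(horizon = 200, b_crit = 5e8, pi_crit = 0.5) {
  stopifnot(horizon > 0, b_crit > 0, pi_crit > 0, pi_crit < 1)
  structure(list(horizon = horizon, b_crit = b_crit, pi_crit = pi_crit),
            class = "survival_criteria")
}

#' Classify a trajectory as survivor or non-survivor
#'
#' @param traj A `sepsis_trajectory` reaching the criteria horizon.
#' @param criteria A [survival_criteria()] object.
#' @return `"survivor"` or `"non-survivor"`.
#' @examples
#' tr <- simulate_sepsis(default_parameters(), g = 0, times = seq(0, 200, 10))
#' classify_survival(tr)   # "survivor": no infection at all
#' @export
classify_survival <- function(traj, criteria = survival_criteria()) {
  tmax <- max(traj$times)
  if (tmax < criteria$horizon)
    stop("trajectory ends at ", tmax, " h, before the ", criteria$horizon,
         " h horizon", call. = FALSE)
  b_end <- stats::approx(traj$times, traj$states[, "B"],
                         xout = criteria$horizon)$y
  pi_end <- stats::approx(traj$times, traj$states[, "PI"],
                          xout = criteria$horizon)$y
  if (b_end < criteria$b_crit && pi_end < criteria$pi_crit) "survivor"
  else "non-survivor"
}
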