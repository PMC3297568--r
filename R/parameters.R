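#' Default model parameter registry
#'
#' Builds the 57-entry parameter registry of the CLP sepsis model: 34 dynamic
#' parameters sampled by MCMC (activation/inhibition thresholds `kappa`, time
#' constants `tau`, and four mass-action rates), 16 observation-mapping
#' parameters (a threshold and a time constant for each of the eight plasma
#' markers), and 7 fixed constants (growth/removal rates, carrying capacities
#' and compartment volume ratios). Prior bounds are log10-uniform ranges per
#' parameter group.
#'
#' Units: thresholds on unit-interval regulators (PI, AI, D, normalized
#' bacteria or neutrophil fractions) are dimensionless; bacterial thresholds
#' driving priming and migration are absolute (CFU/ml); time constants are in
#' hours; mass-action rates carry the units stated in the `unit` column.
#'
#' @return A `data.frame` with columns `id`, `name`, `value`, `unit`, `group`
#'   (one of `"dynamic"`, `"mapping"`, `"constant"`), `sampled` (0/1),
#'   `prior_lo`, `prior_hi`, `description`.
#' @examples
#' reg <- parameter_registry()
#' nrow(reg)            # 57
#' sum(reg$sampled)     # 34
#' @export
parameter_registry <- function() {
  row <- function(id, name, value, unit, group, sampled, lo, hi, desc) {
    data.frame(id = id, name = name, value = value, unit = unit, group = group,
               sampled = sampled, prior_lo = lo, prior_hi = hi,
               description = desc, stringsAsFactors = FALSE)
  }
  dyn <- rbind(
    row(1L,  "kappa_pi_b",    0.50,    "none",      "dynamic", 1L, 1e-2, 2,    "PI activation threshold by bacteria (B/B_inf)"),
    row(2L,  "kappa_pi_d",    0.50,    "none",      "dynamic", 1L, 1e-2, 2,    "PI activation threshold by damage"),
    row(3L,  "kappa_pi_ai",   0.40,    "none",      "dynamic", 1L, 1e-2, 2,    "PI inhibition threshold by AI"),
    row(4L,  "tau_pi",        16,      "hr",        "dynamic", 1L, 0.5,  500,  "PI decay time constant"),
    row(5L,  "kappa_ai_pi",   0.40,    "none",      "dynamic", 1L, 1e-2, 2,    "AI activation threshold by PI"),
    row(6L,  "kappa_pi_esc",  0.75,    "none",      "dynamic", 1L, 1e-2, 2,    "PI level above which AI inhibition of PI is moderated (partial inhibition)"),
    row(7L,  "tau_ai",        24,      "hr",        "dynamic", 1L, 0.5,  500,  "AI decay time constant"),
    row(8L,  "r_release",     3.22e-6, "1/hr",      "dynamic", 1L, 1e-7, 1e-4, "basal neutrophil release rate from bone marrow reserve"),
    row(9L,  "kappa_rel_b",   0.02,    "none",      "dynamic", 1L, 1e-4, 1,    "neutrophil release activation threshold by bacteria (B/B_inf)"),
    row(10L, "r_release_max", 3.15e-7, "1/hr",      "dynamic", 1L, 1e-8, 1e-5, "maximum additional release rate from bone marrow in infection"),
    row(11L, "tau_nr",        8,       "hr",        "dynamic", 1L, 0.5,  500,  "resting blood neutrophil death time constant"),
    row(12L, "kappa_prime_b", 1e6,     "CFU/ml",    "dynamic", 1L, 1e4,  1e8,  "blood neutrophil priming threshold by bacteria"),
    row(13L, "tau_prime",     3,       "hr",        "dynamic", 1L, 0.5,  500,  "blood neutrophil priming time constant"),
    row(14L, "kappa_act_r",   0.70,    "none",      "dynamic", 1L, 1e-2, 2,    "resting neutrophil activation threshold by PI"),
    row(15L, "tau_act_r",     20,      "hr",        "dynamic", 1L, 0.5,  500,  "resting neutrophil activation time constant"),
    row(16L, "tau_np",        12,      "hr",        "dynamic", 1L, 0.5,  500,  "primed neutrophil death time constant"),
    row(17L, "kappa_act_p",   0.60,    "none",      "dynamic", 1L, 1e-2, 2,    "primed neutrophil activation threshold by PI"),
    row(18L, "tau_act_p",     15,      "hr",        "dynamic", 1L, 0.5,  500,  "primed neutrophil activation time constant"),
    row(19L, "tau_mig",       2,       "hr",        "dynamic", 1L, 0.5,  500,  "primed neutrophil migration-to-tissue time constant"),
    row(20L, "tau_na",        12,      "hr",        "dynamic", 1L, 0.5,  500,  "activated blood neutrophil death time constant"),
    row(21L, "kappa_seq",     0.50,    "none",      "dynamic", 1L, 1e-2, 2,    "neutrophil sequestration activation threshold by PI"),
    row(22L, "tau_seq",       8,       "hr",        "dynamic", 1L, 0.5,  500,  "neutrophil sequestration time constant"),
    row(23L, "tau_ns",        20,      "hr",        "dynamic", 1L, 0.5,  500,  "sequestered neutrophil death time constant"),
    row(24L, "tau_lung",      6,       "hr",        "dynamic", 1L, 0.5,  500,  "sequestered-to-lung neutrophil migration time constant"),
    row(25L, "kappa_mig_b",   1e6,     "CFU/ml",    "dynamic", 1L, 1e4,  1e8,  "activation threshold of neutrophil migration to tissue by bacteria"),
    row(26L, "kappa_mig_inh", 0.90,    "none",      "dynamic", 1L, 1e-2, 2,    "PI threshold of migration impairment (systemic activation)"),
    row(27L, "tau_nt",        36,      "hr",        "dynamic", 1L, 0.5,  500,  "tissue neutrophil death time constant"),
    row(28L, "kappa_lung",    0.50,    "none",      "dynamic", 1L, 1e-2, 2,    "sequestered neutrophil migration-to-lung activation threshold by PI"),
    row(29L, "tau_nl",        48,      "hr",        "dynamic", 1L, 0.5,  500,  "lung neutrophil death time constant"),
    row(30L, "kappa_d_ns",    0.015,   "none",      "dynamic", 1L, 1e-3, 1,    "damage activation threshold by sequestered neutrophils (N_s/N_t_max)"),
    row(31L, "kappa_d_nl",    0.015,   "none",      "dynamic", 1L, 1e-3, 1,    "damage activation threshold by lung neutrophils (N_l/N_t_max)"),
    row(32L, "tau_d",         40,      "hr",        "dynamic", 1L, 0.5,  500,  "damage resolution time constant"),
    row(33L, "r_clp",         9.40e7,  "CFU/ml/hr", "dynamic", 1L, 1e7,  1e9,  "bacterial source rate induced by CLP (scaled by severity g)"),
    row(34L, "r_kill",        6.61e-8, "ml/cell/hr","dynamic", 1L, 1e-9, 1e-6, "rate of bacterial removal by migrated tissue neutrophils")
  )
  map <- rbind(
    row(35L, "kappa_tnf",   0.30,  "none", "mapping", 0L, 1e-2, 2,    "TNF-alpha activation threshold by PI"),
    row(36L, "tau_tnf",     4,     "hr",   "mapping", 0L, 0.5,  200,  "TNF-alpha observable time constant"),
    row(37L, "kappa_il1b",  0.35,  "none", "mapping", 0L, 1e-2, 2,    "IL-1beta activation threshold by PI"),
    row(38L, "tau_il1b",    6,     "hr",   "mapping", 0L, 0.5,  200,  "IL-1beta observable time constant"),
    row(39L, "kappa_il6",   0.30,  "none", "mapping", 0L, 1e-2, 2,    "IL-6 activation threshold by PI"),
    row(40L, "tau_il6",     8,     "hr",   "mapping", 0L, 0.5,  200,  "IL-6 observable time constant"),
    row(41L, "kappa_il10",  0.35,  "none", "mapping", 0L, 1e-2, 2,    "IL-10 activation threshold by AI"),
    row(42L, "tau_il10",    10,    "hr",   "mapping", 0L, 0.5,  200,  "IL-10 observable time constant"),
    row(43L, "kappa_lsel",  0.005, "none", "mapping", 0L, 1e-4, 1,    "L-selectin activation threshold by the neutrophil activation flux (flux/N_t_max per hr)"),
    row(44L, "tau_lsel",    8,     "hr",   "mapping", 0L, 0.5,  200,  "L-selectin observable time constant"),
    row(45L, "kappa_hmgb1", 0.35,  "none", "mapping", 0L, 1e-2, 2,    "HMGB1 activation threshold by damage"),
    row(46L, "tau_hmgb1",   24,    "hr",   "mapping", 0L, 0.5,  200,  "HMGB1 observable time constant"),
    row(47L, "kappa_crt",   0.40,  "none", "mapping", 0L, 1e-2, 2,    "creatinine activation threshold by damage"),
    row(48L, "tau_crt",     30,    "hr",   "mapping", 0L, 0.5,  200,  "creatinine observable time constant"),
    row(49L, "kappa_alt",   0.40,  "none", "mapping", 0L, 1e-2, 2,    "ALT activation threshold by damage"),
    row(50L, "tau_alt",     30,    "hr",   "mapping", 0L, 0.5,  200,  "ALT observable time constant")
  )
  cst <- rbind(
    row(51L, "r_growth", 0.1,      "1/hr",     "constant", 0L, NA, NA, "rate of bacterial growth"),
    row(52L, "r_mac",    0.1,      "1/hr",     "constant", 0L, NA, NA, "rate of bacterial removal by resident macrophages"),
    row(53L, "b_inf",    1.0e9,    "CFU/ml",   "constant", 0L, NA, NA, "maximum bacteria in tissue (carrying capacity)"),
    row(54L, "b_mac",    1.0e5,    "CFU/ml",   "constant", 0L, NA, NA, "bacterial level controlled by resident macrophages"),
    row(55L, "nt_max",   2.0e7,    "cells/ml", "constant", 0L, NA, NA, "maximum neutrophils in tissue"),
    row(56L, "v_bt",     34.4 / 25,"none",     "constant", 0L, NA, NA, "volume ratio of blood and tissue"),
    row(57L, "v_bl",     34.4 / 48,"none",     "constant", 0L, NA, NA, "volume ratio of blood and lung")
  )
  reg <- rbind(dyn, map, cst)
  rownames(reg) <- NULL
  reg
}

#' Default model parameter vector
#'
#' Named numeric vector of the 57 registry baseline values, in registry order.
#'
#' @param registry Optionally, a registry data.frame as returned by
#'   [parameter_registry()] (possibly with modified values).
#' @return Named numeric vector of length 57.
#' @export
default_parameters <- function(registry = parameter_registry()) {
  stats::setNames(registry$value, registry$name)
}

#' Indices of the MCMC-sampled parameters
#'
#' @return Integer vector of the 34 registry ids sampled by MCMC.
#' @export
sampled_parameter_ids <- function() {
  reg <- parameter_registry()
  reg$id[reg$sampled == 1L]
}

#' Prior bounds for sampled parameters
#'
#' Log10-uniform prior bounds for a set of parameters. Bounds always cover the
#' registry baseline values.
#'
#' @param ids Registry ids (default: the 34 sampled parameters).
#' @param registry Parameter registry data.frame.
#' @return A `prior_bounds` object: data.frame with columns `id`, `name`,
#'   `lo`, `hi` (natural scale; sampling happens on log10 scale).
#' @export
prior_bounds <- function(ids = sampled_parameter_ids(),
                         registry = parameter_registry()) {
  stopifnot(all(ids %in% registry$id))
  sub <- registry[match(ids, registry$id), ]
  if (any(is.na(sub$prior_lo)) || any(is.na(sub$prior_hi)))
    stop("constant parameters have no prior bounds", call. = FALSE)
  if (any(sub$prior_lo <= 0) || any(sub$prior_lo >= sub$prior_hi))
    stop("invalid prior bounds: need 0 < lo < hi", call. = FALSE)
  if (any(sub$value < sub$prior_lo | sub$value > sub$prior_hi))
    stop("prior bounds must cover the baseline values", call. = FALSE)
  out <- data.frame(id = sub$id, name = sub$name,
                    lo = sub$prior_lo, hi = sub$prior_hi,
                    stringsAsFactors = FALSE)
  class(out) <- c("prior_bounds", "data.frame")
  out
}

#' Read / write a parameter registry CSV
#'
#' The on-disk interface mirrors the registry columns
#' `(id, name, value, unit, group, sampled, prior_lo, prior_hi, description)`.
#'
#' @param path File path.
#' @param registry Registry data.frame to write.
#' @return `read_parameter_registry` returns the registry data.frame.
#' @export
read_parameter_registry <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "value", "unit", "group", "sampled",
            "prior_lo", "prior_hi")
  if (!all(need %in% names(reg)))
    stop("registry file missing columns: ",
         paste(setdiff(need, names(reg)), collapse = ", "), call. = FALSE)
  reg
}

#' @rdname read_parameter_registry
#' @export
write_parameter_registry <- function(registry, path) {
  utils::write.csv(registry, path, row.names = FALSE)
  invisible(path)
}
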