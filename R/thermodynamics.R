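# Nernst feasibility of cathodic hydrogen evolution (2 H+ + 2 e- -> H2).
# With the SHE convention E0 = 0 at every temperature, the equilibrium
# potential at a hydrogen partial-pressure threshold p_H2 is
#   E = -(R T ln10 / F) pH - (R T / 2F) ln(p_H2)
# so temperature enters only through the RT/F terms. The H2 threshold is the
# partial pressure below which hydrogenotrophs cannot sustain growth; it is
# stored per temperature in an editable table calibrated from published
# equilibrium potentials (the underlying literature thresholds may be
# substituted by the user).

#' Hydrogen-evolution condition
#'
#' @param ph catholyte pH.
#' @param temperature_K absolute temperature (> 0).
#' @param p_h2_atm hydrogen partial-pressure threshold in atm (> 0).
#' @return A `her_condition` object.
#' @export
her_condition <- function(ph, temperature_K, p_h2_atm) {
  if (!is.finite(temperature_K) || temperature_K <= 0)
    stop("temperature_K must be > 0", call. = FALSE)
  if (!is.finite(p_h2_atm) || p_h2_atm <= 0)
    stop("p_h2_atm must be > 0", call. = FALSE)
  structure(list(ph = ph, temperature_K = temperature_K,
                 p_h2_atm = p_h2_atm),
            class = "her_condition")
}

#' Equilibrium potential of the hydrogen evolution reaction
#'
#' Nernst potential of `2 H+ + 2 e- -> H2` at the condition's pH,
#' temperature, and H2 threshold partial pressure, vs SHE. At pH 0, 298.15 K,
#' and 1 atm H2 this is 0 V by construction of the SHE scale. The potential
#' drops by `R T ln10 / F` volts per pH unit (about 60 mV at 30 degC) and
#' rises as the H2 threshold decreases.
#'
#' @param cond a [her_condition()].
#' @return Equilibrium potential in V vs SHE.
#' @export
her_potential <- function(cond) {
  stopifnot(inherits(cond, "her_condition"))
  rt_f <- GAS_CONSTANT * cond$temperature_K / FARADAY
  -rt_f * log(10) * cond$ph - rt_f / 2 * log(cond$p_h2_atm)
}

#' Calibrate an H2 threshold from a published equilibrium potential
#'
#' Inverts the Nernst expression: given a known equilibrium potential at a
#' stated pH and temperature, returns the hydrogen partial pressure that
#' reproduces it, `p_H2 = exp(-(2F/RT) (E + (RT ln10 / F) pH))`. Round-trip
#' with [her_potential()] is exact to machine precision, so a threshold table
#' can be seeded from published potentials when the underlying concentration
#' thresholds are not available.
#'
#' @param e_anchor_V equilibrium potential in V vs SHE.
#' @param ph pH at which it was stated.
#' @param temperature_K absolute temperature.
#' @return Hydrogen partial pressure in atm.
#' @export
calibrate_h2_threshold <- function(e_anchor_V, ph, temperature_K) {
  if (!is.finite(e_anchor_V)) stop("anchor must be finite", call. = FALSE)
  rt_f <- GAS_CONSTANT * temperature_K / FARADAY
  exp(-(2 / rt_f) * (e_anchor_V + rt_f * log(10) * ph))
}

#' Feasibility of cathodic H2 evolution at a poised potential
#'
#' Hydrogen can be evolved at a rate useful to hydrogenotrophs only when the
#' cathode sits below the HER equilibrium potential by at least the kinetic
#' overpotential: feasible iff
#' `e_cathode <= her_potential(cond) - overpotential`.
#'
#' @param e_cathode_V poised cathode potential, V vs SHE.
#' @param cond a [her_condition()].
#' @param overpotential_V kinetic overpotential in V (>= 0).
#' @return Logical.
#' @export
her_feasible <- function(e_cathode_V, cond, overpotential_V = 0) {
  if (overpotential_V < 0)
    stop("overpotential_V must be >= 0", call. = FALSE)
  e_cathode_V <= her_potential(cond) - overpotential_V
}

#' Per-temperature H2 threshold table
#'
#' Editable table of hydrogen partial-pressure thresholds used for HER
#' feasibility, one row per temperature. The shipped table is calibrated
#' with [calibrate_h2_threshold()] from equilibrium potentials published at
#' pH 4.5 (-0.038 V at 30 degC, -0.104 V at 75 degC); the 55 degC row is
#' the geometric interpolation of the two calibrated pressures. Users with
#' access to metabolism-specific H2 threshold concentrations should replace
#' these values.
#'
#' @param path optional delimited file with columns `temperature_C`,
#'   `p_h2_atm`; when `NULL` the calibrated defaults are computed.
#' @return Tibble with columns `temperature_C`, `p_h2_atm`.
#' @export
h2_threshold_table <- function(path = NULL) {
  if (!is.null(path)) {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    stopifnot(all(c("temperature_C", "p_h2_atm") %in% names(tab)))
    return(tibble::as_tibble(tab))
  }
  p30 <- calibrate_h2_threshold(-0.038, 4.5, celsius_to_kelvin(30))
  p75 <- calibrate_h2_threshold(-0.104, 4.5, celsius_to_kelvin(75))
  tibble::tibble(
    temperature_C = c(30, 55, 75),
    p_h2_atm = c(p30, sqrt(p30 * p75), p75))
}

#' HER feasibility verdict for a reactor
#'
#' Joins the reactor's pH and temperature with the threshold table and
#' evaluates [her_feasible()] at the reactor's poised potential.
#'
#' @param reactor a [reactor_record()].
#' @param overpotential_V kinetic overpotential in V.
#' @param thresholds output of [h2_threshold_table()].
#' @return One-row tibble: `reactor_id`, `e_her_V`, `her_feasible`.
#' @export
her_verdict <- function(reactor, overpotential_V = 0.2,
                        thresholds = h2_threshold_table()) {
  stopifnot(inherits(reactor, "reactor_record"))
  i <- which.min(abs(thresholds$temperature_C - reactor$temperature_C))
  cond <- her_condition(reactor$ph,
                        celsius_to_kelvin(reactor$temperature_C),
                        thresholds$p_h2_atm[i])
  e <- her_potential(cond)
  tibble::tibble(
    reactor_id = reactor$reactor_id,
    e_her_V = e,
    her_feasible = her_feasible(reactor$cathode_potential_V_SHE, cond,
                                overpotential_V))
}
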