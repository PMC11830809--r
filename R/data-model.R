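# Domain types for cathodic enrichment reactors. Lightweight S3 records with
# constructor-time validation; all internal units are SI (s, A, L, mol, C),
# concentrations cross the boundary in mM and COD in g O2/L.

ELECTRON_ACCEPTORS <- c("FeOx", "NO3", "O2", "SO4", "CO2", "HCOO")
INOCULA <- c("BJ", "LC2")

abort_field <- function(msg) stop(msg, call. = FALSE)

#' Reactor metadata record
#'
#' Binds the experimental factors of one H-cell reactor: inoculum, incubation
#' temperature, catholyte pH, electron acceptor, catholyte volume, run
#' duration, cathode geometric area, and the poised cathode potential.
#' Defaults correspond to the enrichment campaign the package models:
#' 0.25 L catholyte, 6-day runs, a 1.5 x 1.5 cm graphite plate (geometric
#' single-face area 2.25 cm2) poised at -0.6 V vs SHE.
#'
#' @param reactor_id free-text label, e.g. `"LC2-75-4.5-NO3"`.
#' @param inoculum one of `"BJ"`, `"LC2"`.
#' @param temperature_C incubation temperature, degrees C, in \[0, 150\].
#' @param ph catholyte pH, in \[0, 14\].
#' @param electron_acceptor one of `r paste(ELECTRON_ACCEPTORS, collapse = ", ")`.
#' @param catholyte_volume_L catholyte volume in litres (> 0).
#' @param duration_s run duration in seconds (> 0).
#' @param cathode_area_cm2 geometric single-face plate area in cm2 (> 0);
#'   always supplied explicitly, never inferred from plate dimensions.
#' @param cathode_potential_V_SHE poised cathode potential, V vs SHE.
#' @return A `reactor_record` object (a named list).
#' @export
reactor_record <- function(reactor_id,
                           inoculum,
                           temperature_C,
                           ph,
                           electron_acceptor,
                           catholyte_volume_L = 0.25,
                           duration_s = 6 * 86400,
                           cathode_area_cm2 = 2.25,
                           cathode_potential_V_SHE = -0.6) {
  inoculum <- as.character(inoculum)
  electron_acceptor <- as.character(electron_acceptor)
  if (!inoculum %in% INOCULA)
    abort_field(sprintf("unknown inoculum '%s'; allowed: %s",
                        inoculum, paste(INOCULA, collapse = ", ")))
  if (!electron_acceptor %in% ELECTRON_ACCEPTORS)
    abort_field(sprintf("unknown electron_acceptor '%s'; allowed: %s",
                        electron_acceptor, paste(ELECTRON_ACCEPTORS, collapse = ", ")))
  if (!is.finite(temperature_C) || temperature_C < 0 || temperature_C > 150)
    abort_field("temperature_C must lie in [0, 150]")
  if (!is.finite(ph) || ph < 0 || ph > 14)
    abort_field("ph must lie in [0, 14]")
  if (!is.finite(catholyte_volume_L) || catholyte_volume_L <= 0)
    abort_field("catholyte_volume_L must be > 0")
  if (!is.finite(duration_s) || duration_s <= 0)
    abort_field("duration_s must be > 0")
  if (!is.finite(cathode_area_cm2) || cathode_area_cm2 <= 0)
    abort_field("cathode_area_cm2 must be > 0")
  structure(
    list(reactor_id = as.character(reactor_id), inoculum = inoculum,
         temperature_C = temperature_C, ph = ph,
         electron_acceptor = electron_acceptor,
         catholyte_volume_L = catholyte_volume_L, duration_s = duration_s,
         cathode_area_cm2 = cathode_area_cm2,
         cathode_potential_V_SHE = cathode_potential_V_SHE),
    class = "reactor_record")
}

#' Chronoamperometry trace for one reactor electrode
#'
#' Ordered record of (time, current) samples at a fixed electrode potential.
#' Cathodic (consumption) currents are recorded negative by potentiostats;
#' every downstream statistic works on magnitudes, so either a signed trace
#' (`polarity = "cathodic_negative"`) or a pre-rectified one
#' (`polarity = "magnitude"`) can be supplied.
#'
#' @param reactor_id reactor label.
#' @param time_s sample times in seconds, strictly increasing, >= 0.
#' @param current_A currents in amperes, finite.
#' @param area_cm2 cathode geometric area in cm2 (> 0).
#' @param polarity `"cathodic_negative"` or `"magnitude"`.
#' @return A `current_trace` object.
#' @export
current_trace <- function(reactor_id, time_s, current_A, area_cm2,
                          polarity = c("cathodic_negative", "magnitude")) {
  polarity <- match.arg(polarity)
  if (length(time_s) != length(current_A))
    abort_field("time_s and current_A must have equal length")
  if (length(time_s) < 2)
    abort_field("a trace needs at least 2 samples")
  if (any(!is.finite(time_s)) || any(time_s < 0))
    abort_field("times must be finite and >= 0")
  bad <- which(diff(time_s) <= 0)
  if (length(bad))
    abort_field(sprintf("time not increasing at row %d", bad[1] + 1L))
  if (any(!is.finite(current_A)))
    abort_field("currents must be finite")
  if (!is.finite(area_cm2) || area_cm2 <= 0)
    abort_field("area_cm2 must be > 0")
  structure(
    list(reactor_id = as.character(reactor_id),
         time_s = as.numeric(time_s), current_A = as.numeric(current_A),
         area_cm2 = area_cm2, polarity = polarity),
    class = "current_trace")
}

#' Absolute current density of a trace
#'
#' @param trace a [current_trace()].
#' @return Numeric vector of |j| in A/cm2, one value per sample.
#' @export
current_density <- function(trace) {
  stopifnot(inherits(trace, "current_trace"))
  abs(trace$current_A) / trace$area_cm2
}

#' Metabolite concentration time series
#'
#' @param reactor_id reactor label.
#' @param compound_name compound, matched against the registry by
#'   [compound_registry()] consumers.
#' @param timepoints_s sampling times in seconds, increasing.
#' @param concentrations_mM concentrations in mM, >= 0.
#' @return A `metabolite_series` object.
#' @export
metabolite_series <- function(reactor_id, compound_name, timepoints_s,
                              concentrations_mM) {
  if (length(timepoints_s) != length(concentrations_mM))
    abort_field("timepoints_s and concentrations_mM must have equal length")
  if (is.unsorted(timepoints_s, strictly = TRUE))
    abort_field("timepoints must be strictly increasing")
  if (any(!is.finite(concentrations_mM)) || any(concentrations_mM < 0))
    abort_field("concentrations must be finite and >= 0")
  structure(
    list(reactor_id = as.character(reactor_id),
         compound_name = as.character(compound_name),
         timepoints_s = as.numeric(timepoints_s),
         concentrations_mM = as.numeric(concentrations_mM)),
    class = "metabolite_series")
}

#' Net concentration change of a metabolite series
#'
#' Final minus initial concentration (last and first timepoints); intermediate
#' timepoints are carried for reporting but not fit.
#'
#' @param series a [metabolite_series()].
#' @return Delta concentration in mM (negative = net consumption).
#' @export
series_delta_mM <- function(series) {
  stopifnot(inherits(series, "metabolite_series"))
  n <- length(series$concentrations_mM)
  series$concentrations_mM[n] - series$concentrations_mM[1]
}

#' Initial/final chemical oxygen demand measurement
#'
#' @param reactor_id reactor label.
#' @param cod_initial_gO2_per_L,cod_final_gO2_per_L COD in g O2/L, >= 0.
#' @return A `cod_measurement` object.
#' @export
cod_measurement <- function(reactor_id, cod_initial_gO2_per_L,
                            cod_final_gO2_per_L) {
  if (any(!is.finite(c(cod_initial_gO2_per_L, cod_final_gO2_per_L))) ||
      cod_initial_gO2_per_L < 0 || cod_final_gO2_per_L < 0)
    abort_field("COD values must be finite and >= 0")
  structure(
    list(reactor_id = as.character(reactor_id),
         cod_initial_gO2_per_L = cod_initial_gO2_per_L,
         cod_final_gO2_per_L = cod_final_gO2_per_L),
    class = "cod_measurement")
}

#' Absolute 16S qPCR result for one cathode
#'
#' @param reactor_id reactor label.
#' @param bacterial_copies_per_cm2,archaeal_copies_per_cm2 16S gene copies
#'   per cm2 of cathode, >= 0.
#' @return A `qpcr_result` object.
#' @export
qpcr_result <- function(reactor_id, bacterial_copies_per_cm2,
                        archaeal_copies_per_cm2) {
  if (any(!is.finite(c(bacterial_copies_per_cm2, archaeal_copies_per_cm2))) ||
      bacterial_copies_per_cm2 < 0 || archaeal_copies_per_cm2 < 0)
    abort_field("qPCR copy numbers must be finite and >= 0")
  structure(
    list(reactor_id = as.character(reactor_id),
         bacterial_copies_per_cm2 = bacterial_copies_per_cm2,
         archaeal_copies_per_cm2 = archaeal_copies_per_cm2),
    class = "qpcr_result")
}

#' Ordinal biofilm coverage score
#'
#' Microscopy-derived electrode coverage on a 0-5 scale, 5 = full coverage.
#'
#' @param reactor_id reactor label.
#' @param score integer 0-5.
#' @return A `biofilm_score` object.
#' @export
biofilm_score <- function(reactor_id, score) {
  if (!is.finite(score) || score != round(score) || score < 0 || score > 5)
    abort_field("biofilm score must be an integer in 0..5")
  structure(list(reactor_id = as.character(reactor_id),
                 score = as.integer(score)),
            class = "biofilm_score")
}

AMPLICON_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' ASV count table with rank taxonomy
#'
#' Container for a denoised amplicon table: an ASV x sample integer count
#' matrix plus a fixed-depth rank lineage (domain..genus; `"NA"` allowed for
#' unassigned ranks) per ASV. Upstream read processing (denoising, chimera
#' removal, taxonomy assignment) is out of scope; this is the consumed output.
#'
#' @param counts integer matrix (ASVs x samples) with dimnames; counts >= 0.
#' @param taxonomy data frame with column `asv_id` plus the rank columns
#'   `r paste(AMPLICON_RANKS, collapse = ", ")`, one row per ASV.
#' @return An `amplicon_table` object.
#' @export
amplicon_table <- function(counts, taxonomy) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort_field("counts must have ASV rownames and sample colnames")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    abort_field("counts must be non-negative integers")
  taxonomy <- tibble::as_tibble(taxonomy)
  need <- c("asv_id", AMPLICON_RANKS)
  if (!all(need %in% names(taxonomy)))
    abort_field(sprintf("taxonomy must have columns: %s",
                        paste(need, collapse = ", ")))
  if (!setequal(taxonomy$asv_id, rownames(counts)))
    abort_field("taxonomy asv_id set must match counts rownames")
  taxonomy <- taxonomy[match(rownames(counts), taxonomy$asv_id), ]
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "amplicon_table")
}

#' @export
print.reactor_record <- function(x, ...) {
  cat(sprintf(
    "<reactor_record> %s | %s, %g degC, pH %g, acceptor %s | %g L, %g cm2, %g V vs SHE, %g d\n",
    x$reactor_id, x$inoculum, x$temperature_C, x$ph, x$electron_acceptor,
    x$catholyte_volume_L, x$cathode_area_cm2, x$cathode_potential_V_SHE,
    x$duration_s / 86400))
  invisible(x)
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %s | %d samples over %.3g s | area %g cm2 | %s\n",
              x$reactor_id, length(x$time_s), max(x$time_s) - min(x$time_s),
              x$area_cm2, x$polarity))
  invisible(x)
}

#' @export
print.amplicon_table <- function(x, ...) {
  cat(sprintf("<amplicon_table> %d ASVs x %d samples, %s total reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}
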