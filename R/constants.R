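#' Physical constants used throughout the package
#'
#' `FARADAY` is the Faraday constant in C per mole of electrons and
#' `GAS_CONSTANT` the molar gas constant in J/(mol K). All coulomb,
#' electron-equivalent and Nernst computations in the package use these
#' two values.
#'
#' @format Numeric scalars.
#' @name constants
NULL

#' @rdname constants
#' @export
FARADAY <- 96485

#' @rdname constants
#' @export
GAS_CONSTANT <- 8.314

#' Convert a temperature in degrees Celsius to Kelvin
#'
#' @param temperature_C temperature in degrees Celsius.
#' @return Temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(temperature_C) temperature_C + 273.15
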