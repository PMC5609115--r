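## Physical constants and unit conversion factors.
##
## Unit system used throughout the package (matching common usage in
## compartmental modelling): geometry in micrometres, time in ms, voltage in
## mV, concentrations in mM, membrane current densities in mA/cm^2, specific
## capacitance in uF/cm^2, conductance densities in S/cm^2, point currents in
## nA, point conductances in nS, pump surface densities in mol/cm^2.

#' Physical constants
#'
#' `FARADAY` is the Faraday constant in C/mol, `GAS_CONSTANT` the molar gas
#' constant in J/(mol K). `BODY_TEMP_K` is the default simulation
#' temperature (37 C) in kelvin.
#'
#' @name constants
#' @keywords internal
NULL

FARADAY <- 96485.33212
GAS_CONSTANT <- 8.31446262
BODY_TEMP_K <- 310.15

## d[ion]/dt in mM/ms produced by 1 nA of influx into 1 um^3 for a
## monovalent ion: 1e-9 A * 1e-3 s / (F * 1e-15 L) expressed in mM.
## Equals 1e6 / F ~= 10.3643 (mM um^3)/(nA ms).
RATE_PER_NA_UM3 <- 1e6 / FARADAY

## Current density (mA/cm^2) times membrane area (um^2) -> point current (nA).
DENSITY_TO_NA <- 0.01

## Pump turnover (mol cm^-2 ms^-1) -> current density (mA/cm^2) per unit
## charge: 1 C cm^-2 ms^-1 = 1e6 mA/cm^2.
MOLFLUX_TO_MA <- 1e6

#' RT/F in mV
#' @param T_K temperature in kelvin
#' @keywords internal
rtf_mV <- function(T_K) 1000 * GAS_CONSTANT * T_K / FARADAY
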