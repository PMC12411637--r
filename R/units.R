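#' @title Unit conventions and physical constants
#' @description
#' All specific activities are stored internally in Bq/kg, inhalation dose
#' coefficients in uSv/Bq, ambient dose equivalent rates in uSv/h and
#' effective doses in mSv/a. Every unit conversion used by the package is
#' defined here, once, to keep the frequent Bq/kg vs Bq/g and uSv vs mSv
#' slips out of the pathway code.
#' @name units
NULL

# Bq/kg -> Bq/g (geometry factors of the ambient-dose-rate table are
# normalised to 1 Bq/g Ra-226)
BQ_PER_KG_TO_BQ_PER_G <- 1e-3

# Bq/kg -> Bq/mg (dust activity per milligram of airborne dust)
BQ_PER_KG_TO_BQ_PER_MG <- 1e-6

# uSv -> mSv (pathway internals accumulate uSv, reports are mSv/a)
USV_TO_MSV <- 1e-3

SECONDS_PER_HOUR <- 3600

#' Radon-222 decay constant \[1/s\]
#'
#' The value used throughout the radon model (half-life ~3.82 d). Kept at
#' two significant figures to match the assessment it reproduces.
#' @export
LAMBDA_RN222 <- 2.1e-6

#' Radon dose conversion factor, ICRP 65 convention \[mSv m3 / (Bq h)\]
#'
#' Effective dose per unit radon gas exposure, to be multiplied by the
#' equilibrium factor F. This is the coefficient adopted in German
#' regulation (Annex 18 of the Radiation Protection Ordinance: an exposure
#' of 0.32 MBq h/m3 with F = 0.4 corresponds to ~1 mSv).
#' @export
DCF_ICRP65 <- 7.8e-6

#' Radon dose conversion factor, ICRP 137 convention \[mSv m3 / (Bq h)\]
#'
#' Alternative coefficient on the equilibrium-equivalent-concentration basis
#' (~10 mSv per working-level month, the ICRP 137 recommendation for most
#' workplace conditions). Not the package default: regulatory practice in
#' Germany retains the ICRP 65 value.
#' @export
DCF_ICRP137 <- 1.6e-5

#' Maximum allowable workplace concentrations of alveolar (A-) dust \[mg/m3\]
#'
#' `MAC_A_DUST_ROUTINE` (1.25 mg/m3) applies to routine plant areas,
#' `MAC_A_DUST_OCCASIONAL` (3 mg/m3) to occasional exposures such as filter
#' maintenance, per the German Technical Rules for Hazardous Substances.
#' @export
MAC_A_DUST_ROUTINE <- 1.25

#' @rdname MAC_A_DUST_ROUTINE
#' @export
MAC_A_DUST_OCCASIONAL <- 3

# Convert a ventilation (air-change) rate to 1/s.
# unit: "per_hour" or "per_second". Conversion is exact (1/h = 1/3600 1/s);
# rounded per-second figures such as 3e-4 for 1/h visibly shift steady-state
# radon concentrations and are not used.
vent_per_second <- function(v, unit = c("per_hour", "per_second")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(v), all(v >= 0))
  if (unit == "per_hour") v / SECONDS_PER_HOUR else v
}
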