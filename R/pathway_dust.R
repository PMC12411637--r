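#' @title Dust inhalation pathway
#' @description
#' Internal exposure from breathing dust raised from the handled material.
#' The airborne activity of nuclide i is `C_air,i = C_dust * C_i * (1 -
#' f_inh)` (dust concentration times specific activity, reduced by any
#' respirator), and the committed effective dose is `V' * t_exp * sum_i
#' g_inh,i * C_air,i` with breathing rate V' (1.2 m3/h for the reference
#' worker). The dust is assumed to carry the bulk material's nuclide
#' vector; no particle-size enrichment is modelled beyond the fixed
#' AMAD-5-um coefficient table.
#' @name pathway_dust
NULL

#' Configuration of one dust inhalation exposure
#'
#' @param c_dust airborne dust concentration \[mg/m3\], >= 0. Defaults are
#'   available as [MAC_A_DUST_ROUTINE] (1.25, routine plant areas) and
#'   [MAC_A_DUST_OCCASIONAL] (3, occasional work such as filter
#'   maintenance).
#' @param t_exp annual exposure time \[h/a\], >= 0.
#' @param breathing_rate breathing rate V' \[m3/h\]; 1.2 for light work.
#' @param f_inh respirator reduction fraction in \[0, 1\] (0 = no mask;
#'   an FFP-2 mask reaches up to 0.94).
#' @return object of class `dust_exposure_config`.
#' @export
dust_exposure_config <- function(c_dust, t_exp, breathing_rate = 1.2,
                                 f_inh = 0) {
  stopifnot(is.numeric(c_dust), c_dust >= 0,
            is.numeric(t_exp), t_exp >= 0,
            is.numeric(breathing_rate), breathing_rate >= 0,
            is.numeric(f_inh), f_inh >= 0, f_inh <= 1)
  structure(
    list(c_dust = c_dust, t_exp = t_exp, breathing_rate = breathing_rate,
         f_inh = f_inh),
    class = "dust_exposure_config"
  )
}

#' Airborne activity concentrations of dust-borne nuclides
#'
#' `C_air,i = C_dust * C_i * (1 - f_inh)`, with the specific activity
#' converted from Bq/kg to Bq/mg so the product with the mg/m3 dust
#' concentration yields Bq/m3.
#'
#' @param v a [nuclide_vector()].
#' @param cfg a [dust_exposure_config()].
#' @return named numeric vector of activity concentrations \[Bq/m3\], class
#'   `airborne_activity`.
#' @export
airborne_activity <- function(v, cfg) {
  stopifnot(inherits(v, "nuclide_vector"),
            inherits(cfg, "dust_exposure_config"))
  structure(
    v$activities * BQ_PER_KG_TO_BQ_PER_MG * cfg$c_dust * (1 - cfg$f_inh),
    class = "airborne_activity"
  )
}

#' Annual effective dose from dust inhalation
#'
#' `E = V' * t_exp * sum_i g_inh,i * C_air,i`, in mSv/a. Algebraically this
#' factorises as `V' * t_exp * C_dust * (1 - f_inh) * unit_dust_dose(v)`.
#'
#' @param v a [nuclide_vector()].
#' @param dc a [dose_coefficients()] table.
#' @param cfg a [dust_exposure_config()].
#' @return effective dose \[mSv/a\].
#' @examples
#' cfg <- dust_exposure_config(c_dust = MAC_A_DUST_ROUTINE, t_exp = 1000)
#' dust_dose(load_nuclide_vector("nodules_bulk"),
#'           load_dose_coefficients(), cfg)  # ~0.09 mSv/a
#' @export
dust_dose <- function(v, dc, cfg) {
  stopifnot(inherits(dc, "dose_coefficients"),
            inherits(cfg, "dust_exposure_config"))
  c_air <- airborne_activity(v, cfg)
  common <- intersect(names(c_air), names(dc$g_inh))
  usv <- cfg$breathing_rate * cfg$t_exp *
    sum(dc$g_inh[common] * unclass(c_air)[common])
  usv * USV_TO_MSV
}
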