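#' @title External gamma pathway
#' @description
#' External exposure next to stored or handled nodule material is driven by
#' the gamma-emitting short-lived daughters of Ra-226 (Pb-214, Bi-214),
#' which are largely in secular equilibrium with it. The ambient dose
#' equivalent rate H*(10) therefore scales with the Ra-226 specific
#' activity through a geometry-dependent proportionality factor
#' (uSv/h per Bq/g), tabulated for standard storage geometries. Effective
#' dose is `f_con * H*(10) * t_exp * a_s`, with `f_con = 0.6` converting
#' H*(10) to effective dose and `a_s` the transmitted fraction through any
#' shielding. Gamma from the low-activity Th-232 series and from airborne
#' radon progeny is negligible and not modelled.
#' @name pathway_gamma
NULL

#' Tabulated ambient-dose-rate geometry factors
#'
#' Proportionality factors between Ra-226 specific activity and the ambient
#' dose equivalent rate H*(10), normalised to 1000 Bq/kg (= 1 Bq/g)
#' Ra-226, for standard storage geometries: laterally infinitely extended
#' surface (2-pi geometry), cone-shaped pile (4 m diameter, 2 m height),
#' a single 1-m3 big bag, and two big bags side by side or stacked. Values
#' at the surface and at 1 m distance.
#'
#' @return data.frame with columns `geometry`,
#'   `adr_surface_uSv_per_h_per_Bq_g`, `adr_1m_uSv_per_h_per_Bq_g`.
#' @export
geometry_factors <- function() {
  utils::read.csv(
    system.file("extdata", "geometry_factors.csv", package = "noduledose"),
    stringsAsFactors = FALSE
  )
}

#' Construct a geometry factor for the gamma pathway
#'
#' Either pick a tabulated geometry by label (and measurement distance) or
#' give a custom proportionality factor directly.
#'
#' @param label one of the tabulated geometries (see [geometry_factors()]),
#'   or `NULL` when `adr_per_activity` is given.
#' @param distance `"surface"` or `"1m"`.
#' @param adr_per_activity custom proportionality factor
#'   \[uSv/h per Bq/g Ra-226\], >= 0.
#' @return object of class `geometry_factor`.
#' @examples
#' geometry_factor("extended_surface")
#' geometry_factor(adr_per_activity = 0.4, label = "stockpile average")
#' @export
geometry_factor <- function(label = NULL, distance = c("surface", "1m"),
                            adr_per_activity = NULL) {
  distance <- match.arg(distance)
  if (is.null(adr_per_activity)) {
    tab <- geometry_factors()
    i <- match(label, tab$geometry)
    if (is.na(i)) {
      stop("unknown geometry '", label, "'; tabulated: ",
           paste(tab$geometry, collapse = ", "), call. = FALSE)
    }
    adr_per_activity <- if (distance == "surface") {
      tab$adr_surface_uSv_per_h_per_Bq_g[i]
    } else {
      tab$adr_1m_uSv_per_h_per_Bq_g[i]
    }
  }
  stopifnot(is.numeric(adr_per_activity), length(adr_per_activity) == 1,
            is.finite(adr_per_activity), adr_per_activity >= 0)
  structure(
    list(label = if (is.null(label)) "custom" else label,
         adr_per_activity = adr_per_activity,
         distance_note = if (distance == "surface") "at surface" else "at 1 m"),
    class = "geometry_factor"
  )
}

#' Inverse-square scaling of an ambient dose rate with distance
#'
#' Beyond distances comparable to the lateral dimensions of a bounded
#' source, the ambient dose rate falls off approximately with the inverse
#' square of distance. This helper rescales a reference ADR accordingly; it
#' is an approximation — the tabulated 1-m factors are measured/derived
#' values, not computed from this rule.
#'
#' @param adr reference ambient dose rate \[uSv/h\].
#' @param d_ref distance at which `adr` applies \[m\], > 0.
#' @param d target distance \[m\], > 0.
#' @return scaled ambient dose rate \[uSv/h\].
#' @export
adr_at_distance <- function(adr, d_ref, d) {
  stopifnot(adr >= 0, d_ref > 0, d > 0)
  adr * (d_ref / d)^2
}

#' Ambient dose equivalent rate H*(10) next to stored material
#'
#' `H*(10) = ADR_factor * C_Ra-226`, with the Ra-226 specific activity
#' expressed in Bq/g (the tabulated factors are normalised to 1000 Bq/kg).
#'
#' @param v a [nuclide_vector()] containing Ra-226.
#' @param g a [geometry_factor()], or a bare numeric proportionality factor
#'   \[uSv/h per Bq/g\].
#' @return H*(10) \[uSv/h\].
#' @examples
#' ambient_dose_rate(load_nuclide_vector("nodules_bulk"),
#'                   geometry_factor("extended_surface"))
#' @export
ambient_dose_rate <- function(v, g) {
  stopifnot(inherits(v, "nuclide_vector"))
  f <- if (inherits(g, "geometry_factor")) g$adr_per_activity else {
    stopifnot(is.numeric(g), length(g) == 1, g >= 0)
    g
  }
  c_ra <- activity_of(v, "Ra-226") * BQ_PER_KG_TO_BQ_PER_G
  f * c_ra
}

#' Configuration of one external gamma exposure
#'
#' @param geometry a [geometry_factor()] (or numeric factor, uSv/h per
#'   Bq/g).
#' @param t_exp annual exposure time \[h/a\], >= 0.
#' @param shielding transmitted fraction `a_s` in \[0, 1\] (1 = no
#'   shielding; "shielding of the ADR by 50%" means `a_s = 0.5`).
#' @param f_con conversion factor from H*(10) to effective dose, in
#'   (0, 1\]; 0.6 for the reference person.
#' @return object of class `gamma_exposure_config`.
#' @export
gamma_exposure_config <- function(geometry, t_exp, shielding = 1,
                                  f_con = 0.6) {
  if (!inherits(geometry, "geometry_factor")) {
    geometry <- geometry_factor(adr_per_activity = geometry)
  }
  stopifnot(is.numeric(t_exp), length(t_exp) == 1, t_exp >= 0,
            is.numeric(shielding), shielding >= 0, shielding <= 1,
            is.numeric(f_con), f_con > 0, f_con <= 1)
  structure(
    list(geometry = geometry, t_exp = t_exp, shielding = shielding,
         f_con = f_con),
    class = "gamma_exposure_config"
  )
}

#' Annual effective dose from external gamma exposure
#'
#' `E = f_con * H*(10) * t_exp * a_s`, converted to mSv/a. When `cfg` is a
#' list of configurations (several sources), their contributions are
#' summed; `v` may then be a single vector or a parallel list of vectors.
#'
#' @param cfg a [gamma_exposure_config()] or a list of them.
#' @param v a [nuclide_vector()] (or list of vectors parallel to `cfg`).
#' @return effective dose \[mSv/a\].
#' @examples
#' cfg <- gamma_exposure_config(geometry_factor("extended_surface"),
#'                              t_exp = 2000, shielding = 0.5)
#' gamma_dose(cfg, load_nuclide_vector("nodules_bulk"))  # ~0.7 mSv/a
#' @export
gamma_dose <- function(cfg, v) {
  if (inherits(cfg, "gamma_exposure_config")) cfg <- list(cfg)
  vs <- if (inherits(v, "nuclide_vector")) rep(list(v), length(cfg)) else v
  stopifnot(length(vs) == length(cfg))
  doses <- mapply(function(one, vec) {
    stopifnot(inherits(one, "gamma_exposure_config"))
    h10 <- ambient_dose_rate(vec, one$geometry)
    one$f_con * h10 * one$t_exp * one$shielding * USV_TO_MSV
  }, cfg, vs)
  sum(doses)
}
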