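#' @title Radon physics chain
#' @description
#' Radon (Rn-222) is produced by Ra-226 decay inside the nodules, emanates
#' into the pore space and escapes by diffusion. For a thick (> 3 m)
#' layer the surface exhalation rate of an extended source is
#' `P = C_Ra-226 * E * rho * sqrt(D_bulk / lambda) * lambda`, with the bulk
#' diffusion coefficient `D_bulk = D_MA * R_por` (molecular diffusion of
#' radon in air scaled by porosity). Indoors, the activity concentration
#' obeys the one-compartment balance `dC/dt = e' + v*C_a - (lambda + v)*C`
#' with volume-specific entry rate e' and ventilation rate v; the steady
#' state (outdoor term negligible) is `C = e' / (lambda + v)`. Comminution
#' of nodules releases a fraction of the stored radon as a source term
#' `R = C_Ra-226 * f_com * pc`. Inhalation dose is
#' `E = C_Rn * t_exp * F * DCF` with equilibrium factor F (0.4) and the
#' ICRP 65 dose conversion factor.
#' @name radon_model
NULL

#' Radon-relevant material properties of a nodule layer
#'
#' @param c_ra226 Ra-226 specific activity \[Bq/kg\], > 0.
#' @param emanation emanation factor E(Theta) in \[0, 1\]; 0.36 for dry
#'   nodules (the conservative choice — saturated nodules exhale about half
#'   as much, but no measured wet emanation factor is packaged).
#' @param bulk_density bulk density rho \[kg/m3\]; 3300 for nodules.
#' @param porosity measured porosity R_por in (0, 1); 0.6 for nodules.
#' @param d_ma molecular diffusion coefficient of radon in air \[m2/s\].
#' @return object of class `radon_material_props`.
#' @export
radon_material_props <- function(c_ra226, emanation = 0.36,
                                 bulk_density = 3300, porosity = 0.6,
                                 d_ma = 1e-5) {
  stopifnot(is.numeric(c_ra226), c_ra226 >= 0,
            is.numeric(emanation), emanation >= 0, emanation <= 1,
            is.numeric(bulk_density), bulk_density > 0,
            is.numeric(porosity), porosity > 0, porosity < 1,
            is.numeric(d_ma), d_ma > 0)
  structure(
    list(c_ra226 = c_ra226, emanation = emanation,
         bulk_density = bulk_density, porosity = porosity, d_ma = d_ma),
    class = "radon_material_props"
  )
}

#' Bulk diffusion coefficient of radon in the nodule layer
#'
#' `D_bulk = D_MA * R_por` \[m2/s\].
#'
#' @param m a [radon_material_props()].
#' @return bulk diffusion coefficient \[m2/s\].
#' @export
bulk_diffusion <- function(m) {
  stopifnot(inherits(m, "radon_material_props"))
  m$d_ma * m$porosity
}

#' Diffusive radon exhalation rate from a thick extended source
#'
#' `P = C_Ra-226 * E * rho * sqrt(D_bulk / lambda) * lambda`
#' \[Bq/(m2 s)\]. Valid for layer thicknesses well above the diffusion
#' length (> 3 m for nodules); the thickness assumption is the caller's
#' responsibility.
#'
#' @param m a [radon_material_props()].
#' @param lambda Rn-222 decay constant \[1/s\].
#' @return exhalation rate P \[Bq/(m2 s)\]; scales as `sqrt(D_bulk)`.
#' @examples
#' exhalation_rate(radon_material_props(c_ra226 = 2317))  # ~10 Bq/(m2 s)
#' @export
exhalation_rate <- function(m, lambda = LAMBDA_RN222) {
  stopifnot(inherits(m, "radon_material_props"), lambda > 0)
  m$c_ra226 * m$emanation * m$bulk_density *
    sqrt(bulk_diffusion(m) / lambda) * lambda
}

#' Enclosure geometry and ventilation for the indoor radon balance
#'
#' @param volume air volume V \[m3\], > 0.
#' @param area exhaling surface area A \[m2\], > 0. The default cargo-hold
#'   convention takes the hold footprint as the effective exhaling area:
#'   only the top surface of the nodule layer feeds the head space.
#' @param ventilation air-change rate, >= 0, in the unit given by
#'   `vent_unit`.
#' @param vent_unit `"per_hour"` (default) or `"per_second"`; conversion to
#'   1/s is exact (1/h = 1/3600 1/s).
#' @param outdoor_conc outdoor radon concentration C_a \[Bq/m3\]
#'   (default 0: the outdoor term is negligible against nodule sources).
#' @param lambda_rn Rn-222 decay constant \[1/s\].
#' @return object of class `radon_environment` (ventilation stored in 1/s).
#' @examples
#' radon_environment(volume = 4500, area = 900, ventilation = 1)
#' @export
radon_environment <- function(volume, area, ventilation,
                              vent_unit = c("per_hour", "per_second"),
                              outdoor_conc = 0, lambda_rn = LAMBDA_RN222) {
  stopifnot(is.numeric(volume), volume > 0,
            is.numeric(area), area > 0,
            is.numeric(ventilation), ventilation >= 0,
            is.numeric(outdoor_conc), outdoor_conc >= 0,
            is.numeric(lambda_rn), lambda_rn > 0)
  structure(
    list(volume = volume, area = area,
         ventilation = vent_per_second(ventilation, match.arg(vent_unit)),
         outdoor_conc = outdoor_conc, lambda_rn = lambda_rn),
    class = "radon_environment"
  )
}

#' Volume-specific radon entry rate from an exhaling surface
#'
#' `e' = P * A / V` \[Bq/(m3 s)\].
#'
#' @param P exhalation rate \[Bq/(m2 s)\], >= 0.
#' @param env a [radon_environment()].
#' @return entry rate e' \[Bq/(m3 s)\].
#' @export
entry_rate_surface <- function(P, env) {
  stopifnot(is.numeric(P), P >= 0, inherits(env, "radon_environment"))
  P * env$area / env$volume
}

#' Comminution radon source
#'
#' @param pc processing capacity \[kg/s\], > 0.
#' @param f_com fraction of the radon stored in the material released at
#'   comminution, in \[0, 1\]; 0.3 by default.
#' @param f_indoor fraction of the release occurring indoors, in \[0, 1\];
#'   0.5 by default (crushing/milling outdoors, further processing in the
#'   production hall).
#' @return object of class `comminution_source`.
#' @export
comminution_source <- function(pc, f_com = 0.3, f_indoor = 0.5) {
  stopifnot(is.numeric(pc), pc > 0,
            is.numeric(f_com), f_com >= 0, f_com <= 1,
            is.numeric(f_indoor), f_indoor >= 0, f_indoor <= 1)
  structure(list(pc = pc, f_com = f_com, f_indoor = f_indoor),
            class = "comminution_source")
}

#' Radon source term and indoor entry rate from nodule comminution
#'
#' Source term `R = C_Ra-226 * f_com * pc` \[Bq/s\] (the released fraction
#' of the radon activity stored in the processed mass stream), of which a
#' fraction `f_indoor` enters the hall: `e' = R * f_indoor / V`.
#'
#' @param v a [nuclide_vector()] containing Ra-226.
#' @param src a [comminution_source()].
#' @param env a [radon_environment()] for the production hall.
#' @return list with `R_source` \[Bq/s\] and `e_prime` \[Bq/(m3 s)\].
#' @examples
#' hall <- radon_environment(45000, area = 3000, ventilation = 10)
#' entry_rate_comminution(load_nuclide_vector("nodules_bulk"),
#'                        comminution_source(pc = 95), hall)
#' @export
entry_rate_comminution <- function(v, src, env) {
  stopifnot(inherits(v, "nuclide_vector"),
            inherits(src, "comminution_source"),
            inherits(env, "radon_environment"))
  R <- activity_of(v, "Ra-226") * src$f_com * src$pc
  list(R_source = R, e_prime = R * src$f_indoor / env$volume)
}

#' Steady-state indoor radon concentration
#'
#' `C = (e' + v * C_a) / (lambda + v)`; with the default zero outdoor
#' concentration this is the balance of entry against decay plus
#' ventilation. Strictly decreasing in v; for v = 0 it reaches the maximum
#' accumulation `e' / lambda`.
#'
#' @param e_prime volume-specific entry rate \[Bq/(m3 s)\], >= 0.
#' @param env a [radon_environment()].
#' @return steady-state concentration \[Bq/m3\].
#' @examples
#' hold <- radon_environment(4500, 900, ventilation = 1)
#' P <- exhalation_rate(radon_material_props(2317))
#' steady_state_concentration(entry_rate_surface(P, hold), hold)  # ~7000
#' @export
steady_state_concentration <- function(e_prime, env) {
  stopifnot(is.numeric(e_prime), e_prime >= 0,
            inherits(env, "radon_environment"))
  sink <- env$lambda_rn + env$ventilation
  if (sink <= 0) stop("lambda + v must be > 0 (no sink)", call. = FALSE)
  (e_prime + env$ventilation * env$outdoor_conc) / sink
}

#' Transient indoor radon concentration
#'
#' Closed-form solution of the linear balance
#' `dC/dt = e' + v*C_a - (lambda + v) * C`:
#' `C(t) = C_ss + (C_0 - C_ss) * exp(-(lambda + v) t)` with `C_ss` the
#' steady state of [steady_state_concentration()]. With no source and no
#' ventilation this reduces to pure decay `C_0 * exp(-lambda t)`.
#'
#' @param e_prime volume-specific entry rate \[Bq/(m3 s)\], >= 0.
#' @param env a [radon_environment()].
#' @param c0 initial concentration \[Bq/m3\], >= 0.
#' @param t time since `c0` \[s\], >= 0 (vectorised).
#' @return concentration C(t) \[Bq/m3\].
#' @export
transient_concentration <- function(e_prime, env, c0, t) {
  stopifnot(is.numeric(c0), c0 >= 0, is.numeric(t))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  stopifnot(inherits(env, "radon_environment"))
  k <- env$lambda_rn + env$ventilation
  c_ss <- steady_state_concentration(e_prime, env)
  c_ss + (c0 - c_ss) * exp(-k * t)
}

#' Configuration of a radon inhalation exposure
#'
#' @param c_rn radon activity concentration \[Bq/m3\], >= 0.
#' @param t_exp exposure time \[h\], >= 0.
#' @param equilibrium_factor F in \[0, 1\]; 0.4 for typical workplaces.
#' @param dcf dose conversion factor \[mSv m3 / (Bq h)\]; [DCF_ICRP65] by
#'   default ([DCF_ICRP137] is available as an alternative constant).
#' @return object of class `radon_dose_config`.
#' @export
radon_dose_config <- function(c_rn, t_exp, equilibrium_factor = 0.4,
                              dcf = DCF_ICRP65) {
  stopifnot(is.numeric(c_rn), c_rn >= 0,
            is.numeric(t_exp), t_exp >= 0,
            is.numeric(equilibrium_factor), equilibrium_factor >= 0,
            equilibrium_factor <= 1,
            is.numeric(dcf), dcf >= 0)
  structure(
    list(c_rn = c_rn, t_exp = t_exp,
         equilibrium_factor = equilibrium_factor, dcf = dcf),
    class = "radon_dose_config"
  )
}

#' Effective dose from inhalation of radon and its progeny
#'
#' `E = C_Rn * t_exp * F * DCF` \[mSv/a\] — linear in each factor.
#'
#' @param cfg a [radon_dose_config()].
#' @return effective dose \[mSv/a\].
#' @examples
#' radon_dose(radon_dose_config(c_rn = 300, t_exp = 2000))  # 1.87 mSv/a
#' @export
radon_dose <- function(cfg) {
  stopifnot(inherits(cfg, "radon_dose_config"))
  cfg$c_rn * cfg$t_exp * cfg$equilibrium_factor * cfg$dcf
}
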