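#' @title Scenario engine: composing pathways into annual dose reports
#' @description
#' A scenario names a set of exposure pathways bound to materials: external
#' gamma pathways, dust inhalation pathways and (optionally) one radon
#' exposure. The total effective dose is the sum over pathways
#' (`E = E_gamma + E_dust + E_radon`); ingestion is excluded, assuming
#' compliance with standard health-and-safety rules. A surface-layer
#' sensitivity multiplier (up to 3) scales all material specific
#' activities — and hence the gamma and dust doses linearly — to represent
#' the higher activity of the outer ~1 mm nodule layer; a fixed radon
#' concentration is not material-derived and is held constant.
#' @name scenario_engine
NULL

OCCUPATIONAL_THRESHOLD_MSV <- 1   # classification benchmark [mSv/a]
WORKER_DOSE_LIMIT_MSV <- 20       # annual limit for exposed workers [mSv/a]

#' Construct an exposure scenario
#'
#' Pathway entries are plain lists (as loaded from a YAML scenario file):
#'
#' * gamma: `label`, `material` (inventory key), `geometry` (tabulated
#'   label) or `factor` (uSv/h per Bq/g), optional `distance`
#'   (`"surface"`/`"1m"`), `t_exp` \[h/a\], `shielding` (transmitted
#'   fraction, default 1), `f_con` (default 0.6).
#' * dust: `label`, `material`, `c_dust` \[mg/m3\], `t_exp` \[h/a\],
#'   `breathing_rate` (default 1.2 m3/h), `f_inh` (default 0).
#' * radon: `c_rn` \[Bq/m3\], `t_exp` \[h\], `equilibrium_factor`
#'   (default 0.4), `dcf` (default [DCF_ICRP65]); or `NULL` for none.
#'
#' @param label scenario name.
#' @param gamma list of gamma pathway entries (possibly empty).
#' @param dust list of dust pathway entries (possibly empty).
#' @param radon radon entry or `NULL`.
#' @param surface_multiplier activity multiplier >= 1 (default 1; 3 for
#'   the surface-layer sensitivity case).
#' @return object of class `scenario`.
#' @export
scenario <- function(label, gamma = list(), dust = list(), radon = NULL,
                     surface_multiplier = 1) {
  stopifnot(is.list(gamma), is.list(dust),
            is.numeric(surface_multiplier), surface_multiplier >= 1)
  if (length(gamma) + length(dust) == 0 && is.null(radon)) {
    stop("a scenario needs at least one exposure pathway", call. = FALSE)
  }
  structure(
    list(label = as.character(label), gamma = gamma, dust = dust,
         radon = radon, surface_multiplier = surface_multiplier),
    class = "scenario"
  )
}

#' Default material inventory
#'
#' Named list of the packaged nuclide vectors: bulk nodules, the slag of
#' the third reduction stage and the flue (filter) dust of the first
#' reduction stage.
#'
#' @return named list of [nuclide_vector()]s.
#' @export
default_inventory <- function() {
  mats <- c("nodules_bulk", "slag_3rd_reduction", "filter_dust")
  stats::setNames(lapply(mats, load_nuclide_vector), mats)
}

#' Load a scenario from a YAML file
#'
#' @param path YAML scenario file; see
#'   `system.file("extdata", "scenarios", package = "noduledose")` for the
#'   packaged examples.
#' @return a [scenario()].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("no such scenario file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  scenario(
    label = cfg$label,
    gamma = if (is.null(cfg$gamma)) list() else cfg$gamma,
    dust = if (is.null(cfg$dust)) list() else cfg$dust,
    radon = cfg$radon,
    surface_multiplier = if (is.null(cfg$surface_multiplier)) 1 else
      cfg$surface_multiplier
  )
}

#' Packaged reference scenarios
#'
#' `"transport"`: reference person in the engine room of a bulk carrier,
#' gamma only (2000 h/a behind 50% steel shielding next to the laterally
#' extended nodule surface). `"processing_plant"`: reference person
#' covering the five production workplaces (gamma from stored nodules and
#' slag, dust from nodules, slag and filter maintenance) plus the separate
#' radon exposure at the 300 Bq/m3 indoor reference concentration.
#'
#' @param name `"transport"` or `"processing_plant"`.
#' @return a [scenario()].
#' @examples
#' run_scenario(packaged_scenario("transport"))
#' @export
packaged_scenario <- function(name = c("transport", "processing_plant")) {
  name <- match.arg(name)
  load_scenario(system.file("extdata", "scenarios", paste0(name, ".yaml"),
                            package = "noduledose"))
}

.resolve_material <- function(key, inventory) {
  if (is.null(key) || !key %in% names(inventory)) {
    stop("unresolved material reference: '", key, "' (inventory has: ",
         paste(names(inventory), collapse = ", "), ")", call. = FALSE)
  }
  inventory[[key]]
}

.gamma_cfg_from_entry <- function(p) {
  geom <- if (!is.null(p$factor)) {
    geometry_factor(adr_per_activity = p$factor)
  } else {
    geometry_factor(p$geometry,
                    distance = if (is.null(p$distance) || p$distance == "surface")
                      "surface" else "1m")
  }
  gamma_exposure_config(
    geometry = geom, t_exp = p$t_exp,
    shielding = if (is.null(p$shielding)) 1 else p$shielding,
    f_con = if (is.null(p$f_con)) 0.6 else p$f_con
  )
}

.dust_cfg_from_entry <- function(p) {
  dust_exposure_config(
    c_dust = p$c_dust, t_exp = p$t_exp,
    breathing_rate = if (is.null(p$breathing_rate)) 1.2 else p$breathing_rate,
    f_inh = if (is.null(p$f_inh)) 0 else p$f_inh
  )
}

.radon_cfg_from_entry <- function(p) {
  radon_dose_config(
    c_rn = p$c_rn, t_exp = p$t_exp,
    equilibrium_factor = if (is.null(p$equilibrium_factor)) 0.4 else
      p$equilibrium_factor,
    dcf = if (is.null(p$dcf)) DCF_ICRP65 else p$dcf
  )
}

#' Run a scenario and assemble its dose report
#'
#' Resolves each pathway's material from the inventory, applies the
#' surface-layer multiplier to the material activities, evaluates the
#' pathway doses and sums them. Radon is reported separately from the
#' gamma+dust subtotal, mirroring how such assessments present the
#' ventilation-dependent radon contribution.
#'
#' @param s a [scenario()].
#' @param inventory named list of [nuclide_vector()]s;
#'   [default_inventory()] by default.
#' @param coefficients a [dose_coefficients()] table.
#' @return object of class `dose_report`: `pathways` (data.frame with
#'   columns `pathway`, `type`, `dose_mSv`), `subtotal_excl_radon`,
#'   `radon_dose`, `total` \[mSv/a\] and the classification flags of
#'   [classify()].
#' @examples
#' run_scenario(packaged_scenario("processing_plant"))
#' @export
run_scenario <- function(s, inventory = default_inventory(),
                         coefficients = load_dose_coefficients()) {
  stopifnot(inherits(s, "scenario"))
  mult <- s$surface_multiplier

  rows <- list()
  for (p in s$gamma) {
    v <- scale_vector(.resolve_material(p$material, inventory), mult)
    d <- gamma_dose(.gamma_cfg_from_entry(p), v)
    rows[[length(rows) + 1]] <- data.frame(
      pathway = if (is.null(p$label)) "gamma" else p$label,
      type = "gamma", dose_mSv = d, stringsAsFactors = FALSE)
  }
  for (p in s$dust) {
    v <- scale_vector(.resolve_material(p$material, inventory), mult)
    d <- dust_dose(v, coefficients, .dust_cfg_from_entry(p))
    rows[[length(rows) + 1]] <- data.frame(
      pathway = if (is.null(p$label)) "dust" else p$label,
      type = "dust", dose_mSv = d, stringsAsFactors = FALSE)
  }
  radon <- 0
  if (!is.null(s$radon)) {
    radon <- radon_dose(.radon_cfg_from_entry(s$radon))
    rows[[length(rows) + 1]] <- data.frame(
      pathway = "radon inhalation", type = "radon", dose_mSv = radon,
      stringsAsFactors = FALSE)
  }
  pathways <- do.call(rbind, rows)
  subtotal <- sum(pathways$dose_mSv[pathways$type != "radon"])
  total <- subtotal + radon

  rep <- structure(
    list(label = s$label, surface_multiplier = mult, pathways = pathways,
         subtotal_excl_radon = subtotal, radon_dose = radon, total = total),
    class = "dose_report"
  )
  c_ls <- classify(rep)
  rep$occupationally_exposed <- c_ls$occupationally_exposed
  rep$exceeds_limit <- c_ls$exceeds_limit
  rep
}

#' Classify a dose report against the regulatory benchmarks
#'
#' Workers must be classified as occupationally exposed when the effective
#' dose exceeds (or may exceed) 1 mSv/a; the annual limit for occupationally
#' exposed workers is 20 mSv/a.
#'
#' @param report a `dose_report` from [run_scenario()], or a bare total
#'   dose \[mSv/a\].
#' @return list with `total`, `occupationally_exposed` (total >= 1 mSv/a)
#'   and `exceeds_limit` (total > 20 mSv/a).
#' @examples
#' classify(0.7)   # not occupationally exposed
#' classify(2.47)  # exposed, below the 20 mSv/a limit
#' @export
classify <- function(report) {
  total <- if (inherits(report, "dose_report")) report$total else {
    stopifnot(is.numeric(report), report >= 0)
    report
  }
  list(
    total = total,
    occupationally_exposed = total >= OCCUPATIONAL_THRESHOLD_MSV,
    exceeds_limit = total > WORKER_DOSE_LIMIT_MSV
  )
}

#' @export
print.dose_report <- function(x, ...) {
  cat("<dose_report>", x$label,
      if (x$surface_multiplier != 1)
        sprintf("(surface multiplier %g)", x$surface_multiplier) else "",
      "\n")
  df <- x$pathways
  df$dose_mSv <- signif(df$dose_mSv, 3)
  print(df, row.names = FALSE)
  cat(sprintf("subtotal excl. radon: %.3g mSv/a\n", x$subtotal_excl_radon))
  if (x$radon_dose > 0) {
    cat(sprintf("radon inhalation:     %.3g mSv/a\n", x$radon_dose))
  }
  cat(sprintf("total:                %.3g mSv/a\n", x$total))
  cat(if (x$occupationally_exposed) {
    "classification: occupationally exposed (>= 1 mSv/a)"
  } else {
    "classification: not occupationally exposed (< 1 mSv/a)"
  },
  if (x$exceeds_limit) "- EXCEEDS 20 mSv/a LIMIT" else "", "\n")
  invisible(x)
}
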