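#' @title Radionuclide inventory: decay series, activities, dose coefficients
#' @description
#' The radiological fingerprint of a material is a nuclide vector: specific
#' activities (Bq/kg) of the long-lived members of the three natural decay
#' series, optionally with relative measurement uncertainties. Inhalation
#' dose coefficients (uSv/Bq, AMAD 5 um) convert inhaled activity to
#' committed effective dose.
#' @name nuclide_inventory
NULL

# Long-lived members of the three natural decay series known to the package.
# Only nuclides with an inhalation dose coefficient > 0.1 uSv/Bq carry dose;
# short-lived gamma emitters (Pb-214, Bi-214) are listed because Ra-226
# serves as their equilibrium proxy in the gamma pathway.
.nuclide_registry <- function() {
  data.frame(
    nuclide = c(
      "U-238", "Th-234", "U-234", "Th-230", "Ra-226", "Rn-222",
      "Pb-214", "Bi-214", "Pb-210", "Po-210",
      "U-235", "Pa-231", "Ac-227", "Th-227", "Ra-223",
      "Th-232", "Ra-228", "Ac-228", "Th-228", "Ra-224"
    ),
    series = c(
      rep("U-238", 10),
      rep("U-235", 5),
      rep("Th-232", 5)
    ),
    stringsAsFactors = FALSE
  )
}

#' Normalise a nuclide name to canonical "Element-Mass" form
#'
#' Accepts `"Ra-226"`, `"226Ra"`, `"Ra226"`, `"ra-226"` and whitespace
#' variants; unknown nuclides (not members of the U-238, U-235 or Th-232
#' natural decay series tracked by the package) are rejected.
#'
#' @param x character vector of nuclide names in any supported form.
#' @return character vector of canonical names, e.g. `"Ra-226"`.
#' @examples
#' normalize_nuclide(c("226Ra", "Pb210", "u-238"))
#' @export
normalize_nuclide <- function(x) {
  stopifnot(is.character(x))
  x0 <- gsub("[[:space:]_]", "", x)
  # mass-first form: 226Ra
  m1 <- regmatches(x0, regexec("^([0-9]{1,3})-?([A-Za-z]{1,2})$", x0))
  # element-first form: Ra-226 or Ra226
  m2 <- regmatches(x0, regexec("^([A-Za-z]{1,2})-?([0-9]{1,3})$", x0))
  out <- vapply(seq_along(x0), function(i) {
    if (length(m2[[i]]) == 3) {
      el <- m2[[i]][2]; mass <- m2[[i]][3]
    } else if (length(m1[[i]]) == 3) {
      el <- m1[[i]][3]; mass <- m1[[i]][2]
    } else {
      stop("unparseable nuclide name: '", x[i], "'", call. = FALSE)
    }
    el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
    paste0(el, "-", mass)
  }, character(1))
  unknown <- setdiff(out, .nuclide_registry()$nuclide)
  if (length(unknown) > 0) {
    stop("unknown nuclide(s): ", paste(unknown, collapse = ", "),
         " (not in the U-238 / U-235 / Th-232 natural decay series)",
         call. = FALSE)
  }
  out
}

#' Decay series membership of a nuclide
#'
#' @param x character vector of nuclide names (any form accepted by
#'   [normalize_nuclide()]).
#' @return character vector: `"U-238"`, `"U-235"` or `"Th-232"`.
#' @examples
#' nuclide_series("Pa-231")
#' @export
nuclide_series <- function(x) {
  reg <- .nuclide_registry()
  reg$series[match(normalize_nuclide(x), reg$nuclide)]
}

#' Construct a nuclide vector (specific activities of a material)
#'
#' @param activities named numeric vector of specific activities \[Bq/kg\];
#'   names are nuclide identifiers in any form accepted by
#'   [normalize_nuclide()].
#' @param rel_uncertainty optional named numeric vector of relative
#'   uncertainties \[%\] for (a subset of) the same nuclides.
#' @param material_label free-text label of the material.
#' @return object of class `nuclide_vector`: list with `activities`
#'   (canonical names, Bq/kg), `rel_uncertainty` (\[%\], possibly empty) and
#'   `material_label`.
#' @examples
#' nuclide_vector(c("Ra-226" = 2317, "Pb-210" = 1098), material_label = "nodules")
#' @export
nuclide_vector <- function(activities, rel_uncertainty = NULL,
                           material_label = "") {
  stopifnot(is.numeric(activities))
  if (length(activities) > 0) {
    stopifnot(!is.null(names(activities)))
    names(activities) <- normalize_nuclide(names(activities))
  }
  if (anyDuplicated(names(activities))) {
    stop("duplicate nuclide in activity vector: ",
         paste(unique(names(activities)[duplicated(names(activities))]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(activities)) || any(activities < 0)) {
    stop("specific activities must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(rel_uncertainty) && length(rel_uncertainty) > 0) {
    stopifnot(is.numeric(rel_uncertainty), !is.null(names(rel_uncertainty)))
    names(rel_uncertainty) <- normalize_nuclide(names(rel_uncertainty))
    if (any(rel_uncertainty < 0)) {
      stop("relative uncertainties must be >= 0", call. = FALSE)
    }
    extra <- setdiff(names(rel_uncertainty), names(activities))
    if (length(extra) > 0) {
      stop("uncertainty given for nuclide(s) absent from the vector: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  } else {
    rel_uncertainty <- numeric(0)
  }
  structure(
    list(activities = activities,
         rel_uncertainty = rel_uncertainty,
         material_label = as.character(material_label)),
    class = "nuclide_vector"
  )
}

#' @export
print.nuclide_vector <- function(x, ...) {
  cat("<nuclide_vector>", if (nzchar(x$material_label)) x$material_label else "",
      "\n")
  df <- data.frame(
    nuclide = names(x$activities),
    activity_Bq_per_kg = unname(x$activities)
  )
  if (length(x$rel_uncertainty) > 0) {
    df$uncertainty_pct <- unname(x$rel_uncertainty[df$nuclide])
  }
  print(df, row.names = FALSE)
  invisible(x)
}

#' Specific activity of one nuclide in a vector
#'
#' @param v a [nuclide_vector()].
#' @param nuclide nuclide name (any accepted form).
#' @param default value returned when the nuclide is absent; the default
#'   `NULL` raises an error instead.
#' @return specific activity \[Bq/kg\].
#' @export
activity_of <- function(v, nuclide, default = NULL) {
  stopifnot(inherits(v, "nuclide_vector"))
  n <- normalize_nuclide(nuclide)
  if (!n %in% names(v$activities)) {
    if (is.null(default)) {
      stop("nuclide ", n, " not present in material '",
           v$material_label, "'", call. = FALSE)
    }
    return(default)
  }
  unname(v$activities[[n]])
}

#' Scale a nuclide vector by a non-negative factor
#'
#' Multiplies every specific activity by `k` (relative uncertainties are
#' unchanged: a deterministic rescaling leaves CVs invariant). Used for
#' flowsheet enrichment and the surface-layer sensitivity multiplier.
#'
#' @param v a [nuclide_vector()].
#' @param k scalar factor >= 0.
#' @param material_label optional new label.
#' @return a scaled [nuclide_vector()].
#' @export
scale_vector <- function(v, k, material_label = v$material_label) {
  stopifnot(inherits(v, "nuclide_vector"), is.numeric(k), length(k) == 1,
            is.finite(k), k >= 0)
  nuclide_vector(v$activities * k, v$rel_uncertainty, material_label)
}

.fixture_path <- function(name) {
  p <- system.file("extdata", paste0(name, ".csv"), package = "noduledose")
  if (!nzchar(p)) p <- name  # fall back to treating `name` as a path
  p
}

#' Load a nuclide vector from a CSV file or packaged fixture
#'
#' The file must have columns `nuclide`, `activity_Bq_per_kg` and optionally
#' `uncertainty_pct`. Packaged fixtures: `"nodules_bulk"` (bulk nodule
#' activities with measurement uncertainties), `"slag_3rd_reduction"` and
#' `"filter_dust"` (the enriched process streams of the pyrometallurgical
#' flowsheet, as used in the dose assessment).
#'
#' @param source path to a CSV file, or the name of a packaged fixture.
#' @return a [nuclide_vector()].
#' @examples
#' nodules <- load_nuclide_vector("nodules_bulk")
#' activity_of(nodules, "Ra-226")
#' @export
load_nuclide_vector <- function(source) {
  path <- if (file.exists(source)) source else .fixture_path(source)
  if (!file.exists(path)) {
    stop("no such file or packaged fixture: '", source, "'", call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("nuclide", "activity_Bq_per_kg")
  if (!all(need %in% names(df))) {
    stop("nuclide table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(nuclide_vector(numeric(0),
                          material_label = sub("\\.csv$", "", basename(path))))
  }
  acts <- stats::setNames(df$activity_Bq_per_kg, df$nuclide)
  unc <- NULL
  if ("uncertainty_pct" %in% names(df)) {
    keep <- !is.na(df$uncertainty_pct)
    if (any(keep)) unc <- stats::setNames(df$uncertainty_pct[keep], df$nuclide[keep])
  }
  label <- sub("\\.csv$", "", basename(path))
  nuclide_vector(acts, unc, material_label = label)
}

#' Construct an inhalation dose-coefficient table
#'
#' @param g_inh named numeric vector of inhalation dose coefficients
#'   \[uSv/Bq\].
#' @param absorption_class named character vector of lung absorption classes
#'   (`"F"` fast, `"M"` moderate, `"S"` slow) for the same nuclides.
#' @param amad_um activity median aerodynamic diameter the table is valid
#'   for \[um\]; 5 um for the packaged occupational table.
#' @return object of class `dose_coefficients`.
#' @export
dose_coefficients <- function(g_inh, absorption_class = NULL, amad_um = 5) {
  stopifnot(is.numeric(g_inh), !is.null(names(g_inh)))
  names(g_inh) <- normalize_nuclide(names(g_inh))
  if (any(g_inh <= 0)) stop("dose coefficients must be > 0", call. = FALSE)
  if (!is.null(absorption_class)) {
    names(absorption_class) <- normalize_nuclide(names(absorption_class))
    stopifnot(all(absorption_class %in% c("F", "M", "S")))
  } else {
    absorption_class <- character(0)
  }
  structure(
    list(g_inh = g_inh, absorption_class = absorption_class,
         amad_um = amad_um),
    class = "dose_coefficients"
  )
}

#' Load inhalation dose coefficients (packaged ICRP table by default)
#'
#' The packaged table holds the occupational inhalation dose coefficients
#' (AMAD 5 um) for the dose-relevant long-lived nuclides of the natural
#' decay series, i.e. all nuclides with a coefficient above 0.1 uSv/Bq.
#' S absorption classes are used for the thorium isotopes, F for Ac-227 and
#' M otherwise. Nuclides below the cutoff are simply absent and contribute
#' zero dose.
#'
#' @param source path to a CSV with columns `nuclide`, `g_inh_uSv_per_Bq`,
#'   optional `absorption_class`; `NULL` loads the packaged table.
#' @return a [dose_coefficients()] object.
#' @export
load_dose_coefficients <- function(source = NULL) {
  path <- if (is.null(source)) .fixture_path("dose_coefficients") else source
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("nuclide", "g_inh_uSv_per_Bq") %in% names(df)))
  ac <- if ("absorption_class" %in% names(df)) {
    stats::setNames(df$absorption_class, df$nuclide)
  } else NULL
  dose_coefficients(stats::setNames(df$g_inh_uSv_per_Bq, df$nuclide), ac)
}

#' Committed effective dose per unit mass of inhaled dust
#'
#' For a material with specific activities `C_i` \[Bq/kg\] and inhalation
#' dose coefficients `g_inh,i` \[uSv/Bq\], the unit dust dose is
#' `sum_i g_inh,i * C_i`, converted to activity per milligram of dust:
#' the committed effective dose incurred per milligram of the material
#' inhaled as dust \[uSv/mg\]. Nuclides without a tabulated coefficient
#' (below the 0.1 uSv/Bq cutoff) contribute zero; they are reported via a
#' message when `quiet = FALSE`.
#'
#' @param v a [nuclide_vector()].
#' @param dc a [dose_coefficients()] table.
#' @param quiet suppress the message listing skipped nuclides.
#' @return unit dust dose \[uSv/mg\], a non-negative scalar, linear in `v`.
#' @examples
#' unit_dust_dose(load_nuclide_vector("nodules_bulk"), load_dose_coefficients())
#' @export
unit_dust_dose <- function(v, dc = load_dose_coefficients(), quiet = TRUE) {
  stopifnot(inherits(v, "nuclide_vector"), inherits(dc, "dose_coefficients"))
  common <- intersect(names(v$activities), names(dc$g_inh))
  skipped <- setdiff(names(v$activities)[v$activities > 0], common)
  if (length(skipped) > 0 && !quiet) {
    message("no dose coefficient for: ", paste(skipped, collapse = ", "),
            " (contribute zero)")
  }
  sum(dc$g_inh[common] * v$activities[common]) * BQ_PER_KG_TO_BQ_PER_MG
}
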