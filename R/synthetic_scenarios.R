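#' @title Synthetic scenarios: uncertainty propagation by Monte Carlo
#' @description
#' The measured specific activities carry relative uncertainties of
#' 13-45%. This module emulates that variability: activities are drawn
#' from mean-preserving lognormal distributions (arithmetic mean equal to
#' the measured value, CV equal to the printed relative uncertainty), and
#' optionally scenario parameters and the surface-layer multiplier are
#' perturbed within bounded ranges. Because every pathway dose is linear
#' in the activities, mean-preserving sampling keeps the expected dose at
#' the deterministic central value; the spread quantifies how measurement
#' uncertainty propagates to the annual dose. This is forward uncertainty
#' propagation only — no calibration against measurements.
#' @name synthetic_scenarios
NULL

#' Specification of a Monte Carlo sampling experiment
#'
#' @param n_draws number of draws, >= 1.
#' @param seed integer seed; every random quantity in the experiment is
#'   derived from it (no dependence on, or pollution of, the caller's RNG
#'   state).
#' @param activity_model distribution family for activities; only
#'   `"lognormal"` is implemented (parameterised so the arithmetic mean is
#'   the measured value and the CV the printed relative uncertainty).
#' @param parameter_perturbations named list mapping a pathway parameter
#'   (`"t_exp"`, `"c_dust"`, `"shielding"`, `"f_inh"`) to a length-2 range;
#'   per draw, one uniform multiplier-free value is drawn in the range and
#'   assigned to that parameter in every pathway carrying it.
#' @param surface_multiplier_range length-2 well-ordered range for the
#'   surface-layer multiplier, drawn uniformly per draw; `c(1, 3)` spans
#'   the bulk-to-surface-layer activity ratio. Use `c(1, 1)` to hold it
#'   fixed.
#' @param common_mode_cv optional CV \[fraction\] of one shared lognormal
#'   multiplier applied to all nuclides of a draw, modelling correlated
#'   surface-layer enrichment; 0 (default) samples nuclides independently.
#' @return object of class `sampling_spec`.
#' @export
sampling_spec <- function(n_draws, seed, activity_model = "lognormal",
                          parameter_perturbations = list(),
                          surface_multiplier_range = c(1, 3),
                          common_mode_cv = 0) {
  stopifnot(is.numeric(n_draws), n_draws >= 1,
            is.numeric(seed), length(seed) == 1,
            identical(activity_model, "lognormal"),
            is.list(parameter_perturbations),
            is.numeric(surface_multiplier_range),
            length(surface_multiplier_range) == 2,
            is.numeric(common_mode_cv), common_mode_cv >= 0)
  if (diff(surface_multiplier_range) < 0) {
    stop("surface_multiplier_range must be well-ordered", call. = FALSE)
  }
  for (rng in parameter_perturbations) {
    stopifnot(is.numeric(rng), length(rng) == 2)
    if (diff(rng) < 0) stop("perturbation ranges must be well-ordered",
                            call. = FALSE)
  }
  structure(
    list(n_draws = as.integer(n_draws), seed = as.integer(seed),
         activity_model = activity_model,
         parameter_perturbations = parameter_perturbations,
         surface_multiplier_range = surface_multiplier_range,
         common_mode_cv = common_mode_cv),
    class = "sampling_spec"
  )
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Mean-preserving lognormal draws: E[X] = mean, CV[X] = cv.
.rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0 || mean == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

#' Sample synthetic nuclide vectors around a measured base vector
#'
#' Each nuclide's activity is drawn from a mean-preserving lognormal with
#' CV equal to its relative uncertainty; nuclides are independent unless a
#' common-mode multiplier is requested. Draws are reproducible under a
#' fixed seed and strictly positive.
#'
#' @param spec a [sampling_spec()].
#' @param base a [nuclide_vector()]; every sampled nuclide must have a
#'   relative uncertainty entry (use 0 for a degenerate, fixed nuclide).
#' @return list of `spec$n_draws` [nuclide_vector()]s.
#' @examples
#' sp <- sampling_spec(n_draws = 3, seed = 1)
#' draws <- sample_nuclide_vectors(sp, load_nuclide_vector("nodules_bulk"))
#' @export
sample_nuclide_vectors <- function(spec, base) {
  stopifnot(inherits(spec, "sampling_spec"),
            inherits(base, "nuclide_vector"))
  nucs <- names(base$activities)
  missing_u <- setdiff(nucs, names(base$rel_uncertainty))
  if (length(missing_u) > 0) {
    stop("no relative uncertainty for nuclide(s): ",
         paste(missing_u, collapse = ", "),
         " (give 0 to sample them as fixed)", call. = FALSE)
  }
  cvs <- base$rel_uncertainty[nucs] / 100
  .with_seed(spec$seed, {
    per_nuc <- vapply(nucs, function(n) {
      .rlnorm_mean_cv(spec$n_draws, base$activities[[n]], cvs[[n]])
    }, numeric(spec$n_draws))
    per_nuc <- matrix(per_nuc, nrow = spec$n_draws,
                      dimnames = list(NULL, nucs))
    if (spec$common_mode_cv > 0) {
      shared <- .rlnorm_mean_cv(spec$n_draws, 1, spec$common_mode_cv)
      per_nuc <- per_nuc * shared
    }
    lapply(seq_len(spec$n_draws), function(i) {
      nuclide_vector(per_nuc[i, ], base$rel_uncertainty,
                     base$material_label)
    })
  })
}

# Apply a drawn parameter value to every pathway entry carrying the field.
.perturb_scenario <- function(s, values) {
  for (field in names(values)) {
    for (i in seq_along(s$gamma)) {
      if (!is.null(s$gamma[[i]][[field]])) s$gamma[[i]][[field]] <- values[[field]]
    }
    for (i in seq_along(s$dust)) {
      if (!is.null(s$dust[[i]][[field]])) s$dust[[i]][[field]] <- values[[field]]
    }
  }
  s
}

#' Propagate sampling uncertainty through a scenario by Monte Carlo
#'
#' For each draw, every inventory material is replaced by a synthetic
#' vector sampled per [sample_nuclide_vectors()], the surface multiplier
#' and any perturbed parameters are drawn from their ranges, and the
#' scenario is run. Summaries (mean, sd, percentiles 5/50/95) are returned
#' for the gamma+dust subtotal, the radon dose and the total.
#'
#' @param spec a [sampling_spec()].
#' @param scenario a [scenario()].
#' @param inventory named list of [nuclide_vector()]s.
#' @param coefficients a [dose_coefficients()] table.
#' @param return_draws also return the per-draw dose data.frame.
#' @return object of class `mc_dose_summary`: `summary` data.frame
#'   (`quantity`, `mean`, `sd`, `q05`, `q50`, `q95` in mSv/a), `n_draws`,
#'   `seed`, and `draws` when requested.
#' @examples
#' sp <- sampling_spec(n_draws = 200, seed = 42,
#'                     surface_multiplier_range = c(1, 1))
#' monte_carlo_dose(sp, packaged_scenario("processing_plant"))
#' @export
monte_carlo_dose <- function(spec, scenario,
                             inventory = default_inventory(),
                             coefficients = load_dose_coefficients(),
                             return_draws = FALSE) {
  stopifnot(inherits(spec, "sampling_spec"), inherits(scenario, "scenario"))
  mats <- names(inventory)

  draws <- .with_seed(spec$seed, {
    # one sub-seed per material plus one for scenario-level draws,
    # all < 2^31
    sub_seeds <- sample.int(.Machine$integer.max - 1,
                            length(mats) + 1)
    sampled <- lapply(seq_along(mats), function(i) {
      sub <- sampling_spec(spec$n_draws, sub_seeds[i],
                           common_mode_cv = spec$common_mode_cv)
      sample_nuclide_vectors(sub, inventory[[mats[i]]])
    })
    names(sampled) <- mats

    set.seed(sub_seeds[length(sub_seeds)])
    mult <- stats::runif(spec$n_draws,
                         spec$surface_multiplier_range[1],
                         spec$surface_multiplier_range[2])
    perturbed <- lapply(names(spec$parameter_perturbations), function(f) {
      rng <- spec$parameter_perturbations[[f]]
      stats::runif(spec$n_draws, rng[1], rng[2])
    })
    names(perturbed) <- names(spec$parameter_perturbations)

    res <- vapply(seq_len(spec$n_draws), function(i) {
      inv_i <- lapply(sampled, `[[`, i)
      s_i <- scenario
      s_i$surface_multiplier <- mult[i]
      if (length(perturbed) > 0) {
        s_i <- .perturb_scenario(s_i, lapply(perturbed, `[[`, i))
      }
      r <- run_scenario(s_i, inv_i, coefficients)
      c(subtotal_excl_radon = r$subtotal_excl_radon,
        radon = r$radon_dose, total = r$total)
    }, numeric(3))
    as.data.frame(t(res))
  })

  summ <- do.call(rbind, lapply(names(draws), function(q) {
    x <- draws[[q]]
    data.frame(quantity = q, mean = mean(x), sd = stats::sd(x),
               q05 = unname(stats::quantile(x, 0.05)),
               q50 = unname(stats::quantile(x, 0.50)),
               q95 = unname(stats::quantile(x, 0.95)),
               stringsAsFactors = FALSE)
  }))

  structure(
    list(summary = summ, n_draws = spec$n_draws, seed = spec$seed,
         draws = if (return_draws) draws else NULL),
    class = "mc_dose_summary"
  )
}

#' @export
print.mc_dose_summary <- function(x, ...) {
  cat("<mc_dose_summary>", x$n_draws, "draws, seed", x$seed, "\n")
  df <- x$summary
  df[-1] <- lapply(df[-1], signif, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
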