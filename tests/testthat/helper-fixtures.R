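# Shared fixtures: packaged vectors plus the published activity tables,
# re-entered here independently of the CSV fixtures so loader bugs cannot
# silently cancel out.

nodules <- load_nuclide_vector("nodules_bulk")
slag <- load_nuclide_vector("slag_3rd_reduction")
filter_dust <- load_nuclide_vector("filter_dust")
coeffs <- load_dose_coefficients()

published_nodule_activities <- c(
  "U-238" = 55, "U-234" = 58, "Th-230" = 620, "Ra-226" = 2317,
  "Pb-210" = 1098, "Po-210" = 1042, "U-235" = 3, "Pa-231" = 22,
  "Ac-227" = 47, "Th-232" = 56, "Ra-228" = 58, "Th-228" = 60
)

published_slag_activities <- c(
  "U-238" = 120, "U-234" = 127, "Th-230" = 1363, "Ra-226" = 5098,
  "Pb-210" = 2415, "Po-210" = 2293, "U-235" = 6, "Pa-231" = 48,
  "Ac-227" = 104, "Th-232" = 123, "Ra-228" = 127, "Th-228" = 131
)

published_filter_dust_activities <- c("Pb-210" = 10975, "Po-210" = 10422)

published_g_inh <- c(
  "U-238" = 1.6, "U-234" = 2.1, "Th-230" = 28, "Ra-226" = 2.2,
  "Pb-210" = 1.1, "Po-210" = 2.2, "U-235" = 1.8, "Pa-231" = 89,
  "Ac-227" = 630, "Th-232" = 12, "Ra-228" = 1.7, "Th-228" = 22
)

# Independent brute-force oracle for the unit dust dose [uSv/mg]:
# termwise sum over the published tables, with the Bq/kg -> Bq/mg
# conversion written out.
oracle_unit_dust_dose <- function(acts) {
  total <- 0
  for (n in names(acts)) {
    if (n %in% names(published_g_inh)) {
      total <- total + published_g_inh[[n]] * acts[[n]] * 1e-6
    }
  }
  total
}

reference_rule <- partition_rule(dust_mass_rate = 0.297e6,
                                 slag_mass_rate = 1.374e6)
nodule_feed <- material_stream(3.0e6, nodules, "nodule feed")
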