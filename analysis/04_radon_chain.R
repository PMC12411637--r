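#!/usr/bin/env Rscript
# Step 4 — the radon physics chain.
#
# From material properties to workplace concentrations: diffusive
# exhalation from a thick dry nodule layer (~10 Bq/m2/s), accumulation in
# the cargo-hold head space under natural (1/h) and forced (24/h)
# ventilation, and the production-hall balance fed by the comminution
# source term (66 kBq/s, half released indoors). Also shows the transient
# approach to steady state after opening a sealed hold.

library(noduledose)

dir.create("results", showWarnings = FALSE)

props <- radon_material_props(c_ra226 = 2317)
P <- exhalation_rate(props)
cat(sprintf("exhalation rate (dry nodules): %.2f Bq/(m2 s)\n", P))
cat(sprintf("  (saturated nodules exhale about half: %.2f)\n", P / 2))

hold <- radon_environment(volume = 10 * 90 * 5, area = 10 * 90,
                          ventilation = 1)
e_hold <- entry_rate_surface(P, hold)
cat(sprintf("cargo-hold entry rate: %.2f Bq/(m3 s)\n", e_hold))

rows <- data.frame(
  setting = c("cargo hold, natural ventilation 1/h",
              "cargo hold, opened/ventilated 24/h",
              "cargo hold, sealed (v = 0)"),
  concentration_Bq_m3 = c(
    steady_state_concentration(e_hold, hold),
    steady_state_concentration(e_hold,
                               radon_environment(4500, 900, 24)),
    steady_state_concentration(e_hold,
                               radon_environment(4500, 900, 0))
  )
)

hall <- radon_environment(volume = 30 * 100 * 15, area = 30 * 100,
                          ventilation = 10)
cm <- entry_rate_comminution(load_nuclide_vector("nodules_bulk"),
                             comminution_source(pc = 95), hall)
cat(sprintf("comminution source term: %.1f kBq/s, hall entry rate %.3f Bq/(m3 s)\n",
            cm$R_source / 1000, cm$e_prime))
rows <- rbind(rows, data.frame(
  setting = "production hall, 10/h, half of source indoors",
  concentration_Bq_m3 = steady_state_concentration(cm$e_prime, hall)))

rows$concentration_Bq_m3 <- round(rows$concentration_Bq_m3)
print(rows, row.names = FALSE)

# transient: how fast does an opened hold clear?
vented <- radon_environment(4500, 900, 24)
t_min <- c(0, 1, 2, 5, 10, 20, 30)
trans <- data.frame(
  t_min = t_min,
  concentration_Bq_m3 = round(transient_concentration(
    e_hold, vented, c0 = steady_state_concentration(e_hold, hold),
    t = t_min * 60))
)
cat("\nclear-out of the hold after switching to 24/h ventilation:\n")
print(trans, row.names = FALSE)

# dose at the reference concentration
cat(sprintf("\nradon dose at 300 Bq/m3, 2000 h, F = 0.4: %.2f mSv/a\n",
            radon_dose(radon_dose_config(300, 2000))))

write.csv(rows, "results/radon_concentrations.csv", row.names = FALSE)
write.csv(trans, "results/radon_transient.csv", row.names = FALSE)
cat("Wrote results/radon_concentrations.csv and results/radon_transient.csv\n")
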