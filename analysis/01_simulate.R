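#!/usr/bin/env Rscript
# Stage 1: generate the synthetic inputs for the whole analysis.
#
# Two artifacts are produced:
#   (a) a GPP-like long table at the desk-scale study conditions (16 x 16
#       pixels, twice-monthly composites 2020-2022, a -0.247 gC/m2 step at
#       2022-02-24 on top of seasonal + spatial structure with AR(1) noise);
#   (b) monthly shipping route-density rasters for Jan 2021 - Aug 2022 with
#       port activity in 2022 scaled down at Odesa and Mariupol and up at the
#       Danube delta, plus a February-June blackout at Mariupol.
# Summaries go to results/; later stages regenerate the full data from the
# same seeds, so nothing large needs to be stored.

suppressMessages(library(cropgam))
suppressMessages(library(dplyr))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config()            # the package's default study conditions
sim <- simulate_gpp(cfg)
cat(sprintf("GPP scene: %d rows, %d pixels, %d dates; injected step %.3f at %s\n",
            nrow(sim$table), nrow(sim$truth$pixels),
            length(unique(sim$table$date)), cfg$delta, cfg$cutoff))

monthly <- sim$table |>
  group_by(year, month) |>
  summarise(mean_gpp = mean(gpp), n = dplyr::n(), .groups = "drop")
readr::write_csv(monthly, "results/sim_gpp_monthly_means.csv")
cat("wrote results/sim_gpp_monthly_means.csv\n")

months <- seq(as.Date("2021-01-01"), as.Date("2022-08-01"), by = "month")
ports <- rbind(black_sea_ports(), port_zone("Danube", 29.75, 45.25))
year_scale <- data.frame(name = c("Odesa", "Mariupol", "Danube"),
                         year = 2022, scale = c(0.55, 0.38, 1.70))
blackout <- data.frame(name = "Mariupol",
                       from = "2022-02-01", to = "2022-06-30")
stack <- simulate_shipping(months, ports, year_scale = year_scale,
                           blackout = blackout)
ship <- monthly_series(stack, ports)
readr::write_csv(ship, "results/shipping_monthly_density.csv")
cat(sprintf("shipping stack: %d monthly layers, %d x %d cells; %d extracted rows\n",
            length(stack$layers), stack$nrow, stack$ncol, nrow(ship)))
cat("wrote results/shipping_monthly_density.csv\n")
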