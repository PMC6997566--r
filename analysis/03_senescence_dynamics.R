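#!/usr/bin/env Rscript
# Senescence dynamics parameterization: thermal time from the hourly
# temperature record, PSRI and NDVI time series per plot, min-max scaling
# and orientation, linear-interpolation threshold extraction for all
# sources, plus a Gompertz fit of the visual scorings.
#
# Outputs: results/thermal_calendar.csv, results/indices.csv,
#          results/dynamics.csv (linear), results/dynamics_gompertz.csv

suppressPackageStartupMessages({
  library(senodyn)
  library(data.table)
})

temps <- read_temperature_csv("results/simulated/temperatures.csv")
calendar <- accumulate_gdd(temps)
print(calendar)
write_thermal_calendar(calendar, "results/thermal_calendar.csv")

metadata <- fread("results/simulated/metadata.csv")
scorings <- fread("results/simulated/scorings.csv")
spectra <- trim_to_windows(average_replicates(
  read_spectra("results/simulated/spectra.csv", layout = "wide")))

reg <- index_registry()
idx <- rbind(compute_index_series(spectra, reg$PSRI),
             compute_index_series(spectra, reg$NDVI))
fwrite(idx[, .(plot_id, date = as.character(date), index_name, value)],
       "results/indices.csv")

series <- rbind(
  scorings[, .(plot_id, date, value = as.numeric(score), source = "scoring")],
  idx[, .(plot_id, date, value, source = index_name)]
)
orient <- c(PSRI = reg$PSRI$orientation, NDVI = reg$NDVI$orientation)

dyn_lin <- derive_dynamics(series, metadata, calendar, orient,
                           method = "linear")
fwrite(dyn_lin$parameters, "results/dynamics.csv")
cat("linear dynamics:", nrow(dyn_lin$parameters), "parameter sets,",
    nrow(dyn_lin$excluded), "excluded\n")

dyn_gom <- derive_dynamics(series[source == "scoring"], metadata, calendar,
                           orient, method = "gompertz")
fwrite(dyn_gom$parameters, "results/dynamics_gompertz.csv")

summ <- dyn_lin$parameters[status == "ok",
  .(on = mean(on_sen_Cd), mid = mean(mid_sen_Cd),
    end = mean(end_sen_Cd), t_sen = mean(t_sen_Cd), n = .N),
  by = source]
cat("\nMean dynamics parameters (degC days after heading) by source:\n")
print(summ, digits = 4)
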