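#!/usr/bin/env Rscript
# Spectral pre-processing and the reflectance-senescence correlogram.
# Reads the simulated trial from results/simulated/, averages replicate
# records, trims to the VIS/NIR/SWIR windows outside the atmospheric
# water bands, and correlates reflectance at every wavelength with the
# visual senescence degree, overall and per senescence phase.
#
# Outputs: results/correlogram.csv, results/correlogram_phases.csv

suppressPackageStartupMessages({
  library(senodyn)
  library(data.table)
})

spectra_full <- average_replicates(
  read_spectra("results/simulated/spectra.csv", layout = "wide"))
scorings <- fread("results/simulated/scorings.csv")
print(spectra_full)

spectra <- trim_to_windows(spectra_full)
cat("after trimming:", length(spectra$wavelength), "bands retained\n")

cg <- wavelength_correlogram(spectra, scorings)
fwrite(cg, "results/correlogram.csv")

win_summary <- rbind(
  cg[wavelength >= 450 & wavelength <= 680,
     .(window = "VIS 450-680", r_min = min(r), r_max = max(r))],
  cg[wavelength >= 760 & wavelength <= 1300,
     .(window = "NIR 760-1300", r_min = min(r), r_max = max(r))],
  cg[wavelength >= 2000 & wavelength <= 2400,
     .(window = "SWIR 2000-2400", r_min = min(r), r_max = max(r))]
)
cat("\nCorrelation of reflectance with senescence degree by window:\n")
print(win_summary, digits = 3)
sub <- cg[wavelength >= 700 & wavelength <= 1300]
cat("strongest negative response at", sub$wavelength[which.min(sub$r)],
    "nm (red-edge shoulder)\n")

# phase-stratified correlograms (late / intermediate / early senescence)
phases <- wavelength_correlogram(
  spectra, scorings,
  phase_bins = list(late = c(0, 3), intermediate = c(4, 7), early = c(8, 10))
)
fwrite(phases, "results/correlogram_phases.csv")
cat("\nPhase-stratified correlogram written;",
    "per-phase r at 678 nm:\n")
print(phases[wavelength == 678, .(bin, r = round(r, 3), n)])

# derivative and continuum-removed variants are available for
# full-spectrum modelling; both need the untrimmed regular grid
deriv <- first_derivative(spectra_full)
cr <- continuum_removal(spectra_full)
cat("\nfirst derivative: mean |dR/dlambda| =",
    signif(mean(abs(deriv$reflectance)), 3), "per nm\n")
cat("continuum removal: value range",
    paste(signif(range(cr$reflectance), 3), collapse = " .. "), "\n")
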