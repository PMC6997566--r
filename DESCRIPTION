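Package: senodyn
Title: Senescence Dynamics of Wheat Canopies from Hyperspectral Reflectance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Index-based parameterization of wheat canopy senescence dynamics
    from plot-level hyperspectral reflectance time series. Converts hourly
    temperature records to growing degree-days, processes field
    spectroradiometer spectra (averaging, window trimming, derivatives,
    continuum removal, standardization), evaluates spectral vegetation
    indices (PSRI, NDVI and others) via a band-math registry, fits visual
    greenness scorings and scaled index time courses against thermal time
    with linear interpolation and a Gompertz model, and extracts onset,
    midpoint, end and duration of senescence. Includes evaluation tools
    (bias, area-between-curves error, per-wavelength correlograms, band
    sweeps, trait correlations, resampled recursive feature elimination)
    and a synthetic-trial generator with retained ground truth for
    method-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    minpack.lm,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
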