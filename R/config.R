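#' Analysis configuration
#'
#' Bundles the acquisition and analysis constants used across the pipeline.
#' Defaults reflect a 60 Hz driver, the conventional muscle tissue density of
#' 1000 kg/m3, a symmetric 5% ROI trim for stiffness-map statistics, and a
#' 50 mm upper wavelength cutoff beyond which a fitted wavelength is treated
#' as an artefact.
#'
#' @param frequency_hz driver vibration frequency, Hz.
#' @param density_kg_m3 assumed tissue density, kg/m3.
#' @param trim_fraction symmetric trim fraction per tail for stiffness-map
#'   ROI means, in `[0, 0.5)`.
#' @param max_wavelength_mm upper wavelength cutoff, mm.
#' @param signal_floor_fraction PDFF denominator floor, as a fraction of the
#'   Dixon signal scale.
#' @param min_valid_phases minimum number of per-phase wavelength estimates
#'   required before a per-muscle mean wavelength is reported.
#' @param alpha significance level for normality gates and tests.
#' @return A list of class `mre_config`.
#' @export
mre_config <- function(frequency_hz = 60, density_kg_m3 = 1000,
                       trim_fraction = 0.05, max_wavelength_mm = 50,
                       signal_floor_fraction = 0.01, min_valid_phases = 4,
                       alpha = 0.05) {
  stopifnot(frequency_hz > 0, density_kg_m3 > 0,
            trim_fraction >= 0, trim_fraction < 0.5,
            max_wavelength_mm > 0, signal_floor_fraction >= 0,
            min_valid_phases >= 1, alpha > 0, alpha < 1)
  structure(list(frequency_hz = frequency_hz, density_kg_m3 = density_kg_m3,
                 trim_fraction = trim_fraction,
                 max_wavelength_mm = max_wavelength_mm,
                 signal_floor_fraction = signal_floor_fraction,
                 min_valid_phases = min_valid_phases, alpha = alpha),
            class = "mre_config")
}

#' Read a configuration file (YAML)
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path YAML file whose keys are the arguments of [mre_config].
#' @return An `mre_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: no such file: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(mre_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(mre_config, vals)
}
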