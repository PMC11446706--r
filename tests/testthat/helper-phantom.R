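# Small, fast phantom specifications shared across tests.

# One z-aligned cylindrical muscle on the anisotropic sagittal grid.
# Clean (noise/outlier-free) by default; override any phantom_spec argument.
tiny_spec <- function(stiffness_kpa = 3.24, pdff = 0.35, ...) {
  args <- utils::modifyList(
    list(shape = c(8, 32, 96), spacing = c(10, 1.5, 1.5),
         compartments = list(
           muscle_compartment("m1", center = c(40, 24, 72), radius = 14,
                              length = 120, pdff = pdff,
                              stiffness_kpa = stiffness_kpa)),
         dixon_noise_sd = 0, wave_noise_sd = 0, oblique_fraction = 0,
         outlier_fraction = 0, invalid_fraction = 0, vendor_noise_sd_kpa = 0),
    list(...))
  do.call(phantom_spec, args)
}

# Three separated muscles with distinct ground truths.
multi_spec <- function(stiffness_kpa = c(1.44, 3.24, 5.76),
                       pdff = c(0.05, 0.35, 0.6), length = 180, ...) {
  comps <- list(
    muscle_compartment("m1", center = c(55, 16, 108), radius = 14,
                       length = length, pdff = pdff[1],
                       stiffness_kpa = stiffness_kpa[1]),
    muscle_compartment("m2", center = c(55, 48, 108), radius = 14,
                       length = length, pdff = pdff[2],
                       stiffness_kpa = stiffness_kpa[2]),
    muscle_compartment("m3", center = c(55, 80, 108), radius = 14,
                       length = length, pdff = pdff[3],
                       stiffness_kpa = stiffness_kpa[3]))
  args <- utils::modifyList(
    list(shape = c(12, 64, 144), spacing = c(10, 1.5, 1.5),
         compartments = comps,
         dixon_noise_sd = 0, wave_noise_sd = 0, oblique_fraction = 0,
         outlier_fraction = 0, invalid_fraction = 0,
         vendor_noise_sd_kpa = 0),
    list(...))
  do.call(phantom_spec, args)
}

# Measurement-table fixture: n subjects, two sessions, one muscle/metric.
two_session_table <- function(baseline, week1, metric = "stiffness_kPa",
                              muscle = "m1", side = "left",
                              group = "control") {
  n <- length(baseline)
  measurement_table(data.frame(
    subject_id = rep(sprintf("S%02d", seq_len(n)), 2),
    group = group,
    session = rep(c("baseline", "week1"), each = n),
    muscle = muscle, side = side, metric = metric,
    value = c(baseline, week1)))
}
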