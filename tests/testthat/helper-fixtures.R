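# Shared fixture builders.  Published summary tables live in inst/extdata.

published <- function(name) {
  utils::read.csv(system.file("extdata", paste0("published_", name, ".csv"),
                              package = "dmpkr"),
                  stringsAsFactors = FALSE)
}

# Noise-free mono-exponential IV profile on a dense grid.
dense_iv_profile <- function(dose = 2, v = 1, ke = 0.5, t_max = 40, dt = 0.01) {
  times <- seq(0, t_max, by = dt)
  conc_time_profile("iv1", times,
                    one_compartment_conc(times, dose, ke, v, route = "iv"),
                    dose = dose, route = "iv")
}

# Stub NCA-like records for computations that only need group summary values.
nca_stub <- function(dose, auc_0t = NA, cmax = NA, auc_0inf = NA,
                     subject_id = "grp") {
  list(subject_id = subject_id, dose = dose, auc_0t = auc_0t,
       cmax = cmax, auc_0inf = auc_0inf)
}
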