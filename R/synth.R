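#' One-compartment concentration-time model
#'
#' Closed-form single-dose concentrations in ug/L.  Oral:
#' C(t) = F*D*ka / (V*(ka - ke)) * (exp(-ke t) - exp(-ka t)); when ka = ke
#' the limiting form F*D*ka*t*exp(-ka t)/V is used.  IV bolus:
#' C(t) = (D/V) * exp(-ke t).  Dose in mg/kg and V in L/kg give mg/L,
#' converted to ug/L.
#'
#' @param times Times in hours.
#' @param dose Dose, mg/kg.
#' @param ke Elimination rate constant, 1/h.
#' @param v Volume of distribution, L/kg.
#' @param ka Absorption rate constant, 1/h (oral only).
#' @param f Bioavailable fraction (oral only).
#' @param route `"oral"` or `"iv"`.
#' @return Concentrations in ug/L.
#' @export
one_compartment_conc <- function(times, dose, ke, v, ka = NA_real_, f = 1,
                                 route = c("oral", "iv")) {
  route <- match.arg(route)
  if (ke <= 0 || v <= 0 || dose <= 0) stop("rates, volume and dose must be > 0", call. = FALSE)
  if (route == "iv") {
    conc <- dose / v * exp(-ke * times)
  } else {
    if (is.na(ka) || ka <= 0) stop("oral model needs ka > 0", call. = FALSE)
    if (isTRUE(all.equal(ka, ke))) {
      conc <- f * dose * ka * times * exp(-ka * times) / v
    } else {
      conc <- f * dose * ka / (v * (ka - ke)) * (exp(-ke * times) - exp(-ka * times))
    }
  }
  1000 * conc
}

# Mean-preserving multiplicative log-normal noise with coefficient of
# variation cv (bioanalytical convention).
lognormal_noise <- function(x, cv) {
  if (cv <= 0) return(x)
  sdlog <- sqrt(log(1 + cv^2))
  x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate concentration-time profiles
#'
#' One-compartment kinetics with first-order absorption, optional repeated
#' dosing by superposition, log-normal between-subject variability on ke and
#' V, and log-normal residual noise.  Deterministic under a fixed seed.
#'
#' @param model `"oral_1cmt"`, `"iv_1cmt"` or `"multidose_1cmt"`.
#' @param n_subjects Number of subjects.
#' @param dose Dose, mg/kg.
#' @param ka,ke Absorption/elimination rate constants, 1/h.
#' @param v Volume of distribution, L/kg.
#' @param f Bioavailable fraction.
#' @param tau Dosing interval in hours (multidose).
#' @param n_doses Number of doses (multidose).
#' @param times Sampling times in hours (from the first dose).
#' @param noise_cv Residual CV (0 disables).
#' @param between_cv Between-subject CV on ke and v (0 disables).
#' @param species,matrix,loq Profile metadata.
#' @param seed RNG seed (set when not `NULL`).
#' @return List of [conc_time_profile()]s, one per subject.
#' @export
simulate_pk <- function(model = c("oral_1cmt", "iv_1cmt", "multidose_1cmt"),
                        n_subjects = 1, dose = 2, ka = 2, ke = 0.18, v = 8,
                        f = 1, tau = 12, n_doses = 1,
                        times = c(0, 0.083, 0.25, 0.5, 0.75, 1, 2, 4, 6, 8, 12, 24),
                        noise_cv = 0, between_cv = 0,
                        species = "dog", matrix = "plasma", loq = 0,
                        seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (noise_cv < 0 || between_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  route <- if (model == "iv_1cmt") "iv" else "oral"
  lapply(seq_len(n_subjects), function(i) {
    ke_i <- if (between_cv > 0) lognormal_noise(ke, between_cv) else ke
    v_i <- if (between_cv > 0) lognormal_noise(v, between_cv) else v
    conc <- if (model == "multidose_1cmt") {
      out <- numeric(length(times))
      for (d in seq_len(n_doses)) {
        t_rel <- times - (d - 1) * tau
        on <- t_rel >= 0
        out[on] <- out[on] + one_compartment_conc(t_rel[on], dose, ke_i, v_i,
                                                  ka = ka, f = f, route = "oral")
      }
      out
    } else {
      one_compartment_conc(times, dose, ke_i, v_i, ka = ka, f = f, route = route)
    }
    conc <- lognormal_noise(conc, noise_cv)
    conc[times == 0 & route == "oral"] <- 0
    conc_time_profile(sprintf("sim%02d", i), times, conc, dose = dose,
                      route = route, species = species, matrix = matrix,
                      tau = if (model == "multidose_1cmt") tau else NA_real_,
                      loq = loq)
  })
}

#' Simulate a microsomal depletion series
#'
#' remaining(t) = 100 * exp(-ke t), optionally plateauing after
#' `plateau_after` minutes (emulating saturating depletion kinetics), with
#' log-normal replicate noise.
#'
#' @param species Microsome species.
#' @param ke True depletion rate constant, 1/min (0 gives a flat series).
#' @param times Incubation times in minutes.
#' @param n_replicates Replicate incubations.
#' @param noise_cv Residual CV.
#' @param plateau_after Time (min) after which remaining stays at its value
#'   at that time, or `NULL` for log-linear throughout.
#' @param seed RNG seed.
#' @return A [depletion_series()].
#' @export
simulate_depletion <- function(species = "human", ke = 0.00278,
                               times = c(0, 2, 5, 10, 15, 30, 60, 90, 120),
                               n_replicates = 3, noise_cv = 0,
                               plateau_after = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (ke < 0) stop("ke must be >= 0", call. = FALSE)
  remaining <- 100 * exp(-ke * times)
  if (!is.null(plateau_after)) {
    floor_val <- 100 * exp(-ke * plateau_after)
    remaining[times > plateau_after] <- floor_val
  }
  mat <- vapply(seq_len(n_replicates),
                function(i) lognormal_noise(remaining, noise_cv),
                numeric(length(times)))
  depletion_series(species, times, mat)
}

#' Simulate a paired bidirectional transport experiment
#'
#' Linear receiver flux dQ/dt = Papp * A * C0 under sink conditions, with
#' the B-to-A permeability `efflux_factor` times the A-to-B one.  The
#' emitted receiver concentrations include the sampling-and-replacement
#' bookkeeping (each aliquot replaced by blank buffer), so the corrected
#' cumulative-amount analysis inverts the generator exactly at zero noise.
#' `inhibitor` mode sets the efflux factor to 1 and raises the A-to-B
#' permeability to the direction average, mimicking efflux blockade.
#'
#' @param papp_ab True A-to-B permeability, cm/s.
#' @param efflux_factor Ratio of B-to-A over A-to-B permeability.
#' @param c0 Donor concentration, ug/mL.
#' @param times Sampling times, minutes.
#' @param area Monolayer area, cm^2.
#' @param receiver_volume,sample_volume Volumes, uL.
#' @param noise_cv Residual CV on emitted concentrations.
#' @param inhibitor Inhibitor name or `NA`; when set, efflux is abolished.
#' @param seed RNG seed.
#' @return A list with elements `ab` and `ba`, each a
#'   [transport_experiment()].
#' @export
simulate_transport <- function(papp_ab = 1e-5, efflux_factor = 1.9, c0 = 1,
                               times = c(15, 30, 45, 60, 90, 120),
                               area = 0.33, receiver_volume = 1200,
                               sample_volume = 50, noise_cv = 0,
                               inhibitor = NA_character_, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (papp_ab <= 0 || efflux_factor <= 0) stop("permeabilities must be > 0", call. = FALSE)
  if (!is.na(inhibitor)) {
    papp_ab <- papp_ab * (1 + efflux_factor) / 2
    efflux_factor <- 1
  }
  emit <- function(papp, direction, recv_ul) {
    q_true <- papp * area * c0 * times * 60  # ug
    vr <- recv_ul / 1000; vs <- sample_volume / 1000
    conc <- numeric(length(times))
    removed <- 0
    for (i in seq_along(times)) {
      conc[i] <- (q_true[i] - removed) / vr
      removed <- removed + conc[i] * vs
    }
    conc <- lognormal_noise(conc, noise_cv)
    transport_experiment(direction, c0, times, conc, area = area,
                         receiver_volume = recv_ul,
                         sample_volume = sample_volume, inhibitor = inhibitor)
  }
  list(ab = emit(papp_ab, "AtoB", receiver_volume),
       ba = emit(papp_ab * efflux_factor, "BtoA", receiver_volume))
}

#' Simulate a cocktail-inhibition series
#'
#' Logistic activity = bottom + (top - bottom)/(1 + (I/IC50)^hill) with
#' log-normal replicate noise.
#'
#' @param isoform Isoform label.
#' @param ic50 True IC50, umol/L.
#' @param hill Hill coefficient.
#' @param conc Inhibitor concentrations, umol/L.
#' @param top,bottom Activity asymptotes, %.
#' @param n_replicates Replicates per concentration.
#' @param noise_cv Residual CV.
#' @param seed RNG seed.
#' @return An [inhibition_series()].
#' @export
simulate_inhibition <- function(isoform = "3A4", ic50 = 25, hill = 1,
                                conc = c(0.1, 1, 10, 50, 100),
                                top = 100, bottom = 0, n_replicates = 3,
                                noise_cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  activity <- bottom + (top - bottom) / (1 + (conc / ic50)^hill)
  mat <- vapply(seq_len(n_replicates),
                function(i) lognormal_noise(activity, noise_cv),
                numeric(length(conc)))
  inhibition_series(isoform, conc, mat)
}

#' Simulate a composite tissue-distribution panel
#'
#' Blood follows a one-compartment oral profile; each tissue is a
#' partition-coefficient (Kp) scaled oral profile whose absorption rate is
#' solved so that its peak falls at the requested tissue Tmax.  Sampling is
#' the composite (destructive) design: one mean concentration per matrix per
#' time point.
#'
#' @param kp Named vector of tissue-to-blood partition coefficients.
#' @param times Sampling times, hours.
#' @param dose Dose, mg/kg.
#' @param ka,ke,v,f Blood-profile parameters (see [one_compartment_conc()]).
#' @param tissue_tmax Peak time imposed on every tissue, hours (`NULL` keeps
#'   the blood kinetics).
#' @param noise_cv Residual CV.
#' @param seed RNG seed.
#' @return A [tissue_panel()].
#' @export
simulate_tissue <- function(kp = c(brain = 23, liver = 80, lung = 150),
                            times = c(0.25, 2, 6, 24), dose = 20,
                            ka = 2, ke = 0.25, v = 8, f = 0.8,
                            tissue_tmax = 2, noise_cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ka_for_tmax <- function(tmax) {
    # tmax = log(ka/ke)/(ka - ke); solve for ka
    stats::uniroot(function(k) log(k / ke) / (k - ke) - tmax,
                   interval = c(ke * 1.0001, 1000), tol = 1e-10)$root
  }
  blood <- one_compartment_conc(times, dose, ke, v, ka = ka, f = f, route = "oral")
  ka_t <- if (is.null(tissue_tmax)) ka else ka_for_tmax(tissue_tmax)
  tissue_shape <- one_compartment_conc(times, dose, ke, v, ka = ka_t, f = f,
                                       route = "oral")
  conc <- cbind(blood = blood,
                vapply(kp, function(k) k * tissue_shape, numeric(length(times))))
  conc <- apply(conc, 2, lognormal_noise, cv = noise_cv)
  tissue_panel(times, conc, n_per_timepoint = 6)
}

#' Simulate excretion records with programmed route fractions
#'
#' Splits programmed per-route cumulative recoveries (% of dose) across the
#' standard collection intervals and emits per-interval records whose
#' concentration, matrix volume and dilution factor reproduce those
#' fractions exactly through [interval_pct_dose()] at zero noise.
#'
#' @param route_fractions Named vector: final cumulative % of dose per route.
#' @param interval_weights Relative weights splitting each route total
#'   across the intervals (normalized internally).
#' @param intervals List of `c(start, end)` pairs in hours.
#' @param dose_mg_per_kg,body_weight_kg Dosing of the simulated animal.
#' @param feces_dilution Homogenate dilution factor for feces.
#' @param noise_cv Residual CV on concentrations.
#' @param seed RNG seed.
#' @return A list of [excretion_record()]s with attributes `dose_mg_per_kg`
#'   and `body_weight_kg`.
#' @export
simulate_excretion <- function(route_fractions = c(feces = 0.382, urine = 0.292,
                                                   bile = 0.436),
                               interval_weights = c(0.1, 0.4, 0.3, 0.15, 0.05),
                               intervals = list(c(0, 5), c(5, 12), c(12, 24),
                                                c(24, 48), c(48, 72)),
                               dose_mg_per_kg = 20, body_weight_kg = 0.2,
                               feces_dilution = 10, noise_cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- interval_weights / sum(interval_weights)
  dose_ug <- dose_mg_per_kg * body_weight_kg * 1000
  records <- list()
  for (route in names(route_fractions)) {
    dil <- if (route == "feces") feces_dilution else 1
    for (i in seq_along(intervals)) {
      pct <- route_fractions[[route]] * w[i]
      amount_ug <- pct / 100 * dose_ug
      vol <- 2 + 2 * i  # plausible collection volumes, mL
      conc <- lognormal_noise(amount_ug / (vol * dil), noise_cv)
      records[[length(records) + 1]] <- excretion_record(
        route, intervals[[i]], matrix_amount = vol, conc = conc,
        dilution_factor = if (route == "feces") dil else NULL
      )
    }
  }
  attr(records, "dose_mg_per_kg") <- dose_mg_per_kg
  attr(records, "body_weight_kg") <- body_weight_kg
  records
}
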