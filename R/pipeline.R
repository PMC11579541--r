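#' Run a full assay analysis from a configuration
#'
#' Dispatches one assay analysis from a configuration list (or a YAML file
#' path) to the corresponding module and returns an [analysis_report()].
#' Supported assays and the configuration keys they read:
#'
#' * `stability` — `files$stability` (CSV: species, replicate, time_min,
#'   remaining), optional `species` filter, `half_life_constant`.
#' * `nca` — `files$profiles` (long profile CSV, see [read_profiles()]),
#'   optional `method` (trapezoid flavor).
#' * `transport` — `files$transport` (CSV: direction, c0, area_cm2,
#'   receiver_ul, sample_ul, time_min, conc, optional inhibitor),
#'   optional `correct_sampling`.
#' * `ppb` — `files$ppb` (CSV: species, nominal_conc, ct, cf).
#' * `ic50` — `files$inhibition` (CSV: isoform, inhibitor_conc, replicate,
#'   activity_pct).
#' * `excretion` — `files$excretion` (CSV: route, t_start_h, t_end_h,
#'   matrix_amount_ml, conc, dilution_factor), `dose_mg_per_kg`,
#'   `body_weight_kg`.
#'
#' @param config A named list with at least `assay` and `files`, or a path
#'   to a YAML file holding one.
#' @return An [analysis_report()].
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$assay)) stop("config must name an assay", call. = FALSE)
  switch(config$assay,
    stability = analyze_stability(config),
    nca       = analyze_nca(config),
    transport = analyze_transport(config),
    ppb       = analyze_ppb(config),
    ic50      = analyze_ic50(config),
    excretion = analyze_excretion(config),
    stop("unknown assay: ", config$assay, call. = FALSE)
  )
}

param_row <- function(name, value, units, flags = "") {
  data.frame(name = name, value = value, units = units, flags = flags,
             stringsAsFactors = FALSE)
}

analyze_stability <- function(config) {
  path <- config$files$stability
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  species_set <- config$species %||% unique(df$species)
  hl_const <- config$half_life_constant %||% 0.693
  rows <- list()
  for (sp in species_set) {
    g <- df[df$species == sp, ]
    wide <- stats::reshape(g[, c("replicate", "time_min", "remaining")],
                           idvar = "time_min", timevar = "replicate",
                           direction = "wide")
    wide <- wide[order(wide$time_min), ]
    series <- depletion_series(sp, wide$time_min,
                               as.matrix(wide[, -1, drop = FALSE]))
    res <- microsomal_stability(series, half_life_constant = hl_const)
    stable_flag <- if (res$stable) "stable" else ""
    rows[[sp]] <- rbind(
      param_row(paste0(sp, ".t_half"), res$t_half_mean, "min", stable_flag),
      param_row(paste0(sp, ".ke"), res$ke_mean, "1/min"),
      param_row(paste0(sp, ".cl_int"), res$cl_int_mean, "mL/min/kg"),
      param_row(paste0(sp, ".cl_h"), res$cl_h_mean, "mL/min/kg")
    )
  }
  analysis_report("stability", do.call(rbind, rows),
                  files = path, config = config)
}

analyze_nca <- function(config) {
  path <- config$files$profiles
  profiles <- read_profiles(path)
  method <- config$method %||% "linear"
  results <- lapply(profiles, single_dose_nca, method = method)
  fields <- c(auc_0t = "ug/L*h", auc_0inf = "ug/L*h", mrt_0t = "h",
              mrt_0inf = "h", t_half_z = "h", tmax = "h",
              cl_f = "L/h/kg", vz_f = "L/kg", cmax = "ug/L")
  rows <- lapply(names(fields), function(f) {
    vals <- vapply(results, function(r) as.numeric(r[[f]]), numeric(1))
    extrap <- any(vapply(results, function(r) isTRUE(r$flags$high_extrapolation),
                         logical(1)))
    param_row(f, mean(vals, na.rm = TRUE), fields[[f]],
              if (f %in% c("auc_0inf", "mrt_0inf") && extrap) "high_extrapolation" else "")
  })
  analysis_report("nca", do.call(rbind, rows), files = path, config = config)
}

analyze_transport <- function(config) {
  path <- config$files$transport
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"inhibitor" %in% names(df)) df$inhibitor <- NA_character_
  correct <- config$correct_sampling %||% TRUE
  keys <- interaction(df$direction, df$c0, df$inhibitor, drop = TRUE)
  exps <- lapply(split(df, keys), function(g) {
    g <- g[order(g$time_min), ]
    transport_experiment(g$direction[1], g$c0[1], g$time_min, g$conc,
                         area = g$area_cm2[1],
                         receiver_volume = g$receiver_ul[1],
                         sample_volume = g$sample_ul[1],
                         inhibitor = g$inhibitor[1])
  })
  papps <- lapply(exps, apparent_permeability, correct_sampling = correct)
  rows <- list()
  for (k in names(papps)) {
    p <- papps[[k]]
    flags <- paste(c(
      if (isTRUE(p$flags$bbb_permeable)) "bbb_permeable",
      if (isTRUE(p$flags$sink_violation)) "sink_violation",
      if (isTRUE(p$flags$nonpositive_slope)) "nonpositive_slope"
    ), collapse = ";")
    rows[[k]] <- param_row(paste0("papp.", k), p$papp, "cm/s", flags)
  }
  # pair directions per (c0, inhibitor) cell for efflux ratios
  cells <- unique(df[, c("c0", "inhibitor")])
  for (i in seq_len(nrow(cells))) {
    ka <- paste("AtoB", cells$c0[i], cells$inhibitor[i], sep = ".")
    kb <- paste("BtoA", cells$c0[i], cells$inhibitor[i], sep = ".")
    if (ka %in% names(papps) && kb %in% names(papps)) {
      er <- efflux_ratio(papps[[ka]], papps[[kb]])
      rows[[paste0("er.", ka)]] <- param_row(
        paste0("er.", cells$c0[i]), er$er, "ratio",
        if (isTRUE(er$flags$pgp_substrate)) "pgp_substrate" else ""
      )
    }
  }
  analysis_report("transport", do.call(rbind, rows), files = path, config = config)
}

analyze_ppb <- function(config) {
  path <- config$files$ppb
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$binding <- ppb_rate(df$ct, df$cf)
  agg <- stats::aggregate(binding ~ species + nominal_conc, df, mean)
  rows <- lapply(seq_len(nrow(agg)), function(i) {
    param_row(sprintf("ppb.%s.%g", agg$species[i], agg$nominal_conc[i]),
              agg$binding[i], "%")
  })
  analysis_report("ppb", do.call(rbind, rows), files = path, config = config)
}

analyze_ic50 <- function(config) {
  path <- config$files$inhibition
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rows <- list()
  for (iso in unique(df$isoform)) {
    g <- df[df$isoform == iso, ]
    wide <- stats::reshape(g[, c("replicate", "inhibitor_conc", "activity_pct")],
                           idvar = "inhibitor_conc", timevar = "replicate",
                           direction = "wide")
    wide <- wide[order(wide$inhibitor_conc), ]
    series <- inhibition_series(iso, wide$inhibitor_conc,
                                as.matrix(wide[, -1, drop = FALSE]))
    res <- fit_ic50(series)
    flags <- paste(c(if (res$censored) paste0("censored:", res$label),
                     classify_inhibition(res)), collapse = ";")
    rows[[iso]] <- param_row(paste0("ic50.", iso),
                             if (res$censored) res$censor_bound else res$ic50,
                             "umol/L", flags)
  }
  analysis_report("ic50", do.call(rbind, rows), files = path, config = config)
}

analyze_excretion <- function(config) {
  path <- config$files$excretion
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dose <- config$dose_mg_per_kg %||% stop("dose_mg_per_kg required", call. = FALSE)
  bw <- config$body_weight_kg %||% stop("body_weight_kg required", call. = FALSE)
  rows <- list(); finals <- c()
  for (route in unique(df$route)) {
    g <- df[df$route == route, ]
    g <- g[order(g$t_start_h), ]
    pct <- vapply(seq_len(nrow(g)), function(i) {
      rec <- excretion_record(route, c(g$t_start_h[i], g$t_end_h[i]),
                              g$matrix_amount_ml[i], g$conc[i],
                              dilution_factor = g$dilution_factor[i])
      interval_pct_dose(rec, dose, bw)
    }, numeric(1))
    cum <- cumulative_curve(pct)
    finals[route] <- cum[length(cum)]
    rows[[route]] <- param_row(paste0("cumulative.", route),
                               finals[route], "% of dose")
  }
  tot <- total_recovery(finals)
  rows[["total"]] <- param_row("total_recovery", tot$total_pct, "% of dose",
                               if (tot$extensive_metabolism) "extensive_metabolism" else "")
  analysis_report("excretion", do.call(rbind, rows), files = path, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
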