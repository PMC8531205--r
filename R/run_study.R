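#' Default whole-study configuration
#'
#' A complete synthetic-study configuration mirroring the underlying design:
#' two acclimation groups (18 and 25 degC), five respirometry test
#' temperatures (15/20/25/30/34 degC), duplicate sealed cycles in a 43 mL
#' chamber, two heart-protocol test temperatures (18/25 degC) with three
#' blockade conditions, 0.1 degC per minute CTmax ramps, and one year of
#' hourly habitat logging.
#'
#' @param n_animals animals per group and protocol (default 8)
#' @param seed base RNG seed; all per-task seeds are derived from it
#' @param out_dir output directory for [run_study()]
#' @return a named list understood by [run_study()]
#' @export
default_study_config <- function(n_animals = 8, seed = 1L,
                                 out_dir = tempfile("study")) {
  list(
    groups = c("T18", "T25"),
    test_temps_C = c(15, 20, 25, 30, 34),
    heart_temps_C = c(18, 25),
    n_animals = n_animals,
    chamber_ml = 43,
    r2_min = 0.95,
    sat_floor_pct = 80,
    dead_time_s = 60,
    background_umol_h = 0.3,
    sat_noise_sd_pct = 0.5,
    beat_cv = 0.05,
    signal_noise_sd = 0.05,
    signal_duration_s = 360,
    signal_fs_hz = 1000,
    ramp_noise_sd = 0.05,
    habitat_noise_sd = 0.2,
    modules = c("respirometry", "thermal", "cardio", "habitat"),
    seed = as.integer(seed),
    out_dir = out_dir
  )
}

#' Validate a study configuration
#'
#' @param config list as produced by [default_study_config()]
#' @return the config, invisibly; stops with a message on the first
#'   invalid field
#' @export
validate_study_config <- function(config) {
  req <- names(default_study_config())
  missing_f <- setdiff(req, names(config))
  if (length(missing_f) > 0) stop("config is missing field: ", missing_f[1])
  if (config$r2_min < 0 || config$r2_min > 1) {
    stop("r2_min must lie in [0, 1]")
  }
  if (config$sat_floor_pct < 0 || config$sat_floor_pct > 100) {
    stop("sat_floor_pct must lie in [0, 100]")
  }
  if (config$n_animals < 1) stop("n_animals must be >= 1")
  if (length(config$test_temps_C) < 1) stop("test_temps_C must be non-empty")
  if (config$chamber_ml <= 0) stop("chamber_ml must be positive")
  invisible(config)
}

# deterministic small sub-seed per task, keyed by strings; stays < 2^31
derive_seed <- function(base, ...) {
  key <- paste(c(base, ...), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483587
  as.integer(h + 1)
}

#' Seal duration that respects the saturation floor
#'
#' Picks a sealed-phase length using ~85% of the saturation budget above the
#' floor for the expected decline rate, capped to a practical 2--12 minutes.
#' Using most of the budget keeps the decline large relative to sensor noise
#' (which the r-squared criterion needs), while the remaining headroom stops
#' noise from dragging the measured minimum under the floor.
#'
#' @param mo2_umol_g_h expected mass-specific rate, umol O2 per g per h
#' @param mass_g organism mass, g
#' @param chamber_ml chamber volume, mL
#' @param temp_C test temperature, degC
#' @param background_umol_h background rate, umol per h
#' @param sat_floor_pct saturation floor, percent
#' @return seal duration, minutes
#' @export
auto_seal_min <- function(mo2_umol_g_h, mass_g, chamber_ml = 43, temp_C = 25,
                          background_umol_h = 0, sat_floor_pct = 80) {
  v_re_L <- (chamber_ml - mass_g) / 1000
  c_sat <- o2_solubility_umol_l(temp_C)
  decline_pct_min <- (mo2_umol_g_h * mass_g + background_umol_h) /
    v_re_L / c_sat * 100 / 60
  if (decline_pct_min <= 0) return(10)
  budget <- (100 - sat_floor_pct) * 0.85
  min(12, max(2, budget / decline_pct_min))
}

#' Run a full synthetic study end to end
#'
#' Generates every raw input with the synthetic module, runs each analysis
#' pipeline, and writes tidy result CSVs plus a JSON manifest (seeds,
#' thresholds, QC rejection counts, output checksums). Re-running with the
#' same configuration reproduces byte-identical outputs.
#'
#' @param config list from [default_study_config()], possibly modified
#' @return list with the result tables (`estimates`, `scope`, `ctmax`,
#'   `tones`, `habitat`) and the `manifest`, invisibly; files are written
#'   under `config$out_dir`
#' @export
run_study <- function(config = default_study_config()) {
  validate_study_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohorts <- lapply(config$groups, function(g) {
    cd <- cohort_defaults()
    cd <- cd[cd$group == g, ]
    if (nrow(cd) == 0) cd <- data.frame(mass_mean_g = 1, mass_sem_g = 0.1,
                                        n = config$n_animals)
    gen_cohort(g, config$n_animals,
               mass_mean_g = cd$mass_mean_g,
               mass_sd_g = cd$mass_sem_g * sqrt(cd$n),
               tl_mean_mm = cd$tl_mean_mm, pl_mean_mm = cd$pl_mean_mm,
               bw_mm = cd$bw_mean_mm,
               seed = derive_seed(config$seed, "cohort", g))
  })
  names(cohorts) <- config$groups
  results <- list()
  qc_rejected_total <- 0L

  if ("respirometry" %in% config$modules) {
    cond <- condition_defaults()
    rows <- list()
    for (g in config$groups) {
      co <- cohorts[[g]]
      for (kind in c("routine", "maximum")) {
        for (temp in config$test_temps_C) {
          true_mo2 <- cond$mo2_umol_g_h[cond$group == g &
                                        cond$kind == kind &
                                        cond$test_temp_C == temp]
          if (length(true_mo2) != 1) next
          # background measured from a paired empty-chamber control trace
          ctrl <- gen_o2_trace(0, mass_g = 1e-3,
                               chamber_ml = config$chamber_ml,
                               temp_C = temp, n_cycles = 2,
                               seal_min = 12,
                               noise_sd_pct = config$sat_noise_sd_pct,
                               background_umol_h = config$background_umol_h,
                               seed = derive_seed(config$seed, "ctrl", g,
                                                  kind, temp))
          bg <- measure_background(ctrl,
                                   dead_time_s = config$dead_time_s,
                                   sat_floor_pct = config$sat_floor_pct)
          for (i in seq_len(nrow(co))) {
            m <- co$mass_g[i]
            seal <- auto_seal_min(true_mo2, m, config$chamber_ml, temp,
                                  config$background_umol_h,
                                  config$sat_floor_pct)
            tr <- gen_o2_trace(true_mo2, mass_g = m,
                               chamber_ml = config$chamber_ml,
                               temp_C = temp, n_cycles = 2,
                               seal_min = seal,
                               noise_sd_pct = config$sat_noise_sd_pct,
                               background_umol_h = config$background_umol_h,
                               trial_kind = kind, group = g,
                               animal_id = co$animal_id[i],
                               seed = derive_seed(config$seed, "trace", g,
                                                  kind, temp, i))
            est <- mo2_from_trace(tr, background_umol_h = bg,
                                  r2_min = config$r2_min,
                                  sat_floor_pct = config$sat_floor_pct,
                                  dead_time_s = config$dead_time_s)
            qc_rejected_total <- qc_rejected_total + est$n_rejected
            rows[[length(rows) + 1]] <- data.frame(
              group = g, animal_id = co$animal_id[i], test_temp_C = temp,
              kind = kind, mass_g = m,
              mo2_total_umol_h = est$mo2_total_umol_h,
              mo2_mass_specific_umol_g_h = est$mo2_mass_specific_umol_g_h,
              n_used = est$n_used, stringsAsFactors = FALSE)
          }
        }
      }
    }
    results$estimates <- do.call(rbind, rows)
    scope_rows <- lapply(config$groups, function(g) {
      e <- results$estimates[results$estimates$group == g, ]
      r <- e[e$kind == "routine",
             c("test_temp_C", "mo2_mass_specific_umol_g_h")]
      m <- e[e$kind == "maximum",
             c("test_temp_C", "mo2_mass_specific_umol_g_h")]
      names(r)[2] <- "mo2"; names(m)[2] <- "mo2"
      build_scope_curve(r, m, group = g)
    })
    results$scope <- do.call(rbind, scope_rows)
  }

  if ("thermal" %in% config$modules) {
    ctd <- ctmax_defaults()
    rows <- list()
    for (g in config$groups) {
      p <- ctd[ctd$group == g, ]
      if (nrow(p) == 0) next
      for (i in seq_len(config$n_animals)) {
        seed_i <- derive_seed(config$seed, "ramp", g, i)
        set.seed(seed_i)
        ct_true <- stats::rnorm(1, p$ctmax_C, p$ctmax_sem_C * sqrt(p$n))
        ramp <- gen_ctmax_ramp(p$start_C, p$heating_rate_C_min, ct_true,
                               noise_sd = config$ramp_noise_sd,
                               group = g, animal_id = sprintf("%s_%02d", g, i),
                               seed = seed_i + 1L)
        res <- extract_ctmax(ramp)
        rows[[length(rows) + 1]] <- data.frame(
          group = g, animal_id = sprintf("%s_%02d", g, i),
          ctmax_C = res$ctmax_C,
          heating_rate_C_min = res$heating_rate_C_min,
          stringsAsFactors = FALSE)
      }
    }
    results$ctmax <- do.call(rbind, rows)
  }

  if ("cardio" %in% config$modules) {
    hd <- heart_rate_defaults()
    rows <- list()
    for (g in config$groups) {
      for (temp in config$heart_temps_C) {
        per_cond <- list()
        for (cnd in c("routine", "atropine", "double")) {
          fh_true <- hd$fh_bpm[hd$test_temp_C == temp & hd$condition == cnd]
          if (length(fh_true) != 1) next
          fhs <- vapply(seq_len(config$n_animals), function(i) {
            rec <- gen_heart_signal(fh_true,
                                    duration_s = config$signal_duration_s,
                                    fs_hz = config$signal_fs_hz,
                                    beat_cv = config$beat_cv,
                                    noise_sd = config$signal_noise_sd,
                                    condition = cnd, test_temp_C = temp,
                                    group = g,
                                    seed = derive_seed(config$seed, "fh", g,
                                                       temp, cnd, i))
            fh_from_recording(rec)$fh_bpm
          }, 1)
          per_cond[[cnd]] <- mean(fhs)
        }
        if (length(per_cond) == 3) {
          tones <- autonomic_tones(per_cond$routine, per_cond$atropine,
                                   per_cond$double)
          rows[[length(rows) + 1]] <- data.frame(
            group = g, test_temp_C = temp,
            fh_routine = per_cond$routine, fh_atropine = per_cond$atropine,
            fh_double = per_cond$double,
            cholinergic_pct = tones$cholinergic_pct,
            adrenergic_pct = tones$adrenergic_pct,
            stringsAsFactors = FALSE)
        }
      }
    }
    results$tones <- do.call(rbind, rows)
  }

  if ("habitat" %in% config$modules) {
    series <- gen_habitat_series("2019-04-24", "2020-04-23",
                                 noise_sd = config$habitat_noise_sd,
                                 seed = derive_seed(config$seed, "habitat"))
    results$habitat <- period_summary(daily_stats(series))
  }

  # write outputs and a manifest with checksums for provenance
  paths <- character(0)
  for (nm in names(results)) {
    p <- file.path(config$out_dir, paste0(nm, ".csv"))
    utils::write.csv(results[[nm]], p, row.names = FALSE)
    paths[nm] <- p
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("tadscope")),
    seed = config$seed,
    thresholds = list(r2_min = config$r2_min,
                      sat_floor_pct = config$sat_floor_pct),
    routine_slots = if ("respirometry" %in% config$modules) {
      length(config$groups) * length(config$test_temps_C) * config$n_animals
    } else 0L,
    maximum_slots = if ("respirometry" %in% config$modules) {
      length(config$groups) * length(config$test_temps_C) * config$n_animals
    } else 0L,
    qc_rejected = qc_rejected_total,
    outputs = lapply(paths, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  results$manifest <- manifest
  invisible(results)
}
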