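#' Analysis configuration
#'
#' Bundles every tunable of the full burst analysis. The defaults reproduce
#' the headline settings (window `w = 5` s, threshold `Th = 1`) and the
#' sweep grids used for the scale-invariance checks.
#'
#' @param w analysis window in seconds.
#' @param th_theta,th_delta burst thresholds on the ratio.
#' @param Th_sweep thresholds for the threshold collapse (theta sweep uses
#'   `th_theta = Th, th_delta = 1/Th`; delta sweep `th_theta = 1,
#'   th_delta = 1/Th`).
#' @param w_sweep window sizes in seconds for the window collapse
#'   (`NULL` disables the sweep).
#' @param D0_sweep quiet-time duration thresholds in seconds.
#' @param d_star_grid thresholds on the preceding theta duration for the
#'   conditional analysis (seconds).
#' @param bin_c logarithmic bin size for theta durations.
#' @param bin_growth recursive bin growth factor for delta durations.
#' @param alpha power-law exponent used in the threshold-collapse vertical
#'   rescaling.
#' @param dfa_order DFA detrending order.
#' @param n_surr number of coupling surrogates.
#' @param periods periods to analyse (`"h24"` always; `"light"`/`"dark"`
#'   require a schedule).
#' @param seed master seed for all randomized steps.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(w = 5, th_theta = 1, th_delta = 1,
                            Th_sweep = c(1, 1.2, 1.4, 1.6, 1.8, 2),
                            w_sweep = NULL,
                            D0_sweep = c(0, 5, 10, 15, 20, 30),
                            d_star_grid = c(0, 10, 20),
                            bin_c = 0.2, bin_growth = 1.2, alpha = 2.35,
                            dfa_order = 1L, n_surr = 1000,
                            periods = c("h24", "light", "dark"),
                            seed = 1L) {
  stopifnot(all(Th_sweep >= 1), all(D0_sweep >= 0), w > 0)
  structure(list(w = w, th_theta = th_theta, th_delta = th_delta,
                 Th_sweep = Th_sweep, w_sweep = w_sweep,
                 D0_sweep = D0_sweep, d_star_grid = d_star_grid,
                 bin_c = bin_c, bin_growth = bin_growth, alpha = alpha,
                 dfa_order = dfa_order, n_surr = n_surr,
                 periods = periods, seed = seed),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [analysis_config()].
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}

fit_theta_dist <- function(durs, w, bin_c) {
  if (length(durs) < 20) return(NULL)
  bins <- make_bins("logarithmic", w = w, c = bin_c, d_max = max(durs))
  dist <- empirical_pdf(durs, bins, label = "theta", param = w)
  fit <- tryCatch(fit_power_law(dist), error = function(e) NULL)
  list(dist = dist, fit = fit)
}

fit_delta_dist <- function(durs, w, growth) {
  if (length(durs) < 20) return(NULL)
  bins <- make_bins("recursive", w = w, growth = growth, d_max = max(durs))
  dist <- empirical_pdf(durs, bins, label = "delta", param = w)
  fit <- tryCatch(fit_weibull(dist), error = function(e) NULL)
  list(dist = dist, fit = fit)
}

analyse_period <- function(rs_list, period, cfg) {
  bs_list <- lapply(rs_list, function(rs) {
    detect_bursts(rs, cfg$th_theta, cfg$th_delta,
                  period = if (period == "h24") NULL else period)
  })
  th_pool <- unlist(lapply(bs_list, burst_durations, kind = "theta"))
  dl_pool <- unlist(lapply(bs_list, burst_durations, kind = "delta"))
  out <- list(period = period,
              n_theta = length(th_pool), n_delta = length(dl_pool))
  out$theta <- fit_theta_dist(th_pool, cfg$w, cfg$bin_c)
  out$delta <- fit_delta_dist(dl_pool, cfg$w, cfg$bin_growth)

  # threshold sweep and collapses
  if (length(cfg$Th_sweep) >= 2) {
    th_fam <- list(); dl_fam <- list()
    for (Th in cfg$Th_sweep) {
      b_th <- lapply(rs_list, function(rs) {
        detect_bursts(rs, th_theta = Th, th_delta = 1 / Th,
                      period = if (period == "h24") NULL else period)
      })
      b_dl <- lapply(rs_list, function(rs) {
        detect_bursts(rs, th_theta = 1, th_delta = 1 / Th,
                      period = if (period == "h24") NULL else period)
      })
      dth <- unlist(lapply(b_th, burst_durations, kind = "theta"))
      ddl <- unlist(lapply(b_dl, burst_durations, kind = "delta"))
      if (length(dth) >= 20) {
        bins <- make_bins("logarithmic", w = cfg$w, c = cfg$bin_c,
                          d_max = max(dth))
        th_fam[[as.character(Th)]] <-
          empirical_pdf(dth, bins, label = "theta", param = Th)
      }
      if (length(ddl) >= 20) {
        bins <- make_bins("recursive", w = cfg$w, growth = cfg$bin_growth,
                          d_max = max(ddl))
        dl_fam[[as.character(Th)]] <-
          empirical_pdf(ddl, bins, label = "delta", param = Th)
      }
    }
    if (length(th_fam) >= 2) {
      out$collapse_theta_Th <- tryCatch(
        collapse(th_fam, "theta_Th", alpha = cfg$alpha),
        error = function(e) NULL)
    }
    if (length(dl_fam) >= 2) {
      out$collapse_delta_Th <- tryCatch(
        collapse(dl_fam, "delta_mean"), error = function(e) NULL)
    }
  }

  # quiet times over the D0 sweep, rescaled, plus generalized Gamma fit
  qt_fam <- list(); qt_rescaled <- numeric(0)
  for (D0 in cfg$D0_sweep) {
    qts <- lapply(bs_list, quiet_times, D0 = D0)
    dts <- unlist(lapply(qts, `[[`, "deltas"))
    if (length(dts) >= 50) {
      qt_rescaled <- c(qt_rescaled, dts / mean(dts))
      d <- empirical_pdf(dts, make_bins("recursive", w = cfg$w,
                                        growth = cfg$bin_growth,
                                        d_max = max(dts)),
                         label = "quiet", param = D0)
      qt_fam[[as.character(D0)]] <- d
    }
  }
  if (length(qt_fam) >= 2) {
    out$collapse_quiet <- tryCatch(collapse(qt_fam, "quiet_mean"),
                                   error = function(e) NULL)
  }
  if (length(qt_rescaled) >= 200) {
    bins <- make_bins("logarithmic", w = 2 * stats::quantile(qt_rescaled, 0.001),
                      c = cfg$bin_c, d_max = max(qt_rescaled))
    qd <- empirical_pdf(qt_rescaled, bins, label = "quiet")
    out$gengamma <- tryCatch(fit_gen_gamma(qd), error = function(e) NULL)
  }

  # long-range correlations in the duration sequences (per recording)
  dfa_one <- function(bs, kind) {
    d <- bs$bursts$d[bs$bursts$kind == kind]
    if (length(d) < 64) return(NULL)
    tryCatch(dfa(d, order = cfg$dfa_order), error = function(e) NULL)
  }
  th_dfa <- Filter(Negate(is.null), lapply(bs_list, dfa_one, kind = "theta"))
  dl_dfa <- Filter(Negate(is.null), lapply(bs_list, dfa_one, kind = "delta"))
  out$dfa <- list(
    theta = if (length(th_dfa))
      mean(vapply(th_dfa, `[[`, numeric(1), "alpha_d")) else NA_real_,
    delta = if (length(dl_dfa))
      mean(vapply(dl_dfa, `[[`, numeric(1), "alpha_d")) else NA_real_,
    per_recording_theta = th_dfa, per_recording_delta = dl_dfa)

  # coupling: per recording and pooled, with surrogate test
  rho <- vapply(bs_list, function(bs) {
    tryCatch(spearman_coupling(bs)$rho_s, error = function(e) NA_real_)
  }, numeric(1))
  out$coupling <- list(rho_per_recording = rho,
                       rho_mean = mean(rho, na.rm = TRUE))
  pooled <- pool_sequences(bs_list)
  if (!is.null(pooled)) {
    out$coupling$surrogate <- tryCatch(
      surrogate_coupling_test(pooled, n_surr = cfg$n_surr, seed = cfg$seed),
      error = function(e) NULL)
    # conditional probability analysis over the d* grid
    if (length(dl_pool) >= 50) {
      bins <- make_bins("recursive", w = cfg$w, growth = cfg$bin_growth,
                        d_max = max(dl_pool))
      out$conditional <- lapply(cfg$d_star_grid, function(ds) {
        tryCatch(conditional_delta_pdf(pooled, ds, bins),
                 error = function(e) NULL)
      })
      names(out$conditional) <- as.character(cfg$d_star_grid)
    }
  }
  out
}

# concatenate burst sequences, keeping chunks distinct across recordings
pool_sequences <- function(bs_list) {
  bs_list <- Filter(function(b) nrow(b$bursts) > 0, bs_list)
  if (length(bs_list) == 0) return(NULL)
  off <- 0L
  t_off <- 0
  parts <- lapply(bs_list, function(bs) {
    b <- bs$bursts
    b$chunk <- b$chunk + off
    b$t_start <- b$t_start + t_off
    off <<- max(b$chunk)
    t_off <<- max(b$t_start + b$d) + bs$w
    b
  })
  out <- bs_list[[1]]
  out$bursts <- do.call(rbind, parts)
  out
}

#' Run the full burst analysis over one or more recordings
#'
#' For each period (24 h and, when a schedule is present, light and dark)
#' this computes, on data pooled across recordings: theta/delta duration
#' distributions with power-law and Weibull fits, threshold-sweep collapses,
#' the quiet-time analysis over the `D0` sweep with a generalized-Gamma fit,
#' DFA exponents of the theta- and delta-duration sequences, Spearman
#' coupling with its shuffling surrogate test, and conditional delta
#' distributions over the `d*` grid. Optionally repeats the analysis over a
#' window-size sweep for the window collapse. Per-recording failures are
#' caught and logged, and the run continues.
#'
#' @param recordings a list of `raw_recording` objects or file paths
#'   understood by [load_recording()].
#' @param cfg an [analysis_config()].
#' @param out_dir if given, burst tables, distribution tables and a JSON
#'   report (plus a run manifest) are written here.
#' @param preprocessed set `TRUE` if the recordings are already normalized
#'   and filtered.
#' @return a report list (invisibly when `out_dir` is given).
#' @export
run_analysis <- function(recordings, cfg = analysis_config(),
                         out_dir = NULL, preprocessed = FALSE) {
  if (inherits(recordings, "raw_recording")) recordings <- list(recordings)
  errors <- character(0)
  rs_list <- list()
  for (i in seq_along(recordings)) {
    rs <- tryCatch({
      rec <- recordings[[i]]
      if (is.character(rec)) rec <- load_recording(rec, fs = NULL)
      if (!preprocessed) rec <- preprocess(rec)
      band_power_series(rec, w = cfg$w)
    }, error = function(e) {
      errors <<- c(errors, sprintf("recording %d: %s", i, conditionMessage(e)))
      NULL
    })
    if (!is.null(rs)) rs_list[[length(rs_list) + 1]] <- rs
  }
  if (length(errors)) warning(paste(errors, collapse = "; "))
  if (length(rs_list) == 0) stop("no recording could be analysed")

  has_sched <- any(vapply(rs_list, function(rs) nrow(rs$schedule) > 0,
                          logical(1)))
  periods <- intersect(cfg$periods,
                       if (has_sched) c("h24", "light", "dark") else "h24")
  report <- list(config = unclass(cfg), errors = errors)
  report$periods <- lapply(periods, function(p) analyse_period(rs_list, p, cfg))
  names(report$periods) <- periods

  # window-size sweep (recomputes the spectrogram per window size)
  if (!is.null(cfg$w_sweep) && length(cfg$w_sweep) >= 2) {
    report$w_collapse <- tryCatch(
      window_sweep_collapse(recordings, cfg, preprocessed),
      error = function(e) NULL)
  }
  if (!is.null(out_dir)) {
    write_report(report, rs_list, cfg, out_dir)
    return(invisible(report))
  }
  report
}

window_sweep_collapse <- function(recordings, cfg, preprocessed) {
  th_fam <- list(); dl_fam <- list()
  for (wv in cfg$w_sweep) {
    durs_t <- numeric(0); durs_d <- numeric(0)
    for (rec in recordings) {
      if (is.character(rec)) rec <- load_recording(rec, fs = NULL)
      if (!preprocessed) rec <- preprocess(rec)
      rs <- band_power_series(rec, w = wv)
      bs <- detect_bursts(rs, cfg$th_theta, cfg$th_delta)
      durs_t <- c(durs_t, burst_durations(bs, "theta"))
      durs_d <- c(durs_d, burst_durations(bs, "delta"))
    }
    if (length(durs_t) >= 20) {
      bins <- make_bins("logarithmic", w = wv, c = cfg$bin_c,
                        d_max = max(durs_t))
      th_fam[[as.character(wv)]] <-
        empirical_pdf(durs_t, bins, label = "theta", param = wv)
    }
    if (length(durs_d) >= 20) {
      bins <- make_bins("recursive", w = wv, growth = cfg$bin_growth,
                        d_max = max(durs_d))
      dl_fam[[as.character(wv)]] <-
        empirical_pdf(durs_d, bins, label = "delta", param = wv)
    }
  }
  list(theta = if (length(th_fam) >= 2) collapse(th_fam, "theta_w") else NULL,
       delta = if (length(dl_fam) >= 2) collapse(dl_fam, "delta_mean")
       else NULL)
}

report_summary <- function(report) {
  lapply(report$periods, function(p) {
    list(period = p$period, n_theta = p$n_theta, n_delta = p$n_delta,
         alpha = if (!is.null(p$theta$fit)) p$theta$fit$alpha else NA,
         alpha_se = if (!is.null(p$theta$fit)) p$theta$fit$alpha_se else NA,
         weibull_beta = if (!is.null(p$delta$fit)) p$delta$fit$beta else NA,
         weibull_lambda_s = if (!is.null(p$delta$fit)) p$delta$fit$lam else NA,
         weibull_lambda_w = if (!is.null(p$delta$fit))
           p$delta$fit$lam / report$config$w else NA,
         epsilon = if (!is.null(p$collapse_theta_Th))
           p$collapse_theta_Th$exponent_value else NA,
         eta = if (!is.null(p$collapse_delta_Th))
           p$collapse_delta_Th$exponent_value else NA,
         gengamma = if (!is.null(p$gengamma))
           p$gengamma[c("b", "nu", "p")] else NULL,
         dfa_theta = p$dfa$theta, dfa_delta = p$dfa$delta,
         rho_mean = p$coupling$rho_mean,
         surrogate = if (!is.null(p$coupling$surrogate))
           p$coupling$surrogate[c("observed", "surrogate_mean",
                                  "surrogate_sd", "z")] else NULL)
  })
}

write_report <- function(report, rs_list, cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_summary(report),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  for (p in names(report$periods)) {
    per <- report$periods[[p]]
    if (!is.null(per$theta$dist)) {
      write_distribution(per$theta$dist,
                         file.path(out_dir, paste0("theta_dist_", p, ".tsv")))
    }
    if (!is.null(per$delta$dist)) {
      write_distribution(per$delta$dist,
                         file.path(out_dir, paste0("delta_dist_", p, ".tsv")))
    }
  }
  cfg_file <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(package_version = as.character(
    utils::packageVersion("sleepcrit")),
    config = unclass(cfg), n_recordings = length(rs_list)), cfg_file)
  invisible(out_dir)
}
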