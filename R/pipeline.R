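# End-to-end orchestration: per-subject analysis from a raw recording, and
# cohort simulation + analysis + group statistics with deterministic seed
# management.

#' Study configuration
#'
#' @param design `data.frame` with columns `genotype`, `group`, `n`; the
#'   default mirrors the study's sample sizes (WT 8/8/7/7, G301R 9 per
#'   group for male/female/aged male/post-menopausal female).
#' @param master_seed Integer master seed. Per-subject seeds are derived by
#'   a fixed counter scheme (see Details) so reruns are bit-identical.
#' @param preset_overrides Named list forwarded to [group_preset()] for
#'   every subject (e.g. `list(duration_s = 1800)`).
#' @param csd_params,spike_params Detection parameter sets.
#' @param counting_channel Channel whose CSD count defines the frequency.
#' @param analyses Which stages to run per subject: any of `"csd"`,
#'   `"epi"`, `"xcorr"`.
#' @param jitter Between-subject variability of the generator: lognormal
#'   coefficients of variation for the CSD rate, speed and epileptiform
#'   onset, and `wt_develop_prob`, the probability that a wild-type subject
#'   develops any epileptiform activity.
#'
#' @details Per-subject seeds are `(master_seed * 1000003 + 7919 * i) mod
#' 2147483399 + 1` for subject counter `i` (stable across runs and below
#' the 32-bit integer limit).
#' @return Object of class `study_config`.
#' @export
study_config <- function(design = default_design(), master_seed = 1L,
                         preset_overrides = list(),
                         csd_params = csd_detect_params(),
                         spike_params = spike_detect_params(),
                         counting_channel = "S1_left",
                         analyses = c("csd", "epi", "xcorr"),
                         jitter = list(rate_cv = 0.07, speed_cv = 0.05,
                                       onset_cv = 0.25,
                                       wt_develop_prob = 0.35)) {
  stopifnot(is.data.frame(design),
            all(c("genotype", "group", "n") %in% names(design)),
            all(design$n >= 0))
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(list(design = design, master_seed = as.integer(master_seed),
                 preset_overrides = preset_overrides,
                 csd_params = csd_params, spike_params = spike_params,
                 counting_channel = counting_channel, analyses = analyses,
                 jitter = jitter),
            class = "study_config")
}

#' @rdname study_config
#' @export
default_design <- function() {
  data.frame(
    genotype = rep(c("WT", "G301R"), each = 4L),
    group = rep(c("male", "female", "aged_male", "PM_female"), 2L),
    n = c(8L, 8L, 7L, 7L, 9L, 9L, 9L, 9L))
}

subject_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 1000003 + 7919 * i) %% 2147483399) + 1L
}

# Draw one subject's simulation parameters around the group preset.
draw_subject_params <- function(genotype, group, seed, overrides, jitter) {
  set.seed(seed)
  ln <- function(mu, cv) mu * exp(stats::rnorm(1L, -cv^2 / 2, cv))
  base <- do.call(group_preset,
                  c(list(genotype = genotype, group = group), overrides))
  prm <- unclass(base)
  prm$csd_rate_per_hr <- ln(base$csd_rate_per_hr, jitter$rate_cv)
  prm$propagation_speed_mm_per_min <-
    ln(base$propagation_speed_mm_per_min, jitter$speed_cv)
  prm$seed <- subject_seed(seed, 1L)
  if (!is.null(base$epi_onset_s)) {
    develops <- genotype != "WT" ||
      stats::runif(1L) < jitter$wt_develop_prob
    if (develops) {
      prm$epi_onset_s <- min(ln(base$epi_onset_s, jitter$onset_cv),
                             0.9 * base$duration_s)
      if (genotype == "G301R") {
        p_cont <- if (group %in% c("male", "female")) 0.55 else 0.25
        prm$epi_escalation <-
          if (stats::runif(1L) < p_cont) "continuous" else "bouts"
      }
    } else {
      prm["epi_onset_s"] <- list(NULL)
      prm$epi_escalation <- "none"
    }
  }
  do.call(sim_params, prm[intersect(names(prm), names(formals(sim_params)))])
}

#' Analyze one subject's recording
#'
#' Runs the two filter chains independently from the same raw traces
#' (0.005 Hz high pass for CSD detection, 0.5 Hz high pass for
#' epileptiform analysis, both with a 100 Hz low pass) and assembles the
#' per-subject summary used by [run_study()]. A flat channel marks the
#' subject as excluded from cross-correlation comparisons; CSD and
#' epileptiform fields are still computed from the working channels.
#'
#' @param rec An [ecog_recording()].
#' @param csd_params A [csd_detect_params()].
#' @param spike_params A [spike_detect_params()].
#' @param counting_channel Channel whose event count defines CSD frequency.
#' @param analyses Stages to run: subset of `"csd"`, `"epi"`, `"xcorr"`.
#' @return One-row `data.frame` (class `subject_summary`) with columns
#'   `subject_id`, `genotype`, `group`, `csd_frequency`,
#'   `propagation_speed`, `contralateral_silent`, `epi_onset`, `epi_class`,
#'   `severity`, `generalized`, `xc_coeff_*`, `xc_lag_*`, `excluded`.
#'   Stage detail objects are attached as attribute `details`.
#' @export
analyze_subject <- function(rec, csd_params = csd_detect_params(),
                            spike_params = spike_detect_params(),
                            counting_channel = "S1_left",
                            analyses = c("csd", "epi", "xcorr")) {
  stopifnot(inherits(rec, "ecog_recording"))
  analyses <- match.arg(analyses, several.ok = TRUE)
  fs <- rec$fs
  dur <- recording_duration(rec)
  flat <- vapply(rec$channels,
                 function(role) stats::sd(get_channel(rec, role)) < 1e-12,
                 logical(1L))
  out <- data.frame(
    subject_id = rec$subject$subject_id, genotype = rec$subject$genotype,
    group = rec$subject$group,
    csd_frequency = NA_real_, propagation_speed = NA_real_,
    contralateral_silent = NA, epi_onset = NA_real_,
    epi_class = NA_character_, severity = NA_real_, generalized = NA,
    xc_coeff_m1s1 = NA_real_, xc_coeff_m1m1r = NA_real_,
    xc_coeff_s1m1r = NA_real_, xc_lag_m1s1 = NA_real_,
    xc_lag_m1m1r = NA_real_, xc_lag_s1m1r = NA_real_,
    excluded = any(flat), stringsAsFactors = FALSE)
  details <- list(qc_flat_channels = names(flat)[flat])

  if ("csd" %in% analyses) {
    dc <- lapply(rec$channels, function(role) {
      if (flat[[role]]) return(NULL)
      detect_csds(apply_filter(get_channel(rec, role), fs,
                               adapt_spec(csd_filter_spec(), fs)),
                  fs, csd_params, t0 = rec$t0)
    })
    names(dc) <- rec$channels
    details$csd_events <- dc
    if (!is.null(dc[[counting_channel]])) {
      out$csd_frequency <- csd_frequency(dc[[counting_channel]], dur)
    }
    if (!is.null(dc$M1_left) && !is.null(dc$S1_left)) {
      out$propagation_speed <- tryCatch(
        as.numeric(propagation_speed(dc$M1_left, dc$S1_left,
                                     min_dt_s = 1 / fs)),
        error = function(e) NA_real_)
    }
    if (!is.null(dc$M1_right)) {
      out$contralateral_silent <- assert_contralateral_silent(dc$M1_right)
    }
  }

  hp <- NULL
  if (any(c("epi", "xcorr") %in% analyses)) {
    hp <- lapply(rec$channels, function(role) {
      if (flat[[role]]) return(get_channel(rec, role))
      apply_filter(get_channel(rec, role), fs, adapt_spec(epi_filter_spec(), fs))
    })
    names(hp) <- rec$channels
  }

  if ("epi" %in% analyses) {
    ann <- lapply(rec$channels, function(role) {
      if (flat[[role]]) return(NULL)
      annotate_epileptiform(hp[[role]], fs, spike_params, channel = role)
    })
    names(ann) <- rec$channels
    details$epi <- ann
    if (!is.null(ann$M1_left)) {
      out$epi_onset <- ann$M1_left$onset_s
      out$epi_class <- ann$M1_left$activity_class
      out$severity <- ann$M1_left$severity
      if (!is.null(ann$M1_right)) {
        out$generalized <- is_generalized(ann$M1_left, ann$M1_right)
      }
    }
  }

  if ("xcorr" %in% analyses && !any(flat)) {
    i0 <- max(1L, floor(max(dur - 600, 0) * fs) + 1L)
    win <- lapply(hp, function(x) x[i0:length(x)])
    xc <- tryCatch(pairwise_xcorr_traces(win, fs),
                   error = function(e) NULL)
    if (is.null(xc)) {
      out$excluded <- TRUE
    } else {
      out[c("xc_coeff_m1s1", "xc_coeff_m1m1r", "xc_coeff_s1m1r")] <-
        as.list(xc$max_coeff)
      out[c("xc_lag_m1s1", "xc_lag_m1m1r", "xc_lag_s1m1r")] <-
        as.list(xc$lag_s)
      details$xcorr <- xc
    }
  }

  attr(out, "details") <- details
  class(out) <- c("subject_summary", "data.frame")
  out
}

#' Simulate and analyze a full cohort
#'
#' For each design cell, draws per-subject generator parameters around the
#' group preset (deterministically from the master seed), simulates the
#' recording, analyzes it with [analyze_subject()], then runs the group
#' statistics battery with [run_study()]. Reruns with an identical
#' configuration are bit-identical.
#'
#' @param config A [study_config()].
#' @param verbose Print one progress line per subject.
#' @return List of class `cohort_report`: `summaries` (per-subject rows),
#'   `report` (the [run_study()] output), `provenance` (master seed,
#'   per-subject seeds and drawn parameters, detection parameters).
#' @export
run_cohort <- function(config = study_config(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  rows <- list()
  prov_subj <- list()
  counter <- 0L
  for (ci in seq_len(nrow(config$design))) {
    gt <- config$design$genotype[ci]
    gr <- config$design$group[ci]
    for (k in seq_len(config$design$n[ci])) {
      counter <- counter + 1L
      sid <- sprintf("%s_%s_%02d", gt, gr, k)
      seed_i <- subject_seed(config$master_seed, counter)
      prm <- draw_subject_params(gt, gr, seed_i, config$preset_overrides,
                                 config$jitter)
      t_el <- system.time({
        sim <- simulate_recording(prm, subject_meta(gt, gr, sid))
        row <- tryCatch(
          analyze_subject(sim$recording, config$csd_params,
                          config$spike_params, config$counting_channel,
                          config$analyses),
          error = function(e) {
            warning("subject ", sid, " failed: ", conditionMessage(e))
            NULL
          })
      })["elapsed"]
      if (verbose) {
        message(sprintf("[%s] seed=%d %.2fs %s", sid, seed_i, t_el,
                        if (is.null(row)) "FAILED" else "ok"))
      }
      if (!is.null(row)) {
        attr(row, "details") <- NULL
        rows[[length(rows) + 1L]] <- as.data.frame(row)
      }
      prov_subj[[sid]] <- list(seed = seed_i,
                               params = unclass(prm)[c(
                                 "csd_rate_per_hr",
                                 "propagation_speed_mm_per_min",
                                 "epi_onset_s", "epi_escalation",
                                 "severity_growth")])
    }
  }
  summaries <- do.call(rbind, rows)
  report <- run_study(summaries)
  structure(list(
    summaries = summaries, report = report,
    provenance = list(master_seed = config$master_seed,
                      subjects = prov_subj,
                      csd_params = unclass(config$csd_params),
                      spike_params = unclass(config$spike_params),
                      counting_channel = config$counting_channel,
                      analyses = config$analyses,
                      jitter = config$jitter)),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d subjects (master seed %d)\n",
              nrow(x$summaries), x$provenance$master_seed))
  print(x$report)
  invisible(x)
}

#' Write a cohort report bundle to disk
#'
#' @param bundle A [run_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `summaries.csv`, `report.csv` and
#'   `provenance.json`.
#' @export
write_cohort_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$summaries, file.path(dir, "summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$report$tables, file.path(dir, "report.csv"),
                   row.names = FALSE)
  prov <- bundle$provenance
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}
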