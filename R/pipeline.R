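# Staged simulate -> process -> fit -> stats -> report workflow.
#
# Each stage is an exported function reading/writing plain CSV/JSON/YAML in
# an output directory; run_pipeline() sequences them, validates
# prerequisites, and records a manifest (seeds, config hash, per-file
# checksums) so a run is reproducible and re-runnable stage by stage.

#' Build a pipeline run configuration
#'
#' @param synth a [synthetic_config()].
#' @param filter list: `order`, `cutoff_kinematics_hz`, `cutoff_forces_hz`.
#' @param events list: `threshold_n`, `debounce_ms`.
#' @param model list: `outcomes` to fit (subset of the five outcome ids).
#' @param stats list: `alpha`, `epoch_len`, `n_last`, `n_first`.
#' @param raw_trial list: `enabled`, `n_steps` (step pairs for the example
#'   raw trial synthesised in the simulate stage).
#' @return Object of class `run_config`.
#' @export
run_config <- function(synth = synthetic_config(),
                       filter = list(order = 4L, cutoff_kinematics_hz = 6,
                                     cutoff_forces_hz = 20),
                       events = list(threshold_n = 20, debounce_ms = 50),
                       model = list(outcomes = "sla"),
                       stats = list(alpha = 0.05, epoch_len = 100L,
                                    n_last = 100L, n_first = 5L),
                       raw_trial = list(enabled = TRUE, n_steps = 40L)) {
  if (stats$alpha <= 0 || stats$alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(synth = synth, filter = filter, events = events,
                 model = model, stats = stats, raw_trial = raw_trial),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: a
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$synth <- unclass(x$synth)
  x$synth$coeffs <- as.list(x$synth$coeffs)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  cf <- as.data.frame(x$synth$coeffs, stringsAsFactors = FALSE)
  synth <- synthetic_config(
    n_move = x$synth$n_move, n_notmove = x$synth$n_notmove,
    n_steps = x$synth$n_steps, coeffs = cf,
    belt_speed_fast = x$synth$belt_speed_fast,
    belt_speed_slow = x$synth$belt_speed_slow,
    mass_mean = x$synth$mass_mean, mass_sd = x$synth$mass_sd,
    seed = x$synth$seed)
  run_config(synth = synth, filter = x$filter, events = x$events,
             model = x$model, stats = x$stats, raw_trial = x$raw_trial)
}

.need_file <- function(outdir, file, stage) {
  p <- file.path(outdir, file)
  if (!file.exists(p))
    stop(sprintf("missing '%s'; run the '%s' stage first", file, stage),
         call. = FALSE)
  p
}

#' Simulate stage: cohort tables and an example raw trial
#'
#' Writes `participants.csv` (questionnaire roster), `steps.csv`
#' (participant_id, step, step_length_fast_m, step_length_slow_m, sla),
#' `strides.csv` (per-stride work rates per leg, net rate, duration) and,
#' if enabled, an example raw trial under `raw/<id>/`. Step lengths are
#' reconstructed from the SLA series around a constant 1.1 m step-length
#' sum.
#'
#' @param config a `run_config`.
#' @param outdir output directory.
#' @return Invisibly, the files written.
#' @export
run_stage_simulate <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sc <- config$synth
  roster <- generate_participants(sc)
  utils::write.csv(roster, file.path(outdir, "participants.csv"),
                   row.names = FALSE)

  sla_series <- generate_outcome_series(sc, "sla")
  S <- 1.1                               # fast + slow step length, m
  steps <- data.frame(participant_id = sla_series$id,
                      group = sla_series$group,
                      step = sla_series$index,
                      step_length_fast_m = S * (1 + sla_series$value) / 2,
                      step_length_slow_m = S * (1 - sla_series$value) / 2,
                      sla = sla_series$value)
  utils::write.csv(steps, file.path(outdir, "steps.csv"), row.names = FALSE)

  work <- lapply(c("wpos_fast", "wpos_slow", "wneg_fast", "wneg_slow"),
                 function(oc) generate_outcome_series(sc, oc))
  names(work) <- c("wpos_fast", "wpos_slow", "wneg_fast", "wneg_slow")
  dur <- S / ((sc$belt_speed_fast + sc$belt_speed_slow) / 2)
  strides <- data.frame(participant_id = work$wpos_fast$id,
                        group = work$wpos_fast$group,
                        stride = work$wpos_fast$index,
                        wpos_fast = work$wpos_fast$value,
                        wneg_fast = work$wneg_fast$value,
                        wpos_slow = work$wpos_slow$value,
                        wneg_slow = work$wneg_slow$value,
                        duration_s = dur)
  strides$wnet <- strides$wpos_fast + strides$wneg_fast +
    strides$wpos_slow + strides$wneg_slow
  utils::write.csv(strides, file.path(outdir, "strides.csv"),
                   row.names = FALSE)

  files <- c("participants.csv", "steps.csv", "strides.csv")
  if (isTRUE(config$raw_trial$enabled)) {
    truth <- participant_truth(sc, "sla")
    n_raw <- config$raw_trial$n_steps
    s1 <- steps[steps$participant_id == truth$id[1L], ][seq_len(n_raw), ]
    trial <- generate_raw_trial(s1$step_length_fast_m, s1$step_length_slow_m,
                                sc, mass_kg = truth$mass_kg[1L],
                                fast_side = truth$fast_side[1L],
                                id = truth$id[1L])
    write_raw_trial(trial, file.path(outdir, "raw", truth$id[1L]))
    files <- c(files, file.path("raw", truth$id[1L],
                                c("forces.csv", "markers.csv", "meta.yaml")))
  }
  invisible(files)
}

#' Process stage: raw trials through the signal/outcome chain
#'
#' Reads every trial under `raw/`, runs [process_trial()] and writes
#' `processed_steps.csv` and `processed_strides.csv`.
#'
#' @inheritParams run_stage_simulate
#' @export
run_stage_process <- function(config, outdir) {
  raw_root <- file.path(outdir, "raw")
  if (!dir.exists(raw_root))
    stop("missing 'raw/'; run the 'simulate' stage first", call. = FALSE)
  dirs <- list.dirs(raw_root, recursive = FALSE)
  steps <- NULL; strides <- NULL
  for (d in dirs) {
    trial <- read_raw_trial(d)
    pr <- process_trial(trial,
                        cutoff_kinematics_hz = config$filter$cutoff_kinematics_hz,
                        cutoff_forces_hz = config$filter$cutoff_forces_hz,
                        filter_order = config$filter$order,
                        threshold_n = config$events$threshold_n,
                        debounce_ms = config$events$debounce_ms)
    st <- pr$steps; st$participant_id <- trial$id
    wk <- pr$strides; wk$participant_id <- trial$id
    steps <- rbind(steps, st); strides <- rbind(strides, wk)
  }
  utils::write.csv(steps, file.path(outdir, "processed_steps.csv"),
                   row.names = FALSE)
  utils::write.csv(strides, file.path(outdir, "processed_strides.csv"),
                   row.names = FALSE)
  invisible(c("processed_steps.csv", "processed_strides.csv"))
}

.load_outcome <- function(config, outdir, outcome) {
  if (outcome == "sla") {
    p <- .need_file(outdir, "steps.csv", "simulate")
    d <- utils::read.csv(p)
    data.frame(id = d$participant_id, group = d$group, index = d$step,
               value = d$sla, stringsAsFactors = FALSE)
  } else {
    p <- .need_file(outdir, "strides.csv", "simulate")
    d <- utils::read.csv(p)
    data.frame(id = d$participant_id, group = d$group, index = d$stride,
               value = d[[outcome]], stringsAsFactors = FALSE)
  }
}

#' Fit stage: candidate model ladder per outcome
#'
#' For each configured outcome, truncates to the common length and fits the
#' four candidate models (one/two exponents, pooled/by group) by exact
#' marginal ML; writes `model_fits.json` and `selection_table.csv`.
#'
#' @inheritParams run_stage_simulate
#' @export
run_stage_fit <- function(config, outdir) {
  results <- list()
  sel_rows <- NULL
  for (oc in config$model$outcomes) {
    d <- truncate_to_min(.load_outcome(config, outdir, oc))
    fits <- list(
      exp1_pooled = fit_ml(d, 1L, FALSE, se = FALSE),
      exp1_group = fit_ml(d, 1L, TRUE, se = FALSE),
      exp2_pooled = fit_ml(d, 2L, FALSE, se = FALSE),
      exp2_group = fit_ml(d, 2L, TRUE, se = TRUE))
    cmp <- compare_models(fits)
    gt <- tryCatch(coef_group_tests(fits$exp2_group),
                   error = function(e) NULL)
    results[[oc]] <- list(
      fits = lapply(fits, function(f)
        f[c("coef", "sigma_id", "sigma_resid", "logLik", "k", "AIC", "BIC",
            "n_obs", "n_participants", "convergence", "degenerate")]),
      selection = cmp[c("chosen_aic", "chosen_bic", "agree")],
      group_tests = gt)
    sr <- cmp$table; sr$outcome <- oc
    sel_rows <- rbind(sel_rows, sr)
  }
  jsonlite::write_json(results, file.path(outdir, "model_fits.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(sel_rows, file.path(outdir, "selection_table.csv"),
                   row.names = FALSE)
  invisible(c("model_fits.json", "selection_table.csv"))
}

#' Stats stage: demographics, initial values, net work, epoch variability
#'
#' Welch t-tests on demographics, Yates-corrected chi-squared on sex and
#' fast-leg proportions, Welch comparisons of initial (first five strides)
#' outcome values and of end-of-adaptation net work rate, and
#' within-participant epoch variability (Student's t per epoch).
#'
#' @inheritParams run_stage_simulate
#' @export
run_stage_stats <- function(config, outdir) {
  roster <- utils::read.csv(.need_file(outdir, "participants.csv",
                                       "simulate"),
                            stringsAsFactors = FALSE)
  roster <- classify_roster(roster)
  inc <- roster[roster$group != "excluded", ]
  mv <- inc[inc$group == "MOVE", ]; nm <- inc[inc$group == "notMOVE", ]
  demo <- do.call(rbind, lapply(
    c("age_yr", "height_cm", "mass_kg", "minutes_per_week"), function(v) {
      w <- welch_t(mv[[v]], nm[[v]])
      data.frame(comparison = v, test = "welch_t",
                 statistic = w$t, df = w$df, p = w$p,
                 move = w$mean_x, notmove = w$mean_y,
                 stringsAsFactors = FALSE)
    }))
  for (v in c("sex", "fast_side")) {
    tab <- table(inc[[v]], inc$group)
    cs <- if (all(dim(tab) == c(2L, 2L)) && all(rowSums(tab) > 0) &&
              all(colSums(tab) > 0)) chi2_yates(as.matrix(tab))
          else list(statistic = NA_real_, df = NA_integer_, p = NA_real_)
    demo <- rbind(demo, data.frame(comparison = v, test = "chi2_yates",
                                   statistic = cs$statistic, df = cs$df,
                                   p = cs$p, move = NA, notmove = NA))
  }

  strides <- utils::read.csv(.need_file(outdir, "strides.csv", "simulate"),
                             stringsAsFactors = FALSE)
  n_first <- config$stats$n_first
  for (oc in c("wpos_fast", "wneg_fast", "wpos_slow", "wneg_slow")) {
    iv <- tapply(seq_len(nrow(strides)), strides$participant_id, function(ix) {
      d <- strides[ix, ][order(strides$stride[ix]), ]
      initial_value(d[[oc]], n_first)
    })
    grp <- tapply(strides$group, strides$participant_id, function(g) g[1L])
    w <- welch_t(iv[grp == "MOVE"], iv[grp == "notMOVE"])
    demo <- rbind(demo, data.frame(comparison = paste0("initial_", oc),
                                   test = "welch_t", statistic = w$t,
                                   df = w$df, p = w$p, move = w$mean_x,
                                   notmove = w$mean_y))
  }
  steps <- utils::read.csv(.need_file(outdir, "steps.csv", "simulate"),
                           stringsAsFactors = FALSE)
  iv <- tapply(seq_len(nrow(steps)), steps$participant_id, function(ix) {
    d <- steps[ix, ][order(steps$step[ix]), ]
    initial_value(d$sla, n_first)
  })
  grp <- tapply(steps$group, steps$participant_id, function(g) g[1L])
  w <- welch_t(iv[grp == "MOVE"], iv[grp == "notMOVE"])
  demo <- rbind(demo, data.frame(comparison = "initial_sla",
                                 test = "welch_t", statistic = w$t,
                                 df = w$df, p = w$p, move = w$mean_x,
                                 notmove = w$mean_y))

  nw <- tapply(seq_len(nrow(strides)), strides$participant_id, function(ix) {
    d <- strides[ix, ][order(strides$stride[ix]), ]
    net_work_rate_end(d$wnet, config$stats$n_last)
  })
  w <- welch_t(nw[grp == "MOVE"], nw[grp == "notMOVE"])
  demo <- rbind(demo, data.frame(comparison = "net_work_rate_end",
                                 test = "welch_t", statistic = w$t,
                                 df = w$df, p = w$p, move = w$mean_x,
                                 notmove = w$mean_y))
  utils::write.csv(demo, file.path(outdir, "group_stats.csv"),
                   row.names = FALSE)

  ev_rows <- NULL
  for (oc in c("sla", "wpos_fast")) {
    d <- .load_outcome(config, outdir, oc)
    ev <- epoch_variability(d, config$stats$epoch_len)
    tt <- ev$tests; tt$outcome <- oc
    ev_rows <- rbind(ev_rows, tt)
  }
  utils::write.csv(ev_rows, file.path(outdir, "epoch_variability.csv"),
                   row.names = FALSE)
  invisible(c("group_stats.csv", "epoch_variability.csv"))
}

#' Report stage: coefficient table, selection table, adaptation figures
#'
#' Writes `report_coefficients.csv` (per outcome and group: estimates, SEs
#' and group-difference p-values) and, when ggplot2 is available,
#' adaptation-curve figures with model overlays and dashed plateau lines
#' under `figures/`.
#'
#' @inheritParams run_stage_simulate
#' @export
run_stage_report <- function(config, outdir) {
  p <- .need_file(outdir, "model_fits.json", "fit")
  res <- jsonlite::read_json(p, simplifyVector = TRUE)
  rows <- NULL
  for (oc in names(res)) {
    cf <- res[[oc]]$fits$exp2_group$coef
    gt <- res[[oc]]$group_tests
    cf$outcome <- oc
    if (!is.null(gt)) {
      pv <- stats::setNames(gt$p, gt$coefficient)
      for (tm in names(pv)) cf[[paste0(tm, "_p_group")]] <- pv[[tm]]
    }
    rows <- rbind(rows, cf)
  }
  utils::write.csv(rows, file.path(outdir, "report_coefficients.csv"),
                   row.names = FALSE)
  files <- "report_coefficients.csv"

  if (requireNamespace("ggplot2", quietly = TRUE)) {
    dir.create(file.path(outdir, "figures"), showWarnings = FALSE)
    for (oc in names(res)) {
      d <- tryCatch(.load_outcome(config, outdir, oc),
                    error = function(e) NULL)
      if (is.null(d)) next
      cf <- res[[oc]]$fits$exp2_group$coef
      agg <- stats::aggregate(value ~ index + group, d, mean)
      pred <- do.call(rbind, lapply(seq_len(nrow(cf)), function(i)
        data.frame(index = sort(unique(d$index)), group = cf$group[i],
                   value = exp_predict(sort(unique(d$index)), cf$c[i],
                                       cf$a_f[i], cf$r_f[i], cf$a_s[i],
                                       cf$r_s[i]))))
      gp <- ggplot2::ggplot(agg, ggplot2::aes(index, value,
                                              colour = group)) +
        ggplot2::geom_point(size = 0.3, alpha = 0.4) +
        ggplot2::geom_line(data = pred, linewidth = 0.8) +
        ggplot2::geom_hline(data = cf,
                            ggplot2::aes(yintercept = c, colour = group),
                            linetype = "dashed") +
        ggplot2::labs(x = "step/stride", y = oc,
                      title = sprintf("Adaptation of %s", oc)) +
        ggplot2::theme_minimal()
      fp <- file.path(outdir, "figures", paste0(oc, ".pdf"))
      ggplot2::ggsave(fp, gp, width = 7, height = 4)
      files <- c(files, file.path("figures", paste0(oc, ".pdf")))
    }
  }
  invisible(files)
}

#' Run the pipeline
#'
#' Executes the requested stages in canonical order and writes
#' `manifest.json` (package version, seed, config hash, per-file MD5
#' checksums). Any stage failure propagates as an error.
#'
#' @param config a `run_config`.
#' @param outdir output directory.
#' @param stages subset of `c("simulate", "process", "fit", "stats",
#'   "report")`; `"all"` expands to every stage.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "process", "fit", "stats",
                                    "report")) {
  all_stages <- c("simulate", "process", "fit", "stats", "report")
  if (identical(stages, "all")) stages <- all_stages
  stages <- all_stages[all_stages %in% stages]
  if (length(stages) == 0L) stop("no valid stages requested", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(outdir, "config.yaml")
  write_run_config(config, cfg_path)
  files <- character()
  for (st in stages) {
    fn <- switch(st, simulate = run_stage_simulate,
                 process = run_stage_process, fit = run_stage_fit,
                 stats = run_stage_stats, report = run_stage_report)
    files <- c(files, fn(config, outdir))
  }
  files <- files[file.exists(file.path(outdir, files))]
  manifest <- list(
    package_version = as.character(utils::packageVersion("splitbelt")),
    seed = config$synth$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    stages = stages,
    files = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
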