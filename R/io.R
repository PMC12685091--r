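#' Write a growth dataset as CSV
#'
#' Comma-separated, UTF-8, mandatory header \code{arm_id, mouse_id, day,
#' volume_mm3}; a provenance header (\code{#}-prefixed comment lines with
#' package version, seed note and timestamp) precedes the table.
#'
#' @param dataset a [growth_dataset()].
#' @param path output file.
#' @param note optional provenance note (e.g. the generating seed).
#' @return \code{path}, invisibly.
#' @export
write_growth_csv <- function(dataset, path, note = NULL) {
  stopifnot(inherits(dataset, "growth_dataset"))
  rows <- do.call(rbind, lapply(dataset$arms, function(a)
    data.frame(arm_id = a$arm_id, a$observations[, c("mouse_id", "day",
                                                     "volume_mm3")])))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# icdrt growth table (icdrt %s)",
            as.character(utils::packageVersion("icdrt"))),
    sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    if (!is.null(note)) paste("#", note)), con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a growth CSV
#'
#' Parses the dialect written by [write_growth_csv()] and assembles a
#' [growth_dataset()]. Schedules and initial states are not stored in the
#' CSV; each arm's initial burden defaults to its earliest mean observation
#' unless \code{inits}/\code{schedules} are supplied.
#'
#' @param path CSV file with header \code{arm_id, mouse_id, day, volume_mm3}.
#' @param schedules optional named list (by arm_id) of
#'   [treatment_schedule()]s.
#' @param inits optional named list (by arm_id) of initial states.
#' @param ... passed to [growth_dataset()] (observation map, compartment
#'   switches).
#' @return a [growth_dataset()].
#' @export
read_growth_csv <- function(path, schedules = list(), inits = list(), ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("arm_id", "mouse_id", "day", "volume_mm3")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  raw$day <- suppressWarnings(as.numeric(raw$day))
  raw$volume_mm3 <- suppressWarnings(as.numeric(raw$volume_mm3))
  bad <- which(!is.finite(raw$day) | !is.finite(raw$volume_mm3) |
                 raw$volume_mm3 < 0)
  if (length(bad))
    stop(sprintf("unparseable or negative value at data line %d of %s",
                 bad[1L], basename(path)), call. = FALSE)
  arms <- lapply(split(raw, raw$arm_id), function(d) {
    id <- d$arm_id[1L]
    init <- if (!is.null(inits[[id]])) inits[[id]]
            else c(C = min(d$volume_mm3[d$day == min(d$day)]), E = 0, M = 0,
                   Mstar = 0)
    sch <- if (!is.null(schedules[[id]])) schedules[[id]]
           else treatment_schedule()
    dataset_arm(id, init, sch, d[, c("mouse_id", "day", "volume_mm3")])
  })
  growth_dataset(arms, ...)
}

#' Export a simulated trajectory
#'
#' Delimited text with columns \code{day, C, E, M, Mstar, observed_volume}
#' and a provenance comment header.
#'
#' @param trajectory a trajectory from [simulate_tumor()].
#' @param path output file.
#' @param note optional provenance note.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(trajectory, path, note = NULL) {
  stopifnot(inherits(trajectory, "trajectory"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# icdrt trajectory (icdrt %s, rt_mode=%s, obs=%s)",
            as.character(utils::packageVersion("icdrt")),
            attr(trajectory, "rt_mode"), attr(trajectory, "obs_mode")),
    sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    if (!is.null(note)) paste("#", note)), con)
  utils::write.csv(as.data.frame(trajectory), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write / read model configuration as YAML
#'
#' A flat key-value representation of [model_params()],
#' [radiation_params()], compartment switches and (optionally) activation
#' values, with units documented in comments.
#'
#' @param params,rad,A_values,switches configuration to write.
#' @param path file path.
#' @return \code{path} invisibly (write); a list with \code{params},
#'   \code{rad}, \code{A_values}, \code{switches} (read).
#' @export
write_param_config <- function(params, rad = radiation_params(),
                               A_values = NULL,
                               switches = list(use_E = TRUE, use_M = FALSE,
                                               use_Mstar = FALSE),
                               path) {
  obj <- list(model = unclass(params),
              radiation = unclass(rad)[!vapply(unclass(rad), is.null, TRUE)],
              activations = as.list(A_values),
              switches = switches)
  writeLines(c("# icdrt model configuration",
               "# rates per day; volumes mm^3; alpha 1/Gy; beta 1/Gy^2",
               yaml::as.yaml(obj)), path)
  invisible(path)
}

#' @rdname write_param_config
#' @export
read_param_config <- function(path) {
  obj <- yaml::read_yaml(path)
  params <- do.call(model_params, obj$model)
  rad <- do.call(radiation_params, obj$radiation)
  A_values <- if (length(obj$activations)) unlist(obj$activations) else NULL
  list(params = params, rad = rad, A_values = A_values,
       switches = obj$switches)
}

#' Write a staged-fit report
#'
#' Structured text report of a [run_four_step()] result: one row per
#' parameter with its estimate, whether it was frozen, and the stage that
#' produced it, plus per-stage costs.
#'
#' @param fit a \code{four_step_fit}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "four_step_fit"))
  rows <- list()
  for (nm in names(fit$stages)) {
    s <- fit$stages[[nm]]
    for (p in names(s$estimates))
      rows[[length(rows) + 1L]] <- data.frame(stage = nm, parameter = p,
                                              estimate = s$estimates[[p]],
                                              frozen_after = TRUE)
  }
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# icdrt four-step fit report (icdrt %s)",
                     as.character(utils::packageVersion("icdrt"))), con)
  writeLines(sprintf("# stage costs: %s",
                     paste(sprintf("%s=%.6g", names(fit$costs), fit$costs),
                           collapse = ", ")), con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.cli_usage <- function() {
  cat("usage: icdrt <subcommand> [--seed N] [--config FILE] [--out PATH]\n",
      "subcommands: simulate | fit | bootstrap | sensitivity | profile |\n",
      "             efficacy-map | abscopal | synth\n", sep = "")
}

.cli_args <- function(argv) {
  out <- list(seed = 1L, config = NULL, out = ".")
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (a %in% c("--seed", "--config", "--out")) {
      if (i == length(argv)) stop("missing value for ", a, call. = FALSE)
      key <- sub("^--", "", a)
      out[[key]] <- argv[i + 1L]
      i <- i + 2L
    } else stop("unknown flag: ", a, call. = FALSE)
  }
  out$seed <- as.integer(out$seed)
  out
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's functions, usable from
#' \code{Rscript} (see \code{system.file("exec", "icdrt", package =
#' "icdrt")}). Subcommands: \code{synth} writes a four-condition synthetic
#' cohort as growth CSVs; \code{simulate} integrates a configuration and
#' writes the trajectory; \code{fit} runs the four-step calibration on a
#' synthetic suite and writes the report; \code{bootstrap},
#' \code{sensitivity} and \code{profile} analyze that calibration;
#' \code{efficacy-map} sweeps the phase space; \code{abscopal} predicts the
#' out-of-field response. All stochastic subcommands are reproducible from
#' \code{--seed} alone; outputs carry provenance headers.
#'
#' @param argv character vector of arguments (subcommand first), e.g.
#'   \code{c("synth", "--seed", "1", "--out", "data/")}.
#' @return integer exit status, invisibly: 0 on success, 2 on usage error,
#'   1 on runtime failure.
#' @export
run_cli <- function(argv) {
  if (length(argv) < 1L) {
    .cli_usage()
    return(invisible(2L))
  }
  sub <- argv[1L]
  known <- c("simulate", "fit", "bootstrap", "sensitivity", "profile",
             "efficacy-map", "abscopal", "synth")
  if (!sub %in% known) {
    message("unknown subcommand: ", sub)
    .cli_usage()
    return(invisible(2L))
  }
  opts <- tryCatch(.cli_args(argv[-1L]), error = function(e) {
    message(conditionMessage(e))
    .cli_usage()
    NULL
  })
  if (is.null(opts)) return(invisible(2L))
  status <- tryCatch({
    .cli_run(sub, opts)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.cli_run <- function(sub, opts) {
  seed <- opts$seed
  outdir <- opts$out
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  cfg <- if (!is.null(opts$config)) read_param_config(opts$config)
         else { tt <- default_truth()
                list(params = tt$params, rad = tt$rad, A_values = NULL,
                     switches = list(use_E = TRUE, use_M = FALSE,
                                     use_Mstar = FALSE)) }
  log_line <- function(...) {
    cat(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")),
        sprintf(...), "\n", sep = "", file = file.path(outdir, "icdrt.log"),
        append = TRUE)
  }
  log_line("icdrt %s :: %s (seed %d)",
           as.character(utils::packageVersion("icdrt")), sub, seed)
  t0 <- Sys.time()

  if (sub == "synth") {
    suite <- four_condition_suite(seed = seed)
    for (nm in c("wt", "treated", "wt_rt", "treated_rt"))
      write_growth_csv(suite[[nm]], file.path(outdir, paste0(nm, ".csv")),
                       note = paste("seed", seed))
  } else if (sub == "simulate") {
    sw <- cfg$switches
    tr <- simulate_tumor(cfg$params, cfg$rad, treatment_schedule(),
                         init = engrafted_volume(5e5), t_grid = 0:22,
                         use_E = isTRUE(sw$use_E), use_M = isTRUE(sw$use_M),
                         use_Mstar = isTRUE(sw$use_Mstar))
    write_trajectory(tr, file.path(outdir, "trajectory.csv"),
                     note = paste("seed", seed))
  } else if (sub == "fit") {
    suite <- four_condition_suite(seed = seed)
    fit <- run_four_step(suite, params = cfg$params, rad = cfg$rad,
                         n_starts = 4, seed = seed)
    write_fit_report(fit, file.path(outdir, "fit_report.csv"))
  } else if (sub == "bootstrap") {
    suite <- four_condition_suite(seed = seed)
    bt <- bootstrap_params(suite$wt, c("c1", "cmax"), cfg$params, cfg$rad,
                           n = 50, seed = seed)
    utils::write.csv(bt$replicates,
                     file.path(outdir, "bootstrap_replicates.csv"),
                     row.names = FALSE)
    utils::write.csv(bt$summary, file.path(outdir, "bootstrap_summary.csv"),
                     row.names = FALSE)
  } else if (sub == "sensitivity") {
    suite <- four_condition_suite(seed = seed)
    sr <- sensitivity_rank(c("c1", "cmax", "phi_e", "delta_e"),
                           suite$wt, cfg$params, cfg$rad)
    utils::write.csv(sr, file.path(outdir, "sensitivity.csv"),
                     row.names = FALSE)
  } else if (sub == "profile") {
    suite <- four_condition_suite(seed = seed)
    pl <- profile_likelihood("c1", seq(0.5, 0.9, length.out = 7), suite$wt,
                             free = "cmax", params = cfg$params,
                             rad = cfg$rad, seed = seed)
    utils::write.csv(as.data.frame(pl), file.path(outdir, "profile.csv"),
                     row.names = FALSE)
  } else if (sub == "efficacy-map") {
    grid <- efficacy_grid(A_range = c(0, 5, 15), phi_range = c(0, 4.43e-8),
                          dose_range = c(0, 4, 8, 15), params = cfg$params,
                          rad = cfg$rad)
    utils::write.csv(as.data.frame(grid),
                     file.path(outdir, "efficacy_grid.csv"),
                     row.names = FALSE)
  } else if (sub == "abscopal") {
    sch <- treatment_schedule(treatment_event(12, dose = 8, A = 15.32))
    tr <- abscopal_predict(cfg$params, cfg$rad, sch,
                           use_Mstar = TRUE)
    write_trajectory(tr, file.path(outdir, "abscopal.csv"),
                     note = paste("seed", seed))
  }
  log_line("done in %.2fs", as.numeric(Sys.time() - t0, units = "secs"))
  invisible(NULL)
}
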