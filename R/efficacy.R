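#' Treatment efficacy at an evaluation day
#'
#' Percent reduction of the tumor burden relative to an untreated control at
#' a fixed evaluation day:
#' \deqn{\mathrm{Efficacy} = 100\,(C_{control} - C_{treated}) / C_{control}.}
#' The cancer compartment \eqn{C} is compared by default; \code{compare =
#' "observed"} uses the observation map instead. Identical schedules give
#' exactly 0; a fully eliminated treated tumor gives 100; efficacy is
#' negative if treatment accelerates growth.
#'
#' @param params_treated,params_control [model_params()] for each arm
#'   (differ e.g. in \code{phi_mstar} under checkpoint inhibition).
#' @param rad a [radiation_params()] object.
#' @param schedule_treated,schedule_control treatment schedules.
#' @param init shared initial state.
#' @param eval_day evaluation day (default 22).
#' @param compare \code{"C"} (default) or \code{"observed"}.
#' @param ... further arguments to [simulate_tumor()] (compartment switches,
#'   \code{rt_mode}, tolerances, ...).
#' @return efficacy percentage (at most 100).
#' @export
treatment_efficacy <- function(params_treated, rad,
                               schedule_treated,
                               schedule_control = treatment_schedule(),
                               params_control = params_treated,
                               init = engrafted_volume(5e5),
                               eval_day = 22, compare = c("C", "observed"),
                               ...) {
  compare <- match.arg(compare)
  t_grid <- sort(unique(c(0, eval_day)))
  ctrl <- simulate_tumor(params_control, rad, schedule_control, init, t_grid, ...)
  trt <- simulate_tumor(params_treated, rad, schedule_treated, init, t_grid, ...)
  pick <- function(tr) {
    row <- which(tr$day == eval_day)
    if (compare == "C") tr$C[row] else tr$observed_volume[row]
  }
  c_ctrl <- pick(ctrl)
  if (c_ctrl <= 0)
    stop("control tumor extinct at the evaluation day; efficacy undefined",
         call. = FALSE)
  100 * (c_ctrl - pick(trt)) / c_ctrl
}

#' Treatment-efficacy phase map over activation, phagocytosis and dose
#'
#' Full-factorial sweep of [treatment_efficacy()] over immune activation
#' \eqn{A}, treated-macrophage phagocytosis \eqn{\phi_{m^*}} and radiation
#' dose, for a single RT fraction on \code{treatment_day} evaluated at
#' \code{eval_day}. The control arm has no RT and the control phagocytosis
#' value (so the cell at \eqn{A = 0}, control \eqn{\phi}, dose 0 is exactly
#' 0). Isosurface level sets at chosen efficacy levels can be extracted per
#' \eqn{\phi} cross-section with [efficacy_levels()].
#'
#' @param A_range,phi_range,dose_range sorted numeric axes (phi is the
#'   treated-macrophage phagocytosis rate; include the control value to get
#'   the zero-treatment cell).
#' @param params baseline [model_params()]; \code{params$phi_mstar} is the
#'   control phagocytosis value.
#' @param rad a [radiation_params()] object (its \code{resistance_scale}
#'   models radio-resistance).
#' @param treatment_day RT day (reference days: 8, 12 or 14).
#' @param eval_day evaluation day (default 22).
#' @param init initial state.
#' @param compare,... passed to [treatment_efficacy()].
#' @return An object of class \code{efficacy_grid}: long-format data.frame
#'   (\code{A}, \code{phi}, \code{dose_Gy}, \code{efficacy}) with sweep
#'   metadata in attributes; failed cells are \code{NA} with a warning.
#' @export
efficacy_grid <- function(A_range, phi_range, dose_range, params,
                          rad = radiation_params(), treatment_day = 12,
                          eval_day = 22, init = engrafted_volume(5e5),
                          compare = "C", ...) {
  stopifnot(length(A_range) >= 1, length(phi_range) >= 1,
            length(dose_range) >= 1, treatment_day < eval_day)
  cells <- expand.grid(A = sort(A_range), phi = sort(phi_range),
                       dose_Gy = sort(dose_range))
  phi_control <- params$phi_mstar
  n_fail <- 0L
  eff <- vapply(seq_len(nrow(cells)), function(i) {
    A <- cells$A[i]; phi <- cells$phi[i]; d <- cells$dose_Gy[i]
    p_trt <- set_params(params, c(phi_mstar = phi))
    sch <- if (d > 0 || A > 0)
      treatment_schedule(treatment_event(treatment_day, dose = d, A = A))
    else treatment_schedule()
    val <- tryCatch(
      treatment_efficacy(p_trt, rad, sch,
                         params_control = params, init = init,
                         eval_day = eval_day, compare = compare,
                         use_Mstar = TRUE, ...),
      error = function(e) NA_real_)
    if (is.na(val)) n_fail <<- n_fail + 1L
    val
  }, 1)
  if (n_fail > 0L)
    warning(sprintf("%d grid cell(s) failed and are NA", n_fail))
  cells$efficacy <- eff
  structure(cells,
            treatment_day = treatment_day, eval_day = eval_day,
            phi_control = phi_control,
            resistance_scale = rad$resistance_scale,
            n_failed = n_fail,
            class = c("efficacy_grid", "data.frame"))
}

#' Efficacy level sets of a phase map
#'
#' Extracts iso-efficacy contour polylines in the (dose, A) plane for each
#' phagocytosis cross-section of an [efficacy_grid()].
#'
#' @param grid an \code{efficacy_grid}.
#' @param levels efficacy percentages (default the reference isosurface
#'   levels 25, 50, 75, 95).
#' @return data.frame with columns \code{phi}, \code{level}, \code{piece},
#'   \code{dose_Gy}, \code{A} describing the polylines (empty if no contour
#'   crosses the grid).
#' @export
efficacy_levels <- function(grid, levels = c(25, 50, 75, 95)) {
  stopifnot(inherits(grid, "efficacy_grid"))
  out <- list()
  for (phi in unique(grid$phi)) {
    sl <- grid[grid$phi == phi, ]
    doses <- sort(unique(sl$dose_Gy)); As <- sort(unique(sl$A))
    if (length(doses) < 2L || length(As) < 2L) next
    z <- matrix(sl$efficacy[order(sl$A, sl$dose_Gy)],
                nrow = length(doses), ncol = length(As))
    cl <- grDevices::contourLines(doses, As, z, levels = levels)
    for (k in seq_along(cl))
      out[[length(out) + 1L]] <- data.frame(
        phi = phi, level = cl[[k]]$level, piece = k,
        dose_Gy = cl[[k]]$x, A = cl[[k]]$y)
  }
  if (!length(out))
    return(data.frame(phi = numeric(), level = numeric(), piece = integer(),
                      dose_Gy = numeric(), A = numeric()))
  do.call(rbind, out)
}

#' Abscopal (out-of-field) tumor prediction
#'
#' Simulates a non-irradiated tumor that shares growth kinetics, immune
#' context and the primary tumor's ICD: each of the primary schedule's RT
#' events is applied with growth factor \eqn{F = 1 - I} (no direct survival
#' term), with the same \eqn{I = A(1-S)} as computed for the primary dose.
#' Injection events are kept as-is (systemic administration reaches both
#' tumors).
#'
#' @param params,rad model and radiation parameters.
#' @param primary_schedule the irradiated tumor's schedule (at least one RT
#'   event).
#' @param abscopal_init initial state of the out-of-field tumor.
#' @param t_grid output days.
#' @param ... passed to [simulate_tumor()].
#' @return a trajectory of the abscopal tumor.
#' @export
abscopal_predict <- function(params, rad, primary_schedule,
                             abscopal_init = engrafted_volume(1e5),
                             t_grid = 0:22, ...) {
  if (!inherits(primary_schedule, "treatment_schedule"))
    primary_schedule <- treatment_schedule(primary_schedule)
  has_rt <- any(vapply(primary_schedule, function(e) e$kind == "rt", TRUE))
  if (!has_rt)
    stop("primary schedule has no RT event; nothing to share", call. = FALSE)
  absc <- lapply(primary_schedule, function(ev) {
    if (ev$kind == "rt") ev$target <- "abscopal"
    ev
  })
  simulate_tumor(params, rad, treatment_schedule(absc), abscopal_init,
                 t_grid, ...)
}
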