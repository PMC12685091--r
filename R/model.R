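#' Tumor-immune model parameters
#'
#' Rate constants of the cancer-effector (CE) and cancer-effector-macrophage
#' (CEM) models. The cancer cell population \eqn{C} grows logistically at
#' rate \code{c1} with carrying capacity \code{cmax} and is killed by
#' effector cells (\code{phi_e}), wild-type macrophages (\code{phi_m}) and
#' checkpoint-disrupted macrophages (\code{phi_mstar}). Each immune
#' compartment infiltrates at a constant rate (\code{gamma_*}), is exhausted
#' in proportion to its encounters with tumor cells (\code{eta_*}) and is
#' cleared at a constant per-capita rate (\code{delta_*}).
#'
#' Compartments are carried in volume-equivalent units (mm^3 by default;
#' engrafted cell counts convert at \code{kappa} cells per mm^3). Parameters
#' of compartments disabled in [simulate_tumor()] are ignored by the
#' dynamics.
#'
#' @param c1 tumor intrinsic growth rate (1/day, > 0).
#' @param cmax carrying capacity (mm^3, > 0).
#' @param phi_e effector killing coefficient (1/(volume-equivalent day)).
#' @param gamma_e effector infiltration rate (volume-equivalent/day).
#' @param eta_e effector exhaustion coefficient (1/(volume-equivalent day)).
#' @param delta_e effector clearance rate (1/day).
#' @param phi_m,gamma_m,eta_m,delta_m wild-type macrophage analogues.
#' @param phi_mstar,gamma_mstar,eta_mstar,delta_mstar checkpoint-disrupted
#'   (SIRPa-deficient / CD47-SIRPa-treated) macrophage analogues.
#' @param kappa cells per mm^3 conversion used by [engrafted_volume()].
#'
#' @return An object of class \code{model_params} (a named list).
#' @examples
#' p <- model_params(c1 = 0.5, cmax = 1000, phi_e = 0.01,
#'                   gamma_e = 1, eta_e = 0.001, delta_e = 0.1)
#' @export
model_params <- function(c1 = 0.6, cmax = 1500,
                         phi_e = 0, gamma_e = 0, eta_e = 0, delta_e = 0,
                         phi_m = 0, gamma_m = 0, eta_m = 0, delta_m = 0,
                         phi_mstar = 0, gamma_mstar = 0, eta_mstar = 0,
                         delta_mstar = 0, kappa = 1e6) {
  p <- list(c1 = c1, cmax = cmax,
            phi_e = phi_e, gamma_e = gamma_e, eta_e = eta_e, delta_e = delta_e,
            phi_m = phi_m, gamma_m = gamma_m, eta_m = eta_m, delta_m = delta_m,
            phi_mstar = phi_mstar, gamma_mstar = gamma_mstar,
            eta_mstar = eta_mstar, delta_mstar = delta_mstar,
            kappa = kappa)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all model parameters must be finite and nonnegative", call. = FALSE)
  if (c1 <= 0 || cmax <= 0)
    stop("c1 and cmax must be strictly positive", call. = FALSE)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Tumor-immune model parameters (per day, volume-equivalent units)\n")
  cat(sprintf("  growth:     c1 = %g, cmax = %g\n", x$c1, x$cmax))
  cat(sprintf("  effector:   phi_e = %g, gamma_e = %g, eta_e = %g, delta_e = %g\n",
              x$phi_e, x$gamma_e, x$eta_e, x$delta_e))
  cat(sprintf("  macrophage: phi_m = %g, gamma_m = %g, eta_m = %g, delta_m = %g\n",
              x$phi_m, x$gamma_m, x$eta_m, x$delta_m))
  cat(sprintf("  macrophage*: phi_mstar = %g, gamma_mstar = %g, eta_mstar = %g, delta_mstar = %g\n",
              x$phi_mstar, x$gamma_mstar, x$eta_mstar, x$delta_mstar))
  invisible(x)
}

#' Update a parameter object from a named vector
#'
#' @param params a [model_params()] object.
#' @param values named numeric vector of replacements.
#' @return the updated \code{model_params}.
#' @keywords internal
#' @export
set_params <- function(params, values) {
  stopifnot(inherits(params, "model_params"), !is.null(names(values)))
  bad <- setdiff(names(values), names(params))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (nm in names(values)) params[[nm]] <- unname(values[[nm]])
  do.call(model_params, unclass(params))
}

#' Initial state at engraftment
#'
#' Converts an engrafted cell count to an initial tumor burden in mm^3
#' (\code{cells / kappa}); immune compartments start at zero unless given.
#'
#' @param cells number of engrafted tumor cells.
#' @param kappa cells per mm^3 (default 1e6, so 5e5 cells = 0.5 mm^3).
#' @param E,M,Mstar initial immune burdens (volume-equivalent).
#' @return named state vector \code{c(C, E, M, Mstar)}.
#' @examples
#' engrafted_volume(5e5)  # C = 0.5 mm^3
#' @export
engrafted_volume <- function(cells, kappa = 1e6, E = 0, M = 0, Mstar = 0) {
  stopifnot(cells >= 0, kappa > 0, E >= 0, M >= 0, Mstar >= 0)
  c(C = cells / kappa, E = E, M = M, Mstar = Mstar)
}

.check_state <- function(state) {
  if (!is.numeric(state) || any(!is.finite(state)))
    stop("state must be finite numeric", call. = FALSE)
  need <- c("C", "E", "M", "Mstar")
  miss <- setdiff(need, names(state))
  if (length(miss)) {
    add <- stats::setNames(numeric(length(miss)), miss)
    state <- c(state, add)
  }
  state[need]
}

#' Cancer-effector (CE) model right-hand side
#'
#' \deqn{dC/dt = F [\, c_1 C (1 - C/c_{max}) - \phi_e C E \,]}
#' \deqn{dE/dt = \gamma_e - \eta_e C E - \delta_e E}
#' where \eqn{F} is the active post-radiation growth factor (1 before any
#' RT). By default \eqn{F} scales the entire cancer derivative; with
#' \code{scale_growth_only = TRUE} it scales only the logistic term.
#'
#' @param state named numeric state (at least \code{C} and \code{E}).
#' @param params a [model_params()] object.
#' @param rt_factor active growth factor \eqn{F} (dimensionless, finite).
#' @param scale_growth_only logical; see above.
#' @return named vector of derivatives \code{c(C, E)} (per day).
#' @examples
#' p <- model_params(c1 = 0.5, cmax = 1000, phi_e = 0.01,
#'                   gamma_e = 1, eta_e = 0.001, delta_e = 0.1)
#' ce_rhs(c(C = 100, E = 2), p)  # dC = 43, dE = 0.6
#' @export
ce_rhs <- function(state, params, rt_factor = 1, scale_growth_only = FALSE) {
  stopifnot(inherits(params, "model_params"))
  if (!is.finite(rt_factor)) stop("rt_factor must be finite", call. = FALSE)
  state <- .check_state(state)
  d <- cem_core(state, params, rt_factor, scale_growth_only,
                use_M = FALSE, use_Mstar = FALSE)
  d[c("C", "E")]
}

#' Cancer-effector-macrophage (CEM) model right-hand side
#'
#' Extends [ce_rhs()] with phagocytosis and macrophage dynamics:
#' \deqn{dC/dt = F [\, c_1 C (1 - C/c_{max}) - \phi_e C E - \phi_m C M
#'   - \phi_{m^*} C M^* \,]}
#' \deqn{dM^*/dt = \gamma_{m^*} - \eta_{m^*} C M^* - \delta_{m^*} M^*}
#' (and analogously for wild-type \eqn{M}). The effector equation is
#' unchanged. With both macrophage compartments disabled this reduces
#' exactly to the CE model.
#'
#' @inheritParams ce_rhs
#' @param use_M,use_Mstar enable the wild-type / treated macrophage
#'   compartments.
#' @return named vector of derivatives \code{c(C, E, M, Mstar)} (per day).
#' @export
cem_rhs <- function(state, params, rt_factor = 1, scale_growth_only = FALSE,
                    use_M = FALSE, use_Mstar = TRUE) {
  stopifnot(inherits(params, "model_params"))
  if (!is.finite(rt_factor)) stop("rt_factor must be finite", call. = FALSE)
  state <- .check_state(state)
  cem_core(state, params, rt_factor, scale_growth_only, use_M, use_Mstar)
}

# shared derivative kernel; assumes a checked full-length state
cem_core <- function(state, params, rt_factor, scale_growth_only,
                     use_M, use_Mstar) {
  C <- state[["C"]]; E <- state[["E"]]
  M <- if (use_M) state[["M"]] else 0
  Ms <- if (use_Mstar) state[["Mstar"]] else 0
  growth <- params$c1 * C * (1 - C / params$cmax)
  kill <- params$phi_e * C * E + params$phi_m * C * M +
    params$phi_mstar * C * Ms
  dC <- if (scale_growth_only) rt_factor * growth - kill
        else rt_factor * (growth - kill)
  dE <- params$gamma_e - params$eta_e * C * E - params$delta_e * E
  dM <- if (use_M) params$gamma_m - params$eta_m * C * M - params$delta_m * M
        else 0
  dMs <- if (use_Mstar)
    params$gamma_mstar - params$eta_mstar * C * Ms - params$delta_mstar * Ms
  else 0
  c(C = dC, E = dE, M = dM, Mstar = dMs)
}

#' Observed tumor volume
#'
#' Measured in vivo tumor volume includes infiltrated immune cells as well
#' as cancer cells, so the default observation map sums all enabled
#' compartments; \code{mode = "C"} restricts to the cancer compartment.
#'
#' @param state named state vector or a state matrix/data.frame with columns
#'   \code{C}, \code{E}, \code{M}, \code{Mstar}.
#' @param mode \code{"sum"} (default) or \code{"C"}.
#' @return observed volume (mm^3).
#' @examples
#' observed_volume(c(C = 100, E = 20, Mstar = 5))  # 125
#' @export
observed_volume <- function(state, mode = c("sum", "C")) {
  mode <- match.arg(mode)
  if (is.matrix(state) || is.data.frame(state)) {
    cols <- intersect(c("C", "E", "M", "Mstar"), colnames(state))
    if (mode == "C") return(as.numeric(state[, "C"]))
    return(rowSums(as.matrix(state[, cols, drop = FALSE])))
  }
  state <- .check_state(state)
  if (mode == "C") unname(state[["C"]]) else unname(sum(state))
}

#' Treatment event
#'
#' A dated intervention: either a radiotherapy fraction (\code{kind = "rt"},
#' with dose in Gy and immune activation \code{A}) or an injection of
#' checkpoint-disrupted macrophages (\code{kind = "injection"}, with a bolus
#' added to \eqn{M^*}). RT is delivered instantaneously at the start of its
#' day; the delivery time \eqn{\tau} enters only through the repair function.
#'
#' @param day event day (days since engraftment, >= 0).
#' @param kind \code{"rt"} or \code{"injection"}.
#' @param dose RT dose (Gy, >= 0; rt events only).
#' @param A immune activation for this event (>= 0; rt events only).
#' @param target \code{"primary"} (irradiated, F = S - I) or
#'   \code{"abscopal"} (out-of-field, F = 1 - I).
#' @param bolus injected M* amount (volume-equivalent, injection only).
#' @return An object of class \code{treatment_event}.
#' @examples
#' treatment_event(12, dose = 8, A = 15.32)
#' @export
treatment_event <- function(day, kind = c("rt", "injection"), dose = 0,
                            A = 0, target = c("primary", "abscopal"),
                            bolus = 0) {
  kind <- match.arg(kind)
  target <- match.arg(target)
  stopifnot(is.numeric(day), length(day) == 1L, is.finite(day), day >= 0)
  if (!is.finite(dose) || dose < 0)
    stop("dose must be finite and nonnegative", call. = FALSE)
  if (!is.finite(A) || A < 0)
    stop("A must be finite and nonnegative", call. = FALSE)
  if (!is.finite(bolus) || bolus < 0)
    stop("bolus must be finite and nonnegative", call. = FALSE)
  structure(list(day = day, kind = kind, dose = dose, A = A,
                 target = target, bolus = bolus),
            class = "treatment_event")
}

#' Treatment schedule
#'
#' @param ... [treatment_event()] objects (or a single list of them).
#' @return list of events sorted by day, class \code{treatment_schedule}.
#' @examples
#' treatment_schedule(treatment_event(12, dose = 8, A = 15.32))
#' @export
treatment_schedule <- function(...) {
  evs <- list(...)
  if (length(evs) == 1L && is.list(evs[[1L]]) &&
      !inherits(evs[[1L]], "treatment_event"))
    evs <- evs[[1L]]
  stopifnot(all(vapply(evs, inherits, TRUE, "treatment_event")))
  evs <- evs[order(vapply(evs, `[[`, 1, "day"))]
  structure(evs, class = "treatment_schedule")
}

#' Simulate tumor growth under a treatment schedule
#'
#' Integrates the enabled model piecewise between event days with an
#' adaptive stiff-capable solver ([deSolve::ode()], \code{lsoda}), with hard
#' integration breakpoints at every event. At each RT event the survival
#' fraction \eqn{S} (primary target only), ICD magnitude \eqn{I = A(1-S)}
#' and growth factor \eqn{F} are computed and \eqn{F} becomes the active
#' factor on the cancer derivative from that time onward (updated at each
#' subsequent event); at each injection event the bolus is added to
#' \eqn{M^*}. Compartments falling below the extinction threshold are
#' clamped to exactly 0 to prevent numerical resurrection.
#'
#' Two RT semantics are provided. The default \code{rt_mode = "derivative"}
#' applies \eqn{F = S - I} (primary) or \eqn{1 - I} (abscopal) as a
#' persistent factor on the cancer derivative: a persistent factor is the
#' only reading under which \eqn{I > 1} (as calibrated for knockout mice)
#' drives sustained regression. The alternative \code{rt_mode = "jump"}
#' removes the non-surviving fraction as a state jump (\eqn{C^+ = S C^-})
#' and then scales the derivative by \eqn{1 - I}.
#'
#' @param params a [model_params()] object.
#' @param rad a [radiation_params()] object (needed when the schedule has RT
#'   events).
#' @param schedule a [treatment_schedule()] (or list of events); may be
#'   empty.
#' @param init named initial state (see [engrafted_volume()]).
#' @param t_grid increasing vector of output days.
#' @param use_E,use_M,use_Mstar compartment switches; disabled compartments
#'   stay identically zero.
#' @param rt_mode \code{"derivative"} (default) or \code{"jump"}.
#' @param scale_growth_only logical, see [ce_rhs()].
#' @param obs_mode observation map, \code{"sum"} or \code{"C"}.
#' @param extinction_threshold clamp level (mm^3, default 1e-6).
#' @param rtol,atol solver tolerances (defaults 1e-8, 1e-10).
#' @return An object of class \code{trajectory}: a data.frame with columns
#'   \code{day}, \code{C}, \code{E}, \code{M}, \code{Mstar},
#'   \code{observed_volume}, with the applied events (including their
#'   realized S, I, F) in \code{attr(, "events_applied")}.
#' @examples
#' p <- model_params(c1 = 0.5, cmax = 1000)
#' tr <- simulate_tumor(p, init = engrafted_volume(5e5), t_grid = 0:20)
#' tail(tr, 3)
#' @export
simulate_tumor <- function(params, rad = radiation_params(),
                           schedule = treatment_schedule(),
                           init = engrafted_volume(5e5),
                           t_grid = 0:22,
                           use_E = TRUE, use_M = FALSE, use_Mstar = FALSE,
                           rt_mode = c("derivative", "jump"),
                           scale_growth_only = FALSE,
                           obs_mode = c("sum", "C"),
                           extinction_threshold = 1e-6,
                           rtol = 1e-8, atol = 1e-10) {
  rt_mode <- match.arg(rt_mode)
  obs_mode <- match.arg(obs_mode)
  stopifnot(inherits(params, "model_params"), inherits(rad, "radiation_params"))
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing", call. = FALSE)
  init <- .check_state(init)
  if (any(init < 0)) stop("initial state must be nonnegative", call. = FALSE)
  if (!inherits(schedule, "treatment_schedule"))
    schedule <- treatment_schedule(schedule)

  if (!use_E) init[["E"]] <- 0
  if (!use_M) init[["M"]] <- 0
  if (!use_Mstar) init[["Mstar"]] <- 0

  # parameter vector for the compiled RHS (src/rhs.c); F is slot 15
  pvec <- c(params$c1, params$cmax, params$phi_e, params$gamma_e,
            params$eta_e, params$delta_e, params$phi_m, params$gamma_m,
            params$eta_m, params$delta_m, params$phi_mstar,
            params$gamma_mstar, params$eta_mstar, params$delta_mstar,
            1, as.numeric(use_E), as.numeric(use_M), as.numeric(use_Mstar),
            as.numeric(scale_growth_only))

  ev_days <- vapply(schedule, `[[`, 1, "day")
  in_window <- ev_days <= max(t_grid)
  events <- schedule[in_window]
  ev_days <- ev_days[in_window]

  # segment boundaries: start, each event day (>= start), end
  t0 <- t_grid[1L]
  bounds <- sort(unique(c(t0, ev_days[ev_days >= t0], max(t_grid))))

  state <- init
  Fcur <- 1
  out_rows <- NULL
  applied <- list()

  integrate_segment <- function(state, from, to, Fcur) {
    seg_times <- sort(unique(c(from, t_grid[t_grid >= from & t_grid <= to], to)))
    if (length(seg_times) == 1L)
      return(matrix(c(from, state), nrow = 1,
                    dimnames = list(NULL, c("time", names(state)))))
    pvec[15] <- Fcur
    sol <- try(deSolve::ode(y = state, times = seg_times,
                            func = "icdrt_derivs", parms = pvec,
                            dllname = "icdrt", initfunc = "icdrt_initmod",
                            method = "lsoda",
                            rtol = rtol, atol = atol), silent = TRUE)
    if (inherits(sol, "try-error") ||
        attr(sol, "istate")[1L] < 0 ||
        nrow(sol) < length(seg_times))
      stop(sprintf("integration failed on [%g, %g] (active F = %g)",
                   from, to, Fcur), call. = FALSE)
    unclass(sol)
  }

  for (k in seq_len(length(bounds) - 1L)) {
    from <- bounds[k]; to <- bounds[k + 1L]
    # apply events at the segment start (events dated before the grid take
    # effect at the first segment)
    for (ev in events) {
      if (ev$day == from || (k == 1L && ev$day < from)) {
        if (ev$kind == "rt") {
          S <- survival_fraction(ev$dose, rad)
          I <- icd_value(ev$A, S)
          if (rt_mode == "jump") {
            if (ev$target == "primary") state[["C"]] <- S * state[["C"]]
            Fcur <- 1 - I
          } else {
            Fcur <- rt_growth_factor(S, I, ev$target)
          }
          applied[[length(applied) + 1L]] <-
            c(ev, list(S = S, I = I, F = Fcur))
        } else {
          state[["Mstar"]] <- state[["Mstar"]] + ev$bolus
          applied[[length(applied) + 1L]] <-
            c(ev, list(S = NA_real_, I = NA_real_, F = Fcur))
        }
      }
    }
    sol <- integrate_segment(state, from, to, Fcur)
    state <- sol[nrow(sol), c("C", "E", "M", "Mstar")]
    state[state < extinction_threshold] <- 0
    # keep rows on the requested grid; drop the segment end if it is an
    # internal breakpoint (it reappears as the next segment's start)
    rows <- sol[sol[, "time"] %in% t_grid, , drop = FALSE]
    if (k < length(bounds) - 1L)
      rows <- rows[rows[, "time"] < to, , drop = FALSE]
    out_rows <- rbind(out_rows, rows)
  }

  out <- as.data.frame(out_rows)
  names(out)[1L] <- "day"
  sm <- as.matrix(out[, c("C", "E", "M", "Mstar")])
  sm[sm < extinction_threshold & sm > 0] <- 0
  sm[sm < 0] <- 0
  out[, c("C", "E", "M", "Mstar")] <- sm
  out$observed_volume <- observed_volume(sm, mode = obs_mode)
  structure(out,
            events_applied = applied,
            obs_mode = obs_mode, rt_mode = rt_mode,
            class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  ev <- attr(x, "events_applied")
  cat(sprintf("Tumor trajectory: %d time points, day %g to %g (%d events)\n",
              nrow(x), min(x$day), max(x$day), length(ev)))
  for (e in ev) {
    if (e$kind == "rt")
      cat(sprintf("  day %g: RT %g Gy (%s)  S = %.4f, I = %.4f, F = %.4f\n",
                  e$day, e$dose, e$target, e$S, e$I, e$F))
    else
      cat(sprintf("  day %g: injection, bolus = %g\n", e$day, e$bolus))
  }
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...", nrow(x) - 4, "more rows\n")
  invisible(x)
}

#' Closed-form logistic growth
#'
#' Solution of \eqn{dC/dt = c_1 C (1 - C/c_{max})}, used as an independent
#' oracle for the numerical integrator when immune killing is disabled.
#'
#' @param t time(s) in days.
#' @param C0 initial burden.
#' @param c1 growth rate (1/day).
#' @param cmax carrying capacity.
#' @return C(t).
#' @export
logistic_solution <- function(t, C0, c1, cmax) {
  cmax * C0 * exp(c1 * t) / (cmax + C0 * (exp(c1 * t) - 1))
}
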