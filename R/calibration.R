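#' Growth dataset
#'
#' Container for observed cohort growth curves, the unit consumed by the
#' cost function, staged calibration, bootstrap and sensitivity analysis.
#' Each arm couples a treatment schedule and initial condition to per-mouse
#' (day, volume) observations; the per-arm mean curve is the default
#' residual target.
#'
#' @param arms list of arms built with [dataset_arm()].
#' @param obs_mode observation map used when predicting volumes
#'   (\code{"C"} or \code{"sum"}; see [observed_volume()]).
#' @param use_E,use_M,use_Mstar compartment switches shared by all arms.
#' @return An object of class \code{growth_dataset}.
#' @export
growth_dataset <- function(arms, obs_mode = c("C", "sum"),
                           use_E = TRUE, use_M = FALSE, use_Mstar = FALSE) {
  obs_mode <- match.arg(obs_mode)
  stopifnot(length(arms) >= 1L)
  ids <- vapply(arms, `[[`, "", "arm_id")
  if (anyDuplicated(ids)) stop("duplicate arm_id", call. = FALSE)
  names(arms) <- ids
  structure(list(arms = arms, obs_mode = obs_mode,
                 use_E = use_E, use_M = use_M, use_Mstar = use_Mstar),
            class = "growth_dataset")
}

#' Dataset arm
#'
#' @param arm_id character identifier.
#' @param init named initial state (see [engrafted_volume()]).
#' @param schedule a [treatment_schedule()] (possibly empty).
#' @param observations data.frame with columns \code{mouse_id}, \code{day},
#'   \code{volume_mm3} (a single pseudo-mouse is fine for mean curves).
#' @return arm list with a per-day summary (\code{mean}, \code{sd}, \code{n}).
#' @export
dataset_arm <- function(arm_id, init, schedule = treatment_schedule(),
                        observations) {
  stopifnot(is.character(arm_id), length(arm_id) == 1L)
  stopifnot(all(c("mouse_id", "day", "volume_mm3") %in% names(observations)))
  if (any(!is.finite(observations$day)) || any(observations$day < 0))
    stop("observation days must be finite and nonnegative", call. = FALSE)
  if (any(observations$volume_mm3 < 0))
    stop("volumes must be nonnegative", call. = FALSE)
  if (!inherits(schedule, "treatment_schedule"))
    schedule <- treatment_schedule(schedule)
  observations <- observations[order(observations$mouse_id, observations$day), ]
  sm <- do.call(rbind, lapply(split(observations, observations$day), function(d)
    data.frame(day = d$day[1L], mean = mean(d$volume_mm3),
               sd = stats::sd(d$volume_mm3), n = nrow(d))))
  sm <- sm[order(sm$day), ]
  rownames(sm) <- NULL
  ev_days <- vapply(schedule, `[[`, 1, "day")
  if (length(ev_days) && any(ev_days > max(sm$day)))
    stop("schedule references days beyond the observation window",
         call. = FALSE)
  list(arm_id = arm_id, init = .check_state(init), schedule = schedule,
       observations = observations, summary = sm)
}

#' @export
print.growth_dataset <- function(x, ...) {
  cat(sprintf("Growth dataset: %d arms (obs_mode = %s%s)\n",
              length(x$arms), x$obs_mode,
              if (x$use_Mstar) ", M* enabled" else ""))
  for (a in x$arms)
    cat(sprintf("  %-22s %d mice, %d days, %d events\n", a$arm_id,
                length(unique(a$observations$mouse_id)), nrow(a$summary),
                length(a$schedule)))
  invisible(x)
}

# names recognised as radiation parameters in a fit vector
.rad_names <- c("alpha", "beta", "lam", "tau", "beta_g")

# apply a named parameter vector to (params, rad, A_values)
.apply_theta <- function(theta, params, rad, A_values) {
  if (length(theta)) {
    stopifnot(!is.null(names(theta)))
    mp <- intersect(names(theta), names(params))
    if (length(mp)) params <- set_params(params, theta[mp])
    rp <- intersect(names(theta), .rad_names)
    for (nm in rp) rad[[nm]] <- unname(theta[[nm]])
    rest <- setdiff(names(theta), c(mp, rp))
    if (length(rest)) A_values[rest] <- theta[rest]
  }
  list(params = params, rad = rad, A_values = A_values)
}

# resolve event activations against a named A_values vector
.resolve_schedule <- function(schedule, A_values) {
  if (!length(A_values)) return(schedule)
  evs <- lapply(schedule, function(ev) {
    nm <- ev$A_name
    if (!is.null(nm) && nm %in% names(A_values)) ev$A <- unname(A_values[[nm]])
    ev
  })
  structure(evs, class = "treatment_schedule")
}

#' Attach a named activation label to an event
#'
#' Events labelled with \code{A_name} have their activation overridden by
#' matching entries of the \code{A_values} vector during fitting, so one
#' activation parameter per (dose, size-window) pair can be calibrated.
#'
#' @param event a [treatment_event()].
#' @param name character label.
#' @return the labelled event.
#' @export
label_activation <- function(event, name) {
  stopifnot(inherits(event, "treatment_event"), is.character(name))
  event$A_name <- name
  event
}

# predicted volumes at an arm's observation days
.predict_arm <- function(arm, dataset, params, rad, A_values,
                         rtol = 1e-6, atol = 1e-8, ...) {
  days <- arm$summary$day
  t_grid <- sort(unique(c(0, days)))
  sch <- .resolve_schedule(arm$schedule, A_values)
  tr <- simulate_tumor(params, rad, sch, arm$init, t_grid,
                       use_E = dataset$use_E, use_M = dataset$use_M,
                       use_Mstar = dataset$use_Mstar,
                       obs_mode = dataset$obs_mode,
                       rtol = rtol, atol = atol, ...)
  tr$observed_volume[match(days, tr$day)]
}

#' Least-squares cost of a parameter set on a growth dataset
#'
#' Sum over arms and observation days of squared residuals between the
#' per-arm mean observed volume and the model's predicted observed volume.
#' With \code{weighting = "inverse_variance"} each squared residual is
#' divided by the replicate variance at that day (where available and
#' positive).
#'
#' @param theta optional named numeric vector overriding entries of
#'   \code{params}, \code{rad} or \code{A_values} (the fit interface).
#' @param dataset a [growth_dataset()].
#' @param params a [model_params()] object.
#' @param rad a [radiation_params()] object.
#' @param A_values named vector of activation values referenced by labelled
#'   events (see [label_activation()]).
#' @param weighting \code{"none"} (default) or \code{"inverse_variance"}.
#' @param rtol,atol solver tolerances used during fitting.
#' @return nonnegative scalar cost.
#' @export
tumor_cost <- function(theta = NULL, dataset, params, rad = radiation_params(),
                       A_values = NULL, weighting = c("none", "inverse_variance"),
                       rtol = 1e-6, atol = 1e-8) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(dataset, "growth_dataset"))
  ap <- .apply_theta(theta, params, rad, A_values)
  total <- 0
  for (arm in dataset$arms) {
    pred <- tryCatch(
      .predict_arm(arm, dataset, ap$params, ap$rad, ap$A_values,
                   rtol = rtol, atol = atol),
      error = function(e) stop(sprintf("arm '%s': %s", arm$arm_id,
                                       conditionMessage(e)), call. = FALSE))
    res2 <- (arm$summary$mean - pred)^2
    if (weighting == "inverse_variance") {
      v <- arm$summary$sd^2
      w <- ifelse(is.finite(v) & v > 0, 1 / v, 1)
      res2 <- res2 * w
    }
    total <- total + sum(res2)
  }
  total
}

#' Default fitting bounds
#'
#' Literature-plausible positive ranges used by [fit_stage()] when no
#' explicit bounds are supplied. Activation parameters (any name not
#' matching a model or radiation parameter) default to \code{[0, 100]}.
#'
#' @return named list of \code{c(lower, upper)} pairs.
#' @export
default_bounds <- function() {
  list(
    c1 = c(0.01, 2), cmax = c(100, 1e4),
    phi_e = c(1e-6, 1), gamma_e = c(1e-4, 100),
    eta_e = c(1e-8, 1), delta_e = c(1e-3, 10),
    phi_m = c(1e-12, 1e-3), gamma_m = c(1e-2, 1e7),
    eta_m = c(1e-12, 1e-2), delta_m = c(1e-3, 10),
    phi_mstar = c(1e-12, 1e-3), gamma_mstar = c(1e-2, 1e7),
    eta_mstar = c(1e-12, 1e-2), delta_mstar = c(1e-3, 10),
    alpha = c(1e-4, 1), beta = c(1e-7, 0.1), beta_g = c(1e-7, 0.1),
    lam = c(1e-3, 100), tau = c(1e-3, 100)
  )
}

.bounds_for <- function(free, bounds) {
  defaults <- default_bounds()
  out <- lapply(free, function(nm) {
    if (!is.null(bounds[[nm]])) bounds[[nm]]
    else if (!is.null(defaults[[nm]])) defaults[[nm]]
    else c(0, 100)  # activation-style parameter
  })
  names(out) <- free
  out
}

#' Fit one calibration stage
#'
#' Minimizes [tumor_cost()] over the named free parameters with everything
#' else frozen, by bounded quasi-Newton search (\code{optim, L-BFGS-B}) on
#' log10-transformed parameters, restarted from \code{n_starts} seeded
#' starting points drawn log-uniformly within the bounds (the first start is
#' the box midpoint, or the current value when \code{warm_start}). The best
#' converged start wins; results are deterministic given \code{seed}.
#'
#' @param dataset a [growth_dataset()].
#' @param free character vector of parameter names to fit (may be empty).
#' @param params,rad,A_values frozen baseline values (fitted parameters
#'   start from / are bounded around these).
#' @param bounds named list overriding [default_bounds()] entries.
#' @param n_starts number of multistarts (default 20).
#' @param seed RNG seed for the multistart draws.
#' @param warm_start logical; include the baseline values as the first start.
#' @param weighting,rtol,atol passed to [tumor_cost()].
#' @return An object of class \code{fit_result}: list with \code{estimates}
#'   (named vector of the free parameters), \code{params}, \code{rad},
#'   \code{A_values} (assembled full set), \code{free}, \code{frozen},
#'   \code{cost}, \code{starts} (per-start summary), \code{seed}.
#' @export
fit_stage <- function(dataset, free, params, rad = radiation_params(),
                      A_values = NULL, bounds = list(), n_starts = 20,
                      seed = 1, warm_start = FALSE,
                      weighting = "none", rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(dataset, "growth_dataset"))
  free <- unique(free)
  base_cost <- function(th) tumor_cost(th, dataset, params, rad, A_values,
                                       weighting = weighting,
                                       rtol = rtol, atol = atol)
  if (length(free) == 0L) {
    cst <- base_cost(NULL)
    return(structure(list(estimates = stats::setNames(numeric(0), character(0)),
                          params = params, rad = rad, A_values = A_values,
                          free = character(0), frozen = names(params),
                          cost = cst, starts = data.frame(), seed = seed),
                     class = "fit_result"))
  }
  bnd <- .bounds_for(free, bounds)
  lo <- vapply(bnd, `[[`, 1, 1L)
  hi <- vapply(bnd, `[[`, 1, 2L)
  if (any(hi <= 0)) stop("upper bounds must be positive", call. = FALSE)
  lo_eff <- pmax(lo, hi * 1e-9)  # log-scale floor for zero lower bounds
  llo <- log10(lo_eff); lhi <- log10(hi)

  obj <- function(lth) {
    th <- stats::setNames(10^lth, free)
    val <- tryCatch(base_cost(th), error = function(e) NA_real_)
    if (!is.finite(val)) 1e12 else val
  }

  current <- vapply(free, function(nm) {
    v <- NA_real_
    if (nm %in% names(params)) v <- params[[nm]]
    else if (nm %in% .rad_names) v <- if (!is.null(rad[[nm]])) rad[[nm]] else NA
    else if (!is.null(A_values) && nm %in% names(A_values)) v <- A_values[[nm]]
    if (!is.finite(v) || v <= 0) NA_real_ else v
  }, 1)

  set.seed(seed)
  starts <- matrix(stats::runif(n_starts * length(free)), n_starts)
  starts <- sweep(sweep(starts, 2L, lhi - llo, `*`), 2L, llo, `+`)
  first <- if (warm_start && all(is.finite(current)))
    pmin(pmax(log10(current), llo), lhi) else (llo + lhi) / 2
  starts[1L, ] <- first

  runs <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    runs[[i]] <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = llo, upper = lhi,
                   control = list(maxit = 300, factr = 1e7)),
      error = function(e) list(value = Inf, convergence = 99L,
                               par = starts[i, ]))
  }
  vals <- vapply(runs, `[[`, 1, "value")
  conv <- vapply(runs, `[[`, 1L, "convergence")
  if (all(!is.finite(vals)))
    stop("all multistarts failed; per-start status: ",
         paste(conv, collapse = " "), call. = FALSE)
  best <- which.min(vals)
  est <- stats::setNames(10^runs[[best]]$par, free)
  ap <- .apply_theta(est, params, rad, A_values)
  structure(list(estimates = est, params = ap$params, rad = ap$rad,
                 A_values = ap$A_values, free = free,
                 frozen = setdiff(names(params), free),
                 cost = vals[best],
                 starts = data.frame(start = seq_len(n_starts), cost = vals,
                                     converged = conv == 0L),
                 seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit result: %d free parameter(s), cost = %.6g (%d/%d starts converged)\n",
              length(x$free), x$cost, sum(x$starts$converged),
              max(nrow(x$starts), 0L)))
  if (length(x$estimates)) {
    for (nm in names(x$estimates))
      cat(sprintf("  %-12s = %g\n", nm, x$estimates[[nm]]))
  }
  invisible(x)
}

#' Four-step staged calibration
#'
#' Calibrates the model in four stages of increasing complexity, freezing
#' each stage's estimates before the next:
#' \enumerate{
#'   \item baseline growth and effector parameters on wild-type (WT) data
#'     (CE model);
#'   \item treated-macrophage parameters on checkpoint-disrupted data
#'     without RT (CEM model), stage-1 values frozen;
#'   \item LQ radiosensitivity (\code{alpha}, composite \code{beta_g}) on
#'     WT + RT data, stage-1 values frozen;
#'   \item per-(dose, size-window) immune activations \code{A} on
#'     treated + RT data, all prior values frozen. Arms are fitted
#'     independently (each activation enters only its own arm).
#' }
#'
#' @param suite named list of four [growth_dataset()]s: \code{wt},
#'   \code{treated}, \code{wt_rt}, \code{treated_rt}.
#' @param params,rad baseline parameter objects (starting values; parameters
#'   never freed stay at these values).
#' @param free1,free2,free3 free parameter names per stage.
#' @param bounds named list overriding [default_bounds()].
#' @param n_starts,seed,weighting,rtol,atol passed to [fit_stage()].
#' @return An object of class \code{four_step_fit}: list with \code{stages}
#'   (four \code{fit_result}s), assembled \code{params}, \code{rad},
#'   \code{A_values}, and \code{costs}.
#' @export
run_four_step <- function(suite, params, rad = radiation_params(),
                          free1 = c("c1", "cmax"),
                          free2 = "phi_mstar",
                          free3 = c("alpha", "beta_g"),
                          bounds = list(), n_starts = 20, seed = 1,
                          weighting = "none", rtol = 1e-6, atol = 1e-8) {
  need <- c("wt", "treated", "wt_rt", "treated_rt")
  miss <- setdiff(need, names(suite))
  if (length(miss))
    stop("suite is missing condition(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  s1 <- fit_stage(suite$wt, free1, params, rad, bounds = bounds,
                  n_starts = n_starts, seed = seed, weighting = weighting,
                  rtol = rtol, atol = atol)
  s2 <- fit_stage(suite$treated, free2, s1$params, s1$rad, bounds = bounds,
                  n_starts = n_starts, seed = seed + 1L, weighting = weighting,
                  rtol = rtol, atol = atol)
  # stage 3 fits the composite beta*g directly (only the product enters S)
  rad3 <- s1$rad
  if (is.null(rad3$beta_g) && "beta_g" %in% free3)
    rad3$beta_g <- rad3$beta * repair_g(rad3$lam * rad3$tau)
  s3 <- fit_stage(suite$wt_rt, free3, s1$params, rad3, bounds = bounds,
                  n_starts = n_starts, seed = seed + 2L, weighting = weighting,
                  rtol = rtol, atol = atol)

  # stage 4: per-arm activation fits with everything else frozen
  params4 <- s2$params
  rad4 <- s3$rad
  A_hat <- numeric(0)
  arm_fits <- list()
  ds4 <- suite$treated_rt
  for (arm in ds4$arms) {
    labs <- unique(unlist(lapply(arm$schedule, function(ev) ev$A_name)))
    labs <- labs[nzchar(labs)]
    if (!length(labs)) next
    sub <- growth_dataset(list(arm), obs_mode = ds4$obs_mode,
                          use_E = ds4$use_E, use_M = ds4$use_M,
                          use_Mstar = ds4$use_Mstar)
    A0 <- stats::setNames(rep(1, length(labs)), labs)
    f <- fit_stage(sub, labs, params4, rad4, A_values = A0, bounds = bounds,
                   n_starts = max(4L, ceiling(n_starts / 4)),
                   seed = seed + 3L, weighting = weighting,
                   rtol = rtol, atol = atol)
    A_hat <- c(A_hat, f$estimates)
    arm_fits[[arm$arm_id]] <- f
  }
  s4 <- structure(list(estimates = A_hat, params = params4, rad = rad4,
                       A_values = A_hat, free = names(A_hat),
                       frozen = names(params4),
                       cost = tumor_cost(NULL, ds4, params4, rad4, A_hat,
                                         weighting = weighting,
                                         rtol = rtol, atol = atol),
                       starts = data.frame(), seed = seed + 3L,
                       arm_fits = arm_fits),
                  class = "fit_result")

  structure(list(stages = list(wt = s1, treated = s2, wt_rt = s3,
                               treated_rt = s4),
                 params = params4, rad = rad4, A_values = A_hat,
                 costs = c(wt = s1$cost, treated = s2$cost, wt_rt = s3$cost,
                           treated_rt = s4$cost)),
            class = "four_step_fit")
}

#' @export
print.four_step_fit <- function(x, ...) {
  cat("Four-step staged calibration\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  stage %-10s cost = %-12.6g  %s\n", nm, s$cost,
                paste(sprintf("%s=%.4g", names(s$estimates), s$estimates),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Profile likelihood of a parameter
#'
#' Fixes the profiled parameter at each grid value and re-optimizes the
#' remaining free parameters, giving a cost profile whose curvature measures
#' practical identifiability. The profile is summarized on a
#' Gaussian-approximation pseudo-likelihood scale,
#' \eqn{\Delta = (n/2)\,[\log SSR(p) - \log SSR_{min}]}, and classified
#' \code{"flat"} (practically unidentifiable) when the maximal rise stays
#' below \code{threshold} (default 3.84/2, the 95 percent chi-squared
#' quantile with one degree of freedom, halved -- a documented heuristic).
#'
#' @param param_name parameter to profile.
#' @param grid numeric grid of values for the profiled parameter.
#' @param dataset a [growth_dataset()].
#' @param free other parameters re-optimized at each grid value (may be
#'   empty).
#' @param params,rad,A_values baseline values.
#' @param bounds,n_starts,seed,weighting,rtol,atol passed to [fit_stage()].
#' @param threshold pseudo-likelihood rise separating flat from curved.
#' @return An object of class \code{profile_likelihood}: data.frame
#'   (\code{value}, \code{cost}, \code{rise}) with attributes
#'   \code{classification} ("flat" or "curved") and \code{threshold}.
#' @export
profile_likelihood <- function(param_name, grid, dataset, free = character(0),
                               params, rad = radiation_params(),
                               A_values = NULL, bounds = list(),
                               n_starts = 4, seed = 1, weighting = "none",
                               threshold = 3.84 / 2,
                               rtol = 1e-6, atol = 1e-8) {
  stopifnot(length(grid) >= 2L, all(grid > 0) || all(grid >= 0))
  free <- setdiff(free, param_name)
  costs <- numeric(length(grid))
  n_obs <- sum(vapply(dataset$arms, function(a) nrow(a$summary), 1L))
  for (i in seq_along(grid)) {
    th0 <- stats::setNames(grid[i], param_name)
    ap <- .apply_theta(th0, params, rad, A_values)
    f <- fit_stage(dataset, free, ap$params, ap$rad, ap$A_values,
                   bounds = bounds, n_starts = n_starts, seed = seed,
                   warm_start = i > 1L, weighting = weighting,
                   rtol = rtol, atol = atol)
    costs[i] <- f$cost
    # warm-start the next grid point from this re-optimum
    if (length(free)) {
      params <- f$params; rad <- f$rad; A_values <- f$A_values
    }
  }
  eps <- 1e-12
  rise <- (n_obs / 2) * (log(pmax(costs, eps)) - log(max(min(costs), eps)))
  cls <- if (max(rise) < threshold) "flat" else "curved"
  structure(data.frame(value = grid, cost = costs, rise = rise),
            classification = cls, threshold = threshold,
            param = param_name,
            class = c("profile_likelihood", "data.frame"))
}

#' @export
print.profile_likelihood <- function(x, ...) {
  cat(sprintf("Profile likelihood of '%s': %s (max rise %.3g, threshold %.3g)\n",
              attr(x, "param"), attr(x, "classification"),
              max(x$rise), attr(x, "threshold")))
  print.data.frame(x)
  invisible(x)
}
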