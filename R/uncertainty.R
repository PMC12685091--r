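# stacked (optionally weighted) residual vector over arms
.arm_residuals <- function(theta, dataset, params, rad, A_values,
                           weighting = "none", rtol = 1e-6, atol = 1e-8) {
  ap <- .apply_theta(theta, params, rad, A_values)
  unlist(lapply(dataset$arms, function(arm) {
    pred <- .predict_arm(arm, dataset, ap$params, ap$rad, ap$A_values,
                         rtol = rtol, atol = atol)
    r <- arm$summary$mean - pred
    if (weighting == "inverse_variance") {
      v <- arm$summary$sd^2
      r <- r * ifelse(is.finite(v) & v > 0, 1 / sqrt(v), 1)
    }
    r
  }), use.names = FALSE)
}

# warm-started bounded Levenberg-Marquardt refit on log10 parameters; the
# fast path for bootstrap replicates (deterministic, no multistart)
.fit_lm <- function(dataset, free, params, rad, A_values, start,
                    bounds = list(), weighting = "none",
                    rtol = 1e-6, atol = 1e-8, maxiter = 60) {
  bnd <- .bounds_for(free, bounds)
  lo <- vapply(bnd, `[[`, 1, 1L); hi <- vapply(bnd, `[[`, 1, 2L)
  lo_eff <- pmax(lo, hi * 1e-9)
  lpar <- pmin(pmax(log10(pmax(start[free], lo_eff)), log10(lo_eff)),
               log10(hi))
  n_obs <- sum(vapply(dataset$arms, function(a) nrow(a$summary), 1L))
  fn <- function(lp) {
    th <- stats::setNames(10^lp, free)
    r <- tryCatch(.arm_residuals(th, dataset, params, rad, A_values,
                                 weighting, rtol, atol),
                  error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) rep(1e6, n_obs)
    else r
  }
  sol <- minpack.lm::nls.lm(par = lpar, lower = log10(lo_eff),
                            upper = log10(hi), fn = fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter))
  est <- stats::setNames(10^sol$par, free)
  list(estimates = est, cost = sol$deviance,
       converged = sol$info %in% 1:4)
}

#' Bootstrap uncertainty of calibrated parameters
#'
#' Quantifies parameter uncertainty by refitting a stage's free parameters
#' to perturbed copies of the dataset. The default \code{mode = "parametric"}
#' draws each replicate observation from a Poisson law centered on the
#' best-fit model prediction at that day (the prediction, in counts of
#' \code{volume_scale} per mm^3, is rounded to the nearest nonnegative
#' integer before the draw); \code{mode = "resample"} draws each arm's time
#' points with replacement; \code{mode = "exact"} is a degenerate test mode
#' that uses the predictions verbatim. Each replicate is refitted
#' warm-started from the best fit, with one fallback multistart when the
#' warm fit fails to converge. Deterministic given \code{seed}.
#'
#' @param dataset the [growth_dataset()] the fit was obtained on.
#' @param free names of the stage's free parameters to refit.
#' @param params,rad,A_values best-fit parameter set (refits start here).
#' @param n number of bootstrap replicates.
#' @param seed RNG seed.
#' @param mode \code{"parametric"}, \code{"resample"} or \code{"exact"}.
#' @param volume_scale Poisson counts per mm^3 (parametric mode).
#' @param bounds,weighting,rtol,atol passed to [fit_stage()].
#' @param probs percentile-interval probabilities for the summary.
#' @return An object of class \code{bootstrap_result}: list with
#'   \code{replicates} (n x p matrix), \code{summary} (mean, sd and
#'   percentiles per parameter), \code{n}, \code{n_failed}, \code{seed},
#'   \code{mode}.
#' @export
bootstrap_params <- function(dataset, free, params, rad = radiation_params(),
                             A_values = NULL, n = 200, seed = 1,
                             mode = c("parametric", "resample", "exact"),
                             volume_scale = 1, bounds = list(),
                             weighting = "none",
                             probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                             rtol = 1e-6, atol = 1e-8) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "growth_dataset"), n >= 1, length(free) >= 1)
  # per-arm best-fit predictions at the observation days
  preds <- lapply(dataset$arms, function(arm)
    .predict_arm(arm, dataset, params, rad, A_values, rtol = rtol, atol = atol))
  set.seed(seed)
  reps <- matrix(NA_real_, n, length(free),
                 dimnames = list(NULL, free))
  n_failed <- 0L
  for (r in seq_len(n)) {
    arms_r <- dataset$arms
    for (i in seq_along(arms_r)) {
      sm <- arms_r[[i]]$summary
      if (mode == "parametric") {
        lam <- pmax(round(preds[[i]] * volume_scale), 0)
        sm$mean <- stats::rpois(length(lam), lam) / volume_scale
      } else if (mode == "resample") {
        idx <- sample.int(nrow(sm), nrow(sm), replace = TRUE)
        sm <- sm[idx, , drop = FALSE]
      } else {
        sm$mean <- preds[[i]]
      }
      arms_r[[i]]$summary <- sm
    }
    ds_r <- dataset
    ds_r$arms <- arms_r
    start <- vapply(free, function(nm) {
      if (nm %in% names(params)) params[[nm]]
      else if (nm %in% .rad_names) rad[[nm]]
      else unname(A_values[[nm]])
    }, 1)
    f <- tryCatch(
      .fit_lm(ds_r, free, params, rad, A_values, start = start,
              bounds = bounds, weighting = weighting,
              rtol = rtol, atol = atol),
      error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      # fallback multistart via the general stage fitter
      f2 <- tryCatch(
        fit_stage(ds_r, free, params, rad, A_values, bounds = bounds,
                  n_starts = 2, seed = seed + r, warm_start = TRUE,
                  weighting = weighting, rtol = rtol, atol = atol),
        error = function(e) NULL)
      if (!is.null(f2) && (is.null(f) || f2$cost < f$cost)) f <- f2
    }
    if (is.null(f)) n_failed <- n_failed + 1L
    else reps[r, ] <- f$estimates[free]
  }
  if (n_failed > 0.2 * n)
    stop(sprintf("bootstrap: %d of %d replicate fits failed", n_failed, n),
         call. = FALSE)
  if (n_failed > 0L)
    warning(sprintf("bootstrap: %d replicate fit(s) failed and were excluded",
                    n_failed))
  ok <- stats::complete.cases(reps)
  qs <- t(apply(reps[ok, , drop = FALSE], 2L, stats::quantile, probs = probs))
  summary <- data.frame(parameter = free,
                        mean = colMeans(reps[ok, , drop = FALSE]),
                        sd = apply(reps[ok, , drop = FALSE], 2L, stats::sd),
                        qs, check.names = FALSE, row.names = NULL)
  names(summary)[-(1:3)] <- paste0("q", probs * 100)
  structure(list(replicates = reps, summary = summary, n = n,
                 n_failed = n_failed, seed = seed, mode = mode),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap (%s): %d replicates (%d failed), seed %d\n",
              x$mode, x$n, x$n_failed, x$seed))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Local sensitivity ranking of parameters
#'
#' Perturbs each parameter independently by \code{delta} (default 25
#' percent) of its current value in both directions and measures the mean
#' relative change of the least-squares cost,
#' \deqn{s_p = \mathrm{mean}_{\pm\delta}\; |cost(p(1\pm\delta)) - cost(p)| /
#'   \max(cost(p), \epsilon),}
#' ranking parameters from most to least influential. Parameters with no
#' pathway into the observed volume (e.g. a disabled compartment's rates)
#' have index exactly 0.
#'
#' @param parameters names of parameters to rank (model, radiation or
#'   activation names).
#' @param dataset a [growth_dataset()].
#' @param params,rad,A_values the best-fit parameter set.
#' @param delta perturbation fraction (default 0.25).
#' @param eps floor for the relative-change denominator.
#' @param weighting,rtol,atol passed to [tumor_cost()].
#' @return An object of class \code{sensitivity_report}: data.frame
#'   (\code{parameter}, \code{index}) sorted by decreasing index.
#' @export
sensitivity_rank <- function(parameters, dataset, params,
                             rad = radiation_params(), A_values = NULL,
                             delta = 0.25, eps = 1e-10,
                             weighting = "none", rtol = 1e-6, atol = 1e-8) {
  stopifnot(delta > 0, length(parameters) >= 1)
  base <- tumor_cost(NULL, dataset, params, rad, A_values,
                     weighting = weighting, rtol = rtol, atol = atol)
  denom <- max(base, eps)
  idx <- vapply(parameters, function(nm) {
    v <- if (nm %in% names(params)) params[[nm]]
         else if (nm %in% .rad_names) rad[[nm]]
         else A_values[[nm]]
    if (is.null(v)) stop("unknown parameter: ", nm, call. = FALSE)
    ch <- vapply(c(1 + delta, 1 - delta), function(f) {
      val <- tryCatch(
        tumor_cost(stats::setNames(v * f, nm), dataset, params, rad, A_values,
                   weighting = weighting, rtol = rtol, atol = atol),
        error = function(e) NA_real_)
      if (!is.finite(val)) {
        warning(sprintf("perturbation of '%s' failed; index set to Inf", nm))
        return(Inf)
      }
      abs(val - base) / denom
    }, 1)
    mean(ch)
  }, 1)
  out <- data.frame(parameter = parameters, index = unname(idx))
  out <- out[order(-out$index), ]
  rownames(out) <- NULL
  structure(out, class = c("sensitivity_report", "data.frame"))
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Local sensitivity ranking (%d parameters)\n", nrow(x)))
  print.data.frame(x, digits = 4)
  invisible(x)
}
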