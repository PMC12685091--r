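#' Default generating truth for synthetic cohorts
#'
#' The parameter set used by [four_condition_suite()]. Magnitudes mirror the
#' reference MC38 calibration: logistic growth from a 5e5-cell engraftment
#' (0.5 mm^3) reaching roughly 100 mm^3 by day 8 and 400-600 mm^3 by day 14;
#' LQ radiosensitivity whose damage fractions at 4/8/15 Gy match those
#' implied by the bundled anchor table (about 0.04, 0.08, 0.15); treated
#' macrophage phagocytosis at the 1e-8 per-cell scale with the M* compartment
#' carried in cell-equivalent abundance; and per-(day, dose) activations
#' taken from the SIRPa-knockout anchor block. Observed volume is the cancer
#' compartment (cell-equivalent immune abundances are not volume-additive).
#'
#' @return list with \code{params} ([model_params()]), \code{rad}
#'   ([radiation_params()]), \code{A_table} (data.frame day, dose_Gy, A,
#'   A_name), and \code{obs_mode}.
#' @export
default_truth <- function() {
  params <- model_params(
    c1 = 0.7, cmax = 2500,
    phi_e = 0.01, gamma_e = 1, eta_e = 1e-3, delta_e = 0.1,
    phi_mstar = 4.43e-8, gamma_mstar = 1e6, eta_mstar = 1e-2,
    delta_mstar = 0.15
  )
  rad <- radiation_params(alpha = 0.01, beta = 1e-4, lam = 1, tau = 1)
  ko <- subset(mc38_anchors(), model == "SIRPa-KO")
  A_table <- data.frame(day = ko$day, dose_Gy = ko$dose_Gy, A = ko$A,
                        A_name = sprintf("A_d%d_%gGy", ko$day, ko$dose_Gy))
  list(params = params, rad = rad, A_table = A_table, obs_mode = "C")
}

#' Generate a synthetic growth cohort
#'
#' Simulates each arm's trajectory under the truth parameters and samples
#' per-mouse observations from Poisson laws centered on the predicted volume
#' at each observation day (\code{noise = "poisson"}; the volume is scaled
#' by \code{volume_scale} counts per mm^3 before drawing and scaled back),
#' or returns the predictions verbatim (\code{noise = "none"}). Deterministic
#' given \code{seed}.
#'
#' @param arms list of arm specs: each a list with \code{arm_id},
#'   \code{cells} (engrafted cell count) or \code{init} (named state),
#'   \code{schedule} ([treatment_schedule()]), \code{days} (observation
#'   days), and optional \code{n_mice} (default \code{n_mice} argument).
#' @param params,rad truth parameters.
#' @param noise \code{"poisson"} or \code{"none"}.
#' @param n_mice default mice per arm.
#' @param volume_scale Poisson counts per mm^3 (default 1).
#' @param seed RNG seed.
#' @param obs_mode,use_E,use_M,use_Mstar passed to the simulator and stored
#'   on the dataset.
#' @return a [growth_dataset()].
#' @export
generate_cohort <- function(arms, params, rad = radiation_params(),
                            noise = c("poisson", "none"), n_mice = 8,
                            volume_scale = 1, seed = 1,
                            obs_mode = c("C", "sum"),
                            use_E = TRUE, use_M = FALSE, use_Mstar = FALSE) {
  noise <- match.arg(noise)
  obs_mode <- match.arg(obs_mode)
  stopifnot(volume_scale > 0, n_mice >= 1)
  set.seed(seed)
  built <- lapply(arms, function(a) {
    stopifnot(!is.null(a$arm_id), !is.null(a$days))
    init <- if (!is.null(a$init)) a$init
            else engrafted_volume(a$cells, kappa = params$kappa)
    sch <- if (is.null(a$schedule)) treatment_schedule() else a$schedule
    days <- sort(unique(a$days))
    nm <- if (is.null(a$n_mice)) n_mice else a$n_mice
    t_grid <- sort(unique(c(0, days)))
    tr <- simulate_tumor(params, rad, sch, init, t_grid,
                         use_E = use_E, use_M = use_M, use_Mstar = use_Mstar,
                         obs_mode = obs_mode)
    pred <- tr$observed_volume[match(days, tr$day)]
    if (noise == "none") {
      obs <- data.frame(mouse_id = "mean", day = days, volume_mm3 = pred)
    } else {
      lam <- pmax(round(pred * volume_scale), 0)
      draws <- stats::rpois(nm * length(days), rep(lam, each = nm)) / volume_scale
      obs <- data.frame(mouse_id = rep(sprintf("m%02d", seq_len(nm)),
                                       times = length(days)),
                        day = rep(days, each = nm),
                        volume_mm3 = draws)
    }
    dataset_arm(a$arm_id, init, sch, obs)
  })
  growth_dataset(built, obs_mode = obs_mode,
                 use_E = use_E, use_M = use_M, use_Mstar = use_Mstar)
}

#' Four-condition synthetic calibration suite
#'
#' Emits the four datasets the staged calibration expects, generated from
#' one truth set ([default_truth()] unless overridden):
#' \describe{
#'   \item{wt}{untreated wild-type growth, engraftments 5e4 and 5e5 cells
#'     (CE model).}
#'   \item{treated}{checkpoint-disrupted hosts without RT, engraftments 5e3
#'     and 5e5 cells (the small engraftment exposes phagocytosis).}
#'   \item{wt_rt}{wild-type with a single RT fraction: doses 4/8/15 Gy
#'     crossed with treatment days 8/12/14 (A = 0, so F = S).}
#'   \item{treated_rt}{checkpoint-disrupted with RT, same dose-day grid,
#'     each arm's activation taken from the truth table and labelled for
#'     stage-4 fitting.}
#' }
#' Observation days are 6 to 20 every 2 days; observations are per-mouse
#' Poisson draws centered on the model predictions.
#'
#' @param seed RNG seed (arms use derived sub-seeds; the suite is
#'   deterministic given this one integer).
#' @param n_mice mice per arm (default 8).
#' @param noise \code{"poisson"} (default) or \code{"none"}.
#' @param truth truth set as returned by [default_truth()].
#' @param days observation days.
#' @return named list \code{wt}, \code{treated}, \code{wt_rt},
#'   \code{treated_rt} of [growth_dataset()]s, plus \code{truth}.
#' @export
four_condition_suite <- function(seed = 1, n_mice = 8,
                                 noise = c("poisson", "none"),
                                 truth = default_truth(),
                                 days = seq(6, 20, by = 2)) {
  noise <- match.arg(noise)
  params <- truth$params
  rad <- truth$rad
  At <- truth$A_table

  wt_arms <- list(
    list(arm_id = "wt_5e5", cells = 5e5, days = days),
    list(arm_id = "wt_5e4", cells = 5e4, days = days)
  )
  treated_arms <- list(
    list(arm_id = "ko_5e5", cells = 5e5, days = days),
    list(arm_id = "ko_5e3", cells = 5e3, days = days)
  )
  grid <- expand.grid(day = c(8, 12, 14), dose = c(4, 8, 15))
  wt_rt_arms <- lapply(seq_len(nrow(grid)), function(i) {
    d <- grid$day[i]; g <- grid$dose[i]
    list(arm_id = sprintf("wtrt_d%d_%gGy", d, g), cells = 5e5,
         schedule = treatment_schedule(treatment_event(d, dose = g, A = 0)),
         days = days)
  })
  treated_rt_arms <- lapply(seq_len(nrow(grid)), function(i) {
    d <- grid$day[i]; g <- grid$dose[i]
    A <- At$A[At$day == d & At$dose_Gy == g]
    ev <- label_activation(treatment_event(d, dose = g, A = A),
                           sprintf("A_d%d_%gGy", d, g))
    list(arm_id = sprintf("kort_d%d_%gGy", d, g), cells = 5e5,
         schedule = treatment_schedule(ev), days = days)
  })

  list(
    wt = generate_cohort(wt_arms, params, rad, noise, n_mice,
                         seed = seed, obs_mode = truth$obs_mode),
    treated = generate_cohort(treated_arms, params, rad, noise, n_mice,
                              seed = seed + 1000L, obs_mode = truth$obs_mode,
                              use_Mstar = TRUE),
    wt_rt = generate_cohort(wt_rt_arms, params, rad, noise, n_mice,
                            seed = seed + 2000L, obs_mode = truth$obs_mode),
    treated_rt = generate_cohort(treated_rt_arms, params, rad, noise, n_mice,
                                 seed = seed + 3000L,
                                 obs_mode = truth$obs_mode, use_Mstar = TRUE),
    truth = truth
  )
}
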