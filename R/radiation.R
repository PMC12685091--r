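#' Radiation (linear-quadratic) parameters
#'
#' Container for the radiosensitivity parameters of the linear-quadratic
#' survival model with sublethal-damage repair,
#' \deqn{S = \exp(-\alpha d - \beta d^2 g(\lambda\tau)).}
#'
#' Only the product \eqn{\beta g(\lambda\tau)} enters the survival fraction,
#' so \code{lam} and \code{tau} are practically non-identifiable separately
#' from \code{beta} in growth-curve data; supply either \code{(lam, tau)} or
#' the composite \code{beta_g} directly (then \code{beta} is ignored).
#'
#' @param alpha direct-damage radiosensitivity (1/Gy, >= 0).
#' @param beta quadratic-damage radiosensitivity (1/Gy^2, >= 0).
#' @param lam sublethal-damage repair rate (1/time, > 0).
#' @param tau radiotherapy delivery time (same time unit as \code{lam}, > 0).
#' @param beta_g optional composite \eqn{\beta g(\lambda\tau)} (1/Gy^2); when
#'   given it overrides \code{beta * repair_g(lam * tau)}.
#' @param resistance_scale multiplier \eqn{\rho \in (0, 1]} applied to both
#'   alpha and beta for radio-resistance scenarios (1 = nominal sensitivity).
#'
#' @return An object of class \code{radiation_params}.
#' @examples
#' rad <- radiation_params(alpha = 0.01, beta = 1e-4, lam = 1, tau = 1)
#' survival_fraction(8, rad)
#' @export
radiation_params <- function(alpha = 0.01, beta = 1e-4, lam = 1, tau = 1,
                             beta_g = NULL, resistance_scale = 1) {
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha >= 0,
    is.numeric(beta), length(beta) == 1L, is.finite(beta), beta >= 0,
    is.numeric(lam), length(lam) == 1L, lam > 0,
    is.numeric(tau), length(tau) == 1L, tau > 0,
    is.numeric(resistance_scale), length(resistance_scale) == 1L,
    resistance_scale > 0, resistance_scale <= 1
  )
  if (!is.null(beta_g)) {
    stopifnot(is.numeric(beta_g), length(beta_g) == 1L, beta_g >= 0)
  }
  structure(
    list(alpha = alpha, beta = beta, lam = lam, tau = tau,
         beta_g = beta_g, resistance_scale = resistance_scale),
    class = "radiation_params"
  )
}

#' @export
print.radiation_params <- function(x, ...) {
  cat("Linear-quadratic radiation parameters\n")
  cat(sprintf("  alpha = %g /Gy, beta = %g /Gy^2\n", x$alpha, x$beta))
  if (is.null(x$beta_g)) {
    cat(sprintf("  repair: lam = %g, tau = %g  (g = %.4f, beta*g = %g)\n",
                x$lam, x$tau, repair_g(x$lam * x$tau),
                x$beta * repair_g(x$lam * x$tau)))
  } else {
    cat(sprintf("  composite beta*g = %g (lam, tau unused)\n", x$beta_g))
  }
  if (x$resistance_scale < 1)
    cat(sprintf("  radio-resistance scale rho = %g\n", x$resistance_scale))
  invisible(x)
}

#' Sublethal-damage repair function
#'
#' \eqn{g(x) = 2 (x + e^{-x} - 1) / x^2} with \eqn{x = \lambda\tau}, the
#' Lea-Catcheside-type correction for repair of sublethal damage during a
#' finite delivery time. Continuous at 0 with \eqn{g(0) = 1}, strictly
#' decreasing, and asymptotically \eqn{2/x} for large \eqn{x}.
#'
#' @param lam_tau nonnegative numeric vector, the dimensionless product
#'   \eqn{\lambda\tau}.
#' @return numeric vector in (0, 1].
#' @examples
#' repair_g(0)    # 1
#' repair_g(1)    # 2 / e
#' @export
repair_g <- function(lam_tau) {
  if (!is.numeric(lam_tau) || any(!is.finite(lam_tau)) || any(lam_tau < 0))
    stop("lam_tau must be finite and nonnegative", call. = FALSE)
  out <- numeric(length(lam_tau))
  small <- lam_tau < 1e-4
  # second-order Taylor branch avoids catastrophic cancellation near 0
  x <- lam_tau[small]
  out[small] <- 1 - x / 3 + x^2 / 12
  x <- lam_tau[!small]
  out[!small] <- 2 * (x + exp(-x) - 1) / x^2
  out
}

#' Linear-quadratic survival fraction
#'
#' Fraction of tumor cells surviving a single radiation dose,
#' \eqn{S = \exp(-\rho\alpha d - \rho\beta d^2 g(\lambda\tau))}, where
#' \eqn{\rho} is the optional radio-resistance scale.
#'
#' @param dose radiation dose in Gy (nonnegative numeric vector).
#' @param rad a [radiation_params()] object.
#' @return survival fraction(s) in (0, 1]; \code{S(0) = 1}.
#' @examples
#' rad <- radiation_params(alpha = 0.1, beta = 0.01, lam = 1e-6, tau = 1)
#' survival_fraction(2, rad)  # ~ exp(-0.24)
#' @export
survival_fraction <- function(dose, rad) {
  stopifnot(inherits(rad, "radiation_params"))
  if (!is.numeric(dose) || any(!is.finite(dose)) || any(dose < 0))
    stop("dose must be finite and nonnegative (Gy)", call. = FALSE)
  bg <- if (is.null(rad$beta_g)) rad$beta * repair_g(rad$lam * rad$tau) else rad$beta_g
  rho <- rad$resistance_scale
  exp(-rho * rad$alpha * dose - rho * bg * dose^2)
}

#' Immunogenic cell death magnitude
#'
#' ICD is proportional to the radiation-induced damage fraction:
#' \eqn{I = A (1 - S)}, where \eqn{A} is the immune activation parameter and
#' \eqn{S} the LQ survival fraction. With wild-type macrophages \eqn{A = 0}
#' and ICD vanishes at every dose.
#'
#' @param A immune activation (dimensionless, >= 0).
#' @param S survival fraction in (0, 1].
#' @return \eqn{I = A(1-S) \ge 0}.
#' @examples
#' icd_value(34.88, 1 - 1.44 / 34.88)
#' @export
icd_value <- function(A, S) {
  if (!is.numeric(A) || any(!is.finite(A)) || any(A < 0))
    stop("A must be finite and nonnegative", call. = FALSE)
  if (!is.numeric(S) || any(!is.finite(S)) || any(S <= 0) || any(S > 1))
    stop("S must lie in (0, 1]", call. = FALSE)
  A * (1 - S)
}

#' Post-radiation growth factor
#'
#' The factor applied to the cancer-cell time derivative from an RT event
#' onward. For the irradiated (primary) tumor
#' \eqn{dC/dt^+ = S\,dC/dt^- - I\,dC/dt^-}, i.e. \eqn{F = S - I}; the
#' non-irradiated (abscopal) tumor receives no direct dose, so
#' \eqn{F = 1 - I} with the same ICD magnitude as the primary. \eqn{F < 0}
#' means sustained regression.
#'
#' @param S survival fraction in (0, 1].
#' @param I ICD magnitude (>= 0).
#' @param target \code{"primary"} or \code{"abscopal"}.
#' @return dimensionless growth factor (may be negative).
#' @examples
#' rt_growth_factor(0.92, 1.76, "primary")   # -0.84
#' rt_growth_factor(0.92, 1.76, "abscopal")  # -0.76
#' @export
rt_growth_factor <- function(S, I, target = c("primary", "abscopal")) {
  target <- match.arg(target)
  if (!is.numeric(S) || any(S <= 0) || any(S > 1))
    stop("S must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(I) || any(!is.finite(I)) || any(I < 0))
    stop("I must be finite and nonnegative", call. = FALSE)
  if (target == "primary") S - I else 1 - I
}
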