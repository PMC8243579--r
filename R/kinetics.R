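# Closed-form expression profiles for IEG-coupled fluorophore kinetics.
#
# The underlying scheme is a consecutive first-order reaction
#   mRNA --kf--> protein --kd--> degraded protein
# with fluorescence proportional to the protein pool, so a single
# activation event at t = 0 produces a difference of two exponentials.

#' Parameters of the single-activation expression profile
#'
#' Bundles the amplitude and rate constants of the consecutive first-order
#' kinetics model for one activation event. Fluorescence is measured in
#' arbitrary detector units (D.U.) and time in minutes.
#'
#' @param amplitude Fluorescence scale in D.U.; must be non-negative.
#' @param kf Formation (protein synthesis) rate constant, min^-1; > 0.
#' @param kd Degradation rate constant, min^-1; > 0. `kf == kd` is allowed
#'   and handled by the analytic equal-rate limit.
#' @return An object of class `kinetic_params`.
#' @seealso [sac_value()], [time_to_peak()], [dual_activation_params()]
#' @export
#' @examples
#' p <- kinetic_params(amplitude = 1000, kf = 0.0369, kd = 0.0062)
#' sac_value(c(0, 30, 60, 120), p)
kinetic_params <- function(amplitude, kf, kd) {
  check_scalar_finite(amplitude, "amplitude")
  check_scalar_finite(kf, "kf")
  check_scalar_finite(kd, "kd")
  if (amplitude < 0) stop("'amplitude' must be >= 0", call. = FALSE)
  if (kf <= 0 || kd <= 0) stop("rate constants 'kf' and 'kd' must be > 0", call. = FALSE)
  structure(list(amplitude = amplitude, kf = kf, kd = kd),
            class = "kinetic_params")
}

#' Parameters of the double-activation expression profile
#'
#' A second activation event at time `td` re-triggers the same expression
#' machinery, so both events share `amplitude`, `kf` and `kd`; only the
#' event time `td` is additional.
#'
#' @inheritParams kinetic_params
#' @param td Time of the second activation event, minutes; >= 0.
#' @return An object of class `dual_activation_params` (inherits
#'   `kinetic_params`).
#' @export
dual_activation_params <- function(amplitude, kf, kd, td) {
  p <- kinetic_params(amplitude, kf, kd)
  check_scalar_finite(td, "td")
  if (td < 0) stop("'td' must be >= 0", call. = FALSE)
  p$td <- td
  class(p) <- c("dual_activation_params", "kinetic_params")
  p
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(if (inherits(x, "dual_activation_params")) "Double" else "Single",
      "activation kinetic parameters\n")
  cat(sprintf("  amplitude: %g D.U.\n  kf: %g /min  (rise time %.3g min)\n  kd: %g /min  (decay time %.3g min)\n",
              x$amplitude, x$kf, 1 / x$kf, x$kd, 1 / x$kd))
  if (!is.null(x$td)) cat(sprintf("  td: %g min\n", x$td))
  invisible(x)
}

# relative tolerance below which kf and kd are treated as equal
.rate_degeneracy_tol <- 1e-9

#' Are two rate constants numerically degenerate?
#'
#' The dual-exponential profile suffers catastrophic cancellation as
#' `kf -> kd`; below this relative tolerance the analytic equal-rate limit
#' is used instead.
#'
#' @param kf,kd Rate constants, min^-1.
#' @return Logical.
#' @keywords internal
rates_degenerate <- function(kf, kd) {
  abs(kf - kd) < .rate_degeneracy_tol * pmax(kf, kd)
}

#' Single-activation fluorescence profile
#'
#' Evaluates the protein-pool fluorescence following one activation event at
#' t = 0 under consecutive first-order kinetics:
#' \deqn{F_1(t) = A \frac{k_f}{k_f - k_d}\left(e^{-k_d t} - e^{-k_f t}\right)}
#' with the analytic limit \eqn{A k_f t e^{-k_f t}} when the rates are
#' numerically equal.
#'
#' @param t Time(s) since the activation event, minutes; non-negative.
#' @param p A [kinetic_params()] object (a plain named list with fields
#'   `amplitude`, `kf`, `kd` is also accepted).
#' @return Fluorescence value(s) in D.U., same length as `t`; always
#'   non-negative and finite.
#' @export
#' @examples
#' p <- kinetic_params(1, 0.1, 0.02)
#' sac_value(time_to_peak(p), p)  # peak of the curve
sac_value <- function(t, p) {
  check_times(t)
  p <- as_kinetic_params(p)
  sac_value_raw(t, p$amplitude, p$kf, p$kd)
}

# unchecked core used by fitting code (t may be a shifted grid)
sac_value_raw <- function(t, amplitude, kf, kd) {
  if (rates_degenerate(kf, kd)) {
    v <- amplitude * kf * t * exp(-kf * t)
  } else {
    v <- amplitude * kf / (kf - kd) * (exp(-kd * t) - exp(-kf * t))
  }
  # exact zero at t = 0 and guard against tiny negative round-off
  pmax(v, 0)
}

#' Double-activation fluorescence profile
#'
#' Superposition of two single-activation profiles sharing amplitude and
#' rate constants; the second event occurs at `td` and contributes nothing
#' before it:
#' \deqn{F_2(t) = F_1(t) + [t \ge t_d]\, F_1(t - t_d)}
#'
#' @param t Time(s) in minutes, laboratory time with t = 0 at the first
#'   activation event.
#' @param p A [dual_activation_params()] object.
#' @return Fluorescence value(s) in D.U.
#' @export
dac_value <- function(t, p) {
  check_times(t)
  p <- as_dual_params(p)
  dac_value_raw(t, p$amplitude, p$kf, p$kd, p$td)
}

dac_value_raw <- function(t, amplitude, kf, kd, td) {
  v <- sac_value_raw(t, amplitude, kf, kd)
  after <- t >= td
  if (any(after)) {
    v[after] <- v[after] + sac_value_raw(t[after] - td, amplitude, kf, kd)
  }
  v
}

#' Time to maximal response
#'
#' Time at which the single-activation profile peaks, obtained by setting
#' its first derivative to zero:
#' \deqn{T_{max} = \frac{\ln(k_f / k_d)}{k_f - k_d}}
#' reducing to \eqn{1/k_f} when the rates are equal. The expression is
#' symmetric under exchange of the two rates.
#'
#' @param p A [kinetic_params()] object.
#' @return Peak time in minutes, strictly positive.
#' @export
time_to_peak <- function(p) {
  p <- as_kinetic_params(p)
  if (rates_degenerate(p$kf, p$kd)) return(1 / p$kf)
  log(p$kf / p$kd) / (p$kf - p$kd)
}

#' Characteristic rise and decay times
#'
#' The reciprocal rate constants: rise time `1/kf` and decay time `1/kd`,
#' in minutes.
#'
#' @param p A [kinetic_params()] object.
#' @return Named numeric vector `c(rise = 1/kf, decay = 1/kd)`.
#' @export
characteristic_times <- function(p) {
  p <- as_kinetic_params(p)
  c(rise = 1 / p$kf, decay = 1 / p$kd)
}

# ---- internal validation helpers -------------------------------------------

as_kinetic_params <- function(p) {
  if (inherits(p, "kinetic_params")) return(p)
  if (is.list(p) && all(c("amplitude", "kf", "kd") %in% names(p))) {
    return(kinetic_params(p$amplitude, p$kf, p$kd))
  }
  stop("'p' must be a kinetic_params object or a named list with fields ",
       "amplitude, kf, kd", call. = FALSE)
}

as_dual_params <- function(p) {
  if (inherits(p, "dual_activation_params")) return(p)
  if (is.list(p) && all(c("amplitude", "kf", "kd", "td") %in% names(p))) {
    return(dual_activation_params(p$amplitude, p$kf, p$kd, p$td))
  }
  stop("'p' must be a dual_activation_params object or a named list with ",
       "fields amplitude, kf, kd, td", call. = FALSE)
}

check_times <- function(t) {
  if (!is.numeric(t) || length(t) == 0 || any(!is.finite(t))) {
    stop("time 't' must be finite numeric", call. = FALSE)
  }
  if (any(t < 0)) stop("time 't' must be >= 0", call. = FALSE)
  invisible(t)
}

check_scalar_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
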