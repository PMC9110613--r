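#' Physical decay constant of Lu-177
#'
#' The radioactive decay constant \eqn{\lambda = \ln 2 / T_{1/2}} of
#' \eqn{^{177}}Lu, in 1/s. The default half-life is the DDEP/ENSDF evaluated
#' value 6.6443 days; it can be overridden for sensitivity analyses or other
#' nuclides.
#'
#' @param half_life_hours Physical half-life in hours. Default
#'   `6.6443 * 24 = 159.4632` h.
#' @return Decay constant in 1/s.
#' @examples
#' lu177_lambda()                  # ~1.207e-6 /s
#' lu177_lambda(6.647 * 24)        # an alternative evaluation
#' @export
lu177_lambda <- function(half_life_hours = 6.6443 * 24) {
  if (!is.numeric(half_life_hours) || length(half_life_hours) != 1L ||
      !is.finite(half_life_hours) || half_life_hours <= 0) {
    .stop("'half_life_hours' must be a single positive number",
          "tdrc_param_error")
  }
  log(2) / (half_life_hours * .HOUR_S)
}

#' Tri-exponential TDRC parameter set
#'
#' Parameters of the tri-exponential time dose-rate curve (TDRC)
#' \deqn{f(t) = -\Omega_1 e^{-(\lambda+k_1)t} + \Omega_2 e^{-(\lambda+k_2)t}
#'              + \Omega_3 e^{-(\lambda+k_3)t}}
#' describing an uptake phase followed by a rapid washout and a long-term
#' clearance. Amplitudes are organ dose rates in mGy/s, biological rate
#' constants \eqn{k_i} and the physical decay constant \eqn{\lambda} are in
#' 1/s.
#'
#' When `zero_at_origin = TRUE` (the default, matching the boundary
#' condition that the dose rate is zero just before injection) `omega1` may
#' be omitted and is set to `omega2 + omega3`, which makes \eqn{f(0) = 0}
#' exactly.
#'
#' @param omega1,omega2,omega3 Phase amplitudes (mGy/s), all `>= 0`.
#'   `omega1` defaults to `omega2 + omega3`.
#' @param k1,k2,k3 Biological rate constants (1/s) of uptake, rapid washout
#'   and long-term clearance; must satisfy `k1 > k2 > k3 >= 0`.
#' @param lam Physical decay constant (1/s); see [lu177_lambda()].
#' @param zero_at_origin Enforce (and check) `omega1 == omega2 + omega3`.
#' @return An object of class `triexp_params`.
#' @examples
#' p <- triexp_params(omega2 = 1.5e-3, omega3 = 5e-4,
#'                    k1 = 1e-4, k2 = 2e-5, k3 = 2e-6, lam = 0)
#' evaluate_tdrc(p, 0)   # exactly zero
#' @export
triexp_params <- function(omega2, omega3, k1, k2, k3,
                          lam = lu177_lambda(),
                          omega1 = omega2 + omega3,
                          zero_at_origin = TRUE) {
  p <- list(omega1 = as.numeric(omega1), omega2 = as.numeric(omega2),
            omega3 = as.numeric(omega3), k1 = as.numeric(k1),
            k2 = as.numeric(k2), k3 = as.numeric(k3),
            lam = as.numeric(lam),
            zero_at_origin = isTRUE(zero_at_origin))
  class(p) <- "triexp_params"
  validate_triexp_params(p)
  p
}

validate_triexp_params <- function(p) {
  num <- unlist(p[c("omega1", "omega2", "omega3", "k1", "k2", "k3", "lam")])
  if (any(!is.finite(num))) {
    .stop("all TDRC parameters must be finite numbers", "tdrc_param_error")
  }
  if (p$lam <= 0) {
    .stop("physical decay constant 'lam' must be > 0", "tdrc_param_error")
  }
  if (any(p$lam + c(p$k1, p$k2, p$k3) <= 0)) {
    .stop("lam + k_i must be > 0 for every phase (finite integral)",
          "tdrc_divergent_error")
  }
  if (!(p$k1 > p$k2 && p$k2 > p$k3 && p$k3 >= 0)) {
    .stop("rate constants must satisfy k1 > k2 > k3 >= 0", "tdrc_param_error")
  }
  if (any(c(p$omega1, p$omega2, p$omega3) < 0)) {
    .stop("amplitudes omega_i must be >= 0", "tdrc_param_error")
  }
  if (p$zero_at_origin) {
    s <- p$omega2 + p$omega3
    ref <- max(abs(s), .Machine$double.eps)
    if (abs(p$omega1 - s) > 1e-12 * ref) {
      .stop("zero-at-origin parameter sets require omega1 = omega2 + omega3",
            "tdrc_param_error")
    }
  }
  invisible(p)
}

#' @export
print.triexp_params <- function(x, ...) {
  cat("Tri-exponential TDRC parameters (mGy/s, 1/s)\n")
  cat(sprintf("  Omega: %.6g  %.6g  %.6g%s\n", x$omega1, x$omega2, x$omega3,
              if (x$zero_at_origin) "  [Omega1 = Omega2 + Omega3]" else ""))
  cat(sprintf("  k:     %.6g  %.6g  %.6g   lambda: %.6g\n",
              x$k1, x$k2, x$k3, x$lam))
  invisible(x)
}

#' @export
as.list.triexp_params <- function(x, ...) unclass(x)

#' Evaluate the tri-exponential TDRC
#'
#' Organ dose rate (mGy/s) at times `t` seconds post-injection, i.e.
#' \eqn{-\Omega_1 e^{-(\lambda+k_1)t} + \Omega_2 e^{-(\lambda+k_2)t} +
#' \Omega_3 e^{-(\lambda+k_3)t}}. Vectorized over `t`.
#'
#' @param params A [triexp_params()] object.
#' @param t Times in seconds post-injection, `>= 0`.
#' @return Dose rates in mGy/s, same length as `t`.
#' @seealso [integrate_tdrc()] for the closed-form time integral.
#' @export
evaluate_tdrc <- function(params, t) {
  validate_triexp_params(params)
  if (any(!is.finite(t)) || any(t < 0)) {
    .stop("times must be finite and >= 0", "tdrc_domain_error")
  }
  -params$omega1 * exp(-(params$lam + params$k1) * t) +
    params$omega2 * exp(-(params$lam + params$k2) * t) +
    params$omega3 * exp(-(params$lam + params$k3) * t)
}

#' Closed-form absorbed dose from a TDRC
#'
#' Integrates the tri-exponential TDRC analytically over \eqn{[0, \infty)}:
#' \deqn{D = -\frac{\Omega_1}{\lambda+k_1} + \frac{\Omega_2}{\lambda+k_2}
#'           + \frac{\Omega_3}{\lambda+k_3}}
#' and converts the result from mGy to Gy.
#'
#' @inheritParams evaluate_tdrc
#' @return Absorbed dose in Gy.
#' @examples
#' p <- triexp_params(omega2 = 1e-3, omega3 = 0, k1 = 1e-4, k2 = 1e-5,
#'                    k3 = 0, lam = 1e-9, omega1 = 0, zero_at_origin = FALSE)
#' integrate_tdrc(p)
#' @export
integrate_tdrc <- function(params) {
  validate_triexp_params(params)
  d_mGy <- -params$omega1 / (params$lam + params$k1) +
    params$omega2 / (params$lam + params$k2) +
    params$omega3 / (params$lam + params$k3)
  d_mGy / .MGY_PER_GY
}

#' Remove or re-apply physical decay from dose-rate measurements
#'
#' Biological rate constants are fitted on decay-corrected organ dose rates;
#' the correction multiplies each measurement by \eqn{e^{+\lambda t}} and is
#' reversed during evaluation/integration. `decay_correct()` and
#' `decay_uncorrect()` are exact inverses.
#'
#' @param t Times in seconds post-injection, `>= 0`.
#' @param odr Organ dose rates (mGy/s) measured at `t`.
#' @param lam Physical decay constant (1/s).
#' @return Corrected (or uncorrected) dose rates, same length as `odr`.
#' @examples
#' lam <- lu177_lambda()
#' decay_correct(0, 0.01, lam)            # factor 1 at t = 0
#' t_half <- log(2) / lam
#' decay_correct(t_half, 0.01, lam)       # exactly doubled
#' @export
decay_correct <- function(t, odr, lam) {
  if (any(!is.finite(t)) || any(t < 0)) {
    .stop("times must be finite and >= 0", "tdrc_domain_error")
  }
  odr * exp(lam * t)
}

#' @rdname decay_correct
#' @export
decay_uncorrect <- function(t, odr, lam) {
  if (any(!is.finite(t)) || any(t < 0)) {
    .stop("times must be finite and >= 0", "tdrc_domain_error")
  }
  odr * exp(-lam * t)
}

#' Serialize TDRC parameters to a flat unit-annotated record
#'
#' @param params A [triexp_params()] object.
#' @return A named list with unit-annotated field names, suitable for
#'   `jsonlite::toJSON()`.
#' @export
triexp_params_record <- function(params) {
  validate_triexp_params(params)
  list(omega1_mGy_per_s = params$omega1,
       omega2_mGy_per_s = params$omega2,
       omega3_mGy_per_s = params$omega3,
       k1_per_s = params$k1, k2_per_s = params$k2, k3_per_s = params$k3,
       lambda_per_s = params$lam,
       zero_at_origin = params$zero_at_origin)
}
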