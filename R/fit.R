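# Tri-exponential TDRC fitting.
#
# Two-stage scheme: (A) penalized nonlinear least squares over
# (Omega2, Omega3, k2, k3, k1) -- the decay-corrected amplitudes, with
# physical decay re-applied inside the model so residuals live on the
# measurement scale -- with the boundary conditions that the curve is zero
# just before injection (exact, via Omega1 = Omega2 + Omega3) and again at
# 600 h (a pseudo-measurement); (B) 1-D damped Newton/bisection refinement
# of the uptake rate k1 so the model passes through the earliest measurement
# within `tol_first_point`.
#
# Identifiability: a 3-point schedule leaves the early-phase shape
# (k1, k2, Omega2 jointly) under-determined -- a 2-D family of
# tri-exponential curves interpolates the same three measurements exactly.
# Stage A therefore carries weak population priors (log-normal, on the
# k2/k3 rate ratio, the Omega2/Omega3 amplitude ratio, and k1) in the
# manner of population-informed few-time-point dosimetry: data residuals
# are scaled by a small nominal relative uncertainty, so on directions the
# data determine the priors are negligible, while on the flat directions
# they select the population-typical member of the interpolating family.

.K3_GAP <- 1e-3  # k3 <= k2 * (1 - .K3_GAP) keeps the phases ordered

# th = (logO2, logO3, logk2, logit-frac, log(k1/k2 - 1));
# k3 = frac * k2 * (1 - .K3_GAP), k1 = k2 * (1 + exp(th5)) > k2
.params_from_theta <- function(th) {
  o2 <- exp(th[1L]); o3 <- exp(th[2L]); k2 <- exp(th[3L])
  frac <- stats::plogis(th[4L])
  list(omega2 = o2, omega3 = o3, k2 = k2,
       k3 = frac * k2 * (1 - .K3_GAP),
       k1 = k2 * (1 + exp(th[5L])))
}

.theta_from_params <- function(o2, o3, k2, k3, k1) {
  frac <- min(max(k3 / (k2 * (1 - .K3_GAP)), 1e-9), 1 - 1e-9)
  ex <- max(k1 / k2 - 1, 1e-6)
  c(log(max(o2, 1e-300)), log(max(o3, 1e-300)), log(k2),
    stats::qlogis(frac), log(ex))
}

# model on the measurement scale: decay-corrected amplitudes, physical
# decay re-applied
.model_raw <- function(cl, lam, t) {
  om1 <- cl$omega2 + cl$omega3
  -om1 * exp(-(lam + cl$k1) * t) + cl$omega2 * exp(-(lam + cl$k2) * t) +
    cl$omega3 * exp(-(lam + cl$k3) * t)
}

#' Population prior used to resolve the early-phase shape
#'
#' A three-point schedule determines the long-term clearance phase and the
#' overall amplitude well, but leaves the early-phase shape (the uptake rate
#' `k1`, the rapid-washout rate `k2` and its amplitude split `omega2/omega3`)
#' under-determined: a two-parameter family of tri-exponential curves passes
#' exactly through the same three measurements. The fit resolves this the
#' way population-informed few-time-point dosimetry does, with weak
#' log-normal priors on the dimensionless shape ratios. On directions the
#' data determine, the priors have negligible influence.
#'
#' @param k2 Population-typical rapid-washout rate (1/s); the default
#'   corresponds to a washout biological half-life of about 3 h.
#' @param amp_ratio Population-typical amplitude ratio
#'   \eqn{\Omega_2/\Omega_3}.
#' @param k1 Population-typical uptake rate (1/s); default corresponds to
#'   an uptake half-life of 0.5 h. The final `k1` is always refined
#'   against the earliest measurement.
#' @param logsd_k2,logsd_amp_ratio,logsd_k1 Prior standard deviations on
#'   the log scale.
#' @param data_rel_sd Nominal relative uncertainty of the dose-rate
#'   measurements used to scale data residuals against the priors.
#' @return A list of class `tdrc_prior`.
#' @export
tdrc_population_prior <- function(k2 = log(2) / (3 * 3600),
                                  amp_ratio = 5 / 3,
                                  k1 = log(2) / (0.5 * 3600),
                                  logsd_k2 = 0.15,
                                  logsd_amp_ratio = 0.21,
                                  logsd_k1 = 0.15,
                                  data_rel_sd = 3e-4) {
  structure(list(k2 = k2, amp_ratio = amp_ratio, k1 = k1,
                 logsd_k2 = logsd_k2,
                 logsd_amp_ratio = logsd_amp_ratio,
                 logsd_k1 = logsd_k1,
                 data_rel_sd = data_rel_sd),
            class = "tdrc_prior")
}

#' Refine the uptake rate against the earliest measurement
#'
#' One-dimensional damped Newton iteration (with bisection safeguarding) on
#' the scalar gap between the model and the earliest organ dose rate,
#' \eqn{g(k_1) = f(t_1; k_1) - \mathrm{ODR}_1}, with the clearance terms held
#' fixed. `g` is strictly increasing in `k1`, so the root (when it lies in
#' the bracket `(k2, k1_max]`) is unique. Convergence criterion is
#' `|g| < tol` (default 1e-5 mGy/s).
#'
#' @param omega2,omega3,k2,k3 Fixed clearance parameters (mGy/s, 1/s);
#'   `omega1` is implied by the zero-at-origin constraint.
#' @param t1 Time of the earliest measurement, seconds post-injection.
#' @param odr1 Measured organ dose rate at `t1` (mGy/s).
#' @param lam Physical decay constant (1/s).
#' @param tol Convergence tolerance on the gap, mGy/s.
#' @param k1_max Upper bracket bound for `k1` (1/s); default corresponds to
#'   an uptake half-life of about 2.3 minutes.
#' @param max_iter Iteration cap.
#' @return A list with `k1`, the achieved `gap` (mGy/s, signed), the number
#'   of `iterations`, and a `converged` flag.
#' @export
optimize_k1 <- function(omega2, omega3, k2, k3, t1, odr1, lam,
                        tol = 1e-5, k1_max = 5e-3, max_iter = 200L) {
  if (t1 <= 0) .stop("earliest time must be > 0", "tdrc_domain_error")
  om1 <- omega2 + omega3
  gap_fn <- function(k1) {
    (-om1 * exp(-(lam + k1) * t1) + omega2 * exp(-(lam + k2) * t1) +
       omega3 * exp(-(lam + k3) * t1)) - odr1
  }
  lo <- k2 * (1 + 1e-9)
  hi <- k1_max
  if (hi <= lo) hi <- lo * 10
  g_lo <- gap_fn(lo); g_hi <- gap_fn(hi)
  # g is increasing in k1; no sign change => best achievable is at an edge
  if (g_lo > 0 || g_hi < 0) {
    edge <- if (abs(g_lo) < abs(g_hi)) lo else hi
    gap <- gap_fn(edge)
    return(list(k1 = edge, gap = gap, iterations = 0L,
                converged = abs(gap) < tol))
  }
  k1 <- sqrt(lo * hi)
  it <- 0L
  g <- gap_fn(k1)
  while (abs(g) >= tol && it < max_iter) {
    it <- it + 1L
    dg <- om1 * t1 * exp(-(lam + k1) * t1)  # dg/dk1 > 0
    step <- if (dg > 0) -g / dg else 0
    cand <- k1 + step
    if (!is.finite(cand) || cand <= lo || cand >= hi || step == 0) {
      cand <- (lo + hi) / 2  # bisection safeguard
    }
    g_cand <- gap_fn(cand)
    if (g_cand > 0) hi <- cand else lo <- cand
    k1 <- cand
    g <- g_cand
  }
  list(k1 = k1, gap = g, iterations = it, converged = abs(g) < tol)
}

# data-driven initialization on the decay-corrected scale
.init_clearance <- function(t, y) {
  n <- length(t)
  i2 <- n - 1L; i3 <- n
  k3 <- 0
  if (y[i2] > 0 && y[i3] > 0) {
    k3 <- max(log(y[i2] / y[i3]) / (t[i3] - t[i2]), 0)
  }
  k2 <- if (k3 > 0) 10 * k3 else 1 / (24 * .HOUR_S)
  A <- rbind(c(exp(-k2 * t[i2]), exp(-k3 * t[i2])),
             c(exp(-k2 * t[i3]), exp(-k3 * t[i3])))
  amps <- tryCatch(solve(A, y[c(i2, i3)]), error = function(e) NULL)
  ypos <- max(y, 1e-12)
  if (is.null(amps) || any(!is.finite(amps))) amps <- c(ypos / 2, ypos / 2)
  amps <- pmax(amps, 1e-3 * ypos)
  list(omega2 = amps[1L], omega3 = amps[2L], k2 = k2,
       k3 = min(k3, k2 * (1 - 2 * .K3_GAP)))
}

#' Fit a tri-exponential TDRC to organ dose-rate measurements
#'
#' Fits the six-parameter tri-exponential time dose-rate curve to at least
#' three (time, organ dose rate) measurements from one treatment cycle,
#' under the boundary conditions that the dose rate is zero just before the
#' injection (enforced exactly through \eqn{\Omega_1 = \Omega_2 + \Omega_3})
#' and again 600 h after it (a pseudo-measurement). Measurements are
#' decay-corrected before the biological rates are fitted and the physical
#' decay is re-applied in evaluation and integration. The uptake rate `k1`
#' is refined against the earliest measurement until the model passes
#' through it within `tol_first_point` (see [optimize_k1()]). Directions of
#' the parameter space that the schedule leaves under-determined are
#' resolved by a weak population prior (see [tdrc_population_prior()]).
#'
#' @param t_hours Acquisition times, hours post-injection (exact
#'   per-acquisition values), `> 0`, at least 3 distinct.
#' @param odr Organ dose rates (mGy/s) at `t_hours`, `>= 0`.
#' @param lam Physical decay constant (1/s); see [lu177_lambda()].
#' @param tol_first_point Tolerance (mGy/s) on the gap between the fitted
#'   model and the earliest measurement. Default `1e-5` mGy/s, i.e. about
#'   a thousandth of a typical kidney organ dose rate.
#' @param k1_max Upper bound for the uptake rate (1/s).
#' @param n_starts Number of multi-start initializations (the first is the
#'   data-driven initialization, the rest seeded jitters of it).
#' @param seed Integer seed making the multi-start jitter, and hence the
#'   whole fit, deterministic. The caller's RNG state is left untouched.
#' @param max_outer Maximum alternations between the penalized
#'   least-squares stage and the uptake-refinement stage.
#' @param boundary_hours Time of the late zero pseudo-measurement (h).
#' @param prior A [tdrc_population_prior()]; pass
#'   `tdrc_population_prior(data_rel_sd = ...)` to tune, or `NULL` to
#'   disable the priors entirely (not recommended for 3-point schedules).
#' @param n_profile Number of profile points used to marginalize the weakly
#'   identified washout rate over the prior (1 disables profiling).
#' @return An object of class `tdrc_fit`: a list with `params`
#'   ([triexp_params()]), `dose_Gy`, `residuals` (model minus data, mGy/s),
#'   `first_point_gap` (mGy/s), `converged`, `k1_iterations`, and the input
#'   `data`. Methods: [print()], [summary()], [coef()], [predict()],
#'   [residuals()], [plot()], [simulate()].
#' @examples
#' truth <- triexp_params(omega2 = 1.64e-2, omega3 = 9.8e-3,
#'                        k1 = 3.85e-4, k2 = 6.42e-5, k3 = 2.14e-6)
#' t_h <- c(1, 24, 96)
#' fit <- fit_triexp(t_h, evaluate_tdrc(truth, t_h * 3600))
#' c(fit$dose_Gy, integrate_tdrc(truth))
#' @export
fit_triexp <- function(t_hours, odr, lam = lu177_lambda(),
                       tol_first_point = 1e-5, k1_max = 5e-3,
                       n_starts = 4L, seed = 42L, max_outer = 4L,
                       boundary_hours = 600,
                       prior = tdrc_population_prior(),
                       n_profile = 9L) {
  if (length(t_hours) != length(odr)) {
    .stop("'t_hours' and 'odr' must have the same length", "tdrc_param_error")
  }
  keep <- order(t_hours)
  t_hours <- t_hours[keep]; odr <- odr[keep]
  if (length(unique(t_hours)) < 3L) {
    .stop("tri-exponential fitting needs at least 3 distinct time-points",
          "tdrc_insufficient_data")
  }
  if (any(t_hours <= 0)) .stop("times must be > 0 h", "tdrc_domain_error")
  if (any(odr < 0)) .stop("dose rates must be >= 0", "tdrc_domain_error")
  if (max(t_hours) < 48) {
    .warn("no measurement at or beyond 48 h; late-clearance extrapolation is weakly constrained",
          "tdrc_schedule_warning")
  }

  t_s <- t_hours * .HOUR_S
  y <- decay_correct(t_s, odr, lam)          # decay-corrected ODRs
  t_b <- boundary_hours * .HOUR_S
  peak <- max(odr)
  rel <- if (is.null(prior)) 0.005 else prior$data_rel_sd
  sig <- pmax(rel * odr, rel * 0.02 * peak)  # floor keeps tiny late values sane
  sig_b <- 1e-3 * peak                       # 600 h boundary band: |f| <= 1e-3 peak

  resid_fn <- function(cl) {
    r <- c((.model_raw(cl, lam, t_s) - odr) / sig,
           .model_raw(cl, lam, t_b) / sig_b)
    if (!is.null(prior)) {
      r <- c(r,
             log(cl$k2 / prior$k2) / prior$logsd_k2,
             log((cl$omega2 / cl$omega3) / prior$amp_ratio) /
               prior$logsd_amp_ratio,
             log(cl$k1 / prior$k1) / prior$logsd_k1)
    }
    r
  }
  sse <- function(cl) sum(resid_fn(cl)^2)

  init <- .init_clearance(t_s, y)
  k1_init <- if (is.null(prior)) 20 * init$k2 else prior$k1
  th0 <- .theta_from_params(init$omega2, init$omega3, init$k2, init$k3,
                            max(k1_init, init$k2 * 1.5))

  # seeded jitters; caller RNG untouched
  jitters <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    matrix(rnorm(5L * max(n_starts - 1L, 0L), sd = 0.4), nrow = 5L)
  })

  best <- NULL
  for (s in seq_len(max(n_starts, 1L))) {
    th <- if (s == 1L) th0 else th0 + jitters[, s - 1L]
    k1res <- NULL
    prev <- Inf
    for (outer in seq_len(max_outer)) {
      lm <- tryCatch(
        minpack.lm::nls.lm(th, fn = function(u) resid_fn(.params_from_theta(u)),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 400L, ftol = 1e-15, ptol = 1e-13)),
        error = function(e) NULL)
      if (!is.null(lm) && all(is.finite(lm$par)) &&
          sum(lm$fvec^2) <= sse(.params_from_theta(th))) {
        th <- lm$par
      }
      cl <- .params_from_theta(th)
      k1res <- optimize_k1(cl$omega2, cl$omega3, cl$k2, cl$k3,
                           t1 = t_s[1L], odr1 = odr[1L], lam = lam,
                           tol = tol_first_point, k1_max = k1_max)
      cl$k1 <- max(k1res$k1, cl$k2 * (1 + 1e-9))
      th <- .theta_from_params(cl$omega2, cl$omega3, cl$k2, cl$k3, cl$k1)
      val <- sse(cl)
      if (is.finite(prev) && abs(prev - val) <= 1e-12 * (1 + val)) break
      prev <- val
    }
    cl <- .params_from_theta(th)
    cand <- list(cl = cl, k1res = k1res, score = sse(cl))
    if (is.null(best) || cand$score < best$score) best <- cand
  }

  # Marginalize the directions a 3-point schedule leaves flat: constrained
  # refits over a 2-D grid of (washout rate k2, amplitude ratio
  # Omega2/Omega3) spanning the prior, weighted by the quasi-posterior
  # exp(-chi^2/2). The reported curve is the profile member whose
  # closed-form integral is closest to the marginalized dose, so the
  # returned parameters remain an actual fitted curve through the data.
  if (!is.null(prior) && n_profile > 1L) {
    cl0 <- best$cl
    g_k2 <- log(prior$k2) + seq(-3, 3, length.out = n_profile) *
      prior$logsd_k2
    g_q <- log(prior$amp_ratio) +
      seq(-3, 3, length.out = n_profile) * prior$logsd_amp_ratio
    prof <- list()
    for (lk2 in g_k2) for (lq in g_q) {
      k2f <- exp(lk2); qf <- exp(lq)
      # theta3 = (logO3, logit-frac, log(k1/k2f - 1)); O2 = qf * O3
      p3 <- function(u) {
        o3 <- exp(u[1L])
        list(omega2 = qf * o3, omega3 = o3, k2 = k2f,
             k3 = stats::plogis(u[2L]) * k2f * (1 - .K3_GAP),
             k1 = k2f * (1 + exp(u[3L])))
      }
      u0 <- c(log(cl0$omega3),
              stats::qlogis(min(max(cl0$k3 / (k2f * (1 - .K3_GAP)), 1e-9),
                                1 - 1e-9)),
              log(max(cl0$k1 / k2f - 1, 1e-6)))
      lmg <- tryCatch(
        minpack.lm::nls.lm(u0, fn = function(u) resid_fn(p3(u)),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 150L, ftol = 1e-14, ptol = 1e-12)),
        error = function(e) NULL)
      if (is.null(lmg) || !all(is.finite(lmg$par))) next
      clg <- p3(lmg$par)
      kg <- optimize_k1(clg$omega2, clg$omega3, clg$k2, clg$k3,
                        t1 = t_s[1L], odr1 = odr[1L], lam = lam,
                        tol = tol_first_point, k1_max = k1_max)
      clg$k1 <- max(kg$k1, clg$k2 * (1 + 1e-9))
      chi2 <- sse(clg)
      dg <- (-(clg$omega2 + clg$omega3) / (lam + clg$k1) +
               clg$omega2 / (lam + clg$k2) +
               clg$omega3 / (lam + clg$k3)) / .MGY_PER_GY
      prof[[length(prof) + 1L]] <- list(cl = clg, k1res = kg, chi2 = chi2,
                                        dose = dg)
    }
    if (length(prof) >= 2L) {
      chi <- vapply(prof, `[[`, numeric(1L), "chi2")
      dd <- vapply(prof, `[[`, numeric(1L), "dose")
      keep <- is.finite(chi) & is.finite(dd)
      chi <- chi[keep]; dd <- dd[keep]; prof <- prof[keep]
      w <- exp(-(chi - min(chi)) / 2)
      dbar <- sum(w * dd) / sum(w)
      pick <- which.min(abs(dd - dbar))
      if (length(prof) && is.finite(dbar) && prof[[pick]]$k1res$converged) {
        best <- list(cl = prof[[pick]]$cl, k1res = prof[[pick]]$k1res,
                     score = prof[[pick]]$chi2)
      }
    }
  }

  cl <- best$cl
  params <- triexp_params(omega2 = cl$omega2, omega3 = cl$omega3,
                          k1 = min(cl$k1, k1_max * (1 + 1e-9)),
                          k2 = cl$k2, k3 = cl$k3, lam = lam)
  fitted_vals <- evaluate_tdrc(params, t_s)
  res <- fitted_vals - odr
  gap <- abs(fitted_vals[1L] - odr[1L])
  boundary_ok <- abs(evaluate_tdrc(params, t_b)) <= 1e-3 * max(peak, 1e-300)
  converged <- best$k1res$converged && gap < tol_first_point && boundary_ok
  if (!converged) {
    .warn(sprintf("tri-exponential fit did not fully converge (first-point gap %.3g mGy/s, boundary %s); returning best-so-far parameters",
                  gap, if (boundary_ok) "ok" else "violated"),
          "tdrc_nonconvergence")
  }
  if (cl$k3 < 1e-9 * max(cl$k2, 1e-300) ||
      diff(range(odr)) <= 1e-12 * max(peak, 1e-300)) {
    .warn("long-term clearance rate is ~0 (plateau-like data)",
          "tdrc_degenerate_warning")
  }

  structure(list(params = params,
                 dose_Gy = integrate_tdrc(params),
                 residuals = res,
                 fitted = fitted_vals,
                 first_point_gap = gap,
                 converged = converged,
                 k1_iterations = best$k1res$iterations,
                 tol_first_point = tol_first_point,
                 boundary_hours = boundary_hours,
                 data = data.frame(t_hours = t_hours, odr = odr),
                 seed = as.integer(seed)),
            class = "tdrc_fit")
}

#' @export
print.tdrc_fit <- function(x, ...) {
  cat("Tri-exponential TDRC fit\n")
  cat(sprintf("  %d time-points (%.3g-%.3g h), absorbed dose %.4g Gy\n",
              nrow(x$data), min(x$data$t_hours), max(x$data$t_hours),
              x$dose_Gy))
  cat(sprintf("  converged: %s (first-point gap %.3g mGy/s, tol %.3g)\n",
              x$converged, x$first_point_gap, x$tol_first_point))
  print(x$params)
  invisible(x)
}

#' @export
coef.tdrc_fit <- function(object, ...) {
  p <- object$params
  c(omega1 = p$omega1, omega2 = p$omega2, omega3 = p$omega3,
    k1 = p$k1, k2 = p$k2, k3 = p$k3, lam = p$lam)
}

#' @export
residuals.tdrc_fit <- function(object, ...) object$residuals

#' @export
fitted.tdrc_fit <- function(object, ...) object$fitted

#' Predicted organ dose rate from a fitted TDRC
#'
#' @param object A `tdrc_fit`.
#' @param t_hours Times (hours post-injection) at which to evaluate the
#'   fitted curve; defaults to the fitting times.
#' @param ... Unused.
#' @return Dose rates in mGy/s.
#' @export
predict.tdrc_fit <- function(object, t_hours = object$data$t_hours, ...) {
  evaluate_tdrc(object$params, t_hours * .HOUR_S)
}

#' @export
summary.tdrc_fit <- function(object, ...) {
  p <- object$params
  out <- list(coefficients = coef(object),
              dose_Gy = object$dose_Gy,
              half_lives_h = log(2) / (c(uptake = p$k1, washout = p$k2,
                                         clearance = max(p$k3, .Machine$double.xmin)) * .HOUR_S),
              residuals = object$residuals,
              first_point_gap = object$first_point_gap,
              converged = object$converged,
              n = nrow(object$data))
  class(out) <- "summary.tdrc_fit"
  out
}

#' @export
print.summary.tdrc_fit <- function(x, ...) {
  cat("Tri-exponential TDRC fit summary\n")
  cat(sprintf("  n = %d, absorbed dose = %.4g Gy, converged = %s\n",
              x$n, x$dose_Gy, x$converged))
  cat("  biological half-lives (h):\n")
  print(round(x$half_lives_h, 3))
  cat("  residuals (mGy/s):\n")
  print(signif(x$residuals, 4))
  invisible(x)
}

#' @export
plot.tdrc_fit <- function(x, n_grid = 400L, xlim_hours = NULL, ...) {
  if (is.null(xlim_hours)) xlim_hours <- c(0, max(x$data$t_hours) * 1.5)
  tg <- seq(xlim_hours[1L], xlim_hours[2L], length.out = n_grid)
  plot(x$data$t_hours, x$data$odr, pch = 19,
       xlab = "time post-injection (h)", ylab = "organ dose rate (mGy/s)",
       xlim = xlim_hours,
       ylim = range(0, x$data$odr, evaluate_tdrc(x$params, tg * .HOUR_S)), ...)
  lines(tg, evaluate_tdrc(x$params, tg * .HOUR_S), col = "steelblue")
  abline(h = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Simulate noisy re-measurements from a fitted TDRC
#'
#' Draws multiplicative log-normal noise around the fitted curve at the
#' original acquisition times, the same noise model used by the synthetic
#' cohort generator.
#'
#' @param object A `tdrc_fit`.
#' @param nsim Number of replicate measurement sets.
#' @param seed Optional integer seed (caller RNG restored afterwards).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param ... Unused.
#' @return A data frame with columns `sim`, `t_hours`, `odr`.
#' @export
simulate.tdrc_fit <- function(object, nsim = 1L, seed = NULL,
                              noise_cv = 0.05, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  mu <- fitted(object)
  sdlog <- sqrt(log(1 + noise_cv^2))
  do.call(rbind, lapply(seq_len(nsim), function(s) {
    data.frame(sim = s, t_hours = object$data$t_hours,
               odr = mu * rlnorm(length(mu), -sdlog^2 / 2, sdlog))
  }))
}

#' Two-point mono-exponential comparison fit
#'
#' The simplified estimator used for comparison with the tri-exponential
#' model: a single effective washout \eqn{\mu = \ln(\mathrm{ODR}_1 /
#' \mathrm{ODR}_2) / (t_2 - t_1)} through two measurements, integrated over
#' \eqn{[0, \infty)} as \eqn{D = \mathrm{ODR}_1 e^{\mu t_1} / \mu}. The rate
#' must be positive: a non-decreasing pair (typical of low-uptake bone
#' marrow surrogates) is an error, since the integral then diverges.
#'
#' @param t1_hours,odr1 Earlier measurement (h, mGy/s), `odr1 > 0`.
#' @param t2_hours,odr2 Later measurement (h, mGy/s), `odr2 > 0`.
#' @return A list with `mu_per_s` (effective rate, physical decay included),
#'   `effective_half_life_h`, `amplitude_mGy_per_s` (back-extrapolated value
#'   at t = 0) and `dose_Gy`.
#' @examples
#' fit_monoexp(24, 0.5, 96, 0.25)$effective_half_life_h  # 72 h
#' @export
fit_monoexp <- function(t1_hours, odr1, t2_hours, odr2) {
  if (!(t1_hours < t2_hours)) {
    .stop("first point must be earlier than the second", "tdrc_domain_error")
  }
  if (odr1 <= 0 || odr2 <= 0) {
    .stop("both dose rates must be > 0", "tdrc_domain_error")
  }
  if (odr2 >= odr1) {
    .stop("dose rate does not decrease between the two points; the mono-exponential effective rate would be <= 0 and the integral diverges",
          "tdrc_negative_rate_error")
  }
  t1 <- t1_hours * .HOUR_S; t2 <- t2_hours * .HOUR_S
  mu <- log(odr1 / odr2) / (t2 - t1)
  amp <- odr1 * exp(mu * t1)
  list(mu_per_s = mu,
       effective_half_life_h = log(2) / mu / .HOUR_S,
       amplitude_mGy_per_s = amp,
       dose_Gy = amp / mu / .MGY_PER_GY)
}
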