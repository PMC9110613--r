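# Fallback dose estimators for incomplete acquisition schedules:
#   M1 (Missing Time-Point)  - complete a 3-point cycle with the same
#       slot's ODR borrowed from another cycle, scaled by the ratio of
#       injected activities, then fit the tri-exponential as usual;
#   M2 (STP-Intra)           - scale the patient's own fitted reference
#       curve to a single measured ODR;
#   M3 (STP-Inter)           - scale a population-average per-MBq curve to
#       the single (latest) measured ODR;
# plus cumulative-dose extrapolation over entirely missing cycles.

#' Absorbed-dose record with method provenance
#'
#' Every dose the package reports carries a tag identifying how it was
#' obtained; no dose is reported untagged.
#'
#' @param value_Gy Absorbed dose (Gy), `>= 0`.
#' @param voi_label VOI label.
#' @param cycle_id Treatment cycle.
#' @param method_tag One of `"TRIEXP_REF"`, `"M1"`, `"M2"`, `"M3"`,
#'   `"MONOEXP"`, `"EXTRAPOLATED"`.
#' @param provenance Optional free-form provenance (donor cycle, template
#'   contributors, ...).
#' @return An object of class `absorbed_dose`.
#' @export
absorbed_dose <- function(value_Gy, voi_label = NA_character_,
                          cycle_id = NA_integer_,
                          method_tag = c("TRIEXP_REF", "M1", "M2", "M3",
                                         "MONOEXP", "EXTRAPOLATED"),
                          provenance = NULL) {
  method_tag <- match.arg(method_tag)
  if (!is.finite(value_Gy) || value_Gy < 0) {
    .stop("absorbed dose must be a finite number >= 0", "tdrc_domain_error")
  }
  structure(list(value_Gy = value_Gy, voi_label = voi_label,
                 cycle_id = cycle_id, method_tag = method_tag,
                 provenance = provenance),
            class = "absorbed_dose")
}

#' @export
print.absorbed_dose <- function(x, ...) {
  cat(sprintf("absorbed dose %.4g Gy [%s]%s%s\n", x$value_Gy, x$method_tag,
              if (is.na(x$voi_label)) "" else paste0(" voi=", x$voi_label),
              if (is.na(x$cycle_id)) "" else paste0(" cycle=", x$cycle_id)))
  invisible(x)
}

#' @export
as.numeric.absorbed_dose <- function(x, ...) x$value_Gy

#' M1: substitute a missing time-point from another cycle
#'
#' Completes an incomplete 3-point cycle by borrowing the missing slot's
#' organ dose rate from a donor cycle of the same patient, scaled by the
#' ratio of injected activities; the donor's exact acquisition time is
#' used. The completed triple is then fitted with the tri-exponential
#' reference machinery and tagged `M1`.
#'
#' @param target A data frame with columns `t_hours`, `odr` holding the
#'   (at least 2) available measurements of the target cycle.
#' @param target_activity_MBq,target_cycle_id Injected activity and id of
#'   the target cycle.
#' @param donors A data frame with columns `cycle_id`, `t_hours`, `odr`,
#'   `injected_MBq`: candidate measurements of the missing slot from other
#'   cycles.
#' @param donor_policy `"nearest"` picks the donor with the smallest cycle
#'   distance (earlier cycle on ties); `"next-first"` prefers the first
#'   following cycle, falling back to nearest-earlier.
#' @param lam,... Passed to [fit_triexp()].
#' @return A list with `fit` (a `tdrc_fit`), `dose` (an [absorbed_dose()]
#'   tagged `M1`), `substituted` (the synthesized measurement row) and
#'   `donor_cycle_id`.
#' @export
m1_substitute_odr <- function(target, target_activity_MBq, target_cycle_id,
                              donors,
                              donor_policy = c("nearest", "next-first"),
                              lam = lu177_lambda(), ...) {
  donor_policy <- match.arg(donor_policy)
  if (nrow(target) < 2L) {
    .stop("M1 needs at least 2 real measurements in the target cycle",
          "tdrc_insufficient_data")
  }
  if (is.null(donors) || nrow(donors) == 0L) {
    .stop("no donor cycle provides the missing slot",
          "fallback_unavailable_error")
  }
  if (target_activity_MBq <= 0 || any(donors$injected_MBq <= 0)) {
    .stop("injected activities must be > 0", "tdrc_domain_error")
  }
  dist <- abs(donors$cycle_id - target_cycle_id)
  sel <- if (donor_policy == "nearest") {
    # tie -> earlier cycle
    order(dist, donors$cycle_id)[1L]
  } else {
    after <- which(donors$cycle_id > target_cycle_id)
    if (length(after)) after[which.min(donors$cycle_id[after])]
    else order(dist, donors$cycle_id)[1L]
  }
  donor <- donors[sel, , drop = FALSE]
  sub_odr <- donor$odr * (target_activity_MBq / donor$injected_MBq)
  completed_t <- c(target$t_hours, donor$t_hours)
  completed_o <- c(target$odr, sub_odr)
  fit <- fit_triexp(completed_t, completed_o, lam = lam, ...)
  list(fit = fit,
       dose = absorbed_dose(max(fit$dose_Gy, 0), cycle_id = target_cycle_id,
                            method_tag = "M1",
                            provenance = list(donor_cycle_id = donor$cycle_id,
                                              donor_odr = donor$odr,
                                              substituted_odr = sub_odr)),
       substituted = data.frame(t_hours = donor$t_hours, odr = sub_odr),
       donor_cycle_id = donor$cycle_id)
}

#' M2 (STP-Intra): scale the patient's reference curve to a single ODR
#'
#' Assuming the pharmacokinetics of the reference cycle carry over, the
#' whole reference TDRC is scaled by the ratio between the measured single
#' organ dose rate and the reference curve's value at the same time; the
#' absorbed dose scales by the same factor.
#'
#' @param ref_fit A converged [fit_triexp()] result for the reference
#'   cycle of the same patient and VOI.
#' @param t_hours Acquisition time of the single measurement (h).
#' @param odr Measured organ dose rate (mGy/s), `>= 0`.
#' @param cycle_id Cycle the estimate is for (bookkeeping).
#' @return An [absorbed_dose()] tagged `M2`.
#' @export
m2_stp_intra <- function(ref_fit, t_hours, odr, cycle_id = NA_integer_) {
  if (!inherits(ref_fit, "tdrc_fit")) {
    .stop("'ref_fit' must be a tdrc_fit", "tdrc_param_error")
  }
  if (!isTRUE(ref_fit$converged)) {
    .warn("reference fit did not converge; M2 scaling may be unreliable",
          "tdrc_nonconvergence")
  }
  if (odr < 0) .stop("dose rate must be >= 0", "tdrc_domain_error")
  bnd <- if (!is.null(ref_fit$boundary_hours)) ref_fit$boundary_hours else 600
  if (t_hours > bnd) {
    .stop(sprintf("measurement time %.3g h lies beyond the %g h boundary where the reference curve is constrained to zero",
                  t_hours, bnd), "unusable_time_error")
  }
  ref_val <- evaluate_tdrc(ref_fit$params, t_hours * .HOUR_S)
  if (!is.finite(ref_val) || ref_val <= 0) {
    .stop("reference curve is not positive at the measurement time; cannot scale",
          "unusable_time_error")
  }
  scale <- odr / ref_val
  absorbed_dose(scale * ref_fit$dose_Gy, cycle_id = cycle_id,
                method_tag = "M2",
                provenance = list(scale = scale, t_hours = t_hours,
                                  ref_dose_Gy = ref_fit$dose_Gy))
}

#' Population-average TDRC template
#'
#' Each contributor's fitted curve is evaluated on a common time grid,
#' normalized by that patient's injected activity (per-MBq curve), and
#' averaged pointwise. Used by the M3 (STP-Inter) estimator; validated by
#' leave-one-out, in which the left-out patient never contributes to their
#' own template.
#'
#' @param fits Named list of `tdrc_fit` objects, one per contributing
#'   patient (names are patient ids).
#' @param activities_MBq Injected activities (MBq) aligned with `fits`.
#' @param voi_label VOI the template describes.
#' @param grid_step_h Grid resolution in hours (default 0.1 h).
#' @param t_max_h Upper end of the grid (default 600 h, the late boundary).
#' @param leave_out Optional patient id to exclude.
#' @return An object of class `population_template`: `time_h`, `curve`
#'   (mGy/s per MBq), `n_contributors`, `contributors`, `voi_label`.
#' @export
build_population_template <- function(fits, activities_MBq, voi_label = NA,
                                      grid_step_h = 0.1, t_max_h = 600,
                                      leave_out = NULL) {
  if (is.null(names(fits))) names(fits) <- as.character(seq_along(fits))
  if (length(fits) != length(activities_MBq)) {
    .stop("'fits' and 'activities_MBq' lengths differ", "tdrc_param_error")
  }
  keep <- if (is.null(leave_out)) seq_along(fits)
          else which(names(fits) != as.character(leave_out))
  if (length(keep) < 1L) {
    .stop("no contributors left for the population template",
          "insufficient_cohort_error")
  }
  grid_h <- seq(0, t_max_h, by = grid_step_h)
  acc <- numeric(length(grid_h))
  for (i in keep) {
    acc <- acc + evaluate_tdrc(fits[[i]]$params, grid_h * .HOUR_S) /
      activities_MBq[i]
  }
  structure(list(time_h = grid_h, curve = acc / length(keep),
                 n_contributors = length(keep),
                 contributors = names(fits)[keep],
                 voi_label = voi_label,
                 grid_step_h = grid_step_h),
            class = "population_template")
}

#' @export
print.population_template <- function(x, ...) {
  cat(sprintf("population TDRC template%s: %d contributors, grid 0-%g h by %g h\n",
              if (is.na(x$voi_label)) "" else paste0(" [", x$voi_label, "]"),
              x$n_contributors, max(x$time_h), x$grid_step_h))
  cat(sprintf("  integral %.4g Gy per MBq injected\n", template_integral(x)))
  invisible(x)
}

#' Interpolated template value and trapezoid integral
#'
#' @param template A [build_population_template()] result.
#' @param t_hours Time(s) at which to interpolate the per-MBq curve.
#' @return `template_value()`: mGy/s per MBq; `template_integral()`: Gy per
#'   MBq injected (trapezoid rule on the grid).
#' @export
template_value <- function(template, t_hours) {
  if (any(t_hours < min(template$time_h)) ||
      any(t_hours > max(template$time_h))) {
    .stop("time outside the template grid", "unusable_time_error")
  }
  approx(template$time_h, template$curve, xout = t_hours)$y
}

#' @rdname template_value
#' @export
template_integral <- function(template) {
  pracma::trapz(template$time_h, template$curve) * .HOUR_S / .MGY_PER_GY
}

#' M3 (STP-Inter): scale the population template to a single ODR
#'
#' The population-average per-MBq TDRC is scaled by the ratio between the
#' measured organ dose rate and the template value at the same time (linear
#' interpolation on the grid); the dose is the scaled trapezoid integral.
#' When several measurements are supplied, the latest is used for scaling.
#'
#' @param template A [build_population_template()] result.
#' @param t_hours,odr Measurement time(s) (h) and organ dose rate(s)
#'   (mGy/s); the latest pair is used.
#' @param cycle_id Cycle the estimate is for (bookkeeping).
#' @return An [absorbed_dose()] tagged `M3`.
#' @export
m3_stp_inter <- function(template, t_hours, odr, cycle_id = NA_integer_) {
  if (!inherits(template, "population_template")) {
    .stop("'template' must be a population_template", "tdrc_param_error")
  }
  if (length(t_hours) != length(odr) || length(t_hours) < 1L) {
    .stop("need matching non-empty t_hours and odr", "tdrc_param_error")
  }
  latest <- which.max(t_hours)
  t1 <- t_hours[latest]; o1 <- odr[latest]
  tv <- template_value(template, t1)
  if (!is.finite(tv) || tv <= 0) {
    .stop("template curve is not positive at the measurement time",
          "unusable_time_error")
  }
  scale <- o1 / tv
  absorbed_dose(scale * template_integral(template), cycle_id = cycle_id,
                method_tag = "M3",
                provenance = list(scale = scale, t_hours = t1,
                                  contributors = template$contributors))
}

#' Cumulative dose with extrapolation over missing cycles
#'
#' Cycles that were never imaged are approximated by the mean of the
#' available per-cycle doses multiplied by the number of missing cycles.
#'
#' @param doses_Gy Available per-cycle absorbed doses (Gy), non-empty.
#' @param n_missing Number of cycles without any estimate, `>= 0`.
#' @return An [absorbed_dose()] tagged `EXTRAPOLATED` holding the
#'   cumulative dose.
#' @examples
#' extrapolate_missing_cycles(c(3, 3, 2.4), 1)$value_Gy  # 8.4 + 2.8
#' @export
extrapolate_missing_cycles <- function(doses_Gy, n_missing) {
  if (length(doses_Gy) < 1L) {
    .stop("at least one available dose is required",
          "tdrc_insufficient_data")
  }
  if (n_missing < 0) .stop("'n_missing' must be >= 0", "tdrc_domain_error")
  total <- sum(doses_Gy) + mean(doses_Gy) * n_missing
  absorbed_dose(total, method_tag = "EXTRAPOLATED",
                provenance = list(n_available = length(doses_Gy),
                                  n_missing = n_missing,
                                  mean_available_Gy = mean(doses_Gy)))
}
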