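# Comparison statistics: signed percentage dose difference, activity-scaled
# inter-cycle variation coefficients, order-statistic summaries, and
# leave-one-out evaluation of the single-time-point estimators.

#' Signed percentage of dose difference
#'
#' \eqn{100 (D_{method} - D_{ref}) / D_{ref}}; the sign is kept (negative
#' medians mean underestimation by the candidate method).
#'
#' @param d_method Candidate-method dose(s), Gy.
#' @param d_ref Reference dose(s), Gy, `> 0`.
#' @return Percentage difference(s).
#' @examples
#' pdd(1.1, 1.0)   # +10
#' @export
pdd <- function(d_method, d_ref) {
  if (any(!is.finite(d_ref)) || any(d_ref <= 0)) {
    .stop("reference dose must be > 0", "tdrc_domain_error")
  }
  100 * (d_method - d_ref) / d_ref
}

#' Inter-cycle variation coefficient of activity-scaled ODR
#'
#' Each cycle's organ dose rate is scaled to the first cycle's injected
#' activity (multiplied by `activities[1] / activities[i]`), and the
#' coefficient of variation (sample standard deviation over mean, percent)
#' of the scaled values is returned.
#'
#' @param odrs Per-cycle organ dose rates at one time slot (mGy/s), `>= 2`.
#' @param activities_MBq Per-cycle injected activities (MBq), `> 0`.
#' @return Variation coefficient in percent.
#' @examples
#' odr_variation_coefficient(c(1, 2, 3), c(1, 1, 1))  # 50
#' @export
odr_variation_coefficient <- function(odrs, activities_MBq) {
  if (length(odrs) < 2L) {
    .stop("need at least 2 cycles", "tdrc_insufficient_data")
  }
  if (length(odrs) != length(activities_MBq) || any(activities_MBq <= 0)) {
    .stop("activities must be > 0 and aligned with ODRs",
          "tdrc_domain_error")
  }
  scaled <- odrs * (activities_MBq[1L] / activities_MBq)
  m <- mean(scaled)
  if (m == 0) .stop("zero mean scaled ODR; CV undefined", "undefined_cv_error")
  100 * sd(scaled) / m
}

#' Order-statistic summary: minimum, median, maximum, mean, sd
#'
#' The summary convention used for reporting error distributions:
#' `[minimum; median; maximum; mean]`, with the sample standard deviation
#' appended. For a single value the sd is `NA`.
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `(min, median, max, mean, sd)`.
#' @export
summarize_values <- function(values) {
  if (length(values) < 1L || any(!is.finite(values))) {
    .stop("non-empty finite values required", "tdrc_domain_error")
  }
  c(min = min(values), median = median(values), max = max(values),
    mean = mean(values),
    sd = if (length(values) > 1L) sd(values) else NA_real_)
}

# reference fits for every (patient, cycle, voi) with >= 3 points
.reference_fits <- function(measurements, lam, ...) {
  out <- list()
  keys <- unique(measurements[, c("patient_id", "cycle_id", "voi")])
  for (i in seq_len(nrow(keys))) {
    sub <- measurements[measurements$patient_id == keys$patient_id[i] &
                          measurements$cycle_id == keys$cycle_id[i] &
                          measurements$voi == keys$voi[i], ]
    if (nrow(sub) < 3L) next
    fit <- tryCatch(suppressWarnings(
      fit_triexp(sub$t_hours, sub$odr_mGy_per_s, lam = lam, ...)),
      error = function(e) NULL)
    if (is.null(fit)) next
    key <- paste(keys$patient_id[i], keys$cycle_id[i], keys$voi[i],
                 sep = "|")
    out[[key]] <- list(fit = fit,
                       patient_id = keys$patient_id[i],
                       cycle_id = keys$cycle_id[i],
                       voi = as.character(keys$voi[i]),
                       injected_MBq = sub$injected_MBq[1L])
  }
  out
}

#' Leave-one-out evaluation of the single-time-point estimators
#'
#' For every patient with a reference 3-point tri-exponential fit, the
#' absorbed dose is re-estimated from one time slot at a time with the M2
#' (STP-Intra) or M3 (STP-Inter) estimator and compared to the reference
#' dose as a signed percentage difference. For M3 the population template
#' is rebuilt for each patient with that patient excluded, independently
#' per cohort; for M2 the reference cycle is the patient's earliest cycle
#' with >= 3 points and every *other* 3-point cycle of the same patient is
#' evaluated. Patients without the needed fits are skipped (with a reason
#' in the `skipped` attribute).
#'
#' @param measurements Measurement table with columns `cohort_id`,
#'   `patient_id`, `cycle_id`, `injected_MBq`, `voi`, `t_hours`,
#'   `odr_mGy_per_s`, `slot`.
#' @param estimator `"M2"` or `"M3"`.
#' @param slots Slots to evaluate (default `EARLY`, `24H`, `LATE`).
#' @param lam Physical decay constant (1/s).
#' @param grid_step_h Template grid step for M3 (hours).
#' @param ... Passed to [fit_triexp()].
#' @return A list with `pdd` (data frame: cohort, patient, cycle, voi,
#'   slot, estimator, dose_Gy, ref_dose_Gy, pdd, n_contributors),
#'   `summaries` (per voi x slot), `templates` (M3 only, one per cohort x
#'   voi x patient) and `skipped`.
#' @export
loocv_evaluate <- function(measurements, estimator = c("M2", "M3"),
                           slots = c("EARLY", "24H", "LATE"),
                           lam = lu177_lambda(), grid_step_h = 0.1, ...) {
  estimator <- match.arg(estimator)
  .check_measurements(measurements)
  rows <- list(); skipped <- list(); templates <- list()
  for (cohort in unique(measurements$cohort_id)) {
    cm <- measurements[measurements$cohort_id == cohort, ]
    refs <- .reference_fits(cm, lam = lam, ...)
    if (!length(refs)) next
    by_voi <- split(refs, vapply(refs, `[[`, character(1L), "voi"))
    for (voi in names(by_voi)) {
      rv <- by_voi[[voi]]
      pts <- vapply(rv, `[[`, character(1L), "patient_id")
      if (estimator == "M3") {
        # one reference cycle per patient: the earliest fitted cycle
        first_idx <- tapply(seq_along(rv),
                            pts, function(ii) {
                              ii[which.min(vapply(rv[ii], `[[`, numeric(1L),
                                                  "cycle_id"))]
                            })
        rv1 <- rv[unlist(first_idx)]
        ids <- vapply(rv1, `[[`, character(1L), "patient_id")
        fits <- lapply(rv1, `[[`, "fit")
        names(fits) <- ids
        acts <- vapply(rv1, `[[`, numeric(1L), "injected_MBq")
        if (length(fits) < 2L) {
          skipped[[length(skipped) + 1L]] <-
            list(cohort = cohort, voi = voi,
                 reason = "fewer than 2 patients with reference fits")
          next
        }
        for (j in seq_along(rv)) {
          ref <- rv[[j]]
          tpl <- build_population_template(fits, acts, voi_label = voi,
                                           grid_step_h = grid_step_h,
                                           leave_out = ref$patient_id)
          templates[[paste(cohort, voi, ref$patient_id, ref$cycle_id,
                           sep = "|")]] <- tpl
          sub <- cm[cm$patient_id == ref$patient_id &
                      cm$cycle_id == ref$cycle_id & cm$voi == voi, ]
          for (slot in slots) {
            srow <- sub[sub$slot == slot, ]
            if (nrow(srow) != 1L) next
            est <- tryCatch(
              m3_stp_inter(tpl, srow$t_hours, srow$odr_mGy_per_s,
                           cycle_id = ref$cycle_id),
              error = function(e) NULL)
            if (is.null(est)) next
            rows[[length(rows) + 1L]] <- data.frame(
              cohort_id = cohort, patient_id = ref$patient_id,
              cycle_id = ref$cycle_id, voi = voi, slot = slot,
              estimator = "M3", dose_Gy = est$value_Gy,
              ref_dose_Gy = ref$fit$dose_Gy,
              pdd = pdd(est$value_Gy, ref$fit$dose_Gy),
              n_contributors = tpl$n_contributors)
          }
        }
      } else {
        for (pid in unique(pts)) {
          mine <- rv[pts == pid]
          cyc <- vapply(mine, `[[`, numeric(1L), "cycle_id")
          if (length(mine) < 2L) {
            skipped[[length(skipped) + 1L]] <-
              list(cohort = cohort, voi = voi, patient = pid,
                   reason = "M2 needs two cycles with 3-point fits")
            next
          }
          ref <- mine[[which.min(cyc)]]
          for (j in which(cyc != min(cyc))) {
            tgt <- mine[[j]]
            sub <- cm[cm$patient_id == pid & cm$cycle_id == tgt$cycle_id &
                        cm$voi == voi, ]
            for (slot in slots) {
              srow <- sub[sub$slot == slot, ]
              if (nrow(srow) != 1L) next
              est <- tryCatch(
                m2_stp_intra(ref$fit, srow$t_hours, srow$odr_mGy_per_s,
                             cycle_id = tgt$cycle_id),
                error = function(e) NULL)
              if (is.null(est)) next
              rows[[length(rows) + 1L]] <- data.frame(
                cohort_id = cohort, patient_id = pid,
                cycle_id = tgt$cycle_id, voi = voi, slot = slot,
                estimator = "M2", dose_Gy = est$value_Gy,
                ref_dose_Gy = tgt$fit$dose_Gy,
                pdd = pdd(est$value_Gy, tgt$fit$dose_Gy),
                n_contributors = NA_integer_)
            }
          }
        }
      }
    }
  }
  if (!length(rows)) {
    .stop("no evaluable patients", "empty_report_error")
  }
  pdd_df <- do.call(rbind, rows)
  summaries <- do.call(rbind, lapply(
    split(pdd_df, list(pdd_df$voi, pdd_df$slot), drop = TRUE),
    function(g) {
      s <- summarize_values(g$pdd)
      data.frame(voi = g$voi[1L], slot = g$slot[1L], n = nrow(g),
                 min = s["min"], median = s["median"], max = s["max"],
                 mean = s["mean"], sd = s["sd"], row.names = NULL)
    }))
  list(pdd = pdd_df, summaries = summaries, templates = templates,
       skipped = skipped)
}
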