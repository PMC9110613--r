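# The adaptive routing: for every (patient, cycle, VOI) use the reference
# tri-exponential fit when 3 points exist; M1 when one slot of a 3-point
# schedule is missing but recoverable from another cycle; M2 for
# single-point cycles once the patient has a fitted reference curve; M3
# against a population template otherwise. Every reported dose carries its
# method tag and the reason for the fallback.

#' Run the adaptive dosimetry workflow on a measurement table
#'
#' @param measurements Measurement table (see [read_timepoints()]).
#' @param config A [workflow_config()].
#' @param template Optional [build_population_template()] result (or named
#'   list per VOI) enabling M3 for patients without a reference fit. When
#'   absent, templates are built internally per cohort and VOI from the
#'   patients that do have reference fits.
#' @return A data frame with one row per (patient, cycle, VOI):
#'   `cohort_id`, `patient_id`, `cycle_id`, `voi`, `dose_Gy`,
#'   `method_tag`, `converged`, `reason` (routing audit trail), plus
#'   donor/template provenance columns.
#' @export
run_workflow <- function(measurements, config = workflow_config(),
                         template = NULL) {
  .check_measurements(measurements)
  lam <- lu177_lambda(config$half_life_hours)
  fit_args <- list(lam = lam, tol_first_point = config$tol_first_point,
                   seed = config$seed,
                   boundary_hours = config$boundary_hours)

  out <- list()
  for (cohort in unique(measurements$cohort_id)) {
    cm <- measurements[measurements$cohort_id == cohort, ]
    # pass 1: reference fits wherever 3 points exist
    refs <- .reference_fits(cm, lam = lam,
                            tol_first_point = config$tol_first_point,
                            seed = config$seed,
                            boundary_hours = config$boundary_hours)
    ref_key <- function(pid, cyc, voi) paste(pid, cyc, voi, sep = "|")
    # internal per-(cohort, voi) templates from reference fits
    internal_template <- function(voi, exclude_patient = NULL) {
      rv <- refs[vapply(refs, function(r) r$voi == voi, logical(1L))]
      if (!length(rv)) return(NULL)
      pts <- vapply(rv, `[[`, character(1L), "patient_id")
      first_idx <- tapply(seq_along(rv), pts, function(ii) {
        ii[which.min(vapply(rv[ii], `[[`, numeric(1L), "cycle_id"))]
      })
      rv1 <- rv[unlist(first_idx)]
      ids <- vapply(rv1, `[[`, character(1L), "patient_id")
      keep <- if (is.null(exclude_patient)) seq_along(rv1)
              else which(ids != exclude_patient)
      if (!length(keep)) return(NULL)
      fits <- lapply(rv1[keep], `[[`, "fit")
      names(fits) <- ids[keep]
      build_population_template(
        fits, vapply(rv1[keep], `[[`, numeric(1L), "injected_MBq"),
        voi_label = voi, grid_step_h = config$template_grid_step_h)
    }
    keys <- unique(cm[, c("patient_id", "cycle_id", "voi")])
    for (i in seq_len(nrow(keys))) {
      pid <- keys$patient_id[i]; cyc <- keys$cycle_id[i]
      voi <- as.character(keys$voi[i])
      sub <- cm[cm$patient_id == pid & cm$cycle_id == cyc & cm$voi == voi, ]
      act <- sub$injected_MBq[1L]
      row <- data.frame(cohort_id = cohort, patient_id = pid,
                        cycle_id = cyc, voi = voi, dose_Gy = NA_real_,
                        method_tag = NA_character_, converged = NA,
                        reason = NA_character_,
                        donor_cycle_id = NA_integer_,
                        template_contributors = NA_integer_)
      rk <- ref_key(pid, cyc, voi)
      routed <- FALSE
      for (method in config$routing) {
        if (routed) break
        if (method == "TRIEXP_REF" && !is.null(refs[[rk]])) {
          f <- refs[[rk]]$fit
          row$dose_Gy <- f$dose_Gy; row$method_tag <- "TRIEXP_REF"
          row$converged <- f$converged
          row$reason <- sprintf("%d time-points available", nrow(sub))
          routed <- TRUE
        } else if (method == "M1" && nrow(sub) == 2L) {
          miss_slots <- setdiff(c("EARLY", "24H", "LATE"), sub$slot)
          donors <- cm[cm$patient_id == pid & cm$voi == voi &
                         cm$cycle_id != cyc & cm$slot %in% miss_slots, ]
          if (nrow(donors)) {
            m1 <- tryCatch(suppressWarnings(do.call(m1_substitute_odr,
              c(list(target = data.frame(t_hours = sub$t_hours,
                                         odr = sub$odr_mGy_per_s),
                     target_activity_MBq = act, target_cycle_id = cyc,
                     donors = data.frame(cycle_id = donors$cycle_id,
                                         t_hours = donors$t_hours,
                                         odr = donors$odr_mGy_per_s,
                                         injected_MBq = donors$injected_MBq),
                     donor_policy = config$donor_policy),
                fit_args))), error = function(e) NULL)
            if (!is.null(m1)) {
              row$dose_Gy <- m1$dose$value_Gy; row$method_tag <- "M1"
              row$converged <- m1$fit$converged
              row$donor_cycle_id <- m1$donor_cycle_id
              row$reason <- sprintf("slot %s substituted from cycle %d",
                                    paste(miss_slots, collapse = "/"),
                                    m1$donor_cycle_id)
              routed <- TRUE
            }
          }
        } else if (method == "M2") {
          # reference: the patient's earliest cycle with a 3-point fit
          mine <- refs[vapply(refs, function(r)
            r$patient_id == pid && r$voi == voi, logical(1L))]
          if (length(mine) && nrow(sub) >= 1L) {
            cyc_ids <- vapply(mine, `[[`, numeric(1L), "cycle_id")
            ref <- mine[[which.min(cyc_ids)]]
            if (ref$cycle_id != cyc) {
              latest <- which.max(sub$t_hours)
              est <- tryCatch(suppressWarnings(
                m2_stp_intra(ref$fit, sub$t_hours[latest],
                             sub$odr_mGy_per_s[latest], cycle_id = cyc)),
                error = function(e) NULL)
              if (!is.null(est)) {
                row$dose_Gy <- est$value_Gy; row$method_tag <- "M2"
                row$converged <- ref$fit$converged
                row$reason <- sprintf("scaled cycle-%d reference curve at %.3g h",
                                      ref$cycle_id, sub$t_hours[latest])
                routed <- TRUE
              }
            }
          }
        } else if (method == "M3") {
          tpl <- NULL
          if (!is.null(template)) {
            tpl <- if (inherits(template, "population_template")) template
                   else template[[voi]]
          }
          if (is.null(tpl)) tpl <- internal_template(voi,
                                                     exclude_patient = pid)
          if (!is.null(tpl) && nrow(sub) >= 1L) {
            est <- tryCatch(
              m3_stp_inter(tpl, sub$t_hours, sub$odr_mGy_per_s,
                           cycle_id = cyc), error = function(e) NULL)
            if (!is.null(est)) {
              row$dose_Gy <- est$value_Gy; row$method_tag <- "M3"
              row$converged <- NA
              row$template_contributors <- tpl$n_contributors
              row$reason <- sprintf("population template (%d contributors)",
                                    tpl$n_contributors)
              routed <- TRUE
            }
          }
        }
      }
      if (!routed) {
        row$reason <- "no applicable method (insufficient data)"
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cumulative per-patient doses with missing-cycle extrapolation
#'
#' Sums the per-cycle doses of each (patient, VOI); when fewer cycles have
#' estimates than were planned, the cumulative dose is completed by the
#' mean of the available doses times the number of missing cycles and
#' tagged `EXTRAPOLATED`.
#'
#' @param dose_table Output of [run_workflow()].
#' @param n_cycles_planned Planned number of cycles (default 4).
#' @return Data frame: `cohort_id`, `patient_id`, `voi`, `n_available`,
#'   `n_missing`, `cumulative_Gy`, `method_tag`.
#' @export
cumulative_doses <- function(dose_table, n_cycles_planned = 4L) {
  splits <- split(dose_table,
                  list(dose_table$cohort_id, dose_table$patient_id,
                       dose_table$voi), drop = TRUE)
  out <- lapply(splits, function(g) {
    have <- g$dose_Gy[is.finite(g$dose_Gy)]
    n_missing <- max(n_cycles_planned - length(have), 0L)
    cum <- if (length(have)) extrapolate_missing_cycles(have, n_missing)
           else NULL
    data.frame(cohort_id = g$cohort_id[1L], patient_id = g$patient_id[1L],
               voi = g$voi[1L], n_available = length(have),
               n_missing = n_missing,
               cumulative_Gy = if (is.null(cum)) NA_real_ else cum$value_Gy,
               method_tag = if (is.null(cum)) NA_character_
                            else if (n_missing > 0L) "EXTRAPOLATED"
                            else "SUM")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
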