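# Synthetic virtual cohorts with known ground truth. The generator
# emulates the clinical structure: tri-exponential organ kinetics (fast
# uptake, rapid washout, long-term clearance), level-dominated inter-patient
# heterogeneity, inter-cycle amplitude variability, multiplicative
# measurement noise, the clinical schedules (three points at ~1 h / 24 h /
# 96 or 144 h at cycle 1, a single 24 h point afterwards), exact
# acquisition-time jitter, and Table-1-style missingness.

.default_voi_scales <- c(LK = 1.0, RK = 1.1, L = 1.45, S = 1.48,
                         L2L4 = 0.1, L1L5 = 0.1, T9L5 = 0.1)

#' Specification of a synthetic virtual cohort
#'
#' Defaults are the package's study conditions: kidney-like base kinetics
#' (uptake half-life 0.5 h, rapid washout 3 h, long-term clearance 90 h)
#' with amplitudes giving about 3.1 Gy per cycle and a 24 h organ dose rate
#' near 0.01 mGy/s for the left kidney; per-VOI amplitude multipliers put
#' livers/spleens near 4.5 Gy and bone-marrow surrogates near 0.3 Gy per
#' cycle. Inter-patient heterogeneity is level-dominated: a common
#' log-normal amplitude level (CV 35%) on top of smaller per-amplitude
#' shape jitter (CV 15%) and rate jitter (CV 15%). Cycles share a patient's
#' kinetics up to a log-normal amplitude multiplier (CV 10%) and scale with
#' the injected activity; optional inter-cycle jitter of the long-term
#' clearance rate (`inter_cycle_k3_cv`) breaks late-phase kinetics
#' conservation. Measurement noise is multiplicative log-normal (CV 5%).
#'
#' @param n_patients Number of patients.
#' @param vois Named numeric vector of per-VOI amplitude multipliers; the
#'   names are the VOI labels.
#' @param n_cycles Cycles per patient.
#' @param three_point_cycles `"first"` (clinical default: 3 points at cycle
#'   1, single 24 h point afterwards) or `"all"` (validation-style: 3
#'   points at every cycle).
#' @param late_hours Candidate LATE times (h); patients alternate between
#'   them, emulating weekend-constrained scheduling.
#' @param nominal_activity_MBq,activity_sd_MBq Injected activity
#'   distribution per cycle (MBq).
#' @param base_params Baseline kinetics: list with `omega2`, `omega3`
#'   (mGy/s), `k1`, `k2`, `k3` (1/s).
#' @param level_cv Inter-patient common amplitude level CV.
#' @param shape_cv Inter-patient per-amplitude shape CV.
#' @param rate_cv Inter-patient CV of each rate constant.
#' @param inter_cycle_amplitude_cv Inter-cycle amplitude multiplier CV.
#' @param inter_cycle_k3_cv Inter-cycle CV of the long-term clearance rate
#'   (0 = conserved late kinetics).
#' @param noise_cv Multiplicative measurement noise CV.
#' @param time_jitter Relative jitter of exact acquisition times around
#'   the nominal slots (uniform within `±time_jitter`).
#' @param missing Optional data frame with columns `patient_id`,
#'   `cycle_id`, `slot`: scheduled acquisitions to drop ("planned but not
#'   available").
#' @param half_life_hours Physical half-life used for `lam`.
#' @param seed Integer seed; fixes everything downstream.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 13L,
                        vois = .default_voi_scales[c("LK", "RK", "L", "S",
                                                     "L2L4")],
                        n_cycles = 4L,
                        three_point_cycles = c("first", "all"),
                        late_hours = c(96, 144),
                        nominal_activity_MBq = 6832,
                        activity_sd_MBq = 158,
                        base_params = list(omega2 = 1.64e-2,
                                           omega3 = 9.8e-3,
                                           k1 = 3.85e-4,
                                           k2 = 6.42e-5,
                                           k3 = 2.139e-6),
                        level_cv = 0.35, shape_cv = 0.15, rate_cv = 0.15,
                        inter_cycle_amplitude_cv = 0.10,
                        inter_cycle_k3_cv = 0,
                        noise_cv = 0.05,
                        time_jitter = 0.15,
                        missing = NULL,
                        half_life_hours = 6.6443 * 24,
                        seed = 1L) {
  three_point_cycles <- match.arg(three_point_cycles)
  cvs <- c(level_cv, shape_cv, rate_cv, inter_cycle_amplitude_cv,
           inter_cycle_k3_cv, noise_cv, time_jitter)
  if (any(cvs < 0)) .stop("variability parameters must be >= 0",
                          "cohort_spec_error")
  if (n_patients < 1L || n_cycles < 1L) {
    .stop("need at least one patient and one cycle", "cohort_spec_error")
  }
  if (is.null(names(vois)) || any(!nzchar(names(vois))) || any(vois <= 0)) {
    .stop("'vois' must be a named vector of positive multipliers",
          "cohort_spec_error")
  }
  with(base_params, {
    if (!(k1 > k2 && k2 > k3 && k3 >= 0)) {
      .stop("base rates must satisfy k1 > k2 > k3 >= 0", "cohort_spec_error")
    }
  })
  structure(as.list(environment()), class = "cohort_spec")
}

.lnorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-patient, per-VOI tri-exponential parameters from the spec's
#' distributions (re-sampling any draw that violates the rate ordering),
#' applies per-cycle amplitude jitter and injected-activity scaling,
#' evaluates the true curves at jittered exact acquisition times,
#' multiplies by log-normal measurement noise, and applies the missingness
#' rules. Fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `measurements` (data frame: `cohort_id`,
#'   `patient_id`, `cycle_id`, `injected_MBq`, `voi`, `t_hours`,
#'   `odr_mGy_per_s`, `slot`), `truth` (per patient x cycle x voi: true
#'   parameters and `true_dose_Gy`, with `true_dose_Gy` equal to
#'   `integrate_tdrc()` of the stored parameters, bit for bit) and `spec`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    .stop("'spec' must be a cohort_spec", "cohort_spec_error")
  }
  lam <- lu177_lambda(spec$half_life_hours)
  .with_seed(spec$seed, {
    meas <- list(); truth <- list()
    for (p in seq_len(spec$n_patients)) {
      pid <- sprintf("P%02d", p)
      late_h <- spec$late_hours[((p - 1L) %% length(spec$late_hours)) + 1L]
      level <- .lnorm_mult(1L, spec$level_cv)
      for (v in seq_along(spec$vois)) {
        voi <- names(spec$vois)[v]
        vscale <- spec$vois[[v]]
        # re-sample until the rate ordering holds (a few tries suffice)
        for (try in 1:50) {
          o2 <- spec$base_params$omega2 * vscale * level *
            .lnorm_mult(1L, spec$shape_cv)
          o3 <- spec$base_params$omega3 * vscale * level *
            .lnorm_mult(1L, spec$shape_cv)
          k1 <- spec$base_params$k1 * .lnorm_mult(1L, spec$rate_cv)
          k2 <- spec$base_params$k2 * .lnorm_mult(1L, spec$rate_cv)
          k3 <- spec$base_params$k3 * .lnorm_mult(1L, spec$rate_cv)
          if (k1 > k2 && k2 > k3 && k3 >= 0) break
          if (try == 50L) .stop("could not draw ordered rates; check CVs",
                                "cohort_spec_error")
        }
        for (cyc in seq_len(spec$n_cycles)) {
          act <- max(rnorm(1L, spec$nominal_activity_MBq,
                           spec$activity_sd_MBq), 1)
          amp_mult <- .lnorm_mult(1L, spec$inter_cycle_amplitude_cv) *
            act / spec$nominal_activity_MBq
          k3c <- k3 * .lnorm_mult(1L, spec$inter_cycle_k3_cv)
          k3c <- min(k3c, k2 * (1 - 2e-3))
          params <- triexp_params(omega2 = o2 * amp_mult,
                                  omega3 = o3 * amp_mult,
                                  k1 = k1, k2 = k2, k3 = k3c, lam = lam)
          truth[[length(truth) + 1L]] <- data.frame(
            patient_id = pid, cycle_id = cyc, voi = voi,
            injected_MBq = act,
            omega1 = params$omega1, omega2 = params$omega2,
            omega3 = params$omega3, k1 = params$k1, k2 = params$k2,
            k3 = params$k3, lam = lam,
            true_dose_Gy = integrate_tdrc(params))
          three_pt <- spec$three_point_cycles == "all" || cyc == 1L
          slots <- if (three_pt) c("EARLY", "24H", "LATE") else "24H"
          nominal <- c(EARLY = 1, `24H` = 24, LATE = late_h)[slots]
          for (si in seq_along(slots)) {
            t_exact <- nominal[[si]] *
              runif(1L, 1 - spec$time_jitter, 1 + spec$time_jitter)
            odr_true <- evaluate_tdrc(params, t_exact * .HOUR_S)
            odr_meas <- odr_true * .lnorm_mult(1L, spec$noise_cv)
            meas[[length(meas) + 1L]] <- data.frame(
              cohort_id = "COHORT1", patient_id = pid, cycle_id = cyc,
              injected_MBq = act, voi = voi, t_hours = t_exact,
              odr_mGy_per_s = odr_meas, slot = slots[si])
          }
        }
      }
    }
    measurements <- do.call(rbind, meas)
    truth_df <- do.call(rbind, truth)
    if (!is.null(spec$missing) && nrow(spec$missing)) {
      for (i in seq_len(nrow(spec$missing))) {
        drop <- measurements$patient_id == spec$missing$patient_id[i] &
          measurements$cycle_id == spec$missing$cycle_id[i] &
          measurements$slot == spec$missing$slot[i]
        measurements <- measurements[!drop, ]
      }
    }
    rownames(measurements) <- NULL
    rownames(truth_df) <- NULL
    list(measurements = measurements, truth = truth_df, spec = spec)
  })
}

#' Construct a patient whose cycles share kinetics exactly
#'
#' Cycle N's curve is exactly `cycle_scales[N]` times the base curve (same
#' rate constants, amplitudes multiplied), the analytic limit in which the
#' single-time-point STP-Intra estimator is exact. Measurements are
#' noise-free.
#'
#' @param base_params A [triexp_params()] (cycle-1 truth).
#' @param cycle_scales Positive per-cycle amplitude scales (cycle 1 first).
#' @param schedule_hours List of acquisition-time vectors per cycle (h).
#' @param injected_MBq Per-cycle injected activities; defaults to scales x
#'   6832 MBq so that activity-proportional substitution is exact too.
#' @param voi,patient_id,cohort_id Labels.
#' @return Same shape as [generate_cohort()]: `measurements` + `truth`.
#' @export
make_conserved_kinetics_patient <- function(base_params, cycle_scales,
                                            schedule_hours = NULL,
                                            injected_MBq = NULL,
                                            voi = "LK", patient_id = "P01",
                                            cohort_id = "COHORT1") {
  if (any(cycle_scales <= 0)) .stop("cycle scales must be > 0",
                                    "cohort_spec_error")
  n_cyc <- length(cycle_scales)
  if (is.null(schedule_hours)) {
    schedule_hours <- c(list(c(1, 24, 96)),
                        rep(list(24), max(n_cyc - 1L, 0L)))
  }
  if (is.null(injected_MBq)) injected_MBq <- 6832 * cycle_scales
  meas <- list(); truth <- list()
  for (cyc in seq_len(n_cyc)) {
    s <- cycle_scales[cyc]
    params <- triexp_params(omega2 = base_params$omega2 * s,
                            omega3 = base_params$omega3 * s,
                            k1 = base_params$k1, k2 = base_params$k2,
                            k3 = base_params$k3, lam = base_params$lam)
    truth[[cyc]] <- data.frame(
      patient_id = patient_id, cycle_id = cyc, voi = voi,
      injected_MBq = injected_MBq[cyc],
      omega1 = params$omega1, omega2 = params$omega2,
      omega3 = params$omega3, k1 = params$k1, k2 = params$k2,
      k3 = params$k3, lam = params$lam,
      true_dose_Gy = integrate_tdrc(params))
    t_h <- schedule_hours[[cyc]]
    slot <- ifelse(t_h < 6, "EARLY", ifelse(t_h <= 48, "24H", "LATE"))
    meas[[cyc]] <- data.frame(
      cohort_id = cohort_id, patient_id = patient_id, cycle_id = cyc,
      injected_MBq = injected_MBq[cyc], voi = voi, t_hours = t_h,
      odr_mGy_per_s = evaluate_tdrc(params, t_h * .HOUR_S), slot = slot)
  }
  list(measurements = do.call(rbind, meas), truth = do.call(rbind, truth))
}

#' Voxelized ellipsoid phantom with known organ values
#'
#' Builds a scalar volume containing uniform-valued ellipsoid organs on a
#' regular grid, together with one binary mask per organ and the analytic
#' table of assigned values — the mean over each mask equals the assigned
#' value exactly, which makes the phantom an oracle for VOI statistics.
#'
#' @param dim_vox Grid size, length 3.
#' @param spacing_mm Voxel spacing (mm), length 3.
#' @param organs List of organs: each a list with `label`, `center_mm`
#'   (world coordinates), `radii_mm` (semi-axes), `value` (assigned voxel
#'   value). Later organs take priority where they overlap.
#' @param background Background voxel value.
#' @param unit Unit tag of the phantom volume.
#' @return A list with `volume` (a [scalar_volume()]), `masks` (named list
#'   of [voi_mask()]) and `table` (data frame `label`, `value`,
#'   `n_voxels`).
#' @export
generate_phantom <- function(dim_vox = c(32L, 32L, 32L),
                             spacing_mm = c(4.4, 4.4, 4.4),
                             organs, background = 0,
                             unit = "MBq/mL") {
  if (!length(organs)) .stop("need at least one organ", "cohort_spec_error")
  vals <- array(background, dim = dim_vox)
  cx <- (seq_len(dim_vox[1L]) - 1) * spacing_mm[1L]
  cy <- (seq_len(dim_vox[2L]) - 1) * spacing_mm[2L]
  cz <- (seq_len(dim_vox[3L]) - 1) * spacing_mm[3L]
  extent <- (dim_vox - 1) * spacing_mm
  masks <- list(); tab <- list()
  for (org in organs) {
    if (any(org$radii_mm <= 0)) {
      .stop(sprintf("organ '%s' has a zero/negative radius", org$label),
            "cohort_spec_error")
    }
    if (any(org$center_mm - org$radii_mm < 0) ||
        any(org$center_mm + org$radii_mm > extent)) {
      .stop(sprintf("organ '%s' extends outside the grid", org$label),
            "cohort_spec_error")
    }
    dx2 <- ((cx - org$center_mm[1L]) / org$radii_mm[1L])^2
    dy2 <- ((cy - org$center_mm[2L]) / org$radii_mm[2L])^2
    dz2 <- ((cz - org$center_mm[3L]) / org$radii_mm[3L])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
    if (!any(inside)) {
      .stop(sprintf("organ '%s' covers no voxel", org$label),
            "cohort_spec_error")
    }
    vals[inside] <- org$value
    masks[[org$label]] <- voi_mask(inside, label = org$label,
                                   spacing = spacing_mm)
    tab[[length(tab) + 1L]] <- data.frame(label = org$label,
                                          value = org$value,
                                          n_voxels = sum(inside))
  }
  list(volume = scalar_volume(vals, spacing = spacing_mm, unit = unit),
       masks = masks,
       table = do.call(rbind, tab))
}
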