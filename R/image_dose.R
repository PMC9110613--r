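# Quantitative-SPECT plumbing: sensitivity calibration, dead-time
# correction, dose-rate map scaling, and VOI mean dose-rate (ODR)
# extraction. The Monte Carlo dose-rate computation itself is out of scope;
# local_deposition_map() is an explicitly non-Monte-Carlo substitute that
# models no cross-dose.

#' Gamma-camera calibration parameters
#'
#' @param sensitivity_cps_per_MBq Tomographic sensitivity factor (counts
#'   per second per MBq), experimentally determined on a phantom with known
#'   activity; e.g. 7.6 cps/MBq (GE Discovery NM CT 670 with 3/8" crystal)
#'   or 18 cps/MBq (870 DR with 5/8" crystal).
#' @param deadtime_tau_s Dead-time constant in seconds (e.g. `1.87e-6`).
#' @param duration_s Effective acquisition duration per reconstructed
#'   volume, in seconds.
#' @return A list of class `calibration_config`.
#' @export
calibration_config <- function(sensitivity_cps_per_MBq,
                               deadtime_tau_s = 1.87e-6,
                               duration_s = 900) {
  if (sensitivity_cps_per_MBq <= 0) {
    .stop("sensitivity must be > 0", "calibration_error")
  }
  if (deadtime_tau_s < 0) .stop("dead time must be >= 0", "calibration_error")
  if (duration_s <= 0) .stop("duration must be > 0", "calibration_error")
  structure(list(sensitivity_cps_per_MBq = sensitivity_cps_per_MBq,
                 deadtime_tau_s = deadtime_tau_s,
                 duration_s = duration_s),
            class = "calibration_config")
}

#' Convert reconstructed counts to activity concentration
#'
#' Voxel counts acquired over `cal$duration_s` are converted to count
#' rates, divided by the sensitivity factor to obtain voxel activity (MBq),
#' and divided by the voxel volume to give concentration in MBq/mL.
#'
#' @param volume A [scalar_volume()] with unit `"counts"`.
#' @param cal A [calibration_config()].
#' @return A list with `volume` (a `scalar_volume` in MBq/mL) and
#'   `total_MBq` (summed activity).
#' @examples
#' v <- scalar_volume(array(6840, c(1, 1, 1)), spacing = c(4.4, 4.4, 4.4),
#'                    unit = "counts")
#' counts_to_activity(v, calibration_config(7.6, duration_s = 900))$total_MBq
#' @export
counts_to_activity <- function(volume, cal) {
  if (!inherits(volume, "scalar_volume") || volume$unit != "counts") {
    .stop("'volume' must be a scalar_volume with unit 'counts'",
          "unit_error")
  }
  if (!inherits(cal, "calibration_config")) {
    .stop("'cal' must be a calibration_config", "calibration_error")
  }
  vox_ml <- voxel_volume_ml(volume)
  act_MBq <- (volume$values / cal$duration_s) / cal$sensitivity_cps_per_MBq
  conc <- scalar_volume(act_MBq / vox_ml, spacing = volume$spacing,
                        origin = volume$origin, unit = "MBq/mL")
  list(volume = conc, total_MBq = sum(act_MBq))
}

#' Dead-time correction of an observed count rate
#'
#' Recovers the true event rate `n` from the observed rate `m` under the
#' paralyzable detector model \eqn{m = n e^{-\tau n}} (principal branch,
#' via Lambert W), or the non-paralyzable model \eqn{n = m/(1 - m\tau)}.
#' The paralyzable solution exists only while \eqn{m \tau < e^{-1}}; beyond
#' that the observed rate is past the peak of the paralyzable response and
#' a saturation error is raised.
#'
#' @param observed_cps Observed count rate(s), cps, `>= 0`.
#' @param tau_s Dead-time constant in seconds (0 disables the correction).
#' @param model `"paralyzable"` (default for scintillation cameras) or
#'   `"nonparalyzable"`.
#' @return True count rate(s), cps; always `>=` the observed rate.
#' @examples
#' deadtime_correct(10000, 1.87e-6)   # ~1.0192e4 cps
#' @export
deadtime_correct <- function(observed_cps, tau_s,
                             model = c("paralyzable", "nonparalyzable")) {
  model <- match.arg(model)
  if (any(observed_cps < 0)) .stop("count rate must be >= 0",
                                   "tdrc_domain_error")
  if (tau_s < 0) .stop("dead time must be >= 0", "tdrc_domain_error")
  if (tau_s == 0) return(observed_cps)
  if (model == "nonparalyzable") {
    if (any(observed_cps * tau_s >= 1)) {
      .stop("observed rate saturates the non-paralyzable model",
            "deadtime_saturation_error")
    }
    return(observed_cps / (1 - observed_cps * tau_s))
  }
  x <- -tau_s * observed_cps
  if (any(x < -exp(-1))) {
    .stop("observed rate exceeds the peak of the paralyzable response (m*tau >= 1/e); true rate is not recoverable",
          "deadtime_saturation_error")
  }
  # m = n exp(-tau n)  =>  n = -W0(-tau m)/tau
  w <- vapply(x, function(xi) if (xi == 0) 0 else pracma::lambertWp(xi),
              numeric(1L))
  -w / tau_s
}

#' Forward paralyzable dead-time response
#'
#' Observed rate produced by a true rate `n`: \eqn{m = n e^{-\tau n}}.
#' Inverse of [deadtime_correct()] on the solvable branch.
#'
#' @param true_cps True event rate(s), cps.
#' @param tau_s Dead-time constant, seconds.
#' @return Observed count rate(s), cps.
#' @export
deadtime_observe <- function(true_cps, tau_s) {
  true_cps * exp(-tau_s * true_cps)
}

#' Scale a unit-activity dose-rate map to the imaged total activity
#'
#' Dose-rate distributions computed for a normalized 1-MBq source are
#' scaled voxelwise to the total activity estimated from the SPECT image.
#'
#' @param unit_map A [scalar_volume()] with unit `"mGy/s per MBq"`.
#' @param total_MBq Total activity (MBq), `>= 0`.
#' @return A `scalar_volume` in mGy/s.
#' @export
scale_dose_rate_map <- function(unit_map, total_MBq) {
  if (!inherits(unit_map, "scalar_volume") ||
      unit_map$unit != "mGy/s per MBq") {
    .stop("'unit_map' must be a scalar_volume with unit 'mGy/s per MBq'",
          "unit_error")
  }
  if (!is.finite(total_MBq) || total_MBq < 0) {
    .stop("total activity must be >= 0", "tdrc_domain_error")
  }
  scalar_volume(unit_map$values * total_MBq, spacing = unit_map$spacing,
                origin = unit_map$origin, unit = "mGy/s")
}

#' Organ dose rate: mean dose rate over a VOI
#'
#' Arithmetic mean of the dose-rate values of all voxels belonging to the
#' VOI. When map and mask live on different grids, the dose-rate map is
#' interpolated trilinearly onto the mask grid (the mask itself is never
#' interpolated), matching the convention of upsampling dose maps to the
#' CT/VOI spacing.
#'
#' @param map A [scalar_volume()] in mGy/s.
#' @param mask A [voi_mask()].
#' @return Mean dose rate over the VOI (mGy/s).
#' @export
compute_odr <- function(map, mask) {
  if (!inherits(map, "scalar_volume") || map$unit != "mGy/s") {
    .stop("'map' must be a scalar_volume in mGy/s", "unit_error")
  }
  if (!inherits(mask, "voi_mask")) {
    .stop("'mask' must be a voi_mask", "volume_geometry_error")
  }
  if (!any(mask$values)) .stop("empty VOI mask", "empty_voi_error")
  if (!same_grid(map, mask)) {
    map <- resample_trilinear(map, mask)
  }
  mean(map$values[mask$values])
}

#' Local-deposition dose-rate map (non-Monte-Carlo substitute)
#'
#' Converts an activity-concentration volume into a dose-rate map under the
#' local-deposition approximation: every decay deposits a fixed mean energy
#' in its own voxel. No particle transport is performed, so cross-dose
#' (dose to a region from activity elsewhere) is absent by construction;
#' the result is tagged per-MBq (`"mGy/s per MBq"`, normalized by the total
#' activity) for use with [scale_dose_rate_map()].
#'
#' @param activity A [scalar_volume()] in MBq/mL.
#' @param mean_energy_J Mean locally deposited energy per decay (J). The
#'   default `2.37e-14` J (148 keV) is the mean beta plus conversion/Auger
#'   electron energy per Lu-177 decay; photons mostly escape the voxel and
#'   are not modelled here.
#' @param density_g_ml Tissue density (g/mL), default water.
#' @return A list with `unit_map` (a `scalar_volume`, mGy/s per MBq),
#'   `map_mGy_s` (the unnormalized map) and `total_MBq`.
#' @export
local_deposition_map <- function(activity, mean_energy_J = 2.37e-14,
                                 density_g_ml = 1.0) {
  if (!inherits(activity, "scalar_volume") || activity$unit != "MBq/mL") {
    .stop("'activity' must be a scalar_volume in MBq/mL", "unit_error")
  }
  if (!is.finite(mean_energy_J) || mean_energy_J <= 0) {
    .stop("mean energy per decay must be > 0", "calibration_error")
  }
  if (!is.finite(density_g_ml) || density_g_ml <= 0) {
    .stop("density must be > 0", "calibration_error")
  }
  if (any(activity$values < 0)) {
    .stop("activity must be non-negative", "tdrc_domain_error")
  }
  # MBq/mL -> decays/s per mL -> J/s per kg -> mGy/s
  gy_per_s <- activity$values * 1e6 * mean_energy_J /
    (density_g_ml * 1e-3)
  map <- scalar_volume(gy_per_s * 1e3, spacing = activity$spacing,
                       origin = activity$origin, unit = "mGy/s")
  total_MBq <- sum(activity$values) * voxel_volume_ml(activity)
  unit_vals <- if (total_MBq > 0) map$values / total_MBq else map$values
  list(unit_map = scalar_volume(unit_vals, spacing = activity$spacing,
                                origin = activity$origin,
                                unit = "mGy/s per MBq"),
       map_mGy_s = map,
       total_MBq = total_MBq)
}
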