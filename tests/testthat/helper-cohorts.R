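# Shared fixtures, built in code.

# kidney-like baseline truth used across tests
base_truth <- function(scale = 1) {
  triexp_params(omega2 = 1.64e-2 * scale, omega3 = 9.8e-3 * scale,
                k1 = 3.85e-4, k2 = 6.42e-5, k3 = 2.139e-6)
}

# draw one set of heterogeneous organ parameters the way the generator does
draw_organ_params <- function(level_cv = 0.35, shape_cv = 0.15,
                              rate_cv = 0.15) {
  m <- function(cv) {
    sdl <- sqrt(log(1 + cv^2))
    exp(rnorm(1, -sdl^2 / 2, sdl))
  }
  repeat {
    L <- m(level_cv)
    p <- tryCatch(
      triexp_params(omega2 = 1.64e-2 * L * m(shape_cv),
                    omega3 = 9.8e-3 * L * m(shape_cv),
                    k1 = 3.85e-4 * m(rate_cv), k2 = 6.42e-5 * m(rate_cv),
                    k3 = 2.139e-6 * m(rate_cv)),
      error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
}

# cohort of patients sharing identical per-MBq kinetics (the M3 exactness
# limit): amplitudes proportional to injected activity
homogeneous_cohort <- function(n_patients = 10, t_late = 96) {
  meas <- list()
  for (i in seq_len(n_patients)) {
    act <- 6000 + 200 * i
    p <- base_truth(scale = act / 6832)
    t_h <- c(1, 24, t_late)
    meas[[i]] <- data.frame(
      cohort_id = "H", patient_id = sprintf("P%02d", i), cycle_id = 1L,
      injected_MBq = act, voi = "LK", t_hours = t_h,
      odr_mGy_per_s = evaluate_tdrc(p, t_h * 3600),
      slot = c("EARLY", "24H", "LATE"))
  }
  do.call(rbind, meas)
}
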