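#' Synthetic RpaA~P and RpaB~P phosphorylation trajectories
#'
#' Emulates the measured dynamics of the two response regulators under a
#' given light condition, on an arbitrary raw scale (all downstream use is
#' after joint 0-1 normalization across conditions):
#'
#' * RpaA~P is clock-driven and light-insensitive: a monotone logistic
#'   ramp from ~0.2 at dawn to ~1.0 at dusk, centered at hour 6 (time
#'   constant 1.5 h), identical in every condition.
#' * RpaB~P moves opposite to light changes, multiplicatively on a
#'   baseline of 1: it falls 3.1-fold within 15 min of the High Light
#'   pulse onset, rises 1.9-fold within 15 min of the Shade pulse onset,
#'   and rises 1.7-fold between hours 10 and 12 of the Clear Day sunset
#'   ramp (Shade inherits the Clear Day baseline). After a pulse ends the
#'   perturbation relaxes back exponentially with a 30-min time constant.
#'
#' The trajectories are deterministic functions of the condition and time
#' grid; `noise_sd > 0` adds seeded Gaussian measurement noise (clipped at
#' zero) for robustness experiments.
#'
#' @param light a [light_profile()], or a condition name.
#' @param times hours since dawn at which to report levels; defaults to
#'   the light profile's grid.
#' @param noise_sd measurement noise standard deviation on the raw scale.
#' @param seed RNG seed, used only when `noise_sd > 0`.
#' @return named list with data.frames `RpaA` and `RpaB`, each with
#'   columns `time_h` and `value` (raw scale, before 0-1 normalization).
#' @examples
#' tr <- simulate_regulators("HighLightPulse")
#' @export
simulate_regulators <- function(light, times = NULL, noise_sd = 0,
                                seed = 1L) {
  cond <- if (is.character(light)) light else light_condition(light)
  if (is.null(times))
    times <- if (is.character(light)) seq(0, 12, by = 0.05)
             else light$time_h
  rpaA <- 0.2 + 0.8 * stats::plogis((times - 6) / 1.5)
  rpaB <- rpab_raw(cond, times)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    rpaA <- pmax(0, rpaA + stats::rnorm(length(times), 0, noise_sd))
    rpaB <- pmax(0, rpaB + stats::rnorm(length(times), 0, noise_sd))
  }
  list(RpaA = data.frame(time_h = times, value = rpaA),
       RpaB = data.frame(time_h = times, value = rpaB))
}

# Raw RpaB~P level as a deterministic function of condition and time.
# Pulse responses complete linearly over the first 15 min (0.25 h) of the
# pulse, hold until the pulse ends at hour 9, then relax exponentially to
# the ambient baseline with a 30-min time constant. The Clear Day baseline
# carries a multiplicative 1.7-fold linear sunset rise over hours 10-12.
rpab_raw <- function(cond, t) {
  sunset <- function(t) ifelse(t <= 10, 1, 1 + 0.7 * pmin(t - 10, 2) / 2)
  pulse_factor <- function(t, target) {
    ifelse(t < 8, 1,
    ifelse(t < 8.25, 1 + (target - 1) * (t - 8) / 0.25,
    ifelse(t <= 9, target,
           1 + (target - 1) * exp(-(t - 9) / 0.5))))
  }
  switch(cond,
    LowLight = rep(1, length(t)),
    ClearDay = sunset(t),
    HighLightPulse = pulse_factor(t, 1 / 3.1),
    ShadePulse = sunset(t) * pulse_factor(t, 1.9),
    stop("unknown light condition '", cond, "'", call. = FALSE))
}

#' Generate 0-1 normalized regulator inputs for all four light conditions
#'
#' Runs [simulate_regulators()] for every condition, then rescales each
#' regulator's pooled values across all four conditions jointly to `[0,
#' 1]` (see [scale_unit_interval()]), matching how measured
#' phosphorylation levels are prepared as model inputs.
#'
#' @inheritParams simulate_regulators
#' @param conditions conditions to include (the scaling pool).
#' @return long data.frame with columns `condition`, `regulator`,
#'   `time_h`, `value` (values in `[0, 1]`).
#' @export
regulator_inputs <- function(times = seq(0, 12, by = 0.05),
                             conditions = c("LowLight", "ClearDay",
                                            "HighLightPulse",
                                            "ShadePulse"),
                             noise_sd = 0, seed = 1L) {
  raw <- do.call(rbind, lapply(conditions, function(cc) {
    tr <- simulate_regulators(cc, times, noise_sd = noise_sd,
                              seed = seed + match(cc, conditions))
    do.call(rbind, lapply(names(tr), function(r)
      data.frame(condition = cc, regulator = r,
                 time_h = tr[[r]]$time_h, value = tr[[r]]$value)))
  }))
  for (r in unique(raw$regulator)) {
    idx <- raw$regulator == r
    raw$value[idx] <- scale_unit_interval(raw$value[idx])
  }
  rownames(raw) <- NULL
  raw
}
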