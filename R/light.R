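#' Diel light-intensity profiles
#'
#' Generates the four experimental light regimes over a 12-hour light
#' period, updated every 3 minutes (0.05 h):
#' \describe{
#'   \item{LowLight}{constant 50 umol photons m-2 s-1.}
#'   \item{ClearDay}{smooth unimodal half-sine, `600 * sin(pi * t / 12)`,
#'     peaking at 600 at hour 6 — a stand-in for measured clear-sky solar
#'     irradiance.}
#'   \item{HighLightPulse}{Low Light baseline with a 1-hour step up to the
#'     Clear Day intensities on `[8, 9)` h (a cloud clearing).}
#'   \item{ShadePulse}{Clear Day divided by 10 exactly on `[8, 9)` h (a
#'     cloud passing), Clear Day elsewhere.}
#' }
#'
#' @param condition one of `"LowLight"`, `"ClearDay"`, `"HighLightPulse"`,
#'   `"ShadePulse"`.
#' @param step_h time step in hours (default 0.05, i.e. 3 minutes).
#' @return data.frame of class `"light_profile"` with columns `time_h`
#'   (hours since dawn, spanning `[0, 12]`) and `intensity` (umol photons
#'   m-2 s-1), and attribute `condition`.
#' @examples
#' lp <- light_profile("ClearDay")
#' max(lp$intensity)  # 600
#' @export
light_profile <- function(condition, step_h = 0.05) {
  valid <- c("LowLight", "ClearDay", "HighLightPulse", "ShadePulse")
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% valid)
    stop("unknown light condition; must be one of: ",
         paste(valid, collapse = ", "), call. = FALSE)
  t <- seq(0, 12, by = step_h)
  clear <- 600 * sin(pi * t / 12)
  pulse <- t >= 8 & t < 9
  intensity <- switch(condition,
    LowLight = rep(50, length(t)),
    ClearDay = clear,
    HighLightPulse = ifelse(pulse, clear, 50),
    ShadePulse = ifelse(pulse, clear / 10, clear))
  structure(data.frame(time_h = t, intensity = intensity),
            class = c("light_profile", "data.frame"),
            condition = condition)
}

light_condition <- function(light) {
  cond <- attr(light, "condition")
  if (is.null(cond)) stop("not a light_profile object", call. = FALSE)
  cond
}
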