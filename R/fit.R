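#' Fit a dusk-cluster promoter model by multi-start bounded least squares
#'
#' Fits the AND-gate Hill model of one dusk cluster's average expression to
#' scaled (0-1) cluster trajectories, by default jointly to the Clear Day
#' and Shade pulse conditions with shared parameters. Each condition is
#' simulated with its own initial value, taken as that condition's first
#' observation. The objective is the concatenated residual vector over all
#' fitted conditions; minimization uses bounded Levenberg-Marquardt
#' (trust-region) least squares started from `n_starts` Latin-hypercube
#' points inside the parameter box.
#'
#' @param data long data.frame with columns `condition`, `time_h`, `value`
#'   holding the 0-1 scaled cluster mean expression.
#' @param regulators long data.frame with columns `condition`, `regulator`,
#'   `time_h`, `value` holding 0-1 scaled driver levels (`RpaA`, `RpaB`,
#'   and/or a feedback cluster name), or a nested list
#'   `regulators[[condition]][[regulator]]` of data.frames.
#' @param spec a [dusk_model_spec()].
#' @param conditions conditions fitted jointly (default Clear Day and
#'   Shade pulse).
#' @param bounds parameter box, see [hill_bounds()].
#' @param n_starts number of Latin-hypercube starting points (>= 1).
#' @param seed integer seed controlling the starting points; the fit is
#'   reproducible bit-wise for a fixed `(seed, n_starts)`.
#' @param interpolation regulator interpolation rule, `"linear"` or
#'   `"constant"`.
#' @param dt fine-grid step (hours) of the fitting integrator.
#' @return an object of class `"dusk_fit"`; see Details.
#' @details The returned object supports `print()`, `summary()`, `coef()`,
#'   `fitted()`, `residuals()`, `predict()`, `plot()`, `simulate()`,
#'   `deviance()` and `AIC()`. Its `error` element is the root-sum-square
#'   misfit recomputed from an adaptive-integrator simulation of the
#'   best-fit parameters (see [simulate_cluster()], [model_error()]).
#' @export
fit_dusk_model <- function(data, regulators, spec,
                           conditions = c("ClearDay", "ShadePulse"),
                           bounds = hill_bounds(),
                           n_starts = 64L, seed = 1L,
                           interpolation = "linear", dt = 0.01) {
  stopifnot(inherits(spec, "dusk_model_spec"))
  if (n_starts < 1L) stop("'n_starts' must be >= 1", call. = FALSE)
  regs <- as_regulator_list(regulators)
  missing_cond <- setdiff(conditions, intersect(names(regs),
                                                unique(data$condition)))
  if (length(missing_cond))
    stop("no data and/or regulators for condition(s): ",
         paste(missing_cond, collapse = ", "), call. = FALSE)

  obs <- lapply(stats::setNames(conditions, conditions), function(cc) {
    d <- data[data$condition == cc, c("time_h", "value")]
    d[order(d$time_h), ]
  })
  interp <- lapply(regs[conditions], build_interpolants,
                   spec = spec, interpolation = interpolation)

  nm <- param_names(spec)
  lower <- vapply(nm, function(p) bounds[[sub("_[ABY]$", "", p)]][1], 0)
  upper <- vapply(nm, function(p) bounds[[sub("_[ABY]$", "", p)]][2], 0)

  resid_fun <- function(theta) {
    names(theta) <- nm
    unlist(lapply(conditions, function(cc) {
      sim <- simulate_exact_step(as.list(theta), spec, interp[[cc]],
                                 obs[[cc]]$time_h, X0 = obs[[cc]]$value[1],
                                 dt = dt)
      sim - obs[[cc]]$value
    }), use.names = FALSE)
  }

  set.seed(as.integer(seed))
  starts <- lhs::randomLHS(n_starts, length(nm))
  starts <- sweep(sweep(starts, 2, upper - lower, "*"), 2, lower, "+")

  fits <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    fits[[s]] <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) e)
  }
  ok <- vapply(fits, function(f) inherits(f, "nls.lm"), TRUE)
  if (!any(ok)) {
    msgs <- vapply(fits, conditionMessage, "")
    stop("all ", n_starts, " starts failed to converge:\n",
         paste0("  start ", seq_len(n_starts), ": ", msgs, collapse = "\n"),
         call. = FALSE)
  }
  rss_by_start <- vapply(fits, function(f)
    if (inherits(f, "nls.lm")) f$deviance else Inf, 0)
  best <- fits[[which.min(rss_by_start)]]
  theta <- pmin(pmax(best$par, lower), upper)  # guard roundoff at bounds
  params <- dusk_model_params(spec, theta)

  fitted_tr <- lapply(conditions, function(cc)
    simulate_cluster(params, spec, regs[[cc]], obs[[cc]]$time_h,
                     X0 = obs[[cc]]$value[1],
                     interpolation = interpolation))
  names(fitted_tr) <- conditions
  err <- model_error(fitted_tr, lapply(obs, `[[`, "value"))

  structure(list(
    spec = spec, params = params, error = err, rss = err^2,
    n_data = sum(vapply(obs, nrow, 0L)), k_params = n_free_params(spec),
    n_starts = n_starts, seed = as.integer(seed),
    conditions = conditions, data = obs, regulators = regs[conditions],
    fitted = fitted_tr, interpolation = interpolation, bounds = bounds,
    start_rss = rss_by_start,
    convergence = list(info = best$info, message = best$message,
                       n_failed = sum(!ok))
  ), class = "dusk_fit")
}

# Accept either the long data.frame or the nested-list regulator layout.
as_regulator_list <- function(regulators) {
  if (is.data.frame(regulators)) {
    needed <- c("condition", "regulator", "time_h", "value")
    if (!all(needed %in% names(regulators)))
      stop("regulator data.frame needs columns ",
           paste(needed, collapse = ", "), call. = FALSE)
    lapply(split(regulators, regulators$condition), function(d)
      lapply(split(d[c("time_h", "value")], d$regulator),
             function(x) x[order(x$time_h), ]))
  } else if (is.list(regulators)) {
    regulators
  } else stop("'regulators' must be a data.frame or nested list",
              call. = FALSE)
}

#' @export
print.dusk_fit <- function(x, digits = 3, ...) {
  print(x$spec)
  cat("Fitted to ", paste(x$conditions, collapse = " + "),
      " (", x$n_data, " points, ", x$n_starts, " starts, seed ", x$seed,
      ")\n", sep = "")
  cat("Misfit (root-sum-square): ", format(x$error, digits = digits),
      "\n", sep = "")
  cat("Coefficients:\n")
  print(round(stats::setNames(as.numeric(x$params), names(x$params)),
              digits))
  invisible(x)
}

#' @export
summary.dusk_fit <- function(object, ...) {
  per_cond <- vapply(object$conditions, function(cc)
    sqrt(mean((object$fitted[[cc]] - object$data[[cc]]$value)^2)), 0)
  at_bound <- names(object$params)[
    object$params <= vapply(names(object$params), function(p)
      object$bounds[[sub("_[ABY]$", "", p)]][1], 0) |
    object$params >= vapply(names(object$params), function(p)
      object$bounds[[sub("_[ABY]$", "", p)]][2], 0)]
  structure(list(fit = object, rms_by_condition = per_cond,
                 aic = AIC(object), at_bound = at_bound),
            class = "summary.dusk_fit")
}

#' @export
print.summary.dusk_fit <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("Per-condition RMS:\n")
  print(round(x$rms_by_condition, digits))
  cat("AIC (n log(RSS/n) + 2k): ", format(x$aic, digits = digits),
      "\n", sep = "")
  if (length(x$at_bound))
    cat("Parameters at a bound: ", paste(x$at_bound, collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @export
coef.dusk_fit <- function(object, ...) {
  stats::setNames(as.numeric(object$params), names(object$params))
}

#' @export
fitted.dusk_fit <- function(object, ...) object$fitted

#' @export
residuals.dusk_fit <- function(object, ...) {
  lapply(stats::setNames(object$conditions, object$conditions), function(cc)
    object$data[[cc]]$value - object$fitted[[cc]])
}

#' @export
deviance.dusk_fit <- function(object, ...) object$rss

#' AIC for least-squares dusk-cluster fits
#'
#' `AIC = n log(RSS/n) + 2k`, with `n` the number of fitted residuals and
#' `k` the number of free parameters (5 for single-regulator models, 7 for
#' joint activation, 9 with a feedback term).
#'
#' @param object a `dusk_fit`.
#' @param ... ignored.
#' @param k unused; present for generic compatibility.
#' @return numeric scalar.
#' @export
AIC.dusk_fit <- function(object, ..., k = 2) {
  object$n_data * log(object$rss / object$n_data) + 2 * object$k_params
}

#' Predict cluster expression from a fitted model
#'
#' Simulates the fitted model under (possibly new) regulator inputs.
#'
#' @param object a `dusk_fit`.
#' @param regulators optional replacement regulator inputs (same layouts
#'   as in [fit_dusk_model()]); defaults to the training inputs.
#' @param conditions conditions to simulate.
#' @param t_grid optional time grid; defaults to each condition's fitted
#'   observation times.
#' @param X0 optional named vector of initial values per condition;
#'   defaults to the first fitted observation (or the first simulated
#'   regulator steady value for new conditions).
#' @param ... ignored.
#' @return named list of data.frames (`time_h`, `value`), one per
#'   condition.
#' @export
predict.dusk_fit <- function(object, regulators = NULL, conditions = NULL,
                             t_grid = NULL, X0 = NULL, ...) {
  regs <- if (is.null(regulators)) object$regulators
          else as_regulator_list(regulators)
  if (is.null(conditions)) conditions <- intersect(object$conditions,
                                                   names(regs))
  out <- lapply(stats::setNames(conditions, conditions), function(cc) {
    tg <- if (!is.null(t_grid)) t_grid else object$data[[cc]]$time_h
    x0 <- if (!is.null(X0) && cc %in% names(X0)) X0[[cc]]
          else if (cc %in% names(object$data)) object$data[[cc]]$value[1]
          else stop("supply 'X0' for new condition '", cc, "'",
                    call. = FALSE)
    data.frame(time_h = tg,
               value = simulate_cluster(object$params, object$spec,
                                        regs[[cc]], tg, X0 = x0,
                                        interpolation =
                                          object$interpolation))
  })
  out
}

#' Simulate noisy observations from a fitted dusk-cluster model
#'
#' Draws `nsim` replicate measurement sets: the fitted trajectory per
#' condition plus i.i.d. Gaussian noise, clipped at zero.
#'
#' @param object a `dusk_fit`.
#' @param nsim number of replicate data sets.
#' @param seed RNG seed.
#' @param noise_sd measurement noise standard deviation (normalized
#'   expression units).
#' @param ... ignored.
#' @return list of `nsim` long data.frames (`condition`, `time_h`,
#'   `value`).
#' @export
simulate.dusk_fit <- function(object, nsim = 1, seed = NULL,
                              noise_sd = 0.05, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  base <- do.call(rbind, lapply(object$conditions, function(cc)
    data.frame(condition = cc, time_h = object$data[[cc]]$time_h,
               value = object$fitted[[cc]])))
  lapply(seq_len(nsim), function(i) {
    out <- base
    out$value <- pmax(0, out$value + stats::rnorm(nrow(out), 0, noise_sd))
    out
  })
}

#' @export
plot.dusk_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$conditions)))
  on.exit(graphics::par(old))
  for (cc in x$conditions) {
    graphics::plot(x$data[[cc]]$time_h, x$data[[cc]]$value,
                   xlab = "hours since dawn",
                   ylab = "scaled cluster expression",
                   main = paste(x$spec$target, "-", cc),
                   ylim = range(0, 1, x$data[[cc]]$value,
                                x$fitted[[cc]]), ...)
    graphics::lines(x$data[[cc]]$time_h, x$fitted[[cc]], col = 2, lwd = 2)
  }
  invisible(x)
}

#' Rank dusk-cluster model fits by AIC
#'
#' Compares fits of alternative topologies to the same data by
#' `AIC = n log(RSS/n) + 2k`, ranked ascending (most parsimonious
#' adequate model first).
#'
#' @param ... `dusk_fit` objects, or a single list of them.
#' @return data.frame of class `"dusk_model_comparison"` with columns
#'   `model`, `cluster`, `k`, `n`, `error`, `rss`, `aic`, `delta_aic`,
#'   sorted by AIC.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "dusk_fit"))
    fits <- fits[[1]]
  stopifnot(all(vapply(fits, inherits, TRUE, "dusk_fit")))
  n <- unique(vapply(fits, `[[`, 0L, "n_data"))
  if (length(n) != 1L)
    stop("fits were made against different data sizes (n = ",
         paste(n, collapse = ", "), "); AIC comparison is invalid",
         call. = FALSE)
  lab <- vapply(fits, function(f) {
    fb <- f$spec$feedback
    if (is.null(fb)) paste(f$spec$regulators, collapse = " and ")
    else paste0("feedback ", fb$source, " ", substr(fb$mode, 1, 3), ".")
  }, "")
  out <- data.frame(
    model = lab,
    cluster = vapply(fits, function(f) f$spec$target, ""),
    k = vapply(fits, `[[`, 0L, "k_params"),
    n = n,
    error = vapply(fits, `[[`, 0, "error"),
    rss = vapply(fits, `[[`, 0, "rss"),
    aic = vapply(fits, function(f) AIC(f), 0))
  out <- out[order(out$aic), ]
  out$delta_aic <- out$aic - out$aic[1]
  rownames(out) <- NULL
  class(out) <- c("dusk_model_comparison", "data.frame")
  out
}

#' Rank published (or externally computed) fits by AIC
#'
#' Convenience form of [compare_models()] that works from reported misfit
#' values rather than `dusk_fit` objects, e.g. for the bundled reference
#' table ([dusk_model_presets()]).
#'
#' @param errors root-sum-square misfits (same data, same `n`).
#' @param k number of free parameters per model.
#' @param n number of residuals underlying each misfit.
#' @param labels optional model labels.
#' @return data.frame sorted ascending by AIC.
#' @export
aic_rank <- function(errors, k, n, labels = NULL) {
  stopifnot(length(errors) == length(k))
  if (is.null(labels)) labels <- paste0("model", seq_along(errors))
  out <- data.frame(model = labels, k = k, n = n, error = errors,
                    aic = n * log(errors^2 / n) + 2 * k)
  out <- out[order(out$aic), ]
  rownames(out) <- NULL
  out
}

#' @export
print.dusk_model_comparison <- function(x, digits = 3, ...) {
  cat("Model comparison (ascending AIC):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
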