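#' Parameter bounds for the dusk-cluster promoter model
#'
#' The box constraints used for fitting: Hill coefficient `H` in `[0, 7]`,
#' maximal transcription rate `beta` in `[0, 80]` /hr, decay/dilution rate
#' `alpha` in `[0, 80]` /hr, basal transcription rate `B` in `[0, 10]` /hr
#' (all rates in normalized expression units per hour), and coefficients of
#' activation/repression `K` in `[0, 1]` normalized expression units.
#'
#' @return named list of length-2 numeric vectors `c(lower, upper)`.
#' @export
hill_bounds <- function() {
  list(B = c(0, 10), beta = c(0, 80), alpha = c(0, 80),
       K = c(0, 1), H = c(0, 7))
}

#' Specify a dusk-cluster model topology
#'
#' A model describes the average expression `X` of one dusk cluster as an
#' AND gate: `dX/dt = B + beta * prod(f_i(u_i(t))) - alpha * X`, where the
#' product runs over a Hill term per regulator (phosphorylated RpaA and/or
#' RpaB, both activating) and optionally one feedback term driven by the
#' measured expression of another cluster (activating or repressing).
#'
#' @param target cluster being modeled: `"Early"`, `"Middle"` or `"Late"`.
#' @param regulators character subset of `c("RpaA", "RpaB")`.
#' @param feedback `NULL`, or a list/character vector with elements
#'   `source` (the driving cluster, must differ from `target`) and `mode`
#'   (`"activation"` or `"repression"`).
#' @return an object of class `"dusk_model_spec"`.
#' @examples
#' dusk_model_spec("Early", c("RpaA", "RpaB"),
#'                 feedback = list(source = "Late", mode = "repression"))
#' @export
dusk_model_spec <- function(target = c("Early", "Middle", "Late"),
                            regulators = c("RpaA", "RpaB"),
                            feedback = NULL) {
  target <- match.arg(target)
  regulators <- match.arg(regulators, c("RpaA", "RpaB"), several.ok = TRUE)
  if (!is.null(feedback)) {
    feedback <- as.list(feedback)
    if (!all(c("source", "mode") %in% names(feedback)))
      stop("'feedback' needs elements 'source' and 'mode'", call. = FALSE)
    feedback$mode <- match.arg(feedback$mode, c("activation", "repression"))
    if (identical(feedback$source, target))
      stop("feedback source must differ from the target cluster",
           call. = FALSE)
  }
  if (length(regulators) == 0L && is.null(feedback))
    stop("model needs at least one regulator or a feedback term",
         call. = FALSE)
  structure(list(target = target, regulators = regulators,
                 feedback = feedback),
            class = "dusk_model_spec")
}

#' @export
print.dusk_model_spec <- function(x, ...) {
  fb <- if (is.null(x$feedback)) "none" else
    paste0(x$feedback$source, " (", x$feedback$mode, ")")
  cat("Dusk cluster model: ", x$target, "\n",
      "  regulators: ", paste(x$regulators, collapse = " AND "), "\n",
      "  feedback:   ", fb, "\n",
      "  free parameters: ", n_free_params(x), "\n", sep = "")
  invisible(x)
}

# names of the Hill-term inputs, in the order their parameters appear
spec_inputs <- function(spec) {
  c(spec$regulators,
    if (!is.null(spec$feedback)) spec$feedback$source)
}

# 5 for a single-regulator model, 7 joint, 9 with feedback
n_free_params <- function(spec) 3L + 2L * length(spec_inputs(spec))

param_names <- function(spec) {
  inputs <- spec_inputs(spec)
  suffix <- vapply(inputs, function(i)
    switch(i, RpaA = "A", RpaB = "B", "Y"), "")
  c("B", "beta", "alpha",
    as.vector(rbind(paste0("K_", suffix), paste0("H_", suffix))))
}

#' Construct a validated parameter set for a dusk-cluster model
#'
#' @param spec a [dusk_model_spec()].
#' @param theta named or positional numeric vector: `B`, `beta`, `alpha`,
#'   then `(K, H)` per Hill term in the order RpaA, RpaB, feedback source.
#' @return named numeric vector of class `"dusk_model_params"` with the
#'   spec attached as attribute `"spec"`.
#' @export
dusk_model_params <- function(spec, theta) {
  nm <- param_names(spec)
  if (length(theta) != length(nm))
    stop("expected ", length(nm), " parameters (", paste(nm, collapse = ", "),
         "), got ", length(theta), call. = FALSE)
  theta <- as.numeric(theta)
  names(theta) <- nm
  check_param_bounds(theta)
  structure(theta, class = "dusk_model_params", spec = spec)
}

check_param_bounds <- function(theta, bounds = hill_bounds()) {
  for (i in seq_along(theta)) {
    key <- sub("_[ABY]$", "", names(theta)[i])
    b <- bounds[[key]]
    if (is.na(theta[i]) || theta[i] < b[1] || theta[i] > b[2])
      stop(sprintf("parameter %s = %s violates its bound [%g, %g]",
                   names(theta)[i], format(theta[i]), b[1], b[2]),
           call. = FALSE)
  }
  invisible(TRUE)
}

# Build per-input interpolants (functions of t) from a list of
# data.frames with columns time_h, value.
build_interpolants <- function(regulators, spec,
                               interpolation = c("linear", "constant")) {
  interpolation <- match.arg(interpolation)
  inputs <- spec_inputs(spec)
  missing <- setdiff(inputs, names(regulators))
  if (length(missing))
    stop("missing regulator trajectories for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  lapply(stats::setNames(inputs, inputs), function(i) {
    df <- regulators[[i]]
    stats::approxfun(df$time_h, df$value, method = interpolation, rule = 2)
  })
}

# Production rate B + beta * prod f_i(u_i(t)) evaluated at times t
production_rate <- function(t, theta, spec, interp) {
  inputs <- spec_inputs(spec)
  prod_f <- rep(1, length(t))
  for (i in seq_along(inputs)) {
    K <- theta[[3L + 2L * i - 1L]]
    H <- theta[[3L + 2L * i]]
    u <- interp[[inputs[i]]](t)
    mode <- if (!is.null(spec$feedback) && i == length(inputs) &&
                inputs[i] == spec$feedback$source)
      spec$feedback$mode else "activation"
    f <- if (mode == "repression") hill_repression(u, K, H)
         else hill_activation(u, K, H)
    prod_f <- prod_f * f
  }
  theta[["B"]] + theta[["beta"]] * prod_f
}

#' Right-hand side of the dusk-cluster ODE
#'
#' `dX/dt = B + beta * prod(f_i(u_i(t))) - alpha * X`, with one Hill factor
#' per regulator present in the model spec (absent terms contribute 1).
#'
#' @param t time in hours since dawn.
#' @param X current cluster expression (normalized units).
#' @param params a [dusk_model_params()] vector.
#' @param spec the matching [dusk_model_spec()].
#' @param regulators named list of data.frames (`time_h`, `value`), one per
#'   model input (`RpaA`, `RpaB`, feedback source cluster).
#' @param interpolation how to interpolate regulator levels between
#'   measurements: `"linear"` (default) or `"constant"` (previous-value
#'   hold).
#' @return `dX/dt` in normalized expression units per hour.
#' @export
cluster_rhs <- function(t, X, params, spec, regulators,
                        interpolation = "linear") {
  interp <- build_interpolants(regulators, spec, interpolation)
  dom <- range(unlist(lapply(regulators[spec_inputs(spec)],
                             function(d) range(d$time_h))))
  if (any(t < dom[1] - 1e-9) || any(t > dom[2] + 1e-9))
    stop("time ", format(t), " outside the regulator measurement window [",
         dom[1], ", ", dom[2], "]", call. = FALSE)
  production_rate(t, params, spec, interp) - params[["alpha"]] * X
}

#' Simulate a dusk-cluster expression trajectory
#'
#' Integrates the cluster ODE driven by measured (or synthetic) regulator
#' trajectories. The default integrator is adaptive explicit Runge-Kutta
#' (deSolve's `ode45`, relative tolerance 1e-6, absolute 1e-9). The
#' `"exact_step"` method exploits the linearity of the ODE in `X`: on a
#' fine fixed grid the production rate is a known function of time and the
#' update `X[n+1] = X[n] e^(-alpha dt) + integral` is evaluated in closed
#' form assuming production piecewise linear on each step; it is used
#' internally during fitting for speed.
#'
#' @inheritParams cluster_rhs
#' @param t_grid increasing times (hours) at which to report the solution;
#'   the first element is the initial time.
#' @param X0 initial expression level at `t_grid[1]` (>= 0).
#' @param method `"adaptive"` or `"exact_step"`.
#' @param dt fine-grid step (hours) for `"exact_step"`.
#' @return numeric vector of `X` at `t_grid`.
#' @export
simulate_cluster <- function(params, spec, regulators, t_grid, X0,
                             method = c("adaptive", "exact_step"),
                             interpolation = "linear", dt = 0.01) {
  method <- match.arg(method)
  if (X0 < 0) stop("'X0' must be nonnegative", call. = FALSE)
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("'t_grid' must be strictly increasing", call. = FALSE)
  check_param_bounds(unclass(params))
  interp <- build_interpolants(regulators, spec, interpolation)
  dom <- range(unlist(lapply(regulators[spec_inputs(spec)],
                             function(d) range(d$time_h))))
  if (t_grid[1] < dom[1] - 1e-9 || t_grid[length(t_grid)] > dom[2] + 1e-9)
    stop("'t_grid' extends outside the regulator measurement window [",
         dom[1], ", ", dom[2], "]", call. = FALSE)

  if (method == "adaptive") {
    rhs <- function(t, y, p) {
      list(production_rate(t, params, spec, interp) - params[["alpha"]] * y)
    }
    out <- deSolve::ode(y = c(X = X0), times = t_grid, func = rhs,
                        parms = NULL, method = "ode45",
                        rtol = 1e-6, atol = 1e-9)
    if (attr(out, "istate")[1] < 0)
      stop("ODE integration failed; istate = ", attr(out, "istate")[1],
           call. = FALSE)
    unname(out[, "X"])
  } else {
    simulate_exact_step(params, spec, interp, t_grid, X0, dt)
  }
}

# Exact stepping for the linear-in-X ODE on a fine fixed grid, then linear
# interpolation to t_grid. Production is treated as piecewise linear on
# each fine step (trapezoid-order accurate); the homogeneous part is exact.
simulate_exact_step <- function(theta, spec, interp, t_grid, X0, dt) {
  t0 <- t_grid[1]; t1 <- t_grid[length(t_grid)]
  n <- max(2L, ceiling((t1 - t0) / dt) + 1L)
  tt <- seq(t0, t1, length.out = n)
  h <- tt[2] - tt[1]
  p <- production_rate(tt, theta, spec, interp)
  a <- theta[["alpha"]]
  if (a > 0) {
    E <- exp(-a * h)
    I1 <- (1 - E) / a
    I2 <- 1 / a - (1 - E) / (a^2 * h)
  } else {
    E <- 1; I1 <- h; I2 <- h / 2
  }
  pn <- p[-n]; pn1 <- p[-1]
  step_in <- pn * (I1 - I2) + pn1 * I2
  X <- c(X0, stats::filter(step_in, E, method = "recursive", init = X0))
  stats::approx(tt, X, xout = t_grid)$y
}

#' Root-sum-square deviation between simulation and data
#'
#' The model misfit metric: the square root of the sum of squared
#' deviations between simulated and observed cluster expression over all
#' fitted conditions and time points.
#'
#' @param sim,data numeric vectors (or lists of aligned vectors, one per
#'   condition) on the same time grid.
#' @return nonnegative scalar in normalized expression units.
#' @export
model_error <- function(sim, data) {
  sim <- unlist(sim); data <- unlist(data)
  if (length(sim) != length(data))
    stop("simulation and data have different lengths (",
         length(sim), " vs ", length(data),
         "); time grids are misaligned", call. = FALSE)
  sqrt(sum((sim - data)^2))
}
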