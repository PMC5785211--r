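# Shared fixtures and independent oracles for the test suite.

# constant-level regulator trajectories over [t0, t1]
const_regulators <- function(levels, t0 = 0, t1 = 12) {
  lapply(levels, function(v) data.frame(time_h = c(t0, t1),
                                        value = c(v, v)))
}

# Noise-free reference cluster dataset, generated once per test run.
.fixture_env <- new.env(parent = emptyenv())
reference_dataset <- function(noise_sd = 0, seed = 1L) {
  key <- paste0("ds_", noise_sd, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_cluster_dataset(noise_sd = noise_sd,
                                                    seed = seed)
  .fixture_env[[key]]
}

# Independent fixed-step explicit Euler oracle for the cluster ODE.
# Re-implements the Hill terms and interpolation from scratch so that it
# shares no code with simulate_cluster(); the linear-recurrence update
# X[n+1] = X[n] (1 - alpha h) + p[n] h is evaluated with stats::filter
# for speed but is algebraically plain Euler.
euler_oracle <- function(theta, spec, regulators, t_grid, X0,
                         dt = 1e-4) {
  hill <- function(u, K, H, repress) {
    f <- if (H == 0) rep(0.5, length(u))
    else if (K == 0) ifelse(u > 0, 1, 0.5)
    else {
      r <- (u / K)^H
      ifelse(is.infinite(r), 1, r / (1 + r))
    }
    if (repress) 1 - f else f
  }
  inputs <- c(spec$regulators,
              if (!is.null(spec$feedback)) spec$feedback$source)
  t0 <- t_grid[1]; t1 <- t_grid[length(t_grid)]
  tt <- seq(t0, t1, by = dt)
  prod_f <- rep(1, length(tt))
  for (i in seq_along(inputs)) {
    df <- regulators[[inputs[i]]]
    u <- approx(df$time_h, df$value, xout = tt, rule = 2)$y
    repress <- !is.null(spec$feedback) && i == length(inputs) &&
      spec$feedback$mode == "repression"
    prod_f <- prod_f * hill(u, theta[3 + 2 * i - 1], theta[3 + 2 * i],
                            repress)
  }
  p <- theta[1] + theta[2] * prod_f
  a <- theta[3]
  inc <- p[-length(p)] * dt
  X <- c(X0, stats::filter(inc, 1 - a * dt, method = "recursive",
                           init = X0))
  approx(tt, X, xout = t_grid)$y
}

# Dense grid-search cosinor oracle: minimizes SSE over (mesor computed
# in closed form per candidate, amplitude, phase) on a fine grid.
grid_cosinor_oracle <- function(time_h, value, period_h = 24,
                                amp_grid = seq(0, 1, by = 0.002),
                                phase_grid = seq(0, 359.5, by = 0.5)) {
  w <- 2 * pi / period_h
  best <- c(sse = Inf, amplitude = NA, acrophase_deg = NA)
  for (ph in phase_grid) {
    shape <- cos(w * time_h - ph * pi / 180)
    for (A in amp_grid) {
      res <- value - A * shape
      res <- res - mean(res)
      sse <- sum(res^2)
      if (sse < best["sse"])
        best <- c(sse = sse, amplitude = A, acrophase_deg = ph)
    }
  }
  best
}

# Brute-force validator for the three peak-to-gene assignment rules:
# re-tests every (peak, gene) pair directly from the printed criteria.
brute_force_links <- function(peaks, annotation, genome_length,
                              circular, max_distance_bp = 500) {
  sc <- ifelse(annotation$strand == "+", annotation$start - 1,
               annotation$end - 1)
  dist_fun <- function(a, b) {
    d <- abs(a - b)
    if (circular) min(d, genome_length - d) else d
  }
  out <- NULL
  for (i in seq_len(nrow(peaks))) {
    for (g in seq_len(nrow(annotation))) {
      summit <- peaks$summit[i]
      d <- dist_fun(summit, sc[g])
      # rule i: within max_distance_bp of the summit
      if (d > max_distance_bp) next
      # rule ii: summit upstream (5') of the start codon on this strand
      fwd <- if (annotation$strand[g] == "+") sc[g] - summit
             else summit - sc[g]
      if (circular) fwd <- fwd %% genome_length
      if (!(fwd > 0 && fwd == d)) next
      # rule iii: closest gene on the same strand
      same <- which(annotation$strand == annotation$strand[g])
      d_all <- vapply(same, function(j) dist_fun(summit, sc[j]), 0)
      if (d > min(d_all)) next
      out <- rbind(out, data.frame(peak_id = i, summit = summit,
                                   gene_id = annotation$gene_id[g],
                                   distance = d,
                                   strand = annotation$strand[g]))
    }
  }
  if (is.null(out))
    out <- data.frame(peak_id = integer(0), summit = integer(0),
                      gene_id = character(0), distance = integer(0),
                      strand = character(0))
  out
}
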