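#' Synthetic ChIP and mock signal tracks with planted peaks
#'
#' Generates a mock track (constant background plus Poisson counting
#' noise) and an ip track equal to the mock multiplied by a
#' Gaussian-shaped fold profile around each planted summit: the
#' enrichment is `fold` at the summit and decays with standard deviation
#' `width/4` bases. Replicates share summits and planted parameters but
#' have independent noise. Planted peaks must not overlap (within
#' `width/2` of each other) so fixtures stay unambiguous.
#'
#' @param genome_length chromosome length in bases.
#' @param planted data.frame with columns `summit` (0-based), `fold`
#'   (> 0), `width` (bases); may have zero rows.
#' @param background mean mock signal per base.
#' @param n_reps number of replicates.
#' @param circular circular chromosome flag.
#' @param seed RNG seed.
#' @return list of `n_reps` elements, each `list(ip = , mock = )` of raw
#'   (unsmoothed) [signal_track()]s; `planted` is attached as an
#'   attribute.
#' @export
simulate_chip_tracks <- function(genome_length, planted =
                                   data.frame(summit = integer(0),
                                              fold = numeric(0),
                                              width = numeric(0)),
                                 background = 100, n_reps = 2,
                                 circular = TRUE, seed = 1L) {
  if (nrow(planted)) {
    if (any(planted$fold <= 0))
      stop("planted 'fold' values must be positive", call. = FALSE)
    if (any(planted$summit < 0 | planted$summit >= genome_length))
      stop("planted summits must lie within the genome", call. = FALSE)
    if (nrow(planted) > 1L) {
      ord <- order(planted$summit)
      s <- planted$summit[ord]
      w <- planted$width[ord]
      gaps <- diff(s)
      lim <- (w[-length(w)] + w[-1]) / 2
      wrap_gap <- genome_length - s[length(s)] + s[1]
      wrap_lim <- (w[length(w)] + w[1]) / 2
      if (any(gaps < lim) || (circular && wrap_gap < wrap_lim))
        stop("planted peaks overlap; keep fixture summits at least ",
             "(width_i + width_j)/2 apart", call. = FALSE)
    }
  }
  pos <- seq_len(genome_length) - 1L
  fold_profile <- rep(1, genome_length)
  for (i in seq_len(nrow(planted))) {
    d <- abs(pos - planted$summit[i])
    if (circular) d <- pmin(d, genome_length - d)
    fold_profile <- fold_profile +
      (planted$fold[i] - 1) * exp(-d^2 / (2 * (planted$width[i] / 4)^2))
  }
  set.seed(as.integer(seed))
  out <- lapply(seq_len(n_reps), function(r) {
    mock <- stats::rpois(genome_length, background)
    ip <- stats::rpois(genome_length, background * fold_profile)
    list(ip = signal_track(ip, circular = circular),
         mock = signal_track(mock, circular = circular))
  })
  attr(out, "planted") <- planted
  out
}
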