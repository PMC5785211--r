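#' Per-base genomic signal track
#'
#' A light container for one value per genomic position (0-based
#' internally) on a single, possibly circular, chromosome.
#'
#' @param values nonnegative finite numeric vector, one value per base.
#' @param circular whether the chromosome is circular (distances and
#'   smoothing wrap).
#' @param seqname chromosome name used on bedGraph export.
#' @return object of class `"signal_track"`.
#' @export
signal_track <- function(values, circular = TRUE, seqname = "chr") {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("track values must be finite and nonnegative", call. = FALSE)
  structure(list(values = values, genome_length = length(values),
                 circular = isTRUE(circular), seqname = seqname),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("Signal track: ", x$genome_length, " bp",
      if (x$circular) " (circular)", ", mean signal ",
      format(mean(x$values), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Gaussian smoothing of a signal track
#'
#' Convolves the per-base signal with a Gaussian kernel of standard
#' deviation `sd_bp`, truncated to a window of `window_bp` bases
#' (`window_bp/2` on each side) and renormalized to sum to one, so a
#' constant track is unchanged and total signal is conserved on circular
#' genomes. Circular tracks wrap; linear tracks reflect at the edges.
#'
#' @param track a [signal_track()].
#' @param window_bp kernel window size in bases (default 400).
#' @param sd_bp kernel standard deviation in bases (default 50, > 0).
#' @return smoothed [signal_track()].
#' @export
smooth_track <- function(track, window_bp = 400, sd_bp = 50) {
  stopifnot(inherits(track, "signal_track"))
  if (sd_bp <= 0) stop("'sd_bp' must be positive", call. = FALSE)
  half <- floor(window_bp / 2)
  kern <- stats::dnorm(-half:half, sd = sd_bp)
  kern <- kern / sum(kern)
  x <- track$values
  if (track$circular) {
    sm <- stats::filter(x, kern, sides = 2, circular = TRUE)
  } else {
    pad_l <- rev(x[seq_len(min(half, length(x)))])
    pad_r <- rev(x[seq.int(length(x) - min(half, length(x)) + 1,
                           length(x))])
    padded <- c(pad_l, x, pad_r)
    sm <- stats::filter(padded, kern, sides = 2,
                        circular = FALSE)[length(pad_l) + seq_along(x)]
  }
  signal_track(as.numeric(sm), circular = track$circular,
               seqname = track$seqname)
}

#' Call enrichment peaks against a mock control
#'
#' Identifies regions where the (smoothed) immunoprecipitation signal is
#' enriched at least `fold_threshold`-fold over the (smoothed) mock
#' control. Both tracks are first scaled to equal totals (library-size
#' normalization), and mock values below the 5th percentile of its
#' nonzero values are floored there to stabilize ratios. Peaks are
#' maximal runs with `ip/mock >= fold_threshold` at least `min_width_bp`
#' wide; the summit is the position of maximal ip signal within the run
#' (leftmost on ties) and the reported enrichment is the ip/mock ratio at
#' the summit. On circular genomes a run spanning the origin is handled
#' by rotation.
#'
#' @param ip,mock smoothed [signal_track()]s of equal length.
#' @param fold_threshold minimum summit enrichment (default 3.5).
#' @param min_width_bp minimum run width in bases (default 50).
#' @return data.frame of class `"chip_peaks"`: `start`, `end` (0-based,
#'   half-open), `summit` (0-based), `enrichment` (ratio at summit),
#'   `width`.
#' @export
call_peaks <- function(ip, mock, fold_threshold = 3.5, min_width_bp = 50) {
  stopifnot(inherits(ip, "signal_track"), inherits(mock, "signal_track"))
  if (ip$genome_length != mock$genome_length)
    stop("ip and mock tracks have different genome lengths (",
         ip$genome_length, " vs ", mock$genome_length, ")", call. = FALSE)
  n <- ip$genome_length
  x <- ip$values * (sum(mock$values) / sum(ip$values))
  m <- mock$values
  nz <- m[m > 0]
  if (length(nz)) m <- pmax(m, stats::quantile(nz, 0.05))
  ratio <- x / m

  above <- ratio >= fold_threshold
  shift <- 0L
  if (ip$circular && above[1] && above[n] && !all(above)) {
    shift <- which(!above)[1] - 1L  # rotate a gap to the front
    idx <- c((shift + 1L):n, seq_len(shift))
    above <- above[idx]; ratio_r <- ratio[idx]; x_r <- x[idx]
  } else {
    ratio_r <- ratio; x_r <- x
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_width_bp
  peaks <- lapply(which(keep), function(i) {
    s <- starts[i]; e <- ends[i]
    summit <- s + which.max(x_r[s:e]) - 1L
    c(start = s - 1L, end = e, summit = summit - 1L)
  })
  out <- if (length(peaks)) as.data.frame(do.call(rbind, peaks))
         else data.frame(start = integer(0), end = integer(0),
                         summit = integer(0))
  if (shift > 0L && nrow(out)) {      # map rotated coordinates back
    out$start <- (out$start + shift) %% n
    out$end <- ((out$end - 1L + shift) %% n) + 1L
    out$summit <- (out$summit + shift) %% n
  }
  out$enrichment <- if (nrow(out)) ratio[out$summit + 1L] else numeric(0)
  out$width <- ifelse(out$end > out$start, out$end - out$start,
                      n - out$start + out$end)
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  class(out) <- c("chip_peaks", "data.frame")
  attr(out, "genome_length") <- n
  attr(out, "circular") <- ip$circular
  attr(out, "fold_threshold") <- fold_threshold
  out
}

#' Keep peaks detected in both replicates
#'
#' A replicate-1 peak is retained iff its interval overlaps a replicate-2
#' peak by at least one base; reported coordinates are replicate 1's.
#'
#' @param peaks_rep1,peaks_rep2 [call_peaks()] results from the same
#'   genome.
#' @return the overlapping subset of `peaks_rep1`.
#' @export
replicate_consistent_peaks <- function(peaks_rep1, peaks_rep2) {
  if (nrow(peaks_rep1) == 0L || nrow(peaks_rep2) == 0L)
    return(peaks_rep1[integer(0), ])
  n <- attr(peaks_rep1, "genome_length")
  circular <- isTRUE(attr(peaks_rep1, "circular"))
  keep <- vapply(seq_len(nrow(peaks_rep1)), function(i) {
    any(vapply(seq_len(nrow(peaks_rep2)), function(j) {
      intervals_overlap(peaks_rep1$start[i], peaks_rep1$end[i],
                        peaks_rep2$start[j], peaks_rep2$end[j],
                        n, circular)
    }, TRUE))
  }, TRUE)
  peaks_rep1[keep, ]
}

# overlap of two half-open intervals, allowing origin-spanning intervals
# (start > end) on a circular genome
intervals_overlap <- function(s1, e1, s2, e2, n, circular) {
  expand <- function(s, e) {
    if (!is.null(n) && circular && e <= s) list(c(s, n), c(0, e))
    else list(c(s, e))
  }
  for (a in expand(s1, e1)) for (b in expand(s2, e2))
    if (a[1] < b[2] && b[1] < a[2]) return(TRUE)
  FALSE
}

#' Assign peaks to target genes
#'
#' A gene is a target of a peak iff (i) the gene's start codon lies
#' within `max_distance_bp` of the peak summit, (ii) the summit is
#' upstream (5') of the start codon on the gene's strand, and (iii) the
#' gene is the closest gene to the summit among all genes on its strand.
#' Distances wrap on circular genomes. One peak may acquire a target on
#' each strand (divergent promoters).
#'
#' @param peaks a [call_peaks()] result (or data.frame with a `summit`
#'   column, 0-based).
#' @param annotation gene table as from [read_gene_annotation()]: columns
#'   `gene_id`, `start`, `end` (1-based, inclusive), `strand` (`+`/`-`).
#' @param max_distance_bp maximum summit-to-start-codon distance
#'   (default 500).
#' @param genome_length,circular genome geometry; defaults from `peaks`
#'   attributes.
#' @return data.frame `peak_id` (row of `peaks`), `summit`, `gene_id`,
#'   `distance`, `strand` — one row per peak-gene link.
#' @export
assign_peak_targets <- function(peaks, annotation, max_distance_bp = 500,
                                genome_length = attr(peaks,
                                                     "genome_length"),
                                circular = attr(peaks, "circular")) {
  if (is.null(circular)) circular <- TRUE
  if (any(!annotation$strand %in% c("+", "-")))
    stop("every gene needs strand '+' or '-'", call. = FALSE)
  # start codon, 0-based: first base of the ORF on the gene's strand
  sc <- ifelse(annotation$strand == "+", annotation$start - 1L,
               annotation$end - 1L)
  links <- list()
  for (i in seq_len(nrow(peaks))) {
    summit <- peaks$summit[i]
    for (str in c("+", "-")) {
      on_str <- which(annotation$strand == str)
      if (!length(on_str)) next
      d_abs <- point_distance(summit, sc[on_str], genome_length, circular)
      nearest <- on_str[which.min(d_abs)]
      d_near <- min(d_abs)
      # upstream offset: bases from summit to start codon moving along
      # the gene's reading direction
      up <- if (str == "+") sc[nearest] - summit else summit - sc[nearest]
      if (circular && !is.null(genome_length)) up <- up %% genome_length
      upstream <- up > 0 && up == d_near
      if (d_near <= max_distance_bp && upstream)
        links[[length(links) + 1L]] <-
          data.frame(peak_id = i, summit = summit,
                     gene_id = annotation$gene_id[nearest],
                     distance = d_near, strand = str)
    }
  }
  if (!length(links))
    return(data.frame(peak_id = integer(0), summit = integer(0),
                      gene_id = character(0), distance = integer(0),
                      strand = character(0)))
  do.call(rbind, links)
}

point_distance <- function(p, q, n, circular) {
  d <- abs(q - p)
  if (circular && !is.null(n)) d <- pmin(d, n - d)
  d
}

#' Enrichment of peaks across time points
#'
#' Recomputes the summit enrichment of each peak from per-time-point
#' (smoothed) ip tracks against the common mock: tracks are scaled to
#' equal totals, mock floored at the 5th percentile of its nonzero
#' values, and the ip/mock ratio read off at the peak summit.
#'
#' @param peaks a [call_peaks()] result.
#' @param ip_tracks named list of smoothed [signal_track()]s, one per
#'   time point.
#' @param mock smoothed mock [signal_track()].
#' @return matrix, peaks x time points, of summit enrichment ratios.
#' @export
peak_enrichment <- function(peaks, ip_tracks, mock) {
  m <- mock$values
  nz <- m[m > 0]
  if (length(nz)) m <- pmax(m, stats::quantile(nz, 0.05))
  out <- vapply(ip_tracks, function(tr) {
    x <- tr$values * (sum(mock$values) / sum(tr$values))
    (x / m)[peaks$summit + 1L]
  }, numeric(nrow(peaks)))
  out <- matrix(out, nrow = nrow(peaks),
                dimnames = list(NULL, names(ip_tracks)))
  out
}

#' Paired changes in enrichment and downstream expression
#'
#' For each peak-gene link and each `(condition, t, t0)` comparison,
#' computes the log2 change in summit enrichment and the log2 change in
#' the linked gene's expression between the same two time points of the
#' same condition.
#'
#' @param links peak-gene links from [assign_peak_targets()].
#' @param enrichment long data.frame `peak_id`, `condition`, `time_h`,
#'   `enrichment`.
#' @param expression long data.frame `gene_id`, `condition`, `time_h`,
#'   `value`, with `value` on the log2 scale (e.g. from
#'   [log2_relative_expression()]).
#' @param comparisons data.frame `condition`, `t`, `t0` (hours).
#' @return data.frame `peak_id`, `gene_id`, `condition`, `t`, `t0`,
#'   `delta_enrichment`, `delta_expression` (both log2).
#' @export
enrichment_change_table <- function(links, enrichment, expression,
                                    comparisons) {
  lookup <- function(df, key, id, cond, tt, value_col) {
    v <- df[[value_col]][df[[key]] == id & df$condition == cond &
                           abs(df$time_h - tt) < 1e-9]
    if (length(v) != 1L)
      stop("missing ", value_col, " for ", key, " ", id, " at (",
           cond, ", t = ", tt, " h)", call. = FALSE)
    v
  }
  rows <- lapply(seq_len(nrow(comparisons)), function(ci) {
    cond <- comparisons$condition[ci]
    tt <- comparisons$t[ci]; t0 <- comparisons$t0[ci]
    do.call(rbind, lapply(seq_len(nrow(links)), function(li) {
      e1 <- lookup(enrichment, "peak_id", links$peak_id[li], cond, tt,
                   "enrichment")
      e0 <- lookup(enrichment, "peak_id", links$peak_id[li], cond, t0,
                   "enrichment")
      x1 <- lookup(expression, "gene_id", links$gene_id[li], cond, tt,
                   "value")
      x0 <- lookup(expression, "gene_id", links$gene_id[li], cond, t0,
                   "value")
      data.frame(peak_id = links$peak_id[li], gene_id = links$gene_id[li],
                 condition = cond, t = tt, t0 = t0,
                 delta_enrichment = log2(e1 / e0),
                 delta_expression = x1 - x0)
    }))
  })
  do.call(rbind, rows)
}

#' Correlation between enrichment and expression changes
#'
#' Pearson correlation of `delta_enrichment` versus `delta_expression`,
#' computed separately per condition. Conditions with fewer than
#' `min_pairs` pairs or zero variance in either column are reported as
#' `NA`.
#'
#' @param table output of [enrichment_change_table()].
#' @param min_pairs minimum pairs per condition (default 3).
#' @return named numeric vector of correlations, one per condition.
#' @export
delta_correlation <- function(table, min_pairs = 3L) {
  vapply(split(table, table$condition), function(d) {
    if (nrow(d) < min_pairs) return(NA_real_)
    if (stats::sd(d$delta_enrichment) == 0 ||
        stats::sd(d$delta_expression) == 0) {
      warning("zero variance in a delta column; correlation undefined")
      return(NA_real_)
    }
    stats::cor(d$delta_enrichment, d$delta_expression)
  }, 0)
}
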