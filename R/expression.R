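#' Median and ORF-length normalization of read counts
#'
#' Normalizes a raw count matrix across samples, then converts to
#' reads-per-nucleotide units. Each sample is rescaled so that its median
#' count — taken over the genes with a nonzero count in *every* sample —
#' equals a common reference median (the lower median of the per-sample
#' medians; for an odd number of samples this is the usual median). Each
#' gene's normalized value is then divided by its open-reading-frame
#' length in nucleotides.
#'
#' @param counts numeric matrix, genes x samples, nonnegative counts;
#'   rownames are gene ids.
#' @param gene_lengths positive ORF lengths (nt), one per gene, in row
#'   order or named by gene id.
#' @return matrix of normalized reads per nucleotide, same dimensions,
#'   with per-sample scale factors in attribute `"scale_factors"`.
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' rownames(m) <- paste0("g", 1:3)
#' normalize_counts(m, gene_lengths = c(100, 200, 300))  # all 0.1
#' @export
normalize_counts <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts)))
    gene_lengths <- gene_lengths[rownames(counts)]
  if (length(gene_lengths) != nrow(counts) || any(is.na(gene_lengths)) ||
      any(gene_lengths <= 0))
    stop("'gene_lengths' must give a positive length for every gene",
         call. = FALSE)
  if (any(colSums(counts) == 0))
    stop("sample(s) with all-zero counts: scale factor undefined (",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "),
         ")", call. = FALSE)
  common <- rowSums(counts > 0) == ncol(counts)
  if (!any(common))
    stop("no gene has nonzero counts in every sample; cannot anchor the ",
         "median normalization", call. = FALSE)
  med <- apply(counts[common, , drop = FALSE], 2, stats::median)
  ref <- sort(med)[ceiling(length(med) / 2)]  # lower median
  scale <- ref / med
  out <- sweep(counts, 2, scale, "*") / gene_lengths
  attr(out, "scale_factors") <- scale
  out
}

#' Log2 expression relative to a reference condition's mean
#'
#' For each gene, the log2 fold change of every sample from the gene's
#' mean expression over the reference-condition samples:
#' `log2((x + eps) / (ref_mean + eps))`. The pseudocount `eps` defaults to
#' half the smallest nonzero value in the matrix, so that zeros stay
#' finite without distorting well-expressed genes.
#'
#' @param expr nonnegative expression matrix, genes x samples (e.g. the
#'   output of [normalize_counts()]).
#' @param samples data.frame describing the columns of `expr`, with at
#'   least a `condition` column (and typically `time_h`).
#' @param reference_condition condition whose per-gene mean is the
#'   denominator.
#' @param pseudocount `eps`; `NULL` for the default policy above.
#' @return matrix of log2 fold changes, same dimensions as `expr`.
#' @export
log2_relative_expression <- function(expr, samples, reference_condition,
                                     pseudocount = NULL) {
  expr <- as.matrix(expr)
  if (nrow(samples) != ncol(expr))
    stop("'samples' must describe the columns of 'expr'", call. = FALSE)
  ref <- samples$condition == reference_condition
  if (!any(ref))
    stop("reference condition '", reference_condition,
         "' not present among samples", call. = FALSE)
  if (is.null(pseudocount)) {
    nz <- expr[expr > 0]
    pseudocount <- if (length(nz)) min(nz) / 2 else 0
  }
  ref_mean <- rowMeans(expr[, ref, drop = FALSE])
  log2(expr + pseudocount) - log2(ref_mean + pseudocount)
}

#' Single-component cosinor fit
#'
#' Fits `x(t) = mesor + a cos(2 pi t / period) + b sin(2 pi t / period)`
#' by linear least squares and reports the rhythm-adjusted mean (mesor),
#' amplitude `sqrt(a^2 + b^2)` (half the fitted peak-to-trough range, in
#' the units of `value`), and acrophase: the time of the fitted maximum
#' mapped to degrees (`360 * t_max / period`), with 0 degrees at
#' subjective dawn.
#'
#' @param time_h sampling times in hours.
#' @param value measured series (typically log2-scale expression).
#' @param period_h rhythm period in hours (default 24).
#' @return list of class `"cosinor_fit"` with elements `mesor`,
#'   `amplitude`, `acrophase_deg` (in `[0, 360)`), and `coefficients`.
#' @examples
#' t <- 0:11
#' f <- cosinor_fit(t, 2 + 0.5 * cos(2 * pi * (t - 6) / 24))
#' f$acrophase_deg  # 90
#' @export
cosinor_fit <- function(time_h, value, period_h = 24) {
  keep <- is.finite(time_h) & is.finite(value)
  time_h <- time_h[keep]; value <- value[keep]
  if (length(unique(time_h)) < 3L)
    stop("cosinor fit needs >= 3 distinct time points", call. = FALSE)
  w <- 2 * pi / period_h
  X <- cbind(1, cos(w * time_h), sin(w * time_h))
  beta <- stats::lm.fit(X, value)$coefficients
  a <- beta[2]; b <- beta[3]
  amplitude <- sqrt(a^2 + b^2)
  phi <- atan2(b, a)                  # fitted max at w * t == phi
  deg <- (phi * 180 / pi) %% 360
  structure(list(mesor = unname(beta[1]), amplitude = unname(amplitude),
                 acrophase_deg = unname(deg),
                 coefficients = stats::setNames(beta,
                                                c("mesor", "cos", "sin"))),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, digits = 3, ...) {
  cat("Cosinor fit: mesor ", format(x$mesor, digits = digits),
      ", amplitude ", format(x$amplitude, digits = digits),
      ", acrophase ", format(x$acrophase_deg, digits = digits),
      " deg\n", sep = "")
  invisible(x)
}

#' Classify genes as dawn, dusk, or non-circadian
#'
#' Applies the circadian gene definition: a gene is circadian if its
#' cosinor amplitude (on log2-scale expression) exceeds
#' `amplitude_threshold` *and* it reaches at least one read per nucleotide
#' in at least one sample. Circadian genes with acrophase in `[40, 189]`
#' degrees are dawn genes; those in `[190, 360) U [0, 39]` degrees are
#' dusk genes (boundaries inclusive as stated). All others are
#' non-circadian.
#'
#' @param fits named list of [cosinor_fit()] results, one per gene (fit on
#'   the constant-light or Low Light proxy series).
#' @param expr reads-per-nucleotide expression matrix used for the
#'   expression filter; must contain every gene in `fits`.
#' @param amplitude_threshold minimum cosinor amplitude (log2 units).
#' @param min_reads_per_nt expression filter level.
#' @return data.frame with columns `gene_id`, `amplitude`,
#'   `acrophase_deg`, `passed_expression_filter`, `class` (factor with
#'   levels dawn/dusk/non_circadian).
#' @export
classify_circadian <- function(fits, expr, amplitude_threshold = 0.15,
                               min_reads_per_nt = 1) {
  genes <- names(fits)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("gene(s) in 'fits' absent from 'expr': ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  amp <- vapply(fits, `[[`, 0, "amplitude")
  phase <- vapply(fits, `[[`, 0, "acrophase_deg")
  passed <- apply(expr[genes, , drop = FALSE] >= min_reads_per_nt, 1, any)
  is_dawn <- phase >= 40 & phase <= 189
  is_dusk <- (phase >= 190 & phase < 360) | (phase >= 0 & phase <= 39)
  circ <- amp > amplitude_threshold & passed
  cls <- ifelse(circ & is_dawn, "dawn",
         ifelse(circ & is_dusk, "dusk", "non_circadian"))
  data.frame(gene_id = genes, amplitude = unname(amp),
             acrophase_deg = unname(phase),
             passed_expression_filter = unname(passed),
             class = factor(cls, levels = c("dawn", "dusk",
                                            "non_circadian")),
             row.names = NULL)
}
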