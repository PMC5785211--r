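#' Block-wise z-score normalization of an expression matrix
#'
#' Centers and scales each gene's row to mean 0 and standard deviation 1
#' (sample sd, `n - 1` denominator) separately within each block of
#' samples, then concatenates the blocks. Blocks typically correspond to
#' independent experiments (e.g. the four dynamic light conditions versus
#' a prior constant-light perturbation series) whose scales should not be
#' mixed.
#'
#' Genes with zero variance inside any block cannot be standardized; they
#' are dropped from the output and listed in attribute `"excluded"` (with
#' a warning).
#'
#' @param mat numeric matrix, genes x samples.
#' @param blocks factor/character/integer of length `ncol(mat)` assigning
#'   each sample to a block; default puts all samples in one block.
#' @return standardized matrix (possibly with fewer rows), block labels in
#'   attribute `"blocks"`, excluded gene ids in attribute `"excluded"`.
#' @export
zscore_block_normalize <- function(mat, blocks = NULL) {
  mat <- as.matrix(mat)
  if (is.null(blocks)) blocks <- rep(1L, ncol(mat))
  if (length(blocks) != ncol(mat))
    stop("'blocks' must assign every sample (column)", call. = FALSE)
  if (any(table(blocks) < 2L))
    stop("each block needs >= 2 samples", call. = FALSE)
  out <- mat
  zero_var <- rep(FALSE, nrow(mat))
  for (b in unique(blocks)) {
    idx <- blocks == b
    sub <- mat[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    s <- apply(sub, 1, stats::sd)
    zero_var <- zero_var | s == 0 | !is.finite(s)
    out[, idx] <- (sub - mu) / s
  }
  excluded <- rownames(mat)[zero_var]
  if (is.null(excluded)) excluded <- which(zero_var)
  if (any(zero_var)) {
    warning(sum(zero_var), " gene(s) with zero variance within a block ",
            "excluded from the standardized matrix")
    out <- out[!zero_var, , drop = FALSE]
  }
  attr(out, "blocks") <- blocks
  attr(out, "excluded") <- if (any(zero_var)) excluded else
    character(0)
  out
}

#' K-means clustering with Pearson correlation distance
#'
#' Lloyd-type k-means on gene expression rows using the distance
#' `d(x, c) = 1 - r(x, c)` (one minus the Pearson correlation). Rows are
#' standardized (mean 0, unit sample sd) before clustering; each centroid
#' is the mean of its member rows re-standardized the same way — the
#' convention of MATLAB's correlation-distance k-means, which the original
#' analysis used. The best of `n_restarts` random initializations (by
#' total within-cluster distance) is returned; results are deterministic
#' under a fixed seed. A centroid losing all members is re-seeded from the
#' point farthest from its current centroid.
#'
#' @param mat numeric matrix, genes x samples (rows must be nonconstant).
#' @param k number of clusters (default 8).
#' @param n_restarts random restarts (default 50).
#' @param seed RNG seed.
#' @param max_iter iteration cap per restart.
#' @return list of class `"correlation_kmeans"`: `cluster` (named integer
#'   vector), `centers` (k x samples, standardized), `within_dist` (total
#'   within-cluster distance), `sizes`, `iterations`, `seed`.
#' @export
kmeans_correlation <- function(mat, k = 8, n_restarts = 50, seed = 1L,
                               max_iter = 100) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (k > n) stop("'k' (", k, ") exceeds the number of genes (", n, ")",
                  call. = FALSE)
  Z <- row_standardize(mat)
  m <- ncol(Z)
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- Z[sample.int(n, k), , drop = FALSE]
    assign_old <- rep(0L, n)
    wd_history <- numeric(0)
    for (it in seq_len(max_iter)) {
      # r(x, c) = sum(x * c) / (m - 1) for row-standardized vectors
      corr <- tcrossprod(Z, centers) / (m - 1)
      assign_new <- max.col(corr, ties.method = "first")
      wd_history[it] <- sum(1 - corr[cbind(seq_len(n), assign_new)])
      for (j in seq_len(k)) {
        members <- assign_new == j
        if (!any(members)) {        # empty cluster: re-seed from the
          d_own <- 1 - corr[cbind(seq_len(n), assign_new)]
          far <- which.max(d_own)   # farthest point from its centroid
          assign_new[far] <- j
          members <- assign_new == j
        }
        centers[j, ] <- row_standardize(
          matrix(colMeans(Z[members, , drop = FALSE]), 1))
      }
      if (identical(assign_new, assign_old)) break
      assign_old <- assign_new
    }
    corr <- tcrossprod(Z, centers) / (m - 1)
    wd <- sum(1 - corr[cbind(seq_len(n), assign_new)])
    if (is.null(best) || wd < best$within_dist - 1e-12)
      best <- list(cluster = assign_new, centers = centers,
                   within_dist = wd, iterations = it,
                   within_dist_history = wd_history)
  }
  names(best$cluster) <- rownames(mat)
  best$sizes <- tabulate(best$cluster, k)
  best$seed <- as.integer(seed)
  best$k <- k
  class(best) <- "correlation_kmeans"
  best
}

row_standardize <- function(mat) {
  mu <- rowMeans(mat)
  s <- apply(mat, 1, stats::sd)
  if (any(s == 0 | !is.finite(s)))
    stop("constant row(s) cannot be used with correlation distance",
         call. = FALSE)
  (mat - mu) / s
}

#' @export
print.correlation_kmeans <- function(x, ...) {
  cat("Correlation-distance k-means: k = ", x$k, ", ",
      length(x$cluster), " genes\n", sep = "")
  cat("Cluster sizes: ", paste(x$sizes, collapse = ", "), "\n", sep = "")
  cat("Total within-cluster distance: ",
      format(x$within_dist, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Name the major clusters by their order of activation
#'
#' The three largest clusters are named `Early`, `Middle`, and `Late` in
#' increasing order of activation time — the first time their 0-1 scaled
#' Low Light mean trajectory crosses 0.5 (linearly interpolated between
#' sampling times). Remaining clusters are named `other`. A tie in cluster
#' size for third place is broken in favor of the earlier-activating
#' cluster, with a warning.
#'
#' @param clustering a [kmeans_correlation()] result (or any named integer
#'   vector of cluster indices).
#' @param cluster_means data.frame with columns `cluster_index`, `time_h`,
#'   `value`: each cluster's Low Light mean trajectory scaled to `[0, 1]`.
#' @param min_size smallest cluster size eligible for a major name.
#' @return data.frame `gene_id`, `cluster_index`, `cluster_name`, with the
#'   per-cluster naming table in attribute `"cluster_names"`.
#' @export
name_clusters_by_activation <- function(clustering, cluster_means,
                                        min_size = 2L) {
  cluster <- if (inherits(clustering, "correlation_kmeans"))
    clustering$cluster else clustering
  sizes <- table(cluster)
  cross <- vapply(as.integer(names(sizes)), function(j) {
    tr <- cluster_means[cluster_means$cluster_index == j, ]
    tr <- tr[order(tr$time_h), ]
    crossing_time(tr$time_h, tr$value, level = 0.5)
  }, 0)
  names(cross) <- names(sizes)
  eligible <- names(sizes)[sizes >= min_size]
  # three largest; size ties at the cutoff broken by earlier activation
  ord <- eligible[order(-sizes[eligible], cross[eligible])]
  if (length(ord) > 3L && sizes[ord[3]] == sizes[ord[4]])
    warning("tie in cluster sizes for third place; broken by earlier ",
            "activation time")
  major <- utils::head(ord, 3L)
  if (length(major) < 3L)
    warning("only ", length(major), " cluster(s) meet the minimum size; ",
            "naming ", paste(c("Early", "Middle", "Late")[
               seq_along(major)], collapse = "/"), " only")
  major <- major[order(cross[major])]
  name_map <- stats::setNames(rep("other", length(sizes)), names(sizes))
  name_map[major] <- c("Early", "Middle", "Late")[seq_along(major)]
  out <- data.frame(gene_id = names(cluster),
                    cluster_index = as.integer(cluster),
                    cluster_name = unname(name_map[as.character(cluster)]),
                    row.names = NULL)
  attr(out, "cluster_names") <-
    data.frame(cluster_index = as.integer(names(sizes)),
               size = as.integer(sizes),
               activation_time_h = unname(cross),
               cluster_name = unname(name_map))
  out
}

# first time a trajectory crosses `level` going upward, by linear
# interpolation; Inf if it never does
crossing_time <- function(time_h, value, level = 0.5) {
  if (value[1] >= level) return(time_h[1])
  above <- which(value >= level)
  if (!length(above)) return(Inf)
  i <- above[1]
  t0 <- time_h[i - 1]; t1 <- time_h[i]
  v0 <- value[i - 1]; v1 <- value[i]
  t0 + (level - v0) / (v1 - v0) * (t1 - t0)
}

#' Scale a series jointly to the unit interval
#'
#' `(x - min) / (max - min)`, with the minimum and maximum taken over the
#' whole input — when the input pools a gene's (or regulator's) values
#' across all four light conditions, every condition is mapped with the
#' same affine transform, preserving between-condition contrasts.
#'
#' @param x numeric vector (nonconstant).
#' @return vector with minimum 0 and maximum 1.
#' @export
scale_unit_interval <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[2] - r[1] == 0)
    stop("cannot scale a constant series to [0, 1]: range is zero",
         call. = FALSE)
  (x - r[1]) / (r[2] - r[1])
}

#' Mean 0-1 scaled expression trajectory per cluster
#'
#' For each cluster, scales every member gene's expression jointly across
#' all conditions to `[0, 1]` and averages the scaled values per
#' (condition, time) — the quantity the dusk-cluster models are fitted
#' to.
#'
#' @param expr long data.frame `gene_id`, `condition`, `time_h`, `value`.
#' @param assignments data.frame `gene_id`, `cluster_name` (e.g. from
#'   [name_clusters_by_activation()]).
#' @param clusters cluster names to summarize.
#' @return long data.frame `cluster`, `condition`, `time_h`, `value`
#'   (cluster mean), `sd` (within-cluster sd of scaled values).
#' @export
cluster_mean_trajectories <- function(expr, assignments,
                                      clusters = c("Early", "Middle",
                                                   "Late")) {
  scaled <- do.call(rbind, lapply(split(expr, expr$gene_id), function(d) {
    d$value <- scale_unit_interval(d$value)
    d
  }))
  merged <- merge(scaled, assignments[c("gene_id", "cluster_name")],
                  by = "gene_id")
  merged <- merged[merged$cluster_name %in% clusters, ]
  agg <- stats::aggregate(value ~ cluster_name + condition + time_h,
                          data = merged, FUN = mean)
  sds <- stats::aggregate(value ~ cluster_name + condition + time_h,
                          data = merged, FUN = stats::sd)
  names(agg)[names(agg) == "cluster_name"] <- "cluster"
  agg$sd <- sds$value
  agg[order(agg$cluster, agg$condition, agg$time_h), ]
}
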