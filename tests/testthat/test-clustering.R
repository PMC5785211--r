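test_that("correlation k-means handles degenerate and exact cases", {
  set.seed(2)
  m <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), NULL))
  km1 <- kmeans_correlation(m, k = 1, n_restarts = 3, seed = 1)
  expect_true(all(km1$cluster == 1))
  # identical rows always share a cluster (distance zero)
  m2 <- m
  m2[2, ] <- m2[1, ]
  km2 <- kmeans_correlation(m2, k = 3, n_restarts = 10, seed = 1)
  expect_equal(unname(km2$cluster[1]), unname(km2$cluster[2]))
  expect_error(kmeans_correlation(m, k = 20), "exceeds")
})

test_that("planted correlation-distinct groups are recovered near-perfectly", {
  grp <- rep(c("A", "B", "C"), each = 20)
  acro <- c(A = 190, B = 270, C = 350)[grp]
  g <- simulate_gene_counts(n_genes = 60, classes = "dusk",
                            acrophase = acro, cluster = grp,
                            noise_sd = 0.1, seed = 7)
  norm <- normalize_counts(g$counts, g$gene_lengths)
  l2 <- log2_relative_expression(norm, g$samples, "LowLight")
  z <- zscore_block_normalize(l2)
  km <- kmeans_correlation(z, k = 3, n_restarts = 20, seed = 3)
  ari <- adjusted_rand_index(km$cluster, grp)
  expect_gte(ari, 0.95)
  # package ARI agrees with the independent mclust implementation
  expect_equal(ari, mclust::adjustedRandIndex(km$cluster, grp))
  # within-cluster distance is non-increasing across Lloyd iterations
  expect_true(all(diff(km$within_dist_history) <= 1e-10))
  # determinism under seed
  km2 <- kmeans_correlation(z, k = 3, n_restarts = 20, seed = 3)
  expect_identical(km$cluster, km2$cluster)
})

test_that("cluster labels are invariant to positive affine transforms of rows", {
  grp <- rep(c("A", "B", "C"), each = 10)
  acro <- c(A = 190, B = 270, C = 350)[grp]
  g <- simulate_gene_counts(n_genes = 30, classes = "dusk",
                            acrophase = acro, noise_sd = 0.05, seed = 9)
  norm <- normalize_counts(g$counts, g$gene_lengths)
  l2 <- log2_relative_expression(norm, g$samples, "LowLight")
  km <- kmeans_correlation(l2, k = 3, n_restarts = 10, seed = 5)
  set.seed(31)
  l2t <- l2 * runif(nrow(l2), 0.5, 4) + rnorm(nrow(l2))
  kmt <- kmeans_correlation(l2t, k = 3, n_restarts = 10, seed = 5)
  expect_identical(km$cluster, kmt$cluster)
})

test_that("major clusters are named Early/Middle/Late by activation order", {
  mk_traj <- function(idx, cross) {
    t <- seq(0, 12, by = 0.5)
    data.frame(cluster_index = idx, time_h = t,
               value = plogis((t - cross) * 4))
  }
  means <- rbind(mk_traj(1, 9), mk_traj(2, 2), mk_traj(3, 5),
                 mk_traj(4, 1))
  cl <- c(g1 = 1, g2 = 1, g3 = 1, g4 = 2, g5 = 2, g6 = 2,
          g7 = 3, g8 = 3, g9 = 3, g10 = 4)
  named <- name_clusters_by_activation(cl, means)
  tabs <- attr(named, "cluster_names")
  expect_equal(tabs$cluster_name[tabs$cluster_index == 2], "Early")
  expect_equal(tabs$cluster_name[tabs$cluster_index == 3], "Middle")
  expect_equal(tabs$cluster_name[tabs$cluster_index == 1], "Late")
  expect_equal(tabs$cluster_name[tabs$cluster_index == 4], "other")
  expect_equal(named$cluster_name[named$gene_id == "g10"], "other")
  # only two clusters meet the minimum size: name Early/Middle, warn
  cl2 <- c(g1 = 1, g2 = 1, g3 = 2, g4 = 2, g5 = 3)
  expect_warning(named2 <- name_clusters_by_activation(cl2, means),
                 "minimum size")
  tabs2 <- attr(named2, "cluster_names")
  expect_setequal(tabs2$cluster_name,
                  c("Early", "Middle", "other"))
})

test_that("clusters built from reference-model simulations are named by activation order", {
  ds <- reference_dataset()
  # pseudo-genes per cluster: all-condition scaled trajectories plus
  # replicate noise; clustering sees all four conditions, naming uses
  # the Low Light block re-scaled to its own 0-1 range (the Late
  # cluster's Low Light plateau is far below its Clear Day maximum)
  set.seed(6)
  all4 <- ds$data[order(ds$data$cluster, ds$data$condition,
                        ds$data$time_h), ]
  ll_cols <- with(all4[all4$cluster == "Early", ],
                  which(condition == "LowLight"))
  ll_times <- with(all4[all4$cluster == "Early", ],
                   time_h[condition == "LowLight"])
  genes <- do.call(rbind, lapply(split(all4, all4$cluster), function(d) {
    t(replicate(12, scale_unit_interval(d$value) +
                    rnorm(nrow(d), 0, 0.002)))
  }))
  rownames(genes) <- paste0("g", seq_len(nrow(genes)))
  truth <- rep(sort(unique(all4$cluster)), each = 12)
  km <- kmeans_correlation(genes, k = 3, n_restarts = 20, seed = 2)
  means <- do.call(rbind, lapply(1:3, function(j) {
    data.frame(cluster_index = j, time_h = ll_times,
               value = scale_unit_interval(
                 colMeans(genes[km$cluster == j, ll_cols,
                                drop = FALSE])))
  }))
  named <- name_clusters_by_activation(km, means)
  got <- named$cluster_name
  # naming must match the identity of the generating cluster
  expect_gte(mean(got == truth), 0.95)
})
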