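test_that("Gaussian smoothing preserves constants, mass, and linearity", {
  const <- signal_track(rep(3, 2000))
  expect_equal(smooth_track(const)$values, rep(3, 2000))
  # unit impulse reproduces the truncated, renormalized kernel
  imp <- numeric(2000); imp[1000] <- 1
  sm <- smooth_track(signal_track(imp), window_bp = 400, sd_bp = 50)
  kern <- dnorm(-200:200, sd = 50); kern <- kern / sum(kern)
  expect_equal(sm$values[800:1200], kern, tolerance = 1e-12)
  expect_equal(sum(sm$values), 1)     # mass conserved on circular genome
  # linearity
  set.seed(5)
  x <- signal_track(runif(1500)); y <- signal_track(runif(1500))
  sxy <- smooth_track(signal_track(2 * x$values + 3 * y$values))
  expect_equal(sxy$values,
               2 * smooth_track(x)$values + 3 * smooth_track(y)$values)
  expect_error(smooth_track(const, sd_bp = 0), "positive")
})

test_that("peak calling applies the fold threshold at the summit", {
  n <- 20000
  mock <- signal_track(rep(100, n))
  expect_equal(nrow(call_peaks(mock, mock)), 0L)  # ip = mock: ratio 1
  bump <- function(fold, center, sd = 150)
    100 * (1 + (fold - 1) * exp(-((1:n) - center)^2 / (2 * sd^2)))
  ip5 <- signal_track(bump(5, 10000))
  pk <- call_peaks(ip5, mock, min_width_bp = 100)
  expect_equal(nrow(pk), 1L)
  expect_lte(abs(pk$summit - 9999), 1)
  expect_gte(pk$enrichment, 3.5)
  # a 3.4-fold bump is never reported at the 3.5 threshold
  ip34 <- signal_track(bump(3.4, 10000))
  expect_equal(nrow(call_peaks(ip34, mock, min_width_bp = 100)), 0L)
  # invariance to common positive scaling of ip and mock
  pk2 <- call_peaks(signal_track(ip5$values * 7),
                    signal_track(mock$values * 7), min_width_bp = 100)
  expect_equal(pk2$summit, pk$summit)
  expect_equal(pk2$enrichment, pk$enrichment)
  expect_error(call_peaks(ip5, signal_track(rep(100, 500))),
               "genome lengths")
})

test_that("peaks spanning the origin of a circular genome are called once", {
  n <- 10000
  mock <- signal_track(rep(100, n))
  d <- pmin(abs(1:n - 1), n - abs(1:n - 1))  # bump centred at base 0
  ip <- signal_track(100 * (1 + 5 * exp(-d^2 / (2 * 150^2))))
  pk <- call_peaks(ip, mock, min_width_bp = 100)
  expect_equal(nrow(pk), 1L)
  expect_true(pk$summit %in% c(0, n - 1, 1))
  expect_gt(pk$start, pk$end)  # stored as an origin-spanning interval
})

test_that("replicate consistency requires >= 1 bp interval overlap", {
  mk <- function(start, end) {
    df <- data.frame(start = start, end = end,
                     summit = floor((start + end) / 2),
                     enrichment = 5, width = end - start)
    class(df) <- c("chip_peaks", "data.frame")
    attr(df, "genome_length") <- 10000; attr(df, "circular") <- FALSE
    df
  }
  a <- mk(c(100, 2000), c(400, 2300))
  expect_equal(nrow(replicate_consistent_peaks(a, a)), 2L)
  disjoint <- mk(5000, 5200)
  expect_equal(nrow(replicate_consistent_peaks(a, disjoint)), 0L)
  # exactly one base of overlap: [100, 400) vs [399, 600)
  b <- mk(399, 600)
  kept <- replicate_consistent_peaks(a, b)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$start, 100)   # rep1 coordinates are reported
})

test_that("peak-gene assignment follows the three printed rules", {
  anno <- data.frame(gene_id = c("g1300", "g1600", "gM900"),
                     start = c(1300, 1600, 800),
                     end = c(1500, 1900, 900),
                     strand = c("+", "+", "-"))
  pk <- data.frame(summit = 999)
  attr(pk, "genome_length") <- 100000; attr(pk, "circular") <- FALSE
  links <- assign_peak_targets(pk, anno)
  # + strand: g1300 is 300 bp downstream-of-summit and closest; g1600 is
  # not the closest + gene so rule iii excludes it even though < 500 bp
  expect_setequal(links$gene_id, c("g1300", "gM900"))
  expect_equal(links$distance[links$gene_id == "g1300"], 300)
  # - strand gene with start codon at its end coordinate, summit 3' of it
  expect_equal(links$distance[links$gene_id == "gM900"], 100)
  # a gene > 500 bp away is never linked
  anno2 <- data.frame(gene_id = "far", start = 1600, end = 1900,
                      strand = "+")
  expect_equal(nrow(assign_peak_targets(pk, anno2)), 0L)
  # downstream gene on + strand (summit 3' of start codon) is not linked
  anno3 <- data.frame(gene_id = "down", start = 700, end = 950,
                      strand = "+")
  expect_equal(nrow(assign_peak_targets(pk, anno3)), 0L)
  expect_error(assign_peak_targets(pk, data.frame(gene_id = "x",
                                                  start = 1, end = 10,
                                                  strand = ".")),
               "strand")
})

test_that("assignment matches a brute-force validator on random annotations", {
  set.seed(88)
  for (rep in 1:5) {
    n_genes <- 10
    glen <- 2000L * n_genes
    start <- sort(sample.int(glen - 700, n_genes))
    anno <- data.frame(gene_id = sprintf("g%02d", 1:n_genes),
                       start = start, end = start + 600L,
                       strand = sample(c("+", "-"), n_genes, TRUE))
    pk <- data.frame(summit = sort(sample.int(glen, 8) - 1L))
    attr(pk, "genome_length") <- glen
    for (circ in c(TRUE, FALSE)) {
      attr(pk, "circular") <- circ
      got <- assign_peak_targets(pk, anno)
      want <- brute_force_links(pk, anno, glen, circ)
      got <- got[order(got$peak_id, got$strand), ]
      want <- want[order(want$peak_id, want$strand), ]
      rownames(got) <- rownames(want) <- NULL
      for (col in c("peak_id", "summit", "distance")) {
        got[[col]] <- as.numeric(got[[col]])
        want[[col]] <- as.numeric(want[[col]])
      }
      expect_equal(got, want)
      # at most one target gene per strand per peak
      expect_true(all(table(got$peak_id, got$strand) <= 1))
    }
  }
})

test_that("planted promoter peaks are recovered with exact gene links", {
  glen <- 200000
  anno <- data.frame(gene_id = c("gA", "gB", "gC"),
                     start = c(20301, 60501, 99000),
                     end = c(21200, 61400, 99900),
                     strand = c("+", "+", "-"))
  planted <- data.frame(summit = c(20000, 60200, 100100),
                        fold = c(5, 6, 8), width = 600)
  reps <- simulate_chip_tracks(glen, planted, background = 5000,
                               seed = 3)
  called <- lapply(reps, function(r)
    call_peaks(smooth_track(r$ip), smooth_track(r$mock)))
  cons <- replicate_consistent_peaks(called[[1]], called[[2]])
  expect_equal(nrow(cons), 3L)
  expect_true(all(abs(sort(cons$summit) - planted$summit) <= 1))
  links <- assign_peak_targets(cons, anno)
  expect_setequal(links$gene_id, anno$gene_id)
})

test_that("enrichment/expression change tables and correlations are exact", {
  links <- data.frame(peak_id = 1:2, summit = c(100, 300),
                      gene_id = c("gx", "gy"), distance = c(50, 60),
                      strand = "+")
  enr <- expand.grid(peak_id = 1:2, condition = "HighLightPulse",
                     time_h = c(8, 9))
  enr$enrichment <- c(4, 6, 8, 6)        # peak 1 doubles, peak 2 flat
  expr <- expand.grid(gene_id = c("gx", "gy"),
                      condition = "HighLightPulse", time_h = c(8, 9))
  expr$value <- c(1, 0, 3, 1)            # gx quadruples, gy doubles
  cmp <- data.frame(condition = "HighLightPulse", t = 9, t0 = 8)
  tab <- enrichment_change_table(links, enr, expr, cmp)
  expect_equal(tab$delta_enrichment, c(1, 0))
  expect_equal(tab$delta_expression, c(2, 1))
  # t == t0: both deltas zero
  tab0 <- enrichment_change_table(links, enr, expr,
                                  data.frame(condition = "HighLightPulse",
                                             t = 8, t0 = 8))
  expect_equal(tab0$delta_enrichment, c(0, 0))
  expect_equal(tab0$delta_expression, c(0, 0))
  expect_error(enrichment_change_table(links, enr, expr,
                                       data.frame(condition =
                                                    "HighLightPulse",
                                                  t = 10, t0 = 8)),
               "t = 10")
  # correlations: identity, anti-identity, and a closed-form check
  t1 <- data.frame(condition = "A",
                   delta_enrichment = c(0.5, 1, 2),
                   delta_expression = c(0.5, 1, 2))
  expect_equal(unname(delta_correlation(t1)), 1)
  t2 <- t1; t2$delta_expression <- -t2$delta_expression
  expect_equal(unname(delta_correlation(t2)), -1)
  x <- c(1, 2, 3); y <- c(2, 4, 5)
  t3 <- data.frame(condition = "A", delta_enrichment = x,
                   delta_expression = y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(delta_correlation(t3)), r_hand)
  t4 <- t3; t4$delta_expression <- c(1, 1, 1)
  expect_warning(r4 <- delta_correlation(t4), "zero variance")
  expect_true(is.na(r4))
})
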