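test_that("median normalization matches the hand-computed example", {
  m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  rownames(m) <- paste0("g", 1:3)
  out <- normalize_counts(m, gene_lengths = c(100, 200, 300))
  expect_equal(out, matrix(0.1, 3, 2), ignore_attr = TRUE)
  expect_equal(attr(out, "scale_factors"), c(s1 = 1, s2 = 0.5))
  # identical samples: unchanged up to the length division
  m2 <- cbind(a = c(4, 8, 12), b = c(4, 8, 12))
  out2 <- normalize_counts(m2, gene_lengths = c(1, 1, 1))
  expect_equal(out2, m2, ignore_attr = TRUE)
})

test_that("median normalization is invariant to per-sample rescaling", {
  set.seed(10)
  m <- matrix(rpois(60, 40), 15, 4,
              dimnames = list(paste0("g", 1:15), paste0("s", 1:4)))
  len <- sample(300:900, 15)
  base <- normalize_counts(m, len)
  for (cc in c(0.5, 3)) {
    m2 <- m
    m2[, 2] <- m2[, 2] * cc
    out <- normalize_counts(m2, len)
    # rescaling one sample leaves every normalized value unchanged up to
    # one global factor (exactly 1 unless that sample anchored the
    # reference median); relative expression is always preserved
    ratio <- as.vector(out) / as.vector(base)
    expect_lt(diff(range(ratio)), 1e-12)
  }
  expect_error(normalize_counts(cbind(c(0, 0), c(1, 2)), c(10, 10)),
               "all-zero")
})

test_that("log2 relative expression matches hand computations", {
  samples <- data.frame(condition = c("ref", "ref", "test"))
  m <- matrix(c(1, 3, 8), 1, dimnames = list("g1", NULL))
  out <- log2_relative_expression(m, samples, "ref", pseudocount = 0)
  expect_equal(unname(out[1, 3]), log2(8 / 2))
  # constant gene: all zeros
  mc <- matrix(5, 2, 3, dimnames = list(c("a", "b"), NULL))
  expect_equal(unname(log2_relative_expression(mc, samples, "ref")),
               matrix(0, 2, 3))
  # 4x the reference mean is +2
  m4 <- matrix(c(2, 2, 8), 1)
  expect_equal(log2_relative_expression(m4, samples, "ref",
                                        pseudocount = 0)[1, 3], 2)
  expect_error(log2_relative_expression(m, samples, "missing"),
               "not present")
})

test_that("cosinor fit recovers exact cosines and is 24h-shift invariant", {
  t <- 0:11
  x <- 2 + 0.5 * cos(2 * pi * (t - 6) / 24)
  f <- cosinor_fit(t, x)
  expect_equal(f$mesor, 2)
  expect_equal(f$amplitude, 0.5)
  expect_equal(f$acrophase_deg, 90)
  # flat series: amplitude 0
  expect_equal(cosinor_fit(t, rep(3, 12))$amplitude, 0)
  # adding any multiple of 24 h leaves the fit unchanged
  f2 <- cosinor_fit(t + 48, x)
  expect_equal(f2$amplitude, f$amplitude)
  expect_equal(f2$acrophase_deg, f$acrophase_deg)
  expect_error(cosinor_fit(c(1, 1, 1), c(1, 2, 3)), "distinct")
})

test_that("cosinor fit agrees with a dense grid-search oracle on noisy data", {
  set.seed(14)
  t <- seq(0, 22, by = 2)
  x <- 1 + 0.42 * cos(2 * pi * t / 24 - 250 * pi / 180) +
    rnorm(length(t), 0, 0.05)
  f <- cosinor_fit(t, x)
  oracle <- grid_cosinor_oracle(t, x)
  expect_equal(f$amplitude, unname(oracle["amplitude"]),
               tolerance = 0.02)
  d_phase <- abs(f$acrophase_deg - oracle["acrophase_deg"]) %% 360
  expect_lt(min(d_phase, 360 - d_phase), 0.02 * 360)
})

test_that("planted cosinor structure is recovered within 2% at low noise", {
  set.seed(3)
  t <- seq(0, 22, by = 2)
  for (i in 1:10) {
    A <- runif(1, 0.2, 0.6)
    ph <- runif(1, 0, 360)
    x <- 1.5 + A * cos(2 * pi * t / 24 - ph * pi / 180) +
      rnorm(length(t), 0, 0.01)
    f <- cosinor_fit(t, x)
    expect_lt(abs(f$amplitude - A) / A, 0.02)
    d <- abs(f$acrophase_deg - ph) %% 360
    expect_lt(min(d, 360 - d), 0.02 * 360)
  }
})

test_that("classification applies the amplitude, phase, and expression rules", {
  mk_fit <- function(amp, phase)
    structure(list(mesor = 1, amplitude = amp, acrophase_deg = phase),
              class = "cosinor_fit")
  expr <- matrix(2, 5, 3,
                 dimnames = list(paste0("g", 1:5), NULL))
  expr["g5", ] <- 0.2   # fails the one-read-per-nucleotide filter
  fits <- list(g1 = mk_fit(0.2, 100),   # dawn
               g2 = mk_fit(0.2, 250),   # dusk
               g3 = mk_fit(0.2, 39),    # dusk (inclusive boundary)
               g4 = mk_fit(0.10, 250),  # below amplitude threshold
               g5 = mk_fit(0.5, 250))   # filtered out
  cls <- classify_circadian(fits, expr)
  expect_equal(as.character(cls$class),
               c("dawn", "dusk", "dusk", "non_circadian",
                 "non_circadian"))
  expect_equal(cls$passed_expression_filter,
               c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # boundary cases of the windows
  cls2 <- classify_circadian(list(a = mk_fit(0.2, 40),
                                  b = mk_fit(0.2, 189),
                                  c = mk_fit(0.2, 190),
                                  d = mk_fit(0.2, 189.5)),
                             matrix(2, 4, 2,
                                    dimnames = list(letters[1:4], NULL)))
  expect_equal(as.character(cls2$class),
               c("dawn", "dawn", "dusk", "non_circadian"))
  # labels partition the genes: every gene gets exactly one label
  expect_false(anyNA(cls$class))
  expect_error(classify_circadian(list(zz = mk_fit(1, 1)), expr),
               "absent")
})

test_that("block z-scoring standardizes rows and absorbs block scaling", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(5, 1, 0))
  z <- zscore_block_normalize(m)
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))
  expect_equal(unname(rowMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 1, sd)), c(1, 1))
  # two blocks scaled by different constants give the unscaled answer
  m2 <- cbind(m, m * 10)
  blocks <- rep(1:2, each = 3)
  z2 <- zscore_block_normalize(m2, blocks)
  expect_equal(z2[, 1:3], z, ignore_attr = TRUE)
  expect_equal(z2[, 4:6], z, ignore_attr = TRUE)
  # zero-variance gene is excluded with a warning
  m3 <- rbind(m, flat = c(2, 2, 2))
  expect_warning(z3 <- zscore_block_normalize(m3), "zero variance")
  expect_equal(rownames(z3), c("g1", "g2"))
  expect_equal(attr(z3, "excluded"), "flat")
})

test_that("unit-interval scaling is an idempotent linear map", {
  expect_equal(scale_unit_interval(c(2, 4, 6)), c(0, 0.5, 1))
  x <- rnorm(20)
  s <- scale_unit_interval(x)
  expect_equal(min(s), 0)
  expect_equal(max(s), 1)
  expect_equal(scale_unit_interval(s), s)
  expect_error(scale_unit_interval(rep(1, 5)), "constant")
})
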