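test_that("constant data with constant regulators is fit to near-zero error", {
  spec <- dusk_model_spec("Early", "RpaA")
  tg <- seq(0, 12, by = 1)
  data <- data.frame(condition = "ClearDay", time_h = tg, value = 0.4)
  regs <- list(ClearDay = const_regulators(list(RpaA = 0.6)))
  f <- fit_dusk_model(data, regs, spec, conditions = "ClearDay",
                      n_starts = 8, seed = 3)
  expect_s3_class(f, "dusk_fit")
  expect_lt(f$error, 1e-4)
})

test_that("noiseless trajectories from a known model are recovered by refitting", {
  ds <- reference_dataset()
  cl_data <- ds$data[ds$data$cluster == "Early",
                     c("condition", "time_h", "value")]
  f <- fit_dusk_model(cl_data, ds$regulators, ds$models$Early$spec,
                      n_starts = 24, seed = 5)
  expect_lt(f$error, 0.02)
  sim <- unlist(f$fitted)
  obs <- unlist(lapply(f$data, `[[`, "value"))
  expect_lt(sqrt(mean((sim - obs)^2)) / diff(range(obs)), 0.01)
  # fitted parameters respect every bound
  expect_silent(clocklight:::check_param_bounds(unclass(f$params)))
  # reported error equals the misfit recomputed from stored trajectories
  expect_equal(f$error, model_error(f$fitted,
                                    lapply(f$data, `[[`, "value")))
})

test_that("fits are reproducible bit-wise under a fixed seed", {
  ds <- reference_dataset()
  cl_data <- ds$data[ds$data$cluster == "Early",
                     c("condition", "time_h", "value")]
  spec <- dusk_model_spec("Early", "RpaA")
  f1 <- fit_dusk_model(cl_data, ds$regulators, spec, n_starts = 4,
                       seed = 11)
  f2 <- fit_dusk_model(cl_data, ds$regulators, spec, n_starts = 4,
                       seed = 11)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$error, f2$error)
})

test_that("fit input validation and methods behave", {
  ds <- reference_dataset()
  cl_data <- ds$data[ds$data$cluster == "Early",
                     c("condition", "time_h", "value")]
  spec <- dusk_model_spec("Early", "RpaA")
  expect_error(fit_dusk_model(cl_data, ds$regulators, spec,
                              n_starts = 0), "n_starts")
  expect_error(fit_dusk_model(cl_data, ds$regulators, spec,
                              conditions = "Mars"), "Mars")
  f <- fit_dusk_model(cl_data, ds$regulators, spec, n_starts = 2,
                      seed = 1)
  expect_named(coef(f), c("B", "beta", "alpha", "K_A", "H_A"))
  r <- residuals(f)
  expect_equal(unname(lengths(r)),
               vapply(f$data, nrow, 0L, USE.NAMES = FALSE))
  expect_equal(deviance(f), f$error^2)
  pr <- predict(f)
  expect_equal(pr$ClearDay$value, f$fitted$ClearDay, tolerance = 1e-8)
  sims <- simulate(f, nsim = 2, seed = 4, noise_sd = 0.05)
  expect_length(sims, 2)
  expect_true(all(sims[[1]]$value >= 0))
  expect_output(print(summary(f)), "Misfit")
})

test_that("AIC ranks parsimonious models first and obeys its algebra", {
  # equal RSS: fewer parameters win
  mk <- function(rss, k, n) {
    structure(list(rss = rss, error = sqrt(rss), n_data = n,
                   k_params = k,
                   spec = dusk_model_spec("Early",
                                          c("RpaA", "RpaB")[seq_len(
                                            max(1, k %/% 4))])),
              class = "dusk_fit")
  }
  a <- mk(0.5, 5, 50); b <- mk(0.5, 7, 50)
  expect_lt(AIC(a), AIC(b))
  # an RSS ratio of exp(-4/n) exactly compensates two extra parameters
  n <- 50
  c1 <- mk(0.5, 5, n); c2 <- mk(0.5 * exp(-4 / n), 7, n)
  expect_equal(AIC(c1), AIC(c2))
})

test_that("reported misfits of the reference table rank the feedback model first", {
  tab <- dusk_model_presets()
  early <- tab[tab$cluster == "Early" &
                 tab$model %in% c("RpaA-only", "RpaB-only",
                                  "RpaA and RpaB", "Feedback, L rep."), ]
  ranked <- aic_rank(early$error, k = c(5, 5, 7, 9), n = 50,
                     labels = early$model)
  expect_equal(ranked$model[1], "Feedback, L rep.")
  # robust to the (unreported) residual count
  for (n in c(20, 50, 100, 200)) {
    r <- aic_rank(early$error, k = c(5, 5, 7, 9), n = n,
                  labels = early$model)
    expect_match(r$model[1], "Feedback")
  }
})

test_that("compare_models ranks fits and rejects mismatched data sizes", {
  ds <- reference_dataset()
  cl_data <- ds$data[ds$data$cluster == "Early",
                     c("condition", "time_h", "value")]
  f_fb <- fit_dusk_model(cl_data, ds$regulators, ds$models$Early$spec,
                         n_starts = 8, seed = 5)
  f_A <- fit_dusk_model(cl_data, ds$regulators,
                        dusk_model_spec("Early", "RpaA"),
                        n_starts = 8, seed = 5)
  cmp <- compare_models(f_fb, f_A)
  expect_s3_class(cmp, "dusk_model_comparison")
  expect_true(all(diff(cmp$aic) >= 0))
  expect_equal(cmp$delta_aic[1], 0)
  # on noiseless feedback-generated data the feedback topology wins
  expect_match(cmp$model[1], "feedback")
  f_short <- f_A
  f_short$n_data <- 10L
  expect_error(compare_models(f_fb, f_short), "different data sizes")
})

test_that("reference parameter lookups validate their inputs", {
  pre <- dusk_model_preset("Feedback, L rep.", "Early")
  expect_equal(pre$spec$feedback$source, "Late")
  expect_equal(pre$spec$feedback$mode, "repression")
  expect_equal(unname(pre$params["beta"]), 69.34)
  expect_equal(pre$error, 0.21)
  expect_error(dusk_model_preset("RpaB-only", "Middle"), "degenerate")
  expect_error(dusk_model_preset("nope", "Early"), "no reference")
})
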