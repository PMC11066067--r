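test_that("noiseless linear data is recovered exactly", {
  x <- seq(0, 3, length.out = 12)
  tb <- tibble::tibble(phosphate_uM = x, g = 2 - 0.5 * x)
  fit <- fit_abundance_model(tb, "g", "linear")
  expect_equal(fit$slope, -0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 2, tolerance = 1e-12)
  expect_equal(fit$df, 10)
  expect_equal(predict_abundance(fit, 0), 2)
  expect_equal(predict_abundance(fit, 4), 0)  # floored at zero
  expect_error(predict_abundance(fit, -1), "non-negative")
})

test_that("constant response yields slope 0 with no evidence against it", {
  tb <- tibble::tibble(phosphate_uM = 1:10, g = rep(2, 10))
  fit <- fit_abundance_model(tb, "g", "linear")
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_equal(fit$p_value, 1)
})

test_that("the linear fit reproduces the closed-form least-squares solution", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    x <- runif(n, 0, 3.29)
    y <- pmax(rnorm(n, 2 - 0.4 * x, 0.5), 0)
    tb <- tibble::tibble(phosphate_uM = x, g = y)
    fit <- fit_abundance_model(tb, "g", "linear")
    slope_cf <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    expect_equal(fit$slope, slope_cf, tolerance = 1e-9)
    expect_equal(fit$intercept, mean(y) - slope_cf * mean(x), tolerance = 1e-9)
    expect_equal(fit$df, n - 2)
    # slope sign invariant under positive rescaling of abundance units
    tb2 <- tb; tb2$g <- tb2$g * 1e4
    expect_equal(sign(fit_abundance_model(tb2, "g", "linear")$slope),
                 sign(fit$slope))
  }
})

test_that("log-linear fits invert noiseless exponential data", {
  x <- seq(0, 3, length.out = 30)
  tb <- tibble::tibble(phosphate_uM = x, g = exp(1.2 - 0.8 * x))
  fit <- fit_abundance_model(tb, "g", "log-linear", pseudocount = 0)
  expect_equal(fit$slope, -0.8, tolerance = 1e-9)
  expect_equal(fit$intercept, 1.2, tolerance = 1e-9)
  expect_equal(predict_abundance(fit, c(0.5, 2.5)),
               exp(1.2 - 0.8 * c(0.5, 2.5)), tolerance = 1e-9)
})

test_that("degenerate inputs are rejected with advice", {
  tb <- tibble::tibble(phosphate_uM = rep(1, 5), g = 1:5)
  expect_error(fit_abundance_model(tb, "g", "linear"), "zero variance")
  tb0 <- tibble::tibble(phosphate_uM = 1:5, g = rep(0, 5))
  expect_error(fit_abundance_model(tb0, "g", "log-linear"), "pseudocount")
  expect_error(fit_abundance_model(tb0[1:2, ], "g", "linear"), "3 samples")
})

test_that("samples with missing phosphate are dropped and counted", {
  tb <- tibble::tibble(phosphate_uM = c(1, 2, 3, NA, 5), g = c(1, 2, 3, 4, 5))
  fit <- fit_abundance_model(tb, "g", "linear")
  expect_equal(fit$n, 4)
  expect_equal(fit$n_dropped, 1)
  expect_equal(fit$df, 2)
})

test_that("tidy and glance expose broom-style summaries", {
  tb <- simulate_abundance(
    tibble::tibble(gene = "pstS", form = "linear", slope = -0.79,
                   intercept = 3, noise_sd = 0.3),
    seed = 5
  )
  fit <- fit_abundance_model(tb, "pstS", "linear")
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "phosphate_uM"))
  expect_equal(td$estimate[2], fit$slope)
  gl <- glance(fit)
  expect_equal(gl$n, 139)
  expect_equal(gl$df, 137)
  all_fits <- fit_all_genes(tb)
  expect_equal(nrow(all_fits), 1)
})

test_that("threshold ratios recompute the medians faithfully", {
  tb <- tibble::tibble(
    phosphate_uM = c(rep(0.05, 5), rep(0.5, 5)),
    g = c(rep(4, 5), rep(1, 5))
  )
  expect_equal(threshold_ratio(tb, "g", 0.1), 4)
  tb$g <- rep(2, 10)
  expect_equal(threshold_ratio(tb, "g", 0.1), 1)
  set.seed(2)
  tbr <- tibble::tibble(phosphate_uM = runif(60, 0, 3), g = rexp(60))
  r <- threshold_ratio(tbr, "g", 0.5)
  expect_equal(r, median(tbr$g[tbr$phosphate_uM < 0.5]) /
                 median(tbr$g[tbr$phosphate_uM >= 0.5]))
  expect_error(threshold_ratio(tb, "g", 10), "Both sides")
  tbz <- tibble::tibble(phosphate_uM = c(0.05, 0.5), g = c(1, 0))
  expect_warning(rz <- threshold_ratio(tbz, "g", 0.1), "infinite")
  expect_equal(rz, Inf)
})

test_that("abundance tables round-trip through TSV and reject negatives", {
  tb <- simulate_abundance(
    tibble::tibble(gene = "phnJ", form = "log-linear", slope = -0.3,
                   intercept = 0, noise_sd = 0.2),
    n = 20, seed = 9
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tb, path)
  back <- read_abundance_table(path)
  expect_equal(back$phnJ, tb$phnJ, tolerance = 1e-12)
  bad <- tb; bad$phnJ[1] <- -1
  write_abundance_table(bad, path)
  expect_error(read_abundance_table(path), "negative")
})
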