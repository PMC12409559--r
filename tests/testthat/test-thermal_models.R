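temps27 <- rep(seq(100, 300, by = 25), each = 3)

test_that("linear fits reproduce exact data and the closed-form OLS solution", {
  t <- seq(100, 300, by = 25)
  f <- fit_linear(t, 2 + 0.001 * t)
  expect_equal(f$k, 0.001, tolerance = 1e-12)
  expect_equal(f$amplitude, 2, tolerance = 1e-10)
  expect_equal(f$pearson_r, 1, tolerance = 1e-12)
  expect_true(f$converged)
  # constant response: zero slope, undefined r reported as 0, not converged
  fc <- fit_linear(t, rep(5, length(t)))
  expect_equal(fc$k, 0)
  expect_equal(fc$pearson_r, 0)
  expect_false(fc$converged)
  expect_error(fit_linear(rep(100, 5), 1:5), "singular")
  # agreement with lm() on random instances
  set.seed(31)
  for (i in 1:20) {
    y <- rnorm(27, 3 + 0.002 * temps27, 0.5)
    f <- fit_linear(temps27, y)
    cf <- coef(lm(y ~ temps27))
    expect_equal(f$amplitude, unname(cf[1]), tolerance = 1e-10)
    expect_equal(f$k, unname(cf[2]), tolerance = 1e-12)
  }
})

test_that("the OLS solution beats random candidate lines", {
  set.seed(32)
  for (i in 1:50) {
    y <- rnorm(27, 3 + 0.002 * temps27, 0.5)
    f <- fit_linear(temps27, y)
    loss_fit <- sum((y - f$amplitude - f$k * temps27)^2)
    a_cand <- f$amplitude + rnorm(1e4, 0, 0.5)
    k_cand <- f$k + rnorm(1e4, 0, 0.002)
    pred <- outer(temps27, k_cand) + rep(a_cand, each = 27)
    loss_cand <- colSums((y - pred)^2)
    expect_lte(loss_fit, min(loss_cand) + 1e-12)
  }
})

test_that("exponential fits recover exact data and equal the log seed when noiseless", {
  t <- seq(100, 300, by = 25)
  y <- 10 * exp(0.005 * t)
  f <- fit_exponential(t, y)
  expect_equal(f$amplitude, 10, tolerance = 1e-8)
  expect_equal(f$k, 0.005, tolerance = 1e-8)
  expect_true(f$converged)
  expect_equal(f$pearson_r, 1, tolerance = 1e-10)
  # in the zero-residual limit the nonlinear solution equals the
  # log-linear seed
  seed_fit <- lm(log(y) ~ t)
  expect_equal(f$k, unname(coef(seed_fit)[2]), tolerance = 1e-8)
  expect_equal(f$amplitude, exp(unname(coef(seed_fit)[1])), tolerance = 1e-8)
  expect_error(fit_exponential(c(100, 100, 200), c(1, 1, 2)), "3 distinct")
})

test_that("exponential fits are scale-equivariant and shift-covariant", {
  set.seed(33)
  y <- 8 * exp(0.005 * temps27) * (1 + rnorm(27, 0, 0.05))
  f <- fit_exponential(temps27, y)
  # y -> c*y multiplies B0 by c, leaves k unchanged
  fc <- fit_exponential(temps27, 3.7 * y)
  expect_equal(fc$k, f$k, tolerance = 1e-8)
  expect_equal(fc$amplitude / f$amplitude, 3.7, tolerance = 1e-8)
  # T -> T + dT leaves k, multiplies B0 by exp(-k dT)
  dT <- 50
  fs <- fit_exponential(temps27 + dT, y)
  expect_equal(fs$k, f$k, tolerance = 1e-8)
  expect_equal(fs$amplitude, f$amplitude * exp(-f$k * dT),
               tolerance = 1e-6 * f$amplitude)
})

test_that("non-positive responses are dropped from the seed but kept in the fit", {
  set.seed(34)
  y <- 0.3 * exp(0.004 * temps27) + rnorm(27, 0, 0.05)
  y[1] <- -0.05
  f <- fit_exponential(temps27, y)
  expect_true(f$converged)
  expect_lt(abs(f$k - 0.004), 0.001)
  # all-nonpositive responses cannot be fitted
  fneg <- fit_exponential(temps27, rep(-1, 27))
  expect_false(fneg$converged)
})

test_that("exponential parameter recovery is unbiased at the study design", {
  set.seed(35)
  khat <- replicate(200, {
    y <- 8 * exp(0.005 * temps27) * (1 + rnorm(27, 0, 0.05))
    fit_exponential(temps27, y)$k
  })
  expect_lt(abs(mean(khat) - 0.005), 0.02 * 0.005)
  expect_lt(sqrt(mean((khat - 0.005)^2)), 0.10 * 0.005)
})

test_that("per-residue fits recover the generator truth and apply coverage rules", {
  base <- generate_base_structure(12, seed = 36, n_waters = 0)
  ens <- generate_ensemble(base, noiseless_config(k_mode = "varying"),
                           seed = 37)
  f <- fit_profile_series(ens$series, "calpha", "b_raw")
  tr <- ens$truth$residues
  expect_equal(f$k, tr$k[match(f$resseq, tr$resseq)], tolerance = 1e-6)
  expect_equal(f$amplitude, tr$b0[match(f$resseq, tr$resseq)],
               tolerance = 1e-6)
  # a residue present in too few structures is omitted
  s <- ens$series
  for (id in names(s$models)[-(1:2)]) {
    a <- s$models[[id]]$atoms
    s$models[[id]]$atoms <- a[!(a$chain == "A" & a$resseq == 5), ]
  }
  expect_message(f2 <- fit_profile_series(s, "calpha", "b_raw"),
                 "coverage")
  expect_false(5 %in% f2$resseq)
  expect_error(fit_profile_series(temperature_series(list(), "x")),
               "reference|empty")
})

test_that("normalized-B fits are flat when all residues share one thermal constant", {
  base <- generate_base_structure(20, seed = 38, n_waters = 0)
  ens <- generate_ensemble(base, noiseless_config(k_mode = "uniform"),
                           seed = 39)
  for (sel in c("calpha", "side_chain")) {
    fn <- fit_profile_series(ens$series, sel, "b_norm")
    expect_lt(max(abs(fn$k)), 1e-8)
  }
})

test_that("global B(T) fits recover a common truth across channels", {
  base <- generate_base_structure(10, seed = 40, n_waters = 6)
  cfg <- noiseless_config(b0_meanlog = log(5.6), b0_sdlog = 0,
                          k_value = 0.004,
                          water_b0_meanlog = log(5.6), water_b0_sdlog = 0,
                          ion_b0 = 5.6, ligand_b0 = 5.6)
  ens <- generate_ensemble(base, cfg, seed = 41)
  s <- ens$series
  g <- global_b_fits(s)
  for (ch in c("wilson", "side_chain", "calpha")) {
    # the synthetic Wilson channel is quantized to 0.01 A^2
    expect_lt(abs(g[[ch]]$k - 0.004), 5e-4)
    expect_lt(abs(g[[ch]]$amplitude - 5.6), 0.01)
  }
  expect_lt(abs(g$mean_k - 0.004), 5e-4)
  expect_lt(abs(g$mean_b0 - 5.6), 0.01)
  # a channel without data is skipped with a warning, means span the rest
  s2 <- ens$series
  for (id in names(s2$models)) s2$models[[id]]$wilson_b <- NULL
  expect_warning(g2 <- global_b_fits(s2), "Wilson")
  expect_null(g2$wilson)
  expect_equal(g2$mean_k, mean(c(g2$side_chain$k, g2$calpha$k)))
})

test_that("fit tables export as TSV with selection and response columns", {
  base <- generate_base_structure(8, seed = 42, n_waters = 0)
  ens <- generate_ensemble(base, noiseless_config(),
                           temperatures = c(100, 200, 300), n_replicates = 1,
                           seed = 43)
  f <- fit_profile_series(ens$series, "calpha", "b_raw")
  p <- tempfile(fileext = ".tsv")
  write_fits(f, p)
  tab <- read.delim(p)
  expect_equal(nrow(tab), nrow(f))
  expect_true(all(c("amplitude", "k", "pearson_r", "selection", "response")
                  %in% names(tab)))
  expect_equal(tab$selection[1], "calpha")
})
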