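test_that("noiseless saturation curves are recovered exactly", {
  for (kd in c(29, 219)) {
    bc <- make_binding_curve(kd = kd, bmax = 1, sd = 0, replicates = 1,
                             seed = 1)
    f <- fit_saturation(bc$conc_nM, bc$response)
    expect_true(f$converged)
    expect_lt(abs(f$Kd - kd) / kd, 1e-6)
    expect_lt(abs(f$Bmax - 1), 1e-6)
  }
})

test_that("zero-noise recovery is unbiased for arbitrary positive parameters", {
  for (seed in 1:8) {
    truth <- epiunmask:::with_seed(seed, c(kd = stats::runif(1, 5, 300),
                                           bmax = stats::runif(1, 0.3, 4)))
    conc <- truth["kd"] * 2^seq(-3, 4)
    y <- truth["bmax"] * conc / (truth["kd"] + conc)
    f <- fit_saturation(conc, y)
    expect_lt(abs(f$Kd - truth["kd"]) / truth["kd"], 0.03)
  }
})

test_that("saturation fit agrees with an independent least-squares oracle", {
  bc <- make_binding_curve(kd = 29, bmax = 1, sd = 0.05, seed = 99)
  f <- fit_saturation(bc$conc_nM, bc$response)
  sse <- function(par) {
    sum((bc$response - par[2] * bc$conc_nM / (par[1] + bc$conc_nM))^2)
  }
  o <- stats::optim(c(10, 0.5), sse, method = "L-BFGS-B",
                    lower = c(1e-6, 1e-6))
  expect_lt(abs(f$Kd - o$par[1]) / o$par[1], 0.01)
})

test_that("saturation fit validates its input and reports uncertainty", {
  expect_error(fit_saturation(c(1, 2, 3), c(0.1, 0.2, 0.3)),
               "4 distinct")
  expect_error(fit_saturation(1:5, rep(1, 5)), "all equal")
  bc <- make_binding_curve(kd = 29, sd = 0.05, seed = 5)
  f <- fit_saturation(bc$conc_nM, bc$response)
  expect_gt(f$se_Kd, 0)
  # shared intercept recovers a plate blank exactly on a clean curve
  bc0 <- make_binding_curve(kd = 29, sd = 0, replicates = 1)
  f2 <- fit_saturation(bc0$conc_nM, bc0$response + 0.2,
                       background = "shared_intercept")
  expect_equal(f2$c0, 0.2, tolerance = 1e-4)
  expect_equal(f2$Kd, 29, tolerance = 1e-4)
})

test_that("binding SE shrinks roughly as 1/sqrt(replicates)", {
  se_of <- function(reps) {
    se <- vapply(1:40, function(s) {
      bc <- make_binding_curve(kd = 29, sd = 0.05, replicates = reps,
                               seed = 7000 + s)
      fit_saturation(bc$conc_nM, bc$response)$se_Kd
    }, 1)
    stats::median(se)
  }
  expect_equal(se_of(12) / se_of(3), sqrt(3 / 12), tolerance = 0.35)
})

test_that("fold_change reproduces published-style rounding and its reciprocal law", {
  expect_equal(fold_change(2410, 37, 0), 65)
  expect_equal(fold_change(485, 37, 1), 13.1)
  expect_equal(fold_change(5, 5, 0), 1)
  # half-away-from-zero differs from banker's rounding
  expect_equal(fold_change(25, 10, 0), 3)
  expect_equal(fold_change(65, 37, 1, mode = "trunc"), 1.7)
  expect_equal(fold_change(1180, 15, 0, mode = "trunc"), 78)
  for (seed in 1:5) {
    ab <- epiunmask:::with_seed(seed, stats::runif(2, 0.1, 100))
    expect_equal(fold_change(ab[1], ab[2]) * fold_change(ab[2], ab[1]), 1,
                 tolerance = 1e-12)
  }
  expect_error(fold_change(-1, 2), "positive")
  expect_error(fold_change(2, 0), "positive")
})

test_that("a symmetric kill pattern puts the LC50 at the middle dose", {
  f <- fit_probit(c(1, 10, 100), c(20, 20, 20), c(2, 10, 18))
  expect_equal(f$lc50, 10, tolerance = 1e-6)
  expect_true(f$fiducial[1] <= f$lc50 && f$lc50 <= f$fiducial[2])
})

test_that("LC50 is exactly scale-equivariant in dose units", {
  ba <- make_bioassay(lc50 = 15, slope = 2, seed = 21)
  f1 <- fit_probit(ba$dose, ba$n, ba$dead)
  f2 <- fit_probit(2 * ba$dose, ba$n, ba$dead)
  expect_equal(f2$lc50, 2 * f1$lc50, tolerance = 1e-8)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-8)
})

test_that("probit fit matches an independent grid-search MLE within 1%", {
  for (seed in c(11, 23, 37, 51, 68)) {
    truth <- epiunmask:::with_seed(seed, c(lc50 = stats::runif(1, 5, 50),
                                           slope = stats::runif(1, 1, 3)))
    ba <- make_bioassay(lc50 = truth[1], slope = truth[2], seed = seed)
    f <- fit_probit(ba$dose, ba$n, ba$dead)
    g <- probit_grid_mle(ba$dose, ba$n, ba$dead)
    expect_lt(abs(f$lc50 - g$lc50) / g$lc50, 0.01,
              label = paste("seed", seed))
  }
})

test_that("probit fit rejects degenerate designs", {
  expect_error(fit_probit(c(1, 10), c(10, 10), c(2, 8)), "3 distinct")
  expect_error(fit_probit(c(1, 10, 100), c(10, 10, 10), c(0, 0, 10)),
               "complete separation")
  expect_error(fit_probit(c(1, 10, 100), c(10, 10, 10), c(2, 12, 3)),
               "dead <= n")
})

test_that("mortality rate matches hand computation and its invariances", {
  expect_equal(mortality_rate(c(100, 110, 90), c(100, 110, 90))$mortality_pct, 0)
  expect_equal(mortality_rate(c(0, 0), c(50, 60))$mortality_pct, 100)
  m <- mortality_rate(c(40, 50, 60), c(100, 110, 90))
  expect_equal(m$mortality_pct, 50)
  expect_gt(m$se, 0)
  m2 <- mortality_rate(3 * c(40, 50, 60), 3 * c(100, 110, 90))
  expect_equal(m2$mortality_pct, 50)
  expect_lt(mortality_rate(c(120, 130), c(100, 100))$mortality_pct, 0)
  expect_error(mortality_rate(numeric(0), c(1, 2)), "non-empty")
})

test_that("cell-size summary computes means and star categories", {
  expect_equal(size_summary(c(1, 2, 3), c(1, 2, 3))$mean_treated, 2)
  same <- epiunmask:::with_seed(1, stats::rlnorm(50, 5, 0.4))
  expect_equal(size_summary(same, same)$stars, "ns")

  pop <- make_cell_population(n_images = 2, cells_per_image = 100,
                              size_shift = 0.3, seed = 4)
  s <- size_summary(pop$area[pop$group == "control"],
                    pop$area[pop$group == "treated"])
  expect_lt(s$p_value, 0.001)
  expect_equal(s$stars, "***")
  expect_gt(s$mean_treated, s$mean_control)
  expect_error(size_summary(1, c(1, 2)), "at least 2")
})
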