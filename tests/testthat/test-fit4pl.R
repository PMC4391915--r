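noiseless_4pl <- function(doses, bottom = 1, emax = 51, hill = 1, ec50 = 5) {
  bottom + (emax - bottom) / (1 + 10^(hill * (log10(ec50) - log10(doses))))
}

test_that("fit_4pl recovers generating parameters exactly from noiseless data", {
  d <- rep(c(0.2, 1, 5, 25, 125, 625), each = 2)
  fit <- fit_4pl(d, noiseless_4pl(d))
  expect_true(fit$converged)
  expect_equal(fit$ec50, 5, tolerance = 1e-6)
  expect_equal(fit$emax, 51, tolerance = 1e-6)
  expect_equal(fit$bottom, 1, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_lt(fit$residual_ss, 1e-10)
  # vehicle wells are excluded, not fitted
  fit0 <- fit_4pl(c(0, 0, d), c(7, 9, noiseless_4pl(d)))
  expect_equal(fit0$ec50, 5, tolerance = 1e-6)
  expect_identical(fit0$n_points, length(d))
})

test_that("optimizer minimum matches an exhaustive grid search on a fixed noisy dataset", {
  spec <- dr_sim_spec(ec50 = 5.38, emax = 51.3, noise_cv = 0.1, seed = 1)
  fold <- fold_normalize(internal_normalize(simulate_dose_response(spec)),
                         "vehicle")
  keep <- fold$dose_nM > 0
  logd <- log10(fold$dose_nM[keep])
  y <- fold$fold[keep]
  fit <- fit_4pl(fold$dose_nM, fold$fold)
  grid <- grid_search_4pl(
    logd, y,
    logec50_grid = seq(log10(0.5), log10(60), length.out = 60),
    hill_grid = seq(0.5, 2, by = 0.05),
    emax_grid = seq(30, 70, by = 0.5),
    bottom_grid = seq(-2, 4, by = 0.25)
  )
  # optimizer must do at least as well as the grid, and sit within one grid
  # step of the grid optimum in every coordinate
  opt_ss <- ss_4pl(c(logec50 = fit$log_ec50, hill = fit$hill,
                     emax = fit$emax, bottom = fit$bottom), logd, y)
  expect_lte(opt_ss, grid$ss + 1e-9)
  expect_lt(abs(fit$log_ec50 - grid$par[["logec50"]]),
            diff(seq(log10(0.5), log10(60), length.out = 60))[1] + 1e-9)
  expect_lt(abs(fit$hill - grid$par[["hill"]]), 0.05 + 1e-9)
  expect_lt(abs(fit$emax - grid$par[["emax"]]), 0.5 + 1e-9)
  expect_lt(abs(fit$bottom - grid$par[["bottom"]]), 0.25 + 1e-9)
})

test_that("fit is invariant to row order and equivariant to dose units", {
  spec <- dr_sim_spec(ec50 = 8, emax = 25, noise_cv = 0.08, seed = 5)
  fold <- fold_normalize(internal_normalize(simulate_dose_response(spec)),
                         "vehicle")
  keep <- fold$dose_nM > 0
  d <- fold$dose_nM[keep]; y <- fold$fold[keep]
  fit <- fit_4pl(d, y)
  perm <- sample(length(d))
  fit_p <- fit_4pl(d[perm], y[perm])
  expect_equal(coef(fit), coef(fit_p), tolerance = 1e-8)
  # doses in pM instead of nM: EC50 follows the unit change
  fit_u <- fit_4pl(d * 1000, y)
  expect_equal(fit_u$ec50, fit$ec50 * 1000, tolerance = 1e-6)
  expect_equal(fit_u$hill, fit$hill, tolerance = 1e-6)
})

test_that("EC50 confidence interval is log-symmetric, hence asymmetric in nM", {
  spec <- dr_sim_spec(ec50 = 5.38, emax = 51.3, noise_cv = 0.12, seed = 11)
  fold <- fold_normalize(internal_normalize(simulate_dose_response(spec)),
                         "vehicle")
  fit <- fit_4pl(fold$dose_nM, fold$fold)
  lo <- fit$ec50_ci95[1]; hi <- fit$ec50_ci95[2]
  expect_true(lo <= fit$ec50 && fit$ec50 <= hi)
  expect_lt(fit$ec50 - lo, hi - fit$ec50)        # asymmetry in nM
  expect_equal(log10(fit$ec50) - log10(lo), log10(hi) - log10(fit$ec50),
               tolerance = 1e-9)                  # symmetry in log10 nM
  expect_equal(unname(confint(fit, "ec50")[1, ]), unname(fit$ec50_ci95),
               tolerance = 1e-12)
})

test_that("fit_4pl enforces its preconditions", {
  expect_error(fit_4pl(c(1, 2, 3, 4), c(1, 2, 3, 4)), "5 distinct")
  d <- c(0.2, 1, 5, 25, 125)
  expect_error(fit_4pl(d, rep(2, 5)), "no dose dependence")
  expect_error(fit_4pl(d, c(1, 2, -3, 4, 5)), "positive")
  expect_error(fit_4pl(d, c(1, 2, NA, 4, 5)), "finite")
})

test_that("model-object methods are coherent", {
  d <- rep(c(0.2, 1, 5, 25, 125, 625), each = 3)
  set.seed(3)
  y <- noiseless_4pl(d) * exp(rnorm(length(d), sd = 0.08))
  fit <- fit_4pl(d, y)
  expect_equal(fitted(fit) + residuals(fit), y, tolerance = 1e-12)
  expect_equal(predict(fit, fit$ec50), (fit$bottom + fit$emax) / 2,
               tolerance = 1e-9)
  expect_named(coef(fit), c("bottom", "emax", "hill", "ec50"))
  expect_output(print(fit), "EC50")
  expect_gte(fit$emax_observed, max(tapply(y, d, mean)) - 1e-9)
})
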