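test_that("an exact line is fitted exactly and interpolated in closed form", {
  d <- data.frame(x = c(-17, -16, -15), y = c(1, 0, -1))
  fit <- titration_fit(d)
  expect_equal(fit$coef$all, c(-16, -1), tolerance = 1e-12)
  expect_equal(fit$sigma, 0, tolerance = 1e-10)
  ec <- equivalence_point(fit)
  expect_equal(ec$x0, -16)
  expect_equal(ec$conc, 1e-16)
  # shifting the intercept by +1 moves the root one decade
  d2 <- d; d2$y <- d2$y + 1
  expect_equal(equivalence_point(titration_fit(d2))$x0, -15)
})

test_that("duplicating every point leaves the fit unchanged", {
  set.seed(1)
  d <- data.frame(x = rep(-18:-12, 2), y = rep(-18:-12, 2) * -0.9 - 14 +
                    rnorm(14, 0, 0.1))
  f1 <- titration_fit(d)
  f2 <- titration_fit(rbind(d, d))
  expect_equal(f1$coef, f2$coef, tolerance = 1e-12)
})

test_that("group covariate gives shared slope and group intercepts", {
  d <- data.frame(x = rep(c(-17, -16, -15), 2),
                  y = c(1, 0, -1, 1.5, 0.5, -0.5),
                  group = rep(c("low", "high"), each = 3))
  fit <- titration_fit(d)
  expect_equal(fit$coef$low[2L], fit$coef$high[2L])
  expect_equal(equivalence_point(fit, "high")$x0 -
                 equivalence_point(fit, "low")$x0, 0.5)
  sep <- titration_fit(d, shared_slope = FALSE)
  expect_equal(sep$coef$low[2L], -1)
  # residuals orthogonal to the design
  expect_lt(abs(sum(residuals(fit) * fit$data$x)), 1e-10)
  expect_lt(abs(sum(residuals(fit))), 1e-10)
})

test_that("degenerate designs are refused with the assay named", {
  d <- data.frame(x = rep(-16, 4), y = c(0.1, 0.2, 0.3, 0.4))
  expect_error(titration_fit(d, assay = "BADGENE"), "BADGENE")
})

test_that("interpolation agrees with a brute-force grid search", {
  set.seed(7)
  d <- data.frame(x = seq(-19, -11, by = 1),
                  y = -0.93 * seq(-19, -11, by = 1) - 14.4 +
                    rnorm(9, 0, 0.05))
  fit <- titration_fit(d)
  x0 <- equivalence_point(fit)$x0
  grid <- seq(-19, -11, by = 1e-6)
  cf <- fit$coef$all
  oracle <- grid[which.min(abs(cf[1L] + cf[2L] * grid))]
  expect_equal(x0, oracle, tolerance = 1e-5)
})

test_that("degree-2 fits find the in-range root", {
  xs <- seq(-19, -13, by = 1)
  d <- data.frame(x = xs, y = -(xs + 16) + 0.02 * (xs + 16)^2)
  fit <- titration_fit(d, degree = 2)
  expect_equal(equivalence_point(fit)$x0, -16, tolerance = 1e-6)
})

test_that("noiseless simulated ladders fit with zero residual", {
  sc <- expression_scenario(n_per_group = 2,
                            true_log10_fc = c(G1 = 0.3),
                            baseline_log10_conc = c(G1 = -14.2,
                                                    HPRT = -15),
                            noise_sd = 0, seed = 1)
  d <- qge_preprocess(simulate_expression(sc))
  g1 <- d[d$assay == "G1", ]
  g1$x <- log10(g1$competitor_conc_M)
  fit <- titration_fit(g1)
  expect_lt(fit$sigma, 1e-10)
  expect_equal(equivalence_point(fit, "low")$x0, -14.2, tolerance = 1e-9)
  expect_equal(equivalence_point(fit, "high")$x0, -13.9, tolerance = 1e-9)
})

test_that("fold changes compose from equivalence points", {
  # all four equivalence points equal: the exact null
  null <- log_fold_change(-15, -15, -15, -15)
  expect_equal(null$log10_fc, 0)
  expect_equal(null$fold_change, 1)
  # housekeeping shift cancels
  lfc <- log_fold_change(-14, -15.13, -15.5, -15.5)
  expect_equal(lfc$log10_fc, 1.13)
  expect_equal(fc_from_log10(lfc$log10_fc), 13.5)
  # missing housekeeping is flagged, not silently substituted
  expect_warning(u <- log_fold_change(-14, -15), "unnormalized")
  expect_false(u$normalized)
  expect_error(log_fold_change(-14, -15, hk_high = -15), "both groups")
})
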