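test_that("noiseless panels are recovered to numerical precision", {
  sc <- tiny_panel()
  fit <- qge(simulate_expression(sc), B = 100, seed = 1)
  expect_equal(coef(fit), c(G1 = 0.301, G2 = -0.5), tolerance = 1e-9)
  # degenerate resampling of identical ladders: bias and SE are zero
  expect_equal(fit$results$bias, c(0, 0), tolerance = 1e-9)
  expect_equal(fit$results$std_error, c(0, 0), tolerance = 1e-9)
  expect_equal(fit$results$p_value, c(1 / 100, 1 / 100))
})

test_that("fold change and log10 fold change satisfy FC = 10^log10FC", {
  sc <- tiny_panel(noise = 0.1, seed = 8)
  fit <- qge(simulate_expression(sc), B = 200, seed = 2)
  expect_equal(fit$results$fold_change,
               10^fit$results$log10_fold_change, tolerance = 1e-12)
})

test_that("bootstrap inference is reproducible under a fixed seed", {
  sc <- tiny_panel(noise = 0.15, seed = 8)
  d <- simulate_expression(sc)
  f1 <- qge(d, B = 300, seed = 42)
  f2 <- qge(d, B = 300, seed = 42)
  expect_identical(f1$results, f2$results)
  f3 <- qge(d, B = 300, seed = 43)
  expect_false(identical(f1$boot, f3$boot))
})

test_that("swapping group labels negates log10FC and inverts FC", {
  sc <- tiny_panel(noise = 0.1, seed = 13)
  d <- simulate_expression(sc)
  fit <- qge(d, B = 100, seed = 1)
  swapped <- d
  swapped$group <- ifelse(d$group == "high", "low", "high")
  fit_sw <- qge(swapped, B = 100, seed = 1)
  expect_equal(fit_sw$results$log10_fold_change,
               -fit$results$log10_fold_change, tolerance = 1e-12)
  expect_equal(fit_sw$results$fold_change, 1 / fit$results$fold_change,
               tolerance = 1e-12)
})

test_that("a gene normalized against itself is exactly null", {
  sc <- expression_scenario(n_per_group = 3,
                            true_log10_fc = c(HPRT = 0), noise_sd = 0.2,
                            seed = 4)
  d <- simulate_expression(sc)
  d2 <- d
  d2$assay <- "COPY"
  both <- rbind(d, d2)
  fit <- qge(both, B = 100, seed = 1)
  expect_equal(fit$results$log10_fold_change[fit$results$assay == "COPY"],
               0, tolerance = 1e-12)
})

test_that("the closed-form fit agrees with an independent lm fit", {
  sc <- tiny_panel(noise = 0.2, seed = 31, n = 6)
  d <- qge_preprocess(simulate_expression(sc))
  fit <- qge(d, B = 100, seed = 1)
  for (a in c("G1", "G2", "HPRT")) {
    sub <- d[d$assay == a, ]
    lmfit <- stats::lm(y ~ group + x,
                       data = data.frame(y = sub$y,
                                         group = factor(sub$group,
                                                        c("low", "high")),
                                         x = log10(sub$competitor_conc_M)))
    cf <- stats::coef(lmfit)
    x0_low <- -cf[["(Intercept)"]] / cf[["x"]]
    x0_high <- -(cf[["(Intercept)"]] + cf[["grouphigh"]]) / cf[["x"]]
    ec <- fit$ec50[fit$ec50$assay == a, ]
    expect_equal(ec$x0[ec$group == "low"], x0_low, tolerance = 1e-10)
    expect_equal(ec$x0[ec$group == "high"], x0_high, tolerance = 1e-10)
  }
})

test_that("panel output has one row per non-housekeeping assay per breed", {
  sc <- tiny_panel(noise = 0.1, seed = 2)
  d1 <- simulate_expression(sc)
  d1$breed <- "Landrace"
  d2 <- simulate_expression(tiny_panel(noise = 0.1, seed = 9))
  d2$breed <- "Duroc"
  fit <- qge(rbind(d1, d2), B = 100, seed = 5)
  expect_equal(nrow(fit$results), 4L)
  expect_setequal(unique(fit$results$breed), c("Landrace", "Duroc"))
  expect_false("HPRT" %in% fit$results$assay)
  expect_true(all(c("assay", "breed", "fold_change", "log10_fold_change",
                    "bias", "std_error", "p_value", "n_high", "n_low") %in%
                    names(fit$results)))
  expect_true(all(fit$results$p_value >= 0 & fit$results$p_value <= 1))
  expect_true(all(fit$results$std_error >= 0))
})

test_that("empty input and bad configuration fail loudly", {
  expect_warning(fit <- qge(data.frame()), "empty")
  expect_equal(nrow(fit$results), 0L)
  sc <- tiny_panel()
  d <- simulate_expression(sc)
  expect_error(qge(d, housekeeping = "NOPE", B = 50, seed = 1),
               "housekeeping assay 'NOPE' not found")
})
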