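test_that("Hardy-Weinberg chi-square matches hand-computed oracles", {
  expect_equal(hwe_chisq(c(25, 50, 25))$chisq, 0)
  expect_equal(hwe_chisq(c(25, 50, 25))$p, 1)
  expect_equal(hwe_chisq(c(50, 0, 50))$chisq, 100)
  # relabeling the alleles reverses the counts but not the statistic
  cnt <- c(120, 67, 13)
  expect_equal(hwe_chisq(rev(cnt))$chisq, hwe_chisq(cnt)$chisq)
  # monomorphic SNPs are undefined, with a reason
  mono <- hwe_chisq(c(30, 0, 0))
  expect_true(is.na(mono$chisq))
  expect_equal(mono$reason, "monomorphic")
  # genotype-vector input goes through the same tabulation
  g <- c(rep("GG", 25), rep("GT", 50), rep("TT", 25))
  expect_equal(hwe_chisq(g)$chisq, 0)
})

test_that("back-transformed LS means are medians without correction", {
  expect_equal(backtransform_lsmeans(0)$median, 1)
  expect_equal(backtransform_lsmeans(log(3.45))$median, 3.45)
  bt <- backtransform_lsmeans(log(3.45), 0.12 / 3.45)
  expect_equal(bt$se, 0.12, tolerance = 1e-12)
})

test_that("LS means equal raw genotype means on a balanced flat design", {
  geno <- rep(c("GG", "GT", "TT"), each = 20)
  set.seed(9)
  ph <- data.frame(sample_id = sprintf("a%02d", 1:60), sire = "s1",
                   hys = "h1", bulbo_cm = 15,
                   androstenone = exp(rnorm(60, 0.2, 0.3)))
  gt <- data.frame(sample_id = ph$sample_id, snp_id = "SNP1",
                   genotype = geno)
  fit <- assoc_fit(ph, gt)
  raw <- tapply(log(ph$androstenone), geno, mean)
  expect_equal(fit$lsmeans$lsmean_log,
               as.numeric(raw[fit$lsmeans$genotype]), tolerance = 1e-10)
})

test_that("scaling the trait scales medians and leaves tests unchanged", {
  ph <- simulate_phenotypes(phenotype_scenario(n_animals = 400,
                                               geno_effect = 0.2,
                                               seed = 12))
  gt <- data.frame(sample_id = ph$sample_id, snp_id = "SNP1",
                   genotype = ph$genotype)
  f0 <- assoc_fit(ph, gt)
  ph2 <- ph
  ph2$androstenone <- ph2$androstenone * exp(0.7)
  f1 <- assoc_fit(ph2, gt)
  expect_equal(f1$lsmeans$median, f0$lsmeans$median * exp(0.7),
               tolerance = 1e-9)
  expect_equal(f1$f_test$p, f0$f_test$p, tolerance = 1e-12)
  expect_equal(f1$hwe$chisq, f0$hwe$chisq)
})

test_that("model residuals are orthogonal to every design column", {
  ph <- simulate_phenotypes(phenotype_scenario(n_animals = 300, seed = 3))
  gt <- data.frame(sample_id = ph$sample_id, snp_id = "SNP1",
                   genotype = ph$genotype)
  fit <- assoc_fit(ph, gt)
  X <- stats::model.matrix(fit$model)
  expect_true(all(abs(crossprod(X, stats::residuals(fit$model))) < 1e-8))
})

test_that("a simulated genotype contrast is recovered", {
  ph <- simulate_phenotypes(phenotype_scenario(n_animals = 2000,
                                               geno_effect = 0.3,
                                               seed = 7))
  gt <- data.frame(sample_id = ph$sample_id, snp_id = "SNP1",
                   genotype = ph$genotype)
  fit <- assoc_fit(ph, gt)
  s <- summary(fit$model)$coefficients
  est <- s["genotypeGT", "Estimate"]
  se <- s["genotypeGT", "Std. Error"]
  expect_lt(abs(est - 0.3), 3 * se)
  expect_lt(fit$f_test$p, 0.001)
})

test_that("degenerate genotype structures are refused", {
  ph <- simulate_phenotypes(phenotype_scenario(n_animals = 50, seed = 1))
  gt <- data.frame(sample_id = ph$sample_id, snp_id = "SNP1",
                   genotype = "GG")
  expect_error(assoc_fit(ph, gt), "only one genotype class")
  gt2 <- data.frame(sample_id = ph$sample_id, snp_id = "SNP1",
                    genotype = "XY")
  expect_error(assoc_fit(ph, gt2), "two bases")
})

test_that("genotype symmetry: AG and GA are the same genotype", {
  ph <- simulate_phenotypes(phenotype_scenario(n_animals = 200, seed = 5))
  gt <- data.frame(sample_id = ph$sample_id, snp_id = "SNP1",
                   genotype = ph$genotype)
  het <- gt$genotype == "GT"
  gt2 <- gt
  gt2$genotype[het] <- "TG"
  f1 <- assoc_fit(ph, gt)
  f2 <- assoc_fit(ph, gt2)
  expect_equal(f1$lsmeans, f2$lsmeans, tolerance = 1e-12)
})

test_that("genotype frequency report matches printed-style percentages", {
  gt <- data.frame(sample_id = sprintf("a%02d", 1:96), snp_id = "CYB5A_5UTR",
                   genotype = c(rep("GG", 94), rep("GT", 2)))
  rep1 <- genotype_frequency_report(gt)
  expect_equal(rep1$percent[rep1$genotype == "GG"], 98)
  expect_equal(rep1$n, c(94L, 2L, 0L))
  # order invariance
  rep2 <- genotype_frequency_report(gt[sample.int(96), ])
  expect_equal(rep1, rep2)
  # empty input gives an empty table
  expect_equal(nrow(genotype_frequency_report(gt[0, ])), 0L)
})
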