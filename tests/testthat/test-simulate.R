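test_that("noiseless frequencies sit exactly on the measurement model", {
  # at the equivalence concentration the frequency is exactly 1/2
  sc <- expression_scenario(n_per_group = 2,
                            true_log10_fc = c(G1 = 0),
                            baseline_log10_conc = c(G1 = -16, HPRT = -16),
                            noise_sd = 0, seed = 1)
  d <- simulate_expression(sc, point_design(1e-16))
  expect_equal(d$frequency, rep(0.5, nrow(d)))

  # a 2-fold change (log10 FC = 0.301...) gives f = R/(R+1) = 2/3 high
  fc2 <- log10(2)
  sc2 <- expression_scenario(n_per_group = 2,
                             true_log10_fc = c(G1 = fc2),
                             baseline_log10_conc = c(G1 = -16, HPRT = -16),
                             noise_sd = 0, seed = 1)
  d2 <- simulate_expression(sc2, point_design(1e-16))
  expect_equal(unique(d2$frequency[d2$group == "high" & d2$assay == "G1"]),
               2 / 3)
  expect_equal(unique(d2$frequency[d2$group == "low" & d2$assay == "G1"]),
               0.5)
})

test_that("expression simulation is deterministic in the seed and in range", {
  sc <- tiny_panel(noise = 0.2, seed = 11, dropout_rate = 0.1)
  a <- simulate_expression(sc)
  b <- simulate_expression(sc)
  expect_identical(a, b)
  c <- simulate_expression(tiny_panel(noise = 0.2, seed = 12,
                                      dropout_rate = 0.1))
  expect_false(identical(a$frequency, c$frequency))
  f <- a$frequency[!is.na(a$frequency)]
  expect_true(all(f > 0 & f < 1))
  # schema
  expect_named(a, c("sample_id", "group", "assay", "point_index",
                    "competitor_conc_M", "replicate", "frequency"))
})

test_that("dropout produces missing points at the configured rate", {
  sc <- expression_scenario(n_per_group = 120,
                            true_log10_fc = c(G1 = 0.3),
                            noise_sd = 0.1, dropout_rate = 0.15, seed = 5)
  d <- simulate_expression(sc)
  n <- nrow(d)
  expect_gt(n, 1e4)
  rate <- mean(is.na(d$frequency))
  mc <- 3 * sqrt(0.15 * 0.85 / n)
  expect_lt(abs(rate - 0.15), mc)
})

test_that("scenario validation rejects impossible settings", {
  expect_error(expression_scenario(true_log10_fc = c(G1 = 0),
                                   dropout_rate = 1), "dropout_rate")
  expect_error(expression_scenario(true_log10_fc = c(G1 = 0),
                                   noise_sd = -1), "non-negative")
  expect_error(ase_scenario(allele1_fraction = c(high = 1.2, low = 0.5)),
               "invalid scenario")
  expect_error(phenotype_scenario(extreme_fraction = 0.6),
               "invalid scenario")
})

test_that("two-allele frequencies partition the assay and sum to one", {
  sc <- ase_scenario(allele1_fraction = c(high = 0.8, low = 0.8),
                     n_het_per_group = 3, noise_sd = 0, seed = 2)
  d <- simulate_ase(sc, point_design(1e-16))
  # cDNA:competitor 1:1 at the equivalence point, allele 1 carries 80%
  expect_equal(unique(d$frequency[d$allele == "1"]), 0.4)
  expect_equal(unique(d$frequency[d$allele == "2"]), 0.1)
  expect_equal(unique(d$frequency[d$allele == "competitor"]), 0.5)

  noisy <- simulate_ase(ase_scenario(noise_sd = 0.3, seed = 9))
  sums <- tapply(noisy$frequency,
                 paste(noisy$sample_id, noisy$point_index, noisy$replicate),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_identical(noisy, simulate_ase(ase_scenario(noise_sd = 0.3,
                                                    seed = 9)))
})

test_that("genotypes follow Hardy-Weinberg proportions", {
  g <- simulate_genotypes(20000, allele1_freq = 0.8, seed = 4)
  cnt <- table(g$genotype)
  expect_equal(unname(cnt[["GG"]] / 20000), 0.64, tolerance = 0.02)
  expect_equal(unname(cnt[["GT"]] / 20000), 0.32, tolerance = 0.02)
  hw <- hwe_chisq(g$genotype)
  expect_gt(hw$p, 0.001)
})

test_that("phenotypes decompose as stated and select the extreme tails", {
  # all effects and noise zero: every animal sits at the intercept
  sc <- phenotype_scenario(n_animals = 50, meanlog = log(1.17), sdlog = 0,
                           sire_sd = 0, hys_sd = 0, bulbo_slope = 0,
                           seed = 1)
  ph <- simulate_phenotypes(sc)
  expect_equal(ph$androstenone, rep(1.17, 50))
  expect_true(all(ph$androstenone > 0))

  sc2 <- phenotype_scenario(n_animals = 1000, extreme_fraction = 0.06,
                            seed = 8)
  ph2 <- simulate_phenotypes(sc2)
  expect_identical(sum(ph2$extreme_group == "high", na.rm = TRUE), 60L)
  expect_identical(sum(ph2$extreme_group == "low", na.rm = TRUE), 60L)
  expect_true(min(ph2$androstenone[ph2$extreme_group == "high"],
                  na.rm = TRUE) >=
              max(ph2$androstenone[is.na(ph2$extreme_group)]))
  expect_true(all(ph2$androstenone > 0))
})

test_that("default phenotype presets reproduce the population statistics", {
  ph <- simulate_phenotypes(phenotype_scenario("Landrace", seed = 3))
  expect_equal(mean(ph$androstenone), 1.17, tolerance = 0.12)
  phd <- simulate_phenotypes(phenotype_scenario("Duroc", seed = 3))
  expect_equal(mean(phd$androstenone), 3.22, tolerance = 0.35)
  expect_gt(stats::sd(phd$androstenone), stats::sd(ph$androstenone))
})
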