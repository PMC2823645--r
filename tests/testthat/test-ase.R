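test_that("allele ratios follow the average of per-point ratios", {
  # balanced alleles at every point: ratio 1/2
  sc <- ase_scenario(allele1_fraction = c(high = 0.5, low = 0.5),
                     n_het_per_group = 3, noise_sd = 0, seed = 1)
  r <- allele_ratio(simulate_ase(sc))
  expect_equal(r$ratio, rep(0.5, nrow(r)))

  # constant (f1, f2) = (0.2, 0.3) gives 0.4 regardless of the competitor
  d <- expand.grid(sample_id = "s1", group = "high", assay = "A",
                   point_index = 0:4, stringsAsFactors = FALSE)
  d$competitor_conc_M <- 10^-(12 + d$point_index)
  d <- rbind(cbind(d, allele = "1", frequency = 0.2),
             cbind(d, allele = "2", frequency = 0.3),
             cbind(d, allele = "competitor", frequency = 0.5))
  expect_equal(allele_ratio(d)$ratio, 0.4)

  # two points with ratios 0.46 and 0.54 average to 0.50
  e <- d[d$point_index < 2, ]
  e$frequency[e$allele == "1"] <- c(0.23, 0.27)
  e$frequency[e$allele == "2"] <- c(0.27, 0.23)
  e$frequency[e$allele == "competitor"] <- 0.5
  expect_equal(allele_ratio(e)$ratio, 0.5)
})

test_that("allele ratios are invariant to per-point rescaling", {
  sc <- ase_scenario(allele1_fraction = c(high = 0.7, low = 0.6),
                     n_het_per_group = 4, noise_sd = 0.1, seed = 3)
  d <- simulate_ase(sc)
  r0 <- allele_ratio(d)
  scaled <- d
  fac <- 0.5 + 0.4 * (scaled$point_index / 10)
  sel <- scaled$allele %in% c("1", "2")
  scaled$frequency[sel] <- scaled$frequency[sel] * fac[sel]
  r1 <- allele_ratio(scaled)
  expect_equal(r1$ratio, r0$ratio, tolerance = 1e-12)
})

test_that("homozygotes are skipped with a reason code", {
  sc <- ase_scenario(n_het_per_group = 3, seed = 2)
  d <- simulate_ase(sc)
  geno <- data.frame(sample_id = unique(d$sample_id), genotype = "AG")
  geno$genotype[1L] <- "GG"
  r <- allele_ratio(d, genotypes = geno)
  expect_false(geno$sample_id[1L] %in% r$sample_id)
  skipped <- attr(r, "skipped")
  expect_equal(skipped$reason, "homozygous")
})

test_that("summed alleles feed the titration model like a one-product assay", {
  sc <- ase_scenario(allele1_fraction = c(high = 0.8, low = 0.8),
                     n_het_per_group = 3, baseline_log10_conc = -15.5,
                     noise_sd = 0, seed = 1)
  d <- simulate_ase(sc)
  tot <- total_from_alleles(d)
  expect_false("allele" %in% names(tot))
  # equivalent single-product simulation with the same total concentration
  sc1 <- expression_scenario(n_per_group = 3,
                             true_log10_fc = c(ASE1 = 0),
                             baseline_log10_conc = c(ASE1 = -15.5,
                                                     HPRT = -16),
                             noise_sd = 0, seed = 1)
  one <- simulate_expression(sc1)
  one <- one[one$assay == "ASE1", ]
  both <- merge(qge_preprocess(tot), qge_preprocess(one),
                by = c("sample_id", "point_index"))
  expect_equal(both$frequency.x, both$frequency.y, tolerance = 1e-12)
  # fitted equivalence point matches the generator's total concentration
  tot$x <- log10(tot$competitor_conc_M)
  fit <- titration_fit(qge_preprocess(tot))
  expect_equal(equivalence_point(fit, "high")$x0, -15.5, tolerance = 1e-9)
  # corrupt table: alleles summing above 1 are refused
  bad <- d
  bad$frequency[bad$allele == "1"] <- 0.9
  bad$frequency[bad$allele == "2"] <- 0.2
  expect_error(total_from_alleles(bad), "sum above 1")
})

test_that("identically balanced ratios give a null allele effect", {
  sc <- ase_scenario(allele1_fraction = c(high = 0.5, low = 0.5),
                     n_het_per_group = 6, noise_sd = 0, seed = 1)
  fit <- suppressWarnings(ase_fit(simulate_ase(sc)))
  cf <- coef(fit)
  expect_true(all(abs(cf[grep("allele", names(cf))]) < 1e-9))
})

test_that("allele relabeling maps r to 1 - r and keeps p-values", {
  sc <- ase_scenario(allele1_fraction = c(high = 0.75, low = 0.6),
                     n_het_per_group = 10, noise_sd = 0.15, seed = 6)
  d <- simulate_ase(sc)
  sw <- d
  sw$allele[d$allele == "1"] <- "2"
  sw$allele[d$allele == "2"] <- "1"
  r <- allele_ratio(d); rs <- allele_ratio(sw)
  expect_equal(rs$ratio, 1 - r$ratio, tolerance = 1e-12)
  f <- ase_fit(d); fs <- ase_fit(sw)
  expect_equal(fs$p[["allele"]], f$p[["allele"]], tolerance = 1e-8)
  expect_equal(fs$p[["interaction"]], f$p[["interaction"]],
               tolerance = 1e-8)
})

test_that("a strong allele imbalance is detected, level mode included", {
  sc <- ase_scenario(allele1_fraction = c(high = 0.8, low = 0.8),
                     n_het_per_group = 10, noise_sd = 0.1, seed = 4)
  d <- simulate_ase(sc)
  f <- ase_fit(d)
  expect_lt(f$p[["allele"]], 0.001)
  expect_true(is.na(f$p[["treatment"]]))
  fl <- ase_fit(d, response = "level")
  expect_lt(fl$p[["allele"]], 0.001)
  expect_false(is.na(fl$p[["treatment"]]))
  expect_equal(mean(f$table$mean_ratio), 0.8, tolerance = 0.05)
})

test_that("one-group data degrades to an allele-only model with warning", {
  sc <- ase_scenario(n_het_per_group = 5, noise_sd = 0.1, seed = 5)
  d <- simulate_ase(sc)
  d <- d[d$group == "high", ]
  expect_warning(f <- ase_fit(d), "one treatment group")
  expect_true(is.na(f$p[["interaction"]]))
})
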