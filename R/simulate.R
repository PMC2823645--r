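# Synthetic competitive-PCR data: frequency ladders, genotypes, phenotypes.
# The measurement model mirrors the assay: a point at competitor
# concentration c has expected logit y = log10(target) - log10(c); noise is
# additive Gaussian on the logit scale, which is the scale the titration
# model fits.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' Expression-panel simulation scenario
#'
#' Defines a panel of competitive-PCR expression assays measured on two
#' groups of animals (high and low phenotype). Each gene has a true log10
#' fold change (high vs low) and a baseline log10 transcript concentration;
#' exactly one gene is the housekeeping reference and its fold change is 0
#' by definition.
#'
#' The default panel is a 17-gene steroidogenesis panel plus the `HPRT`
#' housekeeping assay, with group sizes of 48 + 48 animals and two printing
#' replicates per titration point, matching the design the simulator
#' emulates.
#'
#' @param n_per_group Animals per group (high and low).
#' @param true_log10_fc Named vector of true log10 fold changes (high vs
#'   low), one per assay. The housekeeping assay is forced to 0.
#' @param baseline_log10_conc Named vector of log10 transcript molar
#'   concentrations in the low group, one per assay. Defaults to an even
#'   spread over \[-17, -13\].
#' @param housekeeping Name of the housekeeping assay (must appear in
#'   `true_log10_fc`).
#' @param noise_sd Measurement noise SD on the logit scale, per replicate
#'   measurement.
#' @param loading_sd SD of a per-animal loading offset (logit scale) shared
#'   by all assays of that animal; this is the artefact housekeeping
#'   normalization removes. Default 0.
#' @param replicate_count Printing replicates per point.
#' @param dropout_rate Probability that a measurement yields no signal
#'   (missing frequency), in \[0, 1).
#' @param seed Integer seed; all randomness of [simulate_expression()]
#'   derives from it.
#' @return An object of class `expression_scenario`.
#' @export
expression_scenario <- function(n_per_group = 48,
                                true_log10_fc = default_panel_fc(),
                                baseline_log10_conc = NULL,
                                housekeeping = "HPRT",
                                noise_sd = 0.1,
                                loading_sd = 0,
                                replicate_count = 2,
                                dropout_rate = 0,
                                seed = 1L) {
  stopifnot(is.numeric(true_log10_fc), !is.null(names(true_log10_fc)))
  if (!housekeeping %in% names(true_log10_fc)) {
    true_log10_fc <- c(true_log10_fc, stats::setNames(0, housekeeping))
  }
  true_log10_fc[housekeeping] <- 0
  assays <- names(true_log10_fc)
  if (anyDuplicated(assays)) stop("assay names must be unique", call. = FALSE)
  if (is.null(baseline_log10_conc)) {
    baseline_log10_conc <- stats::setNames(
      seq(-17, -13, length.out = length(assays)), assays)
  }
  stopifnot(setequal(names(baseline_log10_conc), assays))
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must be in [0, 1)", call. = FALSE)
  }
  if (noise_sd < 0 || loading_sd < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  structure(
    list(n_per_group = as.integer(n_per_group),
         true_log10_fc = true_log10_fc,
         baseline_log10_conc = baseline_log10_conc[assays],
         housekeeping = housekeeping,
         noise_sd = noise_sd, loading_sd = loading_sd,
         replicate_count = as.integer(replicate_count),
         dropout_rate = dropout_rate, seed = as.integer(seed)),
    class = "expression_scenario"
  )
}

#' Default simulated fold changes for the 17-assay expression panel
#'
#' Named log10 fold changes used as simulation presets for the default
#' steroidogenesis panel (testis candidate genes plus isoform and UTR
#' assays). These are generator settings for exercising the pipeline, not
#' measurements.
#'
#' @return Named numeric vector of 17 log10 fold changes.
#' @export
default_panel_fc <- function() {
  c(AKR1C4 = 0.42, CYB5A_5UTR = 0.42, CYB5A_iso = 0.37, CYP11A1 = 0.50,
    CYP17A1 = 0.46, CYP19A2 = -0.10, CYP21_exon9 = -0.91, DHRS4 = 0.41,
    FTL = 0.35, HSD3B_exon2 = 0.06, HSD3B_5UTR = -0.10, HSD17B4 = 0.34,
    NCOA4 = 0.11, PGRMC1 = 0.08, SMPD1 = 0.04, STAR = 1.13, SULT2A1 = 0.48)
}

#' Simulate a competitive-PCR expression experiment
#'
#' Generates the long-format peak-area frequency table the preprocessing
#' and titration stages consume. The noiseless logit at a point with
#' competitor concentration c is
#' `baseline + true_log10_fc * I(group == "high") + loading - log10(c)`,
#' so the frequency passes through 0.5 exactly where transcript and
#' competitor concentrations are equal.
#'
#' @param scenario An [expression_scenario()].
#' @param design A [ladder_design()].
#' @return A data frame with columns `sample_id`, `group` ("high"/"low"),
#'   `assay`, `point_index` (0-based dilution step), `competitor_conc_M`,
#'   `replicate`, `frequency` (NA for dropout), and attribute `"truth"`
#'   holding the scenario. Identical scenario seeds give identical tables.
#' @export
simulate_expression <- function(scenario, design = ladder_design()) {
  stopifnot(inherits(scenario, "expression_scenario"))
  design <- as_ladder_design(design)
  conc <- ladder_concentrations(design)
  x <- log10(conc)
  assays <- names(scenario$true_log10_fc)

  samples <- data.frame(
    sample_id = c(sprintf("low_%03d", seq_len(scenario$n_per_group)),
                  sprintf("high_%03d", seq_len(scenario$n_per_group))),
    group = rep(c("low", "high"), each = scenario$n_per_group),
    stringsAsFactors = FALSE
  )

  grid <- expand.grid(
    replicate = seq_len(scenario$replicate_count),
    point_index = seq_along(conc) - 1L,
    assay = assays,
    sample_row = seq_len(nrow(samples)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$sample_id <- samples$sample_id[grid$sample_row]
  grid$group <- samples$group[grid$sample_row]
  grid$competitor_conc_M <- conc[grid$point_index + 1L]

  mu <- scenario$baseline_log10_conc[grid$assay] +
    scenario$true_log10_fc[grid$assay] * (grid$group == "high") -
    log10(grid$competitor_conc_M)

  out <- with_seed(scenario$seed, {
    loading <- stats::rnorm(nrow(samples), 0, scenario$loading_sd)
    y <- mu + loading[grid$sample_row] +
      stats::rnorm(nrow(grid), 0, scenario$noise_sd)
    f <- inv_logit10(y)
    if (scenario$dropout_rate > 0) {
      f[stats::runif(length(f)) < scenario$dropout_rate] <- NA_real_
    }
    f
  })

  res <- data.frame(
    sample_id = grid$sample_id, group = grid$group, assay = grid$assay,
    point_index = grid$point_index,
    competitor_conc_M = grid$competitor_conc_M,
    replicate = grid$replicate, frequency = out,
    stringsAsFactors = FALSE
  )
  res <- res[order(res$sample_id, res$assay, res$point_index, res$replicate), ]
  rownames(res) <- NULL
  attr(res, "truth") <- scenario
  res
}

#' Allele-specific expression simulation scenario
#'
#' Two-allele assay in heterozygous animals: at each titration point the
#' total cDNA frequency is split between allele 1 and allele 2 so that the
#' expected ratio f1/(f1+f2) equals the group's `allele1_fraction`, and the
#' three product frequencies (allele 1, allele 2, competitor) sum to 1.
#'
#' @param allele1_fraction Named vector with elements `high` and `low`:
#'   expected share of allele 1 in total transcript, in (0, 1).
#' @param n_het_per_group Heterozygous animals per group.
#' @param allele_freq Population frequency of allele 1, used for
#'   Hardy-Weinberg genotype frequencies when genotypes are generated.
#' @param baseline_log10_conc log10 molar concentration of total transcript.
#' @param noise_sd Logit-scale noise SD applied independently to the total
#'   frequency and to the per-point allele ratio.
#' @param replicate_count Printing replicates per point.
#' @param assay Assay name.
#' @param seed Integer seed.
#' @return An object of class `ase_scenario`.
#' @export
ase_scenario <- function(allele1_fraction = c(high = 0.5, low = 0.5),
                         n_het_per_group = 20,
                         allele_freq = 0.2,
                         baseline_log10_conc = -16,
                         noise_sd = 0.1,
                         replicate_count = 2,
                         assay = "ASE1",
                         seed = 1L) {
  stopifnot(all(c("high", "low") %in% names(allele1_fraction)))
  if (any(allele1_fraction <= 0 | allele1_fraction >= 1)) {
    stop("invalid scenario: allele fractions must lie in (0, 1)", call. = FALSE)
  }
  if (allele_freq <= 0 || allele_freq >= 1) {
    stop("invalid scenario: `allele_freq` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(allele1_fraction = allele1_fraction[c("high", "low")],
         n_het_per_group = as.integer(n_het_per_group),
         allele_freq = allele_freq,
         genotype_freq = c(hom1 = allele_freq^2,
                           het = 2 * allele_freq * (1 - allele_freq),
                           hom2 = (1 - allele_freq)^2),
         baseline_log10_conc = baseline_log10_conc,
         noise_sd = noise_sd, replicate_count = as.integer(replicate_count),
         assay = assay, seed = as.integer(seed)),
    class = "ase_scenario"
  )
}

#' Simulate a two-allele (allele-specific expression) assay
#'
#' All simulated animals are heterozygous (homozygotes carry no
#' allele-specific information and are skipped by the estimator). Per
#' titration point the emitted frequencies of allele 1, allele 2 and the
#' competitor sum to 1 exactly.
#'
#' @param scenario An [ase_scenario()].
#' @param design A [ladder_design()].
#' @return Long-format data frame with columns `sample_id`, `group`,
#'   `assay`, `allele` ("1", "2" or "competitor"), `point_index`,
#'   `competitor_conc_M`, `replicate`, `frequency`.
#' @export
simulate_ase <- function(scenario, design = ladder_design()) {
  stopifnot(inherits(scenario, "ase_scenario"))
  design <- as_ladder_design(design)
  conc <- ladder_concentrations(design)

  grid <- expand.grid(
    replicate = seq_len(scenario$replicate_count),
    point_index = seq_along(conc) - 1L,
    sample = seq_len(2L * scenario$n_het_per_group),
    KEEP.OUT.ATTRS = FALSE
  )
  grp <- rep(c("low", "high"), each = scenario$n_het_per_group)
  ids <- sprintf("%s_%03d", grp,
                 c(seq_len(scenario$n_het_per_group),
                   seq_len(scenario$n_het_per_group)))
  grid$sample_id <- ids[grid$sample]
  grid$group <- grp[grid$sample]
  grid$competitor_conc_M <- conc[grid$point_index + 1L]

  mu_total <- scenario$baseline_log10_conc - log10(grid$competitor_conc_M)
  r_true <- scenario$allele1_fraction[grid$group]

  sim <- with_seed(scenario$seed, {
    y_total <- mu_total + stats::rnorm(nrow(grid), 0, scenario$noise_sd)
    r_pt <- inv_logit10(logit10(unname(r_true)) +
                          stats::rnorm(nrow(grid), 0, scenario$noise_sd))
    f_total <- inv_logit10(y_total)
    data.frame(f1 = f_total * r_pt, f2 = f_total * (1 - r_pt),
               fcomp = 1 - f_total)
  })

  base <- data.frame(
    sample_id = grid$sample_id, group = grid$group, assay = scenario$assay,
    point_index = grid$point_index,
    competitor_conc_M = grid$competitor_conc_M,
    replicate = grid$replicate, stringsAsFactors = FALSE
  )
  out <- rbind(
    cbind(base, allele = "1", frequency = sim$f1),
    cbind(base, allele = "2", frequency = sim$f2),
    cbind(base, allele = "competitor", frequency = sim$fcomp)
  )
  out <- out[order(out$sample_id, out$assay, out$point_index,
                   out$replicate, out$allele), ]
  rownames(out) <- NULL
  attr(out, "truth") <- scenario
  out
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Each animal receives two alleles drawn independently with the given
#' allele-1 frequency; the genotype is reported as an unordered
#' two-character string (alphabetical, so "AG" never "GA").
#'
#' @param n Number of animals.
#' @param snp_id SNP identifier.
#' @param alleles Character vector of the two allele bases.
#' @param allele1_freq Frequency of `alleles[1]`, in (0, 1).
#' @param sample_ids Optional animal identifiers (default `animal_0001`...).
#' @param seed Integer seed (optional).
#' @return Data frame with columns `sample_id`, `snp_id`, `genotype`.
#' @export
simulate_genotypes <- function(n, snp_id = "SNP1", alleles = c("G", "T"),
                               allele1_freq = 0.8, sample_ids = NULL,
                               seed = NULL) {
  stopifnot(length(alleles) == 2L, allele1_freq > 0, allele1_freq < 1)
  if (is.null(sample_ids)) sample_ids <- sprintf("animal_%04d", seq_len(n))
  g <- with_seed(seed, {
    a1 <- sample(alleles, n, replace = TRUE,
                 prob = c(allele1_freq, 1 - allele1_freq))
    a2 <- sample(alleles, n, replace = TRUE,
                 prob = c(allele1_freq, 1 - allele1_freq))
    paste0(pmin(a1, a2), pmax(a1, a2))
  })
  data.frame(sample_id = sample_ids, snp_id = snp_id, genotype = g,
             stringsAsFactors = FALSE)
}

#' Phenotype simulation scenario
#'
#' Log-normal androstenone (the boar-taint steroid, in micrograms per gram
#' of adipose tissue) with additive effects on the natural-log scale: sire,
#' herd-year-season batch (hys), bulbo-urethral gland length (a continuous
#' sexual-maturity covariate) and an additive SNP genotype effect.
#'
#' Defaults emulate a Landrace-scale population: marginal mean near
#' 1.17 ug/g with SD near 1.10 ug/g, and 3% of animals selected in each
#' phenotypic tail (6% most extreme in total) for the expression study.
#' `phenotype_scenario(breed = "Duroc")` switches to the Duroc preset
#' (mean 3.22, SD 2.69 ug/g, 4.5% per tail).
#'
#' @param breed "Landrace" or "Duroc" (sets trait location/scale and
#'   `extreme_fraction` presets), or any label if `meanlog`/`sdlog` given.
#' @param n_animals Number of animals.
#' @param meanlog Intercept of ln(androstenone). Default derived from the
#'   breed preset so the marginal distribution matches it.
#' @param sdlog Residual SD of ln(androstenone).
#' @param n_sires,n_hys Numbers of sire and herd-year-season classes.
#' @param sire_sd,hys_sd SDs of the sire and hys effects (log scale).
#' @param geno_effect Additive effect per copy of allele 2 (log scale).
#' @param bulbo_slope Effect of bulbo-urethral gland length, per cm (log
#'   scale); the covariate is centred, so the intercept is unaffected.
#' @param bulbo_mean,bulbo_sd Gland length distribution, cm.
#' @param extreme_fraction Fraction of animals selected per phenotypic tail
#'   (must be < 0.5).
#' @param seed Integer seed.
#' @return An object of class `phenotype_scenario`.
#' @export
phenotype_scenario <- function(breed = c("Landrace", "Duroc"),
                               n_animals = NULL,
                               meanlog = NULL, sdlog = 0.74,
                               n_sires = 50, n_hys = 20,
                               sire_sd = 0.2, hys_sd = 0.2,
                               geno_effect = 0,
                               bulbo_slope = 0.05,
                               bulbo_mean = 15, bulbo_sd = 2,
                               extreme_fraction = NULL,
                               seed = 1L) {
  breed <- breed[1L]
  preset <- switch(breed,
    Landrace = list(mean = 1.17, sd = 1.10, n = 1533, tail = 0.03),
    Duroc = list(mean = 3.22, sd = 2.69, n = 1027, tail = 0.045),
    list(mean = 1.17, sd = 1.10, n = 1000, tail = 0.03))
  if (is.null(n_animals)) n_animals <- preset$n
  if (is.null(extreme_fraction)) extreme_fraction <- preset$tail
  if (is.null(meanlog)) {
    # match the preset's marginal mean given the total log-scale variance
    total_var <- sdlog^2 + sire_sd^2 + hys_sd^2
    meanlog <- log(preset$mean) - total_var / 2
  }
  if (extreme_fraction >= 0.5 || extreme_fraction < 0) {
    stop("invalid scenario: `extreme_fraction` must be in [0, 0.5)",
         call. = FALSE)
  }
  structure(
    list(breed = breed, n_animals = as.integer(n_animals),
         meanlog = meanlog, sdlog = sdlog,
         n_sires = as.integer(n_sires), n_hys = as.integer(n_hys),
         sire_sd = sire_sd, hys_sd = hys_sd, geno_effect = geno_effect,
         bulbo_slope = bulbo_slope, bulbo_mean = bulbo_mean,
         bulbo_sd = bulbo_sd, extreme_fraction = extreme_fraction,
         seed = as.integer(seed)),
    class = "phenotype_scenario"
  )
}

#' Simulate androstenone phenotypes
#'
#' ln(androstenone) is the sum of the scenario intercept, a sire effect, a
#' herd-year-season effect, the centred bulbo-length covariate times its
#' slope, the additive genotype effect (per copy of the second allele) and
#' Gaussian residual noise. The most extreme animals per tail are labelled
#' `"high"`/`"low"` for downstream expression-study selection.
#'
#' @param scenario A [phenotype_scenario()].
#' @param genotypes Optional genotype table (`sample_id`, `snp_id`,
#'   `genotype`) for a single SNP; if `NULL`, one is generated under
#'   Hardy-Weinberg equilibrium with allele-1 frequency 0.8.
#' @return Data frame with columns `sample_id`, `breed`, `sire`, `hys`,
#'   `bulbo_cm`, `genotype`, `androstenone` (ug/g, always > 0) and
#'   `extreme_group` ("high", "low" or NA).
#' @export
simulate_phenotypes <- function(scenario, genotypes = NULL) {
  stopifnot(inherits(scenario, "phenotype_scenario"))
  n <- scenario$n_animals
  ids <- sprintf("animal_%04d", seq_len(n))

  out <- with_seed(scenario$seed, {
    if (is.null(genotypes)) {
      genotypes <- simulate_genotypes(n, sample_ids = ids)
    }
    stopifnot(all(c("sample_id", "genotype") %in% names(genotypes)))
    geno <- genotypes$genotype[match(ids, genotypes$sample_id)]
    if (anyNA(geno)) stop("genotype table does not cover all animals",
                          call. = FALSE)
    alleles <- sort(unique(unlist(strsplit(geno, ""))))
    # additive coding: copies of the last allele in sort order
    copies <- vapply(strsplit(geno, ""),
                     function(a) sum(a == alleles[length(alleles)]), 0)

    sire <- sample(sprintf("sire_%02d", seq_len(scenario$n_sires)), n,
                   replace = TRUE)
    hys <- sample(sprintf("hys_%02d", seq_len(scenario$n_hys)), n,
                  replace = TRUE)
    sire_eff <- stats::setNames(
      stats::rnorm(scenario$n_sires, 0, scenario$sire_sd),
      sprintf("sire_%02d", seq_len(scenario$n_sires)))
    hys_eff <- stats::setNames(
      stats::rnorm(scenario$n_hys, 0, scenario$hys_sd),
      sprintf("hys_%02d", seq_len(scenario$n_hys)))
    bulbo <- stats::rnorm(n, scenario$bulbo_mean, scenario$bulbo_sd)

    lny <- scenario$meanlog + sire_eff[sire] + hys_eff[hys] +
      scenario$bulbo_slope * (bulbo - scenario$bulbo_mean) +
      scenario$geno_effect * copies +
      stats::rnorm(n, 0, scenario$sdlog)

    data.frame(sample_id = ids, breed = scenario$breed,
               sire = sire, hys = hys, bulbo_cm = bulbo,
               genotype = geno, androstenone = exp(lny),
               stringsAsFactors = FALSE)
  })

  k <- floor(scenario$extreme_fraction * n)
  rk <- rank(out$androstenone, ties.method = "first")
  out$extreme_group <- NA_character_
  if (k > 0) {
    out$extreme_group[rk <= k] <- "low"
    out$extreme_group[rk > n - k] <- "high"
  }
  attr(out, "truth") <- scenario
  out
}
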