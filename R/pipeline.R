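#' Run the simulate/preprocess/quantify pipeline
#'
#' Drives the stages in dependency order and writes every stage's output
#' under `out_dir`, together with a JSON run manifest (config hash, seed,
#' package version, per-stage output paths). Rerunning with an identical
#' configuration and seed reproduces identical outputs.
#'
#' Stages: `"simulate"` writes the frequency table (expression assays; a
#' two-allele table as well if the panel has allele-specific assays),
#' `"qge"` the fold-change results TSV (columns `assay`, `breed`,
#' `fold_change`, `log10_fold_change`, `bias`, `std_error`, `p_value`,
#' `n_high`, `n_low`), `"ase"` the allele-expression results, `"assoc"`
#' the association results. A stage failure stops the run; outputs of
#' completed stages remain on disk.
#'
#' @param config A [panel_config()] (or path to its YAML).
#' @param stages Character subset of `c("simulate", "qge", "ase",
#'   "assoc")`, run in that order.
#' @param out_dir Output directory (created if needed).
#' @param freq_table Optional path to an existing frequency table, required
#'   for `"qge"`/`"ase"` when `"simulate"` is not among the stages.
#' @param ase_table Optional path to an existing two-allele table.
#' @param genotypes,phenotypes Optional paths for the `"assoc"` stage; when
#'   omitted and `"simulate"` runs, simulated tables are used.
#' @param seed Overrides the config seed.
#' @param quiet Suppress progress messages.
#' @return The run manifest (named list), invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config, stages = c("simulate", "qge"),
                         out_dir = ".", freq_table = NULL, ase_table = NULL,
                         genotypes = NULL, phenotypes = NULL, seed = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_panel_config(config)
  stopifnot(inherits(config, "panel_config"))
  stages <- match.arg(stages, c("simulate", "qge", "ase", "assoc"),
                      several.ok = TRUE)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("rcpcr")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   stages = list())
  paths <- list()
  hk <- config$assays$id[config$assays$housekeeping]
  expr_ids <- config$assays$id[config$assays$type == "expression" |
                                 config$assays$housekeeping]
  ase_ids <- config$assays$id[config$assays$type %in%
                                c("allele-specific", "isoform")]

  freq <- NULL; ase_data <- NULL; geno <- NULL; pheno <- NULL

  if ("simulate" %in% stages) {
    say("simulate: %d expression assay(s), %d allele-specific assay(s)",
        length(expr_ids), length(ase_ids))
    fc <- stats::setNames(rep(0.3, length(expr_ids)), expr_ids)
    sc <- expression_scenario(true_log10_fc = fc, housekeeping = hk,
                              seed = config$seed)
    freq <- simulate_expression(sc, config$design)
    paths$freq_table <- file.path(out_dir, "frequencies.tsv")
    write_frequency_table(freq, paths$freq_table)
    if (length(ase_ids)) {
      parts <- lapply(seq_along(ase_ids), function(i) {
        simulate_ase(ase_scenario(assay = ase_ids[i],
                                  seed = config$seed + i),
                     config$design)
      })
      ase_data <- do.call(rbind, parts)
      paths$ase_table <- file.path(out_dir, "ase_frequencies.tsv")
      write_frequency_table(ase_data, paths$ase_table)
    }
    geno <- simulate_genotypes(500, seed = config$seed + 101L)
    pheno <- simulate_phenotypes(
      phenotype_scenario(n_animals = 500, seed = config$seed + 102L),
      genotypes = geno)
    paths$genotypes <- file.path(out_dir, "genotypes.csv")
    paths$phenotypes <- file.path(out_dir, "phenotypes.csv")
    utils::write.csv(geno, paths$genotypes, row.names = FALSE, quote = FALSE)
    utils::write.csv(pheno, paths$phenotypes, row.names = FALSE,
                     quote = FALSE)
    manifest$stages$simulate <- paths[c("freq_table", "genotypes",
                                        "phenotypes")]
  }

  if ("qge" %in% stages) {
    if (is.null(freq)) {
      if (is.null(freq_table)) {
        stop("stage 'qge' needs a frequency table: run 'simulate' first or
  pass `freq_table = <path>`", call. = FALSE)
      }
      freq <- read_frequency_table(freq_table)
    }
    say("qge: fitting %d assay(s), B = %d", length(unique(freq$assay)),
        config$B)
    fit <- qge(freq, housekeeping = hk, degree = config$degree,
               B = config$B, seed = config$seed)
    out <- fit$results[c("assay", "breed", "fold_change",
                         "log10_fold_change", "bias", "std_error",
                         "p_value", "n_high", "n_low")]
    paths$qge_results <- file.path(out_dir, "qge_results.tsv")
    write_frequency_table(out, paths$qge_results)
    manifest$stages$qge <- list(out = paths$qge_results)
  }

  if ("ase" %in% stages) {
    if (is.null(ase_data)) {
      if (is.null(ase_table)) {
        stop("stage 'ase' needs a two-allele table: run 'simulate' with
  allele-specific assays or pass `ase_table = <path>`", call. = FALSE)
      }
      ase_data <- read_frequency_table(ase_table)
    }
    say("ase: %d assay(s)", length(unique(ase_data$assay)))
    rows <- lapply(split(ase_data, ase_data$assay), function(d) {
      f <- ase_fit(d)
      data.frame(assay = d$assay[1L],
                 group = f$table$group, mean_ratio = f$table$mean_ratio,
                 n_het = f$table$n_het,
                 allele_p = f$p[["allele"]],
                 treatment_p = f$p[["treatment"]],
                 interaction_p = f$p[["interaction"]])
    })
    paths$ase_results <- file.path(out_dir, "ase_results.tsv")
    write_frequency_table(do.call(rbind, rows), paths$ase_results)
    manifest$stages$ase <- list(out = paths$ase_results)
  }

  if ("assoc" %in% stages) {
    if (is.null(geno)) {
      if (is.null(genotypes)) stop("stage 'assoc' needs genotypes",
                                   call. = FALSE)
      geno <- read_genotype_table(genotypes)
    }
    if (is.null(pheno)) {
      if (is.null(phenotypes)) stop("stage 'assoc' needs phenotypes",
                                    call. = FALSE)
      pheno <- read_phenotype_table(phenotypes)
    }
    snps <- unique(geno$snp_id)
    say("assoc: %d SNP(s)", length(snps))
    rows <- lapply(snps, function(s) {
      f <- assoc_fit(pheno, geno, snp = s)
      data.frame(snp_id = s, genotype = f$lsmeans$genotype,
                 n = f$lsmeans$n, median = f$lsmeans$median,
                 se = f$lsmeans$se, f_p = f$f_test$p,
                 hwe_chi2 = f$hwe$chisq, hwe_p = f$hwe$p)
    })
    paths$assoc_results <- file.path(out_dir, "assoc_results.tsv")
    write_frequency_table(do.call(rbind, rows), paths$assoc_results)
    manifest$stages$assoc <- list(out = paths$assoc_results)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
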