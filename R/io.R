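# Readers and writers for the long-format interchange tables (TSV
# canonical, CSV accepted), the YAML panel configuration, and genotype
# input from CSV or VCF.

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read and validate a long-format frequency table
#'
#' Reads the canonical interchange format of the pipeline: one row per
#' measurement with columns `sample_id`, `group`, `assay`, `point_index`,
#' `competitor_conc_M`, `replicate`, `frequency`, optionally `allele` and
#' `breed`. Concentrations in scientific notation (e.g. `4.04e-11`) parse
#' as numbers. Rows violating the value contracts (frequency outside
#' \[0, 1\], non-positive concentration) raise an error naming the
#' offending rows.
#'
#' @param path TSV (default) or CSV file.
#' @return Validated data frame.
#' @export
read_frequency_table <- function(path) {
  x <- read_table_auto(path)
  required <- c("sample_id", "group", "assay", "point_index",
                "competitor_conc_M", "replicate", "frequency")
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop("frequency table schema error: missing column(s) ",
         paste(miss, collapse = ", "),
         "; expected at least: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("point_index", "competitor_conc_M", "replicate",
                "frequency")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }
  bad_f <- which(!is.na(x$frequency) & (x$frequency < 0 | x$frequency > 1))
  if (length(bad_f)) {
    stop("invalid frequency outside [0, 1] at data row(s): ",
         paste(utils::head(bad_f, 5L), collapse = ", "), call. = FALSE)
  }
  bad_c <- which(is.na(x$competitor_conc_M) | x$competitor_conc_M <= 0)
  if (length(bad_c)) {
    stop("invalid competitor concentration at data row(s): ",
         paste(utils::head(bad_c, 5L), collapse = ", "), call. = FALSE)
  }
  x
}

#' Write a table in the pipeline's TSV interchange format
#'
#' @param x Data frame.
#' @param path Output path (`.csv` switches to comma separation).
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype table from CSV/TSV or VCF
#'
#' Tabular input needs columns `sample_id`, `snp_id`, `genotype` (two-base
#' string). A `.vcf` file is converted internally: biallelic SNP records
#' only, genotypes taken from the per-sample GT field and translated to
#' base pairs.
#'
#' @param path Path to a CSV/TSV or VCF file.
#' @return Data frame with columns `sample_id`, `snp_id`, `genotype`.
#' @export
read_genotype_table <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    return(genotypes_from_vcf(path))
  }
  x <- read_table_auto(path)
  miss <- setdiff(c("sample_id", "snp_id", "genotype"), names(x))
  if (length(miss)) {
    stop("genotype table schema error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x$genotype <- normalize_genotype(x$genotype)
  x
}

genotypes_from_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- t(as.matrix(gt))
  biallelic <- !grepl(",", fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
  if (!any(biallelic)) stop("no biallelic SNP records in VCF", call. = FALSE)
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
  out <- do.call(rbind, lapply(which(biallelic), function(i) {
    alleles <- c(fix[i, "REF"], fix[i, "ALT"])
    g <- gt[i, ]
    keep <- !is.na(g)
    codes <- strsplit(gsub("\\|", "/", g[keep]), "/")
    geno <- vapply(codes, function(cd) {
      cd <- suppressWarnings(as.integer(cd))
      if (length(cd) != 2L || anyNA(cd) || any(cd > 1L)) return(NA_character_)
      paste0(sort(alleles[cd + 1L]), collapse = "")
    }, "")
    data.frame(sample_id = unname(names(g)[keep]), snp_id = unname(ids[i]),
               genotype = unname(geno), stringsAsFactors = FALSE)
  }))
  out <- out[!is.na(out$genotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a phenotype table
#'
#' @param path CSV/TSV with columns `sample_id`, `sire`, `hys`, `bulbo_cm`,
#'   `androstenone`, optionally `breed`.
#' @return Validated data frame (`androstenone` must be positive).
#' @export
read_phenotype_table <- function(path) {
  x <- read_table_auto(path)
  miss <- setdiff(c("sample_id", "sire", "hys", "bulbo_cm", "androstenone"),
                  names(x))
  if (length(miss)) {
    stop("phenotype table schema error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x$androstenone <- as.numeric(x$androstenone)
  if (any(is.na(x$androstenone) | x$androstenone <= 0)) {
    stop("androstenone must be positive (ug/g)", call. = FALSE)
  }
  x
}

#' Panel configuration
#'
#' Describes the assay panel and analysis options: the assay list (with
#' exactly one housekeeping reference), the group and breed labels, the
#' competitor ladder design, and the analysis options (polynomial degree,
#' bootstrap replicates B, significance level alpha, seed).
#'
#' @param assays Data frame (or list coercible to one) with columns `id`,
#'   `type` (`"expression"`, `"allele-specific"` or `"isoform"`) and
#'   `housekeeping` (logical).
#' @param groups Group labels, low first.
#' @param breeds Breed labels (optional).
#' @param design A [ladder_design()] or list of its fields.
#' @param degree,B,alpha,seed Analysis options.
#' @return Object of class `panel_config`.
#' @export
panel_config <- function(assays, groups = c("low", "high"), breeds = NULL,
                         design = ladder_design(), degree = 1, B = 4000,
                         alpha = 0.05, seed = 1L) {
  assays <- as.data.frame(assays)
  stopifnot(all(c("id", "type", "housekeeping") %in% names(assays)))
  assays$housekeeping <- as.logical(assays$housekeeping)
  if (anyDuplicated(assays$id)) stop("assay ids must be unique", call. = FALSE)
  if (sum(assays$housekeeping) != 1L) {
    stop("panel must declare exactly one housekeeping assay", call. = FALSE)
  }
  bad_type <- setdiff(assays$type, c("expression", "allele-specific",
                                     "isoform"))
  if (length(bad_type)) stop("unknown assay type(s): ",
                             paste(bad_type, collapse = ", "), call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  structure(
    list(assays = assays, groups = groups, breeds = breeds,
         design = as_ladder_design(design), degree = degree, B = as.integer(B),
         alpha = alpha, seed = as.integer(seed)),
    class = "panel_config"
  )
}

#' Read a panel configuration from YAML
#'
#' The YAML mirrors [panel_config()]: top-level keys `assays` (list of
#' `{id, type, housekeeping}`), `groups`, `breeds`, `design`
#' (`{start_conc, dilution_factor, n_points, reaction_volume}`) and
#' `options` (`{degree, B, alpha, seed}`).
#'
#' @param path YAML file.
#' @return A `panel_config`.
#' @export
read_panel_config <- function(path) {
  y <- yaml::read_yaml(path)
  assays <- do.call(rbind, lapply(y$assays, function(a) {
    data.frame(id = a$id,
               type = if (is.null(a$type)) "expression" else a$type,
               housekeeping = isTRUE(a$housekeeping))
  }))
  opts <- if (is.null(y$options)) list() else y$options
  panel_config(
    assays = assays,
    groups = if (is.null(y$groups)) c("low", "high") else unlist(y$groups),
    breeds = if (is.null(y$breeds)) NULL else unlist(y$breeds),
    design = if (is.null(y$design)) ladder_design() else
      do.call(ladder_design, y$design),
    degree = if (is.null(opts$degree)) 1 else opts$degree,
    B = if (is.null(opts$B)) 4000 else opts$B,
    alpha = if (is.null(opts$alpha)) 0.05 else opts$alpha,
    seed = if (is.null(opts$seed)) 1L else opts$seed
  )
}

config_hash <- function(config) {
  relevant <- list(assays = config$assays, groups = config$groups,
                   breeds = config$breeds,
                   design = unclass(config$design), degree = config$degree,
                   B = config$B, alpha = config$alpha, seed = config$seed)
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  yaml::write_yaml(relevant, tf)
  unname(tools::md5sum(tf))
}
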