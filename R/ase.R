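# Allele-specific expression from two-allele competitive assays: the
# per-sample ratio f1/(f1+f2) averaged across the titration range (the
# competitor amount cancels from the ratio, so every usable point is
# equally informative), allele summation into total expression, and a
# fixed-effects treatment x allele model.

# Wide (f1, f2, fcomp) per point from the long two-allele table; allele
# labels are taken in sort order so relabeling swaps the columns.
ase_wide <- function(data) {
  stopifnot(is.data.frame(data), "allele" %in% names(data))
  data <- median_replicates(data)
  alleles <- setdiff(sort(unique(as.character(data$allele))), "competitor")
  if (length(alleles) != 2L) {
    stop("expected exactly two allele labels besides 'competitor', got: ",
         paste(alleles, collapse = ", "), call. = FALSE)
  }
  keys <- intersect(c("sample_id", "group", "breed", "assay", "point_index",
                      "competitor_conc_M"), names(data))
  f1 <- data[data$allele == alleles[1L], c(keys, "frequency")]
  f2 <- data[data$allele == alleles[2L], c(keys, "frequency")]
  names(f1)[names(f1) == "frequency"] <- "f1"
  names(f2)[names(f2) == "frequency"] <- "f2"
  wide <- merge(f1, f2, by = keys)
  fc <- data[data$allele == "competitor", c(keys, "frequency")]
  if (nrow(fc)) {
    names(fc)[names(fc) == "frequency"] <- "fcomp"
    wide <- merge(wide, fc, by = keys, all.x = TRUE)
  } else {
    wide$fcomp <- 1 - wide$f1 - wide$f2
  }
  attr(wide, "alleles") <- alleles
  wide
}

#' Per-sample allele-expression ratio
#'
#' For a heterozygous sample the relative expression of allele 1 is the
#' unweighted mean of f1/(f1+f2) over all titration points where at least
#' one allele gave signal. The ratio is invariant to the competitor amount,
#' which divides out of both frequencies.
#'
#' @param data Long two-allele frequency table (columns as in
#'   [simulate_ase()]): must contain an `allele` column with two allele
#'   labels and optionally `"competitor"` rows.
#' @param genotypes Optional genotype table (`sample_id`, `genotype`);
#'   homozygous samples are then skipped and listed in the `"skipped"`
#'   attribute with reason `"homozygous"`.
#' @return Data frame with one row per sample: `sample_id`, grouping
#'   columns, `assay`, `ratio` (allele-1 share, in \[0, 1\], NA when no
#'   point had signal) and `n_points`. Attribute `"alleles"` gives the two
#'   allele labels in the order used (ratio refers to the first).
#' @export
allele_ratio <- function(data, genotypes = NULL) {
  wide <- ase_wide(data)
  alleles <- attr(wide, "alleles")
  if (!is.null(genotypes)) {
    stopifnot(all(c("sample_id", "genotype") %in% names(genotypes)))
    het <- genotypes$sample_id[
      substr(genotypes$genotype, 1, 1) != substr(genotypes$genotype, 2, 2)]
    skipped <- setdiff(unique(wide$sample_id), het)
    wide <- wide[wide$sample_id %in% het, , drop = FALSE]
  } else {
    skipped <- character(0)
  }
  keys <- intersect(c("sample_id", "group", "breed", "assay"), names(wide))
  tot <- wide$f1 + wide$f2
  usable <- !is.na(tot) & tot > 0
  r <- ifelse(usable, wide$f1 / tot, NA_real_)
  agg <- stats::aggregate(r, by = wide[keys],
                          FUN = function(v) mean(v, na.rm = TRUE))
  names(agg)[ncol(agg)] <- "ratio"
  agg$n_points <- stats::aggregate(usable, by = wide[keys], FUN = sum)$x
  agg$ratio[is.nan(agg$ratio)] <- NA_real_
  ord <- do.call(order, agg[keys])
  agg <- agg[ord, c(keys, "ratio", "n_points")]
  rownames(agg) <- NULL
  if (all(wide$f2 == 0, na.rm = TRUE)) {
    attr(agg, "not_detected") <- alleles[2L]
    message(sprintf("product '%s' not detected in any sample", alleles[2L]))
  }
  attr(agg, "alleles") <- alleles
  if (length(skipped)) {
    attr(agg, "skipped") <- data.frame(sample_id = skipped,
                                       reason = "homozygous")
  }
  agg
}

#' Total expression from a two-allele assay
#'
#' Sums the two allele frequencies per point into a single cDNA frequency,
#' giving a one-product table that feeds the titration model unchanged
#' (total gene expression of the assayed locus).
#'
#' @param data Long two-allele frequency table.
#' @return Long single-frequency table with the same schema minus the
#'   `allele` column.
#' @export
total_from_alleles <- function(data) {
  stopifnot(is.data.frame(data), "allele" %in% names(data))
  alleles <- setdiff(sort(unique(as.character(data$allele))), "competitor")
  keys <- intersect(c("sample_id", "group", "breed", "assay", "point_index",
                      "competitor_conc_M", "replicate"), names(data))
  sub <- data[data$allele %in% alleles, , drop = FALSE]
  agg <- stats::aggregate(sub["frequency"], by = sub[keys],
                          FUN = function(v) if (anyNA(v)) NA_real_ else sum(v))
  if (any(agg$frequency > 1 + 1e-9, na.rm = TRUE)) {
    stop("allele frequencies sum above 1: corrupt frequency table",
         call. = FALSE)
  }
  agg$frequency[!is.na(agg$frequency) & agg$frequency == 0] <- NA_real_
  ord <- do.call(order, agg[keys])
  out <- agg[ord, c(keys, "frequency")]
  rownames(out) <- NULL
  out
}

#' Fixed-effects model for differential allelic expression
#'
#' Tests whether the two alleles of a heterozygote are expressed unequally
#' and whether that imbalance differs between the high and low phenotype
#' groups. Rows are sample x allele; fixed effects are treatment
#' (high/low), allele, and optionally their interaction, tested by F-tests
#' from the sequential ANOVA of an ordinary linear model.
#'
#' Two response modes exist. `"ratio"` (default): the allele-1 row carries
#' the sample's allele share r and the allele-2 row 1 - r (logit10 by
#' default); the two rows of a sample are complementary, so the treatment
#' main effect is structurally zero and reported as NA — differential ASE
#' between groups is the treatment:allele interaction. `"level"`: each
#' allele's expression level against the competitor,
#' mean logit10(f_a / (f_a + f_comp)) over points, which gives the
#' treatment main effect meaning as total-expression difference.
#'
#' @param data Long two-allele frequency table (or a ratio table from
#'   [allele_ratio()] when `response = "ratio"`; then `level` mode is
#'   unavailable).
#' @param response `"ratio"` or `"level"`.
#' @param logit Analyse responses on the logit10 scale (default TRUE).
#' @param interaction Include the treatment:allele interaction.
#' @param genotypes Optional genotype table to exclude homozygotes.
#' @return Object of class `ase_fit`: `table` (per group: mean allele-1
#'   ratio and n heterozygotes), `p` (named p-values: `allele`,
#'   `treatment`, `interaction`), the underlying `lm`, and the allele
#'   labels.
#' @export
ase_fit <- function(data, response = c("ratio", "level"), logit = TRUE,
                    interaction = TRUE, genotypes = NULL) {
  response <- match.arg(response)
  if ("allele" %in% names(data)) {
    ratios <- allele_ratio(data, genotypes = genotypes)
    wide <- ase_wide(data)
  } else {
    if (response == "level") {
      stop("`level` response needs the full two-allele table", call. = FALSE)
    }
    ratios <- data
    wide <- NULL
  }
  stopifnot(all(c("sample_id", "group", "ratio") %in% names(ratios)))
  ratios <- ratios[!is.na(ratios$ratio), , drop = FALSE]
  if (!is.null(attr(ratios, "not_detected"))) {
    warning(sprintf("allele '%s' not detected: no allele-specific test",
                    attr(ratios, "not_detected")), call. = FALSE)
  }
  alleles <- attr(ratios, "alleles")
  if (is.null(alleles)) alleles <- c("1", "2")

  if (response == "ratio") {
    eps <- 1e-12
    val1 <- pmin(pmax(ratios$ratio, eps), 1 - eps)
    long <- data.frame(
      sample_id = rep(ratios$sample_id, 2L),
      treatment = factor(rep(as.character(ratios$group), 2L)),
      allele = factor(rep(alleles, each = nrow(ratios))),
      value = c(if (logit) logit10(val1) else val1,
                if (logit) logit10(1 - val1) else 1 - val1)
    )
  } else {
    usable <- !is.na(wide$f1) & !is.na(wide$f2) & !is.na(wide$fcomp) &
      wide$fcomp > 0
    w <- wide[usable, , drop = FALSE]
    lev <- function(fa) {
      z <- fa / (fa + w$fcomp)
      z <- pmin(pmax(z, 1e-12), 1 - 1e-12)
      if (logit) logit10(z) else z
    }
    per <- stats::aggregate(
      data.frame(l1 = lev(w$f1), l2 = lev(w$f2)),
      by = w[intersect(c("sample_id", "group"), names(w))], FUN = mean)
    per <- per[per$sample_id %in% ratios$sample_id, , drop = FALSE]
    long <- data.frame(
      sample_id = rep(per$sample_id, 2L),
      treatment = factor(rep(as.character(per$group), 2L)),
      allele = factor(rep(alleles, each = nrow(per))),
      value = c(per$l1, per$l2)
    )
  }

  one_way <- nlevels(long$treatment) < 2L
  if (one_way) {
    warning("only one treatment group with heterozygotes: ",
            "model degenerates to allele-only", call. = FALSE)
    form <- value ~ allele
  } else {
    form <- if (interaction) value ~ treatment * allele else
      value ~ treatment + allele
  }
  fit <- stats::lm(form, data = long)
  an <- stats::anova(fit)
  pv <- function(term) {
    if (term %in% rownames(an)) an[term, "Pr(>F)"] else NA_real_
  }
  p <- c(allele = pv("allele"),
         treatment = if (response == "ratio") NA_real_ else pv("treatment"),
         interaction = pv("treatment:allele"))

  tab <- stats::aggregate(ratios$ratio, by = list(group = ratios$group),
                          FUN = mean)
  names(tab)[2L] <- "mean_ratio"
  tab$n_het <- stats::aggregate(ratios$ratio,
                                by = list(group = ratios$group),
                                FUN = length)$x

  structure(
    list(table = tab, p = p, model = fit, response = response,
         logit = logit, alleles = alleles, ratios = ratios,
         assay = if ("assay" %in% names(ratios)) ratios$assay[1L] else NA),
    class = "ase_fit"
  )
}

#' @export
print.ase_fit <- function(x, ...) {
  cat(sprintf("Allele-specific expression model (%s response%s)\n",
              x$response, if (x$logit) ", logit10 scale" else ""))
  if (!is.na(x$assay)) cat("Assay:", x$assay, "\n")
  cat(sprintf("Alleles: %s vs %s (ratio = share of '%s')\n",
              x$alleles[1L], x$alleles[2L], x$alleles[1L]))
  print(x$table, row.names = FALSE)
  cat(sprintf("F-tests: allele p = %s, treatment p = %s, interaction p = %s\n",
              format.pval(x$p[["allele"]], digits = 3),
              format.pval(x$p[["treatment"]], digits = 3),
              format.pval(x$p[["interaction"]], digits = 3)))
  invisible(x)
}

#' @export
coef.ase_fit <- function(object, ...) stats::coef(object$model)
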