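# Candidate-gene association of log-normal androstenone: fixed-effects
# linear model ln(androstenone) ~ sire + genotype + hys + bulbo, genotype
# least-squares means back-transformed to medians on the original scale,
# overall genotype F-test, and a Hardy-Weinberg chi-square per SNP.

normalize_genotype <- function(g) {
  a <- strsplit(as.character(g), "")
  vapply(a, function(v) {
    if (length(v) != 2L || !all(v %in% c("A", "C", "G", "T"))) {
      stop("genotype must be two bases from {A,C,G,T}, got: ",
           paste(v, collapse = ""), call. = FALSE)
    }
    paste0(sort(v), collapse = "")
  }, "")
}

#' Association of a SNP with log-normal androstenone
#'
#' Ordinary least-squares fit of `ln(androstenone) ~ sire + genotype + hys
#' + bulbo` for one SNP: sire as fixed effect (guarding against
#' confounding of genotype with sire selection), the combined
#' herd-year-season batch factor `hys`, and bulbo-urethral gland length as
#' a continuous covariate adjusting for sexual maturity. Genotype
#' least-squares means are estimated on the log scale and back-transformed
#' with [backtransform_lsmeans()]; the genotype effect is judged by its
#' overall F-test; Hardy-Weinberg equilibrium is checked by [hwe_chisq()].
#'
#' @param phenotypes Data frame with columns `sample_id`, `sire`, `hys`,
#'   `bulbo_cm`, `androstenone` (> 0, ug/g) and optionally `breed`.
#' @param genotypes Data frame with columns `sample_id`, `snp_id`,
#'   `genotype` (two-character base string, order-insensitive).
#' @param snp SNP to analyse (default: the single SNP present).
#' @param breed Optional breed to subset to.
#' @return Object of class `assoc_fit` with components `lsmeans` (per
#'   genotype: n, log-scale LS mean and SE, back-transformed median and
#'   delta-method SE), `f_test` (overall genotype F statistic, df and p),
#'   `hwe` (chi-square, df, p), the underlying `lm` and the data used.
#' @examples
#' ph <- simulate_phenotypes(phenotype_scenario(n_animals = 300, seed = 2))
#' fit <- assoc_fit(ph, ph[c("sample_id", "genotype")] |>
#'                    transform(snp_id = "SNP1"))
#' fit
#' @export
assoc_fit <- function(phenotypes, genotypes, snp = NULL, breed = NULL) {
  stopifnot(is.data.frame(phenotypes), is.data.frame(genotypes))
  need <- c("sample_id", "sire", "hys", "bulbo_cm", "androstenone")
  miss <- setdiff(need, names(phenotypes))
  if (length(miss)) stop("phenotype table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(c("sample_id", "genotype") %in% names(genotypes))) {
    stop("genotype table needs `sample_id` and `genotype`", call. = FALSE)
  }
  if (!is.null(breed)) {
    if (!"breed" %in% names(phenotypes)) stop("no breed column", call. = FALSE)
    phenotypes <- phenotypes[phenotypes$breed == breed, , drop = FALSE]
  }
  if ("snp_id" %in% names(genotypes)) {
    if (is.null(snp)) {
      snp <- unique(genotypes$snp_id)
      if (length(snp) > 1L) {
        stop("several SNPs present; pick one with `snp =`", call. = FALSE)
      }
    }
    genotypes <- genotypes[genotypes$snp_id == snp, , drop = FALSE]
  } else if (is.null(snp)) snp <- "SNP"

  phenotypes <- phenotypes[setdiff(names(phenotypes), "genotype")]
  d <- merge(phenotypes, genotypes[c("sample_id", "genotype")],
             by = "sample_id")
  if (!nrow(d)) stop("no animals with both phenotype and genotype",
                     call. = FALSE)
  if (any(d$androstenone <= 0)) {
    stop("androstenone must be positive for the log transform", call. = FALSE)
  }
  d$genotype <- factor(normalize_genotype(d$genotype))
  if (nlevels(droplevels(d$genotype)) < 2L) {
    stop(sprintf("SNP %s: only one genotype class observed; effect not estimable",
                 snp), call. = FALSE)
  }
  d$genotype <- droplevels(d$genotype)
  d$sire <- factor(d$sire)
  d$hys <- factor(d$hys)
  d$lny <- log(d$androstenone)

  terms <- c(if (nlevels(d$sire) > 1L) "sire", "genotype",
             if (nlevels(d$hys) > 1L) "hys",
             if (stats::var(d$bulbo_cm) > 0) "bulbo_cm")
  fit <- stats::lm(stats::reformulate(terms, response = "lny"), data = d)

  alias <- stats::alias(fit)$Complete
  if (!is.null(alias) && any(grepl("genotype", rownames(alias)))) {
    stop(sprintf(
      "SNP %s: genotype aliased with other design terms (%s); model not estimable",
      snp, paste(unique(rownames(alias)), collapse = ", ")), call. = FALSE)
  }

  em <- emmeans::emmeans(fit, "genotype")
  es <- as.data.frame(em)
  lsm <- data.frame(
    genotype = as.character(es$genotype),
    n = as.integer(table(d$genotype)[as.character(es$genotype)]),
    lsmean_log = es$emmean, se_log = es$SE
  )
  bt <- backtransform_lsmeans(lsm$lsmean_log, lsm$se_log)
  lsm$median <- bt$median
  lsm$se <- bt$se

  dr <- stats::drop1(fit, scope = ~genotype, test = "F")
  f_test <- list(F = dr["genotype", "F value"],
                 df = c(dr["genotype", "Df"], stats::df.residual(fit)),
                 p = dr["genotype", "Pr(>F)"])

  hwe <- hwe_chisq(genotype_counts(d$genotype))

  structure(
    list(snp = snp, breed = breed, lsmeans = lsm, f_test = f_test,
         hwe = hwe, model = fit, data = d, n = nrow(d)),
    class = "assoc_fit"
  )
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("Association: %s%s (n = %d animals)\n", x$snp,
              if (!is.null(x$breed)) paste0(", ", x$breed) else "", x$n))
  tab <- x$lsmeans
  tab$median <- round(tab$median, 2)
  tab$se <- round(tab$se, 2)
  tab$lsmean_log <- round(tab$lsmean_log, 3)
  tab$se_log <- round(tab$se_log, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Overall genotype F(%d, %d) = %.3f, p = %s\n",
              x$f_test$df[1L], x$f_test$df[2L], x$f_test$F,
              format.pval(x$f_test$p, digits = 3)))
  cat(sprintf("Hardy-Weinberg chi-square = %s (df %s), p = %s\n",
              if (is.na(x$hwe$chisq)) "NA" else sprintf("%.3f", x$hwe$chisq),
              x$hwe$df,
              if (is.na(x$hwe$p)) "NA" else format.pval(x$hwe$p, digits = 3)))
  invisible(x)
}

#' @export
summary.assoc_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying linear model:\n")
  print(summary(object$model))
  invisible(object)
}

#' @export
coef.assoc_fit <- function(object, ...) stats::coef(object$model)

#' Back-transform log-scale LS means to medians
#'
#' `exp()` of a least-squares mean of ln(androstenone), with no
#' lognormal-mean (smearing) correction: for a symmetric distribution on
#' the log scale this estimates the median of the skewed original
#' distribution. The SE is carried over by the delta method,
#' `exp(lsmean) * se_log`.
#'
#' @param lsmean_log LS means on the natural-log scale.
#' @param se_log Their standard errors (optional).
#' @return List with `median` and `se` (NA when `se_log` missing).
#' @export
backtransform_lsmeans <- function(lsmean_log, se_log = NULL) {
  stopifnot(is.numeric(lsmean_log), all(is.finite(lsmean_log)))
  m <- exp(lsmean_log)
  se <- if (is.null(se_log)) rep(NA_real_, length(m)) else m * se_log
  list(median = m, se = se)
}

# Ordered genotype counts (hom1, het, hom2) from a genotype vector.
genotype_counts <- function(g) {
  g <- normalize_genotype(g)
  alleles <- sort(unique(unlist(strsplit(g, ""))))
  if (length(alleles) == 1L) {
    return(stats::setNames(c(length(g), 0L, 0L),
                           c(paste0(alleles, alleles), "het", "hom2")))
  }
  if (length(alleles) > 2L) stop("more than two alleles: not biallelic",
                                 call. = FALSE)
  classes <- c(paste0(alleles[1L], alleles[1L]),
               paste0(alleles[1L], alleles[2L]),
               paste0(alleles[2L], alleles[2L]))
  stats::setNames(as.integer(table(factor(g, levels = classes))), classes)
}

#' Hardy-Weinberg chi-square test
#'
#' Compares observed biallelic genotype counts (hom1, het, hom2) with the
#' Hardy-Weinberg expectations p^2, 2pq, q^2 computed from the observed
#' allele frequencies; the statistic is the usual sum of
#' (obs - exp)^2 / exp with 1 degree of freedom (two free genotype classes
#' minus one estimated allele frequency).
#'
#' @param counts Numeric vector of three genotype counts, in the order
#'   homozygote-1, heterozygote, homozygote-2; or a character vector of
#'   genotypes (then counted via the internal tabulation).
#' @return List with `chisq`, `df` (1), `p`, `observed` and `expected`.
#'   A monomorphic SNP gives `chisq = NA` with `reason = "monomorphic"`.
#' @examples
#' hwe_chisq(c(25, 50, 25)) # exact HWE: chi-square 0
#' hwe_chisq(c(902, 51, 0))
#' @export
hwe_chisq <- function(counts) {
  if (is.character(counts) || is.factor(counts)) {
    counts <- genotype_counts(counts)
  }
  if (length(counts) != 3L || any(counts < 0)) {
    stop("`counts` must be three non-negative genotype counts", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("no genotypes to test", call. = FALSE)
  p <- (2 * counts[[1L]] + counts[[2L]]) / (2 * n)
  if (p == 0 || p == 1) {
    return(list(chisq = NA_real_, df = 1L, p = NA_real_,
                observed = counts, expected = NULL,
                reason = "monomorphic"))
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((counts - expected)^2 / expected)
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
       observed = counts, expected = expected)
}

#' Genotype frequency report
#'
#' Per-SNP (and per-breed, when present) genotype percentages, the summary
#' used to report the allele composition of the assayed population.
#'
#' @param genotypes Data frame with columns `sample_id`, `snp_id`,
#'   `genotype`, optionally `breed`.
#' @param digits Rounding for the percentage column (default 0, the
#'   printed-table convention).
#' @return Data frame with columns `snp_id` (, `breed`), `genotype`,
#'   `n`, `percent`. Empty input gives an empty frame.
#' @export
genotype_frequency_report <- function(genotypes, digits = 0) {
  if (!is.data.frame(genotypes) || !nrow(genotypes)) {
    return(data.frame(snp_id = character(0), genotype = character(0),
                      n = integer(0), percent = numeric(0)))
  }
  stopifnot(all(c("snp_id", "genotype") %in% names(genotypes)))
  genotypes$genotype <- normalize_genotype(genotypes$genotype)
  keys <- intersect(c("snp_id", "breed"), names(genotypes))
  split_by <- interaction(genotypes[keys], drop = TRUE)
  parts <- lapply(split(genotypes, split_by), function(g) {
    cnt <- genotype_counts(g$genotype)
    out <- data.frame(genotype = names(cnt), n = as.integer(cnt),
                      percent = round(100 * as.integer(cnt) / sum(cnt),
                                      digits))
    for (k in rev(keys)) out <- cbind(stats::setNames(list(g[[k]][1L]), k),
                                      out)
    out
  })
  out <- do.call(rbind, parts)
  ord <- do.call(order, out[keys])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
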