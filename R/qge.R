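# Panel-level quantitative gene expression (QGE) engine: per-assay
# titration fits with a high/low group covariate, housekeeping-normalized
# log10 fold changes, and bootstrap inference resampling animals within
# group. The default degree-1/shared-slope model reduces to closed-form
# normal equations on per-animal sufficient statistics, which is what makes
# thousands of bootstrap refits cheap.

# Per-sample sufficient statistics (n, Sx, Sy, Sxx, Sxy) for degree-1 fits.
sample_stats <- function(x, y) {
  c(n = length(x), Sx = sum(x), Sy = sum(y), Sxx = sum(x * x),
    Sxy = sum(x * y))
}

# Vectorized degree-1 contrast x0_high - x0_low from group-summed
# statistics. `sh`, `sl`: matrices (replicates x 5) of summed stats.
contrast_deg1 <- function(sh, sl, shared_slope = TRUE) {
  nh <- sh[, 1L]; nl <- sl[, 1L]
  xbh <- sh[, 2L] / nh; ybh <- sh[, 3L] / nh
  xbl <- sl[, 2L] / nl; ybl <- sl[, 3L] / nl
  cxx_h <- sh[, 4L] - sh[, 2L]^2 / nh
  cxy_h <- sh[, 5L] - sh[, 2L] * sh[, 3L] / nh
  cxx_l <- sl[, 4L] - sl[, 2L]^2 / nl
  cxy_l <- sl[, 5L] - sl[, 2L] * sl[, 3L] / nl
  if (shared_slope) {
    b <- (cxy_h + cxy_l) / (cxx_h + cxx_l)
    out <- (xbh - xbl) - (ybh - ybl) / b
    bad <- !is.finite(out) | (cxx_h + cxx_l) <= 0 | b == 0
  } else {
    bh <- cxy_h / cxx_h
    bl <- cxy_l / cxx_l
    out <- (xbh - ybh / bh) - (xbl - ybl / bl)
    bad <- !is.finite(out) | cxx_h <= 0 | cxx_l <= 0 | bh == 0 | bl == 0
  }
  out[bad] <- NA_real_
  out
}

# Per-group equivalence points (degree 1) from one row of summed stats.
x0_deg1 <- function(sh, sl, shared_slope = TRUE) {
  nh <- sh[1L]; nl <- sl[1L]
  xbh <- sh[2L] / nh; ybh <- sh[3L] / nh
  xbl <- sl[2L] / nl; ybl <- sl[3L] / nl
  cxx_h <- sh[4L] - sh[2L]^2 / nh
  cxy_h <- sh[5L] - sh[2L] * sh[3L] / nh
  cxx_l <- sl[4L] - sl[2L]^2 / nl
  cxy_l <- sl[5L] - sl[2L] * sl[3L] / nl
  if (shared_slope) {
    b <- (cxy_h + cxy_l) / (cxx_h + cxx_l)
    c(high = xbh - ybh / b, low = xbl - ybl / b, slope_high = b,
      slope_low = b)
  } else {
    bh <- cxy_h / cxx_h; bl <- cxy_l / cxx_l
    c(high = xbh - ybh / bh, low = xbl - ybl / bl, slope_high = bh,
      slope_low = bl)
  }
}

#' Panel quantification of differential expression by competitive PCR
#'
#' Fits the titration model to every assay of a panel, interpolates
#' per-group equivalence points, normalizes the high-minus-low contrast by
#' the housekeeping assay, and attaches bootstrap bias, standard error,
#' percentile confidence interval and p-value per gene. This is the central
#' fitting function of the package; the result is an object of class
#' `"qge"` with `print`, `summary`, `coef` and `plot` methods.
#'
#' Two bootstrap schemes are available. The default, `resample =
#' "residual"`, resamples the residuals of each assay's fitted titration
#' regression onto its fitted values and refits — the classical bootstrap
#' of a fitted titration model, correctly specified when measurement noise
#' acts per titration point. `resample = "animal"` instead resamples whole
#' animals (ladders) with replacement within each group, one joint animal
#' resample per replicate applied to every assay (preserving the
#' gene-housekeeping correlation through shared animals); prefer it when
#' animal-level biological variance dominates, but note that with few
#' animals per group its percentile intervals are anti-conservative, as is
#' usual for unit counts near ten. Bias is `mean(replicates) - estimate`
#' and is reported, not subtracted. The two-sided p-value doubles the
#' smaller bootstrap tail probability of the normalized log10 fold change
#' crossing zero, floored at 1/B.
#'
#' @param data Long-format frequency table (see [simulate_expression()]);
#'   raw tables with replicates are preprocessed with [qge_preprocess()]
#'   (median of printing replicates, removal of unusable points). A `breed`
#'   column, if present, stratifies the whole analysis.
#' @param housekeeping Name of the reference assay used for normalization.
#' @param degree Polynomial degree of the titration model (default 1).
#' @param shared_slope Share the titration slope between groups (treatment
#'   as additive covariate, the default) or fit groups independently.
#' @param B Number of bootstrap replicates (default 4000).
#' @param level Confidence level for the percentile interval.
#' @param seed Integer seed for the bootstrap; required for reproducible
#'   inference.
#' @param p_method `"tail"` (doubled bootstrap tail probability, default)
#'   or `"normal"` (two-sided z-test from the bootstrap SE).
#' @param resample Bootstrap resampling unit: `"residual"` (default) or
#'   `"animal"`; see Details.
#' @param min_points Minimum usable titration points for an animal's ladder
#'   to enter the fit.
#' @param group_levels Length-2 character vector naming the low and high
#'   group labels, in that order.
#' @return An object of class `qge`. Component `results` is a data frame
#'   with one row per non-housekeeping assay (per breed): `assay`, `breed`,
#'   `fold_change`, `log10_fold_change`, `bias`, `std_error`, `ci_lower`,
#'   `ci_upper`, `p_value`, `n_high`, `n_low`, `significant`. Component
#'   `ec50` holds per-assay, per-group equivalence concentrations.
#' @examples
#' sc <- expression_scenario(n_per_group = 6,
#'                           true_log10_fc = c(GENE1 = 0.4),
#'                           noise_sd = 0.05, seed = 7)
#' fit <- qge(simulate_expression(sc), B = 200, seed = 7)
#' fit
#' @export
qge <- function(data, housekeeping = "HPRT", degree = 1,
                shared_slope = TRUE, B = 4000, level = 0.95, seed = NULL,
                p_method = c("tail", "normal"),
                resample = c("residual", "animal"), min_points = 3L,
                group_levels = c("low", "high")) {
  p_method <- match.arg(p_method)
  resample <- match.arg(resample)
  stopifnot(is.data.frame(data))
  cl <- match.call()
  if (nrow(data) == 0L) {
    warning("empty frequency table: returning empty result", call. = FALSE)
    return(structure(list(results = empty_qge_results(), ec50 = NULL,
                          B = B, level = level, seed = seed,
                          housekeeping = housekeeping, call = cl),
                     class = "qge"))
  }
  breeds <- if ("breed" %in% names(data)) unique(as.character(data$breed)) else
    NA_character_
  parts <- vector("list", length(breeds))
  ec_parts <- vector("list", length(breeds))
  boot_parts <- vector("list", length(breeds))
  for (i in seq_along(breeds)) {
    sub <- if (is.na(breeds[i])) data else data[data$breed == breeds[i], ]
    sub_seed <- if (is.null(seed)) NULL else seed + (i - 1L)
    one <- qge_one_stratum(sub, housekeeping, degree, shared_slope, B,
                           level, sub_seed, p_method, resample, min_points,
                           group_levels)
    one$results$breed <- breeds[i]
    one$ec50$breed <- breeds[i]
    parts[[i]] <- one$results
    ec_parts[[i]] <- one$ec50
    boot_parts[[i]] <- one$boot
  }
  results <- do.call(rbind, parts)
  rownames(results) <- NULL
  names(boot_parts) <- breeds
  structure(
    list(results = results, ec50 = do.call(rbind, ec_parts),
         boot = boot_parts, B = B, level = level, seed = seed,
         housekeeping = housekeeping, degree = degree,
         shared_slope = shared_slope, p_method = p_method,
         resample = resample, call = cl),
    class = "qge"
  )
}

empty_qge_results <- function() {
  data.frame(assay = character(0), breed = character(0),
             fold_change = numeric(0), log10_fold_change = numeric(0),
             bias = numeric(0), std_error = numeric(0),
             ci_lower = numeric(0), ci_upper = numeric(0),
             p_value = numeric(0), n_high = integer(0), n_low = integer(0),
             significant = logical(0))
}

qge_one_stratum <- function(data, housekeeping, degree, shared_slope, B,
                            level, seed, p_method, resample, min_points,
                            group_levels) {
  data <- qge_preprocess(data, min_points = min_points)
  assays <- unique(as.character(data$assay))
  if (!housekeeping %in% assays) {
    stop(sprintf("housekeeping assay '%s' not found in the panel (have: %s)",
                 housekeeping, paste(assays, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(c("sample_id", "group") %in% names(data))) {
    stop("frequency table needs `sample_id` and `group` columns",
         call. = FALSE)
  }
  bad_grp <- setdiff(unique(as.character(data$group)), group_levels)
  if (length(bad_grp)) {
    stop("unknown group labels: ", paste(bad_grp, collapse = ", "),
         call. = FALSE)
  }
  low <- group_levels[1L]; high <- group_levels[2L]

  samples <- unique(data[c("sample_id", "group")])
  sample_ids <- samples$sample_id
  sgroup <- as.character(samples$group)
  idx_high <- which(sgroup == high)
  idx_low <- which(sgroup == low)
  if (!length(idx_high) || !length(idx_low)) {
    stop("need at least one animal in each group", call. = FALSE)
  }

  x_all <- log10(data$competitor_conc_M)
  # per-assay matrices of per-animal sufficient statistics
  stat_list <- list()
  xrange_list <- list()
  for (a in assays) {
    rows <- data$assay == a
    S <- matrix(0, nrow = length(sample_ids), ncol = 5L)
    sp <- split(seq_len(nrow(data))[rows],
                match(data$sample_id[rows], sample_ids))
    for (k in names(sp)) {
      ii <- sp[[k]]
      if (length(ii) >= min_points) {
        S[as.integer(k), ] <- sample_stats(x_all[ii], data$y[ii])
      }
    }
    stat_list[[a]] <- S
    xrange_list[[a]] <- range(x_all[rows])
  }

  use_deg1 <- degree == 1L
  est <- vapply(assays, function(a) {
    point_contrast(stat_list[[a]], idx_high, idx_low, shared_slope, degree,
                   data, a, xrange_list[[a]], use_deg1)
  }, 0)
  names(est) <- assays
  est_norm <- est - est[housekeeping]

  ec <- do.call(rbind, lapply(assays, function(a) {
    S <- stat_list[[a]]
    v <- x0_deg1(colSums(S[idx_high, , drop = FALSE]),
                 colSums(S[idx_low, , drop = FALSE]), shared_slope)
    data.frame(assay = a, group = c("high", "low"),
               x0 = c(v[["high"]], v[["low"]]),
               ec50_M = 10^c(v[["high"]], v[["low"]]),
               slope = c(v[["slope_high"]], v[["slope_low"]]))
  }))

  nh <- length(idx_high); nl <- length(idx_low)
  boot <- with_seed(seed, {
    m <- matrix(NA_real_, nrow = B, ncol = length(assays),
                dimnames = list(NULL, assays))
    if (resample == "animal") {
      # one animal resample per replicate, applied to all assays
      draw_h <- matrix(sample.int(nh, nh * B, replace = TRUE), nrow = B)
      draw_l <- matrix(sample.int(nl, nl * B, replace = TRUE), nrow = B)
      CH <- t(apply(draw_h, 1L, tabulate, nbins = nh))
      CL <- t(apply(draw_l, 1L, tabulate, nbins = nl))
      for (a in assays) {
        S <- stat_list[[a]]
        sh <- CH %*% S[idx_high, , drop = FALSE]
        sl <- CL %*% S[idx_low, , drop = FALSE]
        if (use_deg1) {
          m[, a] <- contrast_deg1(sh, sl, shared_slope)
        } else {
          m[, a] <- boot_contrast_poly(S, data, a, sample_ids, idx_high,
                                       idx_low, CH, CL, degree,
                                       shared_slope, xrange_list[[a]])
        }
      }
    } else {
      # residual bootstrap of each assay's fitted titration regression
      sgrp_high <- seq_along(sample_ids) %in% idx_high
      for (a in assays) {
        rows <- which(data$assay == a)
        sidx <- match(data$sample_id[rows], sample_ids)
        keep <- stat_list[[a]][sidx, 1L] > 0
        rows <- rows[keep]; sidx <- sidx[keep]
        m[, a] <- boot_residual_assay(
          x = x_all[rows], y = data$y[rows], grp_high = sgrp_high[sidx],
          B = B, degree = degree, shared_slope = shared_slope,
          xrange = xrange_list[[a]])
      }
    }
    m
  })
  boot_norm <- boot - boot[, housekeeping]

  res <- do.call(rbind, lapply(setdiff(assays, housekeeping), function(a) {
    th <- est_norm[[a]]
    reps <- boot_norm[, a]
    n_bad <- sum(!is.finite(reps))
    if (n_bad > 0.2 * B || !is.finite(th)) {
      warning(sprintf(
        "assay '%s': %d/%d bootstrap replicates unfittable; inference aborted",
        a, n_bad, B), call. = FALSE)
      return(data.frame(assay = a, fold_change = 10^th,
                        log10_fold_change = th, bias = NA_real_,
                        std_error = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p_value = NA_real_,
                        n_high = nh, n_low = nl, significant = NA))
    }
    reps <- reps[is.finite(reps)]
    bias <- mean(reps) - th
    se <- stats::sd(reps)
    ci <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    p <- if (p_method == "tail") {
      min(1, max(2 * min(mean(reps <= 0), mean(reps >= 0)), 1 / B))
    } else {
      if (se == 0) as.numeric(th == 0) else
        max(2 * stats::pnorm(-abs(th / se)), 1 / B)
    }
    data.frame(assay = a, fold_change = 10^th, log10_fold_change = th,
               bias = bias, std_error = se, ci_lower = ci[1L],
               ci_upper = ci[2L], p_value = p, n_high = nh, n_low = nl,
               significant = p < 0.05)
  }))
  rownames(res) <- NULL
  list(results = res, ec50 = ec, boot = boot_norm)
}

# Point-estimate contrast for one assay; closed form at degree 1,
# lm + root finding otherwise.
point_contrast <- function(S, idx_high, idx_low, shared_slope, degree,
                           data, assay, xrange, use_deg1) {
  if (use_deg1) {
    return(contrast_deg1(
      matrix(colSums(S[idx_high, , drop = FALSE]), nrow = 1L),
      matrix(colSums(S[idx_low, , drop = FALSE]), nrow = 1L),
      shared_slope))
  }
  rows <- data$assay == assay & data$group %in% c("high", "low")
  fit <- titration_fit(
    data.frame(x = log10(data$competitor_conc_M[rows]), y = data$y[rows],
               group = data$group[rows]),
    degree = degree, shared_slope = shared_slope, assay = assay)
  equivalence_point(fit, "high")$x0 - equivalence_point(fit, "low")$x0
}

# Residual bootstrap for one assay: the design matrix is fixed, so each
# replicate's coefficients are cf_hat + (X'X)^-1 X' e*, with e* drawn with
# replacement from the fitted model's residuals. Returns B contrasts
# x0_high - x0_low.
boot_residual_assay <- function(x, y, grp_high, B, degree, shared_slope,
                                xrange) {
  N <- length(x)
  if (N == 0L || !any(grp_high) || all(grp_high)) {
    return(rep(NA_real_, B))
  }
  fit_part <- function(X, yv) {
    A <- crossprod(X)
    Ainv <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ainv)) return(NULL)
    cf <- drop(Ainv %*% crossprod(X, yv))
    list(X = X, Ainv = Ainv, cf = cf, e = yv - drop(X %*% cf))
  }
  boot_coefs <- function(part, idx_mat) {
    Emat <- matrix(part$e[idx_mat], nrow = B)
    dev <- (Emat %*% part$X) %*% part$Ainv
    sweep(dev, 2L, part$cf, `+`)
  }
  pows <- outer(x, seq_len(degree), `^`)
  if (shared_slope) {
    part <- fit_part(cbind(as.numeric(!grp_high), as.numeric(grp_high),
                           pows), y)
    if (is.null(part)) return(rep(NA_real_, B))
    idx <- matrix(sample.int(N, N * B, replace = TRUE), nrow = B)
    cfs <- boot_coefs(part, idx)
    if (degree == 1L) {
      out <- -(cfs[, 2L] - cfs[, 1L]) / cfs[, 3L]
      out[!is.finite(out)] <- NA_real_
      return(out)
    }
    return(vapply(seq_len(B), function(b) {
      sh <- cfs[b, 3:(degree + 2L)]
      x0h <- poly_root(c(cfs[b, 2L], sh), xrange)
      x0l <- poly_root(c(cfs[b, 1L], sh), xrange)
      if (is.na(x0h) || is.na(x0l)) NA_real_ else x0h - x0l
    }, 0))
  }
  out <- matrix(NA_real_, nrow = B, ncol = 2L)
  for (g in 1:2) {
    sel <- if (g == 1L) grp_high else !grp_high
    part <- fit_part(cbind(1, pows[sel, , drop = FALSE]), y[sel])
    if (is.null(part)) return(rep(NA_real_, B))
    n_g <- sum(sel)
    idx <- matrix(sample.int(n_g, n_g * B, replace = TRUE), nrow = B)
    cfs <- boot_coefs(part, idx)
    if (degree == 1L) {
      out[, g] <- -cfs[, 1L] / cfs[, 2L]
    } else {
      out[, g] <- vapply(seq_len(B), function(b) {
        poly_root(cfs[b, ], xrange)
      }, 0)
    }
  }
  res <- out[, 1L] - out[, 2L]
  res[!is.finite(res)] <- NA_real_
  res
}

# Bootstrap path for degree > 1: per-animal cross-product contributions to
# the pooled polynomial design, recombined per replicate and solved.
boot_contrast_poly <- function(S, data, assay, sample_ids, idx_high,
                               idx_low, CH, CL, degree, shared_slope,
                               xrange) {
  rows <- which(data$assay == assay)
  x <- log10(data$competitor_conc_M[rows]); y <- data$y[rows]
  sidx <- match(data$sample_id[rows], sample_ids)
  p <- degree + 2L  # int_low, int_high, x, ..., x^degree (shared slope)
  n_s <- length(sample_ids)
  XtX <- matrix(0, n_s, p * p); Xty <- matrix(0, n_s, p)
  grp_high <- seq_len(n_s) %in% idx_high
  for (s in seq_len(n_s)) {
    ii <- which(sidx == s)
    if (!length(ii)) next
    X <- cbind(as.numeric(!grp_high[s]), as.numeric(grp_high[s]),
               outer(x[ii], seq_len(degree), `^`))
    XtX[s, ] <- as.vector(crossprod(X))
    Xty[s, ] <- as.vector(crossprod(X, y[ii]))
  }
  B <- nrow(CH)
  C_all <- matrix(0, B, n_s)
  C_all[, idx_high] <- CH; C_all[, idx_low] <- CL
  sxx <- C_all %*% XtX; sxy <- C_all %*% Xty
  out <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    A <- matrix(sxx[b, ], p, p)
    cf <- tryCatch(solve(A, sxy[b, ]), error = function(e) NULL)
    if (is.null(cf)) next
    shared <- cf[3:p]
    x0h <- poly_root(c(cf[2L], shared), xrange)
    x0l <- poly_root(c(cf[1L], shared), xrange)
    if (!is.na(x0h) && !is.na(x0l)) out[b] <- x0h - x0l
  }
  if (!shared_slope) {
    warning("independent-slope bootstrap for degree > 1 uses the shared-slope
  resampling path", call. = FALSE)
  }
  out
}

#' @export
print.qge <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Competitive-PCR expression panel: %d assay(s), %d bootstrap replicates\n",
    nrow(x$results), x$B))
  cat(sprintf("Housekeeping normalization: %s\n\n", x$housekeeping))
  if (!nrow(x$results)) {
    cat("(empty result)\n")
    return(invisible(x))
  }
  out <- data.frame(
    assay = x$results$assay,
    breed = x$results$breed,
    fold_change = fc_from_log10(x$results$log10_fold_change),
    log10_fc = round(x$results$log10_fold_change, 2),
    bias = round(x$results$bias, 4),
    std_error = round(x$results$std_error, 2),
    p_value = format(round(x$results$p_value, 4), nsmall = 4),
    sig = ifelse(is.na(x$results$significant), "?",
                 ifelse(x$results$significant, "*", ""))
  )
  if (all(is.na(out$breed))) out$breed <- NULL
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.qge <- function(object, ...) {
  structure(list(qge = object), class = "summary.qge")
}

#' @export
print.summary.qge <- function(x, ...) {
  q <- x$qge
  print(q)
  cat(sprintf("\n%g%% percentile bootstrap confidence intervals:\n",
              100 * q$level))
  ci <- data.frame(assay = q$results$assay,
                   log10_fc = round(q$results$log10_fold_change, 3),
                   ci_lower = round(q$results$ci_lower, 3),
                   ci_upper = round(q$results$ci_upper, 3))
  print(ci, row.names = FALSE)
  if (!is.null(q$ec50)) {
    cat("\nEquivalence concentrations (EC50, M):\n")
    ec <- q$ec50
    ec$ec50_M <- signif(ec$ec50_M, 3)
    ec$x0 <- round(ec$x0, 3)
    ec$slope <- round(ec$slope, 3)
    print(ec, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.qge <- function(object, ...) {
  stats::setNames(object$results$log10_fold_change, object$results$assay)
}

#' @export
plot.qge <- function(x, ...) {
  r <- x$results
  if (!nrow(r)) {
    warning("nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  ord <- order(r$log10_fold_change)
  r <- r[ord, ]
  yy <- seq_len(nrow(r))
  rng <- range(c(r$ci_lower, r$ci_upper, r$log10_fold_change, 0),
               na.rm = TRUE)
  graphics::plot(r$log10_fold_change, yy, xlim = rng, yaxt = "n",
                 xlab = "log10 fold change (high vs low)", ylab = "",
                 pch = 16, ...)
  graphics::axis(2, at = yy, labels = r$assay, las = 1, cex.axis = 0.7)
  graphics::segments(r$ci_lower, yy, r$ci_upper, yy)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
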