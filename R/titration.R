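# Titration-curve model: least-squares polynomial fit of the logit
# frequency y = log10(f/(1-f)) on x = log10(competitor concentration),
# interpolation of the equivalence point y(x0) = 0, and fold changes as
# differences of equivalence points on the log10 scale.

#' Fit a titration line for one assay
#'
#' Least-squares polynomial regression of the logit-transformed frequency on
#' the log10 competitor concentration, pooling all titration points of all
#' samples of one assay. With a `group` column the default model gives each
#' group its own intercept and a shared polynomial (the treatment enters as
#' an additive covariate); `shared_slope = FALSE` fits the groups
#' independently.
#'
#' Under ideal competitive co-amplification the slope is -1: one decade
#' less competitor raises log10(cDNA/competitor) by one decade. The fitted
#' line's zero crossing is the equivalence concentration (EC50).
#'
#' @param data Data frame with columns `competitor_conc_M` (or `x`, already
#'   log10) and `y` (logit frequency) or `frequency`; optionally `group`.
#' @param degree Polynomial degree (>= 1); default 1, the standard linear
#'   titration model.
#' @param shared_slope Share polynomial coefficients across groups
#'   (group-specific intercepts only)?
#' @param assay Assay label used in messages.
#' @return An object of class `titration_fit` with components `coef` (list
#'   of per-group polynomial coefficients, constant term first), `sigma`
#'   (residual SD), `n`, `degree`, `xrange`, `groups` and the underlying
#'   `lm` fit(s).
#' @examples
#' d <- data.frame(x = c(-17, -16, -15), y = c(1, 0, -1))
#' fit <- titration_fit(d)
#' equivalence_point(fit)
#' @export
titration_fit <- function(data, degree = 1, shared_slope = TRUE,
                          assay = "assay") {
  stopifnot(is.data.frame(data))
  degree <- as.integer(degree)
  if (degree < 1L) stop("`degree` must be >= 1", call. = FALSE)
  x <- if ("x" %in% names(data)) data$x else {
    if (!"competitor_conc_M" %in% names(data)) {
      stop("need `x` or `competitor_conc_M`", call. = FALSE)
    }
    log10(data$competitor_conc_M)
  }
  y <- if ("y" %in% names(data)) data$y else {
    if (!"frequency" %in% names(data)) stop("need `y` or `frequency`",
                                            call. = FALSE)
    logit10(data$frequency)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  grp <- if ("group" %in% names(data)) as.character(data$group)[ok] else
    rep("all", length(x))
  groups <- sort(unique(grp))

  for (g in groups) {
    if (length(unique(x[grp == g])) < degree + 1L) {
      stop(sprintf("singular titration design for assay '%s' (group '%s'):
  need > degree distinct concentrations", assay, g), call. = FALSE)
    }
  }
  if (length(x) < degree + length(groups) + 1L) {
    stop(sprintf("too few points to fit assay '%s'", assay), call. = FALSE)
  }

  df <- data.frame(y = y, x = x, group = factor(grp, levels = groups))
  pow <- paste0("I(x^", seq_len(degree), ")", collapse = " + ")
  if (length(groups) > 1L && shared_slope) {
    fit <- stats::lm(stats::as.formula(paste("y ~ 0 + group +", pow)),
                     data = df)
    cf <- stats::coef(fit)
    shared <- cf[-seq_along(groups)]
    coefs <- lapply(seq_along(groups),
                    function(i) unname(c(cf[i], shared)))
    names(coefs) <- groups
    fits <- list(fit)
    sigma <- stats::sigma(fit)
    n <- nrow(df)
  } else if (length(groups) > 1L) {
    fits <- lapply(groups, function(g) {
      stats::lm(stats::as.formula(paste("y ~", pow)), data = df[df$group == g, ])
    })
    names(fits) <- groups
    coefs <- lapply(fits, function(f) unname(stats::coef(f)))
    sigma <- sqrt(stats::weighted.mean(
      vapply(fits, function(f) stats::sigma(f)^2, 0),
      vapply(fits, function(f) max(stats::df.residual(f), 0), 0)))
    n <- nrow(df)
  } else {
    fit <- stats::lm(stats::as.formula(paste("y ~", pow)), data = df)
    coefs <- list(all = unname(stats::coef(fit)))
    fits <- list(fit)
    sigma <- stats::sigma(fit)
    n <- nrow(df)
  }

  structure(
    list(assay = assay, coef = coefs, degree = degree,
         shared_slope = shared_slope, groups = groups, sigma = sigma,
         n = n, xrange = range(x), fits = fits, data = df),
    class = "titration_fit"
  )
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("Titration fit: %s (degree %d, %d points, residual SD %.4g)\n",
              x$assay, x$degree, x$n, x$sigma))
  for (g in x$groups) {
    ec <- equivalence_point(x, group = g)
    cat(sprintf("  %-6s intercept %8.4f  slope %8.4f  EC50 %.3g M (x0 = %.4f)\n",
                g, x$coef[[g]][1L], x$coef[[g]][2L], ec$conc, ec$x0))
  }
  invisible(x)
}

#' @export
coef.titration_fit <- function(object, ...) object$coef

#' @export
predict.titration_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  x <- if ("x" %in% names(newdata)) newdata$x else
    log10(newdata$competitor_conc_M)
  grp <- if ("group" %in% names(newdata)) as.character(newdata$group) else
    rep(object$groups[1L], length(x))
  vapply(seq_along(x), function(i) {
    cf <- object$coef[[grp[i]]]
    sum(cf * x[i]^(seq_along(cf) - 1L))
  }, 0)
}

#' @export
residuals.titration_fit <- function(object, ...) {
  object$data$y - predict(object, object$data)
}

#' @export
plot.titration_fit <- function(x, ...) {
  df <- x$data
  cols <- stats::setNames(seq_along(x$groups) + 1L, x$groups)
  graphics::plot(df$x, df$y, col = cols[as.character(df$group)], pch = 16,
                 xlab = "log10 competitor concentration (M)",
                 ylab = "logit10 frequency", main = x$assay, ...)
  graphics::abline(h = 0, lty = 3)
  xs <- seq(x$xrange[1L], x$xrange[2L], length.out = 100)
  for (g in x$groups) {
    cf <- x$coef[[g]]
    graphics::lines(xs, vapply(xs, function(v)
      sum(cf * v^(seq_along(cf) - 1L)), 0), col = cols[g])
    ec <- equivalence_point(x, group = g)
    graphics::abline(v = ec$x0, col = cols[g], lty = 2)
  }
  if (length(x$groups) > 1L) {
    graphics::legend("topright", legend = x$groups, col = cols, lty = 1,
                     pch = 16, bty = "n")
  }
  invisible(x)
}

# Real root of a fitted polynomial (constant term first) nearest to /
# inside the observed x range; NA if no real root exists.
poly_root <- function(coefs, xrange) {
  coefs <- coefs[seq_len(max(which(coefs != 0 | seq_along(coefs) <= 2)))]
  if (length(coefs) == 2L) {
    if (coefs[2L] == 0) return(NA_real_)
    return(-coefs[1L] / coefs[2L])
  }
  rts <- polyroot(coefs)
  re <- Re(rts)[abs(Im(rts)) < 1e-8 * (1 + abs(Re(rts)))]
  if (!length(re)) return(NA_real_)
  inside <- re[re >= xrange[1L] & re <= xrange[2L]]
  if (length(inside)) {
    return(inside[which.min(abs(inside - mean(xrange)))])
  }
  re[which.min(pmin(abs(re - xrange[1L]), abs(re - xrange[2L])))]
}

#' Interpolate the equivalence (EC50) concentration
#'
#' Solves the fitted titration curve for y(x0) = 0, the log10 competitor
#' concentration at which cDNA and competitor amplify equally (frequency
#' 0.5). For a degree-1 fit this is `-intercept/slope` in closed form; for
#' higher degrees the real root inside the observed concentration range is
#' taken, falling back (with a warning) to the nearest real root outside
#' it.
#'
#' @param fit A [titration_fit()].
#' @param group Which group's curve to solve (default the first).
#' @return An object of class `equivalence_point`: list with `assay`,
#'   `group`, `x0` (log10 M), `conc` (= 10^x0, M) and `extrapolated`
#'   (TRUE when x0 lies outside the observed ladder range).
#' @export
equivalence_point <- function(fit, group = fit$groups[1L]) {
  stopifnot(inherits(fit, "titration_fit"))
  if (!group %in% fit$groups) stop("unknown group: ", group, call. = FALSE)
  x0 <- poly_root(fit$coef[[group]], fit$xrange)
  if (is.na(x0)) {
    stop(sprintf("no real equivalence point for assay '%s', group '%s'",
                 fit$assay, group), call. = FALSE)
  }
  extrap <- x0 < fit$xrange[1L] || x0 > fit$xrange[2L]
  if (extrap && fit$degree > 1L) {
    warning(sprintf(
      "equivalence point for '%s' (%s) extrapolated beyond the ladder",
      fit$assay, group), call. = FALSE)
  }
  structure(list(assay = fit$assay, group = group, x0 = x0, conc = 10^x0,
                 extrapolated = extrap),
            class = "equivalence_point")
}

#' @export
print.equivalence_point <- function(x, ...) {
  cat(sprintf("Equivalence point [%s, %s]: EC50 = %.4g M (x0 = %.4f%s)\n",
              x$assay, x$group, x$conc, x$x0,
              if (x$extrapolated) ", extrapolated" else ""))
  invisible(x)
}

as_x0 <- function(p) {
  if (inherits(p, "equivalence_point")) p$x0 else as.numeric(p)
}

#' Housekeeping-normalized log10 fold change
#'
#' The fold change between the high and low groups is the difference of
#' their equivalence points on the log10-concentration scale, minus the
#' same difference for the housekeeping assay (which removes sample-loading
#' differences): `log10FC = (x0_high - x0_low) - (x0_hk_high - x0_hk_low)`,
#' and `FC = 10^log10FC`. A larger equivalence concentration means more
#' competitor is needed to balance the cDNA, i.e. more transcript.
#'
#' @param high,low Equivalence points (or bare x0 values, log10 M) of the
#'   target assay in the high and low group.
#' @param hk_high,hk_low Equivalence points of the housekeeping assay. If
#'   omitted (`NULL`), the result is unnormalized and flagged as such.
#' @return List with `log10_fc`, `fold_change` (= 10^log10_fc) and
#'   `normalized` (logical).
#' @export
log_fold_change <- function(high, low, hk_high = NULL, hk_low = NULL) {
  l <- as_x0(high) - as_x0(low)
  normalized <- !is.null(hk_high) || !is.null(hk_low)
  if (normalized) {
    if (is.null(hk_high) || is.null(hk_low)) {
      stop("housekeeping equivalence points must be given for both groups",
           call. = FALSE)
    }
    l <- l - (as_x0(hk_high) - as_x0(hk_low))
  } else {
    warning("no housekeeping assay supplied: fold change is unnormalized",
            call. = FALSE)
  }
  list(log10_fc = l, fold_change = 10^l, normalized = normalized)
}

#' Fold change from a printed log10 fold change
#'
#' Reporting helper enforcing the FC = 10^log10FC contract used in result
#' tables: the displayed fold change is 10^log10FC rounded to `digits`
#' decimals (so a printed log10 fold change of 1.13 corresponds to a
#' printed fold change of 13.5).
#'
#' @param log10_fc log10 fold change(s).
#' @param digits Decimals for display (default 1, the table convention).
#' @return Numeric vector of rounded fold changes.
#' @export
fc_from_log10 <- function(log10_fc, digits = 1) round(10^log10_fc, digits)
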