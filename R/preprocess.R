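#' Base-10 logit of a peak-area frequency
#'
#' `logit10(f) = log10(f / (1 - f))`. In a competitive PCR assay the
#' frequency f is the relative peak area of the cDNA-derived extension
#' product, so `logit10(f)` equals `log10(cDNA / competitor)` and is linear
#' in the log10 competitor concentration with slope -1; the equivalence
#' point (EC50) is where it crosses zero.
#'
#' @param f Frequencies strictly inside (0, 1). `NA` passes through.
#' @return Numeric vector of logit values.
#' @seealso [inv_logit10()]
#' @examples
#' logit10(c(0.5, 10 / 11, 0.2))
#' @export
logit10 <- function(f) {
  if (!is.numeric(f)) stop("`f` must be numeric", call. = FALSE)
  bad <- !is.na(f) & (f <= 0 | f >= 1)
  if (any(bad)) {
    stop("logit10 is defined only on (0, 1); got ",
         paste(utils::head(f[bad], 3L), collapse = ", "), call. = FALSE)
  }
  log10(f / (1 - f))
}

#' Inverse base-10 logit
#'
#' @param y Logit values.
#' @return Frequencies in (0, 1).
#' @export
inv_logit10 <- function(y) 1 / (1 + 10^(-y))

#' Remove unusable titration points
#'
#' Drops points where no signal was detected for either product (recorded as
#' a missing frequency) and flags points with frequency exactly 0 or 1:
#' there the logit is infinite, so they cannot enter the titration fit. The
#' counts of removed points, by reason, are attached as the `"qc"` attribute
#' (a data frame with columns `reason` and `n`).
#'
#' @param x A frequency table with at least a `frequency` column (long
#'   format, one row per measurement).
#' @return The filtered table, with a `"qc"` attribute.
#' @export
drop_bad_points <- function(x) {
  stopifnot(is.data.frame(x), "frequency" %in% names(x))
  no_signal <- is.na(x$frequency)
  boundary <- !no_signal & (x$frequency <= 0 | x$frequency >= 1)
  qc <- data.frame(
    reason = c("no_signal", "boundary_frequency"),
    n = c(sum(no_signal), sum(boundary))
  )
  out <- x[!(no_signal | boundary), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc") <- qc
  out
}

#' Collapse printing replicates to their median
#'
#' Each titration point is printed in replicate; the per-point frequency is
#' the median of the non-missing replicates. Points whose replicates are all
#' missing disappear (they are the no-signal points of [drop_bad_points()]).
#'
#' @param x Long-format frequency table. Grouping uses every column present
#'   among `sample_id`, `group`, `breed`, `assay`, `allele`, `point_index`,
#'   `competitor_conc_M`; the `replicate` column is collapsed.
#' @return A table with one row per point and the same columns minus
#'   `replicate`.
#' @export
median_replicates <- function(x) {
  stopifnot(is.data.frame(x), "frequency" %in% names(x))
  keys <- intersect(
    c("sample_id", "group", "breed", "assay", "allele",
      "point_index", "competitor_conc_M"),
    names(x)
  )
  if (length(keys) == 0L) stop("no grouping columns found", call. = FALSE)
  if (nrow(x) == 0L) {
    out <- x[, c(keys, "frequency"), drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  agg <- stats::aggregate(
    x["frequency"], by = x[keys],
    FUN = function(v) stats::median(v, na.rm = TRUE)
  )
  agg$frequency[is.nan(agg$frequency)] <- NA_real_
  ord <- do.call(order, agg[keys])
  out <- agg[ord, c(keys, "frequency"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Preprocess a raw competitive-PCR frequency table
#'
#' Applies, in order, the two cleaning rules used before titration fitting:
#' printing replicates are collapsed to their median, and unusable points
#' (no signal, or frequency exactly 0/1 where the logit is undefined) are
#' removed. A `y` column with the base-10 logit is added. The operation is
#' idempotent: preprocessing an already clean table returns it unchanged.
#'
#' @param x Long-format frequency table (see [simulate_expression()] for the
#'   schema).
#' @param min_points Minimum usable points for a ladder to be considered
#'   fittable; ladders below this are kept in the output but counted in the
#'   QC report.
#' @return The cleaned table with an added `y` (logit) column and a `"qc"`
#'   attribute: a list with `dropped` (counts by reason) and
#'   `short_ladders` (sample/assay pairs with fewer than `min_points`
#'   usable points).
#' @export
qge_preprocess <- function(x, min_points = 3L) {
  stopifnot(is.data.frame(x))
  x <- median_replicates(x)
  x <- drop_bad_points(x)
  dropped <- attr(x, "qc")
  x$y <- if (nrow(x)) logit10(x$frequency) else numeric(0)

  short <- data.frame(sample_id = character(0), assay = character(0),
                      n_points = integer(0))
  if (nrow(x) && all(c("sample_id", "assay") %in% names(x))) {
    cnt <- stats::aggregate(x$frequency,
                            by = x[c("sample_id", "assay")], FUN = length)
    names(cnt)[3L] <- "n_points"
    short <- cnt[cnt$n_points < min_points, , drop = FALSE]
    rownames(short) <- NULL
  }
  attr(x, "qc") <- list(dropped = dropped, short_ladders = short)
  x
}
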