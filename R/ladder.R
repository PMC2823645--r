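#' Competitor dilution-ladder design
#'
#' Describes the serial dilution of the synthetic competitor that is titrated
#' against a constant amount of cDNA. Point `k` (k = 0, ..., n_points - 1)
#' has molar concentration `start_conc / dilution_factor^k`.
#'
#' The default design is the fine scan used for accurate quantification:
#' eleven points, 7-fold dilution from 4.04e-11 M down to 1.43e-19 M. A
#' coarse 10-fold scan for locating the approximate equivalence point can be
#' expressed with `dilution_factor = 10`.
#'
#' @param start_conc Highest competitor concentration, in mol/L. Must be > 0.
#' @param dilution_factor Fold-dilution per step (> 1).
#' @param n_points Number of titration points (>= 1; >= 3 for a fittable
#'   ladder).
#' @param reaction_volume Reaction volume in litres, used only to report
#'   molecule counts. Defaults to 5 microlitres.
#' @return An object of class `ladder_design`.
#' @seealso [ladder_concentrations()], [molecules_at()]
#' @examples
#' d <- ladder_design()
#' ladder_concentrations(d)
#' @export
ladder_design <- function(start_conc = 4.04e-11, dilution_factor = 7,
                          n_points = 11, reaction_volume = 5e-6) {
  if (!is.numeric(start_conc) || length(start_conc) != 1L || !is.finite(start_conc) ||
      start_conc <= 0) {
    stop("invalid ladder design: `start_conc` must be a single positive number",
         call. = FALSE)
  }
  if (!is.numeric(dilution_factor) || length(dilution_factor) != 1L ||
      !is.finite(dilution_factor) || dilution_factor <= 1) {
    stop("invalid ladder design: `dilution_factor` must be > 1", call. = FALSE)
  }
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 1L) {
    stop("invalid ladder design: `n_points` must be a positive integer",
         call. = FALSE)
  }
  if (!is.numeric(reaction_volume) || reaction_volume <= 0) {
    stop("invalid ladder design: `reaction_volume` must be positive (litres)",
         call. = FALSE)
  }
  structure(
    list(start_conc = start_conc, dilution_factor = dilution_factor,
         n_points = n_points, reaction_volume = reaction_volume),
    class = "ladder_design"
  )
}

#' @export
print.ladder_design <- function(x, ...) {
  conc <- ladder_concentrations(x)
  cat("Competitor dilution ladder\n")
  cat(sprintf("  %d points, %g-fold dilution per step\n",
              x$n_points, x$dilution_factor))
  cat(sprintf("  concentration range: %.3g to %.3g M\n",
              conc[1L], conc[length(conc)]))
  cat(sprintf("  reaction volume: %.3g L (%.3g molecules at the lowest point)\n",
              x$reaction_volume,
              molecules_at(conc[length(conc)], x$reaction_volume)$expected))
  invisible(x)
}

#' Concentrations of a dilution ladder
#'
#' Expands a [ladder_design()] into the ordered vector of competitor molar
#' concentrations, `start_conc / dilution_factor^k` for k = 0, ...,
#' n_points - 1. The sequence is exactly geometric and strictly decreasing.
#'
#' @param design A `ladder_design`.
#' @return Numeric vector of length `design$n_points`, in mol/L, strictly
#'   decreasing.
#' @examples
#' ladder_concentrations(ladder_design(1e-12, 2, 4))
#' @export
ladder_concentrations <- function(design) {
  design <- as_ladder_design(design)
  design$start_conc / design$dilution_factor^(seq_len(design$n_points) - 1)
}

as_ladder_design <- function(design) {
  if (inherits(design, "ladder_design")) return(design)
  if (is.list(design)) return(do.call(ladder_design, design))
  stop("`design` must be a ladder_design (see ladder_design())", call. = FALSE)
}

#' Avogadro constant (1/mol), 2019 SI exact value
#' @keywords internal
AVOGADRO <- 6.02214076e23

#' Molecule count at a molar concentration
#'
#' Converts a molar concentration and a reaction volume into the expected
#' number of molecules, `conc * N_A * volume`. At very low competitor
#' concentrations this is the natural sanity check on a ladder design: for
#' example 1.00e-18 M in 5 microlitres is about 3 molecules, close to the
#' single-molecule limit of the titration.
#'
#' @param conc Molar concentration (mol/L), >= 0. Vectorised.
#' @param volume Reaction volume in litres, > 0.
#' @return A list with `expected` (real-valued count) and `rounded`
#'   (nearest integer).
#' @examples
#' molecules_at(1e-18, 5e-6)
#' @export
molecules_at <- function(conc, volume = 5e-6) {
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc < 0)) {
    stop("`conc` must be non-negative and finite (mol/L)", call. = FALSE)
  }
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) ||
      volume <= 0) {
    stop("`volume` must be a single positive number (litres)", call. = FALSE)
  }
  expected <- conc * AVOGADRO * volume
  list(expected = expected, rounded = round(expected))
}
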