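# Affinity ratios and binding free energy differences.

# Gas constant in kcal mol^-1 K^-1
RGAS_KCAL <- 1.9872e-3

#' Construct an affinity pair
#'
#' Bundles two experimental affinities of the same kind (Ki, KD, IC50 or
#' EC50) measured at one temperature, for ratio-based comparisons. The two
#' values usually refer to one ligand at two targets, or two ligands at one
#' target. Affinities are normalised to nM at construction; for the
#' ratio-based quantities computed from a pair the unit cancels, but a
#' single internal unit keeps printed output unambiguous.
#'
#' The four affinity kinds are treated as interchangeable for ratio
#' purposes (Ki is comparable to KD under the usual competitive-binding
#' assumptions, and IC50/EC50 ratios approximate Ki ratios when measured
#' under matched assay conditions). A pair must nevertheless hold a single
#' kind: mixing, e.g., a Ki with an IC50 is refused rather than silently
#' accepted.
#'
#' @param value_a,value_b Strictly positive affinities.
#' @param temperature Absolute temperature in kelvin, in (200, 400).
#'   Default 298.15.
#' @param kind Affinity kind, one of `"Ki"`, `"KD"`, `"IC50"`, `"EC50"`.
#' @param unit Unit of `value_a`/`value_b`: `"nM"` (default), `"uM"` or
#'   `"M"`. Values are converted to nM.
#' @return An object of class `"affinity_pair"`: a list with elements
#'   `value_a`, `value_b` (nM), `temperature` and `kind`.
#' @examples
#' affinity_pair(3830, 214, temperature = 298.15, kind = "Ki")
#' affinity_pair(118, 5.89, temperature = 293.15, kind = "IC50", unit = "uM")
#' @export
affinity_pair <- function(value_a, value_b, temperature = 298.15,
                          kind = c("Ki", "KD", "IC50", "EC50"),
                          unit = c("nM", "uM", "M")) {
  kind <- match.arg(kind)
  unit <- match.arg(unit)
  stopifnot(is.numeric(value_a), is.numeric(value_b),
            length(value_a) == 1L, length(value_b) == 1L,
            is.numeric(temperature), length(temperature) == 1L)
  if (!is.finite(value_a) || !is.finite(value_b) ||
      value_a <= 0 || value_b <= 0) {
    stop("affinities must be strictly positive and finite", call. = FALSE)
  }
  if (temperature <= 200 || temperature >= 400) {
    stop("temperature must lie in (200, 400) K", call. = FALSE)
  }
  scale <- switch(unit, nM = 1, uM = 1e3, M = 1e9)
  structure(
    list(value_a = value_a * scale, value_b = value_b * scale,
         temperature = temperature, kind = kind),
    class = "affinity_pair"
  )
}

#' @export
print.affinity_pair <- function(x, ...) {
  cat(sprintf("Affinity pair (%s): a = %g nM, b = %g nM, T = %g K\n",
              x$kind, x$value_a, x$value_b, x$temperature))
  invisible(x)
}

#' Fold ratio of two affinities
#'
#' Returns `value_a / value_b` at full precision. The conventional way to
#' quote such a ratio is rounded to the nearest integer ("the halide
#' increases affinity 41 times"); `round()` the result for that form.
#'
#' @param pair An [affinity_pair()].
#' @return The dimensionless ratio, full precision.
#' @examples
#' fold_ratio(affinity_pair(13900, 338))   # ~41.1, quoted as 41-fold
#' @export
fold_ratio <- function(pair) {
  stopifnot(inherits(pair, "affinity_pair"))
  pair$value_a / pair$value_b
}

#' Binding free energy difference from an affinity ratio
#'
#' Computes `R * T * ln(value_a / value_b)` in kcal/mol with
#' R = 1.9872e-3 kcal mol^-1 K^-1. Positive when `value_a > value_b`,
#' i.e. when species/condition *b* binds more favourably (its dissociation
#' constant is lower). Because only the ratio enters, the result is
#' independent of the affinity unit.
#'
#' @param pair An [affinity_pair()]; its `temperature` is used.
#' @return The free energy difference in kcal/mol, full precision.
#' @examples
#' # (S)-norfenfluramine vs (S)-amphetamine at SERT, Ki 214 vs 3830 nM:
#' delta_delta_g(affinity_pair(3830, 214, temperature = 298.15, kind = "Ki"))
#' @export
delta_delta_g <- function(pair) {
  stopifnot(inherits(pair, "affinity_pair"))
  RGAS_KCAL * pair$temperature * log(pair$value_a / pair$value_b)
}
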