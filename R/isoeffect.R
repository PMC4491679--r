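#' Fractionation regimen
#'
#' A prescription expressed as total absorbed dose, number of fractions and
#' dose per fraction. Any two of the three determine the third; if all three
#' are supplied they must agree to 1e-9 relative.
#'
#' @param total_dose Total absorbed dose in Gy.
#' @param n_fractions Number of fractions (positive integer).
#' @param fraction_size Dose per fraction in Gy.
#' @param zero_fraction_ok Permit `fraction_size = 0`, the low-dose-rate /
#'   infinitesimal-fraction limit in which BED equals the physical dose.
#'   Only [compute_bed()] accepts such a regimen; every other operation
#'   requires a strictly positive fraction size.
#' @return An object of class `"regimen"` with fields `total_dose`,
#'   `n_fractions` and `fraction_size`.
#' @examples
#' regimen(total_dose = 79.2, n_fractions = 44)       # 1.8 Gy/fx photon SOC
#' regimen(n_fractions = 38, fraction_size = 2)       # 76 Gy in 38 fx
#' @export
regimen <- function(total_dose = NULL, n_fractions = NULL, fraction_size = NULL,
                    zero_fraction_ok = FALSE) {
  n_given <- sum(!is.null(total_dose), !is.null(n_fractions), !is.null(fraction_size))
  if (n_given < 2L)
    stop("supply at least two of total_dose, n_fractions, fraction_size", call. = FALSE)
  if (is.null(total_dose))    total_dose    <- n_fractions * fraction_size
  if (is.null(n_fractions))   n_fractions   <- total_dose / fraction_size
  if (is.null(fraction_size)) fraction_size <- total_dose / n_fractions

  if (length(total_dose) != 1L || length(n_fractions) != 1L || length(fraction_size) != 1L)
    stop("regimen fields must be scalars", call. = FALSE)
  if (!is.finite(total_dose) || !is.finite(n_fractions) || !is.finite(fraction_size))
    stop("regimen fields must be finite", call. = FALSE)
  if (abs(n_fractions - round(n_fractions)) > 1e-9)
    stop("n_fractions must be a whole number", call. = FALSE)
  n_fractions <- as.integer(round(n_fractions))
  if (n_fractions < 1L) stop("n_fractions must be >= 1", call. = FALSE)
  d_min <- if (zero_fraction_ok) 0 else .Machine$double.xmin
  if (fraction_size < d_min || total_dose < d_min)
    stop("doses must be strictly positive", call. = FALSE)
  # in the zero-fraction-size limit the total dose stands alone (delivered as
  # infinitely many infinitesimal fractions); the product check is vacuous
  if (!(zero_fraction_ok && fraction_size == 0) &&
      abs(total_dose - n_fractions * fraction_size) >
      1e-9 * max(total_dose, n_fractions * fraction_size))
    stop("total_dose, n_fractions and fraction_size are inconsistent", call. = FALSE)

  structure(
    list(total_dose = total_dose, n_fractions = n_fractions,
         fraction_size = fraction_size),
    class = "regimen"
  )
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("Regimen: %.4g Gy in %d fx (%.4g Gy/fx)\n",
              x$total_dose, x$n_fractions, x$fraction_size))
  invisible(x)
}

check_alpha_beta <- function(alpha_beta) {
  if (length(alpha_beta) != 1L || !is.finite(alpha_beta) || alpha_beta <= 0)
    stop("alpha_beta must be a single positive number (Gy)", call. = FALSE)
  alpha_beta
}

#' Biologically effective dose of a regimen
#'
#' `BED = D * (1 + d / (alpha/beta))` under the linear-quadratic model, where
#' `D` is the total dose and `d` the fraction size. Two regimens with equal
#' BED (at the same alpha/beta) are isoeffective.
#'
#' @param reg A [regimen()].
#' @param alpha_beta LQ fractionation-sensitivity parameter in Gy
#'   (prostate bracket: 1, 3 or 5 Gy).
#' @return Object of class `"bed_value"`: list with `bed` (Gy) and
#'   `alpha_beta` (Gy, recorded so downstream isoeffect solves cannot mix
#'   parameter values).
#' @examples
#' compute_bed(regimen(79.2, 44), alpha_beta = 3)  # 126.72 Gy
#' @export
compute_bed <- function(reg, alpha_beta) {
  stopifnot(inherits(reg, "regimen"))
  check_alpha_beta(alpha_beta)
  structure(
    list(bed = reg$total_dose * (1 + reg$fraction_size / alpha_beta),
         alpha_beta = alpha_beta),
    class = "bed_value"
  )
}

#' @export
print.bed_value <- function(x, ...) {
  cat(sprintf("BED = %.4f Gy (alpha/beta = %g Gy)\n", x$bed, x$alpha_beta))
  invisible(x)
}

#' Isoeffective total photon dose at a new fraction number
#'
#' Solves `n * d * (1 + d / ab) = BED` for the fraction size `d` and returns
#' the total dose `n * d`, using the closed-form positive root
#' `D = (n/2) * ab * (-1 + sqrt(1 + 4 BED / (n ab)))`.
#'
#' @param n Number of fractions (positive integer).
#' @param bed A `"bed_value"` from [compute_bed()], or a plain number in Gy
#'   (in which case `alpha_beta` must be given).
#' @param alpha_beta LQ parameter in Gy. When `bed` is a `"bed_value"` this
#'   may be omitted; if supplied it must match the value the BED was computed
#'   with.
#' @return Total photon dose in Gy delivered in `n` fractions producing the
#'   same LQ effect.
#' @examples
#' b <- compute_bed(regimen(79.2, 44), alpha_beta = 3)
#' isoeffective_total_dose(44, b)  # recovers 79.2
#' isoeffective_total_dose(1, b)   # 18.06 Gy single fraction
#' @export
isoeffective_total_dose <- function(n, bed, alpha_beta = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || abs(n - round(n)) > 1e-9)
    stop("n must be a positive whole number", call. = FALSE)
  n <- round(n)
  if (inherits(bed, "bed_value")) {
    if (!is.null(alpha_beta) &&
        abs(alpha_beta - bed$alpha_beta) > 1e-12 * max(1, bed$alpha_beta))
      stop("alpha_beta does not match the value the BED was computed with",
           call. = FALSE)
    alpha_beta <- bed$alpha_beta
    bed <- bed$bed
  }
  if (is.null(alpha_beta))
    stop("alpha_beta required when bed is a bare number", call. = FALSE)
  check_alpha_beta(alpha_beta)
  if (!is.finite(bed) || bed <= 0) stop("bed must be positive", call. = FALSE)
  disc <- 1 + 4 * bed / (n * alpha_beta)
  stopifnot(disc > 0)  # impossible to violate for positive inputs
  (n / 2) * alpha_beta * (-1 + sqrt(disc))
}

#' Convert photon dose to proton absorbed dose at constant RBE
#'
#' Proton absorbed dose producing the same effect as a given photon dose,
#' under the constant clinical RBE model: `D_p = D_gamma / RBE`. Multiplying
#' the result by the RBE recovers the photon-equivalent dose in Gy (RBE).
#'
#' @param photon_dose Photon dose in Gy (vectorized).
#' @param rbe Relative biological effectiveness, default the generic clinical
#'   value 1.1. Must be >= 1 (constant-RBE model).
#' @return Proton absorbed dose in Gy.
#' @examples
#' photon_to_proton_dose(79.2)  # 72 Gy
#' @export
photon_to_proton_dose <- function(photon_dose, rbe = 1.1) {
  if (length(rbe) != 1L || !is.finite(rbe) || rbe <= 0)
    stop("rbe must be a single positive number", call. = FALSE)
  if (rbe < 1) stop("constant-RBE model requires rbe >= 1", call. = FALSE)
  if (any(!is.finite(photon_dose)) || any(photon_dose < 0))
    stop("photon_dose must be non-negative", call. = FALSE)
  photon_dose / rbe
}

#' Max/min uncertainty ratio over an alpha/beta bracket
#'
#' Ratio of the largest to the smallest isoeffective total dose across the
#' alpha/beta bracket, a measure of prescription uncertainty. Ratios above
#' the upper edge of the significance band are flagged clinically
#' significant (comparable in magnitude to dose delivery errors); ratios
#' inside the band are flagged borderline.
#'
#' @param totals Numeric vector (length >= 2) of total doses in Gy, one per
#'   alpha/beta value; all strictly positive.
#' @param significance_band Two ascending ratio thresholds, default
#'   `c(1.05, 1.10)`.
#' @return List with `ratio`, `clinically_significant`, `borderline`.
#' @export
uncertainty_ratio <- function(totals, significance_band = c(1.05, 1.10)) {
  totals <- unlist(totals, use.names = FALSE)
  if (length(totals) < 2L) stop("need at least two totals", call. = FALSE)
  if (any(!is.finite(totals)) || any(totals <= 0))
    stop("totals must be positive", call. = FALSE)
  stopifnot(length(significance_band) == 2L,
            significance_band[1] <= significance_band[2])
  ratio <- max(totals) / min(totals)
  list(ratio = ratio,
       clinically_significant = ratio > significance_band[2],
       borderline = ratio > significance_band[1] & ratio <= significance_band[2])
}

#' Hypofractionation equivalence table
#'
#' For each fraction number in `n_grid` and each alpha/beta in the bracket,
#' computes the proton total dose isoeffective with the reference photon
#' regimen: the photon total from the closed-form LQ isoeffect solve, divided
#' by the RBE. The max/min ratio across the bracket is computed from the
#' unrounded totals.
#'
#' @param reference Reference photon [regimen()]; default 79.2 Gy in 44
#'   fractions (1.8 Gy/fx).
#' @param alpha_beta Bracket of LQ parameters in Gy; default `c(1, 3, 5)`.
#' @param n_grid Fraction numbers for the rows; default the canonical
#'   1--45 grid.
#' @param rbe Constant proton RBE, default 1.1.
#' @param significance_band Passed to [uncertainty_ratio()].
#' @param digits_dose,digits_ratio Rounding applied to the reported dose and
#'   ratio columns (1 and 2 decimals); `NA` disables rounding. Ratios are
#'   always computed before any rounding.
#' @return A data.frame with one row per `n`: columns `frac_<ab>` (proton Gy
#'   per fraction) and `total_<ab>` (proton Gy) for each alpha/beta, plus
#'   `ratio`, `clinically_significant` and `borderline`. The unrounded totals
#'   are attached as attribute `"unrounded"`.
#' @examples
#' eq <- equivalence_table()
#' eq[eq$n == 1, ]  # 16.4 / 18.9 Gy mid/max single-fraction doses
#' @export
equivalence_table <- function(reference = regimen(79.2, 44),
                              alpha_beta = c(1, 3, 5),
                              n_grid = c(1, 3, 5, 10, 15, 20, 25, 30, 35, 38, 40, 44, 45),
                              rbe = 1.1,
                              significance_band = c(1.05, 1.10),
                              digits_dose = 1, digits_ratio = 2) {
  stopifnot(inherits(reference, "regimen"))
  if (length(alpha_beta) == 0L) stop("alpha_beta must be non-empty", call. = FALSE)
  if (length(n_grid) == 0L) stop("n_grid must be non-empty", call. = FALSE)
  alpha_beta <- sort(unique(alpha_beta))
  vapply(alpha_beta, check_alpha_beta, numeric(1))
  n_grid <- sort(unique(as.integer(round(n_grid))))
  if (any(n_grid < 1L)) stop("all n must be >= 1", call. = FALSE)

  beds <- lapply(alpha_beta, function(ab) compute_bed(reference, ab))
  totals <- vapply(seq_along(alpha_beta), function(j) {
    vapply(n_grid, function(n)
      photon_to_proton_dose(isoeffective_total_dose(n, beds[[j]]), rbe),
      numeric(1))
  }, numeric(length(n_grid)))
  totals <- matrix(totals, nrow = length(n_grid),
                   dimnames = list(NULL, paste0("total_", alpha_beta)))
  fracs <- sweep(totals, 1, n_grid, "/")
  colnames(fracs) <- paste0("frac_", alpha_beta)

  ratio_info <- apply(totals, 1, uncertainty_ratio,
                      significance_band = significance_band)
  ratio <- vapply(ratio_info, `[[`, numeric(1), "ratio")

  rnd <- function(x, d) if (is.na(d)) x else round(x, d)
  out <- data.frame(n = n_grid,
                    rnd(fracs, digits_dose),
                    rnd(totals, digits_dose),
                    ratio = rnd(ratio, digits_ratio),
                    clinically_significant =
                      vapply(ratio_info, `[[`, logical(1), "clinically_significant"),
                    borderline = vapply(ratio_info, `[[`, logical(1), "borderline"),
                    check.names = FALSE)
  attr(out, "unrounded") <- data.frame(n = n_grid, fracs, totals, ratio = ratio,
                                       check.names = FALSE)
  attr(out, "alpha_beta") <- alpha_beta
  attr(out, "reference") <- reference
  attr(out, "rbe") <- rbe
  out
}

#' Write an equivalence table as CSV
#'
#' With a three-value alpha/beta bracket, columns are renamed
#' `frac_min, frac_mid, frac_max, total_min, total_mid, total_max` (min/mid/
#' max labelling the ascending alpha/beta values, the convention of the
#' canonical 1/3/5 Gy prostate bracket); otherwise the `frac_<ab>` /
#' `total_<ab>` names are kept.
#'
#' @param tab Result of [equivalence_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_equivalence_csv <- function(tab, path) {
  ab <- attr(tab, "alpha_beta")
  out <- tab[, !(names(tab) %in% c("clinically_significant", "borderline"))]
  if (length(ab) == 3L) {
    names(out) <- c("n", "frac_min", "frac_mid", "frac_max",
                    "total_min", "total_mid", "total_max", "ratio")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
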