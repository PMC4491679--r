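#' Normalize an organ label
#'
#' Case-insensitive, trims whitespace, maps spaces/hyphens to underscores and
#' resolves a small synonym table (e.g. "Anterior Rectal Wall" and
#' "anterior_rectal_wall" are the same organ).
#'
#' @param x Character vector of organ labels.
#' @return Normalized labels.
#' @export
normalize_organ_label <- function(x) {
  y <- tolower(trimws(as.character(x)))
  y <- gsub("[ \\-]+", "_", y)
  synonyms <- c(
    urinary_bladder = "bladder",
    femoral_head = "femoral_heads",
    ant_rectal_wall = "anterior_rectal_wall",
    prox_seminal_vesicles = "proximal_seminal_vesicles",
    dist_seminal_vesicles = "distal_seminal_vesicles"
  )
  hit <- y %in% names(synonyms)
  y[hit] <- synonyms[y[hit]]
  y
}

#' Neutron equivalent dose from absorbed dose
#'
#' Weights a neutron absorbed dose by the mean radiation weighting factor
#' (default 6.2, an average over external and internal stray neutrons in a
#' passively scattered proton treatment).
#'
#' @param absorbed Absorbed dose in Gy (vectorized, non-negative).
#' @param w_bar Mean radiation weighting factor, dimensionless, > 0.
#' @return Equivalent dose in Sv.
#' @export
weight_neutron_dose <- function(absorbed, w_bar = 6.2) {
  if (length(w_bar) != 1L || !is.finite(w_bar) || w_bar <= 0)
    stop("w_bar must be a single positive number", call. = FALSE)
  if (any(!is.finite(absorbed)) || any(absorbed < 0))
    stop("absorbed dose must be non-negative", call. = FALSE)
  absorbed * w_bar
}

#' Mass-corrected lifetime risk coefficient
#'
#' Scales a whole-organ lifetime-attributable-risk (LAR) coefficient by the
#' fraction of the organ's mass actually irradiated. The canonical use is
#' the rectum: the BEIR VII colon coefficient times a fractional mass of 0.2
#' (the rectum is about 20% of the mass of the entire colon) gives the
#' 0.19 %/Sv rectal coefficient.
#'
#' @param whole_organ_lar LAR in % per Sv, >= 0.
#' @param mass_fraction Fraction of organ mass in (0, 1].
#' @return Corrected LAR in % per Sv.
#' @examples
#' derive_mass_corrected_coefficient(0.95, 0.2)  # 0.19 %/Sv
#' @export
derive_mass_corrected_coefficient <- function(whole_organ_lar, mass_fraction) {
  if (any(!is.finite(whole_organ_lar)) || any(whole_organ_lar < 0))
    stop("whole_organ_lar must be non-negative", call. = FALSE)
  if (length(mass_fraction) != 1L || !is.finite(mass_fraction) ||
      mass_fraction <= 0 || mass_fraction > 1)
    stop("mass_fraction must lie in (0, 1]", call. = FALSE)
  whole_organ_lar * mass_fraction
}

#' Default organ risk coefficients
#'
#' BEIR VII-derived lifetime-attributable-risk coefficients for a 60-year-old
#' man: bladder 0.66 %/Sv and rectum 0.19 %/Sv (the rectal value already
#' carries the 0.2 fractional mass correction relative to the whole colon).
#' Other organs carry no default and require user-supplied coefficients.
#'
#' @return data.frame with columns `organ`, `lar_pct_per_sv`, `mass_fraction`.
#' @export
default_risk_coefficients <- function() {
  data.frame(
    organ = c("bladder", "rectum"),
    lar_pct_per_sv = c(0.66, 0.19),
    mass_fraction = c(1.0, 0.2),
    stringsAsFactors = FALSE
  )
}

validate_neutron_table <- function(tab) {
  req <- c("organ", "external_mSv", "internal_mSv", "total_mSv")
  if (!all(req %in% names(tab)))
    stop("organ dose table needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  num <- c("external_mSv", "internal_mSv", "total_mSv")
  if (any(!is.finite(as.matrix(tab[num]))) || any(as.matrix(tab[num]) < 0))
    stop("dose components must be finite and non-negative", call. = FALSE)
  # printed tables are pre-rounded; tolerate 1 mSv of closure error
  off <- abs(tab$total_mSv - (tab$external_mSv + tab$internal_mSv))
  if (any(off > 1 + 1e-9))
    stop("total must equal external + internal within 1 mSv (worst off by ",
         sprintf("%.3f", max(off)), " mSv)", call. = FALSE)
  tab$organ <- normalize_organ_label(tab$organ)
  if (anyDuplicated(tab$organ))
    stop("duplicate organ rows after label normalization", call. = FALSE)
  tab
}

#' Read / write an organ neutron-dose table
#'
#' CSV with header `organ,external_mSv,internal_mSv,total_mSv`. On read,
#' organ labels are normalized and the closure `total = external + internal`
#' is checked to within 1 mSv (printed tables are pre-rounded).
#'
#' @param path File path.
#' @return `read_neutron_table`: validated data.frame.
#' @export
read_neutron_table <- function(path) {
  validate_neutron_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_neutron_table
#' @param tab Organ dose table (data.frame).
#' @export
write_neutron_table <- function(tab, path) {
  tab <- validate_neutron_table(tab)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled organ neutron-dose fixtures
#'
#' Mean stray-neutron equivalent doses (mSv) for one prostate patient from
#' Monte Carlo simulation of a lateral opposed-pair passively scattered
#' proton plan, as transcribed: one table for the standard-of-care (brass
#' aperture) plan and one for the MLC-only plan.
#'
#' @param plan `"soc"` or `"mlc_only"`.
#' @return Organ dose table (data.frame) as from [read_neutron_table()].
#' @export
neutron_dose_fixture <- function(plan = c("soc", "mlc_only")) {
  plan <- match.arg(plan)
  path <- system.file("extdata", paste0("table2_", plan, ".csv"),
                      package = "hypofrac", mustWork = TRUE)
  read_neutron_table(path)
}

#' Lifetime second-cancer risk for one organ
#'
#' Risk (% lifetime incidence) = organ equivalent dose in Sv times the
#' organ-specific LAR coefficient in %/Sv.
#'
#' @param dose One-row organ dose table (or list) with `organ` and
#'   `total_mSv`.
#' @param coeff One-row coefficient table (or list) with `organ` and
#'   `lar_pct_per_sv`; organ labels must match after normalization.
#' @return List with `organ`, `risk_pct`, `dose_sv`, `lar_pct_per_sv`.
#' @export
organ_risk <- function(dose, coeff) {
  org_d <- normalize_organ_label(dose$organ)
  org_c <- normalize_organ_label(coeff$organ)
  if (length(org_d) != 1L || length(org_c) != 1L || org_d != org_c)
    stop("organ mismatch: dose is for '", org_d, "', coefficient for '",
         org_c, "'", call. = FALSE)
  if (coeff$lar_pct_per_sv < 0) stop("LAR coefficient must be >= 0", call. = FALSE)
  dose_sv <- dose$total_mSv / 1000
  list(organ = org_d,
       risk_pct = dose_sv * coeff$lar_pct_per_sv,
       dose_sv = dose_sv,
       lar_pct_per_sv = coeff$lar_pct_per_sv)
}

#' Combined lifetime second-cancer risk over organs
#'
#' Sum of per-organ risks (equivalent dose times LAR coefficient) over the
#' requested organ subset, reported in percent.
#'
#' @param table Organ dose table with columns `organ`, `total_mSv`.
#' @param coeffs Coefficient table with `organ`, `lar_pct_per_sv`; default
#'   [default_risk_coefficients()].
#' @param organs Organs to include; default bladder and rectum.
#' @param digits Decimals for the reported percentage (default 2); `NA`
#'   disables rounding. The unrounded value is attached as attribute
#'   `"unrounded"`.
#' @return Combined risk in % lifetime incidence.
#' @examples
#' combined_risk(neutron_dose_fixture("soc"))  # 0.51
#' @export
combined_risk <- function(table, coeffs = default_risk_coefficients(),
                          organs = c("bladder", "rectum"), digits = 2) {
  table <- validate_neutron_table(table)
  coeffs$organ <- normalize_organ_label(coeffs$organ)
  organs <- normalize_organ_label(organs)
  miss_t <- setdiff(organs, table$organ)
  if (length(miss_t))
    stop("organ(s) missing from dose table: ", paste(miss_t, collapse = ", "),
         call. = FALSE)
  miss_c <- setdiff(organs, coeffs$organ)
  if (length(miss_c))
    stop("no risk coefficient for organ(s): ", paste(miss_c, collapse = ", "),
         call. = FALSE)
  risks <- vapply(organs, function(o) {
    organ_risk(table[table$organ == o, ],
               coeffs[coeffs$organ == o, ])$risk_pct
  }, numeric(1))
  total <- sum(risks)
  out <- if (is.na(digits)) total else round(total, digits)
  attr(out, "unrounded") <- total
  attr(out, "per_organ") <- risks
  out
}

#' Compare two organ neutron-dose tables
#'
#' Per-organ signed differences (`b - a`) in external, internal and total
#' equivalent dose, plus the maximum absolute total-dose difference.
#'
#' @param a,b Organ dose tables over the same organ set.
#' @return List with `per_organ` (data.frame of deltas in mSv) and
#'   `max_abs_total_delta_mSv`.
#' @examples
#' cmp <- compare_plan_doses(neutron_dose_fixture("soc"),
#'                           neutron_dose_fixture("mlc_only"))
#' cmp$max_abs_total_delta_mSv  # 45 (prostate, 1113 - 1068)
#' @export
compare_plan_doses <- function(a, b) {
  a <- validate_neutron_table(a)
  b <- validate_neutron_table(b)
  if (!setequal(a$organ, b$organ))
    stop("organ sets differ between tables", call. = FALSE)
  b <- b[match(a$organ, b$organ), ]
  per <- data.frame(
    organ = a$organ,
    delta_external_mSv = b$external_mSv - a$external_mSv,
    delta_internal_mSv = b$internal_mSv - a$internal_mSv,
    delta_total_mSv = b$total_mSv - a$total_mSv,
    stringsAsFactors = FALSE
  )
  list(per_organ = per,
       max_abs_total_delta_mSv = max(abs(per$delta_total_mSv)))
}
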