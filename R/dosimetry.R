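#' Dose grid and structure mask containers
#'
#' A dose grid is a 3-D array of non-negative dose values in Gy (RBE) on a
#' regular raster; a structure mask is a logical array on the identical
#' raster. Coordinates follow a right-handed patient system (x left--right,
#' y anterior--posterior, z inferior--superior) with voxel-center origin and
#' 0-based voxel indexing. A voxel belongs to a structure iff its center is
#' inside (no partial-volume weighting).
#'
#' @param values 3-D numeric array (Gy) for `dose_grid`; 3-D logical (or
#'   0/1) array for `structure_mask`.
#' @param spacing Voxel spacing `c(dx, dy, dz)` in cm, strictly positive.
#' @param origin Physical position of voxel (0,0,0)'s center, cm.
#' @param label Organ name for masks.
#' @return An object of class `"dose_grid"` / `"structure_mask"`.
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- check_raster(values, spacing, origin)
  if (any(values < 0)) stop("dose values must be >= 0", call. = FALSE)
  structure(values, spacing = as.numeric(spacing), origin = as.numeric(origin),
            class = "dose_grid")
}

#' @rdname dose_grid
#' @export
structure_mask <- function(values, spacing, origin = c(0, 0, 0), label = "structure") {
  storage.mode(values) <- "logical"
  values <- check_raster(values, spacing, origin)
  structure(values, spacing = as.numeric(spacing), origin = as.numeric(origin),
            label = normalize_organ_label(label), class = "structure_mask")
}

check_raster <- function(values, spacing, origin) {
  if (length(dim(values)) != 3L) stop("values must be a 3-D array", call. = FALSE)
  if (any(dim(values) < 1L)) stop("grid shape must be at least (1,1,1)", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers (cm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite numbers (cm)", call. = FALSE)
  if (is.logical(values)) {
    if (anyNA(values)) stop("mask values must not be NA", call. = FALSE)
  } else if (any(!is.finite(values))) {
    stop("values must be finite", call. = FALSE)
  }
  values
}

same_geometry <- function(a, b) {
  identical(dim(a), dim(b)) &&
    isTRUE(all.equal(attr(a, "spacing"), attr(b, "spacing"))) &&
    isTRUE(all.equal(attr(a, "origin"), attr(b, "origin")))
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("Dose grid %s, spacing (%s) cm, range [%.3g, %.3g] Gy\n",
              paste(dim(x), collapse = "x"),
              paste(attr(x, "spacing"), collapse = ", "),
              min(x), max(x)))
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("Structure mask '%s' %s, %d voxels in structure\n",
              attr(x, "label"), paste(dim(x), collapse = "x"), sum(x)))
  invisible(x)
}

#' Mean and maximum dose inside a mask
#'
#' @param grid A [dose_grid()].
#' @param mask A [structure_mask()] on the same raster.
#' @return `mask_mean` / `mask_max`: dose in Gy.
#' @export
mask_mean <- function(grid, mask) {
  check_pair(grid, mask)
  mean(unclass(grid)[unclass(mask)])
}

#' @rdname mask_mean
#' @export
mask_max <- function(grid, mask) {
  check_pair(grid, mask)
  max(unclass(grid)[unclass(mask)])
}

check_pair <- function(grid, mask) {
  stopifnot(inherits(grid, "dose_grid"), inherits(mask, "structure_mask"))
  if (!same_geometry(grid, mask))
    stop("grid and mask geometries differ", call. = FALSE)
  if (!any(mask))
    stop("mask '", attr(mask, "label"), "' is empty", call. = FALSE)
  invisible(TRUE)
}

#' Normalize a plan so the CTV mean equals the prescription
#'
#' Scales the whole grid by `prescription / mean(CTV dose)`, the convention
#' under which plans are compared (CTV mean 76 Gy (RBE) by default). The
#' operation is idempotent and scale-equivariant: any positive rescaling of
#' the input normalizes to the same grid.
#'
#' @param grid A [dose_grid()].
#' @param ctv The CTV [structure_mask()] (non-empty, non-zero mean dose).
#' @param prescription Target CTV mean in Gy (RBE), default 76.
#' @return The normalized [dose_grid()].
#' @export
normalize_to_ctv_mean <- function(grid, ctv, prescription = 76) {
  check_pair(grid, ctv)
  if (prescription <= 0) stop("prescription must be positive", call. = FALSE)
  m <- mask_mean(grid, ctv)
  if (m <= 0) stop("CTV mean dose is zero; cannot normalize", call. = FALSE)
  out <- unclass(grid) * (prescription / m)
  dose_grid(out, attr(grid, "spacing"), attr(grid, "origin"))
}

#' Combine treatment fields at a per-field CTV prescription
#'
#' Each field is normalized to deliver `per_field_prescription` Gy mean in
#' the CTV, then the fields are summed; with the default 34.5 Gy/field a
#' lateral opposed pair delivers a 69 Gy CTV mean.
#'
#' @param fields List of [dose_grid()]s sharing one raster geometry.
#' @param ctv The CTV [structure_mask()].
#' @param per_field_prescription CTV mean per field in Gy, default 34.5.
#' @return Combined [dose_grid()].
#' @export
combine_fields <- function(fields, ctv, per_field_prescription = 34.5) {
  if (!is.list(fields) || length(fields) < 1L)
    stop("fields must be a non-empty list of dose grids", call. = FALSE)
  for (f in fields) {
    stopifnot(inherits(f, "dose_grid"))
    if (!same_geometry(f, fields[[1]]))
      stop("fields have mismatched raster geometries", call. = FALSE)
  }
  scaled <- lapply(fields, normalize_to_ctv_mean, ctv = ctv,
                   prescription = per_field_prescription)
  total <- Reduce(`+`, lapply(scaled, unclass))
  dose_grid(total, attr(fields[[1]], "spacing"), attr(fields[[1]], "origin"))
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the structure volume receiving at least each dose level,
#' evaluated at bin edges `0, bin_width, 2 bin_width, ...` up to one bin
#' above the structure maximum. The curve starts at 100% at dose 0, is
#' monotone non-increasing, and reaches 0% above the maximum dose.
#'
#' @param grid A [dose_grid()].
#' @param mask A non-empty [structure_mask()].
#' @param bin_width Dose bin width in Gy, default 0.1.
#' @return Object of class `"dvh_curve"`: data.frame with `dose_gy` (edges)
#'   and `volume_pct`.
#' @export
cumulative_dvh <- function(grid, mask, bin_width = 0.1) {
  check_pair(grid, mask)
  if (length(bin_width) != 1L || !is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be a single positive number", call. = FALSE)
  d <- unclass(grid)[unclass(mask)]
  edges <- seq(0, (floor(max(d) / bin_width) + 1) * bin_width, by = bin_width)
  vol <- vapply(edges, function(e) 100 * mean(d >= e), numeric(1))
  structure(data.frame(dose_gy = edges, volume_pct = vol),
            class = c("dvh_curve", "data.frame"),
            label = attr(mask, "label"), bin_width = bin_width)
}

#' Per-organ max/mean plan summary
#'
#' @param grid A [dose_grid()].
#' @param masks List of [structure_mask()]s.
#' @param plan Plan label attached to the result.
#' @return Object of class `"plan_summary"`: data.frame with `organ`,
#'   `max_gy`, `mean_gy`. An empty mask yields an `NA` row flagged in the
#'   `error` column rather than a silent omission.
#' @export
dose_summary <- function(grid, masks, plan = "plan") {
  if (!is.list(masks) || length(masks) < 1L)
    stop("masks must be a non-empty list", call. = FALSE)
  rows <- lapply(masks, function(m) {
    stopifnot(inherits(m, "structure_mask"))
    if (!same_geometry(grid, m))
      stop("grid and mask geometries differ", call. = FALSE)
    if (!any(m)) {
      data.frame(organ = attr(m, "label"), max_gy = NA_real_,
                 mean_gy = NA_real_, error = "empty mask",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(organ = attr(m, "label"), max_gy = mask_max(grid, m),
                 mean_gy = mask_mean(grid, m), error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("plan_summary", "data.frame"), plan = plan)
}

#' Signed per-organ differences between two plan summaries
#'
#' @param a,b `"plan_summary"` objects (or data.frames with `organ`,
#'   `max_gy`, `mean_gy`) over the same organ set.
#' @return data.frame with `organ`, `delta_max_gy`, `delta_mean_gy`
#'   (`b - a`).
#' @export
compare_summaries <- function(a, b) {
  for (s in list(a, b))
    if (!all(c("organ", "max_gy", "mean_gy") %in% names(s)))
      stop("summaries need columns organ, max_gy, mean_gy", call. = FALSE)
  ao <- normalize_organ_label(a$organ); bo <- normalize_organ_label(b$organ)
  if (!setequal(ao, bo)) stop("organ sets differ between summaries", call. = FALSE)
  idx <- match(ao, bo)
  data.frame(organ = ao,
             delta_max_gy = b$max_gy[idx] - a$max_gy,
             delta_mean_gy = b$mean_gy[idx] - a$mean_gy,
             stringsAsFactors = FALSE)
}

#' Bundled per-organ plan summary fixture
#'
#' Mean/max organ doses in Gy (RBE), averaged over ten patients, for the
#' three planning techniques (standard of care with custom aperture,
#' MLC + range compensator, MLC only), all normalized to a 76 Gy (RBE) CTV
#' mean. Values are preserved exactly as printed; note that the anterior
#' rectal wall mean for the two MLC techniques (75.90 Gy) duplicates the
#' CTV row and is inconsistent with the 39.48 Gy standard-of-care mean --
#' the row is kept as printed and flagged via the `"suspect_rows"`
#' attribute, not corrected.
#'
#' @param plan `"soc"`, `"mlc_rc"` or `"mlc_only"`.
#' @return A `"plan_summary"` data.frame (`organ`, `max_gy`, `mean_gy`).
#' @export
plan_summary_fixture <- function(plan = c("soc", "mlc_rc", "mlc_only")) {
  plan <- match.arg(plan)
  path <- system.file("extdata", "table1_summaries.csv",
                      package = "hypofrac", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(organ = normalize_organ_label(d$organ),
                    max_gy = d[[paste0(plan, "_max")]],
                    mean_gy = d[[paste0(plan, "_mean")]],
                    stringsAsFactors = FALSE)
  structure(out, class = c("plan_summary", "data.frame"), plan = plan,
            suspect_rows = "anterior_rectal_wall")
}

#' Dose-grid file I/O (NIfTI raster)
#'
#' Grids and masks are stored one scalar volume per file as NIfTI (masks as
#' 0/1), with voxel spacing carried in the header. Requires the RNifti
#' package.
#'
#' @param path File path (`.nii` / `.nii.gz`).
#' @return `read_dose_grid`: a [dose_grid()]; `read_structure_mask`: a
#'   [structure_mask()].
#' @export
read_dose_grid <- function(path) {
  need_rnifti()
  img <- RNifti::readNifti(path)
  dose_grid(array(as.numeric(img), dim = dim(img)),
            spacing = RNifti::pixdim(img)[1:3] / 10)  # NIfTI mm -> cm
}

#' @rdname read_dose_grid
#' @param grid A [dose_grid()].
#' @export
write_dose_grid <- function(grid, path) {
  need_rnifti()
  img <- RNifti::asNifti(unclass(grid) * 1)
  RNifti::pixdim(img) <- attr(grid, "spacing") * 10  # cm -> NIfTI mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_dose_grid
#' @param label Organ label for the mask.
#' @export
read_structure_mask <- function(path, label = "structure") {
  need_rnifti()
  img <- RNifti::readNifti(path)
  structure_mask(array(as.numeric(img) > 0.5, dim = dim(img)),
                 spacing = RNifti::pixdim(img)[1:3] / 10, label = label)
}

#' @rdname read_dose_grid
#' @param mask A [structure_mask()].
#' @export
write_structure_mask <- function(mask, path) {
  need_rnifti()
  img <- RNifti::asNifti(array(as.numeric(mask), dim = dim(mask)))
  RNifti::pixdim(img) <- attr(mask, "spacing") * 10
  RNifti::writeNifti(img, path)
  invisible(path)
}

need_rnifti <- function() {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("grid file I/O requires the RNifti package", call. = FALSE)
}
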