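# run a thunk with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, thunk) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit(if (had) assign(".Random.seed", old, envir = env)
          else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env))
  set.seed(seed)
  thunk()
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Synthetic opposed-lateral proton plan
#'
#' Generates the two dose grids of a lateral opposed-pair passively
#' scattered proton field arrangement plus pelvic structure masks (CTV,
#' bladder, rectum, femoral heads) on one raster, for exercising the
#' dosimetry operations without patient data. Each field's depth profile is
#' a flat plateau over the spread-out Bragg peak (SOBP) interval ending at
#' the beam range, with a sigmoid distal falloff; the lateral profile is a
#' product of error-function penumbrae. The depth-dose shape is deliberately
#' minimal (no Bragg-curve physics, no heterogeneity); the beam entrance
#' region lies outside the grid. Deterministic given `seed`; the caller's
#' RNG state is preserved.
#'
#' @param seed Integer seed.
#' @param shape Grid shape in voxels, default `c(40, 40, 40)`.
#' @param spacing Voxel spacing in cm, default 0.4 cm isotropic (a 16 cm
#'   cube about the isocenter).
#' @param ctv_semi_axes CTV ellipsoid semi-axes `(x, y, z)` in cm; the
#'   implied volume must lie in the clinical 46.3--81.8 cm^3 span.
#' @param range_wet Beam range in cm water-equivalent, in `[22, 27.1]`.
#' @param sobp_width SOBP width in cm water-equivalent, in `[8, 10]`.
#' @param penumbra_sigma Lateral penumbra sigma in cm, default 0.3.
#' @param distal_sigma Distal falloff sigma in cm, default 0.3.
#' @param noise Multiplicative Gaussian dose noise amplitude, default 0.01.
#' @param variant Planning technique emulated; `"mlc_only"` widens the
#'   lateral penumbra by 15% (no range compensator, scalloped field edge),
#'   the other variants share the nominal penumbra.
#' @return List with `fields` (list of two [dose_grid()]s), `masks` (named
#'   list of [structure_mask()]s: `ctv`, `bladder`, `rectum`,
#'   `femoral_heads`), and `spec` (the parameters used, including the CTV
#'   volume in cm^3).
#' @export
synth_plan <- function(seed,
                       shape = c(40L, 40L, 40L),
                       spacing = c(0.4, 0.4, 0.4),
                       ctv_semi_axes = c(3.0, 2.4, 2.0),
                       range_wet = 24.5,
                       sobp_width = 9,
                       penumbra_sigma = 0.3,
                       distal_sigma = 0.3,
                       noise = 0.01,
                       variant = c("soc", "mlc_rc", "mlc_only")) {
  variant <- match.arg(variant)
  if (range_wet < 22 || range_wet > 27.1)
    stop("range_wet must lie in [22, 27.1] cm WET", call. = FALSE)
  if (sobp_width < 8 || sobp_width > 10)
    stop("sobp_width must lie in [8, 10] cm WET", call. = FALSE)
  ctv_vol <- 4 / 3 * pi * prod(ctv_semi_axes)
  if (ctv_vol < 46.3 || ctv_vol > 81.8)
    stop(sprintf("CTV volume %.1f cm^3 outside the clinical span [46.3, 81.8]",
                 ctv_vol), call. = FALSE)
  if (noise < 0) stop("noise must be >= 0", call. = FALSE)
  shape <- as.integer(shape)

  origin <- -(shape - 1) / 2 * spacing
  xs <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]

  sigma <- penumbra_sigma * if (variant == "mlc_only") 1.15 else 1
  # field aperture: CTV cross-section plus margin
  margin <- 0.7
  half_y <- ctv_semi_axes[2] + margin
  half_z <- ctv_semi_axes[3] + margin
  lat <- function(u, half) {
    p <- 0.5 * (erf((u + half) / (sqrt(2) * sigma)) -
                erf((u - half) / (sqrt(2) * sigma)))
    p / max(p)
  }
  # distal SOBP edge placed at the CTV's far surface plus margin; the
  # entrance surface (depth 0) then sits outside the grid
  x_distal <- ctv_semi_axes[1] + 1
  depth_profile <- function(depth) {
    entrance <- 0.85 + 0.15 * stats::plogis((depth - (range_wet - sobp_width)) / 0.25)
    falloff <- stats::plogis((range_wet + 2 * distal_sigma - depth) /
                             (distal_sigma / 2))
    entrance * falloff
  }
  depth1 <- (xs - (x_distal - range_wet))            # field entering from -x
  prof1 <- depth_profile(depth1)
  prof2 <- rev(prof1)                                # opposed field from +x

  lat_y <- lat(ys, half_y)
  lat_z <- lat(zs, half_z)
  base1 <- outer(outer(prof1, lat_y), lat_z)
  base2 <- outer(outer(prof2, lat_y), lat_z)

  fields <- with_seed(seed, function() {
    lapply(list(base1, base2), function(b) {
      if (noise > 0)
        b <- b * pmax(0, 1 + noise * stats::rnorm(length(b)))
      dose_grid(b, spacing, origin)
    })
  })

  ell <- function(center, semi) {
    d2 <- outer(outer(((xs - center[1]) / semi[1])^2,
                      ((ys - center[2]) / semi[2])^2, `+`),
                ((zs - center[3]) / semi[3])^2, `+`)
    d2 <= 1
  }
  masks <- list(
    ctv = structure_mask(ell(c(0, 0, 0), ctv_semi_axes), spacing, origin, "ctv"),
    bladder = structure_mask(ell(c(0, 3.8, 1.2), c(2.2, 2.2, 2.2)),
                             spacing, origin, "bladder"),
    rectum = structure_mask(ell(c(0, -3.4, 0), c(1.4, 1.4, 5.5)),
                            spacing, origin, "rectum"),
    femoral_heads = structure_mask(
      ell(c(-6, 0, 0), c(2.2, 2.2, 2.2)) | ell(c(6, 0, 0), c(2.2, 2.2, 2.2)),
      spacing, origin, "femoral_heads")
  )
  list(fields = fields, masks = masks,
       spec = list(seed = seed, shape = shape, spacing = spacing,
                   ctv_semi_axes = ctv_semi_axes, ctv_volume_cm3 = ctv_vol,
                   range_wet = range_wet, sobp_width = sobp_width,
                   penumbra_sigma = penumbra_sigma, noise = noise,
                   variant = variant))
}

#' Synthetic neutron organ-dose table pair
#'
#' Generates a standard-of-care and an MLC-only organ neutron-dose table
#' with the structure of the bundled fixtures: eight pelvic organs, totals
#' equal to external + internal, MLC-only external strictly below and
#' internal strictly above the standard-of-care values for every organ.
#' With `noise = 0` the base tables are returned unchanged (the bundled
#' fixture by default). Noisy draws violating the sign structure or the
#' 100--1300 mSv range are resampled up to `max_retry` times, then an error
#' is raised.
#'
#' @param seed Integer seed.
#' @param noise Multiplicative Gaussian noise amplitude on the external and
#'   internal components, default 0.03.
#' @param base Named list with `soc` and `mlc_only` organ dose tables;
#'   default the bundled fixtures.
#' @param max_retry Resampling attempts before failing, default 10.
#' @return List with `soc` and `mlc_only` tables (as from
#'   [read_neutron_table()]).
#' @export
synth_neutron_table <- function(seed, noise = 0.03, base = NULL, max_retry = 10L) {
  if (is.null(base))
    base <- list(soc = neutron_dose_fixture("soc"),
                 mlc_only = neutron_dose_fixture("mlc_only"))
  stopifnot(is.list(base), all(c("soc", "mlc_only") %in% names(base)))
  base$soc <- validate_neutron_table(base$soc)
  base$mlc_only <- validate_neutron_table(base$mlc_only)
  if (noise < 0) stop("noise must be >= 0", call. = FALSE)
  if (noise == 0) return(base[c("soc", "mlc_only")])

  n <- nrow(base$soc)
  with_seed(seed, function() {
    for (attempt in seq_len(max_retry)) {
      perturb <- function(x) x * (1 + noise * stats::rnorm(length(x)))
      soc <- base$soc; mlc <- base$mlc_only
      soc$external_mSv <- perturb(soc$external_mSv)
      soc$internal_mSv <- perturb(soc$internal_mSv)
      mlc$external_mSv <- perturb(mlc$external_mSv)
      mlc$internal_mSv <- perturb(mlc$internal_mSv)
      soc$total_mSv <- soc$external_mSv + soc$internal_mSv
      mlc$total_mSv <- mlc$external_mSv + mlc$internal_mSv
      ok_sign <- all(mlc$external_mSv < soc$external_mSv) &&
        all(mlc$internal_mSv > soc$internal_mSv)
      vals <- c(soc$external_mSv, soc$internal_mSv, soc$total_mSv,
                mlc$external_mSv, mlc$internal_mSv, mlc$total_mSv)
      if (ok_sign && all(vals >= 100) && all(vals <= 1300))
        return(list(soc = soc, mlc_only = mlc))
    }
    stop("could not satisfy the external/internal sign structure in ",
         max_retry, " attempts; reduce the noise amplitude", call. = FALSE)
  })
}

#' Synthetic aperture polygon
#'
#' A simple closed polygon from a radial Fourier perturbation of a circle:
#' `r(theta) = R * (1 + p(theta))` with `p` a random combination of
#' harmonics 2--5, rescaled so `max |p| = irregularity`. Star-shaped by
#' construction, hence always simple. `irregularity = 0` gives a regular
#' polygon approximating the circle. Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param mean_radius Circle radius R in cm, > 0.
#' @param irregularity Perturbation amplitude in `[0, 1)`.
#' @param n_vertices Number of polygon vertices, default 64.
#' @return An [aperture_polygon()].
#' @export
synth_aperture <- function(seed, mean_radius = 2.5, irregularity = 0.15,
                           n_vertices = 64L) {
  if (mean_radius <= 0) stop("mean_radius must be positive", call. = FALSE)
  if (irregularity < 0 || irregularity >= 1)
    stop("irregularity must lie in [0, 1)", call. = FALSE)
  theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  pert <- rep(0, n_vertices)
  if (irregularity > 0) {
    pert <- with_seed(seed, function() {
      p <- rep(0, n_vertices)
      for (k in 2:5)
        p <- p + stats::rnorm(1, sd = 1 / k) * cos(k * theta) +
                 stats::rnorm(1, sd = 1 / k) * sin(k * theta)
      if (max(abs(p)) > 0) p <- p / max(abs(p)) * irregularity
      p
    })
  }
  r <- mean_radius * (1 + pert)
  aperture_polygon(r * cos(theta), r * sin(theta))
}

#' Seeded random convex polygon
#'
#' Convex hull of points on an ellipse with jittered radii and angles;
#' used by the leaf-fitting property checks. Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param n_points Points drawn before taking the hull, default 12.
#' @param radius Base radius in cm, default 2.5.
#' @return An [aperture_polygon()] (convex).
#' @export
synth_convex_polygon <- function(seed, n_points = 12L, radius = 2.5) {
  with_seed(seed, function() {
    theta <- sort(stats::runif(n_points, 0, 2 * pi))
    r <- radius * (0.6 + 0.4 * stats::runif(n_points))
    aspect <- 0.6 + 0.8 * stats::runif(1)
    x <- r * cos(theta)
    y <- r * sin(theta) * aspect
    h <- grDevices::chull(x, y)
    aperture_polygon(x[h], y[h])
  })
}
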