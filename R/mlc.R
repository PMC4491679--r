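#' Aperture polygon at the collimator plane
#'
#' A closed, simple (non-self-intersecting) polygon in isocenter-plane cm.
#' The two in-plane axes are called `x` and `y`; by the patient-coordinate
#' convention of a lateral beam, `y` is anterior--posterior and `x`
#' inferior--superior. A duplicated closing vertex is dropped; vertices are
#' reoriented counter-clockwise.
#'
#' @param x,y Vertex coordinates in cm (>= 3 distinct vertices).
#' @return Object of class `"aperture_polygon"`: a two-column matrix with
#'   attributes.
#' @export
aperture_polygon <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  v <- cbind(x = as.numeric(x), y = as.numeric(y))
  if (any(!is.finite(v))) stop("vertices must be finite", call. = FALSE)
  n <- nrow(v)
  if (n >= 2 && all(abs(v[1, ] - v[n, ]) < 1e-12)) v <- v[-n, , drop = FALSE]
  if (nrow(v) < 3L) stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  a <- signed_area(v)
  if (abs(a) < 1e-12) stop("degenerate polygon: zero enclosed area", call. = FALSE)
  if (a < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  if (!is_simple_polygon(v)) stop("polygon is self-intersecting", call. = FALSE)
  structure(v, class = "aperture_polygon")
}

signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (shoelace formula)
#'
#' @param poly An [aperture_polygon()] or two-column vertex matrix.
#' @return Enclosed area in cm^2.
#' @export
polygon_area <- function(poly) abs(signed_area(unclass(poly)))

# proper-crossing test over all non-adjacent edge pairs, vectorized over the
# partner edge; O(n^2) comparisons but O(n) R-level iterations
is_simple_polygon <- function(v) {
  n <- nrow(v)
  p1 <- v; p2 <- v[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 1):n
    js <- js[js != i + 1L & !(i == 1L & js == n)]  # skip shared-vertex pairs
    if (!length(js)) next
    aix <- p2[i, 1] - p1[i, 1]; aiy <- p2[i, 2] - p1[i, 2]
    d1 <- aix * (p1[js, 2] - p1[i, 2]) - aiy * (p1[js, 1] - p1[i, 1])
    d2 <- aix * (p2[js, 2] - p1[i, 2]) - aiy * (p2[js, 1] - p1[i, 1])
    bjx <- p2[js, 1] - p1[js, 1]; bjy <- p2[js, 2] - p1[js, 2]
    d3 <- bjx * (p1[i, 2] - p1[js, 2]) - bjy * (p1[i, 1] - p1[js, 1])
    d4 <- bjx * (p2[i, 2] - p1[js, 2]) - bjy * (p2[i, 1] - p1[js, 1])
    if (any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
            ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))) return(FALSE)
  }
  TRUE
}

# scanline crossings of the polygon boundary with constant-s lines, as flat
# (level index, crossing position) pairs. Half-open edge rule
# (s1 <= s < s2 or s2 <= s < s1) keeps crossing counts even at vertices.
scan_pairs <- function(v, levels, stack_axis = 2L) {
  s <- v[, stack_axis]; t <- v[, 3L - stack_axis]
  n <- length(s)
  s2 <- c(s[-1], s[1]); t2 <- c(t[-1], t[1])
  idx_all <- vector("list", n); val_all <- vector("list", n)
  for (e in seq_len(n)) {
    lo <- min(s[e], s2[e]); hi <- max(s[e], s2[e])
    if (lo == hi) next
    idx <- which(levels >= lo & levels < hi)
    if (!length(idx)) next
    idx_all[[e]] <- idx
    val_all[[e]] <- t[e] + (levels[idx] - s[e]) * (t2[e] - t[e]) / (s2[e] - s[e])
  }
  list(idx = unlist(idx_all), val = unlist(val_all), n_levels = length(levels))
}

# sorted crossing positions per level, as a list
scan_crossings <- function(v, levels, stack_axis = 2L) {
  p <- scan_pairs(v, levels, stack_axis)
  out <- rep(list(numeric(0)), p$n_levels)
  if (length(p$idx)) {
    sp <- split(p$val, p$idx)
    out[as.integer(names(sp))] <- lapply(sp, sort)
  }
  out
}

# NA-padded matrix of sorted crossings (rows = levels); NULL when any level
# crosses more than max_k times
scan_crossings_matrix <- function(v, levels, stack_axis = 2L, max_k = 2L) {
  p <- scan_pairs(v, levels, stack_axis)
  if (!length(p$idx)) return(matrix(NA_real_, p$n_levels, max_k))
  if (max(tabulate(p$idx, nbins = p$n_levels)) > max_k) return(NULL)
  ord <- order(p$idx, p$val)
  idx_s <- p$idx[ord]; val_s <- p$val[ord]
  pos <- stats::ave(val_s, idx_s, FUN = seq_along)
  m <- matrix(NA_real_, p$n_levels, max_k)
  m[cbind(idx_s, pos)] <- val_s
  m
}

#' Fit static MLC leaf positions to an aperture polygon
#'
#' One leaf pair per row of width `leaf_width` stacked along the chosen axis.
#' Each open leaf's tips are placed where the horizontal line through the
#' midpoint of the leaf edge crosses the aperture boundary, so the midpoint
#' of each leaf edge lies exactly on the aperture line. Rows whose midpoint
#' line misses the polygon are closed. When the midline crosses the boundary
#' more than twice (non-convex apertures), the outermost crossings are used
#' (a single pair of leaves per row).
#'
#' @param poly An [aperture_polygon()].
#' @param leaf_width Leaf width in cm, default 0.5.
#' @param orientation Stacking axis: `"y"` (default; leaves travel along x)
#'   or `"x"`.
#' @param anchor Position of the lowest leaf boundary along the stacking
#'   axis; default the polygon's minimum extent, so the leaf grid starts at
#'   the aperture edge. Any numeric value at or below the polygon minimum is
#'   accepted, exposing alternative leaf-grid registrations.
#' @return Object of class `"leaf_bank"`: data.frame with columns `row_min`,
#'   `row_max`, `left_tip`, `right_tip`, `open` (closed rows carry `NA`
#'   tips), with attributes `leaf_width`, `orientation`, `anchor`.
#' @examples
#' sq <- aperture_polygon(c(-2, 2, 2, -2), c(-1, -1, 1, 1))
#' fit_leaf_positions(sq, leaf_width = 0.5)
#' @export
fit_leaf_positions <- function(poly, leaf_width = 0.5,
                               orientation = c("y", "x"), anchor = NULL) {
  stopifnot(inherits(poly, "aperture_polygon"))
  orientation <- match.arg(orientation)
  if (length(leaf_width) != 1L || !is.finite(leaf_width) || leaf_width <= 0)
    stop("leaf_width must be a single positive number", call. = FALSE)
  v <- unclass(poly)
  axis <- if (orientation == "y") 2L else 1L
  s <- v[, axis]
  s_min <- min(s); s_max <- max(s)
  if (is.null(anchor)) anchor <- s_min
  if (anchor > s_min + 1e-12)
    stop("anchor must not lie above the polygon's minimum extent", call. = FALSE)
  n_rows <- max(1L, ceiling((s_max - anchor) / leaf_width - 1e-12))
  row_min <- anchor + (seq_len(n_rows) - 1) * leaf_width
  row_mid <- row_min + leaf_width / 2
  cr <- scan_crossings(v, row_mid, stack_axis = axis)
  open <- lengths(cr) >= 2L
  left <- right <- rep(NA_real_, n_rows)
  left[open] <- vapply(cr[open], min, numeric(1))
  right[open] <- vapply(cr[open], max, numeric(1))
  bank <- data.frame(row_min = row_min, row_max = row_min + leaf_width,
                     left_tip = left, right_tip = right, open = open)
  structure(bank, class = c("leaf_bank", "data.frame"),
            leaf_width = leaf_width, orientation = orientation, anchor = anchor)
}

# per-level symmetric-difference length between the polygon cross-section
# (union of intervals from even-odd pairing) and the leaf interval
symdiff_length_general <- function(crossings, l, r) {
  k <- length(crossings)
  if (k %% 2L == 1L) crossings <- crossings[-k]  # grazing contact; measure zero
  pts <- if (is.na(l)) crossings else c(crossings, l, r)
  if (!length(pts)) return(0)
  pts <- sort(unique(pts))
  if (length(pts) < 2L) return(0)
  mids <- (pts[-1] + pts[-length(pts)]) / 2
  in_poly <- (findInterval(mids, crossings) %% 2L) == 1L
  in_leaf <- if (is.na(l)) rep(FALSE, length(mids)) else (mids >= l & mids <= r)
  sum((pts[-1] - pts[-length(pts)])[xor(in_poly, in_leaf)])
}

#' Scalloping area error of a fitted leaf bank
#'
#' Area of the symmetric difference between the aperture polygon and the
#' union of open-leaf rectangles, in cm^2. Computed by one-dimensional
#' quadrature along the stacking axis: at each sample level the
#' symmetric-difference length between the polygon cross-section and the
#' leaf interval is exact, and levels are sampled at midpoint spacing `ds`.
#'
#' @param poly The [aperture_polygon()] the bank was fitted to.
#' @param bank A [fit_leaf_positions()] result.
#' @param ds Quadrature step along the stacking axis in cm, default 2e-3.
#' @return Symmetric-difference area in cm^2 (>= 0).
#' @export
aperture_area_error <- function(poly, bank, ds = 2e-3) {
  stopifnot(inherits(poly, "aperture_polygon"), inherits(bank, "leaf_bank"))
  v <- unclass(poly)
  axis <- if (attr(bank, "orientation") == "y") 2L else 1L
  lo <- min(min(v[, axis]), min(bank$row_min))
  hi <- max(max(v[, axis]), max(bank$row_max))
  levels <- seq(lo + ds / 2, hi, by = ds)
  # leaf interval at each level
  ri <- findInterval(levels, c(bank$row_min[1], bank$row_max))
  ri[ri < 1L | ri > nrow(bank)] <- NA_integer_
  l <- bank$left_tip[ri]; r <- bank$right_tip[ri]
  m <- scan_crossings_matrix(v, levels, stack_axis = axis, max_k = 2L)
  if (!is.null(m)) {
    L <- m[, 1]; R <- m[, 2]
    has_p <- !is.na(R); has_l <- !is.na(l)
    len <- numeric(length(levels))
    both <- has_p & has_l
    ov <- pmax(0, pmin(R[both], r[both]) - pmax(L[both], l[both]))
    len[both] <- (R[both] - L[both]) + (r[both] - l[both]) - 2 * ov
    len[has_p & !has_l] <- R[has_p & !has_l] - L[has_p & !has_l]
    len[!has_p & has_l] <- r[!has_p & has_l] - l[!has_p & has_l]
    return(sum(len) * ds)
  }
  cr <- scan_crossings(v, levels, stack_axis = axis)
  sum(vapply(seq_along(levels), function(i)
    symdiff_length_general(cr[[i]], l[i], r[i]), numeric(1))) * ds
}

#' Rasterization oracle for the scalloping area error
#'
#' Independent two-dimensional estimate of the symmetric-difference area:
#' the plane is rasterized at `cell` cm, each cell center is classified
#' inside/outside the polygon (even-odd rule) and inside/outside the
#' open-leaf union, and disagreeing cells are counted. Used to cross-check
#' [aperture_area_error()]; quadratically slower, kept deliberately separate
#' from it.
#'
#' @inheritParams aperture_area_error
#' @param cell Raster cell size in cm, default 0.01.
#' @return Estimated symmetric-difference area in cm^2.
#' @export
rasterize_area_error <- function(poly, bank, cell = 0.01) {
  stopifnot(inherits(poly, "aperture_polygon"), inherits(bank, "leaf_bank"))
  v <- unclass(poly)
  axis <- if (attr(bank, "orientation") == "y") 2L else 1L
  s_rng <- range(c(v[, axis], bank$row_min, bank$row_max))
  t_rng <- range(c(v[, 3L - axis], bank$left_tip, bank$right_tip), na.rm = TRUE)
  ss <- seq(s_rng[1] + cell / 2, s_rng[2], by = cell)
  ts <- seq(t_rng[1] + cell / 2, t_rng[2], by = cell)
  sv <- rep(ss, each = length(ts))
  tv <- rep(ts, times = length(ss))
  px <- if (axis == 2L) tv else sv
  py <- if (axis == 2L) sv else tv
  in_poly <- point_in_polygon(px, py, poly)
  ri <- findInterval(sv, c(bank$row_min[1], bank$row_max))
  ri[ri < 1L | ri > nrow(bank)] <- NA_integer_
  l <- bank$left_tip[ri]; r <- bank$right_tip[ri]
  in_bank <- !is.na(l) & tv >= l & tv <= r
  sum(xor(in_poly, in_bank)) * cell^2
}

#' Even-odd point-in-polygon test
#'
#' @param px,py Point coordinates (vectorized).
#' @param poly An [aperture_polygon()] or vertex matrix.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  v <- unclass(poly)
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    hit <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit)
    j <- i
  }
  inside
}

#' Fit both leaf-stacking orientations
#'
#' Fits the leaf bank with leaves stacked along each in-plane axis and
#' reports the scalloping area error of each, for assessing the impact of
#' leaf orientation with respect to the patient.
#'
#' @inheritParams fit_leaf_positions
#' @param ds Quadrature step for the area errors (see
#'   [aperture_area_error()]).
#' @return List with elements `y` and `x`, each a list `bank`, `area_error`.
#' @export
orientation_variants <- function(poly, leaf_width = 0.5, ds = 2e-3) {
  out <- lapply(c(y = "y", x = "x"), function(o) {
    bank <- fit_leaf_positions(poly, leaf_width, orientation = o)
    list(bank = bank, area_error = aperture_area_error(poly, bank, ds = ds))
  })
  out
}

#' Polygon and leaf-bank file I/O
#'
#' Polygons are CSV with header `x_cm,y_cm`, one vertex per row; leaf banks
#' are CSV with header `row_min,row_max,left_tip,right_tip,open`.
#'
#' @param path File path.
#' @return `read_polygon_csv`: an [aperture_polygon()].
#' @export
read_polygon_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x_cm", "y_cm") %in% names(d)))
    stop("polygon CSV needs columns x_cm, y_cm", call. = FALSE)
  aperture_polygon(d$x_cm, d$y_cm)
}

#' @rdname read_polygon_csv
#' @param poly An [aperture_polygon()].
#' @export
write_polygon_csv <- function(poly, path) {
  v <- unclass(poly)
  utils::write.csv(data.frame(x_cm = v[, 1], y_cm = v[, 2]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_polygon_csv
#' @param bank A [fit_leaf_positions()] result.
#' @export
write_leaf_bank_csv <- function(bank, path) {
  utils::write.csv(as.data.frame(bank), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
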