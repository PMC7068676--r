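# Visual outputs (binary z-projection, hue-coded orientation projection)
# and quantitative order statistics for comparing fields.

resolve_z_range <- function(z_range, n_sections) {
  if (is.null(z_range)) return(0:(n_sections - 1L))
  z_range <- as.integer(z_range)
  if (length(z_range) != 2L || z_range[1] > z_range[2])
    stop("z_range must be c(first, last), first <= last (0-based)")
  if (z_range[1] < 0L || z_range[2] >= n_sections)
    stop(sprintf("z_range [%d, %d] outside stack with %d sections",
                 z_range[1], z_range[2], n_sections))
  z_range[1]:z_range[2]
}

#' Binary z-projection of a trace stack or orientation map
#'
#' Per-pixel maximum over the selected optical sections: a pixel is
#' foreground if it is foreground in any selected plane. Given an
#' orientation map, only retained segment pixels project (branch pixels and
#' discarded debris do not).
#'
#' @param x a \code{\link{trace_stack}} or \code{\link{orientation_map}}.
#' @param z_range optional 0-based inclusive section interval
#'   \code{c(first, last)}; default all sections.
#' @return Binary matrix (0/1) of the stack's height x width.
#' @export
project_binary <- function(x, z_range = NULL) UseMethod("project_binary")

#' @export
project_binary.trace_stack <- function(x, z_range = NULL) {
  zi <- resolve_z_range(z_range, x$geometry$n_sections)
  out <- matrix(0L, x$dim[1], x$dim[2])
  for (i in zi) out <- pmax(out, x$planes[[i + 1L]])
  out
}

#' @export
project_binary.orientation_map <- function(x, z_range = NULL) {
  zi <- resolve_z_range(z_range, x$n_sections)
  out <- matrix(0L, x$dim[1], x$dim[2])
  for (s in x$segments) {
    if (s$plane_index %in% zi)
      out[cbind(s$pixels[, "y"] + 1L, s$pixels[, "x"] + 1L)] <- 1L
  }
  out
}

#' Hue look-up table for orientation bins (rainbow ruler)
#'
#' Maps each of \code{n_bins} orientation bins to a fully saturated color
#' whose HSV hue varies monotonically from \code{start_hue} to
#' \code{end_hue}. The default 0 (red) to 300 (magenta) sweep keeps the
#' first and last bins visually distinct despite the axial wrap at 180
#' degrees.
#'
#' @param n_bins number of bins (default 32).
#' @param start_hue,end_hue HSV hue endpoints in degrees.
#' @return Object of class \code{"hue_lut"}: \code{rgb} (n_bins x 3 matrix
#'   in [0, 1]), \code{hex}, \code{hues}, \code{n_bins}.
#' @export
hue_lut <- function(n_bins = 32L, start_hue = 0, end_hue = 300) {
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (start_hue == end_hue && n_bins > 1L)
    stop("degenerate hue range: entries would not be distinct")
  hues <- seq(start_hue, end_hue, length.out = n_bins) %% 360
  hex <- grDevices::hsv(hues / 360, 1, 1)
  if (anyDuplicated(hex)) stop("hue range yields duplicate LUT entries")
  structure(list(rgb = t(grDevices::col2rgb(hex)) / 255,
                 hex = hex, hues = hues,
                 n_bins = as.integer(n_bins),
                 start_hue = start_hue, end_hue = end_hue),
            class = "hue_lut")
}

#' @export
print.hue_lut <- function(x, ...) {
  cat(sprintf("Hue LUT: %d bins, hue %g -> %g deg\n", x$n_bins,
              x$start_hue, x$end_hue))
  invisible(x)
}

#' Render a ruler strip image for a hue LUT
#'
#' A 1-row-per-pixel-high color strip running bin 0 (angle 0) to the last
#' bin (angle just below 180), for figure legends.
#'
#' @param lut a \code{\link{hue_lut}}.
#' @param height strip height in pixels (default 12).
#' @param px_per_bin strip width per bin in pixels (default 8).
#' @return RGB array (height x width x 3, values in [0, 1]).
#' @export
lut_ruler <- function(lut, height = 12L, px_per_bin = 8L) {
  stopifnot(inherits(lut, "hue_lut"))
  w <- lut$n_bins * px_per_bin
  arr <- array(0, c(height, w, 3))
  for (b in seq_len(lut$n_bins)) {
    cols <- ((b - 1L) * px_per_bin + 1L):(b * px_per_bin)
    for (ch in 1:3) arr[, cols, ch] <- lut$rgb[b, ch]
  }
  arr
}

DEGENERATE_GRAY <- 0.5  # reserved neutral gray for axis-less segments

#' Hue-coded orientation projection
#'
#' Projects every retained segment into a single RGB image, painting each
#' pixel with its segment's orientation-bin color. Degenerate segments
#' (no preferred axis) are painted a reserved neutral gray; the background
#' is black. Where segments from different planes overlap in projection the
#' topmost plane (largest section index) wins.
#'
#' @param map an \code{\link{orientation_map}}.
#' @param lut a \code{\link{hue_lut}} with \code{n_bins} matching the map.
#' @param z_range optional 0-based inclusive section interval.
#' @return RGB array (height x width x 3, values in [0, 1]).
#' @export
render_colored_projection <- function(map, lut = hue_lut(map$n_bins),
                                      z_range = NULL) {
  stopifnot(inherits(map, "orientation_map"), inherits(lut, "hue_lut"))
  if (lut$n_bins != map$n_bins)
    stop(sprintf("configuration error: LUT has %d entries but map uses %d bins",
                 lut$n_bins, map$n_bins))
  zi <- resolve_z_range(z_range, map$n_sections)
  img <- array(0, c(map$dim[1], map$dim[2], 3))
  segs <- map$segments
  ord <- order(vapply(segs, `[[`, integer(1), "plane_index"))  # topmost last
  for (s in segs[ord]) {
    if (!(s$plane_index %in% zi)) next
    col <- if (s$degenerate) rep(DEGENERATE_GRAY, 3) else lut$rgb[s$bin_index + 1L, ]
    idx <- cbind(s$pixels[, "y"] + 1L, s$pixels[, "x"] + 1L)
    for (ch in 1:3) img[cbind(idx, ch)] <- col[ch]
  }
  img
}

#' Write an RGB projection as 8-bit PNG
#' @param img RGB array from \code{\link{render_colored_projection}} or
#'   \code{\link{lut_ruler}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_projection_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' Write a binary projection as single-page TIFF
#' @param img binary matrix from \code{\link{project_binary}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_projection_tiff <- function(img, path) {
  tiff::writeTIFF(matrix(as.double(img), nrow(img), ncol(img)), path,
                  bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Angular histogram of segment orientations
#'
#' Counts non-degenerate segments per orientation bin, either one count per
#' segment (default; each traced fiber is one unit) or weighting each
#' segment by its pixel count (longer fibers count more).
#'
#' @param map an \code{\link{orientation_map}}.
#' @param weighting \code{"segment"} or \code{"pixel"}.
#' @return Object of class \code{"angular_histogram"}: \code{counts}
#'   (length \code{n_bins}, bin 0 first), \code{weighting}, \code{total},
#'   \code{n_bins}, \code{bin_width_deg}.
#' @export
angular_histogram <- function(map, weighting = c("segment", "pixel")) {
  stopifnot(inherits(map, "orientation_map"))
  weighting <- match.arg(weighting)
  counts <- numeric(map$n_bins)
  for (s in map$segments) {
    if (s$degenerate) next
    w <- if (weighting == "segment") 1 else s$pixel_count
    counts[s$bin_index + 1L] <- counts[s$bin_index + 1L] + w
  }
  structure(list(counts = counts, weighting = weighting,
                 total = sum(counts), n_bins = map$n_bins,
                 bin_width_deg = 180 / map$n_bins),
            class = "angular_histogram")
}

#' @export
print.angular_histogram <- function(x, ...) {
  cat(sprintf("Angular histogram: %d bins of %.4g deg, %s weighting, total %g\n",
              x$n_bins, x$bin_width_deg, x$weighting, x$total))
  occ <- which(x$counts > 0)
  if (length(occ))
    cat(paste(sprintf("  bin %2d [%6.2f, %6.2f): %g", occ - 1L,
                      (occ - 1L) * x$bin_width_deg, occ * x$bin_width_deg,
                      x$counts[occ]), collapse = "\n"), "\n")
  invisible(x)
}

#' Nematic order parameter and mean axis of an orientation field
#'
#' Axial (180-degree-periodic) circular statistics on the doubled angles
#' phi = 2 * theta: with weights w,
#' S = |sum w * exp(i phi)| / sum w  and
#' mean_axis = arg(sum w * exp(i phi)) / 2 mapped to [0, 180).
#' S = 1 for perfectly parallel orientations, 0 for an isotropic field.
#'
#' @param x an \code{\link{orientation_map}}, or a numeric vector of axial
#'   angles in degrees.
#' @param ... passed to methods.
#' @return Object of class \code{"axial_order_summary"}:
#'   \code{order_parameter} (S in [0, 1]), \code{mean_axis_deg} (in
#'   [0, 180), \code{NA} when S = 0), \code{n}, \code{weighting}.
#' @export
#' @examples
#' axial_order(c(37, 37, 37))$order_parameter  # 1
#' axial_order(c(0, 90))$order_parameter       # 0 (orthogonal cancellation)
axial_order <- function(x, ...) UseMethod("axial_order")

#' @rdname axial_order
#' @param weighting \code{"segment"} (w = 1 per segment) or \code{"pixel"}
#'   (w = pixel count).
#' @export
axial_order.orientation_map <- function(x, weighting = c("segment", "pixel"),
                                        ...) {
  weighting <- match.arg(weighting)
  keep <- !vapply(x$segments, `[[`, logical(1), "degenerate")
  ang <- vapply(x$segments, `[[`, numeric(1), "angle_deg")[keep]
  w <- if (weighting == "segment") rep(1, sum(keep))
       else vapply(x$segments, `[[`, integer(1), "pixel_count")[keep]
  out <- axial_order(ang, weights = w)
  out$weighting <- weighting
  out
}

#' @rdname axial_order
#' @param weights optional non-negative weights, one per angle.
#' @export
axial_order.numeric <- function(x, weights = NULL, ...) {
  x <- x[!is.na(x)]
  if (length(x) < 1L) stop("no usable (non-degenerate) angles")
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) != length(x) || any(weights < 0))
    stop("weights must be non-negative, one per angle")
  phi <- 2 * x * pi / 180
  C <- sum(weights * cos(phi)); S2 <- sum(weights * sin(phi))
  W <- sum(weights)
  if (W <= 0) stop("total weight must be positive")
  S <- sqrt(C^2 + S2^2) / W
  mean_axis <- if (S <= .Machine$double.eps) NA_real_
               else (atan2(S2, C) / 2 * 180 / pi) %% 180
  structure(list(order_parameter = min(S, 1), mean_axis_deg = mean_axis,
                 n = length(x), weighting = "custom"),
            class = "axial_order_summary")
}

#' @export
print.axial_order_summary <- function(x, ...) {
  cat(sprintf("Axial order: S = %.4f, mean axis = %s, n = %d (%s weighting)\n",
              x$order_parameter,
              if (is.na(x$mean_axis_deg)) "undefined"
              else sprintf("%.2f deg", x$mean_axis_deg),
              x$n, x$weighting))
  invisible(x)
}

#' Compare orientational order between two fields
#'
#' Side-by-side angular histograms and nematic order summaries for two
#' orientation maps (e.g. control vs mutant specimens), with the difference
#' in order parameter Delta S = S_a - S_b. No inferential p-value is
#' attached: the comparison is descriptive.
#'
#' @param map_a,map_b \code{\link{orientation_map}}s with equal
#'   \code{n_bins}.
#' @param weighting \code{"segment"} or \code{"pixel"}.
#' @return Object of class \code{"orientation_comparison"}: per-map
#'   summaries and histograms, \code{delta_S}.
#' @export
compare_conditions <- function(map_a, map_b,
                               weighting = c("segment", "pixel")) {
  stopifnot(inherits(map_a, "orientation_map"),
            inherits(map_b, "orientation_map"))
  if (map_a$n_bins != map_b$n_bins)
    stop(sprintf("configuration error: n_bins differ (%d vs %d)",
                 map_a$n_bins, map_b$n_bins))
  weighting <- match.arg(weighting)
  oa <- axial_order(map_a, weighting); ob <- axial_order(map_b, weighting)
  structure(list(label_a = map_a$label, label_b = map_b$label,
                 order_a = oa, order_b = ob,
                 histogram_a = angular_histogram(map_a, weighting),
                 histogram_b = angular_histogram(map_b, weighting),
                 delta_S = oa$order_parameter - ob$order_parameter,
                 weighting = weighting),
            class = "orientation_comparison")
}

#' @export
print.orientation_comparison <- function(x, ...) {
  cat("Orientation comparison (", x$weighting, " weighting)\n", sep = "")
  cat(sprintf("  A%s: S = %.4f (n = %d)\n",
              if (nzchar(x$label_a)) paste0(" '", x$label_a, "'") else "",
              x$order_a$order_parameter, x$order_a$n))
  cat(sprintf("  B%s: S = %.4f (n = %d)\n",
              if (nzchar(x$label_b)) paste0(" '", x$label_b, "'") else "",
              x$order_b$order_parameter, x$order_b$n))
  cat(sprintf("  Delta S = %.4f\n", x$delta_S))
  invisible(x)
}

#' Write an angular histogram as delimiter-separated text
#' @param hist an \code{\link{angular_histogram}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "angular_histogram"))
  df <- data.frame(bin_index = seq_len(hist$n_bins) - 1L,
                   angle_lo_deg = (seq_len(hist$n_bins) - 1L) * hist$bin_width_deg,
                   angle_hi_deg = seq_len(hist$n_bins) * hist$bin_width_deg,
                   count = hist$counts)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
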