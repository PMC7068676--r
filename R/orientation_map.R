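#' Fiber orientation map of a trace stack
#'
#' The central pipeline step: decomposes every binary plane of a stack into
#' individual fiber segments (optional thinning, one branch-point removal
#' pass, connected-component labeling, length filter), computes each
#' segment's second-order central moments and principal-axis orientation,
#' and normalises angles to [0, 180) in \code{n_bins} equal-width bins.
#'
#' @param stack a \code{\link{trace_stack}}.
#' @param n_bins number of angular bins spanning 0-180 degrees (default 32).
#' @param min_segment_length minimum pixels per retained segment (default 5;
#'   suppresses junction debris while keeping short myocyte traces).
#' @param connectivity pixel connectivity, 4 or 8 (default 8).
#' @param thin thin planes to 1-pixel width before decomposition
#'   (default FALSE; drawn-line traces are already 1 pixel wide).
#' @return An object of class \code{"orientation_map"}: \code{label},
#'   \code{dim}, \code{n_sections}, \code{n_bins}, \code{params},
#'   \code{segments} (annotated fiber segments), \code{n_degenerate},
#'   \code{dropped} (per-plane discard tallies),
#'   \code{removed_branch_pixels}.
#' @seealso \code{\link{angular_histogram}}, \code{\link{axial_order}},
#'   \code{\link{render_colored_projection}}, \code{\link{project_binary}}
#' @export
#' @examples
#' pl <- matrix(0L, 20, 20); pl[10, 3:17] <- 1L  # horizontal line
#' st <- trace_stack(list(pl))
#' m <- orientation_map(st)
#' as.data.frame(m)  # one segment at 0 degrees, bin 0
orientation_map <- function(stack, n_bins = 32L, min_segment_length = 5L,
                            connectivity = 8L, thin = FALSE) {
  stopifnot(inherits(stack, "trace_stack"))
  if (n_bins < 1L) stop("n_bins must be >= 1")
  segs <- decompose_stack(stack, min_segment_length = min_segment_length,
                          connectivity = connectivity, thin = thin)
  ann <- annotate_segments(segs, n_bins = n_bins)
  # invariant check: bin consistent with angle for every non-degenerate seg
  for (s in ann) {
    if (!s$degenerate &&
        s$bin_index != floor(s$angle_deg / (180 / n_bins)) %% n_bins)
      stop("internal error: bin_index inconsistent with angle_deg")
  }
  structure(list(label = stack$label,
                 dim = stack$dim,
                 n_sections = stack$geometry$n_sections,
                 n_bins = as.integer(n_bins),
                 params = list(min_segment_length = min_segment_length,
                               connectivity = connectivity, thin = thin),
                 segments = ann,
                 n_degenerate = attr(ann, "n_degenerate"),
                 dropped = attr(segs, "dropped"),
                 removed_branch_pixels = attr(segs, "removed_branch_pixels")),
            class = "orientation_map")
}

#' @export
print.orientation_map <- function(x, ...) {
  cat(sprintf("Fiber orientation map%s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else ""))
  cat(sprintf("  %d x %d px, %d sections; %d segments (%d degenerate), %d bins over 0-180 deg\n",
              x$dim[1], x$dim[2], x$n_sections, length(x$segments),
              x$n_degenerate, x$n_bins))
  cat(sprintf("  discarded: %d sub-threshold components (%d px), %d branch pixels removed\n",
              sum(x$dropped[, "components"]), sum(x$dropped[, "pixels"]),
              sum(x$removed_branch_pixels)))
  invisible(x)
}

#' @export
as.data.frame.orientation_map <- function(x, ...) {
  segs <- x$segments
  if (length(segs) == 0L) {
    return(data.frame(segment_id = integer(0), plane_index = integer(0),
                      pixel_count = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), mu20 = numeric(0),
                      mu02 = numeric(0), mu11 = numeric(0),
                      angle_deg = numeric(0), bin_index = integer(0)))
  }
  data.frame(
    segment_id = vapply(segs, `[[`, integer(1), "segment_id"),
    plane_index = vapply(segs, `[[`, integer(1), "plane_index"),
    pixel_count = vapply(segs, `[[`, integer(1), "pixel_count"),
    centroid_x = vapply(segs, function(s) s$moments$centroid_x, numeric(1)),
    centroid_y = vapply(segs, function(s) s$moments$centroid_y, numeric(1)),
    mu20 = vapply(segs, function(s) s$moments$mu20, numeric(1)),
    mu02 = vapply(segs, function(s) s$moments$mu02, numeric(1)),
    mu11 = vapply(segs, function(s) s$moments$mu11, numeric(1)),
    angle_deg = vapply(segs, `[[`, numeric(1), "angle_deg"),
    bin_index = vapply(segs, `[[`, integer(1), "bin_index"))
}

#' @export
summary.orientation_map <- function(object, weighting = c("segment", "pixel"),
                                    ...) {
  weighting <- match.arg(weighting)
  h <- angular_histogram(object, weighting)
  ord <- if (length(object$segments) - object$n_degenerate > 0)
    axial_order(object, weighting) else NULL
  structure(list(map = object, histogram = h, order = ord),
            class = "summary.orientation_map")
}

#' @export
print.summary.orientation_map <- function(x, ...) {
  print(x$map)
  if (is.null(x$order)) {
    cat("  no non-degenerate segments; order statistics unavailable\n")
  } else {
    cat(sprintf("  nematic order parameter S = %.4f, mean axis = %s deg (%s weighting)\n",
                x$order$order_parameter,
                if (is.na(x$order$mean_axis_deg)) "undefined"
                else sprintf("%.2f", x$order$mean_axis_deg),
                x$order$weighting))
    occ <- which(x$histogram$counts > 0) - 1L
    cat(sprintf("  occupied bins (%d of %d): %s\n", length(occ),
                x$map$n_bins, paste(occ, collapse = " ")))
  }
  invisible(x)
}

#' Plot an orientation map as its hue-coded projection
#'
#' Renders the color-coded z-projection (every segment painted by its
#' orientation bin's hue) and displays it with a rainbow ruler legend
#' along the bottom edge.
#'
#' @param x an \code{\link{orientation_map}}.
#' @param lut a \code{\link{hue_lut}}; defaults to the 32-bin rainbow.
#' @param z_range optional 0-based inclusive section interval
#'   \code{c(first, last)}.
#' @param ruler draw the hue ruler legend (default TRUE).
#' @param ... passed to \code{\link[graphics]{rasterImage}}.
#' @return Invisibly, the rendered RGB array.
#' @export
plot.orientation_map <- function(x, lut = hue_lut(x$n_bins), z_range = NULL,
                                 ruler = TRUE, ...) {
  img <- render_colored_projection(x, lut = lut, z_range = z_range)
  op <- graphics::par(mar = c(if (ruler) 3 else 0.5, 0.5, 1.5, 0.5))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1), asp = ncol(img) / nrow(img))
  graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE, ...)
  graphics::title(main = if (nzchar(x$label)) x$label else "orientation map")
  if (ruler) {
    strip <- lut_ruler(lut, height = 1L)
    graphics::rasterImage(strip, 0.1, -0.12, 0.9, -0.07,
                          interpolate = FALSE, xpd = NA)
    graphics::text(c(0.1, 0.9), -0.15, c("0°", "180°"), xpd = NA,
                   cex = 0.8)
  }
  invisible(img)
}
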