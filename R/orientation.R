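# Axial orientation of a fiber segment from its second-order central
# moments. Angles live on the axial circle [0, 180): a fiber at theta and
# theta + 180 is the same orientation. Frame: image coordinates, x = column
# rightward, y = row downward, angle measured from +x toward +y.

#' Second-order central moments of a pixel set
#'
#' Unweighted moments over the segment's pixels (each pixel counts once;
#' drawn traces carry no intensity): with centroid (xbar, ybar),
#' mu20 = sum (x - xbar)^2, mu02 = sum (y - ybar)^2,
#' mu11 = sum (x - xbar)(y - ybar).
#'
#' @param pixels 2-column matrix (or data frame) of (x, y) coordinates;
#'   real-valued coordinates are accepted.
#' @return List of class \code{"central_moments"}: \code{centroid_x},
#'   \code{centroid_y}, \code{mu20}, \code{mu02}, \code{mu11},
#'   \code{pixel_count}.
#' @export
#' @examples
#' central_moments(cbind(x = 0:2, y = c(0, 0, 0)))  # mu20 = 2, mu02 = 0
central_moments <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L) stop("pixel list must be nonempty")
  x <- pixels[, 1L]; y <- pixels[, 2L]
  xbar <- mean(x); ybar <- mean(y)
  structure(list(centroid_x = xbar, centroid_y = ybar,
                 mu20 = sum((x - xbar)^2),
                 mu02 = sum((y - ybar)^2),
                 mu11 = sum((x - xbar) * (y - ybar)),
                 pixel_count = nrow(pixels)),
            class = "central_moments")
}

#' Principal-axis orientation from second-order central moments
#'
#' The axis of maximal variance of the pixel set:
#' theta = 1/2 * atan2(2 * mu11, mu20 - mu02), mapped into [0, 180).
#' The atan2 form is branch-free at mu20 = mu02 and identical to the
#' leading eigenvector of the covariance matrix. A segment with fewer than
#' two pixels, or with an isotropic moment tensor
#' (|mu20 - mu02| and |mu11| both below 1e-9 * pixel_count), has no
#' preferred axis and is flagged degenerate.
#'
#' @param m a \code{\link{central_moments}} object.
#' @return List of class \code{"axial_angle"}: \code{angle_deg} in
#'   [0, 180) or \code{NA} when degenerate, \code{degenerate} flag,
#'   \code{bin_index} (unassigned, \code{NA}).
#' @export
orientation_angle <- function(m) {
  stopifnot(inherits(m, "central_moments"))
  tol <- 1e-9 * max(1, m$pixel_count)
  if (m$pixel_count < 2L ||
      (abs(m$mu20 - m$mu02) < tol && abs(m$mu11) < tol)) {
    return(structure(list(angle_deg = NA_real_, degenerate = TRUE,
                          bin_index = NA_integer_, n_bins = NA_integer_),
                     class = "axial_angle"))
  }
  theta <- 0.5 * atan2(2 * m$mu11, m$mu20 - m$mu02) * 180 / pi
  theta <- theta %% 180
  if (theta >= 180) theta <- 0  # guard against fp landing exactly on 180
  structure(list(angle_deg = theta, degenerate = FALSE,
                 bin_index = NA_integer_, n_bins = NA_integer_),
            class = "axial_angle")
}

#' Normalise an angle to the axial range and assign its orientation bin
#'
#' Reduces any finite angle modulo 180 into [0, 180) and assigns the
#' half-open equal-width bin floor(angle / (180 / n_bins)); 180 wraps to
#' bin 0 (axial topology). The default 32 bins give a width of 5.625
#' degrees.
#'
#' @param angle_deg finite angle in degrees (any real).
#' @param n_bins number of bins >= 1 (default 32).
#' @return List of class \code{"axial_angle"} with \code{angle_deg} in
#'   [0, 180), \code{bin_index} in [0, n_bins), \code{n_bins}.
#' @export
#' @examples
#' normalize_and_bin(180)$bin_index   # 0  (axial wrap)
#' normalize_and_bin(5.625)$bin_index # 1
normalize_and_bin <- function(angle_deg, n_bins = 32L) {
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (!is.finite(angle_deg)) stop("angle_deg must be finite")
  a <- angle_deg %% 180
  if (a >= 180) a <- 0
  b <- floor(a / (180 / n_bins))
  if (b >= n_bins) b <- n_bins - 1L  # fp guard at the upper edge of a bin
  structure(list(angle_deg = a, degenerate = FALSE,
                 bin_index = as.integer(b), n_bins = as.integer(n_bins)),
            class = "axial_angle")
}

#' Annotate fiber segments with moments, axial angle and bin
#'
#' Computes \code{\link{central_moments}} and
#' \code{\link{orientation_angle}} for every segment and assigns
#' orientation bins. Degenerate segments (single pixels, isotropic remnants)
#' are retained but flagged; downstream histograms and order statistics
#' exclude them.
#'
#' @param segments list of \code{fiber_segment}s from
#'   \code{\link{decompose_stack}} or \code{\link{extract_segments}}.
#' @param n_bins number of angular bins (default 32).
#' @return The segments, each gaining \code{moments}, \code{angle_deg},
#'   \code{degenerate} and \code{bin_index}; attribute
#'   \code{"n_degenerate"} counts flagged segments.
#' @export
annotate_segments <- function(segments, n_bins = 32L) {
  n_deg <- 0L
  out <- lapply(segments, function(seg) {
    m <- central_moments(seg$pixels)
    a <- orientation_angle(m)
    seg$moments <- m
    seg$degenerate <- a$degenerate
    if (a$degenerate) {
      seg$angle_deg <- NA_real_
      seg$bin_index <- NA_integer_
    } else {
      ab <- normalize_and_bin(a$angle_deg, n_bins)
      seg$angle_deg <- ab$angle_deg
      seg$bin_index <- ab$bin_index
    }
    seg
  })
  attr(out, "dropped") <- attr(segments, "dropped")
  attr(out, "n_degenerate") <-
    sum(vapply(out, function(s) s$degenerate, logical(1)))
  out
}
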