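# Seeded synthetic fiber fields with per-fiber ground truth: spatial
# clusters of short line segments, each cluster with a mean axial
# orientation and a von Mises angular dispersion, rasterized as
# 1-pixel-wide digital lines into binary stacks. Emulates manually traced
# myocyte fields ranging from isotropic (kappa = 0) to strongly aligned.

KAPPA_CAP <- 1e8  # above this the distribution is treated as a point mass

# Best-Fisher rejection sampler for the von Mises distribution on [0, 2*pi)
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(16L, ceiling((n - got) * 1.5))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    acc <- (sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1)) + mu)
    take <- min(length(acc), n - got)
    if (take > 0L) out[(got + 1L):(got + take)] <- acc[seq_len(take)]
    got <- got + take
  }
  out %% (2 * pi)
}

#' Sample axial orientations with von Mises dispersion
#'
#' Draws theta in [0, 180) such that the doubled angle 2*theta follows a
#' von Mises distribution with mean 2*mean_axis_deg and concentration
#' kappa — the standard construction for axial (nematic) data.
#' kappa = 0 gives angles uniform on [0, 180); kappa at or above the cap
#' of 1e8 is the zero-dispersion limit and returns the mean axis exactly.
#' Uses R's global random number generator; seed with
#' \code{\link{set.seed}} for reproducibility.
#'
#' @param mean_axis_deg mean axis in degrees.
#' @param kappa concentration >= 0.
#' @param n number of draws (default 1).
#' @return Numeric vector of angles in [0, 180).
#' @export
sample_axial_angle <- function(mean_axis_deg, kappa, n = 1L) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa >= KAPPA_CAP) return(rep(mean_axis_deg %% 180, n))
  phi <- rvonmises(n, 2 * mean_axis_deg * pi / 180, kappa)
  (phi / 2 * 180 / pi) %% 180
}

#' Rasterize one fiber as an 8-connected digital line
#'
#' Converts (center, axial angle, length) into the two implied real-valued
#' endpoints and draws the 1-pixel-wide digital line between them (a
#' Bresenham-style midpoint walk: the exact segment is sampled at unit
#' steps along its driving axis and each sample rounded to the nearest
#' pixel, which keeps the chain 8-connected and free of the angle bias
#' that rounding the endpoints first would introduce for short fibers).
#' The result is clipped to the image bounds. This is the inverse of
#' tracing a line over the long axis of an elongated cell.
#'
#' @param center numeric (x, y), 0-based pixel coordinates.
#' @param angle_deg axial angle in degrees (from +x toward +y, y down).
#' @param length_px fiber length in pixels, >= 2.
#' @param dim image c(height, width).
#' @return Integer matrix with columns \code{x}, \code{y} (0-based);
#'   possibly fewer pixels than \code{length_px} after clipping.
#' @export
rasterize_fiber <- function(center, angle_deg, length_px, dim) {
  if (length_px < 2) stop("length_px must be >= 2")
  t <- angle_deg * pi / 180
  half <- (length_px - 1) / 2
  p0 <- c(center[1] - half * cos(t), center[2] - half * sin(t))
  p1 <- c(center[1] + half * cos(t), center[2] + half * sin(t))
  # exactly one pixel per integer step of the driving axis, the companion
  # coordinate interpolated on the exact line: the chain is 8-connected,
  # every interior pixel has exactly two neighbors, and no angle bias is
  # introduced by rounding the endpoints first
  d <- p1 - p0
  if (abs(d[1]) >= abs(d[2])) {
    xs <- round(p0[1]):round(p1[1])
    ys <- round(p0[2] + (xs - p0[1]) * d[2] / d[1])
  } else {
    ys <- round(p0[2]):round(p1[2])
    xs <- round(p0[1] + (ys - p0[2]) * d[1] / d[2])
  }
  px <- cbind(x = as.integer(xs), y = as.integer(ys))
  keep <- px[, "x"] >= 0L & px[, "x"] < dim[2] &
          px[, "y"] >= 0L & px[, "y"] < dim[1]
  px[keep, , drop = FALSE]
}

#' Specification of one fiber cluster
#'
#' A spatial group of fibers sharing a mean axial orientation: fiber
#' centers are placed uniformly in a rectangular region, angles are drawn
#' by \code{\link{sample_axial_angle}} around \code{mean_axis_deg} with
#' concentration \code{kappa}, lengths uniformly in \code{length_range}.
#'
#' @param mean_axis_deg cluster mean axis in [0, 180).
#' @param kappa angular concentration >= 0 (0 = isotropic).
#' @param n_fibers number of fibers >= 0.
#' @param region c(x0, y0, x1, y1), 0-based inclusive pixel bounds for
#'   fiber centers.
#' @param length_range c(min, max) fiber length in pixels, min >= 2.
#' @return Object of class \code{"cluster_spec"}.
#' @export
cluster_spec <- function(mean_axis_deg, kappa, n_fibers, region,
                         length_range = c(10, 40)) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (n_fibers < 0) stop("n_fibers must be >= 0")
  if (length(region) != 4L || region[1] > region[3] || region[2] > region[4])
    stop("region must be c(x0, y0, x1, y1) with x0 <= x1, y0 <= y1")
  if (length_range[1] < 2 || length_range[1] > length_range[2])
    stop("length_range must be c(min, max) with 2 <= min <= max")
  structure(list(mean_axis_deg = mean_axis_deg %% 180, kappa = kappa,
                 n_fibers = as.integer(n_fibers),
                 region = as.numeric(region),
                 length_range = as.numeric(length_range)),
            class = "cluster_spec")
}

#' Full parametric specification of a synthetic fiber field
#'
#' Together with the seed this fully determines the generated stack and
#' ground truth (bit-reproducible).
#'
#' @param width,height image size in pixels.
#' @param n_sections number of optical sections.
#' @param z_spacing micrometers per section.
#' @param clusters list of \code{\link{cluster_spec}}s.
#' @param seed integer RNG seed.
#' @param allow_crossings if FALSE (default), fibers that would touch or
#'   cross a previously placed fiber in the same plane are re-drawn.
#' @return Object of class \code{"synthetic_field_spec"}.
#' @export
synthetic_field_spec <- function(width = 512L, height = 512L,
                                 n_sections = 10L, z_spacing = 1.51,
                                 clusters = list(), seed = 1L,
                                 allow_crossings = FALSE) {
  for (cl in clusters) {
    stopifnot(inherits(cl, "cluster_spec"))
    if (cl$region[1] < 0 || cl$region[2] < 0 ||
        cl$region[3] >= width || cl$region[4] >= height)
      stop("cluster region outside image bounds")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_sections = as.integer(n_sections),
                 z_spacing = z_spacing, clusters = clusters,
                 seed = as.integer(seed),
                 allow_crossings = isTRUE(allow_crossings)),
            class = "synthetic_field_spec")
}

# 3x3-dilated occupancy test: TRUE if any pixel is on or next to foreground
touches_occupied <- function(occ, px) {
  h <- nrow(occ); w <- ncol(occ)
  for (dy in -1:1) for (dx in -1:1) {
    yy <- px[, "y"] + dy + 1L; xx <- px[, "x"] + dx + 1L
    ok <- yy >= 1L & yy <= h & xx >= 1L & xx <= w
    if (any(occ[cbind(yy[ok], xx[ok])] == 1L)) return(TRUE)
  }
  FALSE
}

#' Generate a synthetic fiber-trace stack with ground truth
#'
#' For each cluster, places \code{n_fibers} fibers with centers uniform in
#' the cluster region, sections chosen uniformly, axial angles from
#' \code{\link{sample_axial_angle}} and lengths uniform in the cluster's
#' length range, rasterized as 1-pixel-wide lines. When crossings are
#' disallowed, a fiber that would touch or cross an already placed fiber
#' in its plane is re-drawn (up to 100 attempts, then dropped and
#' counted). Each cluster draws from a deterministic sub-stream of the
#' seed, so a cluster's fibers are stable when other clusters change.
#'
#' @param spec a \code{\link{synthetic_field_spec}}.
#' @return List with \code{stack} (a \code{\link{trace_stack}}),
#'   \code{truth} (data frame: fiber_id, cluster, plane_index,
#'   true_angle_deg, center_x, center_y, length_px, x0, y0, x1, y1, with
#'   the spec stored as attribute \code{"spec"}) and \code{dropped}
#'   (fibers abandoned after 100 placement attempts).
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "synthetic_field_spec"))
  h <- spec$height; w <- spec$width
  planes <- replicate(spec$n_sections, matrix(0L, h, w), simplify = FALSE)
  rows <- list()
  dropped <- 0L
  fiber_id <- 0L
  total <- sum(vapply(spec$clusters, `[[`, integer(1), "n_fibers"))
  for (k in seq_along(spec$clusters)) {
    cl <- spec$clusters[[k]]
    if (cl$n_fibers == 0L) next
    set.seed((spec$seed %% 1000003L) * 2011L + 7919L * k)  # per-cluster sub-stream
    placed <- 0L
    while (placed < cl$n_fibers) {
      success <- FALSE
      for (attempt in 1:100) {
        cx <- stats::runif(1, cl$region[1], cl$region[3])
        cy <- stats::runif(1, cl$region[2], cl$region[4])
        pi_ <- sample.int(spec$n_sections, 1L) - 1L
        ang <- sample_axial_angle(cl$mean_axis_deg, cl$kappa, 1L)
        len <- round(stats::runif(1, cl$length_range[1], cl$length_range[2]))
        px <- rasterize_fiber(c(cx, cy), ang, len, c(h, w))
        if (nrow(px) < 2L) next
        if (!spec$allow_crossings && touches_occupied(planes[[pi_ + 1L]], px))
          next
        planes[[pi_ + 1L]][cbind(px[, "y"] + 1L, px[, "x"] + 1L)] <- 1L
        fiber_id <- fiber_id + 1L
        rows[[fiber_id]] <- data.frame(
          fiber_id = fiber_id, cluster = k, plane_index = pi_,
          true_angle_deg = ang, center_x = cx, center_y = cy,
          length_px = nrow(px),
          x0 = px[1L, "x"], y0 = px[1L, "y"],
          x1 = px[nrow(px), "x"], y1 = px[nrow(px), "y"])
        placed <- placed + 1L
        success <- TRUE
        break
      }
      if (!success) {
        dropped <- dropped + 1L
        placed <- placed + 1L  # count the slot as consumed
        if (total > 0L && dropped / total > 0.5)
          stop("generation error: drop rate exceeds 50%; enlarge the cluster regions or reduce n_fibers")
      }
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fiber_id = integer(0), cluster = integer(0),
               plane_index = integer(0), true_angle_deg = numeric(0),
               center_x = numeric(0), center_y = numeric(0),
               length_px = integer(0), x0 = integer(0), y0 = integer(0),
               x1 = integer(0), y1 = integer(0))
  attr(truth, "spec") <- spec
  geom <- stack_geometry(spec$n_sections, spec$z_spacing,
                         label = sprintf("synthetic seed %d", spec$seed))
  list(stack = trace_stack(planes, geom,
                           label = sprintf("synthetic seed %d", spec$seed)),
       truth = truth, dropped = dropped)
}

#' Write / read a synthetic ground-truth table
#'
#' Tab-separated with header; columns as in the \code{truth} element of
#' \code{\link{generate_field}}.
#'
#' @param truth ground-truth data frame.
#' @param path file path.
#' @return \code{write_ground_truth}: invisibly, \code{path};
#'   \code{read_ground_truth}: the data frame.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

axial_diff <- function(a, b) {
  # absolute difference on the axial circle, in [0, 90]
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Recovery report: pipeline output vs synthetic ground truth
#'
#' Matches recovered segments to generated fibers by centroid proximity
#' within the same plane (greedy nearest unmatched segment within
#' \code{match_radius}; matching uses geometry only, never ids) and
#' reports the match rate, the mean and maximum absolute axial angle
#' error, and per-cluster mean-axis recovery error (the axial difference
#' between the cluster's specified mean axis and the
#' \code{\link{axial_order}} mean axis of its matched segments).
#'
#' @param truth ground-truth data frame from \code{\link{generate_field}}.
#' @param map the \code{\link{orientation_map}} computed from the
#'   generated stack.
#' @param match_radius maximum centroid distance in pixels (default 3).
#' @return Object of class \code{"recovery_report"}: \code{match_rate},
#'   \code{n_truth}, \code{n_matched}, \code{mean_abs_angle_err_deg},
#'   \code{max_abs_angle_err_deg}, \code{per_cluster} (data frame:
#'   cluster, mean_axis_true_deg, mean_axis_recovered_deg, err_deg, n),
#'   \code{matches} (fiber_id, segment_id pairs).
#' @export
recovery_report <- function(truth, map, match_radius = 3) {
  if (nrow(truth) == 0L) stop("empty ground truth")
  stopifnot(inherits(map, "orientation_map"))
  tab <- as.data.frame(map)
  # fiber center = midpoint of its rasterized endpoints
  fcx <- (truth$x0 + truth$x1) / 2
  fcy <- (truth$y0 + truth$y1) / 2
  used <- rep(FALSE, nrow(tab))
  seg_match <- rep(NA_integer_, nrow(truth))
  err <- rep(NA_real_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cand <- which(!used & tab$plane_index == truth$plane_index[i] &
                    !is.na(tab$angle_deg))
    if (!length(cand)) next
    d <- sqrt((tab$centroid_x[cand] - fcx[i])^2 +
                (tab$centroid_y[cand] - fcy[i])^2)
    j <- cand[which.min(d)]
    if (min(d) <= match_radius) {
      used[j] <- TRUE
      seg_match[i] <- j
      err[i] <- axial_diff(tab$angle_deg[j], truth$true_angle_deg[i])
    }
  }
  matched <- !is.na(seg_match)
  spec <- attr(truth, "spec")
  per_cluster <- do.call(rbind, lapply(sort(unique(truth$cluster)), function(k) {
    sel <- matched & truth$cluster == k
    mean_true <- if (!is.null(spec)) spec$clusters[[k]]$mean_axis_deg
                 else axial_order(truth$true_angle_deg[truth$cluster == k])$mean_axis_deg
    rec <- if (any(sel)) axial_order(tab$angle_deg[seg_match[sel]])$mean_axis_deg
           else NA_real_
    data.frame(cluster = k, mean_axis_true_deg = mean_true,
               mean_axis_recovered_deg = rec,
               err_deg = if (is.na(rec)) NA_real_ else axial_diff(rec, mean_true),
               n = sum(sel))
  }))
  structure(list(match_rate = mean(matched),
                 n_truth = nrow(truth), n_matched = sum(matched),
                 mean_abs_angle_err_deg = mean(err[matched]),
                 max_abs_angle_err_deg = if (any(matched)) max(err[matched]) else NA_real_,
                 per_cluster = per_cluster,
                 matches = data.frame(fiber_id = truth$fiber_id[matched],
                                      segment_id = tab$segment_id[seg_match[matched]])),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery: matched %d / %d fibers (rate %.3f); angle error mean %.3f deg, max %.3f deg\n",
              x$n_matched, x$n_truth, x$match_rate,
              x$mean_abs_angle_err_deg, x$max_abs_angle_err_deg))
  print(x$per_cluster, row.names = FALSE)
  invisible(x)
}

#' Write / read a synthetic field specification as a config file
#'
#' Same key-value dialect as the stack-geometry sidecar: one
#' \code{key = value} per line, clusters keyed as
#' \code{cluster<N>.<field>}.
#'
#' @param spec a \code{\link{synthetic_field_spec}}.
#' @param path file path.
#' @return \code{write_field_spec}: invisibly, \code{path};
#'   \code{read_field_spec}: the reconstructed spec.
#' @export
write_field_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_field_spec"))
  num <- function(v) paste(format(v, digits = 17), collapse = " ")
  lines <- c(sprintf("width = %d", spec$width),
             sprintf("height = %d", spec$height),
             sprintf("n_sections = %d", spec$n_sections),
             sprintf("z_spacing_um = %s", num(spec$z_spacing)),
             sprintf("seed = %d", spec$seed),
             sprintf("allow_crossings = %s",
                     if (spec$allow_crossings) "true" else "false"))
  for (k in seq_along(spec$clusters)) {
    cl <- spec$clusters[[k]]
    lines <- c(lines,
               sprintf("cluster%d.mean_axis_deg = %s", k, num(cl$mean_axis_deg)),
               sprintf("cluster%d.kappa = %s", k, num(cl$kappa)),
               sprintf("cluster%d.n_fibers = %d", k, cl$n_fibers),
               sprintf("cluster%d.region = %s", k, num(cl$region)),
               sprintf("cluster%d.length_range = %s", k, num(cl$length_range)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_field_spec
#' @export
read_field_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", lines))
  if (any(vapply(kv, length, integer(1)) != 3L))
    stop("parse error in field spec file")
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  get <- function(k) {
    if (!k %in% keys) stop("field spec is missing key: ", k)
    as.numeric(strsplit(vals[match(k, keys)], "\\s+")[[1]])
  }
  ids <- sort(unique(as.integer(sub("^cluster([0-9]+)\\..*$", "\\1",
                                    grep("^cluster", keys, value = TRUE)))))
  clusters <- lapply(ids, function(k) {
    p <- function(f) get(sprintf("cluster%d.%s", k, f))
    cluster_spec(p("mean_axis_deg"), p("kappa"), p("n_fibers"),
                 p("region"), p("length_range"))
  })
  synthetic_field_spec(width = get("width"), height = get("height"),
                       n_sections = get("n_sections"),
                       z_spacing = get("z_spacing_um"),
                       clusters = clusters, seed = get("seed"),
                       allow_crossings =
                         tolower(vals[match("allow_crossings", keys)]) %in%
                           c("true", "1", "yes"))
}
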