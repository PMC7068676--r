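#' Stack geometry: physical calibration of a z-stack
#'
#' Records the number of optical sections, the z spacing between sections,
#' and (optionally) the lateral pixel size. The total imaged depth is
#' \code{n_sections * z_spacing}, the convention used when a confocal series
#' of n sections at spacing s micrometers is reported as a depth of
#' \code{n * s} micrometers.
#'
#' @param n_sections integer >= 1, number of optical sections.
#' @param z_spacing  micrometers per section, > 0.
#' @param pixel_size_xy micrometers per pixel, > 0, or \code{NA} when the
#'   lateral calibration is unknown.
#' @param label free-text specimen identifier.
#' @return An object of class \code{"stack_geometry"}.
#' @export
#' @examples
#' g <- stack_geometry(46, 1.51)
#' g$total_depth  # 69.46
stack_geometry <- function(n_sections, z_spacing, pixel_size_xy = NA_real_,
                           label = "") {
  n_sections <- as.integer(n_sections)
  if (length(n_sections) != 1L || is.na(n_sections) || n_sections < 1L)
    stop("n_sections must be a single integer >= 1")
  if (length(z_spacing) != 1L || !is.finite(z_spacing) || z_spacing <= 0)
    stop("z_spacing must be a single positive number (micrometers)")
  if (!is.na(pixel_size_xy) && pixel_size_xy <= 0)
    stop("pixel_size_xy must be positive or NA when unknown")
  structure(list(n_sections = n_sections,
                 z_spacing = z_spacing,
                 pixel_size_xy = pixel_size_xy,
                 total_depth = total_depth(n_sections, z_spacing),
                 label = label),
            class = "stack_geometry")
}

#' Total imaged depth of a z-stack
#'
#' Depth convention: \code{n_sections * z_spacing}, reported to 0.01 um.
#' A series of 46 sections every 1.51 um spans 69.46 um.
#'
#' @param n_sections integer >= 1.
#' @param z_spacing micrometers per section, > 0.
#' @return Depth in micrometers, rounded to 0.01 um.
#' @export
#' @examples
#' total_depth(46, 1.51)  # 69.46
#' total_depth(11, 4.99)  # 54.89
total_depth <- function(n_sections, z_spacing) {
  if (any(n_sections < 1) || any(n_sections != round(n_sections)))
    stop("n_sections must be an integer >= 1")
  if (any(!is.finite(z_spacing)) || any(z_spacing <= 0))
    stop("z_spacing must be > 0")
  round(n_sections * z_spacing, 2)
}

#' Binary trace z-stack
#'
#' Container for an ordered sequence of binary planes (one per optical
#' section) plus physical calibration. Plane 1 is the first optical section.
#' Pixel values are restricted to {0, 1}; foreground pixels are the drawn
#' fiber traces.
#'
#' @param planes list of numeric/integer matrices, all the same dimension,
#'   values in {0, 1} (any nonzero value is coerced to 1).
#' @param geometry a \code{\link{stack_geometry}}; its \code{n_sections} must
#'   equal \code{length(planes)}.
#' @param label free-text specimen identifier.
#' @return An object of class \code{"trace_stack"} with elements
#'   \code{planes}, \code{geometry}, \code{label}, \code{dim} (height, width).
#' @export
trace_stack <- function(planes, geometry = NULL, label = "") {
  if (!is.list(planes) || length(planes) < 1L)
    stop("planes must be a non-empty list of matrices")
  dims <- lapply(planes, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("every plane must be a 2-D matrix")
  d0 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d0), logical(1))))
    stop("all planes must share identical height x width")
  planes <- lapply(planes, function(p) {
    storage.mode(p) <- "integer"
    p[p != 0L] <- 1L
    p
  })
  if (is.null(geometry)) geometry <- stack_geometry(length(planes), 1)
  if (!inherits(geometry, "stack_geometry"))
    stop("geometry must be a stack_geometry object")
  if (geometry$n_sections != length(planes))
    stop(sprintf("geometry says %d sections but %d planes supplied",
                 geometry$n_sections, length(planes)))
  structure(list(planes = planes, geometry = geometry, label = label,
                 dim = d0),
            class = "trace_stack")
}

#' @export
print.trace_stack <- function(x, ...) {
  fg <- sum(vapply(x$planes, sum, numeric(1)))
  cat(sprintf("Binary trace stack%s: %d x %d px, %d sections (z spacing %g um, depth %g um), %d foreground px\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$dim[1], x$dim[2], x$geometry$n_sections,
              x$geometry$z_spacing, x$geometry$total_depth, fg))
  invisible(x)
}

#' Load a binary trace stack from a multi-page TIFF
#'
#' Reads one page per optical section, binarizing every nonzero sample to 1
#' (so 8-bit 0/255 masks from tracing tools are accepted). The physical
#' geometry is supplied alongside, never parsed from TIFF tags; if the file
#' carries a resolution tag that disagrees with the supplied pixel size a
#' warning is emitted and the supplied geometry wins.
#'
#' @param path path to a multi-page TIFF whose page count equals
#'   \code{geometry$n_sections}.
#' @param geometry a \code{\link{stack_geometry}}.
#' @param label specimen identifier; defaults to the geometry's label or the
#'   file name.
#' @return A \code{\link{trace_stack}}.
#' @export
load_trace_stack <- function(path, geometry, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != geometry$n_sections)
    stop(sprintf("geometry error: TIFF has %d pages but geometry declares %d sections",
                 length(pages), geometry$n_sections))
  xres <- attr(pages[[1]], "x.resolution")
  pages <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] > 1L && !all(p[, , 1] == p[, , -1]))
        stop(sprintf("format error: page %d is not a 2-D grayscale image", i))
      p <- p[, , 1]
    }
    if (length(dim(p)) != 2L)
      stop(sprintf("format error: page %d is not 2-D", i))
    d <- dim(p)
    attributes(p) <- NULL  # drop TIFF tag attributes; keep only the image
    dim(p) <- d
    p
  })
  if (!is.null(xres) && !is.na(geometry$pixel_size_xy)) {
    tag_px <- 1e4 / xres  # resolution tags are typically px per cm
    if (is.finite(tag_px) && abs(tag_px - geometry$pixel_size_xy) >
          0.05 * geometry$pixel_size_xy)
      warning(sprintf("TIFF resolution tag implies %.4g um/px but geometry says %.4g um/px; using the supplied geometry",
                      tag_px, geometry$pixel_size_xy))
  }
  if (is.null(label))
    label <- if (nzchar(geometry$label)) geometry$label else basename(path)
  trace_stack(pages, geometry, label = label)
}

#' Write a trace stack to a multi-page TIFF
#'
#' Foreground pixels are written as 255 in an 8-bit grayscale page per
#' section, round-tripping bit-exactly through \code{\link{load_trace_stack}}.
#'
#' @param stack a \code{\link{trace_stack}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_trace_stack <- function(stack, path) {
  stopifnot(inherits(stack, "trace_stack"))
  pages <- lapply(stack$planes, function(p) {
    m <- matrix(as.double(p), nrow(p), ncol(p))
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Read stack geometry from a key-value sidecar file
#'
#' The sidecar is plain text with one \code{key = value} (or
#' \code{key: value}) pair per line; recognised keys are \code{n_sections},
#' \code{z_spacing_um}, \code{pixel_size_um} (optional) and \code{label}
#' (optional). Blank lines and lines starting with \code{#} are ignored.
#'
#' @param path path to the sidecar file.
#' @return A \code{\link{stack_geometry}}.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*[=:]\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad))
    stop("parse error in geometry file at line: ", lines[bad[1]])
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
  n <- get("n_sections"); z <- get("z_spacing_um")
  if (is.na(n) || is.na(z))
    stop("geometry file must define n_sections and z_spacing_um")
  px <- get("pixel_size_um")
  stack_geometry(as.integer(n), as.numeric(z),
                 if (is.na(px)) NA_real_ else as.numeric(px),
                 label = if (is.na(get("label"))) "" else get("label"))
}

#' Write stack geometry to a key-value sidecar file
#' @param geometry a \code{\link{stack_geometry}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "stack_geometry"))
  lines <- c(sprintf("n_sections = %d", geometry$n_sections),
             sprintf("z_spacing_um = %s", format(geometry$z_spacing, digits = 17)),
             if (!is.na(geometry$pixel_size_xy))
               sprintf("pixel_size_um = %s",
                       format(geometry$pixel_size_xy, digits = 17)),
             if (nzchar(geometry$label)) sprintf("label = %s", geometry$label))
  writeLines(lines, path)
  invisible(path)
}

segment_table_cols <- c("segment_id", "plane_index", "pixel_count",
                        "centroid_x", "centroid_y", "mu20", "mu02", "mu11",
                        "angle_deg", "bin_index")

#' Write the per-segment orientation table
#'
#' One row per retained fiber segment: id, plane, pixel count, centroid,
#' second-order central moments, axial angle in degrees and orientation bin.
#' Degenerate segments (no preferred axis) carry \code{NA} angle and bin.
#' Numeric fields are written at full precision and round-trip losslessly
#' through \code{\link{read_segment_table}}.
#'
#' @param x an \code{\link{orientation_map}} or a segment table data frame.
#' @param path output path (tab-separated text with header).
#' @return Invisibly, \code{path}.
#' @export
write_segment_table <- function(x, path) {
  tab <- if (inherits(x, "orientation_map")) as.data.frame(x) else x
  if (!all(segment_table_cols %in% names(tab)))
    stop("segment table is missing columns: ",
         paste(setdiff(segment_table_cols, names(tab)), collapse = ", "))
  tab <- tab[segment_table_cols]
  fmt <- function(v) {
    out <- if (is.double(v)) formatC(v, digits = 17, format = "g")
           else as.character(v)
    out[is.na(v)] <- "NA"
    out
  }
  out <- vapply(tab, fmt, character(nrow(tab)))
  if (nrow(tab) == 1L) out <- matrix(out, nrow = 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(segment_table_cols, collapse = "\t"), con)
  if (nrow(tab) > 0L)
    writeLines(apply(out, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a per-segment orientation table
#'
#' Parses a file written by \code{\link{write_segment_table}} (or matching
#' its schema) and validates the table invariants: unique segment ids,
#' angles in [0, 180) or NA, bins consistent with angles.
#'
#' @param path path to the table.
#' @param n_bins number of angular bins used to validate \code{bin_index};
#'   default 32.
#' @return A data frame with the documented columns.
#' @export
read_segment_table <- function(path, n_bins = 32L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("parse error at line 1: missing header")
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(hdr, segment_table_cols))
    stop("parse error at line 1: unexpected header")
  ints <- c("segment_id", "plane_index", "pixel_count", "bin_index")
  tab <- as.data.frame(matrix(numeric(0), 0, length(hdr),
                              dimnames = list(NULL, hdr)))
  if (length(lines) > 1L) {
    rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
    nf <- vapply(rows, length, integer(1))
    if (any(nf != length(hdr)))
      stop(sprintf("parse error at line %d: expected %d fields, got %d",
                   which(nf != length(hdr))[1] + 1L, length(hdr),
                   nf[nf != length(hdr)][1]))
    m <- do.call(rbind, rows)
    tab <- as.data.frame(lapply(seq_along(hdr), function(j)
      suppressWarnings(as.numeric(m[, j]))))
    names(tab) <- hdr
    bad <- which(rowSums(is.na(tab[setdiff(hdr, c("angle_deg", "bin_index"))])) > 0)
    if (length(bad))
      stop(sprintf("parse error at line %d: non-numeric required field",
                   bad[1] + 1L))
  }
  for (k in ints) tab[[k]] <- as.integer(tab[[k]])
  if (anyDuplicated(tab$segment_id))
    stop("validation error: duplicate segment_id")
  ang <- tab$angle_deg
  if (any(!is.na(ang) & (ang < 0 | ang >= 180)))
    stop(sprintf("validation error at line %d: angle_deg outside [0, 180)",
                 which(!is.na(ang) & (ang < 0 | ang >= 180))[1] + 1L))
  b <- tab$bin_index
  if (any(!is.na(b) & (b < 0L | b >= n_bins)))
    stop(sprintf("validation error at line %d: bin_index outside [0, %d)",
                 which(!is.na(b) & (b < 0L | b >= n_bins))[1] + 1L, n_bins))
  tab
}
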