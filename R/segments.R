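# Per-plane decomposition of binary traces into individual fiber segments:
# prune junction pixels so crossing/touching fibers disconnect, then label
# connected components. Coordinates are 0-based, x = column rightward,
# y = row downward.

neighbor_offsets <- function(connectivity) {
  if (connectivity == 4L)
    cbind(dx = c(1L, -1L, 0L, 0L), dy = c(0L, 0L, 1L, -1L))
  else
    cbind(dx = c(1L, -1L, 0L, 0L, 1L, 1L, -1L, -1L),
          dy = c(0L, 0L, 1L, -1L, 1L, -1L, 1L, -1L))
}

check_binary <- function(plane) {
  if (is.null(dim(plane)) || length(dim(plane)) != 2L)
    stop("plane must be a 2-D matrix")
  if (!all(plane %in% c(0, 1)))
    stop("plane must be binary (values 0/1)")
  storage.mode(plane) <- "integer"
  plane
}

# count of foreground neighbors for every pixel, via shifted copies
neighbor_counts <- function(plane, connectivity) {
  h <- nrow(plane); w <- ncol(plane)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- plane
  off <- neighbor_offsets(connectivity)
  cnt <- matrix(0L, h, w)
  for (k in seq_len(nrow(off))) {
    # neighbor at (x+dx, y+dy): shift the padded image the opposite way
    cnt <- cnt + pad[(2:(h + 1L)) + off[k, "dy"], (2:(w + 1L)) + off[k, "dx"]]
  }
  cnt
}

#' Remove branch points from a binary trace plane
#'
#' A branch point (skeleton junction) is a foreground pixel with three or
#' more foreground neighbors under the chosen connectivity; fibers that
#' cross or touch share such pixels. Removing them disconnects the fibers
#' so orientation can be computed fiber by fiber. Exactly one removal pass
#' is applied: iterating to a fixpoint can erode staircase diagonals of
#' genuine single fibers, while one pass suffices to break junctions of
#' 1-pixel-wide traces.
#'
#' @param plane binary matrix (values 0/1).
#' @param connectivity 4 or 8 (default 8; hand-drawn diagonal strokes are
#'   8-connected chains).
#' @return A binary matrix; output foreground is a subset of the input
#'   foreground.
#' @export
remove_branch_points <- function(plane, connectivity = 8L) {
  plane <- check_binary(plane)
  connectivity <- match.arg(as.character(connectivity), c("8", "4"))
  connectivity <- as.integer(connectivity)
  cnt <- neighbor_counts(plane, connectivity)
  out <- plane
  out[plane == 1L & cnt >= 3L] <- 0L
  out
}

# Zhang-Suen thinning; optional pre-step for inputs thicker than drawn lines
thin_plane <- function(plane, max_iter = 1000L) {
  plane <- check_binary(plane)
  h <- nrow(plane); w <- ncol(plane)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- plane
  nb <- function(p) {
    i <- 2:(h + 1L); j <- 2:(w + 1L)
    # clockwise from north: p2..p9
    list(p[i - 1L, j], p[i - 1L, j + 1L], p[i, j + 1L], p[i + 1L, j + 1L],
         p[i + 1L, j], p[i + 1L, j - 1L], p[i, j - 1L], p[i - 1L, j - 1L])
  }
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (phase in 1:2) {
      n <- nb(pad)
      B <- Reduce(`+`, n)
      ring <- c(n, n[1])
      A <- Reduce(`+`, lapply(1:8, function(k)
        (ring[[k]] == 0L) & (ring[[k + 1L]] == 1L)))
      core <- pad[2:(h + 1L), 2:(w + 1L)] == 1L
      if (phase == 1L)
        cond <- (n[[1]] * n[[3]] * n[[5]] == 0L) & (n[[3]] * n[[5]] * n[[7]] == 0L)
      else
        cond <- (n[[1]] * n[[3]] * n[[7]] == 0L) & (n[[1]] * n[[5]] * n[[7]] == 0L)
      del <- core & B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) {
        tmp <- pad[2:(h + 1L), 2:(w + 1L)]
        tmp[del] <- 0L
        pad[2:(h + 1L), 2:(w + 1L)] <- tmp
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(h + 1L), 2:(w + 1L)]
}

# label foreground pixels into connected components (igraph); returns a
# data frame of (x, y, comp) with components renumbered 1..k in raster-scan
# order (top-to-bottom, then left-to-right) of each component's first pixel
label_components <- function(plane, connectivity = 8L) {
  idx <- which(plane == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(x = integer(0), y = integer(0), comp = integer(0)))
  y <- idx[, 1L] - 1L; x <- idx[, 2L] - 1L
  ord <- order(y, x)  # raster order
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  key <- y * ncol(plane) + x
  pos <- seq_len(n)
  names(pos) <- as.character(key)
  off <- neighbor_offsets(connectivity)
  edges <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    nx <- x + off[k, "dx"]; ny <- y + off[k, "dy"]
    inb <- nx >= 0L & nx < ncol(plane) & ny >= 0L & ny < nrow(plane)
    j <- rep(NA_integer_, n)
    j[inb] <- pos[as.character(ny[inb] * ncol(plane) + nx[inb])]
    ok <- !is.na(j)
    edges[[k]] <- cbind(pos[ok], j[ok])
  }
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(
    if (is.null(el) || nrow(el) == 0L) matrix(integer(0), 0, 2) else el,
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  comp <- match(comp, unique(comp))  # first pixel in raster order defines id
  data.frame(x = x, y = y, comp = comp)
}

new_segment <- function(segment_id, plane_index, pixels) {
  structure(list(segment_id = as.integer(segment_id),
                 plane_index = as.integer(plane_index),
                 pixels = pixels,
                 pixel_count = nrow(pixels)),
            class = "fiber_segment")
}

#' Extract fiber segments from one pruned binary plane
#'
#' Labels connected components of a plane that has already passed
#' \code{\link{remove_branch_points}} and returns one segment per component
#' with at least \code{min_segment_length} pixels. Components below the
#' threshold (junction debris) are discarded; their count and pixel total
#' are reported in the \code{"dropped"} attribute. Segment ids follow the
#' raster-scan order of each component's first pixel, so the decomposition
#' is deterministic.
#'
#' @param plane binary matrix.
#' @param plane_index 0-based index of the optical section.
#' @param min_segment_length minimum pixels per retained segment (>= 1).
#' @param connectivity 4 or 8.
#' @return List of \code{fiber_segment} objects (fields \code{segment_id},
#'   \code{plane_index}, \code{pixels} — a 2-column 0-based (x, y) matrix —
#'   and \code{pixel_count}), with attribute \code{"dropped"} = c(components,
#'   pixels).
#' @export
extract_segments <- function(plane, plane_index = 0L, min_segment_length = 5L,
                             connectivity = 8L) {
  if (min_segment_length < 1L) stop("min_segment_length must be >= 1")
  plane <- check_binary(plane)
  lab <- label_components(plane, connectivity)
  out <- list()
  dropped <- c(components = 0L, pixels = 0L)
  if (nrow(lab) > 0L) {
    sizes <- tabulate(lab$comp)
    keep <- which(sizes >= min_segment_length)
    dropped <- c(components = length(sizes) - length(keep),
                 pixels = sum(sizes[sizes < min_segment_length]))
    out <- lapply(seq_along(keep), function(i) {
      sel <- lab$comp == keep[i]
      new_segment(i, plane_index,
                  cbind(x = lab$x[sel], y = lab$y[sel]))
    })
  }
  attr(out, "dropped") <- dropped
  out
}

#' Decompose a whole trace stack into fiber segments
#'
#' Applies optional thinning, one branch-removal pass and component
#' labeling to every plane, concatenating the per-plane segments with
#' stack-wide unique ids (plane order, then raster order within a plane).
#'
#' @param stack a \code{\link{trace_stack}}.
#' @param min_segment_length minimum pixels per retained segment.
#' @param connectivity 4 or 8.
#' @param thin if TRUE, thin each plane to 1-pixel width before branch
#'   removal (for outline-style input; drawn-line input needs no thinning).
#' @return List of \code{fiber_segment}s with attributes \code{"dropped"}
#'   (per-plane matrix of discarded component/pixel tallies) and
#'   \code{"removed_branch_pixels"} (per-plane count).
#' @export
decompose_stack <- function(stack, min_segment_length = 5L,
                            connectivity = 8L, thin = FALSE) {
  stopifnot(inherits(stack, "trace_stack"))
  segs <- list()
  nplanes <- length(stack$planes)
  dropped <- matrix(0L, nplanes, 2L,
                    dimnames = list(NULL, c("components", "pixels")))
  removed <- integer(nplanes)
  next_id <- 1L
  for (pi in seq_len(nplanes)) {
    pl <- stack$planes[[pi]]
    if (thin) pl <- thin_plane(pl)
    pruned <- remove_branch_points(pl, connectivity)
    removed[pi] <- sum(pl) - sum(pruned)
    s <- extract_segments(pruned, plane_index = pi - 1L,
                          min_segment_length = min_segment_length,
                          connectivity = connectivity)
    dropped[pi, ] <- attr(s, "dropped")
    for (seg in s) {
      seg$segment_id <- next_id
      next_id <- next_id + 1L
      segs[[length(segs) + 1L]] <- seg
    }
  }
  attr(segs, "dropped") <- dropped
  attr(segs, "removed_branch_pixels") <- removed
  segs
}
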