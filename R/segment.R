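#' Label connected components of a binary mask
#'
#' 8-connected (default) component labeling of the foreground pixels of a
#' logical matrix, built on the pixel adjacency graph. Labels are assigned in
#' raster-scan order of each component's top-left pixel (smallest row, then
#' smallest column), so the labeling is deterministic.
#'
#' @param mask Logical matrix, `TRUE` = foreground.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of the same shape; 0 = background, components
#'   numbered from 1.
#' @keywords internal
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(labels)
  pos <- integer(nr * nc)
  pos[idx] <- seq_len(n)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  fg <- logical(nr * nc)
  fg[idx] <- TRUE
  edge_to <- function(sel, off) {
    nb <- idx[sel] + off
    keep <- fg[nb]
    cbind(pos[idx[sel][keep]], pos[nb[keep]])
  }
  edges <- rbind(
    edge_to(r < nr, 1L),        # down
    edge_to(cc < nc, nr)        # right
  )
  if (connectivity == 8) {
    edges <- rbind(
      edges,
      edge_to(r < nr & cc < nc, nr + 1L),  # down-right
      edge_to(r > 1L & cc < nc, nr - 1L)   # up-right
    )
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  memb <- igraph::components(g)$membership[seq_len(n)]
  # renumber components by raster-scan (row-major) order of their first pixel
  rowmajor <- (r - 1L) * nc + cc
  first <- tapply(rowmajor, memb, min)
  rank <- match(memb, as.integer(names(sort(first))))
  labels[idx] <- rank
  labels
}

# Contour-based perimeter per label: sum of chain steps along the outer
# boundary, diagonal steps counting sqrt(2). Objects too small to carry a
# contour (1 pixel) get the unit-square boundary length 4.
perimeter_from_labels <- function(labels, ids) {
  oc <- EBImage::ocontour(labels)
  vapply(ids, function(id) {
    ctr <- oc[[as.character(id)]]
    if (is.null(ctr) || nrow(ctr) < 2L) return(4)
    closed <- rbind(ctr, ctr[1L, , drop = FALSE])
    sum(sqrt(rowSums(diff(closed)^2)))
  }, numeric(1))
}

# Build the object table for a label matrix whose pixel values are object ids.
objects_from_labels <- function(labels) {
  idx <- which(labels > 0L)
  if (!length(idx)) {
    return(structure(
      tibble::tibble(
        object_id = integer(), area_px = integer(), perimeter_px = double(),
        shape_ratio = double(), centroid_x_px = double(),
        centroid_y_px = double(), truncated = logical()
      ),
      labels = labels, class = c("plant_objects", "tbl_df", "tbl", "data.frame")
    ))
  }
  nr <- nrow(labels); nc <- ncol(labels)
  lab <- labels[idx]
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  ids <- sort(unique(lab))
  # contiguous relabeling keeps ocontour indexing simple
  relab <- matrix(0L, nr, nc)
  relab[idx] <- match(lab, ids)
  per <- perimeter_from_labels(relab, seq_along(ids))
  f <- factor(lab, levels = ids)
  area <- as.integer(tabulate(f))
  # pixel centers at half-integer offsets in the corner-origin continuous frame
  cx <- tapply(cc - 0.5, f, mean)
  cy <- tapply(r - 0.5, f, mean)
  trunc <- tapply(r == 1L | r == nr | cc == 1L | cc == nc, f, any)
  out <- tibble::tibble(
    object_id = ids,
    area_px = area,
    perimeter_px = as.numeric(per),
    shape_ratio = as.numeric(per) / area,
    centroid_x_px = as.numeric(cx),
    centroid_y_px = as.numeric(cy),
    truncated = as.logical(trunc)
  )
  structure(out, labels = labels,
            class = c("plant_objects", "tbl_df", "tbl", "data.frame"))
}

#' Extract candidate plant objects from a vegetation mask
#'
#' Labels the 8-connected components of a binary vegetation mask and returns
#' one row per object with its area, contour perimeter (diagonal steps
#' weighted by sqrt(2)), perimeter/area shape ratio, and continuous-pixel
#' centroid. Pixel centers sit at half-integer coordinates in the corner-origin
#' frame, so a single pixel in (0-based) row 5, column 5 has centroid
#' (5.5, 5.5). Objects touching the image border are flagged `truncated`.
#'
#' @param mask Logical matrix from [threshold_vegetation()].
#' @return A tibble of class `plant_objects` with columns `object_id`,
#'   `area_px`, `perimeter_px`, `shape_ratio`, `centroid_x_px`,
#'   `centroid_y_px`, `truncated`, ordered by raster-scan position. The label
#'   matrix (pixel values = `object_id`) is attached as attribute `"labels"`.
#' @export
extract_objects <- function(mask) {
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  objects_from_labels(label_components(mask, connectivity = 8))
}

#' Filter outlier objects by relative area and shape
#'
#' Keeps objects whose area exceeds `t_area` times the mean area of the input
#' collection AND whose perimeter/area shape ratio passes the shape test, with
#' both means taken over the input collection (so the cutoffs adapt to the
#' scene). With the defaults `t_area = t_shape = 0.3`, small specks well below
#' typical plant size are dropped.
#'
#' The shape test direction is configurable because "keep ratio greater than
#' a fraction of the mean" favors ragged outlines while compact plants have
#' LOW perimeter/area: `shape_keep = "above"` keeps
#' `shape_ratio > t_shape * mean`, `"below"` keeps
#' `shape_ratio < mean / t_shape`.
#'
#' @param objects A `plant_objects` tibble from [extract_objects()].
#' @param t_area,t_shape Positive threshold fractions (defaults 0.3).
#' @param shape_keep `"above"` (default) or `"below"`.
#' @return The surviving subset, same class, with the label matrix attribute
#'   updated (removed objects zeroed out).
#' @export
filter_objects <- function(objects, t_area = 0.3, t_shape = 0.3,
                           shape_keep = c("above", "below")) {
  shape_keep <- match.arg(shape_keep)
  stopifnot(is.data.frame(objects), t_area > 0, t_shape > 0)
  if (nrow(objects) == 0L) return(objects)
  mean_area <- mean(objects$area_px)
  mean_shape <- mean(objects$shape_ratio)
  ok_area <- objects$area_px > t_area * mean_area
  ok_shape <- if (shape_keep == "above") {
    objects$shape_ratio > t_shape * mean_shape
  } else {
    objects$shape_ratio < mean_shape / t_shape
  }
  keep <- ok_area & ok_shape
  labels <- attr(objects, "labels")
  if (!is.null(labels) && any(!keep)) {
    labels[labels %in% objects$object_id[!keep]] <- 0L
  }
  out <- objects[keep, , drop = FALSE]
  structure(out, labels = labels,
            class = c("plant_objects", "tbl_df", "tbl", "data.frame"))
}

#' Merge fragmented objects via dilation buffers
#'
#' Expands every object by a disc of radius `dilation_radius_px` and merges
#' objects whose dilated buffers overlap (transitively, as connected
#' components of the overlap graph). This re-joins fragments of one plant
#' split by shadow or thin stems; the radius encodes prior knowledge of the
#' plant interval — it must stay well below half the expected within-row
#' spacing or neighboring plants merge.
#'
#' @param objects A `plant_objects` tibble carrying its label matrix.
#' @param dilation_radius_px Dilation radius in pixels (>= 0; 0 = no-op).
#' @return A `plant_objects` tibble; merged objects get recomputed area,
#'   perimeter and centroid and fresh raster-scan ids. Total vegetation pixel
#'   count is conserved.
#' @export
merge_fragments <- function(objects, dilation_radius_px) {
  stopifnot(is.data.frame(objects), dilation_radius_px >= 0)
  labels <- attr(objects, "labels")
  if (nrow(objects) <= 1L || dilation_radius_px == 0) return(objects)
  if (is.null(labels)) stop("`objects` is missing its label matrix attribute",
                            call. = FALSE)
  size <- 2L * as.integer(ceiling(dilation_radius_px)) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  dil <- EBImage::dilate((labels > 0L) * 1, brush)
  groups <- label_components(dil > 0, connectivity = 8)
  # group id of each object = dilated component containing its pixels
  first_px <- match(objects$object_id, labels)
  grp <- groups[first_px]
  if (anyDuplicated(grp) == 0L) return(objects)
  merged <- labels
  merged[merged > 0L] <- grp[match(labels[labels > 0L], objects$object_id)]
  objects_from_labels(merged)
}
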