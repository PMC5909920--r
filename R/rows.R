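# Internal line helpers. A row line is stored point-direction: an anchor on
# the line plus the unit direction u = (cos d, sin d) for row angle d; the
# unit normal is nvec = (-sin d, cos d). All ridges in a scene share d, so a
# line is fully described by its signed offset anchor . nvec.

row_direction <- function(angle_rad) c(cos(angle_rad), sin(angle_rad))

# normal oriented toward +x (or +y for horizontal rows) so that signed
# offsets, and hence ridge ids, ascend left-to-right across vertical rows
row_normal <- function(angle_rad) {
  nv <- c(-sin(angle_rad), cos(angle_rad))
  if (nv[1] < 0 || (nv[1] == 0 && nv[2] < 0)) nv <- -nv
  nv
}

# signed perpendicular offset of points from the origin-through line family
signed_offset <- function(x, y, angle_rad) {
  nv <- row_normal(angle_rad)
  x * nv[1] + y * nv[2]
}

# slope/intercept form, defined only for non-vertical lines
line_params <- function(anchor_x, anchor_y, angle_rad) {
  if (abs(cos(angle_rad)) > 1e-6) {
    k <- tan(angle_rad)
    c(k = k, b = anchor_y - k * anchor_x)
  } else {
    c(k = NA_real_, b = NA_real_)
  }
}

#' Detect crop row (ridge) lines from corrected plant positions
#'
#' Implements the iterative buffer procedure: pick an unassigned seed plant,
#' cast a line through it at the known row angle, collect every unassigned
#' plant within a perpendicular buffer of `buffer_frac * row_width_m`
#' (default one third of the row width), recentre the line on the members'
#' mean position, and emit it as a ridge; repeat until every plant is
#' assigned. The row angle and row width are prior knowledge of the planting
#' pattern, supplied per image.
#'
#' @param plants A tibble of corrected plants with columns `object_id`,
#'   `ax_m`, `ay_m` (from [correct_plants()]).
#' @param angle_deg Row angle in degrees, measured counterclockwise from the
#'   +x (rightward) axis of the metric frame, in `[0, 180)`. Vertical image
#'   rows are 90.
#' @param row_width_m Nominal distance between adjacent rows (meters).
#' @param buffer_frac Buffer half-width as a fraction of `row_width_m`
#'   (default 1/3).
#' @param seed_method `"center"` (default) seeds each ridge with the
#'   unassigned plant nearest `center`, which is deterministic; `"random"`
#'   draws the seed plant at random (set the RNG seed beforehand for
#'   reproducibility).
#' @param center Point `c(x_m, y_m)` used by `seed_method = "center"`;
#'   defaults to the centroid of the plant bounding box. Pass the camera's
#'   [nadir_point()] when available.
#' @param refine_iters After the first collect-recentre pass, how many times
#'   to re-collect members around the updated line until membership
#'   stabilizes (default 1 = the single pass of the original procedure;
#'   capped at 10).
#' @return A tibble of class `ridge_set`, one row per ridge, sorted by signed
#'   perpendicular offset: `ridge_id`, `angle_rad`, `anchor_x_m`,
#'   `anchor_y_m`, `offset_m`, `n_members`, `k`, `b` (slope/intercept, `NA`
#'   for vertical rows) and `members` (list-column of member `object_id`s).
#'   Every plant is assigned to exactly one ridge.
#' @export
detect_ridges <- function(plants, angle_deg, row_width_m, buffer_frac = 1 / 3,
                          seed_method = c("center", "random"), center = NULL,
                          refine_iters = 1) {
  seed_method <- match.arg(seed_method)
  stopifnot(is.data.frame(plants), row_width_m > 0,
            buffer_frac > 0, buffer_frac < 0.5)
  if (nrow(plants) == 0L) {
    return(structure(
      tibble::tibble(
        ridge_id = integer(), angle_rad = double(), anchor_x_m = double(),
        anchor_y_m = double(), offset_m = double(), n_members = integer(),
        k = double(), b = double(), members = list()
      ),
      class = c("ridge_set", "tbl_df", "tbl", "data.frame")
    ))
  }
  angle_rad <- (angle_deg %% 180) * pi / 180
  buffer_m <- buffer_frac * row_width_m
  refine_iters <- min(max(refine_iters, 1L), 10L)
  x <- plants$ax_m
  y <- plants$ay_m
  off <- signed_offset(x, y, angle_rad)
  if (is.null(center)) {
    center <- c(mean(range(x)), mean(range(y)))
  }
  d_center <- sqrt((x - center[1])^2 + (y - center[2])^2)

  unassigned <- rep(TRUE, nrow(plants))
  out <- list()
  while (any(unassigned)) {
    cand <- which(unassigned)
    seed_i <- if (seed_method == "center") {
      cand[which.min(d_center[cand])]
    } else {
      cand[sample.int(length(cand), 1L)]
    }
    line_off <- off[seed_i]
    members <- NULL
    for (it in seq_len(refine_iters)) {
      new_members <- cand[abs(off[cand] - line_off) <= buffer_m]
      line_off <- mean(off[new_members])
      if (identical(new_members, members)) break
      members <- new_members
    }
    anchor <- c(mean(x[members]), mean(y[members]))
    out[[length(out) + 1L]] <- list(members = members, anchor = anchor)
    unassigned[members] <- FALSE
  }

  res <- purrr::map_dfr(out, function(rg) {
    kb <- line_params(rg$anchor[1], rg$anchor[2], angle_rad)
    tibble::tibble(
      angle_rad = angle_rad,
      anchor_x_m = rg$anchor[1],
      anchor_y_m = rg$anchor[2],
      offset_m = signed_offset(rg$anchor[1], rg$anchor[2], angle_rad),
      n_members = length(rg$members),
      k = kb[["k"]],
      b = kb[["b"]],
      members = list(plants$object_id[rg$members])
    )
  })
  res <- dplyr::arrange(res, .data$offset_m)
  res <- tibble::add_column(res, ridge_id = seq_len(nrow(res)), .before = 1)
  structure(res, class = c("ridge_set", "tbl_df", "tbl", "data.frame"))
}

#' Drop sparsely populated ridges
#'
#' In weedy scenes, weeds between rows can seed their own low-membership
#' "ridges". True crop rows carry many plants, so ridges whose member count
#' falls below an absolute minimum or below a fraction of the best-populated
#' ridge are pruned; their members then fail the ridge-distance weed test.
#'
#' @param ridges A `ridge_set` from [detect_ridges()].
#' @param min_members Absolute minimum member count (default 2).
#' @param member_frac Relative minimum as a fraction of the largest ridge's
#'   member count (default 0 = no relative pruning).
#' @return The surviving `ridge_set`, ids renumbered in offset order.
#' @export
prune_ridges <- function(ridges, min_members = 2, member_frac = 0) {
  stopifnot(inherits(ridges, "ridge_set"))
  if (nrow(ridges) == 0L) return(ridges)
  cutoff <- max(min_members, ceiling(member_frac * max(ridges$n_members)))
  out <- ridges[ridges$n_members >= cutoff, , drop = FALSE]
  out$ridge_id <- seq_len(nrow(out))
  structure(out, class = c("ridge_set", "tbl_df", "tbl", "data.frame"))
}

#' Flag plants outside the row buffers as weeds
#'
#' Row crops grow on the planting ridges; vegetation found beyond a tolerance
#' from every detected ridge line is flagged as weed and excluded from
#' spacing calculations. The conventional tolerance equals the membership
#' buffer, `buffer_frac * row_width`.
#'
#' @param plants Corrected-plant tibble with `ax_m`, `ay_m`.
#' @param ridges A `ridge_set` (typically after [prune_ridges()]).
#' @param tolerance_m Maximum perpendicular distance from the nearest ridge
#'   (meters, > 0).
#' @return `plants` with added columns `ridge_id` (nearest ridge),
#'   `dist_to_ridge_m`, and `weed` (logical). Kept and removed sets partition
#'   the input.
#' @export
filter_weeds <- function(plants, ridges, tolerance_m) {
  stopifnot(is.data.frame(plants), tolerance_m > 0)
  out <- tibble::as_tibble(plants)
  if (nrow(ridges) == 0L) {
    warning("no ridges to test against; all plants flagged as weeds")
    out$ridge_id <- NA_integer_
    out$dist_to_ridge_m <- Inf
    out$weed <- TRUE
    return(out)
  }
  off <- signed_offset(out$ax_m, out$ay_m, ridges$angle_rad[1])
  dmat <- abs(outer(off, ridges$offset_m, "-"))
  nearest <- apply(dmat, 1L, which.min) # ties -> lowest ridge_id
  out$ridge_id <- ridges$ridge_id[nearest]
  out$dist_to_ridge_m <- dmat[cbind(seq_len(nrow(out)), nearest)]
  out$weed <- out$dist_to_ridge_m > tolerance_m
  out
}
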