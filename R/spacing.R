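#' Project plants onto their nearest ridge line
#'
#' Each corrected stem position is assigned to the ridge minimizing its
#' perpendicular distance (ties break to the lowest `ridge_id`) and replaced
#' by its orthogonal projection — the perpendicular foot — on that ridge
#' line. Interval distances are then measured between feet along the line.
#'
#' @param plants Corrected-plant tibble with `object_id`, `ax_m`, `ay_m`.
#'   Rows flagged `weed` (if the column exists) are dropped first.
#' @param ridges A `ridge_set` from [detect_ridges()] / [prune_ridges()].
#' @return `plants` (kept rows) with added columns `ridge_id`,
#'   `dist_to_ridge_m`, `foot_x_m`, `foot_y_m`.
#' @export
project_to_ridges <- function(plants, ridges) {
  stopifnot(is.data.frame(plants))
  if (nrow(ridges) == 0L) stop("no ridges to project onto", call. = FALSE)
  out <- tibble::as_tibble(plants)
  if ("weed" %in% names(out)) out <- out[!out$weed, , drop = FALSE]
  angle <- ridges$angle_rad[1]
  u <- row_direction(angle)
  nv <- row_normal(angle)
  off <- signed_offset(out$ax_m, out$ay_m, angle)
  dmat <- abs(outer(off, ridges$offset_m, "-"))
  nearest <- apply(dmat, 1L, which.min)
  out$ridge_id <- ridges$ridge_id[nearest]
  out$dist_to_ridge_m <- dmat[cbind(seq_len(nrow(out)), nearest)]
  # foot = point minus its normal component relative to the ridge line
  resid <- off - ridges$offset_m[nearest]
  out$foot_x_m <- out$ax_m - resid * nv[1]
  out$foot_y_m <- out$ay_m - resid * nv[2]
  out
}

#' Order plants along each ridge and measure consecutive intervals
#'
#' For every ridge, a reference point is placed far before the first plant
#' along the row direction (at `anchor - ref_mult * scene_diagonal * u`, a
#' construction that works for every row orientation, including vertical rows
#' where a literal far-left x-intercept is undefined). Each foot point's
#' distance to the reference is computed, feet are sorted in ascending
#' distance, and consecutive differences become the interval distances.
#'
#' @param projected Output of [project_to_ridges()].
#' @param ridges The matching `ridge_set`.
#' @param cam Optional [camera_model()]; its ground diagonal sets the
#'   reference distance scale. Without it the span of the data is used.
#' @param ref_mult Multiple of the scene diagonal at which the reference
#'   point is placed (default 10).
#' @return A tibble of class `spacing_table`, one row per consecutive pair
#'   within a ridge: `ridge_id`, `plant_id_a`, `plant_id_b`, `interval_m`,
#'   `cum_a_m`, `cum_b_m` (distances from the row start), `duplicate_pair`
#'   (zero-length interval), `truncated_pair` (either plant clipped at the
#'   image border, when known). Ridges with a single plant contribute no
#'   pairs; zero intervals raise a duplicate-plant warning.
#' @export
measure_spacing <- function(projected, ridges, cam = NULL, ref_mult = 10) {
  stopifnot(is.data.frame(projected), nrow(ridges) >= 1L)
  diag_m <- if (!is.null(cam)) {
    cam$l_diagonal_m
  } else {
    max(diff(range(projected$foot_x_m)), diff(range(projected$foot_y_m)), 1)
  }
  angle <- ridges$angle_rad[1]
  u <- row_direction(angle)
  trunc <- if ("truncated" %in% names(projected)) projected$truncated else
    rep(FALSE, nrow(projected))

  res <- purrr::map_dfr(seq_len(nrow(ridges)), function(i) {
    rid <- ridges$ridge_id[i]
    sel <- which(projected$ridge_id == rid)
    if (length(sel) < 2L) {
      if (length(sel) == 1L) {
        warning("ridge ", rid, " has a single plant; no intervals")
      }
      return(NULL)
    }
    ref <- c(ridges$anchor_x_m[i], ridges$anchor_y_m[i]) - ref_mult * diag_m * u
    d_ref <- metric_distance(projected$foot_x_m[sel], projected$foot_y_m[sel],
                             ref[1], ref[2])
    ord <- order(d_ref, projected$object_id[sel])
    sel <- sel[ord]
    d_ref <- d_ref[ord]
    cum <- d_ref - d_ref[1]
    n <- length(sel)
    tibble::tibble(
      ridge_id = rid,
      plant_id_a = projected$object_id[sel[-n]],
      plant_id_b = projected$object_id[sel[-1]],
      interval_m = diff(d_ref),
      cum_a_m = cum[-n],
      cum_b_m = cum[-1],
      duplicate_pair = diff(d_ref) == 0,
      truncated_pair = trunc[sel[-n]] | trunc[sel[-1]]
    )
  })
  if (nrow(res) > 0 && any(res$duplicate_pair)) {
    warning(sum(res$duplicate_pair),
            " zero-length interval(s): coincident plants flagged as duplicates")
  }
  structure(res, class = c("spacing_table", "tbl_df", "tbl", "data.frame"))
}

#' Per-ridge spacing summary
#'
#' @param spacing A `spacing_table` from [measure_spacing()].
#' @param exclude_truncated Drop pairs involving border-truncated plants
#'   (default `FALSE`).
#' @return A tibble with one row per ridge: `ridge_id`, `n_intervals`,
#'   `mean_interval_m`, `sd_interval_m`.
#' @export
summarize_spacing <- function(spacing, exclude_truncated = FALSE) {
  stopifnot(is.data.frame(spacing))
  dat <- spacing
  if (exclude_truncated && "truncated_pair" %in% names(dat)) {
    dat <- dat[!dat$truncated_pair, , drop = FALSE]
  }
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(dat), .data$ridge_id),
    n_intervals = dplyr::n(),
    mean_interval_m = mean(.data$interval_m),
    sd_interval_m = stats::sd(.data$interval_m),
    .groups = "drop"
  )
}
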