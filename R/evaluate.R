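#' Match detected ridges to ground-truth row lines
#'
#' Rows are matched on their signed perpendicular offsets: each detected
#' ridge is paired with the nearest truth row, keeping matches closer than
#' `max_offset_m` and resolving contention for the same truth row in favor of
#' the nearest ridge.
#'
#' @param ridges A `ridge_set` from the pipeline.
#' @param true_rows Truth row tibble with `row_id` and `offset_m` (e.g.
#'   `scene$truth$rows`).
#' @param max_offset_m Maximum offset mismatch (default half the median truth
#'   row spacing, or `Inf` for a single row).
#' @return A tibble with columns `ridge_id`, `row_id`, `offset_error_m`.
#' @export
match_ridges <- function(ridges, true_rows, max_offset_m = NULL) {
  stopifnot(is.data.frame(ridges), is.data.frame(true_rows))
  if (nrow(ridges) == 0L || nrow(true_rows) == 0L) {
    return(tibble::tibble(ridge_id = integer(), row_id = integer(),
                          offset_error_m = double()))
  }
  if (is.null(max_offset_m)) {
    max_offset_m <- if (nrow(true_rows) > 1) {
      stats::median(diff(sort(true_rows$offset_m))) / 2
    } else Inf
  }
  d <- abs(outer(ridges$offset_m, true_rows$offset_m, "-"))
  nearest <- apply(d, 1L, which.min)
  out <- tibble::tibble(
    ridge_id = ridges$ridge_id,
    row_id = true_rows$row_id[nearest],
    offset_error_m = d[cbind(seq_len(nrow(ridges)), nearest)]
  )
  out <- out[out$offset_error_m <= max_offset_m, , drop = FALSE]
  # at most one ridge per truth row: keep the nearest
  out <- dplyr::slice_min(dplyr::group_by(out, .data$row_id),
                          .data$offset_error_m, n = 1, with_ties = FALSE)
  dplyr::ungroup(out)
}

#' Evaluate a pipeline run against simulator ground truth
#'
#' Matches detected ridges to truth rows, pairs estimated and true intervals
#' by along-row rank within each matched row, and computes the accuracy
#' metrics in centimeters (the conventional reporting unit).
#'
#' With `mode = "pairwise"` the paired metrics `d_e`, `r` (relative to the
#' design interval) and `d_t` are computed over all pairs pooled across rows;
#' when a row's estimated and true interval counts differ (missed or merged
#' plants), only the first `min(n, n')` ranks pair up — the row-wise mode
#' exists precisely because field counts differ. With `mode = "rowwise"` the
#' unpaired per-row bias `d_t` and relative error `r` are returned, one row
#' of output per matched row.
#'
#' @param run A `spacing_run` from [run_pipeline()].
#' @param truth Scene truth from [render_scene()] (list with `rows` and
#'   `intervals`).
#' @param mode `"pairwise"` or `"rowwise"`.
#' @param design_d_m Nominal planting interval in meters (required for
#'   `"pairwise"`; e.g. `spec$interval_m`).
#' @param exclude_truncated Drop interval pairs involving border-truncated
#'   plants before evaluating (default `FALSE`).
#' @return For `"pairwise"`: a one-row tibble `d_e_cm`, `r_pct`, `d_t_cm`,
#'   `n`. For `"rowwise"`: a tibble with one row per matched row: `row_id`,
#'   `ridge_id`, `d_t_cm`, `r_pct`, `n`, `n_prime`.
#' @export
evaluate_run <- function(run, truth, mode = c("pairwise", "rowwise"),
                         design_d_m = NULL, exclude_truncated = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(run, "spacing_run"))
  matches <- match_ridges(run$ridges, truth$rows)
  if (nrow(matches) == 0L) {
    stop("alignment error: no detected ridge matches a truth row",
         call. = FALSE)
  }
  spacing <- run$spacing
  if (exclude_truncated && "truncated_pair" %in% names(spacing)) {
    spacing <- spacing[!spacing$truncated_pair, , drop = FALSE]
  }

  per_row <- purrr::map_dfr(seq_len(nrow(matches)), function(i) {
    est <- spacing$interval_m[spacing$ridge_id == matches$ridge_id[i]]
    tru <- truth$intervals$interval_m[
      truth$intervals$row_id == matches$row_id[i]]
    tru <- tru[order(truth$intervals$rank[
      truth$intervals$row_id == matches$row_id[i]])]
    tibble::tibble(
      row_id = matches$row_id[i],
      ridge_id = matches$ridge_id[i],
      est = list(est), tru = list(tru)
    )
  })
  per_row <- per_row[
    lengths(per_row$est) > 0 & lengths(per_row$tru) > 0, , drop = FALSE]
  if (nrow(per_row) == 0L) {
    stop("undefined metric: no row with both estimated and true intervals",
         call. = FALSE)
  }

  if (mode == "pairwise") {
    if (is.null(design_d_m)) {
      stop("`design_d_m` is required for pairwise evaluation", call. = FALSE)
    }
    pairs <- purrr::map_dfr(seq_len(nrow(per_row)), function(i) {
      k <- min(lengths(per_row$est[i]), lengths(per_row$tru[i]))
      tibble::tibble(est = per_row$est[[i]][seq_len(k)],
                     tru = per_row$tru[[i]][seq_len(k)])
    })
    pairwise_metrics(pairs$est * 100, pairs$tru * 100,
                     design_d = design_d_m * 100) |>
      dplyr::rename(d_e_cm = "d_e", d_t_cm = "d_t")
  } else {
    purrr::map_dfr(seq_len(nrow(per_row)), function(i) {
      m <- rowwise_metrics(per_row$est[[i]] * 100, per_row$tru[[i]] * 100)
      tibble::add_column(
        dplyr::rename(m, d_t_cm = "d_t"),
        row_id = per_row$row_id[i], ridge_id = per_row$ridge_id[i],
        .before = 1
      )
    })
  }
}
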