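#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pipeline run into its interval table
#'
#' @param x A `spacing_run`.
#' @param ... Unused.
#' @return The `spacing_table` tibble: one row per consecutive plant pair
#'   with its ridge, interval distance and quality flags.
#' @export
tidy.spacing_run <- function(x, ...) {
  tibble::as_tibble(x$spacing)
}

#' One-row summary of a pipeline run
#'
#' @param x A `spacing_run`.
#' @param ... Unused.
#' @return A one-row tibble: object/plant/weed/ridge/interval counts, mean
#'   and SD of the interval distances (m), the EXG threshold used, and the
#'   config hash.
#' @export
glance.spacing_run <- function(x, ...) {
  n_weeds <- if ("weed" %in% names(x$plants)) sum(x$plants$weed) else 0L
  tibble::tibble(
    n_objects = nrow(x$objects),
    n_plants = nrow(x$plants) - n_weeds,
    n_weeds = n_weeds,
    n_ridges = nrow(x$ridges),
    n_intervals = nrow(x$spacing),
    mean_interval_m = if (nrow(x$spacing)) mean(x$spacing$interval_m)
                      else NA_real_,
    sd_interval_m = if (nrow(x$spacing) > 1) stats::sd(x$spacing$interval_m)
                    else NA_real_,
    exg_threshold = x$threshold,
    config_hash = x$config$hash
  )
}
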