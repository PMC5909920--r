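#' Pairwise interval-accuracy metrics
#'
#' Compares estimated interval distances against their paired ground-truth
#' values. Three metrics summarize the agreement:
#' * `d_e`, the mean absolute error `mean(|ed_i - d_i|)`;
#' * `r`, the relative error `d_e / d` against the design (nominal planting)
#'   interval `d`, reported in percent;
#' * `d_t`, the signed mean error (bias) `mean(ed_i - d_i)`; negative values
#'   mean underestimation.
#'
#' `d_e >= |d_t|` always; errors of opposite sign cancel in `d_t` but not in
#' `d_e`. All three scale with the input units (use cm in, get cm out); `r`
#' is unit-free.
#'
#' @param estimated,truth Numeric vectors of paired interval distances, same
#'   length, same units.
#' @param design_d The nominal planting interval `d` in the same units (> 0).
#' @return A one-row tibble: `d_e`, `r_pct`, `d_t`, `n`.
#' @examples
#' pairwise_metrics(c(10, 19), c(9, 18), design_d = 9)
#' @export
pairwise_metrics <- function(estimated, truth, design_d) {
  if (length(estimated) != length(truth)) {
    stop("pairing error: `estimated` and `truth` must have equal length",
         call. = FALSE)
  }
  if (length(estimated) == 0L) {
    stop("undefined metric: no interval pairs", call. = FALSE)
  }
  stopifnot(is.numeric(estimated), is.numeric(truth),
            is.numeric(design_d), design_d > 0)
  err <- estimated - truth
  tibble::tibble(
    d_e = mean(abs(err)),
    r_pct = 100 * mean(abs(err)) / design_d,
    d_t = mean(err),
    n = length(err)
  )
}

#' Row-wise interval-accuracy metrics
#'
#' Field rows rarely yield the same number of estimated and measured
#' intervals (missed plants, merged neighbors, uncounted weeds), so the
#' row-wise bias compares unpaired means:
#' `d_t = mean(estimated) - mean(truth)`, with relative error
#' `r = d_t / mean(truth)` in percent. Both depend on the means only, not on
#' the ordering or pairing within the row.
#'
#' @param estimated Numeric vector of estimated intervals for one row
#'   (length `n`).
#' @param truth Numeric vector of measured intervals for the same row
#'   (length `n'`, may differ from `n`).
#' @return A one-row tibble: `d_t`, `r_pct`, `n`, `n_prime`.
#' @examples
#' rowwise_metrics(c(21, 21), c(20, 20, 20)) # d_t = +1, r = +5%
#' @export
rowwise_metrics <- function(estimated, truth) {
  if (length(truth) == 0L || length(estimated) == 0L) {
    stop("undefined metric: empty interval list", call. = FALSE)
  }
  stopifnot(is.numeric(estimated), is.numeric(truth))
  d_t <- mean(estimated) - mean(truth)
  tibble::tibble(
    d_t = d_t,
    r_pct = 100 * d_t / mean(truth),
    n = length(estimated),
    n_prime = length(truth)
  )
}
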