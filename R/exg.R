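#' Excess-green (EXG) vegetation index
#'
#' Computes the per-pixel EXG score `2g - r - b` on chromatic coordinates,
#' where `r = R*/(R* + G* + B*)` etc. and the starred bands are the raw bands
#' normalized by a band maximum. EXG separates green vegetation (high, up to
#' 2 for pure green) from soil and residue (near or below 0); a perfectly
#' gray pixel scores exactly 0.
#'
#' @param image A numeric array `[rows, cols, 3]` of RGB values. Values may be
#'   on `[0, 1]` (as returned by [png::readPNG()] / [tiff::readTIFF()]) or
#'   `0..255`; they are only used through ratios.
#' @param normalize How to normalize each band before forming chromatic
#'   coordinates: `"image"` (default) divides each band by its own per-image
#'   maximum; `"depth"` divides by the bit-depth maximum (`max_value`), making
#'   EXG independent of image content.
#' @param max_value Bit-depth maximum used when `normalize = "depth"`.
#'   Defaults to 1 for images on `[0, 1]`, 255 otherwise.
#' @return A numeric matrix `[rows, cols]` of EXG values in `[-1, 2]`.
#'   Pixels whose normalized bands sum to zero (sensor dropouts) score 0.
#' @examples
#' img <- array(0, dim = c(2, 2, 3))
#' img[1, 1, 2] <- 1 # pure green
#' compute_exg(img)[1, 1] # 2
#' @export
compute_exg <- function(image, normalize = c("image", "depth"),
                        max_value = NULL) {
  normalize <- match.arg(normalize)
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop("`image` must be a [rows, cols, 3] RGB array", call. = FALSE)
  }
  if (any(image < 0, na.rm = TRUE)) {
    stop("negative channel values", call. = FALSE)
  }
  R <- image[, , 1]; G <- image[, , 2]; B <- image[, , 3]
  if (normalize == "image") {
    # per-image band maxima; an all-zero band stays zero
    div <- function(m) if ((mx <- max(m)) > 0) m / mx else m
    R <- div(R); G <- div(G); B <- div(B)
  } else {
    if (is.null(max_value)) max_value <- if (max(image) > 1) 255 else 1
    R <- R / max_value; G <- G / max_value; B <- B / max_value
  }
  s <- R + G + B
  zero <- s == 0
  s[zero] <- 1 # avoid 0/0; those pixels are defined as EXG = 0
  exg <- (2 * G - R - B) / s
  exg[zero] <- 0
  exg
}

#' Threshold an EXG image into a vegetation mask
#'
#' Binarizes an EXG image into vegetation (TRUE) and background. `"otsu"`
#' computes the threshold maximizing between-class variance of the EXG
#' histogram; `"fixed"` uses a user-supplied EXG cutoff (e.g. 0 for clean
#' indoor scenes, 0.1 for field scenes with brighter backgrounds).
#'
#' @param exg EXG matrix from [compute_exg()].
#' @param mode `"otsu"` or `"fixed"`.
#' @param fixed_value EXG threshold, required when `mode = "fixed"`.
#' @param levels Histogram resolution for Otsu (default 256).
#' @return A logical matrix, `TRUE` = vegetation (`exg > threshold`), with the
#'   threshold used attached as attribute `"threshold"`.
#' @export
threshold_vegetation <- function(exg, mode = c("otsu", "fixed"),
                                 fixed_value = NULL, levels = 256) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(exg))
  if (mode == "fixed") {
    if (is.null(fixed_value) || !is.numeric(fixed_value)) {
      stop("`fixed_value` is required when mode = \"fixed\"", call. = FALSE)
    }
    thr <- fixed_value
  } else {
    rng <- range(exg)
    if (diff(rng) == 0) {
      stop("degenerate EXG histogram: constant image has no Otsu threshold",
           call. = FALSE)
    }
    # EBImage::otsu works on [0, 1]; rescale EXG there and map back
    scaled <- (exg - rng[1]) / diff(rng)
    t01 <- EBImage::otsu(scaled, range = c(0, 1), levels = levels)
    thr <- rng[1] + t01 * diff(rng)
  }
  mask <- exg > thr
  attr(mask, "threshold") <- thr
  mask
}
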