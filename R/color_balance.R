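#' Color-balance an underwater photoquadrat
#'
#' Underwater imagery loses red light with depth, leaving a green/blue cast.
#' The balancing operator works in two fixed steps on raw 8-bit values:
#'
#' 1. Red compensation: with `G_bar`, `B_bar` the input means of the green
#'    and blue channels, every pixel's red value becomes
#'    `R + alpha * (G_bar + B_bar) / 2` (green and blue unchanged).
#' 2. Brightness reduction: all three channels of every pixel are multiplied
#'    by `1 - beta`, countering overexposure.
#'
#' Results are rounded half-up and clipped to `[0, 255]` after each step.
#' With `alpha = 0, beta = 0` the output equals the input bit-exactly.
#'
#' @param img A [raster_image()].
#' @param alpha Red gain, non-negative (default 0.3): the red shift is
#'   proportional to the image-average green/blue level.
#' @param beta Brightness reduction fraction in `[0, 1)` (default 0.1).
#' @return A [raster_image()] with the applied parameters attached as the
#'   `balance_params` attribute.
#' @examples
#' img <- raster_image(array(100, dim = c(8, 8, 3)))
#' out <- balance(img, alpha = 0.3, beta = 0.1)
#' out[1, 1, ]  # 117, 90, 90
#' @export
balance <- function(img, alpha = 0.3, beta = 0.1) {
  img <- assert_raster(img)
  if (!is.numeric(alpha) || alpha < 0)
    stop_reefquad("`alpha` must be non-negative", "reefquad_invalid_params")
  if (!is.numeric(beta) || beta < 0 || beta >= 1)
    stop_reefquad("`beta` must lie in [0, 1)", "reefquad_invalid_params")
  g_bar <- mean(img[, , 2]); b_bar <- mean(img[, , 3])
  out <- array(as.numeric(unclass(img)), dim = dim(img))
  out[, , 1] <- clip255(round_half_up(out[, , 1] + alpha * (g_bar + b_bar) / 2))
  out <- clip255(round_half_up(out * (1 - beta)))
  res <- raster_image(out)
  attr(res, "balance_params") <- list(alpha = alpha, beta = beta,
                                      green_mean = g_bar, blue_mean = b_bar)
  res
}

#' Quantify the change in green/blue cast after balancing
#'
#' Returns the absolute gap between the mean red channel and the mean
#' green/blue level, after minus before:
#' `|R_bar - (G_bar + B_bar)/2|_after - |...|_before`. Negative values mean
#' the cast was reduced; red overshoot past the green/blue level scores
#' positive, not negative.
#'
#' @param before,after [raster_image()]s of identical dimensions.
#' @return A scalar score.
#' @export
cast_reduction_score <- function(before, after) {
  before <- assert_raster(before); after <- assert_raster(after)
  if (!identical(dim(before), dim(after)))
    stop_reefquad("`before` and `after` must have identical dimensions",
                  "reefquad_dim_mismatch")
  gap <- function(x) abs(mean(x[, , 1]) - (mean(x[, , 2]) + mean(x[, , 3])) / 2)
  gap(after) - gap(before)
}

#' Closed-form red gain that equalizes red to the green/blue level
#'
#' Solves step 1 of [balance()] for the `alpha` that makes the output red
#' mean equal the input green/blue mean level:
#' `alpha* = (G_bar + B_bar - 2 R_bar) / (G_bar + B_bar)` (0 when the image
#' has no positive cast).
#'
#' @param img A [raster_image()].
#' @return Non-negative scalar `alpha`.
#' @export
suggest_alpha <- function(img) {
  img <- assert_raster(img)
  r <- mean(img[, , 1]); g <- mean(img[, , 2]); b <- mean(img[, , 3])
  if (g + b <= 0) return(0)
  max(0, (g + b - 2 * r) / (g + b))
}

#' Color-balance a directory of images
#'
#' @param in_dir,out_dir Input/output directories (PNG).
#' @param alpha,beta Passed to [balance()].
#' @return Data.frame listing processed images; parameters are echoed to a
#'   JSON sidecar `balance_params.json` in `out_dir`.
#' @export
balance_batch <- function(in_dir, out_dir, alpha = 0.3, beta = 0.1) {
  files <- list.files(in_dir, pattern = "\\.png$", full.names = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (f in files) write_image(balance(read_image(f), alpha, beta),
                               file.path(out_dir, basename(f)))
  jsonlite::write_json(list(alpha = alpha, beta = beta),
                       file.path(out_dir, "balance_params.json"),
                       auto_unbox = TRUE, digits = NA)
  data.frame(image = basename(files), alpha = alpha, beta = beta)
}
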