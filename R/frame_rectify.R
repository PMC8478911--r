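#' Rotate a raster image about its center
#'
#' Rotates image content by `angle_deg` (positive = counter-clockwise in
#' pixel coordinates) about the image center, keeping the output dimensions.
#' Bilinear interpolation with edge-reflection padding is used by default;
#' an exact zero angle returns the input unchanged, so the pure-crop path of
#' [rectify_and_crop()] is bit-exact.
#'
#' @param img A [raster_image()].
#' @param angle_deg Rotation angle in degrees.
#' @param method `"bilinear"` or `"nearest"`.
#' @return A [raster_image()] of the same dimensions.
#' @export
rotate_raster <- function(img, angle_deg, method = c("bilinear", "nearest")) {
  img <- assert_raster(img)
  method <- match.arg(method)
  if (abs(angle_deg) < 1e-12) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  src <- rotation_source_coords(h, w, angle_deg)
  out <- array(0L, dim = c(h, w, 3))
  if (method == "nearest") {
    sx <- reflect_coord(round(src$x), w); sy <- reflect_coord(round(src$y), h)
    idx <- cbind(sy + 1, sx + 1)
    for (j in 1:3) out[, , j] <- matrix(img[, , j][idx], h, w)
  } else {
    x0 <- floor(src$x); y0 <- floor(src$y)
    fx <- src$x - x0; fy <- src$y - y0
    x0r <- reflect_coord(x0, w); x1r <- reflect_coord(x0 + 1, w)
    y0r <- reflect_coord(y0, h); y1r <- reflect_coord(y0 + 1, h)
    i00 <- cbind(y0r + 1, x0r + 1); i01 <- cbind(y0r + 1, x1r + 1)
    i10 <- cbind(y1r + 1, x0r + 1); i11 <- cbind(y1r + 1, x1r + 1)
    for (j in 1:3) {
      ch <- img[, , j]
      v <- (1 - fy) * ((1 - fx) * ch[i00] + fx * ch[i01]) +
        fy * ((1 - fx) * ch[i10] + fx * ch[i11])
      out[, , j] <- matrix(clip255(round_half_up(v)), h, w)
    }
  }
  raster_image(out)
}

# inverse-map source coordinates (0-based) for every output pixel
rotation_source_coords <- function(h, w, angle_deg) {
  t <- angle_deg * pi / 180
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  px <- rep(0:(w - 1), each = h); py <- rep(0:(h - 1), times = w)
  dx <- px - cx; dy <- py - cy
  list(x = cx + cos(t) * dx + sin(t) * dy,
       y = cy - sin(t) * dx + cos(t) * dy)
}

reflect_coord <- function(s, n) {
  s <- abs(s)
  over <- s > (n - 1)
  s[over] <- 2 * (n - 1) - s[over]
  pmin(pmax(s, 0), n - 1)
}

#' Rotate an integer label map (nearest neighbour)
#'
#' Companion to [rotate_raster()] for ground-truth label rasters; pixels
#' sampled from outside the source grid get label 0.
#'
#' @param map Integer matrix (e.g. `truth$label_map`).
#' @param angle_deg Rotation angle in degrees.
#' @return Integer matrix of the same dimensions, `labels` attribute kept.
#' @export
rotate_label_map <- function(map, angle_deg) {
  if (abs(angle_deg) < 1e-12) return(map)
  h <- nrow(map); w <- ncol(map)
  src <- rotation_source_coords(h, w, angle_deg)
  sx <- round(src$x); sy <- round(src$y)
  ok <- sx >= 0 & sx <= (w - 1) & sy >= 0 & sy <= (h - 1)
  out <- integer(h * w)
  out[ok] <- map[cbind(sy[ok] + 1, sx[ok] + 1)]
  out <- matrix(out, h, w)
  attr(out, "labels") <- attr(map, "labels")
  out
}

#' Detect the PVC quadrat frame in a photoquadrat
#'
#' Thresholds near-white pixels (all three channels at or above
#' `brightness_threshold`), keeps the largest connected component, and finds
#' the rotation in `[-20, 20]` degrees that axis-aligns the band by
#' minimising the area of the component's bounding box over candidate
#' rotations (coarse-to-fine search on the convex hull). The largest
#' axis-aligned rectangle interior to the band after that rotation is
#' returned, along with a confidence score: the fraction of a mid-band
#' perimeter rectangle covered by bright pixels.
#'
#' @param img A [raster_image()] (at least 64 px per side).
#' @param brightness_threshold Near-white channel threshold in `[0, 255]`
#'   (default 200).
#' @param min_band_fraction Minimum perimeter coverage required to accept a
#'   detection (default 0.6); below it a `reefquad_frame_not_found` error is
#'   signalled (post-2014 imagery has no frame, so callers may catch it and
#'   skip rectification).
#' @return A list of class `frame_detection` with `rotation_deg` (the
#'   counter-clockwise correction to apply), `inner_bbox` (0-based half-open
#'   `c(top, left, bottom, right)`, valid after rotation), and `confidence`.
#' @export
detect_frame <- function(img, brightness_threshold = 200, min_band_fraction = 0.6) {
  img <- assert_raster(img, min_side = 64L)
  h <- dim(img)[1]; w <- dim(img)[2]
  mask <- img[, , 1] >= brightness_threshold &
    img[, , 2] >= brightness_threshold &
    img[, , 3] >= brightness_threshold
  if (sum(mask) < 0.002 * h * w)
    stop_reefquad("frame not found: too few near-white pixels", "reefquad_frame_not_found")

  cc <- EBImage::bwlabel(mask * 1L)
  sizes <- tabulate(cc[cc > 0])
  comp <- cc == which.max(sizes)
  if (max(sizes) < 0.002 * h * w)
    stop_reefquad("frame not found: no sufficiently large bright component",
                  "reefquad_frame_not_found")

  idx <- which(comp)
  py <- (idx - 1) %% h; px <- (idx - 1) %/% h     # 0-based (row, col)
  hull <- grDevices::chull(px, py)
  hx <- px[hull]; hy <- py[hull]
  cx <- (w - 1) / 2; cy <- (h - 1) / 2

  bbox_area <- function(t_deg) {
    t <- t_deg * pi / 180
    dx <- hx - cx; dy <- hy - cy
    x2 <- cos(t) * dx - sin(t) * dy
    y2 <- sin(t) * dx + cos(t) * dy
    (max(x2) - min(x2)) * (max(y2) - min(y2))
  }
  coarse <- seq(-20, 20, by = 0.5)
  t1 <- coarse[which.min(vapply(coarse, bbox_area, numeric(1)))]
  fine <- seq(max(-20, t1 - 0.6), min(20, t1 + 0.6), by = 0.02)
  rot <- fine[which.min(vapply(fine, bbox_area, numeric(1)))]

  # derotate the component mask and locate the band's inner edges by scanning
  # outward from the component centroid
  comp_r <- rotate_label_map(matrix(as.integer(comp), h, w), rot) == 1L
  ridx <- which(comp_r)
  if (!length(ridx))
    stop_reefquad("frame not found: band lost after rotation", "reefquad_frame_not_found")
  ry <- (ridx - 1) %% h + 1; rx <- (ridx - 1) %/% h + 1   # 1-based
  rcen <- round(mean(range(ry))); ccen <- round(mean(range(rx)))

  colv <- comp_r[, ccen]; rowv <- comp_r[rcen, ]
  above <- which(colv[seq_len(rcen)])
  below <- which(colv[rcen:h]) + rcen - 1
  lefts <- which(rowv[seq_len(ccen)])
  rights <- which(rowv[ccen:w]) + ccen - 1
  if (!length(above) || !length(below) || !length(lefts) || !length(rights))
    stop_reefquad("frame not found: band does not enclose the image center",
                  "reefquad_frame_not_found")
  top_e <- max(above); bottom_e <- min(below)
  left_e <- max(lefts); right_e <- min(rights)

  # band thickness estimate from the contiguous runs at the four crossings
  run_len <- function(v, from, dir) {
    n <- 0L; i <- from
    while (i >= 1 && i <= length(v) && v[i]) { n <- n + 1L; i <- i + dir }
    n
  }
  th <- stats::median(c(run_len(colv, top_e, -1L), run_len(colv, bottom_e, 1L),
                        run_len(rowv, left_e, -1L), run_len(rowv, right_e, 1L)))

  # 2 px safety margin inside the inner edge (0-based half-open)
  first_r <- top_e + 1 + 2; last_r <- bottom_e - 1 - 2
  first_c <- left_e + 1 + 2; last_c <- right_e - 1 - 2
  if (last_r <= first_r || last_c <= first_c)
    stop_reefquad("frame not found: degenerate interior", "reefquad_frame_not_found")
  bbox <- c(top = first_r - 1, left = first_c - 1, bottom = last_r, right = last_c)

  # confidence: mid-band perimeter coverage
  off <- max(1L, floor(th / 2))
  pr <- pmin(pmax(c(top_e - off, bottom_e + off), 1), h)
  pc <- pmin(pmax(c(left_e - off, right_e + off), 1), w)
  per <- rbind(cbind(pr[1], pc[1]:pc[2]), cbind(pr[2], pc[1]:pc[2]),
               cbind(pr[1]:pr[2], pc[1]), cbind(pr[1]:pr[2], pc[2]))
  confidence <- mean(comp_r[per])
  if (confidence < min_band_fraction)
    stop_reefquad(sprintf(
      "frame not found: perimeter coverage %.2f below min_band_fraction %.2f",
      confidence, min_band_fraction), "reefquad_frame_not_found")

  structure(list(rotation_deg = rot, inner_bbox = bbox, confidence = confidence),
            class = "frame_detection")
}

#' @export
print.frame_detection <- function(x, ...) {
  cat(sprintf("<frame_detection> rotation %.2f deg, confidence %.2f\n",
              x$rotation_deg, x$confidence))
  cat(sprintf("  inner bbox (top,left,bottom,right): %d %d %d %d\n",
              x$inner_bbox[1], x$inner_bbox[2], x$inner_bbox[3], x$inner_bbox[4]))
  invisible(x)
}

#' Rotate a photoquadrat square and crop to the frame's inside edge
#'
#' Applies the rotation from a [detect_frame()] result (bilinear
#' interpolation) and crops to the detected interior rectangle, which
#' excludes the frame band plus a 2 px safety margin.
#'
#' @param img The [raster_image()] the detection was produced from.
#' @param det A `frame_detection`.
#' @return The rectified, cropped [raster_image()].
#' @export
rectify_and_crop <- function(img, det) {
  img <- assert_raster(img)
  stopifnot(inherits(det, "frame_detection"))
  b <- det$inner_bbox
  area <- (b["bottom"] - b["top"]) * (b["right"] - b["left"])
  if (area < 0.25 * prod(dim(img)[1:2]))
    stop_reefquad("interior rectangle covers < 25% of the image", "reefquad_degenerate_crop")
  rot <- rotate_raster(img, det$rotation_deg, method = "bilinear")
  out <- unclass(rot)[(b["top"] + 1):b["bottom"], (b["left"] + 1):b["right"], , drop = FALSE]
  raster_image(out)
}

#' Rectify a directory of photoquadrat images
#'
#' Batch wrapper: detects and crops the frame in each PNG, writing outputs
#' and a rectification report. Images whose frame is not found are copied
#' through unchanged when `skip_missing_frame` is TRUE (surveys after 2014
#' dropped the frame).
#'
#' @param in_dir,out_dir Input/output directories.
#' @param brightness_threshold,min_band_fraction Passed to [detect_frame()].
#' @param skip_missing_frame Copy frameless images through instead of
#'   erroring.
#' @return Data.frame report: `image`, `rotation_deg`, `confidence`,
#'   `status` (`"rectified"`, `"no_frame"`, or `"error"`).
#' @export
rectify_batch <- function(in_dir, out_dir, brightness_threshold = 200,
                          min_band_fraction = 0.6, skip_missing_frame = TRUE) {
  files <- list.files(in_dir, pattern = "\\.png$", full.names = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rep_rows <- lapply(files, function(f) {
    img <- read_image(f)
    res <- tryCatch({
      det <- detect_frame(img, brightness_threshold, min_band_fraction)
      out <- rectify_and_crop(img, det)
      write_image(out, file.path(out_dir, basename(f)))
      data.frame(image = basename(f), rotation_deg = det$rotation_deg,
                 confidence = det$confidence, status = "rectified")
    }, reefquad_frame_not_found = function(e) {
      if (skip_missing_frame) {
        write_image(img, file.path(out_dir, basename(f)))
        data.frame(image = basename(f), rotation_deg = NA_real_,
                   confidence = NA_real_, status = "no_frame")
      } else {
        data.frame(image = basename(f), rotation_deg = NA_real_,
                   confidence = NA_real_, status = "error")
      }
    })
    res
  })
  report <- do.call(rbind, rep_rows)
  utils::write.csv(report, file.path(out_dir, "rectification_report.csv"),
                   row.names = FALSE)
  report
}
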