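#' Specify a synthetic photoquadrat scene
#'
#' Defines a renderable benthic scene with known ground truth: spatially
#' coherent class patches, an optional near-white PVC quadrat frame at a small
#' rotation, a green/blue underwater color cast, and optional overexposure.
#' Rendering such scenes lets every downstream stage (rectification, color
#' balance, point annotation, cover estimation) be tested against known truth
#' without real imagery.
#'
#' @param width_px,height_px Image dimensions in pixels (each >= 64).
#' @param class_fractions Named numeric vector of benthic label fractions;
#'   must sum to 1 (tolerance 1e-9). Names are label codes (see
#'   [label_schema()]).
#' @param frame_present Logical; composite a PVC-style frame band over the
#'   scene.
#' @param frame_rotation_deg Frame rotation in degrees, in `[-20, 20]`.
#'   Positive values rotate the frame counter-clockwise in pixel coordinates.
#' @param frame_inner_margin_px Thickness of the frame band in pixels (the
#'   inner edge sits this far inside the outer edge).
#' @param cast_green,cast_blue Additive channel offsets in `[0, 255]` applied
#'   after scene composition, emulating the underwater green/blue cast.
#' @param overexposure_gain Multiplicative brightness gain >= 1 applied after
#'   the cast.
#' @param n_patches Number of Voronoi patches used to lay out class regions.
#' @param noise_sd Per-pixel Gaussian channel noise (pre-cast), in channel
#'   units.
#' @param seed Integer seed; all stochastic rendering derives from it.
#' @return A list of class `scene_spec`.
#' @seealso [render_quadrat()]
#' @export
scene_spec <- function(width_px = 400L, height_px = 400L,
                       class_fractions = c(SC = 0.2, MA = 0.2, SA = 0.3, CS = 0.3),
                       frame_present = TRUE, frame_rotation_deg = 0,
                       frame_inner_margin_px = 12L,
                       cast_green = 30, cast_blue = 20,
                       overexposure_gain = 1,
                       n_patches = 60L, noise_sd = 6, seed = 1L) {
  if (width_px < 64 || height_px < 64)
    stop_reefquad("width_px and height_px must be >= 64", "reefquad_invalid_spec")
  if (is.null(names(class_fractions)) || any(!nzchar(names(class_fractions))))
    stop_reefquad("class_fractions must be named by label code", "reefquad_invalid_spec")
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9)
    stop_reefquad("class_fractions must be non-negative and sum to 1", "reefquad_invalid_spec")
  if (abs(frame_rotation_deg) > 20)
    stop_reefquad("frame_rotation_deg must lie in [-20, 20]", "reefquad_invalid_spec")
  if (cast_green < 0 || cast_green > 255 || cast_blue < 0 || cast_blue > 255)
    stop_reefquad("cast offsets must lie in [0, 255]", "reefquad_invalid_spec")
  if (overexposure_gain < 1)
    stop_reefquad("overexposure_gain must be >= 1", "reefquad_invalid_spec")
  structure(list(width_px = as.integer(width_px), height_px = as.integer(height_px),
                 class_fractions = class_fractions, frame_present = isTRUE(frame_present),
                 frame_rotation_deg = frame_rotation_deg,
                 frame_inner_margin_px = as.integer(frame_inner_margin_px),
                 cast_green = cast_green, cast_blue = cast_blue,
                 overexposure_gain = overexposure_gain,
                 n_patches = as.integer(n_patches), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# reserved label for frame-band pixels in ground-truth label maps
FRAME_LABEL <- "FRAME"

# base sRGB colors per label code; all channels <= 230 so the near-white
# frame (>= 240 pre-cast) stays separable by thresholding
label_base_colors <- function(labels) {
  defaults <- rbind(
    SC   = c(205, 120, 110),  # scleractinian corals: pink-brown
    MA   = c(60, 140, 70),    # macroalgae: green
    LTA  = c(110, 150, 60),   # long turfing algae
    OCT  = c(150, 110, 170),  # octocorals: purple
    SP   = c(185, 120, 60),   # sponges: orange
    SA   = c(210, 195, 150),  # sand: tan
    RU   = c(150, 150, 140),  # rubble: grey
    CS   = c(130, 118, 96)    # consolidated substrate: brown
  )
  out <- matrix(NA_real_, length(labels), 3, dimnames = list(labels, NULL))
  known <- intersect(labels, rownames(defaults))
  out[known, ] <- defaults[known, ]
  other <- setdiff(labels, rownames(defaults))
  if (length(other)) {
    # deterministic fallback palette for user-defined labels
    hue <- (seq_along(other) * 137) %% 360
    rgb <- grDevices::col2rgb(grDevices::hcl(hue, c = 45, l = 55))
    out[other, ] <- t(pmin(rgb, 230))
  }
  out
}

# largest-remainder apportionment of N pixels to fractions (exact sum)
apportion_counts <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    idx <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[idx] <- counts[idx] + 1
  }
  as.integer(counts)
}

# frame geometry: outer/inner half-sizes chosen so the band stays inside the
# image with a small border at any rotation up to 20 degrees
frame_geometry <- function(w, h, thickness) {
  border <- 4
  t20 <- 20 * pi / 180
  cs <- cos(t20); sn <- sin(t20)
  hx0 <- w / 2; hy0 <- h / 2
  s <- min((w / 2 - border) / (cs * hx0 + sn * hy0),
           (h / 2 - border) / (sn * hx0 + cs * hy0))
  hxo <- s * hx0; hyo <- s * hy0
  list(hxo = hxo, hyo = hyo, hxi = hxo - thickness, hyi = hyo - thickness)
}

#' Render a synthetic photoquadrat with ground truth
#'
#' Lays benthic classes out as random Voronoi patches (so point sampling sees
#' spatially coherent regions, as in real quadrats), composites the frame
#' band if requested, then applies the color cast and overexposure gain. The
#' per-pixel label map is returned alongside the image. Class fractions are
#' met exactly (to one pixel) over the frame interior (the whole image when
#' no frame is present).
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `image` (a [raster_image()]) and `truth`, a
#'   `quadrat_truth` list holding `label_map` (integer matrix with a
#'   `labels` attribute; frame pixels carry the reserved `"FRAME"` label),
#'   `frame_rotation_deg`, `inner_bbox` (0-based half-open
#'   `c(top, left, bottom, right)` in rectified coordinates, i.e. after
#'   undoing the frame rotation about the image center), and
#'   `class_fractions_interior`.
#' @examples
#' sc <- render_quadrat(scene_spec(width_px = 96, height_px = 96,
#'                                 frame_present = FALSE, seed = 3))
#' sc$truth$class_fractions_interior
#' @export
render_quadrat <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  w <- spec$width_px; h <- spec$height_px
  labels <- names(spec$class_fractions)
  with_seed(spec$seed, {
    # --- Voronoi patch layout ---
    sx <- runif(spec$n_patches, 0, w - 1)
    sy <- runif(spec$n_patches, 0, h - 1)
    px <- rep(0:(w - 1), each = h)   # column-major over h x w matrix
    py <- rep(0:(h - 1), times = w)
    cell <- rep(1L, h * w)
    best <- (px - sx[1])^2 + (py - sy[1])^2
    for (k in seq_len(spec$n_patches)[-1]) {
      d <- (px - sx[k])^2 + (py - sy[k])^2
      upd <- d < best
      cell[upd] <- k
      best[upd] <- d[upd]
    }

    # --- frame masks (in original pixel coordinates) ---
    if (spec$frame_present) {
      g <- frame_geometry(w, h, spec$frame_inner_margin_px)
      a <- spec$frame_rotation_deg * pi / 180
      cx <- (w - 1) / 2; cy <- (h - 1) / 2
      dx <- px - cx; dy <- py - cy
      u <- cos(a) * dx + sin(a) * dy
      v <- -sin(a) * dx + cos(a) * dy
      inside_outer <- abs(u) <= g$hxo & abs(v) <= g$hyo
      inside_inner <- abs(u) <= g$hxi & abs(v) <= g$hyi
      band <- inside_outer & !inside_inner
      interior <- inside_inner
    } else {
      band <- rep(FALSE, h * w)
      interior <- rep(TRUE, h * w)
    }

    # --- exact label apportionment over interior pixels, ordered by cell ---
    lab <- integer(h * w)
    int_idx <- which(interior)
    ord <- int_idx[order(cell[int_idx], int_idx)]
    counts <- apportion_counts(spec$class_fractions, length(ord))
    lab[ord] <- rep(seq_along(labels), counts)
    # exterior (non-band, non-interior) pixels inherit their cell's majority
    # interior label; cells with no interior pixels draw from the fractions
    ext_idx <- which(!interior & !band)
    if (length(ext_idx)) {
      cell_lab <- integer(spec$n_patches)
      tab <- table(cell[ord], lab[ord])
      have <- as.integer(rownames(tab))
      cell_lab[have] <- as.integer(colnames(tab))[max.col(tab, ties.method = "first")]
      miss <- which(cell_lab == 0L)
      if (length(miss))
        cell_lab[miss] <- sample.int(length(labels), length(miss), replace = TRUE,
                                     prob = spec$class_fractions)
      lab[ext_idx] <- cell_lab[cell[ext_idx]]
    }

    # --- paint ---
    if (any(band)) lab[band] <- length(labels) + 1L
    cols <- label_base_colors(labels)
    n_px <- h * w
    chan <- matrix(0, n_px, 3)
    for (j in 1:3) chan[, j] <- cols[pmin(lab, length(labels)), j]
    chan <- chan + matrix(stats::rnorm(n_px * 3, 0, spec$noise_sd), n_px, 3)
    chan <- pmin(pmax(chan, 0), 235)
    if (any(band)) {
      nb <- sum(band)
      fb <- matrix(246 + stats::rnorm(nb * 3, 0, 2), nb, 3)
      chan[band, ] <- pmin(pmax(fb, 240), 255)
    }

    # --- color cast + overexposure (after composition) ---
    chan[, 2] <- chan[, 2] + spec$cast_green
    chan[, 3] <- chan[, 3] + spec$cast_blue
    chan <- chan * spec$overexposure_gain
    chan <- clip255(round_half_up(chan))

    img <- raster_image(array(c(chan[, 1], chan[, 2], chan[, 3]), dim = c(h, w, 3)))
    label_map <- matrix(lab, h, w)
    attr(label_map, "labels") <- c(labels, if (spec$frame_present) FRAME_LABEL)

    truth <- ground_truth(label_map, spec)
    list(image = img, truth = truth)
  })
}

# assemble the quadrat_truth record; interior fractions are measured from the
# rendered label map, derotated when a frame is present
ground_truth <- function(label_map, spec) {
  h <- nrow(label_map); w <- ncol(label_map)
  labels <- attr(label_map, "labels")
  n_benthic <- length(spec$class_fractions)
  if (spec$frame_present) {
    g <- frame_geometry(w, h, spec$frame_inner_margin_px)
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    bbox <- c(top = ceiling(cy - g$hyi) + 1, left = ceiling(cx - g$hxi) + 1,
              bottom = floor(cy + g$hyi), right = floor(cx + g$hxi))
    derot <- rotate_label_map(label_map, -spec$frame_rotation_deg)
    sub <- derot[(bbox["top"] + 1):bbox["bottom"], (bbox["left"] + 1):bbox["right"]]
    cnt <- tabulate(sub[sub >= 1 & sub <= n_benthic], nbins = n_benthic)
  } else {
    bbox <- c(top = 0, left = 0, bottom = h, right = w)
    cnt <- tabulate(label_map[label_map <= n_benthic], nbins = n_benthic)
  }
  fr <- cnt / sum(cnt)
  names(fr) <- labels[seq_len(n_benthic)]
  structure(list(label_map = label_map,
                 frame_rotation_deg = if (spec$frame_present) spec$frame_rotation_deg else NA_real_,
                 inner_bbox = bbox,
                 class_fractions_interior = fr),
            class = "quadrat_truth")
}

#' Simulate a multi-site benthic cover time series
#'
#' Draws per-image proportional cover from a beta distribution whose mean
#' follows an inverse-logit trend: for label l at site s in year t,
#' `mu = plogis(qlogis(baseline_l) + trend_l * (t - min(years)) + b_{s,l})`
#' with site intercepts `b_{s,l} ~ N(0, site_sd^2)`, and
#' `cover ~ Beta(mu * precision, (1 - mu) * precision)`. Ground-truth means
#' are returned alongside the draws, enabling parameter-recovery tests of the
#' trend models.
#'
#' @param n_sites Number of sites.
#' @param years Integer vector of at least 2 distinct survey years.
#' @param trend Per-label slope on the logit scale per year: either a named
#'   numeric vector (one slope per label), or a named list mapping each label
#'   to a named vector of per-reef-type slopes (e.g.
#'   `list(SC = c(patch = 0, forereef = 0.25))`).
#' @param reef_types Optional named character vector mapping site name to
#'   reef type (`"patch"` or `"forereef"`). Default: first half patch, rest
#'   forereef.
#' @param precision Beta precision parameter `phi > 0` (default 30).
#' @param seed Integer seed.
#' @param n_images Images per site-year (rows per site-year-label).
#' @param baseline Optional named vector of baseline covers in (0,1); labels
#'   missing from it default to 0.10.
#' @param site_sd Standard deviation of the per-site, per-label logit
#'   intercepts (default 0.3).
#' @param fixed_sites Character vector of sites surveyed with fixed transects
#'   (others are marked `"random"`).
#' @return A data.frame with columns `site`, `year`, `reef_type`,
#'   `transect_type`, `image`, `label`, `cover`, `true_mean`.
#' @examples
#' d <- simulate_cover_series(4, 2014:2018, trend = c(SC = 0.25), seed = 7)
#' head(d)
#' @export
simulate_cover_series <- function(n_sites, years, trend, reef_types = NULL,
                                  precision = 30, seed = NULL, n_images = 1L,
                                  baseline = NULL, site_sd = 0.3,
                                  fixed_sites = NULL) {
  if (length(unique(years)) < 2)
    stop_reefquad("`years` must contain at least 2 distinct values", "reefquad_invalid_spec")
  if (!is.numeric(precision) || precision <= 0)
    stop_reefquad("`precision` must be > 0", "reefquad_invalid_spec")
  if (is.null(names(trend)))
    stop_reefquad("`trend` must be named by label", "reefquad_invalid_spec")
  labels <- names(trend)
  if (is.null(reef_types)) {
    sites <- paste0("S", seq_len(n_sites))
    reef_types <- stats::setNames(
      ifelse(seq_len(n_sites) <= ceiling(n_sites / 2), "patch", "forereef"), sites)
  } else {
    sites <- names(reef_types)
    if (length(sites) != n_sites)
      stop_reefquad("`reef_types` must name exactly n_sites sites", "reefquad_invalid_spec")
  }
  base <- stats::setNames(rep(0.10, length(labels)), labels)
  if (!is.null(baseline)) base[names(baseline)] <- baseline
  if (any(base <= 0 | base >= 1))
    stop_reefquad("baseline covers must lie strictly in (0, 1)", "reefquad_invalid_spec")

  with_seed(seed, {
    site_eff <- matrix(stats::rnorm(n_sites * length(labels), 0, site_sd),
                       n_sites, length(labels), dimnames = list(sites, labels))
    grid <- expand.grid(image_k = seq_len(n_images), site = sites, year = sort(unique(years)),
                        label = labels, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    slope <- if (is.list(trend)) {
      mapply(function(l, rt) trend[[l]][[rt]], grid$label,
             unname(reef_types[grid$site]))
    } else trend[grid$label]
    mu <- stats::plogis(stats::qlogis(base[grid$label]) +
                          slope * (grid$year - min(years)) +
                          site_eff[cbind(grid$site, grid$label)])
    cover <- stats::rbeta(nrow(grid), mu * precision, (1 - mu) * precision)
    # rbeta can return exact 0/1 by underflow at extreme means; nudge inside
    eps <- .Machine$double.eps
    cover <- pmin(pmax(cover, eps), 1 - eps)
    data.frame(site = grid$site, year = grid$year,
               reef_type = unname(reef_types[grid$site]),
               transect_type = ifelse(grid$site %in% (fixed_sites %||% character()),
                                      "fixed", "random"),
               image = sprintf("%s_%d_img%02d", grid$site, grid$year, grid$image_k),
               label = grid$label, cover = cover, true_mean = unname(mu),
               stringsAsFactors = FALSE)
  })
}

# --- scene-set persistence: PNG + JSON sidecar + manifest CSV -------------

# run-length encode an integer vector (keeps JSON sidecars compact)
rle_pack <- function(x) {
  r <- rle(as.integer(x))
  list(lengths = r$lengths, values = r$values)
}

rle_unpack <- function(p) inverse.rle(structure(list(lengths = p$lengths,
                                                     values = p$values), class = "rle"))

#' Write a set of rendered scenes to disk
#'
#' Writes one PNG per scene, a JSON sidecar holding its ground truth
#' (label map run-length encoded), and a manifest CSV with per-image
#' metadata.
#'
#' @param scenes List of `render_quadrat()` results.
#' @param dir Output directory (created if missing).
#' @param meta Data.frame with one row per scene: columns `site`, `year`,
#'   `reef_type`, `transect_type`, `area_m2`.
#' @return Path to the manifest CSV, invisibly.
#' @export
write_scene_set <- function(scenes, dir, meta) {
  if (nrow(meta) != length(scenes))
    stop_reefquad("`meta` must have one row per scene", "reefquad_invalid_spec")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(scenes))
  for (i in seq_along(scenes)) {
    stem <- sprintf("quadrat_%03d", i)
    paths[i] <- file.path(dir, paste0(stem, ".png"))
    write_image(scenes[[i]]$image, paths[i])
    tr <- scenes[[i]]$truth
    side <- list(frame_rotation_deg = tr$frame_rotation_deg,
                 inner_bbox = as.list(tr$inner_bbox),
                 class_fractions_interior = as.list(tr$class_fractions_interior),
                 label_levels = attr(tr$label_map, "labels"),
                 label_map_dim = dim(tr$label_map),
                 label_map_rle = rle_pack(tr$label_map))
    jsonlite::write_json(side, file.path(dir, paste0(stem, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- cbind(data.frame(image_path = paths, stringsAsFactors = FALSE), meta)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a ground-truth sidecar written by [write_scene_set()]
#'
#' @param path Path to the JSON sidecar.
#' @return A `quadrat_truth` list.
#' @export
read_truth_sidecar <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  lm <- matrix(rle_unpack(s$label_map_rle), s$label_map_dim[1], s$label_map_dim[2])
  attr(lm, "labels") <- s$label_levels
  structure(list(label_map = lm,
                 frame_rotation_deg = s$frame_rotation_deg %||% NA_real_,
                 inner_bbox = unlist(s$inner_bbox),
                 class_fractions_interior = unlist(s$class_fractions_interior)),
            class = "quadrat_truth")
}
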