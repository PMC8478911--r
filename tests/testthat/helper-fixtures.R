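# shared fixtures: all synthetic, generated in code at test time

# a small frameless two-class scene with exact known fractions
two_class_scene <- function(frac_sc = 0.5, side = 200L, seed = 1L) {
  render_quadrat(scene_spec(width_px = side, height_px = side,
                            class_fractions = c(SC = frac_sc, SA = 1 - frac_sc),
                            frame_present = FALSE, seed = seed))
}

# fraction of pixels in the detected interior that belong to the frame band,
# judged against the ground-truth label map derotated by the detected angle
frame_contamination <- function(truth, det) {
  lm_r <- rotate_label_map(truth$label_map, det$rotation_deg)
  b <- det$inner_bbox
  sub <- lm_r[(b["top"] + 1):b["bottom"], (b["left"] + 1):b["right"]]
  frame_id <- match("FRAME", attr(truth$label_map, "labels"))
  mean(sub == frame_id)
}

# independent angle oracle: least-squares line fit to the top outer edge of
# the rendered frame-band mask (central columns only, away from corners)
frame_angle_by_line_fit <- function(truth) {
  frame_id <- match("FRAME", attr(truth$label_map, "labels"))
  mask <- truth$label_map == frame_id
  top_y <- apply(mask, 2, function(col) if (any(col)) which(col)[1] else NA_real_)
  xs <- which(!is.na(top_y))
  mid <- xs[xs > stats::quantile(xs, 0.3) & xs < stats::quantile(xs, 0.7)]
  fit <- stats::lm(y ~ x, data = data.frame(x = mid, y = top_y[mid]))
  atan(unname(stats::coef(fit)[2])) * 180 / pi
}

# manifest for the default six-site design, with explicit reef-type map
default_reef_types <- function() {
  man <- default_site_manifest()
  stats::setNames(man$reef_type, man$site)
}

# image-level cover table + manifest from a simulate_cover_series() result
series_to_cover <- function(d) {
  list(cover = data.frame(image_id = d$image, label = d$label, cover = d$cover,
                          n_points_included = NA_integer_, stringsAsFactors = FALSE),
       manifest = unique(data.frame(image_id = d$image, site = d$site, year = d$year,
                                    reef_type = d$reef_type,
                                    transect_type = d$transect_type,
                                    stringsAsFactors = FALSE)))
}
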