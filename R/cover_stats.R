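#' Default site manifest for the six-locality survey design
#'
#' Two patch reefs, one fringing reef treated as patch-like, and three
#' forereefs; two of the forereefs are surveyed with fixed transects, the
#' rest with random transects.
#'
#' @return Data.frame with columns `site`, `reef_type`, `transect_type`.
#' @export
default_site_manifest <- function() {
  data.frame(
    site = c("CBC Lagoon Reef", "Curlew Patch Reef", "CBC House Reef",
             "CBC Reef Central", "South Reef Central", "Tobacco Reef"),
    reef_type = c("patch", "patch", "patch", "forereef", "forereef", "forereef"),
    transect_type = c("random", "random", "random", "fixed", "fixed", "random"),
    stringsAsFactors = FALSE)
}

#' Per-image percent cover from finalized point annotations
#'
#' Quality-category points (shadow, transect tape, unidentifiable) are
#' removed and the denominator renormalized over the remaining points, so
#' benthic covers sum to 1 per image. Images left with zero benthic points
#' are flagged (cover `NA`, `n_points_included = 0`) with a warning, never
#' silently dropped.
#'
#' @param points Finalized annotation data.frame (needs `image_id`,
#'   `final_label`).
#' @param schema A [label_schema()].
#' @return Data.frame with one row per image x benthic label: `image_id`,
#'   `label`, `cover`, `n_points_included`.
#' @export
image_cover <- function(points, schema = label_schema()) {
  if (is.null(points$final_label) || anyNA(points$final_label))
    stop_reefquad("all points must be finalized before computing cover",
                  "reefquad_invalid_params")
  benthic <- benthic_codes(schema)
  rows <- lapply(split(points, points$image_id), function(pp) {
    keep <- pp$final_label %in% benthic
    n <- sum(keep)
    if (n == 0) {
      warning(sprintf("image '%s' has no benthic points after quality-label exclusion; cover undefined",
                      pp$image_id[1]), call. = FALSE)
      return(data.frame(image_id = pp$image_id[1], label = benthic,
                        cover = NA_real_, n_points_included = 0L,
                        stringsAsFactors = FALSE))
    }
    cnt <- table(factor(pp$final_label[keep], levels = benthic))
    data.frame(image_id = pp$image_id[1], label = benthic,
               cover = as.numeric(cnt) / n, n_points_included = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Resampling-median percent cover for one site-year
#'
#' For surveys with many more images than the standard replication (e.g. a
#' year with 80+ images per site), draws `n_sub` images without replacement
#' per iteration, computes per-label mean cover, and returns the per-label
#' median across `n_iter` iterations. Medians taken label-wise need not sum
#' to 1; the result carries a `sums_to_one` attribute and a warning when they
#' do not (tolerance 1e-6).
#'
#' @param cover Image-level cover rows for a single site-year (from
#'   [image_cover()]).
#' @param n_sub Images per subsample (default 20).
#' @param n_iter Iterations (default 1000).
#' @param seed Integer seed.
#' @return Named numeric vector of per-label median cover.
#' @export
resample_median_cover <- function(cover, n_sub = 20L, n_iter = 1000L, seed = NULL) {
  imgs <- sort(unique(cover$image_id))   # canonical order: result does not
  if (length(imgs) < n_sub)              # depend on input row order
    stop_reefquad(sprintf(
      "only %d images but n_sub = %d: too few images to subsample, use the plain mean (site_year_cover)",
      length(imgs), n_sub), "reefquad_too_few_images")
  labels <- sort(unique(cover$label))
  # wide image x label matrix for fast subsample means
  m <- matrix(NA_real_, length(imgs), length(labels),
              dimnames = list(imgs, labels))
  m[cbind(match(cover$image_id, imgs), match(cover$label, labels))] <- cover$cover
  meds <- with_seed(seed, {
    acc <- matrix(NA_real_, n_iter, length(labels))
    for (i in seq_len(n_iter)) {
      pick <- sample.int(length(imgs), n_sub)
      acc[i, ] <- colMeans(m[pick, , drop = FALSE])
    }
    apply(acc, 2, stats::median)
  })
  names(meds) <- labels
  s1 <- abs(sum(meds) - 1) <= 1e-6
  if (!s1)
    warning("per-label resampling medians do not sum to 1; reported as-is", call. = FALSE)
  attr(meds, "sums_to_one") <- s1
  meds
}

#' Aggregate image-level cover to site-year means with standard errors
#'
#' @param cover Image-level cover rows (from [image_cover()]).
#' @param manifest Data.frame mapping `image_id` to `site`, `year`, and
#'   optionally `reef_type`, `transect_type`.
#' @return Data.frame: `site`, `year`, (`reef_type`,) `label`, `cover`
#'   (mean over images), `se` (sd over images / sqrt(n_images); `NA` for a
#'   single image), `n_images`.
#' @export
site_year_cover <- function(cover, manifest) {
  need <- c("image_id", "site", "year")
  if (!all(need %in% names(manifest)))
    stop_reefquad("manifest must contain image_id, site, year", "reefquad_invalid_params")
  df <- merge(cover, manifest, by = "image_id")
  df <- df[!is.na(df$cover), , drop = FALSE]
  key <- interaction(df$site, df$year, df$label, drop = TRUE)
  rows <- lapply(split(df, key), function(g) {
    n <- nrow(g)
    out <- data.frame(site = g$site[1], year = g$year[1], label = g$label[1],
                      cover = mean(g$cover),
                      se = if (n > 1) stats::sd(g$cover) / sqrt(n) else NA_real_,
                      n_images = n, stringsAsFactors = FALSE)
    if (!is.null(g$reef_type)) out$reef_type <- g$reef_type[1]
    if (!is.null(g$transect_type)) out$transect_type <- g$transect_type[1]
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$site, out$year, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Image-area bias regression
#'
#' Before quadrat areas were standardized, images captured varying seafloor
#' areas. This check regresses per-image cover of each major benthic group
#' (mean cover above `min_mean_cover`, default 1%) on the log10-transformed
#' image area, by ordinary least squares, reporting the slope and two-sided
#' p-value per label. A null outcome across labels justifies using raw cover
#' values without area scaling.
#'
#' @param cover Image-level cover rows (from [image_cover()]).
#' @param areas Named numeric vector: `image_id` -> area in square meters.
#' @param min_mean_cover Minimum mean cover for a label to be tested
#'   (default 0.01).
#' @return Data.frame: `label`, `slope`, `p_value`, `n`.
#' @export
area_bias_check <- function(cover, areas, min_mean_cover = 0.01) {
  df <- cover[!is.na(cover$cover) & cover$image_id %in% names(areas), , drop = FALSE]
  df$area <- areas[df$image_id]
  if (length(unique(df$image_id)) < 3)
    stop_reefquad("need at least 3 images with areas", "reefquad_invalid_params")
  if (length(unique(df$area)) < 2)
    stop_reefquad("all image areas are identical: regression slope undefined",
                  "reefquad_degenerate_design")
  mean_cov <- tapply(df$cover, df$label, mean)
  keep <- names(mean_cov)[mean_cov > min_mean_cover]
  rows <- lapply(keep, function(l) {
    g <- df[df$label == l, ]
    fit <- stats::lm(cover ~ log10(area), data = g)
    sm <- summary(fit)$coefficients
    data.frame(label = l, slope = sm[2, 1], p_value = sm[2, 4], n = nrow(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
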