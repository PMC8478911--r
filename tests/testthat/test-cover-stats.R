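finalized <- function(labels, image_id = "q") {
  data.frame(image_id = image_id, row = seq_along(labels) - 1, col = 0,
             machine_label = labels, machine_confidence = 1,
             manual_label = NA_character_, final_label = labels, status = "auto",
             stringsAsFactors = FALSE)
}

test_that("homogeneous points give full cover for one label", {
  cov <- image_cover(finalized(rep("SC", 25)))
  expect_equal(cov$cover[cov$label == "SC"], 1)
  expect_true(all(cov$cover[cov$label != "SC"] == 0))
  expect_true(all(cov$n_points_included == 25))
})

test_that("quality labels are excluded and the denominator renormalized", {
  cov <- image_cover(finalized(c(rep("TAPE", 2), rep("SC", 4), rep("SA", 4))))
  expect_equal(cov$cover[cov$label == "SC"], 0.5)
  expect_equal(cov$cover[cov$label == "SA"], 0.5)
  expect_true(all(cov$n_points_included == 8))
  expect_equal(sum(cov$cover), 1)
})

test_that("an image with only quality points is flagged, not dropped", {
  expect_warning(cov <- image_cover(finalized(rep("SHAD", 5))), "cover undefined")
  expect_true(all(is.na(cov$cover)))
  expect_true(all(cov$n_points_included == 0))
})

test_that("point-count cover is unbiased against ground truth (binomial oracle)", {
  sc <- two_class_scene(frac_sc = 0.3, side = 400, seed = 21)
  pts <- generate_points(sc$image, 1e4, seed = 22, image_id = "q")
  labs <- attr(sc$truth$label_map, "labels")
  truth_lab <- labs[sc$truth$label_map[cbind(pts$row + 1, pts$col + 1)]]
  fin <- finalized(truth_lab)      # perfect scoring
  cov <- image_cover(fin)
  expect_lt(abs(cov$cover[cov$label == "SC"] - 0.3), 3 * sqrt(0.3 * 0.7 / 1e4))
  expect_equal(sum(cov$cover), 1)
})

test_that("resampling median of constant data is the constant", {
  cov <- data.frame(image_id = rep(sprintf("i%02d", 1:80), each = 2),
                    label = rep(c("SC", "SA"), 80),
                    cover = rep(c(0.2, 0.8), 80))
  med <- resample_median_cover(cov, n_sub = 20, n_iter = 50, seed = 1)
  expect_equal(unname(med["SC"]), 0.2)
  expect_equal(unname(med["SA"]), 0.8)
  expect_true(attr(med, "sums_to_one"))
})

test_that("subsampling all images reduces to the plain mean", {
  set.seed(5)
  x <- runif(30, 0, 0.4)
  cov <- data.frame(image_id = sprintf("i%02d", 1:30), label = "SC", cover = x)
  med <- suppressWarnings(resample_median_cover(cov, n_sub = 30, n_iter = 10, seed = 2))
  expect_equal(unname(med["SC"]), mean(x))
})

test_that("resampling medians concentrate near the grand mean", {
  set.seed(7)
  x <- runif(80, 0, 0.4)
  cov <- data.frame(image_id = sprintf("i%02d", 1:80), label = "SC", cover = x)
  med <- suppressWarnings(resample_median_cover(cov, n_sub = 20, n_iter = 1000, seed = 3))
  expect_lt(abs(med["SC"] - mean(x)), 0.01)
})

test_that("resampling is invariant to image ordering and errors when too few images", {
  set.seed(9)
  cov <- data.frame(image_id = sprintf("i%02d", 1:40), label = "SC",
                    cover = runif(40, 0, 0.4))
  a <- suppressWarnings(resample_median_cover(cov, n_sub = 20, n_iter = 100, seed = 4))
  b <- suppressWarnings(resample_median_cover(cov[sample(40), ], n_sub = 20,
                                              n_iter = 100, seed = 4))
  expect_equal(a, b)
  expect_error(resample_median_cover(cov[1:10, ], n_sub = 20),
               class = "reefquad_too_few_images")
})

test_that("site-year aggregation matches hand arithmetic", {
  cov <- data.frame(image_id = c("a", "b"), label = "SC", cover = c(0.1, 0.3),
                    n_points_included = 25L)
  man <- data.frame(image_id = c("a", "b"), site = "S1", year = 2014)
  agg <- site_year_cover(cov, man)
  expect_equal(agg$cover, 0.2)
  expect_equal(agg$se, 0.1)
  single <- site_year_cover(cov[1, ], man[1, ])
  expect_true(is.na(single$se))
})

test_that("aggregation recovers generator site-year means within 3 SE", {
  hits <- 0L; total <- 0L
  for (s in 1:500) {
    d <- simulate_cover_series(2, c(2014, 2016), trend = c(SC = 0), seed = s,
                               n_images = 15)
    sc <- series_to_cover(d)
    agg <- site_year_cover(sc$cover, sc$manifest)
    truth <- unique(d[, c("site", "year", "true_mean")])
    j <- match(paste(agg$site, agg$year), paste(truth$site, truth$year))
    ok <- abs(agg$cover - truth$true_mean[j]) <= 3 * agg$se
    hits <- hits + sum(ok); total <- total + length(ok)
  }
  expect_gte(hits / total, 0.95)
})

test_that("area-bias regression has calibrated type-I error on null data", {
  p <- vapply(1:500, function(s) {
    set.seed(s)
    areas <- setNames(10^runif(42, -0.5, 0.3), sprintf("i%02d", 1:42))
    cov <- data.frame(image_id = names(areas), label = "SC",
                      cover = rbeta(42, 0.2 * 30, 0.8 * 30))
    area_bias_check(cov, areas)$p_value
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.025)
})

test_that("a real cover-area dependence is detected at n = 42", {
  det <- vapply(1:20, function(s) {
    set.seed(100 + s)
    areas <- setNames(10^runif(42, -0.5, 0.3), sprintf("i%02d", 1:42))
    cov <- data.frame(image_id = names(areas), label = "SC",
                      cover = 0.2 + 0.1 * log10(areas) + rnorm(42, 0, 0.04))
    res <- area_bias_check(cov, areas)
    res$slope > 0 & res$p_value < 0.05
  }, logical(1))
  expect_gte(mean(det), 0.8)
})

test_that("labels below the mean-cover floor are excluded; degenerate areas error", {
  areas <- setNames(10^seq(-0.3, 0.3, length.out = 10), sprintf("i%02d", 1:10))
  cov <- rbind(data.frame(image_id = names(areas), label = "SC",
                          cover = runif(10, 0.2, 0.4)),
               data.frame(image_id = names(areas), label = "SP",
                          cover = rep(0.005, 10)))
  res <- area_bias_check(cov, areas)
  expect_false("SP" %in% res$label)
  expect_true("SC" %in% res$label)
  same <- setNames(rep(1, 10), names(areas))
  expect_error(area_bias_check(cov, same), class = "reefquad_degenerate_design")
})
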