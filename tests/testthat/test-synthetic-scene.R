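test_that("degenerate single-class scene is all that class", {
  sc <- render_quadrat(scene_spec(width_px = 100, height_px = 100,
                                  class_fractions = c(SC = 1),
                                  frame_present = FALSE, seed = 2))
  expect_equal(unname(sc$truth$class_fractions_interior), 1)
  expect_equal(names(sc$truth$class_fractions_interior), "SC")
  expect_true(all(sc$truth$label_map == 1L))
})

test_that("interior class fractions match the request within quantization", {
  for (s in 1:4) {
    fr <- c(SC = 0.2, MA = 0.15, SA = 0.4, CS = 0.25)
    sc <- render_quadrat(scene_spec(width_px = 160, height_px = 120,
                                    class_fractions = fr,
                                    frame_present = FALSE, seed = s))
    expect_lt(max(abs(sc$truth$class_fractions_interior[names(fr)] - fr)),
              1 / min(120, 160))
  }
  # with a frame, interior fractions are exact over the inner opening
  fr <- c(SC = 0.5, SA = 0.5)
  sc <- render_quadrat(scene_spec(width_px = 150, height_px = 150,
                                  class_fractions = fr, frame_rotation_deg = 0,
                                  seed = 7))
  expect_lt(max(abs(sc$truth$class_fractions_interior[names(fr)] - fr)), 1 / 150)
})

test_that("rendered frame band angle matches the spec by independent line fit", {
  for (a in c(-12, 0, 7)) {
    sc <- render_quadrat(scene_spec(width_px = 300, height_px = 300,
                                    frame_rotation_deg = a, seed = 5))
    expect_equal(sc$truth$frame_rotation_deg, a)
    expect_lt(abs(frame_angle_by_line_fit(sc$truth) - a), 0.1)
  }
})

test_that("rendering is deterministic under a fixed seed", {
  a <- render_quadrat(scene_spec(width_px = 120, height_px = 96, seed = 9))
  b <- render_quadrat(scene_spec(width_px = 120, height_px = 96, seed = 9))
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$truth$label_map, b$truth$label_map)
})

test_that("color cast changes channels but never the label map", {
  base <- scene_spec(width_px = 100, height_px = 100, frame_present = FALSE,
                     cast_green = 0, cast_blue = 0, seed = 4)
  cast <- scene_spec(width_px = 100, height_px = 100, frame_present = FALSE,
                     cast_green = 60, cast_blue = 40, seed = 4)
  a <- render_quadrat(base); b <- render_quadrat(cast)
  expect_identical(a$truth$label_map, b$truth$label_map)
  expect_gt(mean(b$image[, , 2]), mean(a$image[, , 2]))
  expect_false(identical(unclass(a$image), unclass(b$image)))
})

test_that("invalid scene specs are rejected", {
  expect_error(scene_spec(class_fractions = c(SC = 0.5, SA = 0.4)),
               class = "reefquad_invalid_spec")
  expect_error(scene_spec(frame_rotation_deg = 25), class = "reefquad_invalid_spec")
  expect_error(scene_spec(overexposure_gain = 0.5), class = "reefquad_invalid_spec")
  expect_error(scene_spec(width_px = 32), class = "reefquad_invalid_spec")
})

test_that("scene sets round-trip through PNG + sidecar + manifest", {
  dir <- withr::local_tempdir()
  scs <- lapply(1:2, function(s)
    render_quadrat(scene_spec(width_px = 80, height_px = 80,
                              frame_present = FALSE, seed = s)))
  meta <- data.frame(site = c("A", "B"), year = c(2014, 2016),
                     reef_type = "patch", transect_type = "random", area_m2 = 0.74)
  mp <- write_scene_set(scs, dir, meta)
  man <- read.csv(mp)
  expect_equal(nrow(man), 2)
  img <- read_image(man$image_path[1])
  expect_identical(unclass(img), unclass(scs[[1]]$image))
  tr <- read_truth_sidecar(sub("\\.png$", ".json", man$image_path[1]))
  expect_identical(dim(tr$label_map), dim(scs[[1]]$truth$label_map))
  expect_equal(tr$class_fractions_interior, scs[[1]]$truth$class_fractions_interior)
  expect_identical(as.integer(tr$label_map), as.integer(scs[[1]]$truth$label_map))
})

test_that("cover series generator has no trend when slopes are zero", {
  # oracle: ordinary regression of simulated logits on year, per replicate
  slopes <- vapply(1:200, function(s) {
    d <- simulate_cover_series(4, 2014:2018, trend = c(SC = 0), seed = s)
    unname(coef(lm(qlogis(cover) ~ year, data = d))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 1.96 * sd(slopes) / sqrt(length(slopes)))
})

test_that("positive logit trend yields increasing mean cover", {
  yrs <- 2014:2018
  acc <- matrix(0, 1000, length(yrs))
  for (s in 1:1000) {
    d <- simulate_cover_series(6, yrs, trend = c(SC = 0.25), seed = s)
    acc[s, ] <- tapply(d$cover, d$year, mean)
  }
  expect_true(all(diff(colMeans(acc)) > 0))
})

test_that("cover series is deterministic and validates inputs", {
  a <- simulate_cover_series(3, 2014:2016, trend = c(SC = 0.1), seed = 11)
  b <- simulate_cover_series(3, 2014:2016, trend = c(SC = 0.1), seed = 11)
  expect_identical(a, b)
  expect_true(all(a$cover > 0 & a$cover < 1))
  expect_error(simulate_cover_series(3, 2014, trend = c(SC = 0)),
               class = "reefquad_invalid_spec")
  expect_error(simulate_cover_series(3, 2014:2016, trend = c(SC = 0), precision = -1),
               class = "reefquad_invalid_spec")
})

test_that("generator means follow the stated inverse-logit mean function", {
  d <- simulate_cover_series(2, 2014:2018, trend = c(SC = 0.3), seed = 3,
                             n_images = 400, site_sd = 0)
  by_year <- tapply(d$cover, d$year, mean)
  truth <- tapply(d$true_mean, d$year, mean)
  expect_equal(as.numeric(truth), plogis(qlogis(0.1) + 0.3 * (2014:2018 - 2014)),
               tolerance = 1e-12)
  # beta sd <= 0.5/sqrt(phi+1) ~ 0.09; 3 x Monte-Carlo SE at 800 draws/year
  expect_lt(max(abs(by_year - truth)), 3 * 0.09 / sqrt(800))
})
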