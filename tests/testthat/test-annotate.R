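test_that("a 1x1 image forces the single point", {
  expect_equal(generate_points(c(1L, 1L), 1, seed = 1)[, c("row", "col")],
               data.frame(row = 0L, col = 0L))
})

test_that("25 points are distinct and in bounds", {
  sc <- two_class_scene(seed = 1, side = 64)
  pts <- generate_points(sc$image, 25, seed = 2)
  expect_equal(nrow(pts), 25)
  expect_equal(nrow(unique(pts[, c("row", "col")])), 25)
  expect_true(all(pts$row >= 0 & pts$row < 64 & pts$col >= 0 & pts$col < 64))
  expect_error(generate_points(c(4L, 4L), 17), class = "reefquad_invalid_params")
})

test_that("point sampling hits classes in proportion to their area", {
  sc <- two_class_scene(frac_sc = 0.5, side = 400, seed = 9)
  pts <- generate_points(sc$image, 1e5, seed = 3)
  labs <- attr(sc$truth$label_map, "labels")
  frac <- mean(labs[sc$truth$label_map[cbind(pts$row + 1, pts$col + 1)]] == "SC")
  sigma <- sqrt(0.5 * 0.5 / 1e5)
  expect_lt(abs(frac - 0.5), 3 * sigma)
})

test_that("point sampling is uniform over a 4x4 grid (chi-square, seed aggregate)", {
  counts <- matrix(0, 4, 4)
  for (s in 1:10) {
    pts <- generate_points(c(200L, 200L), 1e4, seed = s)
    counts <- counts + table(factor(pts$row %/% 50, levels = 0:3),
                             factor(pts$col %/% 50, levels = 0:3))
  }
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.01)
})

test_that("the confidence gate partitions exhaustively with ties to the machine", {
  pts <- data.frame(image_id = "q", row = 0:2, col = 0:2,
                    machine_label = c("SC", "SA", "MA"),
                    machine_confidence = c(0.6, 0.4, 0.5))
  g <- gate_annotations(pts, threshold = 0.5)
  expect_equal(g$auto$machine_label, c("SC", "MA"))    # >= gate: 0.5 goes auto
  expect_equal(g$manual_queue$machine_label, "SA")
  expect_equal(nrow(g$auto) + nrow(g$manual_queue), nrow(pts))
  expect_equal(g$auto$final_label, g$auto$machine_label)
})

test_that("gate edge cases: certain classifier and manual-only mode", {
  pts <- data.frame(image_id = "q", row = 0:1, col = 0:1,
                    machine_label = c("SC", "SA"), machine_confidence = c(1, 1))
  expect_equal(nrow(gate_annotations(pts, 0.5)$manual_queue), 0)
  pts$machine_confidence <- c(0.9, 0.99)
  expect_equal(nrow(gate_annotations(pts, 1)$auto), 0)
  pts$machine_confidence[1] <- NA
  expect_error(gate_annotations(pts), class = "reefquad_invalid_params")
})

test_that("gate partition is always exhaustive and exclusive", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    pts <- data.frame(image_id = "q", row = seq_len(n) - 1, col = 0,
                      machine_label = "SC", machine_confidence = runif(n))
    thr <- runif(1, 0.05, 1)
    g <- gate_annotations(pts, thr)
    expect_equal(nrow(g$auto) + nrow(g$manual_queue), n)
    expect_true(all(g$auto$machine_confidence >= thr))
    expect_true(all(g$manual_queue$machine_confidence < thr))
  }
})

test_that("a perfect classifier reproduces ground-truth point cover exactly", {
  sc <- two_class_scene(frac_sc = 0.3, side = 150, seed = 4)
  pts <- generate_points(sc$image, 200, seed = 5, image_id = "q")
  ann <- simulated_classifier(pts, sc$truth, accuracy = 1, seed = 6)
  ann$machine_confidence <- 1    # certain classifier
  fin <- gate_annotations(ann, 0.5)$auto
  labs <- attr(sc$truth$label_map, "labels")
  truth_lab <- labs[sc$truth$label_map[cbind(pts$row + 1, pts$col + 1)]]
  expect_equal(mean(fin$final_label == "SC"), mean(truth_lab == "SC"))
})

test_that("simulated classifier accuracy matches the binomial oracle", {
  sc <- two_class_scene(frac_sc = 0.5, side = 300, seed = 7)
  pts <- generate_points(sc$image, 1e4, seed = 8)
  ann <- simulated_classifier(pts, sc$truth, accuracy = 0.8, seed = 9)
  labs <- attr(sc$truth$label_map, "labels")
  truth_lab <- labs[sc$truth$label_map[cbind(pts$row + 1, pts$col + 1)]]
  agree <- mean(ann$machine_label == truth_lab)
  expect_lt(abs(agree - 0.8), 3 * sqrt(0.8 * 0.2 / 1e4))
  again <- simulated_classifier(pts, sc$truth, accuracy = 0.8, seed = 9)
  expect_identical(ann, again)
})

test_that("overall confidence counts manual points as certain", {
  pts <- data.frame(image_id = "q", row = 0:1, col = 0:1,
                    machine_label = c("SC", "SA"),
                    machine_confidence = c(0.8, 0.2),
                    manual_label = c(NA, "SA"),
                    final_label = c("SC", "SA"), status = c("auto", "manual"))
  expect_equal(overall_confidence(pts), 0.9)
  expect_equal(overall_confidence(pts[pts$status == "manual", , drop = FALSE]), 1)
  expect_error(overall_confidence(pts[0, ]), class = "reefquad_invalid_params")
  pts$final_label[1] <- NA
  expect_error(overall_confidence(pts), class = "reefquad_invalid_params")
})

test_that("annotation CSV export/import round-trips field-for-field", {
  sc <- two_class_scene(seed = 11, side = 80)
  pts <- generate_points(sc$image, 25, seed = 12, image_id = "quad_001")
  ann <- simulated_classifier(pts, sc$truth, accuracy = 0.9, seed = 13)
  fin <- score_points(ann, sc$truth, 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(fin, path)
  back <- read_annotations(path)
  expect_equal(back$image_id, fin$image_id)
  expect_equal(back$row, fin$row)
  expect_equal(back$col, fin$col)
  expect_equal(back$final_label, fin$final_label)
  expect_equal(back$machine_confidence, fin$machine_confidence, tolerance = 1e-12)
})

test_that("label schema validates and round-trips through YAML", {
  sch <- label_schema()
  expect_equal(sum(sch$category == "benthic"), 8)
  expect_equal(sum(sch$category == "quality"), 3)
  path <- withr::local_tempfile(fileext = ".yml")
  write_label_schema(sch, path)
  expect_equal(as.data.frame(read_label_schema(path)), as.data.frame(sch))
  expect_error(label_schema(benthic = data.frame(code = c("A", "A"), name = c("a", "b"))),
               class = "reefquad_invalid_schema")
})
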