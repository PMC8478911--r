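#' Benthic label schema
#'
#' The default schema follows broad functional-group labels in the CATAMI
#' tradition: eight benthic classes (macroalgae, long turfing algae,
#' scleractinian corals, octocorals, sponges, sand, rubble, and consolidated
#' substrate — the epilithic algal matrix available for settlement) plus
#' three quality classes used to flag points that cannot be scored (shadow,
#' transect tape, unidentifiable). Quality points are excluded from cover
#' denominators by [image_cover()].
#'
#' @param benthic Data.frame with columns `code`, `name` for benthic labels.
#' @param quality Data.frame with columns `code`, `name` for quality labels.
#' @return Data.frame of class `label_schema` with columns `code`, `name`,
#'   `category`.
#' @export
label_schema <- function(benthic = NULL, quality = NULL) {
  if (is.null(benthic))
    benthic <- data.frame(
      code = c("MA", "LTA", "SC", "OCT", "SP", "SA", "RU", "CS"),
      name = c("macroalgae", "long turfing algae", "scleractinian corals",
               "octocorals", "sponges", "sand", "rubble", "consolidated substrate"),
      stringsAsFactors = FALSE)
  if (is.null(quality))
    quality <- data.frame(code = c("SHAD", "TAPE", "UNID"),
                          name = c("shadow", "transect tape", "unidentifiable"),
                          stringsAsFactors = FALSE)
  out <- rbind(cbind(benthic, category = "benthic"),
               if (nrow(quality)) cbind(quality, category = "quality"))
  if (anyDuplicated(out$code))
    stop_reefquad("label codes must be unique", "reefquad_invalid_schema")
  if (!any(out$category == "benthic"))
    stop_reefquad("schema needs at least one benthic label", "reefquad_invalid_schema")
  structure(out, class = c("label_schema", "data.frame"))
}

benthic_codes <- function(schema) schema$code[schema$category == "benthic"]
quality_codes <- function(schema) schema$code[schema$category == "quality"]

#' Write / read a label schema as YAML
#'
#' @param schema A [label_schema()].
#' @param path File path.
#' @return `read_label_schema()` returns a [label_schema()];
#'   `write_label_schema()` returns `path` invisibly.
#' @export
write_label_schema <- function(schema, path) {
  yaml::write_yaml(lapply(seq_len(nrow(schema)), function(i) as.list(schema[i, ])), path)
  invisible(path)
}

#' @rdname write_label_schema
#' @export
read_label_schema <- function(path) {
  rows <- yaml::read_yaml(path)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  label_schema(benthic = df[df$category == "benthic", c("code", "name")],
               quality = df[df$category == "quality", c("code", "name")])
}

#' Generate random annotation points over an image
#'
#' Points are drawn uniformly without replacement over the pixel grid
#' (duplicate points add no information). 25 points per image is the
#' conventional effort for functional-group cover estimates.
#'
#' @param img A [raster_image()], or an integer vector `c(height, width)`.
#' @param n_points Number of points (default 25); must not exceed the pixel
#'   count.
#' @param seed Integer seed.
#' @param image_id Identifier recorded with each point.
#' @return Data.frame with columns `image_id`, `row`, `col` (0-based pixel
#'   indices).
#' @export
generate_points <- function(img, n_points = 25L, seed = NULL, image_id = "image") {
  d <- if (is.numeric(img) && length(img) == 2) as.integer(img) else dim(assert_raster(img))[1:2]
  h <- d[1]; w <- d[2]
  if (n_points < 1) stop_reefquad("n_points must be >= 1", "reefquad_invalid_params")
  if (n_points > h * w)
    stop_reefquad("n_points exceeds the number of pixels", "reefquad_invalid_params")
  idx <- with_seed(seed, sample.int(h * w, n_points)) - 1L
  data.frame(image_id = image_id, row = idx %% h, col = idx %/% h,
             stringsAsFactors = FALSE)
}

truth_label_at <- function(truth, row, col) {
  labels <- attr(truth$label_map, "labels")
  labels[truth$label_map[cbind(row + 1L, col + 1L)]]
}

#' Simulated machine annotator
#'
#' Test stand-in for a trained image classifier: each point receives the
#' ground-truth label with probability `accuracy`, otherwise a uniformly
#' chosen wrong benthic label. Confidence is drawn from beta distributions
#' whose parameters differ for correct and incorrect calls, mimicking a
#' classifier that is better calibrated when it is right.
#'
#' @param points Data.frame from [generate_points()].
#' @param truth A `quadrat_truth` (see [render_quadrat()]).
#' @param accuracy Probability in (0, 1] of returning the true label.
#' @param confidence_model List with beta shape pairs `correct` and
#'   `incorrect` (defaults `c(8, 2)` and `c(2, 3)`: mean confidence 0.8 when
#'   right, 0.4 when wrong).
#' @param seed Integer seed.
#' @param schema A [label_schema()]; wrong labels are drawn from its benthic
#'   codes.
#' @return `points` with added `machine_label` and `machine_confidence`.
#' @export
simulated_classifier <- function(points, truth, accuracy = 0.9,
                                 confidence_model = list(correct = c(8, 2),
                                                         incorrect = c(2, 3)),
                                 seed = NULL, schema = label_schema()) {
  if (accuracy <= 0 || accuracy > 1)
    stop_reefquad("accuracy must lie in (0, 1]", "reefquad_invalid_params")
  true_lab <- truth_label_at(truth, points$row, points$col)
  pool <- benthic_codes(schema)
  with_seed(seed, {
    correct <- stats::runif(nrow(points)) <= accuracy
    wrong <- vapply(true_lab, function(l) {
      alt <- setdiff(pool, l)
      alt[sample.int(length(alt), 1)]
    }, character(1))
    points$machine_label <- ifelse(correct, true_lab, wrong)
    pc <- confidence_model$correct; pw <- confidence_model$incorrect
    conf <- numeric(nrow(points))
    conf[correct] <- stats::rbeta(sum(correct), pc[1], pc[2])
    conf[!correct] <- stats::rbeta(sum(!correct), pw[1], pw[2])
    points$machine_confidence <- conf
    points
  })
}

#' Partition machine annotations by confidence
#'
#' Points at or above the confidence threshold are auto-scored with the
#' machine label; the rest are queued for manual annotation. The partition is
#' exhaustive and exclusive. The gate comparator is `>=`: a point at exactly
#' the threshold goes to the machine (ties to the machine; the threshold is
#' configurable).
#'
#' @param points Data.frame with `machine_label` and `machine_confidence`.
#' @param threshold Confidence gate in (0, 1], default 0.5.
#' @return List with data.frames `auto` (finalized: `final_label`, `status`
#'   set) and `manual_queue`.
#' @export
gate_annotations <- function(points, threshold = 0.5) {
  if (is.null(points$machine_confidence) || anyNA(points$machine_confidence))
    stop_reefquad("all points need a machine_confidence", "reefquad_invalid_params")
  if (threshold <= 0 || threshold > 1)
    stop_reefquad("threshold must lie in (0, 1]", "reefquad_invalid_params")
  is_auto <- points$machine_confidence >= threshold
  auto <- points[is_auto, , drop = FALSE]
  if (nrow(auto)) {
    auto$final_label <- auto$machine_label
    auto$status <- "auto"
  } else {
    auto$final_label <- character(0); auto$status <- character(0)
  }
  queue <- points[!is_auto, , drop = FALSE]
  list(auto = auto, manual_queue = queue)
}

#' Manually score queued points
#'
#' @param queue Data.frame from [gate_annotations()]`$manual_queue`.
#' @param labels Character vector of manual labels, one per queued point (in
#'   simulation, typically the ground-truth labels).
#' @return The queue with `manual_label`, `final_label`, `status = "manual"`.
#' @export
manual_score <- function(queue, labels) {
  if (length(labels) != nrow(queue))
    stop_reefquad("need one manual label per queued point", "reefquad_invalid_params")
  queue$manual_label <- labels
  queue$final_label <- labels
  queue$status <- if (nrow(queue)) "manual" else character(0)
  queue
}

#' Run the full confidence-gated scoring workflow against ground truth
#'
#' Convenience wrapper used throughout the synthetic pipeline: machine
#' annotations are gated at `threshold`, and queued points are manually
#' scored from the ground-truth label map (a simulated perfect human
#' annotator).
#'
#' @param points Data.frame with machine output (see
#'   [simulated_classifier()]).
#' @param truth A `quadrat_truth`.
#' @param threshold Confidence gate (default 0.5).
#' @return Finalized annotation data.frame (auto + manual rows).
#' @export
score_points <- function(points, truth, threshold = 0.5) {
  g <- gate_annotations(points, threshold)
  auto <- g$auto
  auto$manual_label <- rep(NA_character_, nrow(auto))
  manual <- manual_score(g$manual_queue,
                         truth_label_at(truth, g$manual_queue$row, g$manual_queue$col))
  cols <- c("image_id", "row", "col", "machine_label", "machine_confidence",
            "manual_label", "final_label", "status")
  out <- rbind(auto[, cols, drop = FALSE], manual[, cols, drop = FALSE])
  out[order(out$row, out$col), , drop = FALSE]
}

#' Overall annotation confidence
#'
#' The project-level confidence figure: the mean machine confidence with
#' manually scored points counted at confidence 1.0 (a human call is taken as
#' certain). Mixing manual scoring into a low-confidence project therefore
#' raises the figure.
#'
#' @param points Finalized annotation data.frame (every point has a
#'   `final_label` and `status`).
#' @return Fraction in `[0, 1]`.
#' @export
overall_confidence <- function(points) {
  if (!nrow(points))
    stop_reefquad("no points supplied", "reefquad_invalid_params")
  if (is.null(points$status) || is.null(points$final_label) ||
      anyNA(points$final_label) || anyNA(points$status))
    stop_reefquad("all points must be finalized", "reefquad_invalid_params")
  mean(ifelse(points$status == "manual", 1, points$machine_confidence))
}

#' Annotation CSV interchange
#'
#' Reads and writes point annotations in a CoralNet-export-style CSV dialect:
#' columns `Name` (image), `Row`, `Column`, `Label`, `Machine confidence`
#' (UTF-8, header required). Export followed by import reproduces the point
#' set field-for-field.
#'
#' @param points Finalized annotation data.frame.
#' @param path CSV file path.
#' @return `read_annotations()` returns a data.frame with columns `image_id`,
#'   `row`, `col`, `final_label`, `machine_confidence`.
#' @export
write_annotations <- function(points, path) {
  out <- data.frame(Name = points$image_id, Row = points$row, Column = points$col,
                    Label = points$final_label,
                    `Machine confidence` = points$machine_confidence %||% NA_real_,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        stringsAsFactors = FALSE)
  need <- c("Name", "Row", "Column", "Label")
  if (!all(need %in% names(df)))
    stop_reefquad(paste("annotation CSV must contain columns:",
                        paste(need, collapse = ", ")), "reefquad_invalid_csv")
  data.frame(image_id = df$Name, row = as.integer(df$Row), col = as.integer(df$Column),
             final_label = df$Label,
             machine_confidence = if ("Machine confidence" %in% names(df))
               as.numeric(df[["Machine confidence"]]) else NA_real_,
             stringsAsFactors = FALSE)
}
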