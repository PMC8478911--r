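#' Boundary squeeze transform for proportions
#'
#' The beta distribution cannot accommodate exact 0 or 1 observations, so
#' observed proportions are shifted off the boundary with
#' `p* = (p * (n - 1) + 0.5) / n`, where `n` is the total number of
#' observations entering the model. The transform is strictly inside (0, 1)
#' for any `p` in `[0, 1]` and `n >= 2`, monotone in `p`, and leaves
#' `p = 0.5` fixed.
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @param n Total number of observations (count, `>= 2`).
#' @return Transformed proportion(s) strictly in (0, 1).
#' @examples
#' squeeze_transform(0, 100)   # 0.005
#' squeeze_transform(1, 100)   # 0.995
#' squeeze_transform(0.5, 17)  # 0.5
#' @export
squeeze_transform <- function(p, n) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop_reefquad("p must lie in [0, 1]", "reefquad_invalid_params")
  if (anyNA(n) || any(n < 2))
    stop_reefquad("n must be >= 2", "reefquad_invalid_params")
  (p * (n - 1) + 0.5) / n
}

inverse_squeeze <- function(p_star, n) (p_star * n - 0.5) / (n - 1)

#' Fit a beta GAM for temporal trends in benthic cover
#'
#' Models image-level proportional cover with a beta response (logit link):
#' a separate penalized smooth of year per reef type, a parametric reef-type
#' contrast, and a random-intercept-style penalized term for locality
#' absorbing reef-to-reef differences:
#'
#' `cover* ~ reef_type + s(year, by = reef_type, k = k) + s(locality, bs = "re")`
#'
#' The response is squeezed off the boundary with [squeeze_transform()]
#' using `n = nrow(model data)`. With `global_smooth = TRUE` an additional
#' global `s(year)` is included; that structure is exactly concurve with the
#' per-type smooths (the global trend can be absorbed by either side), so its
#' term-wise tests are unreliable and the default omits it.
#'
#' The smooth basis dimension `k` defaults to 5 and must not exceed the
#' number of distinct years.
#'
#' @param data Data.frame with columns `cover` (proportion in `[0, 1]`),
#'   `year`, `reef_type`, and `locality` (or `site`); optionally `label`.
#' @param label If `data` holds several labels, the single response label to
#'   model.
#' @param k Basis dimension for the year smooths.
#' @param global_smooth Also include the redundant global `s(year)` term.
#' @param reef_terms Include reef-type terms (set `FALSE` for single-type
#'   data, e.g. the fixed-transect sensitivity refit).
#' @return Object of class `trend_gam`: the fitted mgcv model plus tidied
#'   term tests (z statistics for parametric terms, chi-square for smooths),
#'   deviance explained, and back-transformed fitted year curves with 95%
#'   intervals per reef type.
#' @seealso [fixed_transect_sensitivity()], [squeeze_transform()]
#' @export
fit_trend_gam <- function(data, label = NULL, k = 5, global_smooth = FALSE,
                          reef_terms = TRUE) {
  d <- as.data.frame(data)
  if (!is.null(d$label) && !is.null(label)) d <- d[d$label == label, , drop = FALSE]
  if (is.null(d$locality) && !is.null(d$site)) d$locality <- d$site
  need <- c("cover", "year", "reef_type", "locality")
  if (!all(need %in% names(d)))
    stop_reefquad(paste("data must contain columns:", paste(need, collapse = ", ")),
                  "reefquad_invalid_params")
  d <- d[!is.na(d$cover), , drop = FALSE]
  if (length(unique(d$year)) < 2)
    stop_reefquad("need at least 2 distinct years", "reefquad_invalid_params")
  d$reef_type <- factor(d$reef_type)
  d$locality <- factor(d$locality)
  if (reef_terms && nlevels(d$reef_type) < 2) reef_terms <- FALSE
  k <- min(k, length(unique(d$year)))

  use_re <- nlevels(d$locality) >= 2
  if (!use_re)
    warning("single locality: random effect dropped", call. = FALSE)

  n_obs <- nrow(d)
  d$cover_star <- squeeze_transform(d$cover, n_obs)

  terms <- c(if (reef_terms) "reef_type",
             if (global_smooth) sprintf("s(year, k = %d)", k),
             if (reef_terms) sprintf("s(year, by = reef_type, k = %d)", k)
             else sprintf("s(year, k = %d)", k),
             if (use_re) "s(locality, bs = \"re\")")
  form <- stats::as.formula(paste("cover_star ~", paste(terms, collapse = " + ")))

  fit <- tryCatch(
    mgcv::gam(form, family = mgcv::betar(link = "logit"), data = d, method = "REML"),
    error = function(e) stop_reefquad(
      paste("beta GAM failed to fit:", conditionMessage(e)), "reefquad_gam_failure"))
  if (!fit$converged)
    stop_reefquad(paste0("beta GAM did not converge (REML iterations exhausted); ",
                         "deviance = ", format(fit$deviance)), "reefquad_gam_failure")

  sm <- summary(fit)
  pt <- sm$p.table; st <- sm$s.table
  term_table <- rbind(
    data.frame(term = rownames(pt), type = "parametric",
               statistic = pt[, "z value"], p_value = pt[, 4],
               edf = NA_real_, stringsAsFactors = FALSE),
    data.frame(term = rownames(st), type = "smooth",
               statistic = st[, "Chi.sq"], p_value = st[, "p-value"],
               edf = st[, "edf"], stringsAsFactors = FALSE))
  rownames(term_table) <- NULL

  # fitted year curves by reef type, random effect excluded
  yrs <- sort(unique(d$year))
  lv <- levels(d$reef_type)
  nd <- expand.grid(year = yrs, reef_type = factor(lv, levels = lv),
                    KEEP.OUT.ATTRS = FALSE)
  nd$locality <- d$locality[1]
  pr <- mgcv::predict.gam(fit, newdata = nd, type = "link", se.fit = TRUE,
                          exclude = if (use_re) "s(locality)" else NULL,
                          newdata.guaranteed = TRUE)
  curves <- data.frame(year = nd$year, reef_type = as.character(nd$reef_type),
                       mean = stats::plogis(pr$fit),
                       lo95 = stats::plogis(pr$fit - 1.96 * pr$se.fit),
                       hi95 = stats::plogis(pr$fit + 1.96 * pr$se.fit),
                       stringsAsFactors = FALSE)

  structure(list(model = fit, terms = term_table, dev_expl = sm$dev.expl,
                 curves = curves, n_obs = n_obs, squeeze_n = n_obs,
                 label = label %||% NA_character_, formula = form,
                 random_effect = use_re, reef_terms = reef_terms),
            class = "trend_gam")
}

#' @export
print.trend_gam <- function(x, ...) {
  cat("Beta GAM for benthic cover trend\n")
  if (!is.na(x$label)) cat("  response label:", x$label, "\n")
  cat("  formula:", deparse(x$formula), "\n")
  cat(sprintf("  n = %d image-level observations; deviance explained = %.1f%%\n",
              x$n_obs, 100 * x$dev_expl))
  invisible(x)
}

#' @export
summary.trend_gam <- function(object, ...) {
  structure(list(terms = object$terms, dev_expl = object$dev_expl,
                 n_obs = object$n_obs, label = object$label),
            class = "summary.trend_gam")
}

#' @export
print.summary.trend_gam <- function(x, ...) {
  cat(sprintf("Term tests (n = %d, deviance explained = %.1f%%)\n",
              x$n_obs, 100 * x$dev_expl))
  tt <- x$terms
  tt$statistic <- signif(tt$statistic, 5)
  tt$p_value <- signif(tt$p_value, 4)
  print(tt, row.names = FALSE)
  invisible(x)
}

#' @export
coef.trend_gam <- function(object, ...) stats::coef(object$model)

#' Predict mean cover from a fitted trend model
#'
#' @param object A `trend_gam`.
#' @param newdata Data.frame with `year`, `reef_type`, `locality`; defaults
#'   to the fitted data.
#' @param type `"response"` (mean cover, back-transformed through the inverse
#'   squeeze and clamped to `[0, 1]`) or `"link"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.trend_gam <- function(object, newdata = NULL, type = c("response", "link"), ...) {
  type <- match.arg(type)
  pr <- if (is.null(newdata)) mgcv::predict.gam(object$model, type = type)
  else mgcv::predict.gam(object$model, newdata = newdata, type = type)
  if (type == "response") pmin(pmax(inverse_squeeze(pr, object$squeeze_n), 0), 1)
  else as.numeric(pr)
}

#' @export
residuals.trend_gam <- function(object, type = "deviance", ...)
  stats::residuals(object$model, type = type)

#' Plot fitted cover trends by reef type
#'
#' @param x A `trend_gam`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.trend_gam <- function(x, ...) {
  cv <- x$curves
  lv <- unique(cv$reef_type)
  cols <- stats::setNames(grDevices::hcl.colors(max(2, length(lv)), "Dark 2")[seq_along(lv)], lv)
  graphics::plot(range(cv$year), range(c(cv$lo95, cv$hi95)), type = "n",
                 xlab = "year", ylab = "mean cover", ...)
  for (l in lv) {
    g <- cv[cv$reef_type == l, ]
    graphics::polygon(c(g$year, rev(g$year)), c(g$lo95, rev(g$hi95)),
                      col = grDevices::adjustcolor(cols[l], 0.2), border = NA)
    graphics::lines(g$year, g$mean, col = cols[l], lwd = 2)
  }
  graphics::legend("topleft", legend = lv, col = cols[lv], lwd = 2, bty = "n")
  invisible(x)
}

#' Refit the trend model on fixed transects only
#'
#' Sensitivity analysis for the mixing of fixed and random transects: the
#' data are restricted to fixed-transect sites and the model refit without
#' the reef-type terms (a single reef type remains under the default survey
#' design, where both fixed-transect sites are forereefs).
#'
#' @param data As for [fit_trend_gam()], with a `transect_type` column.
#' @param ... Passed to [fit_trend_gam()].
#' @return A `trend_gam`.
#' @export
fixed_transect_sensitivity <- function(data, ...) {
  if (is.null(data$transect_type))
    stop_reefquad("data must contain a transect_type column", "reefquad_invalid_params")
  d <- data[data$transect_type == "fixed", , drop = FALSE]
  if (!nrow(d))
    stop_reefquad("no fixed-transect rows in data", "reefquad_invalid_params")
  fit_trend_gam(d, reef_terms = FALSE, ...)
}
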