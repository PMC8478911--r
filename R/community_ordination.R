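#' Build the site-year community matrix
#'
#' Widens aggregated mean cover into a site-year x benthic-group matrix with
#' the square-root transform applied entrywise (the usual down-weighting of
#' dominant groups before dissimilarity-based ordination). Absent groups are
#' 0; duplicated site-year-label rows are an error.
#'
#' @param cover Aggregated cover rows (from [site_year_cover()]): columns
#'   `site`, `year`, `label`, `cover`, optionally `reef_type`.
#' @return Numeric matrix of class `community_matrix` (rows `site_year`,
#'   columns labels, entries `sqrt(cover)`), with a `meta` attribute holding
#'   `site`, `year` (and `reef_type`) per row.
#' @export
build_matrix <- function(cover) {
  need <- c("site", "year", "label", "cover")
  if (!all(need %in% names(cover)))
    stop_reefquad(paste("cover must contain columns:", paste(need, collapse = ", ")),
                  "reefquad_invalid_params")
  key <- paste(cover$site, cover$year, cover$label, sep = "\r")
  if (anyDuplicated(key))
    stop_reefquad("duplicate site-year-label rows in cover", "reefquad_invalid_params")
  units <- unique(cover[, c("site", "year")])
  units <- units[order(units$site, units$year), , drop = FALSE]
  labels <- sort(unique(cover$label))
  m <- matrix(0, nrow(units), length(labels),
              dimnames = list(paste(units$site, units$year, sep = "_"), labels))
  ri <- match(paste(cover$site, cover$year, sep = "\r"),
              paste(units$site, units$year, sep = "\r"))
  m[cbind(ri, match(cover$label, labels))] <- sqrt(cover$cover)
  meta <- units
  if (!is.null(cover$reef_type)) {
    unit_key <- paste(units$site, units$year, sep = "\r")
    cover_key <- paste(cover$site, cover$year, sep = "\r")
    meta$reef_type <- cover$reef_type[match(unit_key, cover_key)]
  }
  rownames(meta) <- NULL
  structure(m, meta = meta, class = c("community_matrix", "matrix", "array"))
}

#' Non-metric multidimensional scaling of the community matrix
#'
#' Ordinates the square-root cover matrix by NMDS (Bray-Curtis dissimilarity
#' by default, configurable to Euclidean) with seeded random restarts,
#' reporting the final stress and its conventional interpretation band
#' (0.1-0.2 is read as good to excellent agreement between the original
#' dissimilarities and the reduced space).
#'
#' @param m A [build_matrix()] result (or any numeric matrix).
#' @param k Target dimensionality (default 2); needs at least `k + 2` rows.
#' @param seed Integer seed (restarts are deterministic under it).
#' @param distance `"bray"` or `"euclidean"`.
#' @param trymax Maximum random restarts (default 20).
#' @return List of class `nmds_result`: `coords` (rows x k), `stress`,
#'   `stress_band`, `distance`, `converged`.
#' @export
run_nmds <- function(m, k = 2, seed = NULL, distance = c("bray", "euclidean"),
                     trymax = 20) {
  distance <- match.arg(distance)
  if (nrow(m) < k + 2)
    stop_reefquad(sprintf("need at least %d rows for k = %d", k + 2, k),
                  "reefquad_invalid_params")
  if (all(apply(m, 2, function(col) diff(range(col)) == 0)))
    stop_reefquad("all rows identical: ordination is degenerate", "reefquad_degenerate_design")
  mm <- unclass(m)
  attr(mm, "meta") <- NULL
  if (is.null(rownames(mm))) rownames(mm) <- paste0("row", seq_len(nrow(mm)))
  if (is.null(colnames(mm))) colnames(mm) <- paste0("g", seq_len(ncol(mm)))
  fit <- with_seed(seed, vegan::metaMDS(mm, k = k, distance = distance,
                                        trymax = trymax, trace = FALSE))
  stress <- fit$stress
  band <- if (stress < 0.1) "excellent"
  else if (stress < 0.2) "good to excellent"
  else if (stress < 0.3) "usable with caution"
  else "poor"
  structure(list(coords = fit$points, stress = stress, stress_band = band,
                 distance = distance, converged = isTRUE(fit$converged) || fit$converged > 0,
                 meta = attr(m, "meta")),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS (%s distance): %d points, stress = %.3f (%s)\n",
              x$distance, nrow(x$coords), x$stress, x$stress_band))
  invisible(x)
}

#' Redundancy analysis with permutation ANOVA
#'
#' Constrained ordination of the (column-centered) community matrix on the
#' row metadata, with significance by unrestricted row permutation. Terms
#' are added sequentially; each term's constrained variance is the sum of
#' squares of the projection of the response onto the orthogonal increment
#' of its design columns, and its pseudo-F is
#' `(SS_term / df_term) / (SS_residual / df_residual)`. P-values are
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`, so the smallest attainable
#' p-value is `1 / (n_perm + 1)`. Rows are canonically ordered by site and
#' year before analysis, making results invariant to input row order.
#'
#' @param m A [build_matrix()] result (its `meta` attribute supplies the
#'   predictors), or a plain matrix with `meta` passed explicitly.
#' @param terms Character vector of predictor columns in the metadata, fitted
#'   in the given (sequential) order. `year` is treated as a numeric
#'   covariate, other terms as factors.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param meta Optional data.frame of row metadata overriding the attribute.
#' @return Object of class `rda_perm`: `table` (term, df, variance,
#'   proportion, F, p_value), `total_variance`, `residual_variance`,
#'   `residual_df`, `n_perm`.
#' @export
rda_perm_anova <- function(m, terms = c("reef_type", "locality", "year"),
                           n_perm = 999, seed = NULL, meta = NULL) {
  meta <- meta %||% attr(m, "meta")
  if (is.null(meta))
    stop_reefquad("row metadata required (build the matrix with build_matrix or pass meta=)",
                  "reefquad_invalid_params")
  if ("locality" %in% terms && is.null(meta$locality) && !is.null(meta$site))
    meta$locality <- meta$site
  missing_terms <- setdiff(terms, names(meta))
  if (length(missing_terms))
    stop_reefquad(paste("metadata lacks terms:", paste(missing_terms, collapse = ", ")),
                  "reefquad_invalid_params")

  Y <- unclass(m); attr(Y, "meta") <- NULL
  ord <- do.call(order, meta[intersect(c("site", "year"), names(meta))])
  if (length(ord) == nrow(Y)) { Y <- Y[ord, , drop = FALSE]; meta <- meta[ord, , drop = FALSE] }
  Y <- scale(Y, center = TRUE, scale = FALSE)
  n <- nrow(Y)
  total <- sum(Y^2)

  # sequential orthonormal bases per term
  X <- matrix(1, n, 1)
  Qs <- list(); dfs <- integer(length(terms))
  for (j in seq_along(terms)) {
    v <- meta[[terms[j]]]
    blk <- if (terms[j] == "year" && is.numeric(v)) matrix(as.numeric(v), n, 1)
    else stats::model.matrix(~ f - 1, data.frame(f = factor(v)))
    Xn <- cbind(X, blk)
    qr_prev <- qr(X); qr_new <- qr(Xn)
    r_inc <- qr_new$rank - qr_prev$rank
    if (r_inc == 0)
      stop_reefquad(sprintf("term '%s' is aliased with preceding terms (adds no rank)",
                            terms[j]), "reefquad_aliased_term")
    Qfull <- qr.Q(qr_new)[, seq_len(qr_new$rank), drop = FALSE]
    Qs[[j]] <- Qfull[, (qr_prev$rank + 1):qr_new$rank, drop = FALSE]
    dfs[j] <- r_inc
    X <- Xn
  }
  df_res <- n - 1 - sum(dfs)
  if (df_res < 1)
    stop_reefquad("no residual degrees of freedom left", "reefquad_degenerate_design")

  Qall <- do.call(cbind, Qs)
  blk_idx <- rep(seq_along(terms), dfs)
  term_ss <- function(Yp) {
    proj <- crossprod(Qall, Yp)            # (sum df) x p
    rowsq <- rowSums(proj^2)
    vapply(seq_along(terms), function(j) sum(rowsq[blk_idx == j]), numeric(1))
  }
  ss_obs <- term_ss(Y)
  ss_res_obs <- total - sum(ss_obs)
  f_obs <- (ss_obs / dfs) / (ss_res_obs / df_res)

  exceed <- numeric(length(terms))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      Yp <- Y[sample.int(n), , drop = FALSE]
      ssp <- term_ss(Yp)
      fp <- (ssp / dfs) / ((total - sum(ssp)) / df_res)
      exceed <- exceed + (fp >= f_obs)
    }
  })
  pvals <- (1 + exceed) / (1 + n_perm)

  tab <- data.frame(term = terms, df = dfs, variance = ss_obs / (n - 1),
                    proportion = ss_obs / total, F = f_obs, p_value = pvals,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, total_variance = total / (n - 1),
                 residual_variance = ss_res_obs / (n - 1), residual_df = df_res,
                 n_perm = n_perm),
            class = "rda_perm")
}

#' @export
print.rda_perm <- function(x, ...) {
  cat(sprintf("RDA permutation ANOVA (n_perm = %d)\n", x$n_perm))
  tab <- x$table
  tab$variance <- signif(tab$variance, 5)
  tab$proportion <- signif(tab$proportion, 4)
  tab$F <- signif(tab$F, 5)
  print(tab, row.names = FALSE)
  cat(sprintf("Residual variance %.5g on %d df (total %.5g)\n",
              x$residual_variance, x$residual_df, x$total_variance))
  invisible(x)
}
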