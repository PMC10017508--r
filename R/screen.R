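#' Screen spatial resolutions by held-out predictive performance
#'
#' For each candidate resolution and cross-validation seed, fits the
#' spatial model on training cells and the nonspatial baseline on the same
#' split, and evaluates pooled test-cell R-squared. The baseline ignores
#' the graph, so its performance is resolution-invariant; the profile of
#' the spatial model over resolutions locates the length scale of
#' cell-cell dependency. A paired two-sided t-test across seeds compares
#' the best spatial model with the baseline.
#'
#' @param dataset a [spatial_dataset()].
#' @param resolutions numeric vector of at least 2 radii (micrometres).
#' @param variant spatial design variant, `"interaction"` or
#'   `"global_sender"`.
#' @param seeds integer vector of at least 2 cross-validation seeds; each
#'   seed re-draws the train/validation/test split.
#' @param scale_node_size multiply predictions by per-cell size factors.
#' @return List of class `resolution_screen` with a long `table`
#'   (resolution, seed, model, r2), the per-resolution mean `delta_r2`,
#'   `best_resolution`, and the paired t-test result `comparison`.
#' @export
resolution_screen <- function(dataset, resolutions, variant = "interaction",
                              seeds = 1:3, scale_node_size = FALSE) {
  if (length(resolutions) < 2L) stop("need at least 2 resolutions")
  if (length(seeds) < 2L) stop("need at least 2 seeds for the paired test")
  resolutions <- sort(resolutions)
  sf <- if (scale_node_size) size_factors(dataset) else NULL
  rows <- list()
  for (seed in seeds) {
    split <- split_nodes(dataset, seed)
    tr <- split$train; te <- split$test
    gm <- colMeans(dataset$expression[tr, , drop = FALSE])
    base_design <- build_design(dataset, variant = "baseline")
    r2_base <- screen_fit_eval(base_design, dataset$expression, tr, te, gm, sf)
    rows[[length(rows) + 1L]] <-
      data.frame(resolution = resolutions, seed = seed, model = "baseline",
                 r2 = r2_base)
    r2_sp <- vapply(resolutions, function(res) {
      g <- build_graph(dataset, res)
      des <- build_design(dataset, g, variant = variant)
      screen_fit_eval(des, dataset$expression, tr, te, gm, sf)
    }, numeric(1))
    rows[[length(rows) + 1L]] <-
      data.frame(resolution = resolutions, seed = seed, model = "ncem",
                 r2 = r2_sp)
  }
  tab <- do.call(rbind, rows)
  mean_r2 <- tapply(tab$r2[tab$model == "ncem"], tab$resolution[tab$model == "ncem"], mean)
  base_mean <- mean(tab$r2[tab$model == "baseline"])
  delta <- mean_r2 - base_mean
  best <- as.numeric(names(which.max(mean_r2)))
  ncem_best <- tab$r2[tab$model == "ncem" & tab$resolution == best]
  base_by_seed <- tab$r2[tab$model == "baseline" & tab$resolution == resolutions[1]]
  comparison <- stats::t.test(ncem_best, base_by_seed, paired = TRUE)
  structure(
    list(table = tab,
         delta_r2 = data.frame(resolution = as.numeric(names(mean_r2)),
                               mean_r2 = as.numeric(mean_r2),
                               delta_r2 = as.numeric(delta)),
         baseline_r2 = base_mean,
         best_resolution = best,
         comparison = comparison),
    class = "resolution_screen"
  )
}

# fit on train rows, pooled test R2 against training gene means; with node
# size scaling the model is fit on depth-normalized expression and its
# predictions are rescaled by the test cells' size factors
screen_fit_eval <- function(design, Y, train, test, gene_means_train, sf) {
  Yfit <- if (is.null(sf)) Y else Y / sf
  sub <- design
  sub$values <- design$values[train, , drop = FALSE]
  fit <- fit_ols(sub, Yfit[train, , drop = FALSE])
  test_design <- design
  test_design$values <- design$values[test, , drop = FALSE]
  yhat <- predict(fit, test_design,
                  size_factors = if (is.null(sf)) NULL else sf[test])
  r_squared(Y[test, , drop = FALSE], yhat, gene_means_train)$pooled
}

#' @export
print.resolution_screen <- function(x, ...) {
  cat("resolution screen (pooled test R2):\n")
  print(x$delta_r2, row.names = FALSE)
  cat(sprintf("baseline R2 %.4f; best resolution %.1f um; paired t-test p = %.3g\n",
              x$baseline_r2, x$best_resolution, x$comparison$p.value))
  invisible(x)
}
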