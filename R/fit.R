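#' Ordinary least squares fit of a linear NCEM
#'
#' Fits all genes jointly by OLS on the supplied design. Rank deficiency
#' (e.g. the structural collinearity between the full receiver-type and
#' domain one-hot blocks, or never-observed interaction columns) is
#' handled by the minimum-norm solution through the SVD pseudo-inverse;
#' columns involved in any exact collinearity are flagged non-estimable
#' and excluded from testing.
#'
#' Standard errors come from the gene-wise residual variance (denominator
#' N - rank) times the diagonal of the generalized inverse of X'X. The
#' per-gene `sigma` is the maximum-likelihood residual SD (denominator N),
#' matching the Gaussian likelihood used as the training objective.
#'
#' @param design an [build_design()] result (or any `ncem_design`).
#' @param Y numeric cells x genes response matrix.
#' @return An object of class `ncem_fit` with elements `coefficients`
#'   (P x J), `standard_errors`, `sigma`, `fitted`, `residual_df`, `rank`,
#'   `estimable` (logical per column), `observed` (non-all-zero columns),
#'   the design `provenance`/`variant`, and after [wald_test()] the
#'   matrices `p_values`/`q_values` over interaction columns x genes.
#' @export
fit_ols <- function(design, Y) {
  X <- design$values
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 rows to fit")
  if (nrow(Y) != n) stop("design and response disagree on the number of rows")
  p <- ncol(X)
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  r <- sum(pos)
  u <- sv$u[, pos, drop = FALSE]
  d <- sv$d[pos]
  v <- sv$v[, pos, drop = FALSE]
  beta <- v %*% ((crossprod(u, Y)) / d)
  fitted <- X %*% beta
  rss <- colSums((Y - fitted)^2)
  df <- n - r
  sigma <- sqrt(rss / n)
  s2 <- if (df > 0) rss / df else rep(NA_real_, ncol(Y))
  # diag of (X'X)^+ = rowSums((V / d)^2)
  covdiag <- rowSums(sweep(v, 2, d, "/")^2)
  se <- sqrt(outer(covdiag, s2))
  estimable <- rep(TRUE, p)
  if (r < p) {
    vnull <- sv$v[, !pos, drop = FALSE]
    estimable <- rowSums(vnull^2) < 1e-12
  }
  observed <- colSums(abs(X)) > 0
  dimnames(beta) <- list(colnames(X), colnames(Y))
  dimnames(se) <- dimnames(beta)
  structure(
    list(coefficients = beta, standard_errors = se, sigma = sigma,
         fitted = fitted, residual_df = df, rank = r,
         estimable = estimable, observed = observed,
         provenance = design$provenance, variant = design$variant,
         types = design$types, domains = design$domains,
         p_values = NULL, q_values = NULL),
    class = "ncem_fit"
  )
}

#' @export
print.ncem_fit <- function(x, ...) {
  cat(sprintf("ncem_fit (%s): %d coefficients x %d genes, rank %d, df %d\n",
              x$variant, nrow(x$coefficients), ncol(x$coefficients),
              x$rank, x$residual_df))
  if (!is.null(x$q_values))
    cat(sprintf("  Wald test: %d interaction x gene hypotheses, %d at q < 0.05\n",
                sum(!is.na(x$q_values)), sum(x$q_values < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Predict from a fitted linear NCEM
#'
#' @param object an [fit_ols()] result.
#' @param design an `ncem_design` over the cells to predict.
#' @param size_factors optional per-cell factors multiplying predictions.
#' @param ... unused.
#' @return Numeric cells x genes matrix of predictions.
#' @export
predict.ncem_fit <- function(object, design, size_factors = NULL, ...) {
  yhat <- design$values %*% object$coefficients
  if (!is.null(size_factors)) yhat <- yhat * size_factors
  yhat
}

#' Wald tests on sender-receiver interaction coefficients
#'
#' Tests each (interaction column, gene) coefficient with the statistic
#' beta / SE referred to a two-sided t distribution on N - rank(X) degrees
#' of freedom, then applies Benjamini-Hochberg FDR correction jointly
#' across all tested pairs. Non-estimable (collinear) and never-observed
#' (all-zero) interaction columns are excluded and reported.
#'
#' @param fit an [fit_ols()] result from an interaction-variant design.
#' @return The fit with `p_values` and `q_values` matrices (interaction
#'   columns x genes; NA for untestable columns) and a data frame
#'   `untestable` naming excluded columns, attached.
#' @export
wald_test <- function(fit) {
  ia <- which(fit$provenance$block == "interaction")
  if (!length(ia)) stop("wald_test requires an interaction-variant fit")
  if (fit$residual_df <= 0) stop("no residual degrees of freedom for inference")
  testable <- fit$estimable[ia] & fit$observed[ia]
  b <- fit$coefficients[ia, , drop = FALSE]
  se <- fit$standard_errors[ia, , drop = FALSE]
  tstat <- b / se
  pv <- matrix(NA_real_, length(ia), ncol(b), dimnames = dimnames(b))
  pv[testable, ] <- 2 * stats::pt(-abs(tstat[testable, , drop = FALSE]),
                                  df = fit$residual_df)
  qv <- pv
  qv[testable, ] <- matrix(stats::p.adjust(pv[testable, , drop = FALSE], method = "BH"),
                           nrow = sum(testable))
  fit$statistics <- tstat
  fit$p_values <- pv
  fit$q_values <- qv
  fit$untestable <- fit$provenance[ia[!testable], , drop = FALSE]
  fit
}

#' Mean Gaussian log-likelihood of predictions
#'
#' The per-entry average (not sum) over cells and genes of the Gaussian
#' log density with gene-wise standard deviations.
#'
#' @param Y,Yhat observed and predicted cells x genes matrices.
#' @param sigma positive gene-wise standard deviations (length J).
#' @return A single number.
#' @export
gaussian_ll <- function(Y, Yhat, sigma) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat))) stop("Y and Yhat must have the same shape")
  if (length(sigma) == 1L) sigma <- rep(sigma, ncol(Y))
  if (any(sigma <= 0)) stop("sigma must be positive")
  resid2 <- sweep((Y - Yhat)^2, 2, sigma^2, "/")
  terms <- sweep(-0.5 * resid2, 2, log(sqrt(2 * pi) * sigma), "-")
  mean(terms)
}

#' Coefficient of determination on held-out cells
#'
#' Per cell i, `R2_i = 1 - sum_j (y_ij - yhat_ij)^2 / sum_j (y_ij -
#' ybar_j)^2` where `ybar_j` are gene means computed on training cells
#' only. Also reports the pooled value over all test entries. Cells whose
#' denominator is zero are excluded with a warning.
#'
#' @param Y_test,Yhat_test observed and predicted matrices on test cells.
#' @param gene_means_train numeric length-J vector of training gene means.
#' @return List with `per_cell` (NA where undefined) and `pooled`.
#' @export
r_squared <- function(Y_test, Yhat_test, gene_means_train) {
  Y_test <- as.matrix(Y_test); Yhat_test <- as.matrix(Yhat_test)
  if (length(gene_means_train) != ncol(Y_test))
    stop("gene_means_train must have one entry per gene")
  num <- rowSums((Y_test - Yhat_test)^2)
  cent <- sweep(Y_test, 2, gene_means_train)
  den <- rowSums(cent^2)
  per_cell <- ifelse(den > 0, 1 - num / den, NA_real_)
  if (anyNA(per_cell))
    warning(sprintf("%d cell(s) with zero variance around training means excluded",
                    sum(is.na(per_cell))))
  pooled_den <- sum(den)
  pooled <- if (pooled_den > 0) 1 - sum(num) / pooled_den else NA_real_
  list(per_cell = per_cell, pooled = pooled)
}
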