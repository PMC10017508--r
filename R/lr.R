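#' Resolve a ligand-receptor pair list against a dataset
#'
#' @param pairs data frame with columns `receptor` and `ligand` (gene
#'   symbols), e.g. read from a two-column TSV.
#' @param dataset a [spatial_dataset()] whose gene names the pairs must
#'   resolve to.
#' @return Data frame of class `lr_map` with receptor/ligand names and
#'   resolved column indices; duplicated pairs are dropped.
#' @export
lr_map <- function(pairs, dataset) {
  pairs <- as.data.frame(pairs)
  if (!all(c("receptor", "ligand") %in% names(pairs)))
    stop("pairs must have columns 'receptor' and 'ligand'")
  missing <- setdiff(unique(c(pairs$receptor, pairs$ligand)), dataset$gene_names)
  if (length(missing))
    stop("gene name(s) not in dataset: ", paste(missing, collapse = ", "))
  pairs <- unique(pairs[, c("receptor", "ligand")])
  pairs$receptor_idx <- match(pairs$receptor, dataset$gene_names)
  pairs$ligand_idx <- match(pairs$ligand, dataset$gene_names)
  rownames(pairs) <- NULL
  class(pairs) <- c("lr_map", "data.frame")
  pairs
}

#' Receptor-activity graph kernel
#'
#' Embeds each cell into a K-dimensional receptor-activity space: for
#' ligand-receptor pair k, `z[i, k]` is the sum over neighbours m of
#' `f_R(receptor expression of cell i) * f_L(ligand expression of cell
#' m)`. With the default identity transforms this is the index cell's
#' receptor expression times the summed ligand expression of its
#' neighbourhood. Isolated cells get zero activity.
#'
#' @param Y cells x genes expression matrix.
#' @param graph a [build_graph()] result.
#' @param map an [lr_map()].
#' @param f_R,f_L elementwise transforms of receptor and ligand
#'   expression; identity by default.
#' @return Numeric cells x K activity matrix (columns named
#'   `receptor_ligand`).
#' @export
lr_kernel <- function(Y, graph, map, f_R = identity, f_L = identity) {
  Y <- as.matrix(Y)
  rec <- f_R(Y[, map$receptor_idx, drop = FALSE])
  lig <- f_L(Y[, map$ligand_idx, drop = FALSE])
  z <- rec * as.matrix(graph$adjacency %*% lig)
  colnames(z) <- paste(map$receptor, map$ligand, sep = "_")
  z
}

#' Fit the ligand-receptor NCEM and its intracellular baseline
#'
#' The LR model decodes all genes from the receptor-activity latent space
#' ([lr_kernel()]) plus domain covariates through a fully connected
#' stack. The baseline replaces the kernel activations with the index
#' cell's own receptor expression (same decoder shape), i.e. it imputes
#' expression from intracellular receptor levels without the niche.
#'
#' @param dataset a [spatial_dataset()].
#' @param graph a [build_graph()] result.
#' @param map an [lr_map()].
#' @param depth,width decoder hidden layers and width.
#' @param pair_weights learn a per-pair softplus scaling of the kernel
#'   activations.
#' @param lr_grid,split,seed,... as in [fit_nl_ncem()].
#' @return List of class `lr_ncem_fit` with the fitted `model`, the
#'   `baseline`, their pooled test `r2`, and the kernel activations `z`.
#' @export
fit_lr_ncem <- function(dataset, graph, map, depth = 1, width = 16,
                        pair_weights = FALSE,
                        lr_grid = c(0.5, 0.05, 0.005),
                        split = NULL, seed = 1, ...) {
  if (!nrow(map)) stop("empty ligand-receptor map")
  if (is.null(split)) split <- split_nodes(dataset, seed)
  z <- lr_kernel(dataset$expression, graph, map)
  xc <- one_hot(dataset$domain)
  model <- train_lr_decoder(dataset, cbind(z, xc), ncol(z), pair_weights,
                            depth, width, lr_grid, split, seed, ...)
  rec <- dataset$expression[, map$receptor_idx, drop = FALSE]
  baseline <- train_lr_decoder(dataset, cbind(rec, xc), ncol(rec), FALSE,
                               depth, width, lr_grid, split, seed, ...)
  structure(
    list(model = model, baseline = baseline, z = z, map = map,
         r2 = c(model = model$r2[["test"]], baseline = baseline$r2[["test"]]),
         split = split),
    class = "lr_ncem_fit"
  )
}

# shared decoder trainer: features are fixed (kernel activations are
# constant wrt the parameters), optionally with learned per-pair softplus
# scaling of the first `k` feature columns. The bottleneck block is
# standardized with training statistics so kernel activations (which scale
# with expression squared times degree) enter on a unit scale.
train_lr_decoder <- function(dataset, x, k, pair_weights, depth, width,
                             lr_grid, split, seed, ...) {
  y <- dataset$expression
  mu_x <- colMeans(x[split$train, seq_len(k), drop = FALSE])
  sd_x <- pmax(apply(x[split$train, seq_len(k), drop = FALSE], 2, stats::sd),
               1e-8)
  x[, seq_len(k)] <- sweep(sweep(x[, seq_len(k), drop = FALSE], 2, mu_x),
                           2, sd_x, "/")
  j <- ncol(y)
  hidden <- rep(width, depth)
  softplus <- function(r) log1p(exp(-abs(r))) + pmax(r, 0)
  make_model <- function() {
    params <- withr::with_seed(seed, {
      p <- list(layers = mlp_init(ncol(x), hidden, j), log_sigma = rep(0, j))
      if (pair_weights) p$rho <- rep(0, k)
      p
    })
    params$layers[[length(params$layers)]]$b <-
      colMeans(y[split$train, , drop = FALSE])
    params$log_sigma <-
      log(pmax(apply(y[split$train, , drop = FALSE], 2, stats::sd), 1e-3))
    features <- function(params, idx) {
      xi <- x[idx, , drop = FALSE]
      if (pair_weights)
        xi[, seq_len(k)] <- sweep(xi[, seq_len(k), drop = FALSE], 2,
                                  softplus(params$rho), "*")
      xi
    }
    eval_loss <- function(params, idx) {
      fw <- mlp_forward(params$layers, features(params, idx))
      nll_terms(y[idx, , drop = FALSE], fw$out, params$log_sigma)$loss
    }
    loss_grad <- function(params, idx) {
      xi <- features(params, idx)
      fw <- mlp_forward(params$layers, xi)
      nt <- nll_terms(y[idx, , drop = FALSE], fw$out, params$log_sigma)
      mb <- mlp_backward(params$layers, fw, nt$dyhat)
      grads <- list(layers = mb$grads, log_sigma = nt$dlog_sigma)
      if (pair_weights) {
        dz <- mb$dx[, seq_len(k), drop = FALSE]
        raw <- x[idx, seq_len(k), drop = FALSE]
        grads$rho <- colSums(dz * raw) * stats::plogis(params$rho)
      }
      list(loss = nt$loss, grads = grads)
    }
    list(params = params, loss_grad = loss_grad, loss = eval_loss)
  }
  gm_val <- colMeans(y[split$train, , drop = FALSE])
  eval_r2 <- function(params) {
    idx <- split$validation
    xi <- x[idx, , drop = FALSE]
    if (pair_weights)
      xi[, seq_len(k)] <- sweep(xi[, seq_len(k), drop = FALSE], 2,
                                softplus(params$rho), "*")
    yh <- mlp_forward(params$layers, xi)$out
    r_squared(y[idx, , drop = FALSE], yh, gm_val)$pooled
  }
  grid <- nn_train_grid(make_model, split, dataset$domain, lr_grid, seed,
                        eval_r2 = eval_r2, ...)
  fit <- grid$fit
  best <- grid$best
  xi <- x
  if (pair_weights)
    xi[, seq_len(k)] <- sweep(xi[, seq_len(k), drop = FALSE], 2,
                              softplus(fit$params$rho), "*")
  yhat <- mlp_forward(fit$params$layers, xi)$out
  gm <- colMeans(y[split$train, , drop = FALSE])
  r2 <- vapply(c(train = "train", validation = "validation", test = "test"),
               function(role) {
                 idx <- split[[role]]
                 r_squared(y[idx, , drop = FALSE], yhat[idx, , drop = FALSE], gm)$pooled
               }, numeric(1))
  list(params = fit$params, predictions = yhat, r2 = r2,
       lr_selected = lr_grid[best], history = fit$history)
}

#' @export
print.lr_ncem_fit <- function(x, ...) {
  cat(sprintf("lr_ncem_fit: %d pairs; test R2 %.4f (baseline %.4f)\n",
              nrow(x$map), x$r2[["model"]], x$r2[["baseline"]]))
  invisible(x)
}

#' Differential receptor activity between niche-defined groups
#'
#' Two-sample t-tests per receptor-activity latent unit between cells
#' with and without a property (typically: receiver-type cells with vs
#' without a given sender type in their neighbourhood), with
#' Benjamini-Hochberg correction, ranked by |t|.
#'
#' @param z cells x K receptor-activity matrix from [lr_kernel()].
#' @param group_mask logical/0-1 vector over the rows of `z` defining the
#'   "with" group; the complement is the "without" group.
#' @return Data frame (class `receptor_activity_ranking`) with columns
#'   pair, t, p, q, mean_with, mean_without, sorted by |t| decreasing.
#' @export
differential_receptor_activity <- function(z, group_mask) {
  z <- as.matrix(z)
  g <- as.logical(group_mask)
  if (length(g) != nrow(z)) stop("group_mask must have one entry per cell")
  if (sum(g) < 2L || sum(!g) < 2L) stop("both groups need at least 2 cells")
  res <- lapply(seq_len(ncol(z)), function(k) {
    a <- z[g, k]; b <- z[!g, k]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      data.frame(t = 0, p = 1, mean_with = mean(a), mean_without = mean(b))
    } else {
      tt <- stats::t.test(a, b)
      data.frame(t = unname(tt$statistic), p = tt$p.value,
                 mean_with = mean(a), mean_without = mean(b))
    }
  })
  out <- do.call(rbind, res)
  out <- cbind(pair = colnames(z) %||% paste0("unit_", seq_len(ncol(z))), out)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(-abs(out$t)), c("pair", "t", "p", "q", "mean_with", "mean_without")]
  rownames(out) <- NULL
  class(out) <- c("receptor_activity_ranking", "data.frame")
  out
}
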