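#' One-layer graph-convolution embedding of niche composition
#'
#' Computes `softmax(ReLU(Abar %*% X_type %*% W))` per cell: the
#' neighbourhood-averaged type fractions are mapped linearly by `W`,
#' rectified, and normalized with a softmax across the embedding features
#' of each cell (rows sum to 1). Isolated cells have an all-zero
#' pre-activation and therefore a uniform `1/H` embedding.
#'
#' @param normalized_adjacency row-normalized adjacency (`Abar`).
#' @param types one-hot cells x types matrix.
#' @param W numeric types x H weight matrix.
#' @return Numeric cells x H embedding with unit row sums.
#' @export
gcn_embed <- function(normalized_adjacency, types, W) {
  if (nrow(W) != ncol(types)) stop("W must have one row per cell type")
  pre <- pmax(as.matrix(normalized_adjacency %*% types) %*% W, 0)
  softmax_rows(pre)
}

softmax_rows <- function(z) {
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

#' Indicator embedding of the niche
#'
#' Feature-wise max pooling of one-hot cell types across the
#' neighbourhood, excluding the index cell: identical to
#' [sender_presence()] (shared implementation).
#'
#' @inheritParams sender_presence
#' @return Binary cells x types matrix.
#' @export
indicator_embed <- function(graph, types) sender_presence(graph, types)

# gaussian negative log-likelihood (mean over entries) and its gradients
nll_terms <- function(y, yhat, log_sigma) {
  nb <- nrow(y); j <- ncol(y)
  sigma2 <- exp(2 * log_sigma)
  r <- yhat - y
  r2s <- sweep(r^2, 2, sigma2, "/")
  loss <- (sum(sweep(0.5 * r2s, 2, log_sigma + log(sqrt(2 * pi)), "+"))) / (nb * j)
  dyhat <- sweep(r, 2, sigma2, "/") / (nb * j)
  dls <- colSums(1 - r2s) / (nb * j)
  list(loss = loss, dyhat = dyhat, dlog_sigma = dls)
}

# assemble features for the deterministic nonlinear family; the indicator
# aggregator uses the interaction design (the nesting of the linear NCEM),
# "none" is the nonspatial neural baseline
nl_features <- function(dataset, graph, aggregator, gcn_width) {
  xl <- one_hot(dataset$cell_type)
  xc <- one_hot(dataset$domain)
  switch(aggregator,
    indicator = list(kind = "fixed",
                     x = build_design(dataset, graph, "interaction")$values),
    none = list(kind = "fixed", x = cbind(xl, xc)),
    gcn = list(kind = "gcn", xl = xl, xc = xc,
               m = as.matrix(graph$normalized_adjacency %*% xl),
               h = gcn_width),
    stop("unknown aggregator: ", aggregator))
}

nl_input_width <- function(feat) {
  if (feat$kind == "fixed") ncol(feat$x)
  else ncol(feat$xl) + feat$h + ncol(feat$xc)
}

nl_forward_params <- function(params, feat, idx, activation) {
  if (feat$kind == "fixed") {
    x <- feat$x[idx, , drop = FALSE]
    list(x = x, fw = mlp_forward(params$layers, x, activation))
  } else {
    pre <- feat$m[idx, , drop = FALSE] %*% params$gcn_w
    relu <- pmax(pre, 0)
    emb <- softmax_rows(relu)
    x <- cbind(feat$xl[idx, , drop = FALSE], emb, feat$xc[idx, , drop = FALSE])
    list(x = x, fw = mlp_forward(params$layers, x, activation),
         pre = pre, emb = emb)
  }
}

#' Fit a nonlinear (or nonspatial neural) NCEM
#'
#' Trains a fully connected network on niche features with the shared
#' Gaussian likelihood (learned gene-wise standard deviations) and the
#' standard schedule ([training_config()]). Aggregators:
#' * `"indicator"`: binary per-type sender presence crossed with the
#'   receiver type (with zero hidden layers this is exactly the linear
#'   NCEM's design, making the linear model a special case);
#' * `"gcn"`: a learned one-layer graph convolution ([gcn_embed()])
#'   concatenated with the receiver-type and domain one-hots;
#' * `"none"`: the nonspatial neural baseline (type and domain only).
#'
#' A model is trained per learning rate in `lr_grid` and the one with the
#' best validation loss is returned.
#'
#' @param dataset a [spatial_dataset()].
#' @param graph a [build_graph()] result (not needed for `"none"`).
#' @param aggregator niche aggregator, see above.
#' @param depth number of hidden layers (0 for a linear map).
#' @param width hidden-layer width.
#' @param gcn_width embedding width H of the graph convolution.
#' @param activation `"relu"` or `"tanh"`.
#' @param lr_grid learning rates to screen.
#' @param split a [split_nodes()] assignment; defaults to seed `seed`.
#' @param scale_node_size multiply predictions by per-cell size factors.
#' @param seed integer seed controlling initialization and batching.
#' @param ... passed to [training_config()] (e.g. `max_epochs`,
#'   `nodes_per_image`).
#' @return List of class `nl_ncem_fit` with `params`, `predictions` (all
#'   cells), `sigma`, per-split pooled `r2`, the training `history` of the
#'   selected model, `lr_selected`, and the `split`.
#' @export
fit_nl_ncem <- function(dataset, graph = NULL,
                        aggregator = c("indicator", "gcn", "none"),
                        depth = 0, width = 16, gcn_width = NULL,
                        activation = "relu",
                        lr_grid = c(0.5, 0.05, 0.005),
                        split = NULL, scale_node_size = FALSE,
                        seed = 1, ...) {
  aggregator <- match.arg(aggregator)
  if (aggregator != "none" && is.null(graph)) stop("spatial aggregators need a graph")
  if (is.null(gcn_width)) gcn_width <- nlevels(dataset$cell_type)
  if (is.null(split)) split <- split_nodes(dataset, seed)
  y <- dataset$expression
  j <- ncol(y)
  sf <- if (scale_node_size) size_factors(dataset) else NULL
  feat <- nl_features(dataset, graph, aggregator, gcn_width)
  n_in <- nl_input_width(feat)
  hidden <- rep(width, depth)

  make_model <- function() {
    params <- withr::with_seed(seed, {
      p <- list(layers = mlp_init(n_in, hidden, j),
                log_sigma = rep(0, j))
      if (feat$kind == "gcn")
        p$gcn_w <- matrix(stats::rnorm(ncol(feat$xl) * gcn_width, sd = 0.1),
                          ncol(feat$xl), gcn_width)
      p
    })
    # start the output at the training gene means / SDs for fast convergence
    gm_tr <- colMeans(y[split$train, , drop = FALSE])
    sd_tr <- pmax(apply(y[split$train, , drop = FALSE], 2, stats::sd), 1e-3)
    params$layers[[length(params$layers)]]$b <- gm_tr
    params$log_sigma <- log(sd_tr)
    eval_loss <- function(params, idx) {
      fwd <- nl_forward_params(params, feat, idx, activation)
      yhat <- fwd$fw$out
      if (!is.null(sf)) yhat <- yhat * sf[idx]
      nll_terms(y[idx, , drop = FALSE], yhat, params$log_sigma)$loss
    }
    loss_grad <- function(params, idx) {
      fwd <- nl_forward_params(params, feat, idx, activation)
      yhat_raw <- fwd$fw$out
      yhat <- if (is.null(sf)) yhat_raw else yhat_raw * sf[idx]
      nt <- nll_terms(y[idx, , drop = FALSE], yhat, params$log_sigma)
      dyraw <- if (is.null(sf)) nt$dyhat else nt$dyhat * sf[idx]
      mb <- mlp_backward(params$layers, fwd$fw, dyraw, activation)
      grads <- list(layers = mb$grads, log_sigma = nt$dlog_sigma)
      if (feat$kind == "gcn") {
        l <- ncol(feat$xl)
        de <- mb$dx[, l + seq_len(gcn_width), drop = FALSE]
        dpre <- (de - rowSums(de * fwd$emb)) * fwd$emb
        dpre <- dpre * (fwd$pre > 0)
        grads$gcn_w <- crossprod(feat$m[idx, , drop = FALSE], dpre)
      }
      list(loss = nt$loss, grads = grads)
    }
    list(params = params, loss_grad = loss_grad, loss = eval_loss)
  }

  gm_val <- colMeans(y[split$train, , drop = FALSE])
  eval_r2 <- function(params) {
    idx <- split$validation
    fwd <- nl_forward_params(params, feat, idx, activation)
    yh <- fwd$fw$out
    if (!is.null(sf)) yh <- yh * sf[idx]
    r_squared(y[idx, , drop = FALSE], yh, gm_val)$pooled
  }
  grid <- nn_train_grid(make_model, split, dataset$domain, lr_grid, seed,
                        eval_r2 = eval_r2, ...)
  fit <- grid$fit
  best <- grid$best
  vals <- grid$vals
  fwd <- nl_forward_params(fit$params, feat, seq_len(nrow(y)), activation)
  yhat <- fwd$fw$out
  if (!is.null(sf)) yhat <- yhat * sf
  gm <- colMeans(y[split$train, , drop = FALSE])
  r2 <- vapply(c(train = "train", validation = "validation", test = "test"),
               function(role) {
                 idx <- split[[role]]
                 r_squared(y[idx, , drop = FALSE], yhat[idx, , drop = FALSE], gm)$pooled
               }, numeric(1))
  structure(
    list(params = fit$params, aggregator = aggregator, depth = depth,
         activation = activation, predictions = yhat,
         sigma = exp(fit$params$log_sigma), r2 = r2,
         lr_selected = lr_grid[best],
         lr_val_losses = stats::setNames(vals, lr_grid),
         lr_val_r2 = stats::setNames(grid$val_r2, lr_grid),
         history = fit$history, best_epoch = fit$best_epoch,
         split = split, feat = feat, scale = sf),
    class = "nl_ncem_fit"
  )
}

#' @export
print.nl_ncem_fit <- function(x, ...) {
  cat(sprintf("nl_ncem_fit (%s, depth %d): test R2 %.4f (lr %.3g, best epoch %d)\n",
              x$aggregator, x$depth, x$r2[["test"]], x$lr_selected, x$best_epoch))
  invisible(x)
}

#' @export
predict.nl_ncem_fit <- function(object, idx = NULL, ...) {
  if (is.null(idx)) return(object$predictions)
  object$predictions[idx, , drop = FALSE]
}
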