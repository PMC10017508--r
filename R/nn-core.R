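# Minimal dense neural-network machinery used by the nonlinear NCEM
# family: fully connected stacks with ReLU/tanh activations, hand-coded
# backpropagation and an Adam optimizer. All randomness flows through the
# caller's RNG context so training is deterministic given a seed.

act_fun <- function(z, activation) {
  switch(activation, relu = pmax(z, 0), tanh = tanh(z),
         stop("unknown activation: ", activation))
}

act_grad <- function(z, a, activation) {
  switch(activation, relu = (z > 0) + 0, tanh = 1 - a^2)
}

# hidden: integer vector of hidden widths (possibly length 0 -> linear map)
mlp_init <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  lapply(seq_len(length(sizes) - 1L), function(k) {
    list(W = matrix(stats::rnorm(sizes[k] * sizes[k + 1L],
                                 sd = sqrt(1 / sizes[k])),
                    sizes[k], sizes[k + 1L]),
         b = rep(0, sizes[k + 1L]))
  })
}

# forward pass keeping caches for backprop; last layer is linear
mlp_forward <- function(layers, x, activation = "relu") {
  nl <- length(layers)
  inputs <- vector("list", nl)
  pre <- vector("list", nl)
  a <- x
  for (k in seq_len(nl)) {
    inputs[[k]] <- a
    z <- a %*% layers[[k]]$W
    z <- sweep(z, 2, layers[[k]]$b, "+")
    pre[[k]] <- z
    a <- if (k < nl) act_fun(z, activation) else z
  }
  list(out = a, inputs = inputs, pre = pre)
}

# dout: gradient of the loss wrt the network output
mlp_backward <- function(layers, cache, dout, activation = "relu") {
  nl <- length(layers)
  grads <- vector("list", nl)
  d <- dout
  for (k in rev(seq_len(nl))) {
    if (k < nl) {
      a_k <- act_fun(cache$pre[[k]], activation)
      d <- d * act_grad(cache$pre[[k]], a_k, activation)
    }
    grads[[k]] <- list(W = crossprod(cache$inputs[[k]], d),
                       b = colSums(d))
    d <- d %*% t(layers[[k]]$W)
  }
  list(grads = grads, dx = d)
}

# ---- Adam over arbitrary nested lists of numeric arrays ----

nn_zeros_like <- function(p) {
  if (is.list(p)) lapply(p, nn_zeros_like) else p * 0
}

adam_init <- function(params) {
  list(m = nn_zeros_like(params), v = nn_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

#' Training schedule for the neural NCEM family
#'
#' Mirrors the shared optimization schedule: Adam, a reduce-on-plateau
#' learning-rate scheduler on the validation loss (patience 20 epochs,
#' factor 0.5), early stopping with patience 100 epochs, and batches that
#' draw a fixed number of nodes per image per step.
#'
#' @param learning_rate initial Adam learning rate.
#' @param max_epochs hard epoch cap.
#' @param scheduler_patience epochs without validation improvement before
#'   the learning rate is halved.
#' @param scheduler_factor multiplicative learning-rate decay.
#' @param early_stopping_patience epochs without validation improvement
#'   before training stops.
#' @param nodes_per_image nodes sampled per image per step (`Inf` for
#'   full-batch).
#' @param seed integer seed for batching and initialization.
#' @return List of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.05, max_epochs = 500,
                            scheduler_patience = 20, scheduler_factor = 0.5,
                            early_stopping_patience = 100,
                            nodes_per_image = 128, seed = 1) {
  stopifnot(learning_rate > 0, scheduler_patience > 0,
            early_stopping_patience > 0, max_epochs >= 1)
  structure(
    list(learning_rate = learning_rate, max_epochs = max_epochs,
         scheduler_patience = scheduler_patience,
         scheduler_factor = scheduler_factor,
         early_stopping_patience = early_stopping_patience,
         nodes_per_image = nodes_per_image, seed = seed),
    class = "training_config"
  )
}

# Generic training loop. `model` is a list with elements:
#   params      initial parameter list
#   loss_grad   function(params, idx) -> list(loss=, grads=)
#   loss        function(params, idx) -> scalar (deterministic evaluation)
# `domain` assigns each observation to an image for per-image batching.
nn_train <- function(model, split, domain, config) {
  if (!length(split$validation)) stop("empty validation set")
  withr::with_seed(config$seed, {
    params <- model$params
    state <- adam_init(params)
    lr <- config$learning_rate
    best <- list(val = Inf, params = params, epoch = 0L)
    wait_sched <- 0L; wait_stop <- 0L
    hist <- vector("list", config$max_epochs)
    train_by_dom <- split(split$train, domain[split$train])
    for (epoch in seq_len(config$max_epochs)) {
      idx <- unlist(lapply(train_by_dom, function(ix) {
        if (length(ix) <= config$nodes_per_image) ix
        else ix[sample.int(length(ix), config$nodes_per_image)]
      }), use.names = FALSE)
      step <- model$loss_grad(params, idx)
      if (!is.finite(step$loss))
        stop(sprintf("non-finite training loss at epoch %d", epoch))
      upd <- adam_step(params, step$grads, state, lr)
      params <- upd$params; state <- upd$state
      val <- model$loss(params, split$validation)
      hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                  train_loss = step$loss, val_loss = val)
      if (val < best$val - 1e-12) {
        best <- list(val = val, params = params, epoch = epoch)
        wait_sched <- 0L; wait_stop <- 0L
      } else {
        wait_sched <- wait_sched + 1L
        wait_stop <- wait_stop + 1L
      }
      if (wait_sched >= config$scheduler_patience) {
        lr <- lr * config$scheduler_factor
        wait_sched <- 0L
      }
      if (wait_stop >= config$early_stopping_patience) break
    }
    list(params = best$params, best_val_loss = best$val,
         best_epoch = best$epoch,
         history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]))
  })
}

# run the learning-rate grid; a diverging rate (non-finite loss) is skipped
# and only fails if every rate diverges. The best grid member is selected
# by validation R^2 of its best-validation-loss checkpoint (`eval_r2`,
# a function(params) -> scalar); ties and absence of an eval function fall
# back to validation loss.
nn_train_grid <- function(make_model, split, domain, lr_grid, seed,
                          eval_r2 = NULL, ...) {
  runs <- lapply(lr_grid, function(lr) {
    cfg <- training_config(learning_rate = lr, seed = seed, ...)
    tryCatch(nn_train(make_model(), split, domain, cfg),
             error = function(e)
               list(params = NULL, best_val_loss = Inf, best_epoch = NA_integer_,
                    history = NULL, error = conditionMessage(e)))
  })
  vals <- vapply(runs, `[[`, numeric(1), "best_val_loss")
  if (!any(is.finite(vals)))
    stop("training diverged at every learning rate: ", runs[[1]]$error)
  score <- if (is.null(eval_r2)) -vals else
    vapply(runs, function(r)
      if (is.finite(r$best_val_loss)) eval_r2(r$params) else -Inf, numeric(1))
  best <- which.max(score)
  list(fit = runs[[best]], vals = vals, val_r2 = if (is.null(eval_r2)) NULL
       else score, best = best)
}
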