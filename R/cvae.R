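#' Conditional VAE loss: negative likelihood plus KL divergence
#'
#' The training objective of the CVAE-NCEM: the negative mean Gaussian
#' log-likelihood of the reconstruction plus the closed-form KL
#' divergence between the diagonal-Gaussian posterior and the
#' standard-normal prior, the KL averaged with the same per-entry
#' `1/(N*J)` convention as the likelihood so both terms share a scale.
#'
#' @param Y,Yhat observed and reconstructed cells x genes matrices.
#' @param sigma gene-wise likelihood standard deviations.
#' @param mu,logvar posterior means and log-variances (cells x latent).
#' @return List with `loss`, `nll` and `kl` (all scalars on the per-entry
#'   scale).
#' @export
cvae_loss <- function(Y, Yhat, sigma, mu, logvar) {
  if (!all(is.finite(mu)) || !all(is.finite(logvar)))
    stop("non-finite posterior parameters")
  nll <- -gaussian_ll(Y, Yhat, sigma)
  kl <- 0.5 * sum(mu^2 + exp(logvar) - logvar - 1) / (nrow(Y) * ncol(Y))
  list(loss = nll + kl, nll = nll, kl = kl)
}

# conditions for the CVAE: receiver type, niche embedding (indicator
# sender presence), domain; the nonspatial variant drops the niche term
cvae_conditions <- function(dataset, graph, spatial) {
  xl <- one_hot(dataset$cell_type)
  xc <- one_hot(dataset$domain)
  if (spatial) cbind(xl, sender_presence(graph, xl), xc) else cbind(xl, xc)
}

#' Fit a conditional variational autoencoder NCEM
#'
#' Models cell-intrinsic latent states: the encoder maps a cell's
#' expression plus its conditions (cell type, indicator niche embedding,
#' domain) to a diagonal-Gaussian posterior over `z`; the decoder
#' reconstructs expression from `z` and the same conditions. Trained with
#' [cvae_loss()] under the standard schedule, with the reparameterization
#' trick; evaluation uses posterior means. The nonspatial CVAE baseline
#' (`spatial = FALSE`) omits the niche embedding from the conditions.
#'
#' @param dataset a [spatial_dataset()].
#' @param graph a [build_graph()] result.
#' @param latent latent dimension of `z`.
#' @param depth,width hidden layers and width of encoder and decoder.
#' @param kl_weight multiplier on the KL term (default 1).
#' @param target_cell_type optional single receiver type; training and
#'   evaluation are restricted to cells of this type (removes the
#'   type/latent non-identifiability).
#' @param spatial include the niche embedding in the conditions.
#' @param lr_grid,split,seed,... as in [fit_nl_ncem()].
#' @return List of class `cvae_ncem_fit` with `params`, posterior
#'   means/log-variances, `reconstructions` (posterior-mean decoding for
#'   all modelled cells), pooled reconstruction `r2` per split, the cell
#'   subset `cells`, and the training history.
#' @export
fit_cvae <- function(dataset, graph, latent = 4, depth = 1, width = 32,
                     kl_weight = 1, target_cell_type = NULL, spatial = TRUE,
                     lr_grid = c(0.5, 0.05, 0.005), split = NULL, seed = 1,
                     ...) {
  cond_full <- cvae_conditions(dataset, graph, spatial)
  cells <- seq_len(n_cells(dataset))
  if (!is.null(target_cell_type)) {
    if (!target_cell_type %in% levels(dataset$cell_type))
      stop("unknown target_cell_type: ", target_cell_type)
    cells <- which(dataset$cell_type == target_cell_type)
  }
  y <- dataset$expression[cells, , drop = FALSE]
  cond <- cond_full[cells, , drop = FALSE]
  domain <- dataset$domain[cells]
  if (is.null(split)) split <- split_nodes(length(cells), seed)
  j <- ncol(y)
  hidden <- rep(width, depth)

  make_model <- function() {
    params <- withr::with_seed(seed, list(
      enc = mlp_init(j + ncol(cond), hidden, 2L * latent),
      dec = mlp_init(latent + ncol(cond), hidden, j),
      log_sigma = rep(0, j)
    ))
    gm_tr <- colMeans(y[split$train, , drop = FALSE])
    sd_tr <- pmax(apply(y[split$train, , drop = FALSE], 2, stats::sd), 1e-3)
    params$dec[[length(params$dec)]]$b <- gm_tr
    params$log_sigma <- log(sd_tr)
    # encoder sees standardized expression (training means/SDs) so its
    # activations start on a unit scale regardless of the data's range
    y_std <- sweep(sweep(y, 2, gm_tr), 2, sd_tr, "/")
    encode <- function(params, idx) {
      fw <- mlp_forward(params$enc, cbind(y_std[idx, , drop = FALSE],
                                          cond[idx, , drop = FALSE]))
      list(fw = fw, mu = fw$out[, seq_len(latent), drop = FALSE],
           logvar = fw$out[, latent + seq_len(latent), drop = FALSE])
    }
    # deterministic evaluation: posterior mean, KL still counted
    eval_loss <- function(params, idx) {
      en <- encode(params, idx)
      de <- mlp_forward(params$dec, cbind(en$mu, cond[idx, , drop = FALSE]))
      nt <- nll_terms(y[idx, , drop = FALSE], de$out, params$log_sigma)
      kl <- 0.5 * sum(en$mu^2 + exp(en$logvar) - en$logvar - 1) /
        (length(idx) * j)
      nt$loss + kl_weight * kl
    }
    loss_grad <- function(params, idx) {
      nb <- length(idx)
      en <- encode(params, idx)
      eps <- matrix(stats::rnorm(nb * latent), nb, latent)
      sd_z <- exp(0.5 * en$logvar)
      zz <- en$mu + sd_z * eps
      de <- mlp_forward(params$dec, cbind(zz, cond[idx, , drop = FALSE]))
      nt <- nll_terms(y[idx, , drop = FALSE], de$out, params$log_sigma)
      kl <- 0.5 * sum(en$mu^2 + exp(en$logvar) - en$logvar - 1) / (nb * j)
      db <- mlp_backward(params$dec, de, nt$dyhat)
      dz <- db$dx[, seq_len(latent), drop = FALSE]
      dmu <- dz + kl_weight * en$mu / (nb * j)
      dlogvar <- dz * eps * 0.5 * sd_z +
        kl_weight * 0.5 * (exp(en$logvar) - 1) / (nb * j)
      eb <- mlp_backward(params$enc, en$fw, cbind(dmu, dlogvar))
      list(loss = nt$loss + kl_weight * kl,
           grads = list(enc = eb$grads, dec = db$grads,
                        log_sigma = nt$dlog_sigma))
    }
    list(params = params, loss_grad = loss_grad, loss = eval_loss,
         encode = encode)
  }

  probe <- make_model()
  gm_val <- colMeans(y[split$train, , drop = FALSE])
  eval_r2 <- function(params) {
    idx <- split$validation
    en <- probe$encode(params, idx)
    yh <- mlp_forward(params$dec, cbind(en$mu, cond[idx, , drop = FALSE]))$out
    r_squared(y[idx, , drop = FALSE], yh, gm_val)$pooled
  }
  grid <- nn_train_grid(make_model, split, domain, lr_grid, seed,
                        eval_r2 = eval_r2, ...)
  fit <- grid$fit
  best <- grid$best
  mdl <- make_model()
  all_idx <- seq_len(nrow(y))
  en <- mdl$encode(fit$params, all_idx)
  recon <- mlp_forward(fit$params$dec, cbind(en$mu, cond))$out
  gm <- colMeans(y[split$train, , drop = FALSE])
  r2 <- vapply(c(train = "train", validation = "validation", test = "test"),
               function(role) {
                 idx <- split[[role]]
                 r_squared(y[idx, , drop = FALSE], recon[idx, , drop = FALSE], gm)$pooled
               }, numeric(1))
  structure(
    list(params = fit$params, latent = latent, kl_weight = kl_weight,
         spatial = spatial, cells = cells, cond = cond, y = y,
         mu = en$mu, logvar = en$logvar, reconstructions = recon,
         sigma = exp(fit$params$log_sigma), r2 = r2,
         lr_selected = lr_grid[best], history = fit$history,
         split = split, seed = seed),
    class = "cvae_ncem_fit"
  )
}

#' @export
print.cvae_ncem_fit <- function(x, ...) {
  cat(sprintf("cvae_ncem_fit (latent %d%s): reconstruction test R2 %.4f\n",
              x$latent, if (x$spatial) ", spatial" else ", nonspatial",
              x$r2[["test"]]))
  invisible(x)
}

#' Style transfer between two cells
#'
#' Encodes the latent state of a source cell (posterior mean by default)
#' and decodes it under the conditions — cell type, niche embedding and
#' domain — of a target cell, probing how the model uses its conditions.
#' With `source == target` this is the ordinary reconstruction.
#'
#' @param model a [fit_cvae()] result.
#' @param source,target indices into the modelled cell subset
#'   (`model$cells` positions).
#' @param sample draw `z` from the posterior instead of using its mean.
#' @param seed seed for posterior sampling.
#' @return Numeric length-J predicted expression vector for the target
#'   conditions.
#' @export
style_transfer <- function(model, source, target, sample = FALSE, seed = 1) {
  n <- nrow(model$mu)
  if (source < 1 || source > n || target < 1 || target > n)
    stop("unknown cell index")
  zz <- model$mu[source, , drop = FALSE]
  if (sample) {
    eps <- withr::with_seed(seed, stats::rnorm(ncol(zz)))
    zz <- zz + exp(0.5 * model$logvar[source, , drop = FALSE]) *
      matrix(eps, 1)
  }
  drop(mlp_forward(model$params$dec,
                   cbind(zz, model$cond[target, , drop = FALSE]))$out)
}
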