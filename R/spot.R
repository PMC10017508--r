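#' Deconvoluted spot transcriptomics container
#'
#' Holds the output of a spot deconvolution (e.g. cell2location): one
#' expression vector per (spot, cell type) combination that is present,
#' plus the inferred per-spot type abundance matrix. The spot composition
#' is the niche: it is shared by all per-type prediction problems of a
#' spot.
#'
#' @param expression numeric M x J matrix, one row per present
#'   (spot, type) combination.
#' @param spot factor/character of length M: spot identifier per row.
#' @param type factor/character of length M: deconvoluted cell type per row.
#' @param composition numeric S x L non-negative abundance matrix; row
#'   names are spot identifiers, column names the full type set.
#' @param coords optional S x 2 spot coordinates.
#' @param covariates optional S x C numeric covariate matrix (e.g. one-hot
#'   batch); defaults to a single constant column.
#' @return An object of class `deconvoluted_spots`.
#' @export
deconvoluted_spots <- function(expression, spot, type, composition,
                               coords = NULL, covariates = NULL) {
  expression <- as.matrix(expression)
  m <- nrow(expression)
  if (length(spot) != m || length(type) != m)
    stop("spot and type must have one entry per expression row")
  composition <- as.matrix(composition)
  if (any(composition < 0)) stop("negative abundances in composition")
  if (is.null(rownames(composition))) stop("composition needs spot row names")
  if (is.null(colnames(composition))) stop("composition needs type column names")
  spot <- factor(as.character(spot), levels = rownames(composition))
  if (anyNA(spot)) stop("expression rows reference spots absent from composition")
  type <- factor(as.character(type), levels = sort(colnames(composition)))
  if (anyNA(type)) stop("expression rows reference types absent from composition")
  composition <- composition[, levels(type), drop = FALSE]
  s <- nrow(composition)
  if (is.null(covariates)) {
    covariates <- matrix(1, s, 1, dimnames = list(rownames(composition), "intercept"))
  } else {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != s) stop("covariates must have one row per spot")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != s) stop("coords must have one row per spot")
  }
  if (is.null(colnames(expression)))
    colnames(expression) <- paste0("gene_", seq_len(ncol(expression)))
  structure(
    list(expression = expression, spot = spot, type = type,
         composition = composition, coords = coords, covariates = covariates,
         gene_names = colnames(expression)),
    class = "deconvoluted_spots"
  )
}

#' @export
print.deconvoluted_spots <- function(x, ...) {
  cat(sprintf("deconvoluted_spots: %d (spot, type) rows over %d spots, %d types, %d genes\n",
              nrow(x$expression), nrow(x$composition), nlevels(x$type),
              ncol(x$expression)))
  invisible(x)
}

#' Design matrix for the spot-level linear NCEM
#'
#' Each present (spot s, type k) expression vector is one observation.
#' Its design row concatenates the receiver-type one-hot, the outer
#' product of that one-hot with the spot's composition vector (the
#' vector-shaped niche summary, receiver-major), and the spot covariates.
#' For the baseline variant the composition block is omitted.
#'
#' @param data a [deconvoluted_spots()] object.
#' @param variant `"interaction"` (spot NCEM) or `"baseline"`.
#' @param normalize_composition divide each spot's abundances by their sum
#'   to use proportions instead of raw abundances.
#' @return An `ncem_design` over the M present rows.
#' @export
build_spot_design <- function(data, variant = c("interaction", "baseline"),
                              normalize_composition = FALSE) {
  variant <- match.arg(variant)
  comp <- data$composition
  if (normalize_composition) {
    tot <- rowSums(comp)
    comp <- comp / ifelse(tot > 0, tot, 1)
  }
  xl <- one_hot(data$type)
  types <- colnames(xl)
  l <- ncol(xl)
  comp_rows <- comp[as.integer(data$spot), , drop = FALSE]
  xc <- data$covariates[as.integer(data$spot), , drop = FALSE]
  prov_l <- data.frame(block = "receiver_type", receiver = types, sender = NA_character_)
  prov_c <- data.frame(block = "domain",
                       receiver = colnames(xc) %||% paste0("cov_", seq_len(ncol(xc))),
                       sender = NA_character_)
  if (variant == "baseline") {
    values <- cbind(xl, xc)
    prov <- rbind(prov_l, prov_c)
  } else {
    xts <- matrix(0, nrow(xl), l * l)
    for (r in seq_len(l)) {
      cols <- (r - 1L) * l + seq_len(l)
      xts[, cols] <- xl[, r] * comp_rows
    }
    colnames(xts) <- paste0(rep(types, each = l), ":", rep(types, l))
    values <- cbind(xl, xts, xc)
    prov <- rbind(prov_l,
                  data.frame(block = "interaction",
                             receiver = rep(types, each = l),
                             sender = rep(types, l)),
                  prov_c)
  }
  rownames(prov) <- NULL
  prov$column <- colnames(values)
  structure(
    list(values = values, provenance = prov, variant = variant,
         types = types, domains = colnames(xc)),
    class = "ncem_design"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the spot NCEM and compare it with the composition-blind baseline
#'
#' Fits the interaction spot NCEM on the full data (with Wald tests) and
#' cross-validates both the NCEM and the baseline by splitting at the
#' spot level (all per-type rows of a spot share a fold), reporting
#' pooled and per-receiver-type test R-squared.
#'
#' @param data a [deconvoluted_spots()] object.
#' @param seeds integer cross-validation seeds.
#' @param normalize_composition see [build_spot_design()].
#' @return List of class `spot_ncem_fit`: the full-data `fit`, the long
#'   `cv` table (seed, model, pooled r2), `per_type` test R-squared, and
#'   `delta_r2` per seed.
#' @export
fit_spot_ncem <- function(data, seeds = 1:3, normalize_composition = FALSE) {
  if (nlevels(droplevels(data$type)) < 2L) stop("need at least 2 cell types")
  des_full <- build_spot_design(data, "interaction", normalize_composition)
  fit <- wald_test(fit_ols(des_full, data$expression))
  des_base <- build_spot_design(data, "baseline", normalize_composition)
  s <- nrow(data$composition)
  spots_per_type <- table(data$type[!duplicated(paste(data$spot, data$type))])
  rare <- names(spots_per_type)[spots_per_type < 3]
  if (length(rare))
    warning(sprintf("type(s) present in fewer than 3 spots excluded from per-type reporting: %s",
                    paste(rare, collapse = ", ")))
  cv <- list(); per_type <- list()
  for (seed in seeds) {
    split <- split_nodes(s, seed)
    tr_rows <- which(as.integer(data$spot) %in% split$train)
    te_rows <- which(as.integer(data$spot) %in% split$test)
    gm <- colMeans(data$expression[tr_rows, , drop = FALSE])
    for (model in c("ncem", "baseline")) {
      des <- if (model == "ncem") des_full else des_base
      sub <- des; sub$values <- des$values[tr_rows, , drop = FALSE]
      f <- fit_ols(sub, data$expression[tr_rows, , drop = FALSE])
      tdes <- des; tdes$values <- des$values[te_rows, , drop = FALSE]
      yhat <- predict(f, tdes)
      r2 <- r_squared(data$expression[te_rows, , drop = FALSE], yhat, gm)
      cv[[length(cv) + 1L]] <- data.frame(seed = seed, model = model, r2 = r2$pooled)
      for (ty in setdiff(levels(data$type), rare)) {
        sel <- data$type[te_rows] == ty
        if (!any(sel)) next
        num <- sum((data$expression[te_rows, , drop = FALSE][sel, , drop = FALSE] -
                      yhat[sel, , drop = FALSE])^2)
        den <- sum(sweep(data$expression[te_rows, , drop = FALSE][sel, , drop = FALSE], 2, gm)^2)
        per_type[[length(per_type) + 1L]] <-
          data.frame(seed = seed, type = ty, model = model,
                     r2 = if (den > 0) 1 - num / den else NA_real_)
      }
    }
  }
  cv <- do.call(rbind, cv)
  per_type <- do.call(rbind, per_type)
  wide <- stats::reshape(cv, idvar = "seed", timevar = "model", direction = "wide")
  delta <- data.frame(seed = wide$seed, delta_r2 = wide$r2.ncem - wide$r2.baseline)
  structure(
    list(fit = fit, cv = cv, per_type = per_type, delta_r2 = delta),
    class = "spot_ncem_fit"
  )
}

#' @export
print.spot_ncem_fit <- function(x, ...) {
  cat("spot NCEM cross-validation (pooled test R2):\n")
  print(x$cv, row.names = FALSE)
  cat(sprintf("mean delta R2 (NCEM - baseline): %.4f\n", mean(x$delta_r2$delta_r2)))
  invisible(x)
}

#' Coefficient-vector stability between two fits
#'
#' For each ordered (sender, receiver) type pair, the coefficient of
#' determination between the interaction coefficient vectors over genes
#' of a reference fit and a comparison fit (e.g. a fit to subsampled
#' spots): `1 - sum((b_ref - b_cmp)^2) / sum((b_ref - mean(b_ref))^2)`.
#'
#' @param fit_full reference `ncem_fit` (interaction variant).
#' @param fit_subsampled comparison `ncem_fit` over the same genes/types.
#' @return Data frame with sender, receiver and `r2` per pair.
#' @export
coefficient_stability <- function(fit_full, fit_subsampled) {
  if (!identical(colnames(fit_full$coefficients), colnames(fit_subsampled$coefficients)))
    stop("fits have mismatched gene sets")
  ia_f <- fit_full$provenance$block == "interaction"
  ia_s <- fit_subsampled$provenance$block == "interaction"
  pf <- fit_full$provenance[ia_f, ]
  ps <- fit_subsampled$provenance[ia_s, ]
  if (!identical(paste(pf$receiver, pf$sender), paste(ps$receiver, ps$sender)))
    stop("fits have mismatched type pair sets")
  bf <- fit_full$coefficients[ia_f, , drop = FALSE]
  bs <- fit_subsampled$coefficients[ia_s, , drop = FALSE]
  r2 <- vapply(seq_len(nrow(bf)), function(i) {
    ref <- bf[i, ]; cmp <- bs[i, ]
    den <- sum((ref - mean(ref))^2)
    if (den == 0) return(NA_real_)
    1 - sum((ref - cmp)^2) / den
  }, numeric(1))
  data.frame(receiver = pf$receiver, sender = pf$sender, r2 = r2)
}
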