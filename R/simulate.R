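#' Configuration for the synthetic tissue generators
#'
#' Defaults reproduce the validation design used throughout the package:
#' gene means drawn uniformly on (0, 10), niche effects on 50% of genes
#' with effect sizes uniform on (4, 6), and unit Gaussian noise. Cells are
#' placed uniformly in a square per domain whose side is chosen so the
#' radius graph at `interaction_radius` has approximately `mean_degree`
#' neighbours per cell.
#'
#' @param n_cells total number of cells across domains.
#' @param n_genes number of genes.
#' @param n_types number of cell types (1 for the null design, 2 for the
#'   dependency design).
#' @param mean_expression_range range of the uniform gene-mean draw.
#' @param dependent_gene_fraction fraction of genes carrying a niche effect.
#' @param effect_size_range range of the uniform effect-size draw.
#' @param noise_sd Gaussian noise standard deviation.
#' @param interaction_radius radius (micrometres) at which the planted
#'   dependency acts.
#' @param mean_degree target mean node degree at `interaction_radius`.
#' @param n_domains number of independent images.
#' @param directions `"both"` for mutual dependencies between the two
#'   types, or `"a_to_b"` to plant effects only of sender A on receiver B.
#' @param n_latent_factors number of cell-intrinsic latent factors (0 to
#'   disable). Each cell draws standard-normal factor scores; genes load
#'   on the factors with `N(0, latent_sd^2)` loadings, creating
#'   niche-independent covariation between genes within a cell (the
#'   structure a conditional VAE models).
#' @param latent_sd loading scale of the intrinsic factors.
#' @param seed integer seed; every generator is deterministic given it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 1000, n_genes = 100, n_types = 2,
                              mean_expression_range = c(0, 10),
                              dependent_gene_fraction = 0.5,
                              effect_size_range = c(4, 6),
                              noise_sd = 1, interaction_radius = 50,
                              mean_degree = 6, n_domains = 1,
                              directions = c("both", "a_to_b"),
                              n_latent_factors = 0, latent_sd = 1,
                              seed = 1) {
  stopifnot(n_cells >= 1, n_genes >= 1, n_types >= 1,
            dependent_gene_fraction >= 0, dependent_gene_fraction <= 1,
            noise_sd >= 0, interaction_radius > 0, mean_degree > 0,
            diff(mean_expression_range) >= 0, diff(effect_size_range) >= 0,
            n_latent_factors >= 0, latent_sd >= 0)
  structure(
    list(n_cells = n_cells, n_genes = n_genes, n_types = n_types,
         mean_expression_range = mean_expression_range,
         dependent_gene_fraction = dependent_gene_fraction,
         effect_size_range = effect_size_range, noise_sd = noise_sd,
         interaction_radius = interaction_radius, mean_degree = mean_degree,
         n_domains = n_domains, directions = match.arg(directions),
         n_latent_factors = n_latent_factors, latent_sd = latent_sd,
         seed = seed),
    class = "simulation_config"
  )
}

# intrinsic-factor component: cells x genes contribution plus its pieces
sim_latent_factors <- function(n, j, config) {
  k <- config$n_latent_factors
  if (k == 0) return(list(contribution = 0, scores = NULL, loadings = NULL))
  scores <- matrix(stats::rnorm(n * k), n, k)
  loadings <- matrix(stats::rnorm(k * j, sd = config$latent_sd), k, j)
  list(contribution = scores %*% loadings, scores = scores,
       loadings = loadings)
}

# uniform coordinates per domain, square sized for the target mean degree
sim_coords <- function(n, n_domains, radius, mean_degree) {
  per_dom <- diff(round(seq(0, n, length.out = n_domains + 1)))
  coords <- matrix(NA_real_, n, 2)
  domain <- character(n)
  at <- 0L
  for (d in seq_len(n_domains)) {
    nd <- per_dom[d]
    side <- sqrt(nd * pi * radius^2 / mean_degree)
    coords[at + seq_len(nd), ] <- cbind(stats::runif(nd, 0, side),
                                        stats::runif(nd, 0, side))
    domain[at + seq_len(nd)] <- sprintf("image_%d", d)
    at <- at + nd
  }
  list(coords = coords, domain = domain)
}

#' Simulate a tissue without spatial dependencies
#'
#' All cells are drawn from one cell type and are independent and
#' identically distributed: gene means uniform on the configured range
#' plus Gaussian noise. Used for type-I error calibration.
#'
#' @param config a [simulation_config()] (its `n_types` is forced to 1).
#' @return List of class `ncem_simulation` with `dataset`, `graph` (at
#'   `interaction_radius`), `ground_truth` (zero effects) and `config`.
#' @export
simulate_null <- function(config = simulation_config(n_types = 1)) {
  withr::with_seed(config$seed, {
    geo <- sim_coords(config$n_cells, config$n_domains,
                      config$interaction_radius, config$mean_degree)
    mu <- stats::runif(config$n_genes, config$mean_expression_range[1],
                       config$mean_expression_range[2])
    lf <- sim_latent_factors(config$n_cells, config$n_genes, config)
    y <- matrix(stats::rnorm(config$n_cells * config$n_genes, sd = config$noise_sd),
                config$n_cells)
    y <- sweep(y, 2, mu, "+") + lf$contribution
    colnames(y) <- sprintf("gene_%03d", seq_len(config$n_genes))
    ds <- spatial_dataset(y, geo$coords,
                          cell_type = rep("type_A", config$n_cells),
                          domain = geo$domain)
    structure(
      list(dataset = ds,
           graph = build_graph(ds, config$interaction_radius),
           ground_truth = list(gene_means = stats::setNames(mu, colnames(y)),
                               effects = data.frame(gene = character(0),
                                                    receiver = character(0),
                                                    sender = character(0),
                                                    effect = numeric(0)),
                               dependent_genes = character(0),
                               latent_scores = lf$scores,
                               latent_loadings = lf$loadings),
           config = config),
      class = "ncem_simulation"
    )
  })
}

#' Simulate a tissue with planted niche dependencies
#'
#' Cells belong to one of two types. For a configured fraction of genes,
#' an additive effect drawn uniformly on the configured range is added to
#' a cell's mean whenever the respective other cell type is present in
#' its neighbourhood (radius graph at `interaction_radius`). With
#' `directions = "a_to_b"` only receiver B cells respond to sender A.
#'
#' @param config a [simulation_config()] with `n_types = 2`.
#' @return List of class `ncem_simulation`; `ground_truth$effects` holds
#'   one row per planted (gene, receiver, sender) effect.
#' @export
simulate_dependency <- function(config = simulation_config()) {
  if (config$n_types != 2L) stop("the dependency design uses exactly 2 cell types")
  withr::with_seed(config$seed, {
    n <- config$n_cells; j <- config$n_genes
    geo <- sim_coords(n, config$n_domains, config$interaction_radius,
                      config$mean_degree)
    type <- sample(c("type_A", "type_B"), n, replace = TRUE)
    mu <- stats::runif(j, config$mean_expression_range[1],
                       config$mean_expression_range[2])
    genes <- sprintf("gene_%03d", seq_len(j))
    n_dep <- round(config$dependent_gene_fraction * j)
    dep <- sort(sample.int(j, n_dep))
    pairs <- if (config$directions == "both") {
      data.frame(receiver = c("type_A", "type_B"), sender = c("type_B", "type_A"))
    } else {
      data.frame(receiver = "type_B", sender = "type_A")
    }
    eff <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(p) {
      data.frame(gene = genes[dep], receiver = pairs$receiver[p],
                 sender = pairs$sender[p],
                 effect = stats::runif(n_dep, config$effect_size_range[1],
                                       config$effect_size_range[2]))
    }))
    lf <- sim_latent_factors(n, j, config)
    y <- matrix(stats::rnorm(n * j, sd = config$noise_sd), n)
    y <- sweep(y, 2, mu, "+") + lf$contribution
    colnames(y) <- genes
    ds <- spatial_dataset(y, geo$coords, cell_type = type, domain = geo$domain)
    graph <- build_graph(ds, config$interaction_radius)
    presence <- sender_presence(graph, one_hot(ds$cell_type))
    for (p in seq_len(nrow(pairs))) {
      rows <- which(type == pairs$receiver[p] & presence[, pairs$sender[p]] > 0)
      e <- eff$effect[eff$receiver == pairs$receiver[p] & eff$sender == pairs$sender[p]]
      ds$expression[rows, dep] <- ds$expression[rows, dep] +
        matrix(e, length(rows), n_dep, byrow = TRUE)
    }
    structure(
      list(dataset = ds, graph = graph,
           ground_truth = list(gene_means = stats::setNames(mu, genes),
                               effects = eff, dependent_genes = genes[dep],
                               latent_scores = lf$scores,
                               latent_loadings = lf$loadings),
           config = config),
      class = "ncem_simulation"
    )
  })
}

#' Simulate cell-segmentation errors by mass transfer between neighbours
#'
#' Selects a fraction of cells at random, picks one spatial neighbour of
#' each uniformly at random, and moves a fraction of the selected cell's
#' whole expression vector to that neighbour. Transfers are computed from
#' the original expression matrix and applied simultaneously, so total
#' counts per image are conserved exactly. Selected cells with no
#' neighbour are skipped and reported.
#'
#' @param dataset a [spatial_dataset()].
#' @param graph the matching [build_graph()] result.
#' @param cell_fraction fraction of cells to corrupt (e.g. 0.1 or 0.5).
#' @param transfer_fraction fraction of the expression vector moved.
#' @param seed integer seed.
#' @return The corrupted dataset; attribute `skipped` holds the indices of
#'   isolated selected cells.
#' @export
simulate_segmentation_error <- function(dataset, graph, cell_fraction,
                                        transfer_fraction = 0.5, seed = 1) {
  stopifnot(cell_fraction >= 0, cell_fraction <= 1,
            transfer_fraction > 0, transfer_fraction <= 1)
  n <- n_cells(dataset)
  withr::with_seed(seed, {
    chosen <- sort(sample.int(n, round(cell_fraction * n)))
    adj <- graph$adjacency
    skipped <- integer(0)
    y0 <- dataset$expression
    delta <- matrix(0, nrow(y0), ncol(y0))
    for (i in chosen) {
      nb <- which(adj[i, ] > 0)
      if (!length(nb)) { skipped <- c(skipped, i); next }
      target <- nb[sample.int(length(nb), 1L)]
      moved <- transfer_fraction * y0[i, ]
      delta[i, ] <- delta[i, ] - moved
      delta[target, ] <- delta[target, ] + moved
    }
    dataset$expression <- y0 + delta
    attr(dataset, "skipped") <- skipped
    dataset
  })
}

#' Simulate a tissue with planted ligand-receptor signalling
#'
#' Generates a two-type tissue in which one ligand-receptor pair is truly
#' active: the true ligand is expressed predominantly by sender (type A)
#' cells, every receptor is expressed broadly, and a set of target genes
#' is driven linearly by the true pair's receptor activity (the
#' [lr_kernel()] value, standardized). The remaining pairs are decoys
#' whose ligands are expressed uniformly across types. Gene layout:
#' receptors `rec_k`, ligands `lig_k`, targets `target_t`, then unrelated
#' filler genes up to `config$n_genes`.
#'
#' @param config a [simulation_config()]; `n_genes` must be at least
#'   `2 * n_pairs + n_targets`.
#' @param n_pairs number of ligand-receptor pairs (first one is active).
#' @param n_targets number of genes driven by the active pair.
#' @param target_effect effect size per unit of standardized receptor
#'   activity added to each target gene.
#' @return List of class `ncem_lr_simulation` with `dataset`, `graph`,
#'   `map` (an [lr_map()] over all pairs), and `ground_truth` (`true_pair`,
#'   `target_genes`, per-cell `activity`).
#' @export
simulate_lr <- function(config = simulation_config(n_genes = 40),
                        n_pairs = 5, n_targets = 10, target_effect = 2) {
  j <- config$n_genes
  if (j < 2 * n_pairs + n_targets)
    stop("n_genes must cover receptors, ligands and targets")
  withr::with_seed(config$seed, {
    n <- config$n_cells
    geo <- sim_coords(n, config$n_domains, config$interaction_radius,
                      config$mean_degree)
    type <- sample(c("type_A", "type_B"), n, replace = TRUE)
    genes <- c(sprintf("rec_%02d", seq_len(n_pairs)),
               sprintf("lig_%02d", seq_len(n_pairs)),
               sprintf("target_%02d", seq_len(n_targets)),
               if (j > 2 * n_pairs + n_targets)
                 sprintf("other_%03d", seq_len(j - 2 * n_pairs - n_targets)))
    mu <- stats::runif(j, config$mean_expression_range[1],
                       config$mean_expression_range[2])
    names(mu) <- genes
    mu[sprintf("rec_%02d", seq_len(n_pairs))] <- stats::runif(n_pairs, 2, 8)
    y <- sweep(matrix(stats::rnorm(n * j, sd = config$noise_sd), n), 2, mu, "+")
    colnames(y) <- genes
    # the true ligand is a marker of the sender type; decoys are uniform
    y[, "lig_01"] <- ifelse(type == "type_A", 6, 0.5) +
      stats::rnorm(n, sd = config$noise_sd)
    y <- pmax(y, 0)
    ds <- spatial_dataset(y, geo$coords, cell_type = type, domain = geo$domain)
    graph <- build_graph(ds, config$interaction_radius)
    map <- lr_map(data.frame(receptor = sprintf("rec_%02d", seq_len(n_pairs)),
                             ligand = sprintf("lig_%02d", seq_len(n_pairs))),
                  ds)
    z1 <- lr_kernel(ds$expression, graph, map[1, , drop = FALSE])[, 1]
    z_std <- if (stats::sd(z1) > 0) (z1 - mean(z1)) / stats::sd(z1) else z1
    targets <- sprintf("target_%02d", seq_len(n_targets))
    ds$expression[, targets] <- ds$expression[, targets] +
      target_effect * z_std
    structure(
      list(dataset = ds, graph = graph, map = map,
           ground_truth = list(true_pair = "rec_01_lig_01",
                               target_genes = targets, activity = z1),
           config = config),
      class = "ncem_lr_simulation"
    )
  })
}

#' Simulate deconvoluted spot transcriptomics with known niche effects
#'
#' Simulates a single-cell tissue (dependency design unless
#' `config$n_types == 1`), bins cells into square spots, and emits the
#' deconvolution-shaped view: per-spot type abundances (true counts) and
#' per-(spot, type) expression vectors (within-spot type means). Empty
#' spots are dropped.
#'
#' @param config a [simulation_config()].
#' @param spot_size side length of the square spot bins, micrometres;
#'   defaults to the interaction radius so within-spot cells are
#'   (approximately) mutual neighbours.
#' @return List of class `ncem_spot_simulation` with `spots` (a
#'   [deconvoluted_spots()]), the underlying cell-level `simulation`, and
#'   `ground_truth`.
#' @export
simulate_spots <- function(config = simulation_config(), spot_size = NULL) {
  sim <- if (config$n_types == 1L) simulate_null(config) else simulate_dependency(config)
  if (is.null(spot_size)) spot_size <- config$interaction_radius
  ds <- sim$dataset
  gx <- floor(ds$coords[, 1] / spot_size)
  gy <- floor(ds$coords[, 2] / spot_size)
  spot_id <- sprintf("%s_s%d_%d", as.character(ds$domain), gx, gy)
  spots <- sort(unique(spot_id))
  l <- levels(ds$cell_type)
  comp <- matrix(0, length(spots), length(l),
                 dimnames = list(spots, l))
  tab <- table(factor(spot_id, levels = spots), ds$cell_type)
  comp[] <- as.numeric(tab)
  key <- paste(spot_id, as.character(ds$cell_type))
  keys <- unique(key)
  expr <- rowsum(ds$expression, key) / as.vector(table(key)[sort(unique(key))])
  meta <- do.call(rbind, strsplit(rownames(expr), " "))
  sp_dom <- vapply(spots, function(s) {
    as.character(ds$domain[match(s, spot_id)])
  }, character(1))
  covar <- one_hot(factor(sp_dom))
  rownames(covar) <- spots
  cent <- cbind(tapply((gx + 0.5) * spot_size, factor(spot_id, levels = spots), mean),
                tapply((gy + 0.5) * spot_size, factor(spot_id, levels = spots), mean))
  spots_obj <- deconvoluted_spots(expr, spot = meta[, 1], type = meta[, 2],
                                  composition = comp, coords = cent,
                                  covariates = covar)
  structure(
    list(spots = spots_obj, simulation = sim,
         ground_truth = sim$ground_truth, config = config),
    class = "ncem_spot_simulation"
  )
}
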