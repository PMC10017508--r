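#' Construct a spatial expression dataset
#'
#' Bundles a cells x genes expression matrix with 2-D spatial coordinates
#' (micrometres), a cell-type label and a domain (image/batch) label per
#' cell. This is the container every model in the package consumes.
#'
#' @param expression numeric matrix, cells x genes, non-negative. Column
#'   names are used as gene names; unnamed columns get `gene_1..J`.
#' @param coords numeric matrix or data frame with two columns (x, y) in
#'   micrometres.
#' @param cell_type character or factor of length `nrow(expression)`.
#' @param domain character or factor of length `nrow(expression)`; the
#'   image or patient identifier. Edges of the spatial graph never cross
#'   domains.
#' @param condition optional character or factor of per-cell condition
#'   labels (e.g. genotype).
#' @param gene_names optional character vector overriding column names.
#'
#' @return An object of class `spatial_dataset`: a list with elements
#'   `expression`, `coords`, `cell_type`, `domain`, `condition`,
#'   `gene_names` and a `log1p` provenance flag. Factor levels are sorted
#'   lexicographically so one-hot layouts are reproducible.
#' @export
spatial_dataset <- function(expression, coords, cell_type, domain,
                            condition = NULL, gene_names = NULL) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  n <- nrow(expression)
  j <- ncol(expression)
  if (n < 1L || j < 1L) stop("expression must have at least one cell and one gene")
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L) stop("coords must have exactly two columns (x, y)")
  if (nrow(coords) != n) stop("coords and expression disagree on the number of cells")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (length(cell_type) != n) stop("cell_type must have one label per cell")
  if (length(domain) != n) stop("domain must have one label per cell")
  if (anyNA(cell_type) || anyNA(domain)) stop("cell_type and domain may not contain NA")
  if (is.null(gene_names)) gene_names <- colnames(expression)
  if (is.null(gene_names)) gene_names <- paste0("gene_", seq_len(j))
  gene_names <- as.character(gene_names)
  if (length(gene_names) != j) stop("gene_names length must equal the number of genes")
  if (anyDuplicated(gene_names)) stop("gene_names must be unique")
  colnames(expression) <- gene_names
  colnames(coords) <- c("x", "y")
  ct <- factor(as.character(cell_type), levels = sort(unique(as.character(cell_type))))
  dm <- factor(as.character(domain), levels = sort(unique(as.character(domain))))
  cond <- NULL
  if (!is.null(condition)) {
    if (length(condition) != n) stop("condition must have one label per cell")
    cond <- factor(as.character(condition), levels = sort(unique(as.character(condition))))
  }
  structure(
    list(expression = expression, coords = coords, cell_type = ct,
         domain = dm, condition = cond, gene_names = gene_names,
         log1p = FALSE),
    class = "spatial_dataset"
  )
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf(
    "spatial_dataset: %d cells x %d genes, %d cell types, %d domains%s\n",
    nrow(x$expression), ncol(x$expression), nlevels(x$cell_type),
    nlevels(x$domain), if (isTRUE(x$log1p)) " (log1p)" else ""))
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$expression)

n_cells <- function(dataset) nrow(dataset$expression)
n_genes <- function(dataset) ncol(dataset$expression)

# one-hot matrix with one column per factor level, lexicographic level order
one_hot <- function(f) {
  f <- as.factor(f)
  m <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

#' Per-cell size factors
#'
#' The size factor of cell i is its total expression divided by the mean
#' total expression across cells, so the factors average to exactly one.
#' Model predictions are multiplied cell-wise by these factors when
#' node-size output scaling is enabled.
#'
#' @param dataset a [spatial_dataset()].
#' @return Numeric vector of length `n` with mean 1.
#' @export
size_factors <- function(dataset) {
  totals <- rowSums(dataset$expression)
  bad <- which(totals <= 0)
  if (length(bad)) {
    stop(sprintf("cell(s) with zero total counts: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  totals / mean(totals)
}

#' log(1 + y) transform of the expression matrix
#'
#' @param dataset a [spatial_dataset()].
#' @return The dataset with `log1p(expression)` and the `log1p` provenance
#'   flag set.
#' @export
log_transform <- function(dataset) {
  if (any(dataset$expression < 0)) stop("expression contains negative entries")
  dataset$expression <- log1p(dataset$expression)
  dataset$log1p <- TRUE
  dataset
}

#' Decompose total expression variance into cell-type components
#'
#' Splits the total sum of squares around the grand mean into an
#' intra-cell-type term (deviations of cells from their type-gene mean),
#' an inter-cell-type term (deviations of type-gene means from the gene
#' mean) and a gene term (deviations of gene means from the grand mean).
#' The three terms sum exactly to the total.
#'
#' @param dataset a [spatial_dataset()].
#' @return A list of class `variance_decomposition` with the three sums of
#'   squares, the total, and their fractions of the total.
#' @export
variance_decomposition <- function(dataset) {
  y <- dataset$expression
  ct <- dataset$cell_type
  grand <- mean(y)
  gene_means <- colMeans(y)
  type_gene <- rowsum(y, ct) / as.vector(table(ct))   # L x J type-gene means
  tg_per_cell <- type_gene[as.integer(ct), , drop = FALSE]
  intra <- sum((y - tg_per_cell)^2)
  inter <- sum((sweep(tg_per_cell, 2, gene_means))^2)
  gene <- nrow(y) * sum((gene_means - grand)^2)
  total <- sum((y - grand)^2)
  fr <- if (total > 0) c(intra, inter, gene) / total else c(NA_real_, NA_real_, NA_real_)
  structure(
    list(intra_type_ss = intra, inter_type_ss = inter, gene_ss = gene,
         total_ss = total,
         fractions = stats::setNames(fr, c("intra_type", "inter_type", "gene"))),
    class = "variance_decomposition"
  )
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("variance decomposition (sums of squares):\n")
  cat(sprintf("  intra-cell-type: %.4g (%.1f%%)\n", x$intra_type_ss, 100 * x$fractions[1]))
  cat(sprintf("  inter-cell-type: %.4g (%.1f%%)\n", x$inter_type_ss, 100 * x$fractions[2]))
  cat(sprintf("  gene:            %.4g (%.1f%%)\n", x$gene_ss, 100 * x$fractions[3]))
  cat(sprintf("  total:           %.4g\n", x$total_ss))
  invisible(x)
}
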