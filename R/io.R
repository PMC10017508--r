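#' Read a spatial dataset from files
#'
#' Expression is read either from MatrixMarket (`.mtx`, cells x genes,
#' with a one-column gene-name sidecar TSV) or from a dense CSV/TSV whose
#' header names the genes and whose optional `cell` column carries cell
#' identifiers. Metadata is a TSV with required columns `x`, `y`,
#' `cell_type`, `image` and optional `cell` and `condition` columns. When
#' both files carry cell identifiers the metadata is joined by identifier,
#' so its row order does not matter.
#'
#' @param expr_path path to the expression matrix.
#' @param meta_path path to the metadata TSV.
#' @param genes_path gene-name sidecar (required for MTX input).
#' @return A [spatial_dataset()].
#' @export
read_dataset <- function(expr_path, meta_path, genes_path = NULL) {
  for (p in c(expr_path, meta_path, genes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  cell_ids <- NULL
  if (grepl("\\.mtx$", expr_path, ignore.case = TRUE)) {
    expr <- as.matrix(Matrix::readMM(expr_path))
    if (is.null(genes_path)) stop("MTX input requires a gene-name sidecar TSV")
    gn <- utils::read.delim(genes_path, header = FALSE)[[1]]
    if (length(gn) != ncol(expr))
      stop("gene sidecar length does not match the matrix gene dimension")
    colnames(expr) <- as.character(gn)
  } else {
    sep <- if (grepl("\\.csv$", expr_path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(expr_path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if ("cell" %in% names(tab)) {
      cell_ids <- as.character(tab$cell)
      tab$cell <- NULL
    }
    expr <- as.matrix(tab)
    if (!is.numeric(expr)) stop("expression matrix contains non-numeric entries")
  }
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  required <- c("x", "y", "cell_type", "image")
  miss <- setdiff(required, names(meta))
  if (length(miss))
    stop("metadata is missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(meta) != nrow(expr))
    stop(sprintf("dimension mismatch: %d metadata rows vs %d expression rows",
                 nrow(meta), nrow(expr)))
  if (!is.null(cell_ids) && "cell" %in% names(meta)) {
    if (anyDuplicated(cell_ids) || anyDuplicated(meta$cell))
      stop("duplicate cell identifiers")
    ord <- match(cell_ids, as.character(meta$cell))
    if (anyNA(ord)) stop("metadata cell identifiers do not match expression")
    meta <- meta[ord, , drop = FALSE]
  }
  spatial_dataset(expr, cbind(meta$x, meta$y), meta$cell_type, meta$image,
                  condition = meta$condition)
}

#' Write a spatial dataset as TSV files
#'
#' Writes `expression.tsv` (cell identifier plus one column per gene) and
#' `metadata.tsv` (cell, x, y, cell_type, image, condition). Floating
#' values are serialized with 17 significant digits so a round trip is
#' exact.
#'
#' @param dataset a [spatial_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("cell_%d", seq_len(n_cells(dataset)) - 1L)
  expr <- data.frame(cell = ids,
                     signif17(dataset$expression), check.names = FALSE)
  p1 <- file.path(dir, "expression.tsv")
  utils::write.table(expr, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(cell = ids, x = signif17(dataset$coords[, 1]),
                     y = signif17(dataset$coords[, 2]),
                     cell_type = as.character(dataset$cell_type),
                     image = as.character(dataset$domain))
  if (!is.null(dataset$condition)) meta$condition <- as.character(dataset$condition)
  p2 <- file.path(dir, "metadata.tsv")
  utils::write.table(meta, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}

signif17 <- function(x) {
  if (is.matrix(x)) {
    out <- apply(x, 2, function(col) format(col, digits = 17, trim = TRUE,
                                            scientific = FALSE))
    as.data.frame(out, stringsAsFactors = FALSE)
  } else {
    format(x, digits = 17, trim = TRUE, scientific = FALSE)
  }
}

#' Write the edge list of a cell graph
#'
#' @param graph a [build_graph()] result.
#' @param path output TSV with columns source, target, distance (0-based
#'   cell indices).
#' @export
write_edge_list <- function(graph, path) {
  e <- graph$edges
  e$source <- e$source - 1L
  e$target <- e$target - 1L
  e$distance <- signif17(e$distance)
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a YAML analysis configuration
#'
#' Recognized keys: `resolution`, `resolutions`, `scale_node_size`,
#' `log1p`, `seed`, plus simulator fields matching
#' [simulation_config()] arguments. Unknown keys raise an error.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("resolution", "resolutions", "scale_node_size", "log1p", "seed",
               "n_cells", "n_genes", "n_types", "mean_expression_range",
               "dependent_gene_fraction", "effect_size_range", "noise_sd",
               "interaction_radius", "mean_degree", "n_domains", "directions",
               "cell_fraction", "transfer_fraction", "spot_size")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg
}

# run manifest: config snapshot, seeds, input checksums, outputs, timings
write_manifest <- function(dir, command, config, seeds, inputs, outputs,
                           started) {
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("ncemr")),
    config = if (is.list(config)) unclass(config) else config,
    seeds = seeds,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = outputs,
    elapsed_seconds = as.numeric(difftime(Sys.time(), started, units = "secs"))
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
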