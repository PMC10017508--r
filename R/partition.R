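#' Train/validation/test split of cells
#'
#' Randomly selects 10% of all cells, pooled across images and domains, as
#' the test set; from the remaining cells, 10% are selected as the
#' validation set. Sizes use round-half-up, so `|test| = round(0.10 * N)`
#' and `|validation| = round(0.10 * (N - |test|))`. Deterministic given
#' `seed`; the global RNG state is left untouched.
#'
#' @param dataset a [spatial_dataset()], or an integer number of cells.
#' @param seed integer seed recorded in the result.
#' @return An object of class `split_assignment`: a list with factor
#'   `role` ("train"/"validation"/"test") per cell, index vectors `train`,
#'   `validation`, `test`, and the `seed`.
#' @export
split_nodes <- function(dataset, seed) {
  n <- if (inherits(dataset, "spatial_dataset")) n_cells(dataset) else as.integer(dataset)
  if (n < 10L) stop("need at least 10 cells for a non-empty test set")
  round_half_up <- function(x) floor(x + 0.5)
  n_test <- round_half_up(0.10 * n)
  n_val <- round_half_up(0.10 * (n - n_test))
  idx <- withr::with_seed(seed, {
    test <- sample.int(n, n_test)
    rest <- setdiff(seq_len(n), test)
    val <- rest[sample.int(length(rest), n_val)]
    list(test = sort(test), validation = sort(val))
  })
  role <- rep("train", n)
  role[idx$test] <- "test"
  role[idx$validation] <- "validation"
  role <- factor(role, levels = c("train", "validation", "test"))
  structure(
    list(role = role, train = which(role == "train"),
         validation = idx$validation, test = idx$test, seed = seed),
    class = "split_assignment"
  )
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("split_assignment (seed %d): %d train / %d validation / %d test\n",
              x$seed, length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}
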