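#' Binary sender presence in each cell's neighbourhood
#'
#' Entry (i, l) is 1 when at least one neighbour of cell i has type l.
#' The index cell itself is never counted (the adjacency has a zero
#' diagonal), so a cell's own type does not imply sender presence.
#'
#' @param graph a [build_graph()] result.
#' @param types one-hot cells x types matrix.
#' @return Binary matrix of the same shape as `types`.
#' @export
sender_presence <- function(graph, types) {
  if (nrow(types) != nrow(graph$adjacency))
    stop("graph and type matrix are over different numbers of cells")
  m <- as.matrix(graph$adjacency %*% types)
  out <- (m > 0) + 0
  dimnames(out) <- dimnames(types)
  out
}

#' Build the design matrix of a linear NCEM
#'
#' Three variants are supported, all without a global intercept (the full
#' receiver-type one-hot block plays that role):
#' * `baseline`: `(X_type, X_domain)` — the nonspatial model, P = L + C.
#' * `global_sender`: `(X_type, X_sender, X_domain)` — additive sender
#'   presence, P = 2L + C.
#' * `interaction`: `(X_type, X_type_x_sender, X_domain)` — the linear
#'   NCEM with receiver x sender interaction terms, P = L + L^2 + C.
#'
#' The interaction block is the row-wise outer product of the receiver
#' one-hot with the sender-presence indicator, laid out receiver-major:
#' the pair (receiver r, sender s) occupies column (r-1)*L + s of the
#' block.
#'
#' @param dataset a [spatial_dataset()].
#' @param graph a [build_graph()] result (ignored for `baseline`).
#' @param variant one of `"baseline"`, `"global_sender"`, `"interaction"`.
#' @return An object of class `ncem_design`: list with numeric `values`
#'   (N x P), a `provenance` data frame (block, receiver, sender per
#'   column), the `variant`, and the type/domain level sets.
#' @export
build_design <- function(dataset, graph = NULL, variant = c("interaction", "baseline", "global_sender")) {
  variant <- match.arg(variant)
  xl <- one_hot(dataset$cell_type)
  xc <- one_hot(dataset$domain)
  types <- colnames(xl)
  l <- ncol(xl)
  prov_l <- data.frame(block = "receiver_type", receiver = types, sender = NA_character_)
  prov_c <- data.frame(block = "domain", receiver = NA_character_, sender = NA_character_)
  prov_c <- prov_c[rep(1L, ncol(xc)), ]
  prov_c$receiver <- colnames(xc)
  if (variant == "baseline") {
    values <- cbind(xl, xc)
    prov <- rbind(prov_l, prov_c)
  } else {
    if (is.null(graph)) stop("spatial variants require a cell graph")
    xs <- sender_presence(graph, xl)
    if (variant == "global_sender") {
      colnames(xs) <- paste0("sender_", types)
      values <- cbind(xl, xs, xc)
      prov <- rbind(prov_l,
                    data.frame(block = "sender_presence",
                               receiver = NA_character_, sender = types),
                    prov_c)
    } else {
      # receiver-major outer product: column (r-1)*L + s of the block
      xts <- matrix(0, nrow(xl), l * l)
      pairs <- expand.grid(sender = seq_len(l), receiver = seq_len(l))[, c(2, 1)]
      for (r in seq_len(l)) {
        cols <- (r - 1L) * l + seq_len(l)
        xts[, cols] <- xl[, r] * xs
      }
      colnames(xts) <- paste0(rep(types, each = l), ":", rep(types, l))
      values <- cbind(xl, xts, xc)
      prov <- rbind(prov_l,
                    data.frame(block = "interaction",
                               receiver = rep(types, each = l),
                               sender = rep(types, l)),
                    prov_c)
    }
  }
  rownames(prov) <- NULL
  prov$column <- colnames(values)
  structure(
    list(values = values, provenance = prov, variant = variant,
         types = types, domains = colnames(xc)),
    class = "ncem_design"
  )
}

#' @export
print.ncem_design <- function(x, ...) {
  cat(sprintf("ncem_design (%s): %d cells x %d columns (%d types, %d domains)\n",
              x$variant, nrow(x$values), ncol(x$values),
              length(x$types), length(x$domains)))
  invisible(x)
}
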