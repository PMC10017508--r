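#' Type coupling analysis of a fitted linear NCEM
#'
#' Summarizes each ordered (sender, receiver) type pair by the number of
#' genes with a significant interaction coefficient (BH q below `alpha`)
#' and the L1 norm of those significant coefficients. Pairs whose
#' significant-gene count falls below `min_genes` are flagged as hidden
#' for plotting but kept in the table; untestable (collinear or
#' never-observed) pairs carry no statistics.
#'
#' @param fit a [wald_test()]-annotated interaction fit.
#' @param alpha FDR threshold (default 0.05).
#' @param min_genes minimum significant genes for a plotted edge
#'   (default 200).
#' @return Data frame of class `coupling_table` with sender, receiver,
#'   n_significant, l1_norm, testable and plot flags; attribute `genes`
#'   holds the gene-level records per pair.
#' @export
type_coupling <- function(fit, alpha = 0.05, min_genes = 200) {
  if (fit$variant != "interaction")
    stop("type coupling requires an interaction-variant fit")
  if (is.null(fit$q_values)) fit <- wald_test(fit)
  ia <- which(fit$provenance$block == "interaction")
  prov <- fit$provenance[ia, ]
  b <- fit$coefficients[ia, , drop = FALSE]
  qv <- fit$q_values
  genes <- colnames(b)
  rows <- lapply(seq_len(nrow(prov)), function(k) {
    testable <- !all(is.na(qv[k, ]))
    sig <- !is.na(qv[k, ]) & qv[k, ] < alpha
    data.frame(sender = prov$sender[k], receiver = prov$receiver[k],
               testable = testable,
               n_significant = if (testable) sum(sig) else NA_integer_,
               l1_norm = if (testable) sum(abs(b[k, sig])) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$plot <- !is.na(out$n_significant) & out$n_significant >= min_genes
  gene_records <- do.call(rbind, lapply(seq_len(nrow(prov)), function(k) {
    data.frame(sender = prov$sender[k], receiver = prov$receiver[k],
               gene = genes, coefficient = b[k, ],
               p = fit$p_values[k, ], q = qv[k, ], row.names = NULL)
  }))
  attr(out, "genes") <- gene_records
  attr(out, "alpha") <- alpha
  class(out) <- c("coupling_table", "data.frame")
  out
}

# shared slice helper for sender/receiver effect analyses
effect_slice <- function(fit, fixed, role = c("sender", "receiver"),
                         top_k = NULL) {
  role <- match.arg(role)
  other <- setdiff(c("sender", "receiver"), role)
  if (is.null(fit$q_values)) fit <- wald_test(fit)
  ia <- which(fit$provenance$block == "interaction")
  prov <- fit$provenance[ia, ]
  if (!fixed %in% prov[[role]]) stop("unknown cell type: ", fixed)
  sel <- which(prov[[role]] == fixed)
  coef <- t(fit$coefficients[ia[sel], , drop = FALSE])
  qv <- t(fit$q_values[sel, , drop = FALSE])
  colnames(coef) <- colnames(qv) <- prov[[other]][sel]
  testable <- !apply(qv, 2, function(x) all(is.na(x)))
  coef[, !testable] <- NA_real_
  if (!is.null(top_k)) {
    score <- apply(abs(coef) * (qv < attr(qv, "alpha") %||% 0.05), 1,
                   max, na.rm = TRUE)
    keep <- order(score, decreasing = TRUE)[seq_len(min(top_k, nrow(coef)))]
    coef <- coef[keep, , drop = FALSE]
    qv <- qv[keep, , drop = FALSE]
  }
  list(coefficients = coef, q_values = qv, testable = testable)
}

#' Gene-wise effects of one sender type on all receivers
#'
#' @param fit an interaction-variant [fit_ols()] result.
#' @param sender sender cell type.
#' @param top_k optionally keep only the top genes by largest significant
#'   |coefficient|.
#' @return List with genes x receivers `coefficients` and `q_values`
#'   matrices (untestable pairs masked to NA) and a `testable` flag.
#' @export
sender_effect <- function(fit, sender, top_k = NULL) {
  effect_slice(fit, sender, "sender", top_k)
}

#' Gene-wise effects of all senders on one receiver type
#'
#' @param fit an interaction-variant [fit_ols()] result.
#' @param receiver receiver cell type.
#' @param top_k optionally keep only the top genes.
#' @return List with genes x senders `coefficients` and `q_values`.
#' @export
receiver_effect <- function(fit, receiver, top_k = NULL) {
  effect_slice(fit, receiver, "receiver", top_k)
}

#' Sender similarity for one receiver type
#'
#' Pearson correlations over genes between the interaction coefficient
#' vectors of all (observable) sender types for a fixed receiver,
#' hierarchically clustered with average linkage on 1 - correlation.
#' Senders with constant coefficient vectors have undefined correlation
#' and are masked.
#'
#' @param fit an interaction-variant [fit_ols()] result.
#' @param receiver receiver cell type.
#' @return List with the `correlation` matrix, the `hclust` tree, and the
#'   dendrogram leaf `order` (sender names).
#' @export
sender_similarity <- function(fit, receiver) {
  sl <- receiver_effect(fit, receiver)
  coef <- sl$coefficients[, sl$testable, drop = FALSE]
  if (ncol(coef) < 2L) stop("need at least 2 observable senders")
  sds <- apply(coef, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant coefficient vector(s) masked: ",
            paste(colnames(coef)[sds == 0], collapse = ", "))
  }
  cm <- suppressWarnings(stats::cor(coef))
  cm[sds == 0, ] <- NA_real_; cm[, sds == 0] <- NA_real_
  diag(cm) <- 1
  ok <- sds > 0
  hc <- stats::hclust(stats::as.dist(1 - cm[ok, ok, drop = FALSE]),
                      method = "average")
  list(correlation = cm, hclust = hc, order = colnames(coef)[ok][hc$order])
}

#' Niche-cluster enrichment via Fisher's exact test
#'
#' Tests association between membership in an expression subcluster and
#' the presence of a sender type in the neighbourhood with a two-sided
#' Fisher exact test on the 2x2 contingency table, BH-corrected across
#' all supplied (cluster, sender) combinations. Tables with an empty
#' margin are degenerate and reported with p = 1.
#'
#' @param cluster_mask logical vector or cells x clusters logical matrix.
#' @param sender_presence_column logical vector or cells x senders matrix
#'   (e.g. columns of [sender_presence()]).
#' @return Data frame with cluster, sender, odds_ratio, p, q and a
#'   `degenerate` flag.
#' @export
cluster_enrichment <- function(cluster_mask, sender_presence_column) {
  cm <- as.matrix(cluster_mask) * 1
  sp <- as.matrix(sender_presence_column) * 1
  if (nrow(cm) != nrow(sp)) stop("masks must cover the same cells")
  if (is.null(colnames(cm))) colnames(cm) <- paste0("cluster_", seq_len(ncol(cm)))
  if (is.null(colnames(sp))) colnames(sp) <- paste0("sender_", seq_len(ncol(sp)))
  grid <- expand.grid(cluster = colnames(cm), sender = colnames(sp),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    a <- cm[, grid$cluster[i]] > 0
    b <- sp[, grid$sender[i]] > 0
    tab <- table(factor(a, c(FALSE, TRUE)), factor(b, c(FALSE, TRUE)))
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    if (degenerate) {
      data.frame(odds_ratio = NA_real_, p = 1, degenerate = TRUE)
    } else {
      ft <- stats::fisher.test(tab)
      data.frame(odds_ratio = unname(ft$estimate), p = ft$p.value,
                 degenerate = FALSE)
    }
  })
  out <- cbind(grid, do.call(rbind, res))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
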