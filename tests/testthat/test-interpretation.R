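# small deterministic fit used across the interpretation tests
interp_fit <- function() {
  memo("interp_fit", {
    sim <- standard_benchmark()
    wald_test(fit_ols(build_design(sim$dataset, sim$graph, "interaction"),
                      sim$dataset$expression))
  })
}

test_that("type coupling counts significant genes and sums their |coefficients|", {
  fit <- interp_fit()
  # synthetic check of the definition on a doctored copy
  doctored <- fit
  ia <- which(doctored$provenance$block == "interaction")
  doctored$coefficients[ia[1], 1:3] <- c(1, -2, 0)
  doctored$q_values[1, ] <- 1
  doctored$q_values[1, 1:3] <- c(0.01, 0.01, 0.01)
  ct <- type_coupling(doctored, alpha = 0.05, min_genes = 2)
  expect_equal(ct$l1_norm[1], 1 + 2 + abs(doctored$coefficients[ia[1], 3]))
  expect_equal(ct$n_significant[1], 3)
  # no significant genes: zero norm and count
  none <- fit
  none$q_values[] <- 1
  ct0 <- type_coupling(none, min_genes = 1)
  expect_true(all(ct0$l1_norm[ct0$testable] == 0))
  expect_true(all(ct0$n_significant[ct0$testable] == 0))
  # the min_genes filter hides pairs from the plot set but keeps them
  ct_hidden <- type_coupling(fit, min_genes = 1e6)
  expect_true(all(!ct_hidden$plot))
  expect_equal(nrow(ct_hidden), 4)
  base <- fit_ols(build_design(standard_benchmark()$dataset,
                               variant = "baseline"),
                  standard_benchmark()$dataset$expression)
  expect_error(type_coupling(base), "interaction")
})

test_that("coupling norms ignore gene order and coefficient signs", {
  fit <- interp_fit()
  flipped <- fit
  flipped$coefficients <- -flipped$coefficients
  expect_equal(type_coupling(fit, min_genes = 1)$l1_norm,
               type_coupling(flipped, min_genes = 1)$l1_norm)
  perm <- withr::with_seed(1, sample.int(ncol(fit$coefficients)))
  shuffled <- fit
  shuffled$coefficients <- fit$coefficients[, perm]
  shuffled$p_values <- fit$p_values[, perm]
  shuffled$q_values <- fit$q_values[, perm]
  expect_equal(type_coupling(fit, min_genes = 1)$l1_norm,
               type_coupling(shuffled, min_genes = 1)$l1_norm)
})

test_that("sender and receiver effect slices partition the coefficient block", {
  fit <- interp_fit()
  ia <- which(fit$provenance$block == "interaction")
  full <- fit$coefficients[ia, , drop = FALSE]
  reassembled <- do.call(rbind, lapply(fit$types, function(s) {
    sl <- sender_effect(fit, s)
    t(sl$coefficients)
  }))
  expect_setequal(as.vector(na.omit(as.vector(reassembled))),
                  as.vector(full[fit$estimable[ia] & fit$observed[ia], ]))
  re <- receiver_effect(fit, "type_B")
  expect_equal(colnames(re$coefficients), fit$types)
  expect_error(sender_effect(fit, "no_such_type"), "unknown")
})

test_that("a planted effect tops the receiver-effect ranking", {
  sim <- standard_benchmark()
  fit <- interp_fit()
  re <- receiver_effect(fit, "type_B")
  top_genes <- rownames(re$coefficients)[
    order(abs(re$coefficients[, "type_A"]), decreasing = TRUE)[1:10]]
  expect_true(all(top_genes %in% sim$ground_truth$dependent_genes))
})

test_that("sender similarity is a Pearson correlation with average linkage", {
  fit <- interp_fit()
  ss <- sender_similarity(fit, "type_B")
  cm <- ss$correlation
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, nrow(cm)))
  # brute-force Pearson on random coefficient sets
  withr::with_seed(3, coefs <- matrix(rnorm(150), 30, 5))
  ref <- matrix(NA_real_, 5, 5)
  for (a in 1:5) for (b in 1:5) {
    ca <- coefs[, a] - mean(coefs[, a]); cb <- coefs[, b] - mean(coefs[, b])
    ref[a, b] <- sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
  }
  expect_equal(stats::cor(coefs), ref, tolerance = 1e-12)
})

test_that("duplicated sender coefficient vectors cluster adjacently", {
  fit <- interp_fit()
  dup <- fit
  ia <- which(dup$provenance$block == "interaction")
  # make sender type_A's effect on receiver B identical to sender type_B's
  rows <- ia[dup$provenance$receiver[ia] == "type_B"]
  dup$coefficients[rows[1], ] <- dup$coefficients[rows[2], ]
  ss <- sender_similarity(dup, "type_B")
  expect_equal(ss$correlation["type_A", "type_B"], 1)
  expect_true(all(abs(diff(match(c("type_A", "type_B"), ss$order))) == 1))
})

test_that("cluster enrichment agrees with hypergeometric enumeration", {
  # perfect separation on 20 cells
  cl <- rep(c(TRUE, FALSE), each = 10)
  sp <- rep(c(TRUE, FALSE), each = 10)
  res <- cluster_enrichment(cl, sp)
  # two-sided Fisher p by explicit enumeration of the hypergeometric tail
  m <- 10; n <- 10; k <- 10
  probs <- dhyper(0:10, m, n, k)
  p_ref <- sum(probs[probs <= dhyper(10, m, n, k) * (1 + 1e-7)])
  expect_equal(res$p, p_ref, tolerance = 1e-10)
  expect_lt(res$p, 1e-4)
  # independent random masks give calibrated p-values
  withr::with_seed(7, {
    ps <- replicate(300, {
      cluster_enrichment(sample(c(TRUE, FALSE), 40, replace = TRUE),
                         sample(c(TRUE, FALSE), 40, replace = TRUE))$p
    })
  })
  expect_gt(mean(ps), 0.3)   # no systematic inflation under independence
  # degenerate margin: all cells in the cluster
  deg <- cluster_enrichment(rep(TRUE, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(deg$p, 1)
  expect_true(deg$degenerate)
})

test_that("FDR control flows through to coupling counts on null data", {
  sim <- simulate_null(simulation_config(n_cells = 700, n_genes = 120,
                                         n_types = 1, seed = 17))
  fit <- wald_test(fit_ols(build_design(sim$dataset, sim$graph, "interaction"),
                           sim$dataset$expression))
  ct <- type_coupling(fit, min_genes = 1)
  expect_lte(max(ct$n_significant, na.rm = TRUE),
             0.05 * ncol(sim$dataset$expression) +
               3 * sqrt(0.05 * 0.95 * ncol(sim$dataset$expression)))
})
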