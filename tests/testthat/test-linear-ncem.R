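test_that("sender presence excludes the index cell and pools the niche", {
  # clique of three cells typed A, A, B
  ds <- spatial_dataset(matrix(1, 3, 1), rbind(c(0, 0), c(1, 0), c(0, 1)),
                        c("A", "A", "B"), rep("i", 3))
  g <- build_graph(ds, 2)
  xs <- sender_presence(g, ncemr:::one_hot(ds$cell_type))
  expect_equal(unname(xs), rbind(c(1, 1), c(1, 1), c(1, 0)))
  # isolated cell: all-zero row
  iso <- spatial_dataset(matrix(1, 2, 1), rbind(c(0, 0), c(500, 0)),
                         c("A", "B"), rep("i", 2))
  expect_equal(unname(sender_presence(build_graph(iso, 10),
                                      ncemr:::one_hot(iso$cell_type))),
               matrix(0, 2, 2))
})

test_that("interaction design rows are receiver-major outer products", {
  # cell of type A with one B neighbour, L = 2, C = 1
  ds <- spatial_dataset(matrix(1, 2, 1), rbind(c(0, 0), c(1, 0)),
                        c("A", "B"), rep("i", 2))
  g <- build_graph(ds, 5)
  des <- build_design(ds, g, "interaction")
  expect_equal(unname(des$values[1, ]), c(1, 0, 0, 1, 0, 0, 1))
  expect_equal(des$provenance$block,
               c("receiver_type", "receiver_type", rep("interaction", 4),
                 "domain"))
  expect_equal(des$provenance$receiver[3:6], c("A", "A", "B", "B"))
  expect_equal(des$provenance$sender[3:6], c("A", "B", "A", "B"))
  # baseline has L + C columns; global sender has 2L + C
  expect_equal(ncol(build_design(ds, variant = "baseline")$values), 3)
  expect_equal(ncol(build_design(ds, g, "global_sender")$values), 5)
})

test_that("an empty graph collapses the interaction model onto the baseline", {
  ds <- random_dataset(n = 50, j = 4, seed = 4)
  far <- build_graph(ds, 1e-6)
  expect_equal(sum(far$degree), 0)
  des_i <- build_design(ds, far, "interaction")
  des_b <- build_design(ds, variant = "baseline")
  expect_true(all(des_i$values[, des_i$provenance$block == "interaction"] == 0))
  fit_i <- fit_ols(des_i, ds$expression)
  fit_b <- fit_ols(des_b, ds$expression)
  expect_equal(fit_i$fitted, fit_b$fitted, tolerance = 1e-10)
})

test_that("OLS recovers noiseless coefficients exactly and flags collinearity", {
  withr::with_seed(1, {
    x <- matrix(rnorm(40 * 5), 40, 5)
    beta <- matrix(rnorm(5 * 3), 5, 3)
  })
  des <- structure(list(values = x,
                        provenance = data.frame(block = rep("receiver_type", 5),
                                                receiver = NA, sender = NA),
                        variant = "baseline"),
                   class = "ncem_design")
  fit <- fit_ols(des, x %*% beta)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-9)
  # duplicated column: both members of the pair are non-estimable
  x2 <- cbind(x, x[, 5])
  des2 <- des; des2$values <- x2
  des2$provenance <- rbind(des2$provenance, des2$provenance[5, ])
  fit2 <- fit_ols(des2, x %*% beta)
  expect_false(fit2$estimable[5])
  expect_false(fit2$estimable[6])
  expect_true(all(fit2$estimable[1:4]))
  des1 <- des; des1$values <- x[1, , drop = FALSE]
  expect_error(fit_ols(des1, (x %*% beta)[1, , drop = FALSE]), "2 rows")
})

test_that("coefficients and standard errors match the normal-equations oracle", {
  withr::with_seed(99, {
    x <- matrix(rnorm(50 * 7), 50, 7)
    y <- matrix(rnorm(50 * 3), 50, 3)
  })
  des <- structure(list(values = x,
                        provenance = data.frame(block = rep("receiver_type", 7),
                                                receiver = NA, sender = NA),
                        variant = "baseline"),
                   class = "ncem_design")
  fit <- fit_ols(des, y)
  xtx_inv <- solve(crossprod(x))
  beta_ref <- xtx_inv %*% crossprod(x, y)
  resid <- y - x %*% beta_ref
  s2 <- colSums(resid^2) / (50 - 7)
  se_ref <- sqrt(outer(diag(xtx_inv), s2))
  expect_equal(unname(fit$coefficients), unname(beta_ref), tolerance = 1e-8)
  expect_equal(unname(fit$standard_errors), unname(se_ref), tolerance = 1e-8)
  expect_equal(fit$sigma, unname(sqrt(colSums(resid^2) / 50)), tolerance = 1e-8)
})

test_that("Wald p-values match an incomplete-beta oracle and zero beta gives p = 1", {
  withr::with_seed(5, {
    tstats <- rnorm(20) * 3
    dofs <- sample(5:50, 20, replace = TRUE)
  })
  for (k in seq_along(tstats)) {
    p_pkg <- 2 * stats::pt(-abs(tstats[k]), dofs[k])
    # independent route: t two-sided p via the incomplete beta function
    p_ref <- stats::pbeta(dofs[k] / (dofs[k] + tstats[k]^2), dofs[k] / 2, 0.5)
    expect_equal(p_pkg, p_ref, tolerance = 1e-10)
  }
  sim <- standard_benchmark()
  fit <- fit_ols(build_design(sim$dataset, sim$graph, "interaction"),
                 sim$dataset$expression)
  fit$coefficients[fit$provenance$block == "interaction", ][1, 1] <- 0
  wt <- wald_test(fit)
  expect_equal(wt$p_values[1, 1], 1)
  expect_true(all(wt$q_values >= wt$p_values - 1e-12, na.rm = TRUE))
  expect_true(all(wt$q_values <= 1, na.rm = TRUE))
})

test_that("Gaussian log-likelihood matches the printed normalization", {
  y <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(gaussian_ll(y, y, c(1, 1)), -log(sqrt(2 * pi)))
  expect_equal(gaussian_ll(matrix(1), matrix(2), 1),
               -log(sqrt(2 * pi)) - 0.5)
  # doubling residuals at fixed sigma strictly decreases the likelihood
  yhat <- y + 0.5
  yhat2 <- y + 1
  expect_lt(gaussian_ll(y, yhat2, c(1, 1)), gaussian_ll(y, yhat, c(1, 1)))
  expect_error(gaussian_ll(y, y, c(1, 0)), "positive")
})

test_that("R squared follows the printed per-cell ratio", {
  withr::with_seed(2, {
    y <- matrix(rnorm(30), 10, 3)
    yhat <- y + matrix(rnorm(30, sd = 0.3), 10, 3)
    gm <- rnorm(3)
  })
  r2 <- r_squared(y, yhat, gm)
  ref <- sapply(1:10, function(i)
    1 - sum((y[i, ] - yhat[i, ])^2) / sum((y[i, ] - gm)^2))
  expect_equal(r2$per_cell, ref, tolerance = 1e-12)
  expect_equal(r_squared(y, y, gm)$pooled, 1)
  # predicting the training means scores zero pooled R2
  pred_mean <- matrix(gm, 10, 3, byrow = TRUE)
  expect_equal(r_squared(y, pred_mean, gm)$pooled, 0)
  const <- rbind(gm, y)
  expect_warning(r_squared(const, const + 0.1, gm), "zero variance")
})

test_that("nested designs never lose training R squared", {
  sim <- standard_benchmark()
  ds <- sim$dataset
  fits <- lapply(c("baseline", "global_sender", "interaction"), function(v)
    fit_ols(build_design(ds, sim$graph, v), ds$expression))
  gm <- colMeans(ds$expression)
  r2s <- vapply(fits, function(f)
    r_squared(ds$expression, f$fitted, gm)$pooled, numeric(1))
  expect_true(all(diff(r2s) >= -1e-12))
})

test_that("null Wald p-values are uniform (Kolmogorov-Smirnov)", {
  sim <- simulate_null(simulation_config(n_cells = 600, n_genes = 150,
                                         n_types = 1, seed = 21))
  fit <- wald_test(fit_ols(build_design(sim$dataset, sim$graph, "interaction"),
                           sim$dataset$expression))
  p <- fit$p_values[!is.na(fit$p_values)]
  expect_gte(length(p), 100)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})

test_that("the resolution screen has a graph-blind baseline and honest nulls", {
  sim <- simulate_null(simulation_config(n_cells = 400, n_genes = 20,
                                         n_types = 1, seed = 31))
  sc <- resolution_screen(sim$dataset, c(20, 50, 100), seeds = 1:2)
  base <- sc$table[sc$table$model == "baseline", ]
  for (s in unique(base$seed))
    expect_equal(length(unique(base$r2[base$seed == s])), 1)
  # without planted effects the spatial gain on test data is not positive
  expect_lte(mean(sc$delta_r2$delta_r2), 0.02)
  expect_error(resolution_screen(sim$dataset, 50, seeds = 1:2), "2 resolutions")
})
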