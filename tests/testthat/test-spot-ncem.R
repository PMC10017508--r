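make_spots <- function(expr, spot, type, comp) {
  deconvoluted_spots(expr, spot, type, comp)
}

test_that("spot design rows interact the receiver one-hot with spot composition", {
  comp <- rbind(s1 = c(A = 0.5, B = 0.5), s2 = c(A = 1, B = 0))
  expr <- matrix(1:6, 3, 2, dimnames = list(NULL, c("g1", "g2")))
  sp <- make_spots(expr, c("s1", "s1", "s2"), c("A", "B", "A"), comp)
  des <- build_spot_design(sp, "interaction")
  # (s1, A): [1,0 | 0.5,0.5,0,0 | 1]
  expect_equal(unname(des$values[1, ]), c(1, 0, 0.5, 0.5, 0, 0, 1))
  # (s1, B): interaction block lands in the receiver-B columns
  expect_equal(unname(des$values[2, ]), c(0, 1, 0, 0, 0.5, 0.5, 1))
  # composition all on the target type reduces to a self-composition column
  expect_equal(unname(des$values[3, ]), c(1, 0, 1, 0, 0, 0, 1))
  # identical compositions give identical interaction blocks per receiver
  comp2 <- rbind(s1 = c(A = 2, B = 3), s2 = c(A = 2, B = 3))
  sp2 <- make_spots(expr, c("s1", "s2", "s2"), c("A", "A", "B"), comp2)
  d2 <- build_spot_design(sp2, "interaction")
  expect_equal(d2$values[1, 3:6], d2$values[2, 3:6])
  expect_equal(ncol(build_spot_design(sp, "baseline")$values), 3)
  expect_error(make_spots(expr, c("s1", "s1", "s2"), c("A", "B", "A"),
                          -comp), "negative")
})

test_that("one-type-per-spot binary composition matches the single-cell design", {
  # spots holding exactly one cell each, composition = one-hot of that type:
  # the interaction block must equal the self-niche single-cell design
  types <- c("A", "B", "A")
  comp <- ncemr:::one_hot(factor(types))
  rownames(comp) <- paste0("s", 1:3)
  expr <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("g1", "g2")))
  sp <- make_spots(expr, paste0("s", 1:3), types, comp)
  des_spot <- build_spot_design(sp, "interaction")
  # single-cell analogue: each cell neighbours only itself-typed cells
  ia <- des_spot$provenance$block == "interaction"
  for (i in 1:3) {
    expected <- tcrossprod(ncemr:::one_hot(factor(types, levels = c("A", "B")))[i, ],
                           comp[i, ])
    expect_equal(unname(des_spot$values[i, ia]), as.vector(t(expected)))
  }
})

test_that("spot NCEM beats the composition-blind baseline on planted effects", {
  sp <- memo("spot_benchmark",
             simulate_spots(simulation_config(n_cells = 3000, n_genes = 30,
                                              mean_degree = 2, seed = 5),
                            spot_size = 100))
  fit <- suppressWarnings(fit_spot_ncem(sp$spots, seeds = 1:3))
  expect_gte(sum(fit$delta_r2$delta_r2 > 0), 2)
  # composition with zero effect: gain vanishes on held-out spots
  sp0 <- simulate_spots(simulation_config(n_cells = 1500, n_genes = 20,
                                          effect_size_range = c(0, 0),
                                          mean_degree = 2, seed = 6),
                        spot_size = 100)
  fit0 <- suppressWarnings(fit_spot_ncem(sp0$spots, seeds = 1:3))
  expect_lt(abs(mean(fit0$delta_r2$delta_r2)), 0.05)
})

test_that("coefficient stability is 1 for identical fits and matches brute force", {
  sp <- memo("spot_benchmark",
             simulate_spots(simulation_config(n_cells = 3000, n_genes = 30,
                                              mean_degree = 2, seed = 5),
                            spot_size = 100))
  des <- build_spot_design(sp$spots, "interaction")
  fit <- fit_ols(des, sp$spots$expression)
  same <- coefficient_stability(fit, fit)
  expect_true(all(same$r2[!is.na(same$r2)] == 1))
  # noisy copy: matches the direct formula
  fit2 <- fit
  withr::with_seed(3, {
    noise <- matrix(rnorm(length(fit2$coefficients), sd = 0.1),
                    nrow(fit2$coefficients))
  })
  fit2$coefficients <- fit2$coefficients + noise
  st <- coefficient_stability(fit, fit2)
  ia <- which(fit$provenance$block == "interaction")
  for (k in seq_along(ia)) {
    ref <- fit$coefficients[ia[k], ]
    cmp <- fit2$coefficients[ia[k], ]
    expect_equal(st$r2[k], 1 - sum((ref - cmp)^2) / sum((ref - mean(ref))^2),
                 tolerance = 1e-12)
  }
  # orthogonal random vectors: non-positive in expectation
  withr::with_seed(9, {
    f1 <- fit; f2 <- fit
    f1$coefficients[ia, ] <- rnorm(length(ia) * ncol(f1$coefficients))
    f2$coefficients[ia, ] <- rnorm(length(ia) * ncol(f2$coefficients))
  })
  expect_lt(mean(coefficient_stability(f1, f2)$r2), 0.5)
})

test_that("coefficient stability degrades monotonically with subsampling", {
  sp <- memo("spot_benchmark",
             simulate_spots(simulation_config(n_cells = 3000, n_genes = 30,
                                              mean_degree = 2, seed = 5),
                            spot_size = 100))
  full_des <- build_spot_design(sp$spots, "interaction")
  full_fit <- fit_ols(full_des, sp$spots$expression)
  sub_fit <- function(frac, seed) {
    s <- nrow(sp$spots$composition)
    keep <- withr::with_seed(seed, sample.int(s, ceiling(frac * s)))
    rows <- which(as.integer(sp$spots$spot) %in% keep)
    des <- full_des
    des$values <- full_des$values[rows, , drop = FALSE]
    fit_ols(des, sp$spots$expression[rows, , drop = FALSE])
  }
  r2_75 <- mean(coefficient_stability(full_fit, sub_fit(0.75, 1))$r2,
                na.rm = TRUE)
  r2_05 <- mean(coefficient_stability(full_fit, sub_fit(0.05, 1))$r2,
                na.rm = TRUE)
  expect_gt(r2_75, r2_05)
})
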