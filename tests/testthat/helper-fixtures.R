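# Shared fixtures. Heavy simulations are memoised so several test files
# can reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a tiny hand-checkable dataset: 4 cells, 2 types, 1 domain
toy_dataset <- function() {
  spatial_dataset(
    expression = matrix(c(1, 2, 3, 4,
                          5, 6, 7, 8), 4, 2,
                        dimnames = list(NULL, c("g1", "g2"))),
    coords = rbind(c(0, 0), c(3, 4), c(100, 100), c(103, 100)),
    cell_type = c("A", "B", "A", "B"),
    domain = rep("img1", 4)
  )
}

# random dataset with arbitrary structure for property tests
random_dataset <- function(n = 60, j = 5, l = 3, c_dom = 2, seed = 1) {
  withr::with_seed(seed, {
    spatial_dataset(
      expression = matrix(stats::rexp(n * j), n, j),
      coords = matrix(stats::runif(n * 2, 0, 100), n, 2),
      cell_type = sample(letters[seq_len(l)], n, replace = TRUE),
      domain = sample(paste0("d", seq_len(c_dom)), n, replace = TRUE)
    )
  })
}

# the standard single-cell synthetic benchmark (dependency design)
standard_benchmark <- function() {
  memo("standard_benchmark",
       simulate_dependency(simulation_config(n_cells = 800, n_genes = 40,
                                             seed = 7)))
}

# benchmark with cell-intrinsic latent factors (CVAE reconstruction task)
intrinsic_benchmark <- function() {
  memo("intrinsic_benchmark",
       simulate_dependency(simulation_config(n_cells = 800, n_genes = 40,
                                             n_latent_factors = 4, seed = 7)))
}
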