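# Shared fixtures, all built in code.

# Rectangular-tiling partitions on a square domain.
square_partitions <- function(n_coarse = 4, n_fine = 9, size = 3000) {
  make_misaligned_partitions(c(0, size, 0, size), n_coarse, n_fine,
                             style = "grid", seed = 1)
}

# Units that each contain exactly one quadrature point: unit squares equal
# to lattice cells, so areal quantities collapse to pointwise ones.
degenerate_point_units <- function(cells_coarse, cells_fine, cell = 100) {
  cell_ring <- function(ij) {
    rect_ring((ij[1] - 1) * cell, ij[1] * cell, (ij[2] - 1) * cell, ij[2] * cell)
  }
  dplyr::bind_rows(
    area_units(sprintf("c%02d", seq_len(nrow(cells_coarse))), "coarse",
               apply(cells_coarse, 1, cell_ring, simplify = FALSE)),
    area_units(sprintf("f%02d", seq_len(nrow(cells_fine))), "fine",
               apply(cells_fine, 1, cell_ring, simplify = FALSE))
  )
}

# A small synthetic dataset + grid ready for likelihood work.
small_fixture <- function(seed = 1, n_coarse = 6, n_fine = 12, size = 4000,
                          spacing = 250, sim_spacing = 250,
                          params = NULL) {
  sc <- synthetic_scenario(domain = c(0, size, 0, size), n_coarse = n_coarse,
                           n_fine = n_fine, style = "grid",
                           sim_grid_spacing = sim_spacing,
                           true_params = params, seed = seed)
  data <- simulate_dataset(sc, seed = seed + 100)
  grid <- if (spacing == sim_spacing) sc$sim_grid else
    build_quadrature_grid(sc$units, spacing, quiet = TRUE, on_empty = "centroid")
  list(scenario = sc, data = data, grid = grid, params = sc$true_params)
}

random_params <- function() {
  model_params(
    alpha = stats::rnorm(2, 75, 3), beta = stats::rnorm(2, -0.2, 0.2),
    gamma = stats::rnorm(1, 30, 5), tau2 = stats::runif(1, 50, 600),
    delta = stats::runif(1, 300, 3000), nu2 = stats::runif(1, 1, 30),
    omega = {
      w1 <- stats::runif(1, 2, 20); w2 <- stats::runif(1, 2, 20)
      rho <- stats::runif(1, -0.8, 0.8)
      c(w1, w2, rho * sqrt(w1 * w2))
    }
  )
}
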