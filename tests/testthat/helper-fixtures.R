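# Shared fixtures built in code.

# Regular grid at 5-km spacing, all "other" region unless a top fraction
# of rows is flagged hokkaido.
regular_grid <- function(n_rows, n_cols, spacing = 5, hokkaido_rows = 0L) {
  row_i <- rep(seq_len(n_rows), times = n_cols)
  col_i <- rep(seq_len(n_cols), each = n_rows)
  region <- ifelse(row_i > n_rows - hokkaido_rows, "hokkaido", "other")
  cell_grid(seq_len(n_rows * n_cols), (col_i - 1) * spacing,
            (row_i - 1) * spacing, region)
}

# Irregular scattered grid for oracle comparisons.
scattered_grid <- function(n, extent_km = 100, seed = 1) {
  set.seed(seed)
  cell_grid(seq_len(n), runif(n, 0, extent_km), runif(n, 0, extent_km),
            sample(c("hokkaido", "other"), n, replace = TRUE))
}

# O(N^2) brute-force reference for the distance-weighted neighborhood
# occupancy; the independent oracle for neighborhood_occupancy().
brute_force_d <- function(x, y, occ, radius, p) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    nb <- which(d > 0 & d <= radius)
    if (!length(nb)) return(0)
    w <- if (p == 0) rep(1, length(nb)) else d[nb]^(-p)
    sum(w * occ[nb]) / sum(w)
  }, numeric(1))
}

# Synthetic transition dataset of roughly n cells generated from the
# reference coefficients; used for recovery and oracle tests.
make_transition_dataset <- function(n_rows, n_cols, seed,
                                    params = sika_dynamics_params(),
                                    dispersal = neighborhood_spec(25, 2),
                                    surface_epoch = c("second", "first")) {
  surface_epoch <- match.arg(surface_epoch)
  land <- generate_landscape(landscape_config(n_rows = n_rows, n_cols = n_cols,
                                              seed = seed))
  model <- sika_habitat_model()
  occ1 <- simulate_initial_occupancy(model, land$env_first, land$grid, seed = seed)
  d <- suppressWarnings(neighborhood_occupancy(occ1, land$grid, dispersal))
  env_h <- if (surface_epoch == "second") land$env_second else land$env_first
  h <- as.numeric(suitability(model, env_h, land$grid))
  occ2 <- simulate_transition(params, occ1, d, h, seed = seed)
  list(grid = land$grid, env_first = land$env_first,
       env_second = land$env_second, occ_first = occ1, occ_second = occ2,
       d = d, h = h,
       data = transition_data(unclass(occ1), unclass(occ2), d, h))
}

# Batch-means Monte-Carlo standard error of a posterior median estimate.
mcse_batch <- function(draws, n_batches = 30) {
  m <- length(draws) %/% n_batches
  means <- vapply(seq_len(n_batches), function(b) {
    mean(draws[((b - 1) * m + 1):(b * m)])
  }, numeric(1))
  sd(means) / sqrt(n_batches)
}
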