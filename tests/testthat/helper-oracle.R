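# Independent brute-force oracle for the penalized maxent objective.
# Written against the objective definition only; it never calls the
# package optimizer.  Minimizes
#   ln sum_S exp(F l) - mean_P (F l) + sum_j beta_j |l_j|
# by iteratively refined dense grid search over the coefficient space.

oracle_objective <- function(F, p_idx, beta, lambda) {
  eta <- drop(F %*% lambda)
  mx <- max(eta)
  (mx + log(sum(exp(eta - mx)))) - mean(eta[p_idx]) +
    sum(beta * abs(lambda))
}

oracle_grid_fit <- function(F, p_idx, beta, lo = -10, hi = 10,
                            pts = 15, rounds = 7) {
  K <- ncol(F)
  centers <- rep(0, K)
  half <- rep((hi - lo) / 2, K)
  best <- NULL
  for (r in seq_len(rounds)) {
    axes <- lapply(seq_len(K), function(j)
      seq(centers[j] - half[j], centers[j] + half[j], length.out = pts))
    grid <- as.matrix(expand.grid(axes))
    vals <- apply(grid, 1, function(l)
      oracle_objective(F, p_idx, beta, l))
    i <- which.min(vals)
    centers <- grid[i, ]
    best <- list(lambda = centers, objective = vals[i])
    half <- half * 2.5 / (pts - 1)   # keep a margin around the best point
  }
  best
}

# small deterministic presence-background fixture on raw variables
make_tiny_swd <- function(n_p = 4, n_b = 8, n_var = 1, seed = 1) {
  set.seed(seed)
  vars <- paste0("v", seq_len(n_var))
  df <- data.frame(class = rep(c("presence", "background"),
                               c(n_p, n_b)))
  for (v in vars)
    df[[v]] <- c(rnorm(n_p, 1), rnorm(n_b, 0))
  df
}

# quick synthetic world reused across tests (small but fully featured)
make_small_world <- function(seed = 7, n = 50) {
  synthetic_landscape(n_rows = n, n_cols = n, seed = seed,
                      n_pa = 8, n_countries = 3)
}

make_toy_mask <- function(grid, vals) {
  raster_layer(grid, "mask", matrix(vals, grid$n_rows, grid$n_cols))
}
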