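# Shared builders and independent oracles used across the suite.

make_records <- function(n = 10, seed = 1, states = c("AA", "BB"),
                         window = c("2015-01", "2015-12")) {
  withr::with_seed(seed, {
    months <- month_seq(window[1], window[2])
    tibble::tibble(
      state = sample(states, n, replace = TRUE),
      date = sample(months, n, replace = TRUE) + sample(0:27, n, replace = TRUE),
      n_injured = sample(0:3, n, replace = TRUE),
      n_killed = sample(0:2, n, replace = TRUE),
      intent = sample(c("assault", "self_harm", "unintentional", "undetermined"),
                      n, replace = TRUE),
      mass_shooting = FALSE
    )
  })
}

make_pop <- function(states, years, population = 5e6) {
  tidyr::expand_grid(state = states, year = years) |>
    dplyr::mutate(population = population)
}

# Enumerate the simplex grid with the given step for J coordinates.
simplex_grid <- function(J, step) {
  s <- round(1 / step)
  if (J == 1) {
    return(matrix(1, 1, 1))
  }
  grids <- do.call(expand.grid, rep(list(0:s), J - 1))
  keep <- rowSums(grids) <= s
  g <- as.matrix(grids[keep, , drop = FALSE])
  cbind(g, s - rowSums(g)) / s
}

# Brute-force minimum of the importance-weighted predictor discrepancy over
# a simplex grid of candidate weight vectors.
grid_min_objective <- function(X1, X0, v, G) {
  R <- matrix(X1, nrow(G), length(X1), byrow = TRUE) - G %*% t(X0)
  min((R^2) %*% (v / sum(v)))
}

# Small simulated study used by several files.
tiny_study <- function(seed = 7, n_donors = 8, ...) {
  generate_panel(factor_config(
    n_treated = 1, n_donors = n_donors,
    window = c("2015-01", "2019-12"), seed = seed, ...
  ))
}
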