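# Shared fixtures: all built in code, no data files.

fs_game <- function() game_params(15, 10, 9, 6, 1, -1, c = 0.6)

fs_pop <- function(n = 100) {
  population_params(n = n, male_fraction = 0.493, rho_NE = 0.188,
                    rho_NE_S = 0.05, rho_E_S = 0.75)
}

# Build a lattice population with prescribed payoffs (row-major) and genders,
# attributes back-derived from the payoff under the default game, so the
# payoff-consistency invariant holds on hand-made fixtures.
fixture_population <- function(payoffs, gender, n = sqrt(length(payoffs))) {
  stopifnot(n == round(n), length(payoffs) == n^2)
  gp <- fs_game()
  lut <- data.frame(payoff = c(15, 10, 9, 6, 1, -1),
                    education = c("NE", "NE", "E", "E", "NE", "E"),
                    outcome = c("S", "S", "S", "S", "NS", "NS"),
                    kind = c("A", "B", "A", "B", "A", "A"))
  m <- match(payoffs, lut$payoff)
  stopifnot(!anyNA(m))
  idx <- seq_len(n^2) - 1L
  pop <- tibble::tibble(row = idx %/% n, col = idx %% n,
                        gender = rep_len(gender, n^2),
                        kind = lut$kind[m],
                        education = lut$education[m],
                        outcome = lut$outcome[m],
                        payoff = payoffs)
  structure(pop, class = c("lattice_population", class(pop)),
            n = as.integer(n), game_params = gp)
}

# Independent enumeration of the i.i.d. prevalence via stats::dmultinom,
# used to cross-check the package's log-gamma implementation.
dmultinom_prevalence <- function(pi, values, theta) {
  g <- expand.grid(k1 = 0:8, k2 = 0:8, k3 = 0:8, k4 = 0:8, k5 = 0:8)
  g <- as.matrix(g[rowSums(g) <= 8, ])
  comps <- cbind(g, 8 - rowSums(g))
  pr <- apply(comps, 1, function(k) stats::dmultinom(k, 8, pi))
  nbhd <- as.vector(comps %*% values) / 8
  tot <- 0
  for (j in seq_along(values)) {
    if (pi[j] > 0) tot <- tot + pi[j] * sum(pr[nbhd - values[j] > theta])
  }
  tot
}
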