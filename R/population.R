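#' Demographic composition of the lattice population
#'
#' Holds the lattice side and the configured category fractions. The success
#' fractions `rho_NE_S` and `rho_E_S` are *absolute* population fractions
#' (shares of the whole population that are successful nonstudents resp.
#' successful students), so the unsuccessful shares are
#' `rho_NE - rho_NE_S` (payoff `p`) and `(1 - rho_NE) - rho_E_S` (payoff `s`).
#'
#' @param n Lattice side; the population has `n^2` individuals. Must be at
#'   least 3 so that every Moore neighbourhood has eight distinct members.
#' @param male_fraction Fraction of men, strictly inside `(0, 1)` (both gender
#'   strata must be non-empty for the prevalence ratio to be defined).
#' @param rho_NE Fraction of nonstudents.
#' @param rho_NE_S Fraction of the population that are successful nonstudents;
#'   at most `rho_NE`.
#' @param rho_E_S Fraction of the population that are successful students; at
#'   most `1 - rho_NE`.
#'
#' @return An object of class `population_params` with the supplied fields and
#'   derived fractions `rho_E`, `rho_NE_NS`, `rho_E_NS`.
#' @examples
#' population_params() # the default UK-2014-16 composition
#' @export
population_params <- function(n = 100, male_fraction = 0.493, rho_NE = 0.188,
                              rho_NE_S = 0.05, rho_E_S = 0.75) {
  if (!(is.numeric(n) && length(n) == 1 && is.finite(n) && n == round(n) && n >= 3)) {
    abort("population_params: `n` must be an integer >= 3.")
  }
  fr <- c(male_fraction = male_fraction, rho_NE = rho_NE,
          rho_NE_S = rho_NE_S, rho_E_S = rho_E_S)
  if (!all(is.finite(fr)) || any(fr < 0) || any(fr > 1)) {
    abort("population_params: all fractions must lie in [0, 1].")
  }
  if (male_fraction <= 0 || male_fraction >= 1) {
    abort("population_params: `male_fraction` must lie strictly in (0, 1).")
  }
  tol <- 1e-9
  if (rho_NE_S > rho_NE + tol) {
    abort("population_params: `rho_NE_S` cannot exceed `rho_NE`.")
  }
  if (rho_E_S > 1 - rho_NE + tol) {
    abort("population_params: `rho_E_S` cannot exceed `1 - rho_NE`.")
  }
  structure(list(
    n = as.integer(n),
    male_fraction = male_fraction,
    rho_NE = rho_NE,
    rho_E = 1 - rho_NE,
    rho_NE_S = rho_NE_S,
    rho_E_S = rho_E_S,
    rho_NE_NS = max(rho_NE - rho_NE_S, 0),
    rho_E_NS = max(1 - rho_NE - rho_E_S, 0)
  ), class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf("Lattice population: %d x %d (%d individuals)\n", x$n, x$n, x$n^2))
  cat(sprintf("  male fraction      : %.3f\n", x$male_fraction))
  cat(sprintf("  nonstudents rho_NE : %.3f (successful %.3f, unsuccessful %.3f)\n",
              x$rho_NE, x$rho_NE_S, x$rho_NE_NS))
  cat(sprintf("  students    rho_E  : %.3f (successful %.3f, unsuccessful %.3f)\n",
              x$rho_E, x$rho_E_S, x$rho_E_NS))
  invisible(x)
}

#' Integer category counts by largest-remainder apportionment
#'
#' Splits `total` individuals among categories proportionally to `fractions`,
#' so realised counts match the configured fractions exactly rather than only
#' in expectation. Each count is `floor(fraction * total)` plus at most one
#' remainder unit; remainder units go to the largest fractional remainders,
#' ties broken by category order.
#'
#' @param fractions Non-negative numeric vector summing to 1 (tolerance 1e-9).
#' @param total Positive integer.
#' @return An integer vector of the same length as `fractions`, summing to
#'   `total`.
#' @examples
#' allocate_counts(c(0.493, 0.507), 10000) # 4930 5070
#' allocate_counts(c(1, 1, 1) / 3, 10) # 4 3 3
#' @export
allocate_counts <- function(fractions, total) {
  if (any(!is.finite(fractions)) || any(fractions < 0)) {
    abort("allocate_counts: fractions must be non-negative and finite.")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort("allocate_counts: fractions must sum to 1 (tolerance 1e-9).")
  }
  if (!(length(total) == 1 && is.finite(total) && total == round(total) && total > 0)) {
    abort("allocate_counts: `total` must be a positive integer.")
  }
  exact <- fractions * total
  base <- floor(exact + 1e-9) # guard against 4930 landing as 4929.999...
  rem <- exact - base
  short <- as.integer(round(total - sum(base)))
  counts <- as.integer(base)
  if (short > 0) {
    take <- order(-rem, seq_along(rem))[seq_len(short)]
    counts[take] <- counts[take] + 1L
  }
  counts
}

# The six payoff-category fractions pi(t_A), pi(t_B), pi(r_A), pi(r_B),
# pi(p), pi(s) implied by a population/game configuration. Kind is independent
# of education and outcome, so success payoffs split c : (1 - c).
payoff_category_fractions <- function(pp, gp) {
  pi <- c(t_A = pp$rho_NE_S * gp$c,
          t_B = pp$rho_NE_S * (1 - gp$c),
          r_A = pp$rho_E_S * gp$c,
          r_B = pp$rho_E_S * (1 - gp$c),
          p = pp$rho_NE_NS,
          s = pp$rho_E_NS)
  pmax(pi, 0)
}

payoff_category_values <- function(gp) {
  c(t_A = gp$t_A, t_B = gp$t_B, r_A = gp$r_A, r_B = gp$r_B, p = gp$p, s = gp$s)
}

#' Moore-neighbourhood index of a toroidal lattice
#'
#' For an `n x n` square lattice with periodic (toroidal) boundaries, returns
#' the eight Moore neighbours of every cell as an `n^2 x 8` integer matrix of
#' linear cell indices. Cells are ordered row-major over 0-based coordinates
#' (`row`, `col`), i.e. cell `(row, col)` has linear index `row * n + col + 1`;
#' this matches the row order of [assign_population()]. Neighbour columns are
#' in the fixed offset order (-1,-1), (-1,0), (-1,1), (0,-1), (0,1), (1,-1),
#' (1,0), (1,1).
#'
#' @param n Lattice side, at least 3 (below that the wrapped neighbourhood
#'   would contain duplicate cells).
#' @return An integer matrix of class `torus_neighbors` with attribute `n`.
#' @examples
#' nb <- torus_neighbors(3)
#' sort(nb[1, ]) # the 3x3 torus is complete: all 8 other cells
#' @export
torus_neighbors <- function(n) {
  if (!(length(n) == 1 && is.finite(n) && n == round(n) && n >= 3)) {
    abort("torus_neighbors: `n` must be an integer >= 3.")
  }
  n <- as.integer(n)
  idx <- seq_len(n^2) - 1L
  row <- idx %/% n
  col <- idx %% n
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  nb <- matrix(0L, nrow = n^2, ncol = 8)
  for (k in seq_len(8)) {
    nb[, k] <- ((row + offs[k, 1]) %% n) * n + ((col + offs[k, 2]) %% n) + 1L
  }
  structure(nb, class = "torus_neighbors", n = n)
}

neighbors_for <- function(pop, neighbors = NULL) {
  n <- attr(pop, "n") %||% as.integer(round(sqrt(nrow(pop))))
  if (is.null(neighbors)) {
    neighbors <- torus_neighbors(n)
  } else if (!identical(attr(neighbors, "n"), n)) {
    abort("`neighbors` was built for a different lattice side.")
  }
  neighbors
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign gender, kind, strategy and payoff to every lattice cell
#'
#' Draws one population realisation. Category counts are fixed exactly by
#' [allocate_counts()] (not per-individual Bernoulli draws): the six payoff
#' categories `t_A, t_B, r_A, r_B, p, s` are apportioned over the whole
#' population from the fractions `pi(t_A) = rho_NE_S * c`,
#' `pi(t_B) = rho_NE_S * (1 - c)`, `pi(r_A) = rho_E_S * c`,
#' `pi(r_B) = rho_E_S * (1 - c)`, `pi(p) = rho_NE - rho_NE_S`,
#' `pi(s) = (1 - rho_NE) - rho_E_S`, with the kind-A fraction `c` also applied
#' exactly within each unsuccessful category (so kind carries no information
#' about education or outcome). Assignment uses two independent random
#' shuffles of exact-count label pools, consumed in the documented order
#' gender first, then joint (strategy, kind); gender is therefore independent
#' of payoff. Payoffs are recomputable from the attributes via
#' [payoff_value()].
#'
#' @param pp A [population_params()] object.
#' @param gp A [game_params()] object.
#' @param seed Optional integer seed; with the same seed the realisation is
#'   reproduced bit-exactly and the caller's RNG state is left untouched.
#' @return A tibble of class `lattice_population` with one row per cell and
#'   columns `row`, `col` (0-based coordinates), `gender` ("male"/"female"),
#'   `kind` ("A"/"B"), `education` ("E"/"NE"), `outcome` ("S"/"NS") and
#'   `payoff`. Rows are in row-major cell order, aligned with
#'   [torus_neighbors()]. Attributes `n`, `pop_params`, `game_params` carry
#'   the configuration.
#' @examples
#' pop <- assign_population(population_params(n = 10), game_params(), seed = 1)
#' dplyr::count(pop, education, outcome, payoff)
#' @export
assign_population <- function(pp, gp, seed = NULL) {
  if (!inherits(pp, "population_params")) abort("`pp` must be a `population_params` object.")
  validate_game(gp)
  n <- pp$n
  N <- n^2
  gender_counts <- allocate_counts(c(pp$male_fraction, 1 - pp$male_fraction), N)
  pi <- payoff_category_fractions(pp, gp)
  cat_counts <- allocate_counts(pi / sum(pi), N) # t_A t_B r_A r_B p s
  p_kind <- allocate_counts(c(gp$c, 1 - gp$c), max(cat_counts[5], 1))
  s_kind <- allocate_counts(c(gp$c, 1 - gp$c), max(cat_counts[6], 1))
  if (cat_counts[5] == 0) p_kind <- c(0L, 0L)
  if (cat_counts[6] == 0) s_kind <- c(0L, 0L)
  # eight (education, outcome, kind) cells in fixed label order
  cells <- c("NE_S_A", "NE_S_B", "E_S_A", "E_S_B",
             "NE_NS_A", "NE_NS_B", "E_NS_A", "E_NS_B")
  cell_counts <- c(cat_counts[1:4], p_kind, s_kind)

  draws <- with_seed_if(seed, list(
    gender = sample(rep(c("male", "female"), gender_counts)),
    cell = sample(rep(cells, cell_counts))
  ))
  gender <- draws$gender
  cell <- draws$cell

  idx <- seq_len(N) - 1L
  education <- ifelse(startsWith(cell, "NE"), "NE", "E")
  outcome <- ifelse(grepl("_NS_", cell), "NS", "S")
  kind <- ifelse(endsWith(cell, "A"), "A", "B")
  pop <- tibble(
    row = idx %/% n,
    col = idx %% n,
    gender = gender,
    kind = kind,
    education = education,
    outcome = outcome,
    payoff = payoff_value(education, outcome, kind, gp)
  )
  structure(pop,
            class = c("lattice_population", class(pop)),
            n = n, pop_params = pp, game_params = gp)
}
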