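# Cache for the 1287 compositions of 8 neighbours into 6 payoff categories.
the <- new.env(parent = emptyenv())

compositions_8_into_6 <- function() {
  if (!is.null(the$comps)) {
    return(the$comps)
  }
  g <- expand.grid(k1 = 0:8, k2 = 0:8, k3 = 0:8, k4 = 0:8, k5 = 0:8)
  g <- as.matrix(g[rowSums(g) <= 8, ])
  comps <- cbind(g, k6 = 8L - rowSums(g))
  stopifnot(nrow(comps) == choose(13, 5)) # 1287
  the$comps <- comps
  comps
}

#' Exact prevalence under the i.i.d. approximation
#'
#' Independent analytic reference for the simulated prevalence: the own payoff
#' is drawn from the categorical distribution `pi` over the six payoff values
#' implied by the configuration, and the eight neighbours' payoffs are an
#' independent multinomial draw from the same `pi`. The depression probability
#' at threshold `theta` is then
#' `sum_q pi(q) * sum_k Multinomial(k; 8, pi) * 1[(sum_v k_v v)/8 - q > theta]`,
#' evaluated by exact enumeration of all `choose(13, 5) = 1287` neighbour
#' compositions. Men use `sigma`, women `tau` (the payoff distribution does
#' not depend on gender); the overall value is the gender-weighted mean.
#'
#' The lattice simulator assigns payoffs with exact category counts rather
#' than i.i.d. draws; the resulting discrepancy is O(1/n^2) and negligible at
#' the default lattice side.
#'
#' @inheritParams assign_population
#' @inheritParams transition_states
#' @return A one-row tibble with `x`, `x_male`, `x_female`, `ratio`.
#' @examples
#' fs <- first_set_config()
#' exact_prevalence(fs$pop, fs$game, thresholds(0.8, 0.6))
#' @export
exact_prevalence <- function(pp, gp, th) {
  if (!inherits(pp, "population_params")) abort("`pp` must be a `population_params` object.")
  validate_game(gp)
  if (!inherits(th, "thresholds")) abort("`th` must be a `thresholds` object.")
  pi <- payoff_category_fractions(pp, gp)
  vals <- payoff_category_values(gp)
  comps <- compositions_8_into_6()

  logpi <- ifelse(pi > 0, log(pi), 0)
  logmult <- lgamma(9) - rowSums(lgamma(comps + 1))
  pr <- exp(logmult + as.vector(comps %*% logpi))
  # compositions using a zero-probability category have probability zero
  zero <- pi <= 0
  if (any(zero)) {
    pr[rowSums(comps[, zero, drop = FALSE]) > 0] <- 0
  }
  nbhd <- as.vector(comps %*% vals) / 8

  prev_at <- function(theta) {
    tot <- 0
    for (j in seq_along(vals)) {
      if (pi[[j]] > 0) {
        tot <- tot + pi[[j]] * sum(pr[nbhd - vals[[j]] > theta])
      }
    }
    tot
  }
  x_m <- prev_at(th$sigma)
  x_f <- prev_at(th$tau)
  w <- pp$male_fraction
  ratio <- if (x_m == 0 && x_f == 0) NA_real_ else x_f / x_m
  tibble(x = w * x_m + (1 - w) * x_f, x_male = x_m, x_female = x_f,
         ratio = ratio)
}
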