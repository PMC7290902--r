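#' Gender-specific frustration thresholds
#'
#' An individual becomes depressed when the mean payoff of the eight Moore
#' neighbours exceeds the personal payoff by strictly more than `sigma` (men)
#' or `tau` (women). The thresholds are unconstrained in sign.
#'
#' @param sigma Threshold for men.
#' @param tau Threshold for women.
#' @return An object of class `thresholds`.
#' @examples
#' thresholds(0.8, 0.6)
#' @export
thresholds <- function(sigma, tau) {
  if (!(is.numeric(sigma) && length(sigma) == 1 && is.finite(sigma) &&
        is.numeric(tau) && length(tau) == 1 && is.finite(tau))) {
    abort("thresholds: `sigma` and `tau` must be finite numeric scalars.")
  }
  structure(list(sigma = sigma, tau = tau), class = "thresholds")
}

#' @export
print.thresholds <- function(x, ...) {
  cat(sprintf("Frustration thresholds: sigma (men) = %g, tau (women) = %g\n",
              x$sigma, x$tau))
  invisible(x)
}

#' Mean payoff of each cell's Moore neighbourhood
#'
#' The arithmetic mean of the eight neighbours' payoffs under toroidal
#' wrap-around; the cell's own payoff is excluded.
#'
#' @param pop A `lattice_population` (see [assign_population()]), or any tibble
#'   in the same row order with a `payoff` column.
#' @param neighbors Optional precomputed [torus_neighbors()] index (reusing it
#'   across replicates avoids rebuilding).
#' @return A numeric vector, one mean per cell, in the row order of `pop`.
#' @export
neighborhood_mean <- function(pop, neighbors = NULL) {
  nb <- neighbors_for(pop, neighbors)
  q <- pop$payoff
  if (length(q) != nrow(nb)) abort("`pop` and `neighbors` disagree in size.")
  rowSums(matrix(q[nb], ncol = 8L)) / 8
}

#' Apply the one-shot healthy-to-depressed transition rule
#'
#' All individuals start healthy; the rule is evaluated once, simultaneously,
#' for every cell (no cascade): cell *i* becomes depressed iff
#' `qbar_i - q_i > sigma` for men, `> tau` for women, with a *strict*
#' inequality (a gap exactly equal to the threshold stays healthy).
#'
#' @inheritParams neighborhood_mean
#' @param th A [thresholds()] object.
#' @return `pop` with three added columns: `nbhd_mean` (the neighbourhood mean
#'   payoff), `payoff_gap` (`nbhd_mean - payoff`) and logical `depressed`.
#' @examples
#' pop <- assign_population(population_params(n = 10), game_params(), seed = 1)
#' states <- transition_states(pop, thresholds(0.8, 0.6))
#' prevalence(states)
#' @export
transition_states <- function(pop, th, neighbors = NULL) {
  if (!inherits(th, "thresholds")) abort("`th` must be a `thresholds` object.")
  if (!all(c("gender", "payoff") %in% names(pop))) {
    abort("`pop` must have `gender` and `payoff` columns.")
  }
  qbar <- neighborhood_mean(pop, neighbors)
  gap <- qbar - pop$payoff
  cut <- ifelse(pop$gender == "male", th$sigma, th$tau)
  out <- dplyr::mutate(pop, nbhd_mean = qbar, payoff_gap = gap,
                       depressed = gap > cut)
  for (a in c("n", "pop_params", "game_params")) {
    attr(out, a) <- attr(pop, a)
  }
  out
}

#' Depression prevalence, by gender and overall
#'
#' @param pop A tibble with logical `depressed` and `gender` columns, as
#'   returned by [transition_states()].
#' @return A one-row tibble with columns `x` (overall depressed fraction),
#'   `x_male`, `x_female`, `ratio` (`x_female / x_male`; `Inf` when only women
#'   are depressed, `NA` when nobody is), `n_male`, `n_female`.
#' @export
prevalence <- function(pop) {
  if (!all(c("gender", "depressed") %in% names(pop))) {
    abort("`pop` must have `gender` and `depressed` columns; run transition_states() first.")
  }
  male <- pop$gender == "male"
  n_m <- sum(male)
  n_f <- sum(!male)
  if (n_m == 0 || n_f == 0) abort("both gender strata must be non-empty.")
  d_m <- sum(pop$depressed[male])
  d_f <- sum(pop$depressed[!male])
  x_m <- d_m / n_m
  x_f <- d_f / n_f
  ratio <- if (d_m == 0 && d_f == 0) NA_real_ else x_f / x_m
  tibble(x = (d_m + d_f) / (n_m + n_f), x_male = x_m, x_female = x_f,
         ratio = ratio, n_male = n_m, n_female = n_f)
}

#' Draw one population and measure prevalence at fixed thresholds
#'
#' Convenience wrapper: [assign_population()], [transition_states()],
#' [prevalence()].
#'
#' @inheritParams assign_population
#' @inheritParams transition_states
#' @return The one-row prevalence tibble of [prevalence()].
#' @export
simulate_prevalence <- function(pp, gp, th, seed = NULL, neighbors = NULL) {
  pop <- assign_population(pp, gp, seed = seed)
  prevalence(transition_states(pop, th, neighbors))
}
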