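#' Post-calibration ensemble of independent replicates
#'
#' Runs `eta` independent replicates at fixed thresholds: each replicate draws
#' a fresh population with its own sub-seed (derived from `seed`), applies the
#' one-shot transition rule and records prevalence. The torus neighbour index
#' is built once and shared across replicates.
#'
#' @inheritParams assign_population
#' @inheritParams transition_states
#' @param eta Number of replicates (at least 1).
#' @param seed Optional master seed; it determines every replicate bit-exactly.
#' @return An object of class `frustration_ensemble`: a list with the
#'   per-replicate tibble `replicates` (columns `replicate`, `seed`, `x`,
#'   `x_male`, `x_female`, `ratio`), the summary scalars `x_bar`, `x_sd`
#'   (`0` by convention when `eta = 1`), `x_bar_male`, `x_bar_female`, `ratio`
#'   (ratio of mean female to mean male prevalence), `mean_ratio` (mean of the
#'   finite per-replicate ratios), `eta`, and the inputs. [tidy()] returns the
#'   replicate tibble, [glance()] a one-row summary.
#' @examples
#' fs <- first_set_config()
#' ens <- run_ensemble(population_params(n = 30), fs$game, thresholds(4.75, 1.75),
#'                     eta = 10, seed = 1)
#' glance(ens)
#' @export
run_ensemble <- function(pp, gp, th, eta = 100, seed = NULL) {
  if (!(length(eta) == 1 && is.finite(eta) && eta == round(eta) && eta >= 1)) {
    abort("run_ensemble: `eta` must be a positive integer.")
  }
  if (!inherits(th, "thresholds")) abort("`th` must be a `thresholds` object.")
  nb <- torus_neighbors(pp$n)
  sub_seeds <- with_seed_if(seed, draw_subseeds(eta))
  reps <- purrr::map2_dfr(seq_len(eta), sub_seeds, function(i, s) {
    dplyr::mutate(simulate_prevalence(pp, gp, th, seed = s, neighbors = nb),
                  replicate = i, seed = s, .before = 1)
  })
  x_bar_m <- mean(reps$x_male)
  x_bar_f <- mean(reps$x_female)
  finite_ratios <- reps$ratio[is.finite(reps$ratio)]
  structure(list(
    replicates = reps,
    x_bar = mean(reps$x),
    x_sd = if (eta == 1) 0 else sd(reps$x),
    x_bar_male = x_bar_m,
    x_bar_female = x_bar_f,
    ratio = if (x_bar_m == 0 && x_bar_f == 0) NA_real_ else x_bar_f / x_bar_m,
    mean_ratio = if (length(finite_ratios) > 0) mean(finite_ratios) else NA_real_,
    eta = as.integer(eta),
    thresholds = th, pop_params = pp, game_params = gp, seed = seed
  ), class = "frustration_ensemble")
}

#' @export
print.frustration_ensemble <- function(x, ...) {
  cat(sprintf("Prevalence ensemble: eta = %d replicates, n = %d, sigma = %g, tau = %g\n",
              x$eta, x$pop_params$n, x$thresholds$sigma, x$thresholds$tau))
  cat(sprintf("  x_bar = %.4f (sd %.4f); male %.4f, female %.4f; ratio %.3f\n",
              x$x_bar, x$x_sd, x$x_bar_male, x$x_bar_female, x$ratio))
  invisible(x)
}

#' @rdname run_ensemble
#' @param x A `frustration_ensemble` object.
#' @param ... Unused.
#' @method tidy frustration_ensemble
#' @export
tidy.frustration_ensemble <- function(x, ...) x$replicates

#' @rdname run_ensemble
#' @method glance frustration_ensemble
#' @export
glance.frustration_ensemble <- function(x, ...) {
  tibble(eta = x$eta, x_bar = x$x_bar, x_sd = x$x_sd,
         x_bar_male = x$x_bar_male, x_bar_female = x$x_bar_female,
         ratio = x$ratio, mean_ratio = x$mean_ratio,
         sigma = x$thresholds$sigma, tau = x$thresholds$tau)
}
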