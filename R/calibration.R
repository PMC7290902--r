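#' Specification of the threshold-calibration loop
#'
#' @param x_o Target prevalence fraction, strictly inside `(0, 1)`.
#' @param epsilon Maximum absolute prevalence error tolerated at acceptance.
#' @param delta Adaptation step for the thresholds (positive).
#' @param sigma0,tau0 Initial thresholds.
#' @param ratio_low,ratio_high Acceptance band for the female/male prevalence
#'   ratio.
#' @param max_iterations Safety cap on calibration steps.
#' @param resample If `TRUE`, a fresh population is drawn at every iteration
#'   (sensitivity-analysis mode). The default `FALSE` draws one calibration
#'   population up front and reuses it, which makes the measured prevalence a
#'   deterministic, monotone step function of the thresholds so the loop
#'   terminates cleanly.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(x_o = 0.2, epsilon = 0.01, delta = 0.05,
                             sigma0 = 1, tau0 = 1,
                             ratio_low = 1.5, ratio_high = 3,
                             max_iterations = 1000, resample = FALSE) {
  if (!(x_o > 0 && x_o < 1)) abort("calibration_spec: `x_o` must lie in (0, 1).")
  if (!(epsilon > 0)) abort("calibration_spec: `epsilon` must be positive.")
  if (!(delta > 0)) abort("calibration_spec: `delta` must be positive.")
  if (!(ratio_low < ratio_high)) abort("calibration_spec: `ratio_low` must be below `ratio_high`.")
  if (!(max_iterations >= 1)) abort("calibration_spec: `max_iterations` must be at least 1.")
  structure(list(x_o = x_o, epsilon = epsilon, delta = delta,
                 sigma0 = sigma0, tau0 = tau0,
                 ratio_low = ratio_low, ratio_high = ratio_high,
                 max_iterations = as.integer(max_iterations),
                 resample = isTRUE(resample)),
            class = "calibration_spec")
}

#' Calibrate the frustration thresholds to a target prevalence
#'
#' Iterative corrective adaptation of `(sigma, tau)`. At step `j` the
#' prevalence `x(j)` and female/male ratio are measured on the calibration
#' population with the current thresholds, then:
#'
#' * if `x(j) - x_o > epsilon` (too much depression) both thresholds
#'   *increase* by `delta` — raising a threshold shrinks the depressed set;
#' * if `x(j) - x_o < -epsilon` both thresholds *decrease* by `delta`;
#' * once `|x(j) - x_o| <= epsilon`, the ratio is checked: below `ratio_low`,
#'   `tau` decreases by `delta` (more depressed women, higher ratio); above
#'   `ratio_high` — or undefined because no man is depressed — `tau`
#'   increases. After a `tau`-only step the prevalence criterion is
#'   re-verified on the next iteration.
#'
#' The loop stops at the first step `T` where both criteria hold, returning
#' `sigma* = sigma(T)`, `tau* = tau(T)`. Threshold values are maintained as
#' integer step counts on the `delta`-grid (`sigma0 + k * delta`), so grid
#' values are reproduced without floating-point drift. If `max_iterations` is
#' exceeded (e.g. `delta` too coarse to land inside the `epsilon` band) the
#' result is flagged `converged = FALSE` and carries the full trace.
#'
#' @inheritParams assign_population
#' @param spec A [calibration_spec()].
#' @param seed Optional integer seed controlling the calibration population
#'   (and, with `resample = TRUE`, the per-iteration redraws).
#' @return An object of class `frustration_calibration`: a list with
#'   `sigma_star`, `tau_star`, `steps` (the stopping step `T`), `converged`,
#'   `x_final`, `ratio_final`, the per-iteration `trace` tibble
#'   (`j`, `sigma`, `tau`, `x`, `x_male`, `x_female`, `ratio`, `action`), and
#'   the inputs. [tidy()] returns the trace, [glance()] a one-row summary.
#' @examples
#' fs <- first_set_config()
#' cal <- calibrate(population_params(n = 30), fs$game, fs$calibration, seed = 1)
#' glance(cal)
#' @export
calibrate <- function(pp, gp, spec = calibration_spec(), seed = NULL) {
  if (!inherits(pp, "population_params")) abort("`pp` must be a `population_params` object.")
  if (!inherits(spec, "calibration_spec")) abort("`spec` must be a `calibration_spec` object.")
  validate_game(gp)
  nb <- torus_neighbors(pp$n)

  with_seed_if(seed, {
    pop <- assign_population(pp, gp)
    male <- pop$gender == "male"
    gap <- neighborhood_mean(pop, nb) - pop$payoff
    n_m <- sum(male)
    n_f <- sum(!male)

    measure <- function(sigma, tau) {
      if (spec$resample) {
        pop <- assign_population(pp, gp)
        male <- pop$gender == "male"
        gap <- neighborhood_mean(pop, nb) - pop$payoff
      }
      d_m <- sum(gap[male] > sigma)
      d_f <- sum(gap[!male] > tau)
      c(x = (d_m + d_f) / (n_m + n_f), x_male = d_m / n_m, x_female = d_f / n_f)
    }

    k_sigma <- 0L
    k_tau <- 0L
    rows <- vector("list", spec$max_iterations + 1L)
    converged <- FALSE
    T_stop <- NA_integer_
    for (j in 0:spec$max_iterations) {
      sigma <- spec$sigma0 + spec$delta * k_sigma
      tau <- spec$tau0 + spec$delta * k_tau
      m <- measure(sigma, tau)
      ratio <- if (m[["x_male"]] == 0 && m[["x_female"]] == 0) NA_real_ else
        m[["x_female"]] / m[["x_male"]]
      ratio_ok <- !is.na(ratio) && is.finite(ratio) &&
        ratio >= spec$ratio_low && ratio <= spec$ratio_high
      err <- m[["x"]] - spec$x_o
      action <- if (abs(err) <= spec$epsilon) {
        if (ratio_ok) {
          "accept"
        } else if (is.na(ratio) || ratio > spec$ratio_high) {
          "increase_tau"
        } else {
          "decrease_tau"
        }
      } else if (err > spec$epsilon) {
        "increase_both"
      } else {
        "decrease_both"
      }
      rows[[j + 1L]] <- tibble(j = j, sigma = sigma, tau = tau,
                               x = m[["x"]], x_male = m[["x_male"]],
                               x_female = m[["x_female"]], ratio = ratio,
                               action = action)
      switch(action,
             accept = {
               converged <- TRUE
               T_stop <- j
             },
             increase_both = {
               k_sigma <- k_sigma + 1L
               k_tau <- k_tau + 1L
             },
             decrease_both = {
               k_sigma <- k_sigma - 1L
               k_tau <- k_tau - 1L
             },
             increase_tau = {
               k_tau <- k_tau + 1L
             },
             decrease_tau = {
               k_tau <- k_tau - 1L
             })
      if (converged) break
    }
    trace <- dplyr::bind_rows(rows)
    last <- trace[nrow(trace), ]
    structure(list(
      sigma_star = if (converged) last$sigma else NA_real_,
      tau_star = if (converged) last$tau else NA_real_,
      steps = T_stop,
      converged = converged,
      x_final = last$x,
      ratio_final = last$ratio,
      ratio_extension_used = any(trace$action == "increase_tau"),
      trace = trace,
      spec = spec, pop_params = pp, game_params = gp, seed = seed
    ), class = "frustration_calibration")
  })
}

#' @export
print.frustration_calibration <- function(x, ...) {
  cat("Frustration-threshold calibration\n")
  if (x$converged) {
    cat(sprintf("  converged at step T = %d: sigma* = %g, tau* = %g\n",
                x$steps, x$sigma_star, x$tau_star))
    cat(sprintf("  final prevalence x = %.4f (target %g +/- %g), ratio = %.3f\n",
                x$x_final, x$spec$x_o, x$spec$epsilon, x$ratio_final))
  } else {
    cat(sprintf("  DID NOT converge within %d iterations (delta may be too coarse for epsilon)\n",
                x$spec$max_iterations))
  }
  invisible(x)
}

#' @rdname calibrate
#' @param x A `frustration_calibration` object.
#' @param ... Unused.
#' @method tidy frustration_calibration
#' @export
tidy.frustration_calibration <- function(x, ...) x$trace

#' @rdname calibrate
#' @method glance frustration_calibration
#' @export
glance.frustration_calibration <- function(x, ...) {
  tibble(sigma_star = x$sigma_star, tau_star = x$tau_star, steps = x$steps,
         converged = x$converged, x_final = x$x_final,
         ratio_final = x$ratio_final, iterations = nrow(x$trace),
         ratio_extension_used = x$ratio_extension_used)
}
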