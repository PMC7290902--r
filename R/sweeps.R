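# Shared driver: run one ensemble per grid row. `points` must carry the
# columns rho_NE, rho_NE_S, rho_E_S and feasible; infeasible rows are kept,
# flagged, and skipped rather than dropped.
run_sweep_points <- function(points, pp, gp, th, eta, seed, swept) {
  sub_seeds <- with_seed_if(seed, draw_subseeds(nrow(points)))
  res <- purrr::pmap_dfr(
    list(seq_len(nrow(points)), sub_seeds),
    function(i, s) {
      pt <- points[i, ]
      if (!pt$feasible) {
        return(dplyr::mutate(pt, x_bar = NA_real_, x_sd = NA_real_,
                             x_bar_male = NA_real_, x_bar_female = NA_real_,
                             ratio = NA_real_, eta = NA_integer_,
                             replicates = list(NULL)))
      }
      pp_i <- population_params(n = pp$n, male_fraction = pp$male_fraction,
                                rho_NE = pt$rho_NE, rho_NE_S = pt$rho_NE_S,
                                rho_E_S = pt$rho_E_S)
      ens <- run_ensemble(pp_i, gp, th, eta = eta, seed = s)
      dplyr::mutate(pt, x_bar = ens$x_bar, x_sd = ens$x_sd,
                    x_bar_male = ens$x_bar_male, x_bar_female = ens$x_bar_female,
                    ratio = ens$ratio, eta = ens$eta,
                    replicates = list(ens$replicates))
    }
  )
  structure(res, class = c("frustration_sweep", class(res)),
            swept = swept, thresholds = th, base_pop = pp, game_params = gp,
            seed = seed)
}

feas_tol <- 1e-9

#' Sweep the successful-nonstudent fraction
#'
#' Varies `rho_NE_S` at fixed `rho_NE` (the unsuccessful-nonstudent fraction
#' `rho_NE_NS = rho_NE - rho_NE_S` adjusts) and runs an ensemble at every
#' feasible grid point. Grid values above `rho_NE` are flagged infeasible and
#' skipped, not dropped.
#'
#' @param pp Base [population_params()]; `rho_NE`, `rho_E_S`, `male_fraction`
#'   and `n` are held at these values.
#' @param gp A [game_params()] object.
#' @param th Fixed [thresholds()] (typically the first-set calibrated values;
#'   the thresholds are treated as psychological characteristics of the
#'   population and are not recalibrated per point).
#' @param grid Numeric vector of `rho_NE_S` values.
#' @param eta Replicates per grid point.
#' @param seed Optional master seed for the whole sweep.
#' @return A tibble of class `frustration_sweep`, one row per grid point, with
#'   the swept fractions, a `feasible` flag, ensemble summaries (`x_bar`,
#'   `x_sd`, `x_bar_male`, `x_bar_female`, `ratio`, `eta`) and the
#'   per-replicate tibbles in the `replicates` list-column.
#' @export
sweep_rho_ne_s <- function(pp, gp, th, grid = seq(0, pp$rho_NE, by = 0.01),
                           eta = 100, seed = NULL) {
  points <- tibble(rho_NE_S = grid, rho_NE = pp$rho_NE, rho_E_S = pp$rho_E_S,
                   feasible = grid <= pp$rho_NE + feas_tol &
                     pp$rho_E_S <= 1 - pp$rho_NE + feas_tol)
  run_sweep_points(points, pp, gp, th, eta, seed, swept = "rho_NE_S")
}

#' Sweep the successful-student fraction
#'
#' Varies `rho_E_S` at fixed `rho_E = 1 - rho_NE` (`rho_E_NS` adjusts), for
#' one or more values of `rho_NE_S`. Grid values above `1 - rho_NE` are
#' flagged infeasible (clipped), matching the absolute-fraction reading of the
#' success shares.
#'
#' @inheritParams sweep_rho_ne_s
#' @param grid Numeric vector of `rho_E_S` values.
#' @param rho_ne_s_variants Values of `rho_NE_S` for which the sweep is
#'   repeated (e.g. `0` for a learning environment with no unschooled success,
#'   `0.05` for a labour market).
#' @return As [sweep_rho_ne_s()], with an additional `rho_NE_S` column
#'   distinguishing the variants. Use [sweep_argmax()] for the per-variant
#'   location of the prevalence maximum.
#' @export
sweep_rho_e_s <- function(pp, gp, th, grid = seq(0, 1 - pp$rho_NE, by = 0.05),
                          rho_ne_s_variants = c(0, 0.05), eta = 100,
                          seed = NULL) {
  points <- tidyr::expand_grid(rho_NE_S = rho_ne_s_variants, rho_E_S = grid)
  points <- dplyr::mutate(points, rho_NE = pp$rho_NE,
                          feasible = .data$rho_E_S <= 1 - pp$rho_NE + feas_tol &
                            .data$rho_NE_S <= pp$rho_NE + feas_tol)
  run_sweep_points(points, pp, gp, th, eta, seed, swept = "rho_E_S")
}

#' Sweep the nonstudent fraction
#'
#' Varies `rho_NE` at fixed `rho_NE_S` and `rho_E_S`. Points where
#' `rho_E_S > 1 - rho_NE` or `rho_NE_S > rho_NE` are flagged infeasible.
#'
#' @inheritParams sweep_rho_ne_s
#' @param grid Numeric vector of `rho_NE` values.
#' @export
sweep_rho_ne <- function(pp, gp, th, grid = seq(0.05, 0.25, by = 0.01),
                         eta = 100, seed = NULL) {
  points <- tibble(rho_NE = grid, rho_NE_S = pp$rho_NE_S, rho_E_S = pp$rho_E_S,
                   feasible = pp$rho_E_S <= 1 - grid + feas_tol &
                     pp$rho_NE_S <= grid + feas_tol)
  run_sweep_points(points, pp, gp, th, eta, seed, swept = "rho_NE")
}

#' Full factorial sweep over the three payoff-category fractions
#'
#' Factorial grid over `rho_NE_S`, `rho_NE` and `rho_E_S`; infeasible cells
#' (`rho_NE_S > rho_NE` or `rho_E_S > 1 - rho_NE`) are flagged and skipped.
#' With the default 2.5-point resolution and `eta = 100` this is by far the
#' most expensive operation in the package; reduce `eta` or coarsen the grids
#' for exploratory runs.
#'
#' @inheritParams sweep_rho_ne_s
#' @param grid_ne_s,grid_ne,grid_e_s Numeric grids for the three fractions.
#' @return As [sweep_rho_ne_s()]. [sweep_argmax()] grouped on
#'   `c("rho_NE_S", "rho_NE")` gives, per slice, the `rho_E_S` maximising the
#'   mean prevalence.
#' @export
sweep_grid_3d <- function(pp, gp, th,
                          grid_ne_s = seq(0, 0.10, by = 0.025),
                          grid_ne = seq(0, 0.30, by = 0.025),
                          grid_e_s = seq(0, 1, by = 0.025),
                          eta = 100, seed = NULL) {
  points <- tidyr::expand_grid(rho_NE_S = grid_ne_s, rho_NE = grid_ne,
                               rho_E_S = grid_e_s)
  points <- dplyr::mutate(points,
                          feasible = .data$rho_NE_S <= .data$rho_NE + feas_tol &
                            .data$rho_E_S <= 1 - .data$rho_NE + feas_tol)
  run_sweep_points(points, pp, gp, th, eta, seed, swept = "rho_E_S")
}

#' Location of the prevalence maximum along a sweep
#'
#' @param sweep A `frustration_sweep` tibble.
#' @param by Optional grouping columns (e.g. `"rho_NE_S"` for the
#'   two-variant student-success sweep); the argmax is reported per group.
#' @return A tibble with the grouping columns, the swept value attaining the
#'   maximal `x_bar`, and that maximum.
#' @export
sweep_argmax <- function(sweep, by = NULL) {
  swept <- attr(sweep, "swept")
  dat <- dplyr::filter(sweep, .data$feasible)
  if (!is.null(by)) {
    dat <- dplyr::group_by(dat, dplyr::across(dplyr::all_of(by)))
  }
  out <- dplyr::slice_max(dat, .data$x_bar, n = 1, with_ties = FALSE)
  out <- dplyr::ungroup(out)
  dplyr::select(out, dplyr::all_of(c(by, swept)), x_bar = "x_bar")
}
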