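#' The first-set study configuration (UK young adults, 2014-16)
#'
#' The reference configuration used throughout the package: payoffs
#' `t_A = 15, t_B = 10, r_A = 9, r_B = 6, p = 1, s = -1` with kind-A fraction
#' `c = 60%`; a `100 x 100` toroidal lattice (10,000 individuals) with 49.3%
#' men and 50.7% women; nonstudent fraction `rho_NE = 18.8%`; successful
#' nonstudents `rho_NE_S = 5%` and successful students `rho_E_S = 75%` of the
#' population; calibration targeting a depression prevalence of
#' `x_o = 20%` within `epsilon = 1%` from `sigma(0) = tau(0) = 1` in steps of
#' `delta = 0.05`, with the female/male prevalence ratio required to lie in
#' `[1.5, 3.0]`.
#'
#' @param n Lattice side (default 100; reduce for quick experiments).
#' @return A list with elements `pop` ([population_params()]), `game`
#'   ([game_params()]) and `calibration` ([calibration_spec()]).
#' @examples
#' fs <- first_set_config(n = 30)
#' fs$pop
#' @export
first_set_config <- function(n = 100) {
  list(
    pop = population_params(n = n, male_fraction = 0.493, rho_NE = 0.188,
                            rho_NE_S = 0.05, rho_E_S = 0.75),
    game = game_params(t_A = 15, t_B = 10, r_A = 9, r_B = 6, p = 1, s = -1,
                       c = 0.6),
    calibration = calibration_spec(x_o = 0.2, epsilon = 0.01, delta = 0.05,
                                   sigma0 = 1, tau0 = 1,
                                   ratio_low = 1.5, ratio_high = 3)
  )
}
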