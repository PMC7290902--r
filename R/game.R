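#' Payoff parameters of the investing-in-education game
#'
#' The game is played once, "against the field": the individual chooses whether
#' to invest in a formal education (E) or not (NE), and the labour market
#' returns success (S) or nonsuccess (NS). Successful individuals earn `t`
#' (nonstudents) or `r` (students), each split into a high-earning kind A and a
#' low-earning kind B; unsuccessful individuals earn `p` (nonstudents) or `s`
#' (students) regardless of kind.
#'
#' A well-formed game satisfies the prisoner's-dilemma chain `t > r > p > s`
#' for each kind, together with `t_A > t_B` and `r_A > r_B`. The additional
#' dilemma condition `r > (t + s) / 2` is checked by
#' [check_dilemma_ordering()] and reported as a warning here, not an error,
#' so that borderline parameter sets can still be constructed and inspected.
#'
#' @param t_A,t_B Payoff of a successful nonstudent of kind A resp. B.
#' @param r_A,r_B Payoff of a successful student of kind A resp. B.
#' @param p Payoff of an unsuccessful nonstudent (any kind).
#' @param s Payoff of an unsuccessful student (any kind).
#' @param c Fraction of kind-A individuals in the population, in `[0, 1]`.
#'
#' @return An object of class `game_params`: a named list with the seven
#'   fields above.
#' @examples
#' gp <- game_params() # the default UK-2014-16 payoffs
#' check_dilemma_ordering(gp)
#' @export
game_params <- function(t_A = 15, t_B = 10, r_A = 9, r_B = 6, p = 1, s = -1,
                        c = 0.6) {
  vals <- list(t_A = t_A, t_B = t_B, r_A = r_A, r_B = r_B, p = p, s = s, c = c)
  bad <- names(vals)[!vapply(vals, function(v) is.numeric(v) && length(v) == 1 && is.finite(v), logical(1))]
  if (length(bad) > 0) {
    abort(paste0("game_params: fields must be finite numeric scalars: ",
                 paste(bad, collapse = ", ")))
  }
  if (c < 0 || c > 1) abort("game_params: `c` must lie in [0, 1].")
  gp <- structure(vals, class = "game_params")
  if (!(t_A > r_A && r_A > p && p > s && t_B > r_B && r_B > p)) {
    warn(paste0("game_params: payoff chain t > r > p > s is violated for at ",
                "least one kind; simulations will refuse these parameters."))
  } else if (!(t_A > t_B && r_A > r_B)) {
    warn("game_params: kind-A payoffs should strictly exceed kind-B payoffs.")
  } else if (!check_dilemma_ordering(gp)) {
    warn(paste0("game_params: r > (t + s)/2 fails for at least one kind; the ",
                "game is not a strict prisoner's dilemma."))
  }
  gp
}

#' @export
print.game_params <- function(x, ...) {
  cat("Investing-in-education game payoffs\n")
  cat(sprintf("  success   : t_A = %g, t_B = %g (nonstudents), r_A = %g, r_B = %g (students)\n",
              x$t_A, x$t_B, x$r_A, x$r_B))
  cat(sprintf("  nonsuccess: p = %g (nonstudents), s = %g (students)\n", x$p, x$s))
  cat(sprintf("  kind-A fraction c = %g\n", x$c))
  cat(sprintf("  dilemma ordering (incl. r > (t+s)/2): %s\n",
              if (check_dilemma_ordering(x)) "satisfied" else "VIOLATED"))
  invisible(x)
}

#' Does a payoff set satisfy the full prisoner's-dilemma ordering?
#'
#' Returns `TRUE` iff `t > r > p > s` holds for both kinds **and**
#' `r > (t + s) / 2` holds for both kinds. Simulation entry points use this
#' (via [validate_game()]) as a gate.
#'
#' @param params A [game_params()] object (or a bare named list with fields
#'   `t_A`, `t_B`, `r_A`, `r_B`, `p`, `s`).
#' @return A single logical.
#' @examples
#' check_dilemma_ordering(game_params()) # TRUE
#' @export
check_dilemma_ordering <- function(params) {
  with(params,
       isTRUE(t_A > r_A && r_A > p && p > s &&
              t_B > r_B && r_B > p &&
              r_A > (t_A + s) / 2 && r_B > (t_B + s) / 2))
}

# Gate used by simulation entry points: hard error on a broken payoff chain,
# warning only for the parenthetical dilemma condition r > (t+s)/2.
validate_game <- function(gp) {
  if (!inherits(gp, "game_params")) abort("expected a `game_params` object.")
  ok_chain <- with(gp, t_A > r_A && r_A > p && p > s && t_B > r_B && r_B > p &&
                       t_A > t_B && r_A > r_B)
  if (!ok_chain) {
    abort("payoff chain t > r > p > s (with t_A > t_B, r_A > r_B) is violated.")
  }
  if (!check_dilemma_ordering(gp)) {
    warn("r > (t + s)/2 fails for at least one kind (weak dilemma).")
  }
  invisible(gp)
}

#' Payoff earned for a strategy/outcome pair
#'
#' Deterministic, vectorised mapping from an individual's education choice,
#' labour-market outcome and kind to the payoff: `t` for (NE, S), `r` for
#' (E, S), `p` for (NE, NS) and `s` for (E, NS); the kind (A/B) only
#' differentiates the two success payoffs.
#'
#' @param education Character vector over `{"E", "NE"}`.
#' @param outcome Character vector over `{"S", "NS"}`.
#' @param kind Character vector over `{"A", "B"}`.
#' @param params A [game_params()] object.
#' @return A numeric vector of payoffs, recycled to the common length.
#' @examples
#' payoff_value("NE", "S", "A", game_params()) # 15
#' payoff_value("E", "NS", c("A", "B"), game_params()) # -1 -1
#' @export
payoff_value <- function(education, outcome, kind, params) {
  if (!all(education %in% c("E", "NE"))) {
    abort("`education` must only contain \"E\" or \"NE\".")
  }
  if (!all(outcome %in% c("S", "NS"))) {
    abort("`outcome` must only contain \"S\" or \"NS\".")
  }
  if (!all(kind %in% c("A", "B"))) {
    abort("`kind` must only contain \"A\" or \"B\".")
  }
  nn <- max(length(education), length(outcome), length(kind))
  education <- rep_len(education, nn)
  outcome <- rep_len(outcome, nn)
  kind <- rep_len(kind, nn)
  out <- numeric(nn)
  succ <- outcome == "S"
  stud <- education == "E"
  a <- kind == "A"
  out[succ & !stud & a] <- params$t_A
  out[succ & !stud & !a] <- params$t_B
  out[succ & stud & a] <- params$r_A
  out[succ & stud & !a] <- params$r_B
  out[!succ & !stud] <- params$p
  out[!succ & stud] <- params$s
  out
}
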