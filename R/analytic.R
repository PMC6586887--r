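# Closed-form survival probabilities.  The suicidal strategy decomposes
# into scenario products built from geometric series over rounds in which
# every shot misses; the abstention strategy reduces to a B-first duel
# between B and C followed by a duel in which A shoots first.  Both are
# cross-validated against the exact Markov-chain solver in the test suite.

#' Double geometric series
#'
#' Evaluates \deqn{\sum_{n=0}^{\infty} y^n \sum_{k=0}^{n} x^k =
#' \frac{1}{1-x}\left(\frac{1}{1-y} - \frac{x}{1-xy}\right),}
#' the series that arises when a player must die to his own shot in some
#' round no later than the round in which the surviving opponent lands the
#' decisive shot.
#'
#' @param x,y series ratios in \eqn{[0, 1)}.
#' @return The value of the double series.
#' @examples
#' double_geometric_sum(0, 0.5)    # plain geometric series: 2
#' double_geometric_sum(0.5, 0.5)  # 8/3
#' @export
double_geometric_sum <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == 1L, length(y) == 1L)
  if (x < 0 || y < 0) stop("'x' and 'y' must be non-negative", call. = FALSE)
  if (x >= 1 || y >= 1)
    stop("series diverges: 'x' and 'y' must be < 1", call. = FALSE)
  (1 / (1 - y) - x / (1 - x * y)) / (1 - x)
}

# Truncated evaluation of the same series; retained as an internal oracle
# for the closed form (tolerance-driven, hard cap on terms).
.double_geometric_trunc <- function(x, y, tol = 1e-12, max_terms = 10000L) {
  total <- 0
  inner <- 0
  ypow <- 1
  xpow <- 1
  for (n in 0:max_terms) {
    if (n > 0) {
      xpow <- xpow * x
      ypow <- ypow * y
    }
    inner <- inner + xpow          # sum_{k=0}^{n} x^k
    term <- ypow * inner
    total <- total + term
    if (term < tol && n > 0) break
  }
  total
}

#' Scenario probabilities for the suicidal strategy
#'
#' While all three players are alive under the suicidal strategy, each
#' round consists of A firing at himself (hit probability \eqn{a}), B
#' firing at C and C firing at B.  The three-alive phase ends in one of
#' three ways, and each opening is followed by a duel:
#' \describe{
#'   \item{\code{s_a1}}{A survives his own shot and B kills C, leaving an
#'     A-versus-B duel with A shooting first;}
#'   \item{\code{s_a2}}{A wins that duel;}
#'   \item{\code{s_a3}}{A survives his own shot, B misses, and C kills B,
#'     leaving an A-versus-C duel with A shooting first;}
#'   \item{\code{s_a4}}{A wins that duel;}
#'   \item{\code{s_b3}}{A dies by his own shot and B kills C in the ensuing
#'     B-first duel;}
#'   \item{\code{s_c3}}{A dies by his own shot and C kills B in that duel.}
#' }
#' With complements \eqn{\bar a = 1-a} etc., the openings are geometric:
#' \eqn{s_{a1} = \bar a b / (1 - \bar a \bar b \bar c)},
#' \eqn{s_{a2} = a / (1 - \bar a \bar b)},
#' \eqn{s_{a3} = \bar a \bar b c / (1 - \bar a \bar b \bar c)},
#' \eqn{s_{a4} = a / (1 - \bar a \bar c)}, and \eqn{s_{b3}, s_{c3}} involve
#' the double series of [double_geometric_sum()].
#'
#' @inheritParams truel
#' @return Named list with components \code{s_a1}, \code{s_a2}, \code{s_a3},
#'   \code{s_a4}, \code{s_b3}, \code{s_c3}, all probabilities.
#' @examples
#' scenario_probs_suicidal(0.3, 0.5, 1.0)
#' @export
scenario_probs_suicidal <- function(a, b, c) {
  m <- validate_marksmanship(a, b, c)
  a <- m[[1L]]; b <- m[[2L]]; c <- m[[3L]]
  ab <- 1 - a; bb <- 1 - b; cb <- 1 - c
  d3 <- 1 - ab * bb * cb   # > 0 since c > 0
  s_a1 <- ab * b / d3
  s_a3 <- ab * bb * c / d3
  # duel conditionals; the A-vs-B duel is unreachable when a = b = 0 (its
  # geometric denominator vanishes), so its conditional is set to 0 there
  s_a2 <- if (a == 0 && b == 0) 0 else a / (1 - ab * bb)
  s_a4 <- a / (1 - ab * cb)   # denominator >= c > 0
  if (a == 0) {
    s_b3 <- 0
    s_c3 <- 0
  } else {
    D <- double_geometric_sum(ab, bb * cb)
    s_b3 <- a * b * D
    s_c3 <- a * bb * c * D
  }
  list(s_a1 = s_a1, s_a2 = s_a2, s_a3 = s_a3, s_a4 = s_a4,
       s_b3 = s_b3, s_c3 = s_c3)
}

#' Closed-form survival under the suicidal strategy
#'
#' Combines the scenario probabilities of [scenario_probs_suicidal()] into
#' the survival distribution:
#' \deqn{P_A = s_{a1} s_{a2} + s_{a3} s_{a4}, \quad
#'       P_B = s_{a1}(1 - s_{a2}) + s_{b3}, \quad
#'       P_C = s_{a3}(1 - s_{a4}) + s_{c3}.}
#' The scenario-product form is used throughout; an algebraically factored
#' variant of \eqn{P_A} sometimes quoted for this game replaces the factor
#' \eqn{\bar b} by \eqn{\bar a} in its second summand and does not match
#' the exact chain (see the test suite).
#'
#' @inheritParams truel
#' @return Named numeric vector \code{c(A =, B =, C =)} summing to 1.
#' @examples
#' survival_suicidal(0.3, 0.5, 1.0)
#' exact_survival(truel(0.3, 0.5, 1.0, strategy = "suicide"))  # identical
#' @export
survival_suicidal <- function(a, b, c) {
  s <- scenario_probs_suicidal(a, b, c)
  c(A = s$s_a1 * s$s_a2 + s$s_a3 * s$s_a4,
    B = s$s_a1 * (1 - s$s_a2) + s$s_b3,
    C = s$s_a3 * (1 - s$s_a4) + s$s_c3)
}

#' Closed-form survival under the abstention strategy
#'
#' When A fires into the air while both opponents are alive, B and C fight
#' a duel in which B shoots first (winning with probability
#' \eqn{W = b / (1 - \bar b \bar c)}); A then enters a duel against the
#' winner as first shooter.  Hence
#' \deqn{P_A = W\, d(a, b) + (1 - W)\, d(a, c),}
#' with \eqn{d} the first-shooter duel win probability of
#' [duel_first_shooter_win()], and \eqn{P_B = W (1 - d(a, b))},
#' \eqn{P_C = (1 - W)(1 - d(a, c))}.
#'
#' @inheritParams truel
#' @return Named numeric vector \code{c(A =, B =, C =)} summing to 1.
#' @examples
#' survival_abstention(0.3, 0.5, 1.0)
#' @export
survival_abstention <- function(a, b, c) {
  m <- validate_marksmanship(a, b, c)
  a <- m[[1L]]; b <- m[[2L]]; c <- m[[3L]]
  W <- b / (1 - (1 - b) * (1 - c))   # denominator >= c > 0
  d_ab <- if (W > 0) duel_first_shooter_win(a, b) else 0
  d_ac <- if (W < 1) duel_first_shooter_win(a, c) else 0
  c(A = W * d_ab + (1 - W) * d_ac,
    B = W * (1 - d_ab),
    C = (1 - W) * (1 - d_ac))
}

#' Survival when A targets the middle player B
#'
#' Survival distribution when A fires at B while all three players are
#' alive (computed with the exact solver; no simple closed form is needed).
#' When \eqn{c = 1} this strategy gives A exactly the same survival
#' probability as the suicidal strategy: in either case A survives only if
#' he reaches the second round with C already dead, because a live C — a
#' perfect shot once B is gone — would kill A immediately.
#'
#' @inheritParams truel
#' @return Named numeric vector \code{c(A =, B =, C =)} summing to 1.
#' @examples
#' survival_target_b(0.3, 0.5, 1.0)["A"] == survival_suicidal(0.3, 0.5, 1.0)["A"]
#' @export
survival_target_b <- function(a, b, c) {
  exact_survival(truel(a, b, c, strategy = "target_b"))
}
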