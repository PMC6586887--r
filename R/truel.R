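#' Sequential three-player truels
#'
#' A sequential truel is a shooting contest between three players A, B and C
#' with marksmanship (single-shot hit probabilities) \eqn{0 \le a \le b \le c
#' \le 1}.  Players fire one shot each in alphabetic order, skipping dead
#' players, until a single survivor remains.  While all three are alive, B and
#' C always target their strongest live opponent (B fires at C, C fires at B);
#' the weakest player A follows one of seven strategies.  Once only one
#' opponent remains, every strategy collapses to firing at that opponent.
#'
#' @details
#' Available strategies for player A while both opponents are alive:
#' \describe{
#'   \item{\code{"strongest"}}{fire at C, the strongest opponent.}
#'   \item{\code{"abstain"}}{fire into the air (a guaranteed miss).}
#'   \item{\code{"suicide"}}{fire at himself, hitting with probability
#'     \eqn{a}.}
#'   \item{\code{"target_b"}}{fire at B, the middle player.}
#'   \item{\code{"random2"}}{pick the target uniformly between B and C.}
#'   \item{\code{"random3"}}{pick the target uniformly among A (self), B
#'     and C.}
#'   \item{\code{"switch_suicide_air"}}{each turn, independently fire at
#'     himself with probability \code{switch_prob} and into the air
#'     otherwise.}
#' }
#'
#' @param a,b,c hit probabilities of players A, B and C.  Must satisfy
#'   \eqn{0 \le a \le b \le c \le 1} and \eqn{c > 0} (with \eqn{a = b = c =
#'   0} no shot could ever land and the game would never end).
#' @param strategy strategy used by player A while both opponents are alive;
#'   see Details.
#' @param switch_prob per-turn probability of choosing suicide over
#'   abstention; used only by \code{"switch_suicide_air"}.
#' @return An object of class \code{"truel"}: a list with components
#'   \code{marksmanship} (named numeric vector \code{c(a =, b =, c =)}),
#'   \code{strategy} and \code{switch_prob}.
#' @seealso [exact_survival()], [simulate.truel()], [survival_suicidal()],
#'   [truel_sweep()]
#' @examples
#' x <- truel(0.3, 0.5, 1.0, strategy = "suicide")
#' exact_survival(x)
#' summary(truel(0.3, 0.5, 1.0, strategy = "abstain"))
#' @export
truel <- function(a, b, c, strategy = truel_strategies(), switch_prob = 0.5) {
  strategy <- match.arg(strategy)
  m <- validate_marksmanship(a, b, c)
  if (!is.numeric(switch_prob) || length(switch_prob) != 1L ||
      !is.finite(switch_prob) || switch_prob < 0 || switch_prob > 1)
    stop("'switch_prob' must be a single probability in [0, 1]", call. = FALSE)
  structure(
    list(marksmanship = m, strategy = strategy, switch_prob = switch_prob),
    class = "truel"
  )
}

#' Strategy names for player A
#'
#' @return Character vector of the seven supported strategy names, in the
#'   package's canonical order.
#' @examples
#' truel_strategies()
#' @export
truel_strategies <- function() {
  c("strongest", "abstain", "suicide", "target_b",
    "random2", "random3", "switch_suicide_air")
}

#' Validate a marksmanship triple
#'
#' Checks the standing assumption \eqn{0 \le a \le b \le c \le 1} and the
#' termination requirement \eqn{c > 0}.  If all three marksmanships were
#' zero, no shot could ever land and the truel would continue forever.
#'
#' @inheritParams truel
#' @return The validated triple as a named numeric vector
#'   \code{c(a =, b =, c =)}.
#' @examples
#' validate_marksmanship(0.3, 0.5, 1.0)
#' @export
validate_marksmanship <- function(a, b, c) {
  for (nm in c("a", "b", "c")) {
    v <- get(nm, inherits = FALSE)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    if (v < 0 || v > 1)
      stop(sprintf("'%s' must lie in [0, 1] (got %g)", nm, v), call. = FALSE)
  }
  if (a > b)
    stop(sprintf("marksmanship ordering violated: a <= b required (a = %g, b = %g)",
                 a, b), call. = FALSE)
  if (b > c)
    stop(sprintf("marksmanship ordering violated: b <= c required (b = %g, c = %g)",
                 b, c), call. = FALSE)
  if (c == 0)
    stop("non-terminating game: c = 0 (with a = b = c = 0 no shot can ever land)",
         call. = FALSE)
  c(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c))
}

#' @export
print.truel <- function(x, ...) {
  m <- x$marksmanship
  cat("Sequential truel\n")
  cat(sprintf("  marksmanship: a = %g, b = %g, c = %g\n", m[1L], m[2L], m[3L]))
  if (x$strategy == "switch_suicide_air")
    cat(sprintf("  strategy of A: %s (switch_prob = %g)\n",
                x$strategy, x$switch_prob))
  else
    cat(sprintf("  strategy of A: %s\n", x$strategy))
  cat("  B and C target the strongest live opponent\n")
  invisible(x)
}

#' @export
coef.truel <- function(object, ...) object$marksmanship

#' Summarise a truel
#'
#' Computes the exact survival distribution via the absorbing-Markov-chain
#' solver and, where a closed form is implemented (suicidal and abstention
#' strategies), the matching analytic values.
#'
#' @param object a [truel] object.
#' @param ... unused.
#' @return An object of class \code{"summary.truel"}.
#' @export
summary.truel <- function(object, ...) {
  exact <- exact_survival(object)
  m <- object$marksmanship
  analytic <- switch(object$strategy,
    suicide = survival_suicidal(m[1L], m[2L], m[3L]),
    abstain = survival_abstention(m[1L], m[2L], m[3L]),
    NULL)
  structure(list(truel = object, exact = exact, analytic = analytic),
            class = "summary.truel")
}

#' @export
print.summary.truel <- function(x, ...) {
  print(x$truel)
  cat("\nExact survival probabilities (absorbing Markov chain):\n")
  print(round(x$exact, 6L))
  if (!is.null(x$analytic)) {
    cat("Closed-form survival probabilities:\n")
    print(round(x$analytic, 6L))
  }
  invisible(x)
}
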