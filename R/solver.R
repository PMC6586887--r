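# Exact solver for the sequential truel, treated as a finite absorbing
# Markov chain on states (set of live players, player about to shoot).
# Players are coded 1 = A, 2 = B, 3 = C internally; live sets are bitmasks
# (bit 1 = A, bit 2 = B, bit 3 = C), so the full game has at most nine
# transient states and three absorbing single-survivor states.

.PLAYERS <- c("A", "B", "C")

.mask_has <- function(mask, p) bitwAnd(mask, bitwShiftL(1L, p - 1L)) != 0L

.mask_drop <- function(mask, p) bitwAnd(mask, bitwNot(bitwShiftL(1L, p - 1L)))

.popcount3 <- function(mask) {
  (bitwAnd(mask, 1L) != 0L) + (bitwAnd(mask, 2L) != 0L) + (bitwAnd(mask, 4L) != 0L)
}

# First live player strictly after p in the cycle A -> B -> C -> A.
# p itself need not be alive (it may just have shot itself).
.next_alive <- function(mask, p) {
  for (k in 1:3) {
    q <- (p + k - 1L) %% 3L + 1L
    if (.mask_has(mask, q)) return(q)
  }
  stop("no live player in state", call. = FALSE)
}

# Per-turn target mass for `shooter` in live set `mask`, as a length-4
# numeric: index 1 = air, indices 2:4 = players A, B, C (mass on the
# shooter's own index means suicide).  Strategies only apply while both
# opponents are alive; with a single opponent left every player targets it.
.target_probs <- function(strategy, switch_prob, shooter, mask) {
  w <- numeric(4L)
  opp <- setdiff(1:3, shooter)
  opp <- opp[vapply(opp, function(p) .mask_has(mask, p), logical(1L))]
  if (length(opp) == 0L)
    stop("shooter has no live opponent", call. = FALSE)
  if (length(opp) == 1L) {
    w[opp + 1L] <- 1
    return(w)
  }
  if (shooter == 2L) {           # B fires at C, the strongest opponent
    w[4L] <- 1
  } else if (shooter == 3L) {    # C fires at B, the strongest opponent
    w[3L] <- 1
  } else {
    switch(strategy,
      strongest = { w[4L] <- 1 },
      abstain   = { w[1L] <- 1 },
      suicide   = { w[2L] <- 1 },
      target_b  = { w[3L] <- 1 },
      random2   = { w[3L] <- 0.5; w[4L] <- 0.5 },
      random3   = { w[2L] <- 1 / 3; w[3L] <- 1 / 3; w[4L] <- 1 / 3 },
      switch_suicide_air = { w[2L] <- switch_prob; w[1L] <- 1 - switch_prob },
      stop(sprintf("unknown strategy '%s'", strategy), call. = FALSE)
    )
  }
  w
}

.as_player_id <- function(p) {
  i <- match(p, .PLAYERS)
  if (is.na(i)) stop(sprintf("unknown player '%s'", p), call. = FALSE)
  i
}

.as_mask <- function(alive) {
  idx <- match(alive, .PLAYERS)
  if (anyNA(idx) || anyDuplicated(idx))
    stop("'alive' must be a subset of c(\"A\", \"B\", \"C\") without duplicates",
         call. = FALSE)
  sum(bitwShiftL(1L, idx - 1L))
}

#' Next shooter in the firing cycle
#'
#' Players fire in the cyclic alphabetic order A, B, C, skipping dead
#' players.  Given the set of live players and the player who has just
#' fired, returns the next player to shoot.
#'
#' @param alive character vector, a subset of \code{c("A", "B", "C")} with at
#'   least two members.
#' @param turn the player who has just fired; must be in \code{alive}.
#' @return A single player id, \code{"A"}, \code{"B"} or \code{"C"}.
#' @examples
#' next_shooter(c("A", "B", "C"), "A")  # "B"
#' next_shooter(c("A", "B"), "B")       # "A", C is skipped
#' @export
next_shooter <- function(alive, turn) {
  mask <- .as_mask(alive)
  p <- .as_player_id(turn)
  if (!.mask_has(mask, p))
    stop("'turn' must be one of the live players", call. = FALSE)
  if (.popcount3(mask) < 2L)
    stop("absorbing state: a single survivor has no next shooter", call. = FALSE)
  .PLAYERS[.next_alive(mask, p)]
}

#' Per-turn target distribution
#'
#' The probability mass a shooter places on each possible target under the
#' game rules: B and C always fire at their strongest live opponent, player
#' A follows the strategy stored in \code{x}, and every player fires at the
#' sole remaining opponent once the truel has become a duel.  Firing into
#' the air is a guaranteed miss; a shot at oneself hits with the shooter's
#' own marksmanship.
#'
#' @param x a [truel] object.
#' @param shooter the player about to fire (\code{"A"}, \code{"B"} or
#'   \code{"C"}).
#' @param alive character vector of live players; must contain
#'   \code{shooter} and at least one opponent.
#' @return Named numeric vector \code{c(self =, A =, B =, C =, air =)}
#'   summing to 1; the \code{self} component carries any mass the shooter
#'   places on himself, so the \code{A}/\code{B}/\code{C} components refer
#'   to opponents only.
#' @examples
#' x <- truel(0.3, 0.5, 1.0, strategy = "suicide")
#' target_distribution(x, "A", c("A", "B", "C"))  # all mass on self
#' target_distribution(x, "A", c("A", "C"))       # all mass on C
#' @export
target_distribution <- function(x, shooter, alive) {
  stopifnot(inherits(x, "truel"))
  mask <- .as_mask(alive)
  p <- .as_player_id(shooter)
  if (!.mask_has(mask, p))
    stop("shooter must be alive", call. = FALSE)
  w <- .target_probs(x$strategy, x$switch_prob, p, mask)
  out <- c(self = w[p + 1L], A = w[2L], B = w[3L], C = w[4L], air = w[1L])
  out[p + 1L] <- 0   # shooter's own slot is reported as 'self'
  out
}

#' Win probability of the first shooter in an alternating duel
#'
#' In a two-player duel where shots alternate, the player who fires first
#' with hit probability \code{p_first} against an opponent with hit
#' probability \code{p_second} survives with probability
#' \deqn{\frac{p_1}{1 - (1 - p_1)(1 - p_2)},}
#' the sum of the geometric series over rounds in which both players miss.
#'
#' @param p_first,p_second hit probabilities in \eqn{[0, 1]}; they must not
#'   both be zero, or neither player could ever win.
#' @return The first shooter's survival probability.
#' @examples
#' duel_first_shooter_win(0.5, 0.5)  # 2/3: the first shot is an advantage
#' @export
duel_first_shooter_win <- function(p_first, p_second) {
  stopifnot(is.numeric(p_first), is.numeric(p_second),
            p_first >= 0, p_first <= 1, p_second >= 0, p_second <= 1)
  if (p_first == 0 && p_second == 0)
    stop("non-terminating duel: both hit probabilities are zero", call. = FALSE)
  p_first / (1 - (1 - p_first) * (1 - p_second))
}

#' Exact survival probabilities
#'
#' Solves the sequential truel exactly by enumerating the reachable
#' (live-set, shooter) states, assembling the one-step transition law from
#' each shooter's target distribution and marksmanship, and solving the
#' linear system for the absorption probabilities into the three
#' single-survivor states.  This is the package's reference solver: the
#' closed forms and the Monte Carlo simulator are validated against it.
#'
#' @param x a [truel] object.
#' @return Named numeric vector \code{c(A =, B =, C =)} of survival
#'   probabilities, summing to 1 (within 1e-12).
#' @examples
#' exact_survival(truel(0.3, 0.5, 1.0, strategy = "suicide"))
#' exact_survival(truel(1, 1, 1, strategy = "abstain"))  # A survives surely
#' @export
exact_survival <- function(x) {
  stopifnot(inherits(x, "truel"))
  m <- unname(x$marksmanship)

  # breadth-first enumeration of reachable transient states from
  # (all alive, A to shoot)
  key <- function(mask, p) (mask - 1L) * 3L + p
  id_of <- rep(NA_integer_, 21L)
  st_mask <- integer(0L)
  st_turn <- integer(0L)
  queue <- list(c(7L, 1L))
  id_of[key(7L, 1L)] <- 1L
  st_mask[1L] <- 7L
  st_turn[1L] <- 1L
  trans <- list()   # per state: list of c(to_id_or_-survivor, prob)

  while (length(queue)) {
    st <- queue[[1L]]
    queue <- queue[-1L]
    mask <- st[1L]; p <- st[2L]
    i <- id_of[key(mask, p)]
    w <- .target_probs(x$strategy, x$switch_prob, p, mask)
    h <- m[p]
    edges <- list()
    add_edge <- function(mask2, p_from, prob) {
      if (prob <= 0) return(invisible())
      if (.popcount3(mask2) == 1L) {
        surv <- .next_alive(mask2, 0L)  # the single live player
        edges[[length(edges) + 1L]] <<- c(-surv, prob)
        return(invisible())
      }
      nxt <- .next_alive(mask2, p_from)
      k <- key(mask2, nxt)
      if (is.na(id_of[k])) {
        j <- length(st_mask) + 1L
        id_of[k] <<- j
        st_mask[j] <<- mask2
        st_turn[j] <<- nxt
        queue[[length(queue) + 1L]] <<- c(mask2, nxt)
      }
      edges[[length(edges) + 1L]] <<- c(id_of[k], prob)
    }
    # air shot or any miss: same live set, next shooter
    p_stay <- w[1L] + (1 - h) * (w[2L] + w[3L] + w[4L])
    add_edge(mask, p, p_stay)
    for (t in 1:3) {
      ph <- w[t + 1L] * h
      if (ph > 0) add_edge(.mask_drop(mask, t), p, ph)
    }
    trans[[i]] <- edges
  }

  ns <- length(st_mask)
  Q <- matrix(0, ns, ns)
  R <- matrix(0, ns, 3L)
  for (i in seq_len(ns)) {
    for (e in trans[[i]]) {
      if (e[1L] < 0) R[i, -e[1L]] <- R[i, -e[1L]] + e[2L]
      else Q[i, e[1L]] <- Q[i, e[1L]] + e[2L]
    }
  }
  sol <- tryCatch(solve(diag(ns) - Q, R),
                  error = function(e)
                    stop("non-terminating game: the truel has a recurrent class with no exit",
                         call. = FALSE))
  res <- sol[1L, ]
  if (abs(sum(res) - 1) > 1e-9)
    stop("non-terminating game: absorption probabilities do not sum to 1",
         call. = FALSE)
  names(res) <- .PLAYERS
  res
}
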