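# Monte Carlo replay of the sequential truel.  `play_one` is a literal
# turn-by-turn game loop used as a readable reference; `simulate.truel`
# runs all games simultaneously with vectorised per-turn updates so the
# paper-scale protocol (one million rounds per parameter combination) is
# feasible in plain R.

#' Play a single truel
#'
#' Simulates one game turn by turn using the current RNG stream: each turn
#' the shooter's target is sampled from [target_distribution()] and the
#' shot lands with the shooter's marksmanship (shots into the air always
#' miss).  Use [simulate.truel()] for estimation runs.
#'
#' @param x a [truel] object.
#' @param max_shots guard against non-termination (unreachable for valid
#'   marksmanship); exceeding it is an error.
#' @return The survivor, \code{"A"}, \code{"B"} or \code{"C"}.
#' @examples
#' set.seed(1)
#' play_one(truel(0.3, 0.5, 1.0, strategy = "suicide"))
#' @export
play_one <- function(x, max_shots = 1e6) {
  stopifnot(inherits(x, "truel"))
  m <- x$marksmanship
  alive <- c("A", "B", "C")
  turn <- "A"
  shots <- 0L
  while (length(alive) > 1L) {
    shots <- shots + 1L
    if (shots > max_shots)
      stop("shot cap exceeded: game did not terminate", call. = FALSE)
    w <- target_distribution(x, turn, alive)
    pick <- sample(names(w), 1L, prob = w)
    if (pick == "self") pick <- turn
    hit <- pick != "air" && stats::runif(1L) < m[[.as_player_id(turn)]]
    prev <- turn
    if (hit) alive <- setdiff(alive, pick)
    if (length(alive) > 1L) {
      # next live player after the shooter, whether or not he survived
      idx <- .as_player_id(prev)
      repeat {
        idx <- idx %% 3L + 1L
        if (.PLAYERS[idx] %in% alive) break
      }
      turn <- .PLAYERS[idx]
    }
  }
  alive
}

# Vectorised target choice for shooter s over the rows of `al` (an n x 3
# logical matrix of live players, shooter alive in every row, >= 2 alive).
# Returns an integer vector: 0 = air, 1..3 = targeted player.
.pick_targets_vec <- function(strategy, switch_prob, s, al) {
  n <- nrow(al)
  others <- setdiff(1:3, s)
  o1 <- others[1L]; o2 <- others[2L]
  a1 <- al[, o1]; a2 <- al[, o2]
  both <- a1 & a2
  tgt <- integer(n)
  tgt[!both] <- ifelse(a1[!both], o1, o2)     # duel: the sole live opponent
  k <- sum(both)
  if (k > 0L) {
    t3 <- if (s == 2L) rep.int(3L, k)         # B fires at C
      else if (s == 3L) rep.int(2L, k)        # C fires at B
      else switch(strategy,
        strongest = rep.int(3L, k),
        abstain   = rep.int(0L, k),
        suicide   = rep.int(1L, k),
        target_b  = rep.int(2L, k),
        random2   = ifelse(stats::runif(k) < 0.5, 2L, 3L),
        random3   = sample.int(3L, k, replace = TRUE),
        switch_suicide_air = ifelse(stats::runif(k) < switch_prob, 1L, 0L),
        stop(sprintf("unknown strategy '%s'", strategy), call. = FALSE))
    tgt[both] <- t3
  }
  tgt
}

# Next live player after shooter s, vectorised over rows of `al`
# (each row has >= 2 live players).
.next_alive_vec <- function(s, al) {
  c1 <- s %% 3L + 1L
  c2 <- c1 %% 3L + 1L
  ifelse(al[, c1], c1, c2)
}

.sim_engine <- function(m, strategy, switch_prob, n, max_shots) {
  alive <- matrix(TRUE, n, 3L)
  turn <- rep.int(1L, n)
  winner <- integer(n)
  shots <- integer(n)
  active <- seq_len(n)
  it <- 0L
  while (length(active)) {
    it <- it + 1L
    if (it > max_shots)
      stop("shot cap exceeded: some games did not terminate", call. = FALSE)
    shots[active] <- it
    cur <- turn[active]
    finished <- logical(length(active))
    for (s in 1:3) {
      rel <- which(cur == s)
      if (!length(rel)) next
      j <- active[rel]
      al <- alive[j, , drop = FALSE]
      tgt <- .pick_targets_vec(strategy, switch_prob, s, al)
      hit <- logical(length(j))
      real <- tgt > 0L
      if (any(real)) hit[real] <- stats::runif(sum(real)) < m[s]
      if (any(hit)) {
        alive[cbind(j[hit], tgt[hit])] <- FALSE
        al <- alive[j, , drop = FALSE]
      }
      done <- rowSums(al) == 1L
      if (any(done)) {
        winner[j[done]] <- max.col(al[done, , drop = FALSE], ties.method = "first")
        finished[rel[done]] <- TRUE
      }
      if (any(!done))
        turn[j[!done]] <- .next_alive_vec(s, al[!done, , drop = FALSE])
    }
    active <- active[!finished]
  }
  list(winner = winner, max_shots_hit = if (n) max(shots) else 0L)
}

#' Monte Carlo estimation of survival probabilities
#'
#' Replays \code{nsim} independent truels and returns the empirical
#' survival distribution with binomial standard errors.  Results are
#' bit-reproducible for a given \code{(object, nsim, seed)}.  The default
#' \code{nsim} matches the one-million-rounds protocol used for the
#' published winner-region maps; tests and interactive exploration should
#' use far fewer.
#'
#' @param object a [truel] object.
#' @param nsim number of games (positive integer).
#' @param seed integer seed for the simulation stream.  If \code{NULL}, a
#'   seed is drawn (and reported in the result); either way the caller's
#'   RNG state is restored afterwards.
#' @param max_shots per-game shot cap guarding against non-termination.
#' @param ... unused.
#' @return An object of class \code{"truel_sim"}: a list with \code{wins}
#'   (named counts), \code{n}, \code{estimates}, \code{std_errors}
#'   (\eqn{\sqrt{\hat p (1 - \hat p) / n}}), \code{seed} and
#'   \code{max_shots_hit} (the longest game observed, in shots).
#' @examples
#' x <- truel(0.3, 0.5, 1.0, strategy = "suicide")
#' sim <- simulate(x, nsim = 10000, seed = 42)
#' sim
#' exact_survival(x)
#' @export
simulate.truel <- function(object, nsim = 1e6, seed = NULL, max_shots = 1e6, ...) {
  stopifnot(inherits(object, "truel"))
  if (!is.numeric(nsim) || length(nsim) != 1L || is.na(nsim) || nsim < 1)
    stop("'nsim' must be a positive integer", call. = FALSE)
  n <- as.integer(nsim)

  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  if (is.null(seed)) {
    if (!has_seed) stats::runif(1L)
    seed <- sample.int(.Machine$integer.max, 1L)
  }
  seed <- as.integer(seed)
  set.seed(seed)

  eng <- .sim_engine(unname(object$marksmanship), object$strategy,
                     object$switch_prob, n, max_shots)
  wins <- tabulate(eng$winner, nbins = 3L)
  names(wins) <- .PLAYERS
  est <- wins / n
  structure(
    list(wins = wins, n = n, estimates = est,
         std_errors = sqrt(est * (1 - est) / n),
         seed = seed, max_shots_hit = eng$max_shots_hit,
         truel = object),
    class = "truel_sim"
  )
}

#' @export
print.truel_sim <- function(x, ...) {
  cat(sprintf("Monte Carlo truel: %d games (seed %d), longest game %d shots\n",
              x$n, x$seed, x$max_shots_hit))
  tab <- rbind(wins = x$wins,
               estimate = round(x$estimates, 5L),
               std_error = signif(x$std_errors, 3L))
  print(tab)
  invisible(x)
}
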