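test_that("marksmanship validation enforces ordering and termination", {
  expect_equal(unname(validate_marksmanship(0.3, 0.5, 1.0)), c(0.3, 0.5, 1.0))
  expect_equal(unname(validate_marksmanship(0, 0, 0.2)), c(0, 0, 0.2))
  expect_error(validate_marksmanship(0.5, 0.3, 1.0), "a <= b")
  expect_error(validate_marksmanship(0.1, 0.9, 0.5), "b <= c")
  expect_error(validate_marksmanship(0, 0, 0), "non-terminating")
  expect_error(validate_marksmanship(-0.1, 0.5, 1.0), "\\[0, 1\\]")
  expect_error(validate_marksmanship(0.2, 0.5, 1.2), "\\[0, 1\\]")
  expect_error(truel(0.3, 0.5, 1, switch_prob = 2), "switch_prob")
})

test_that("firing order cycles alphabetically and skips the dead", {
  expect_identical(next_shooter(c("A", "B", "C"), "A"), "B")
  expect_identical(next_shooter(c("A", "B", "C"), "C"), "A")
  expect_identical(next_shooter(c("A", "B"), "B"), "A")
  expect_identical(next_shooter(c("A", "C"), "A"), "C")
  expect_error(next_shooter("A", "A"), "absorbing")
  expect_error(next_shooter(c("A", "B"), "C"), "live")

  # repeated application visits exactly the live players, in cyclic
  # alphabetic order, for every live set of size >= 2
  for (alive in list(c("A", "B"), c("A", "C"), c("B", "C"), c("A", "B", "C"))) {
    start <- alive[1L]
    seen <- start
    cur <- start
    for (k in seq_len(2L * length(alive))) {
      cur <- next_shooter(alive, cur)
      seen <- c(seen, cur)
    }
    # the visit sequence is the live players repeated in order
    expect_identical(unique(seen), alive)
    expect_identical(seen[seq_along(alive)],
                     seen[seq_along(alive) + length(alive)])
  }
})

test_that("target distributions follow the strategy table", {
  trio <- c("A", "B", "C")
  m <- c(0.3, 0.5, 1.0)
  # B and C always fire at the strongest live opponent
  x <- truel(m[1], m[2], m[3], "strongest")
  expect_equal(target_distribution(x, "B", trio)[["C"]], 1)
  expect_equal(target_distribution(x, "C", trio)[["B"]], 1)

  # A while both opponents are alive, per strategy
  pick <- function(s, ...) target_distribution(truel(m[1], m[2], m[3], s, ...), "A", trio)
  expect_equal(pick("strongest")[["C"]], 1)
  expect_equal(pick("abstain")[["air"]], 1)
  expect_equal(pick("suicide")[["self"]], 1)
  expect_equal(pick("target_b")[["B"]], 1)
  expect_equal(unname(pick("random2")[c("B", "C")]), c(0.5, 0.5))
  expect_equal(unname(pick("random3")[c("self", "B", "C")]), rep(1 / 3, 3L))
  sw <- pick("switch_suicide_air", switch_prob = 0.25)
  expect_equal(unname(sw[c("self", "air")]), c(0.25, 0.75))

  # collapse: with a single opponent left, all mass goes to that opponent
  for (s in all_strategies) {
    x <- truel(m[1], m[2], m[3], s)
    expect_equal(target_distribution(x, "A", c("A", "C"))[["C"]], 1)
    expect_equal(target_distribution(x, "A", c("A", "B"))[["B"]], 1)
    expect_equal(target_distribution(x, "C", c("A", "C"))[["A"]], 1)
  }

  # masses are a probability distribution with nothing on dead players
  for (s in all_strategies) {
    x <- truel(0.2, 0.6, 0.9, s)
    for (alive in list(trio, c("A", "B"), c("B", "C"))) {
      for (sh in alive) {
        w <- target_distribution(x, sh, alive)
        expect_true(all(w >= 0))
        expect_equal(sum(w), 1)
        dead <- setdiff(c("A", "B", "C"), alive)
        if (length(dead)) expect_true(all(w[dead] == 0))
      }
    }
  }
})

test_that("first-shooter duel win probability matches the geometric series", {
  expect_equal(duel_first_shooter_win(1.0, 0.4), 1.0)
  expect_equal(duel_first_shooter_win(0.0, 0.4), 0.0)
  # independent oracle: sum over rounds where both players miss
  series <- sum(0.5 * (0.5 * 0.5)^(0:200))
  expect_equal(duel_first_shooter_win(0.5, 0.5), series, tolerance = 1e-12)
  expect_equal(duel_first_shooter_win(0.5, 0.5), 2 / 3, tolerance = 1e-15)
  expect_error(duel_first_shooter_win(0, 0), "non-terminating")

  # monotone: non-decreasing in own marksmanship, non-increasing in the
  # opponent's
  grid <- seq(0.05, 1, by = 0.05)
  for (p2 in grid) {
    v <- vapply(grid, duel_first_shooter_win, numeric(1L), p_second = p2)
    expect_true(all(diff(v) >= 0))
  }
  for (p1 in grid) {
    v <- vapply(grid, function(q) duel_first_shooter_win(p1, q), numeric(1L))
    expect_true(all(diff(v) <= 0))
  }
})

test_that("exact solver reproduces deterministic traces", {
  # with perfect marksmanship every game is a forced line of play
  expect_equal(exact_survival(truel(1, 1, 1, "strongest")), c(A = 0, B = 1, C = 0))
  expect_equal(exact_survival(truel(1, 1, 1, "abstain")), c(A = 1, B = 0, C = 0))
  expect_equal(exact_survival(truel(1, 1, 1, "suicide")), c(A = 0, B = 1, C = 0))
  # A kills B, then C (a perfect shot) kills A
  expect_equal(exact_survival(truel(1, 1, 1, "target_b")), c(A = 0, B = 0, C = 1))
})

test_that("exact solver matches the hand-computed chain decomposition", {
  # (a, b, c) = (0.3, 0.5, 1): the three-alive phase ends in one round
  # (c = 1 kills B unless B killed C or A killed himself first), so the
  # absorption probabilities are a short sum of duel products:
  #   A suicides:              0.3        -> B beats C (B first): 1/2 each
  #   A misses, B kills C:     0.7 * 0.5  -> A-vs-B duel, A first
  #   A misses, B misses, C kills B: 0.35 -> A-vs-C duel, A first
  p_ab <- 0.3 / (1 - 0.7 * 0.5)
  p_ac <- 0.3
  expected <- c(A = 0.35 * p_ab + 0.35 * p_ac,
                B = 0.3 * 0.5 + 0.35 * (1 - p_ab),
                C = 0.3 * 0.5 + 0.35 * (1 - p_ac))
  got <- exact_survival(truel(0.3, 0.5, 1.0, "suicide"))
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(unname(got[["A"]]), 0.2665384615384615, tolerance = 1e-12)
})

test_that("survival probabilities conserve mass across strategies", {
  set.seed(101)
  for (i in 1:200) {
    m <- rand_marksmanship()
    for (s in all_strategies) {
      p <- exact_survival(truel(m[1], m[2], m[3], s))
      expect_true(abs(sum(p) - 1) < 1e-12)
      expect_true(all(p >= 0 & p <= 1))
    }
  }
})

test_that("solver sub-games reduce to the duel formula", {
  # when a = 0 player A is harmless: under the suicidal strategy the game
  # is just the B-versus-C duel with B shooting first, and A can never win
  # the final duel either
  set.seed(11)
  for (i in 1:20) {
    bc <- sort(stats::runif(2L, min = 0.05))
    p <- exact_survival(truel(0, bc[1], bc[2], "suicide"))
    expect_equal(p[["A"]], 0)
    expect_equal(p[["B"]], duel_first_shooter_win(bc[1], bc[2]),
                 tolerance = 1e-12)
    expect_equal(p[["C"]], 1 - duel_first_shooter_win(bc[1], bc[2]),
                 tolerance = 1e-12)
  }
})
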