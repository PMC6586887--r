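---
title: "Sequential truels: model, closed forms and numerical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential truels: model, closed forms and numerical design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(truel)
```

## The game

A sequential truel is a shooting contest between players A, B and C with
marksmanship $0 \le a \le b \le c \le 1$: each shot hits its chosen target
with the shooter's marksmanship, independently of everything else. Players
fire one shot each in the cyclic alphabetic order A, B, C, skipping dead
players, until a single survivor remains. The model's standing assumptions
are:

* marksmanship is independent of the target — in particular a shot at
  oneself hits with the shooter's own marksmanship, and a shot into the
  air never hits anything;
* while all three players are alive, B and C fire at their strongest live
  opponent (B at C, C at B), and are not configurable;
* once only one opponent is left, *every* player fires at that opponent —
  the exotic behaviours (suicide, abstention, random choice) are defined
  only for the three-alive phase;
* $c > 0$ is required: if no player could ever hit anything the game
  would never end. Any triple with $c > 0$ terminates with probability 1,
  because in every state some reachable shot can land (the absorbing-chain
  structure below makes this an assertion the solver actually checks).

The interesting question is what the weakest player A should do with his
turn. Because B and C fight each other first, A is effectively granted a
bye into an alternating two-player duel in which he shoots first, and the
first shot is valuable: the first shooter with hit probability $p_1$
against $p_2$ wins with probability
$$d(p_1, p_2) = \frac{p_1}{1 - (1-p_1)(1-p_2)},$$
the geometric sum over rounds in which both players miss
(`duel_first_shooter_win()`). This is why counterintuitive strategies —
deliberately wasting the shot, or even firing at oneself — can be
rational for A: the worst thing A can do early is *win* the wrong duel.

## Exact solver

The game is a finite absorbing Markov chain on states
$(\text{live set}, \text{shooter})$: at most nine transient states and
three absorbing single-survivor states. `exact_survival()` enumerates the
states reachable from (all alive, A shoots), builds the one-step
transition law from each shooter's target distribution
(`target_distribution()`) and marksmanship, and solves
$(I - Q)\,X = R$ for the absorption probabilities, reporting the row of
the initial state. The solver is the package's reference: the closed
forms and the simulator are validated against it, never the other way
around. A singular system (possible only for inputs that bypass
validation, such as $c = 0$) is reported as a non-termination error, and
the absorption row is checked to sum to 1.

One rule deserves emphasis because everything downstream depends on it:
after a death **the cycle continues from the shooter's position**. When B
or C fires the fatal shot of the three-alive phase, the next live player
in cycle order is A — so A enters the ensuing duel as first shooter,
which is exactly what makes his weakness survivable.

## Closed forms for the suicidal strategy

With A firing at himself while both opponents live, a full round is
A (self, $a$), B (at C, $b$), C (at B, $c$), and the three-alive phase
ends in one of three ways. Writing $\bar a = 1-a$ etc., the geometric
recursion "either it happens this round or everyone misses and we
restart" gives the opening probabilities
$$s_{a1} = \frac{\bar a\, b}{1 - \bar a \bar b \bar c}, \qquad
  s_{a3} = \frac{\bar a\, \bar b\, c}{1 - \bar a \bar b \bar c},$$
(A survives himself and B kills C; A survives himself, B misses, C kills
B), each followed by a duel that A starts:
$$s_{a2} = \frac{a}{1 - \bar a \bar b}, \qquad
  s_{a4} = \frac{a}{1 - \bar a \bar c},$$
so that $P_A = s_{a1} s_{a2} + s_{a3} s_{a4}$. The remaining mass is the
event that A dies by his own hand while both opponents live; B then
beats C in a B-first duel with the double-series probability
$$s_{b3} = a\,b \sum_{n=0}^{\infty} (\bar b \bar c)^n \sum_{k=0}^{n} \bar a^k,
  \qquad
  s_{c3} = a\,\bar b\, c \sum_{n=0}^{\infty} (\bar b \bar c)^n \sum_{k=0}^{n} \bar a^k,$$
and $P_B = s_{a1}(1 - s_{a2}) + s_{b3}$,
$P_C = s_{a3}(1 - s_{a4}) + s_{c3}$.

`double_geometric_sum()` evaluates the double series in closed form,
$$\sum_{n\ge 0} y^n \sum_{k=0}^{n} x^k
  = \frac{1}{1-x}\left(\frac{1}{1-y} - \frac{x}{1-xy}\right),$$
valid for $0 \le x, y < 1$; a tolerance-driven partial-sum evaluation is
kept as an internal oracle. Note the truncation tail is geometric,
$y^{N+1}/((1-y)(1-x))$: near $x = y = 0.9$ several hundred terms are
needed before a $10^{-12}$ comparison against the closed form is
meaningful, which is why the tests use a 2000-term oracle.

**A caution about the factored form.** Multiplying out
$P_A = s_{a1}s_{a2} + s_{a3}s_{a4}$ gives
$$P_A = \frac{a \bar a}{1 - \bar a \bar b \bar c}
  \left(\frac{b}{1 - \bar a \bar b} + \frac{\bar b c}{1 - \bar a \bar c}\right),$$
but a factored variant in circulation for this game has $\bar a c$ in
place of $\bar b c$ in the second summand. The two agree only on the
diagonal $a = b$; off it the variant disagrees with the exact chain (at
$(0.3, 0.5, 1)$ it gives $0.3085$ against the true $0.26654$). The
package implements the scenario-product form, and the test suite pins the
variant's deviation down so the discrepancy stays documented.

**Degenerate corners.** When $a = b = 0$ the A-versus-B duel is
unreachable and its conditional $s_{a2}$ has a vanishing denominator; it
is defined as 0 there (A could never win that duel anyway), which keeps
the closed form equal to the solver at every valid triple, including
$(0, 0, c)$. When $a = 0$ the "A dead by his own hand" scenarios carry no
mass and the double series (whose $x$-ratio would be $\bar a = 1$) is
never evaluated.

## Abstention, and targeting B

No bespoke algebra is needed for abstention: with A firing into the air,
the three-alive phase is simply a B-versus-C duel with B shooting first,
won by B with probability $W = d(b, c) = b/(1 - \bar b \bar c)$, after
which A duels the winner as first shooter:
$$P_A = W\, d(a, b) + (1 - W)\, d(a, c), \quad
  P_B = W\,(1 - d(a, b)), \quad P_C = (1 - W)(1 - d(a, c)).$$

`survival_target_b()` (A fires at B while all live) is computed with the
exact solver. At $c = 1$ it gives A *exactly* the suicidal survival
probability: with a perfect C on the board, A's survival requires
reaching the endgame with C already dead, and both "A hits himself" and
"A hits B" (after which C immediately kills A) remove A's chances in the
same way. The equivalence holds cell-for-cell at $10^{-10}$ across the
sweep grid and breaks for $c < 1$, both asserted in the tests.

## Monte Carlo simulator

`simulate()` replays the game rules literally: sample the shooter's
target from `target_distribution()`, then a Bernoulli hit with the
shooter's marksmanship. Design choices:

* **RNG.** One Mersenne–Twister stream seeded once per run (`set.seed`),
  consumed in a fixed serial order by a vectorised engine that advances
  all pending games one shot per pass. Results are bit-reproducible for a
  given `(truel, nsim, seed)`; the caller's RNG state is saved and
  restored, following `stats::simulate()` conventions. Per-game
  substreams were considered and rejected: the package never executes
  games in parallel, so a single stream gives the same guarantee with
  less machinery.
* **Shot cap.** A per-game cap (default $10^6$) guards against
  non-termination; it is unreachable for validated inputs, since the
  probability a game survives $k$ full rounds decays geometrically. The
  longest game actually observed is reported (`max_shots_hit`).
* **Scale.** The default `nsim` is $10^6$, matching the protocol used for
  the published region maps; the tests run at $10^4$–$10^5$ so the suite
  stays desk-scale. At $n = 10^5$ the binomial standard error is at most
  $\approx 0.0016$, which is why the concentration tests use a
  $4\,\mathrm{SE}$ band around the exact values (false-alarm probability
  well under $10^{-3}$ across the suite).
* `play_one()` is a deliberately naive scalar implementation of the same
  rules, kept as a readable reference and cross-checked statistically
  against the solver — a third, independent route to the same numbers.

What the simulator does *not* emulate: the game model itself is the
stated world (independent Bernoulli shots, fixed turn order, fixed B/C
behaviour). There is no real data behind it, so a green test establishes
internal consistency of the three routes and the qualitative claims below
— not anything about empirical contests.

## Winner-region sweeps

`truel_sweep()` evaluates the survival distribution on the lattice
$\{0, s, 2s, \dots, 1\}^2$ restricted to $a \le b$ (and $b \le c$; cells
violating the ordering are skipped with a warning when $c < 1$), then
labels each cell with the player whose survival probability is the
*strict* argmax. Numerical choices:

* **Ties.** A cell is labelled `TIE` when the top two probabilities are
  within `tie_tol` (default $10^{-12}$ for the exact method, 0 for Monte
  Carlo) rather than crowning an arbitrary winner; exact ties do occur,
  e.g. at isolated boundary cells.
* **Resolution.** The published maps use step 0.001 with $10^6$ Monte
  Carlo rounds per cell; the package's default is step 0.02 with the
  exact solver (1,326 cells, a few seconds), which reproduces every
  qualitative claim. The full 0.001 grid ($\approx 5\times10^5$ cells)
  remains reachable through the same interface.
* **Grid arithmetic.** Lattice values come from `seq()` and carry
  $\sim\!10^{-16}$ rounding noise; cells are clamped ($b$ to $c$, $a$ to
  $b$) before validation so diagonal cells are not spuriously rejected.

The claims the acceptance tests pin down, all at $c = 1$, step 0.02,
exact method: the suicidal strategy leaves A no winning cell; so does the
three-way random strategy; the two-opponent random strategy leaves a
small A region (7 cells, far fewer than B's); abstention's A region (547
cells) dwarfs strongest-opponent targeting's (64); and the per-turn
random switch between suicide and abstention restores a large A region
(281 cells at `switch_prob = 0.5`).

**Open interpretation, resolved.** Two points the model statement leaves
open were decided as follows. (i) The random strategies choose among
*players* only — `random2` between B and C, `random3` among A, B, C — and
never the air; that is the literal reading of "randomly between/among".
(ii) The suicide/abstention switch is an independent fair coin per A-turn
(`switch_prob = 0.5`, exposed as a parameter), the minimal reading of
"randomly switches between the two strategies"; a per-game switch would
instead mix the two survival distributions, which at $c=1$ would inherit
part of the suicide strategy's empty region — the per-turn reading is
both simpler and strictly a new strategy rather than a mixture.

## Limitations

* B's and C's behaviour is fixed at strongest-opponent targeting; the
  package does not search for equilibria or let B/C strategise.
* Marksmanship is target-independent: suicide uses the same hit
  probability as an aimed shot. Decoupling the two is a natural extension
  the data structures would support, but it is out of scope.
* Exactly three players, sequential fire; no simultaneous-fire or
  $n$-player variants.
* Closed forms are provided for the suicidal and abstention strategies
  only; the random and switch strategies are handled by the exact solver
  (their closed forms would be routine but add nothing the solver does
  not already give at machine precision).
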