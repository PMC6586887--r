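# truel

Survival analysis for the **sequential truel**: a three-player
generalisation of the duel in which players A, B and C — with single-shot
hit probabilities ("marksmanship") 0 ≤ *a* ≤ *b* ≤ *c* ≤ 1 — fire one shot
each in alphabetic order, skipping the dead, until a single survivor
remains. Truels are a standard toy model for three-way conflict in game
theory, ecology and the social sciences, famous for "survival of the
weakest": the best shot does not necessarily have the best chance of
living.

While all three players are alive, B and C behave rationally and fire at
their strongest live opponent (B at C, C at B). The package studies what
the *weakest* player A should do with his turn, under seven strategies:

| strategy             | A's action while both opponents live            |
|----------------------|-------------------------------------------------|
| `strongest`          | fire at C                                       |
| `abstain`            | fire into the air (a guaranteed miss)           |
| `suicide`            | fire at himself (hits with probability *a*)     |
| `target_b`           | fire at B                                       |
| `random2`            | fire at B or C, uniformly                       |
| `random3`            | fire at himself, B or C, uniformly              |
| `switch_suicide_air` | per turn: suicide w.p. `switch_prob`, else air  |

Once only one opponent remains, every strategy collapses to firing at that
opponent; the survivor of the opening phase then meets A in an alternating
duel, where shooting first is an advantage: the first shooter with hit
probability *p₁* against *p₂* wins with probability

    p₁ / (1 − (1 − p₁)(1 − p₂)).

Three routes to the same numbers are provided and cross-validated:

* **exact**: the game is a finite absorbing Markov chain on
  (live set, shooter) states; `exact_survival()` solves the linear system
  for the absorption probabilities (`A`, `B`, `C` single-survivor states).
* **closed form**: geometric-series expressions for the suicidal strategy
  (`survival_suicidal()`, via scenario probabilities such as
  s_A1 = āb / (1 − āb̄c̄) with ā = 1 − a, and the double series
  Σₙ yⁿ Σ_{k≤n} xᵏ of `double_geometric_sum()`) and for abstention
  (`survival_abstention()`).
* **Monte Carlo**: a seeded, bit-reproducible simulator
  (`simulate()` on a `truel` object; `play_one()` for a single game).

`truel_sweep()` maps the (a, b) parameter triangle at fixed c and labels
each cell with the player holding the strictly highest survival
probability, reproducing the published winner-region results: abstention
dramatically enlarges A's winning region relative to strongest-opponent
play; pure suicide leaves A *no* winning region (at c = 1 it is exactly
equivalent to targeting B, for A); randomly mixing suicide with abstention
restores a sizeable region; random targeting of the two opponents leaves a
small region that vanishes once suicide is added to the random menu.

## Worked example

```r
library(truel)

x <- truel(0.3, 0.5, 1.0, strategy = "suicide")
exact_survival(x)
#>         A         B         C
#> 0.2665385 0.3384615 0.3950000

survival_suicidal(0.3, 0.5, 1.0)   # closed form, identical
#>         A         B         C
#> 0.2665385 0.3384615 0.3950000

simulate(x, nsim = 1e5, seed = 42)
#> Monte Carlo truel: 100000 games (seed 42), longest game 28 shots
#>                    A          B          C
#> wins      2.6872e+04 3.3972e+04 3.9156e+04
#> estimate  2.6872e-01 3.3972e-01 3.9156e-01
#> std_error 1.4000e-03 1.5000e-03 1.5400e-03
```

So the suicidal marksman survives 26.7% of games — better than his raw 30%
marksmanship would suggest in this company, but *worse* than abstaining
(`survival_abstention(0.3, 0.5, 1)` gives A 38.1%), and never the best of
the three:

```r
region_summary(truel_sweep("suicide", c = 1, step = 0.02))
#> Winner regions: strategy suicide, c = 1, step = 0.02, method exact
#>   1326 cells: A 0 (0.0%), B 954 (71.9%), C 371 (28.0%), ties 1

region_summary(truel_sweep("switch_suicide_air", c = 1, step = 0.02))
#> Winner regions: strategy switch_suicide_air, c = 1, step = 0.02, method exact
#>   1326 cells: A 281 (21.2%), B 700 (52.8%), C 343 (25.9%), ties 2
```

`plot()` on a sweep draws the winner map; `write_sweep_csv()` /
`read_sweep_csv()` round-trip the grid.

## Command line

`exec/truel` exposes the same operations as subcommands:

```sh
truel exact --strategy suicide -a 0.3 -b 0.5 -c 1 --format json
truel simulate --strategy abstain -a 0.3 -b 0.5 -c 1 -n 100000 --seed 7
truel sweep --strategy random2 --step 0.02 --out grid.csv
truel compare --strategy1 strongest --strategy2 abstain --step 0.02
```

Flags can also come from a JSON `--config` file (flags win); logs go to
standard error.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computations from
scratch — the exact solver and closed forms at a reference triple, a
seeded Monte Carlo run, and the six winner-region sweeps at c = 1 — and
writes its results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

See `vignettes/truel-methods.Rmd` for the model, the closed-form
derivations and the package's numerical design choices.
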