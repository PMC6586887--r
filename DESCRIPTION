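Package: truel
Title: Survival Analysis for Sequential Three-Player Truels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the sequential truel, a three-player
    generalisation of the duel in which players fire one shot each in
    alphabetic order, skipping the dead, until one survives.  Provides an
    exact absorbing-Markov-chain solver for the survival probabilities of
    all three players under seven strategies for the weakest player
    (strongest-opponent, abstention, suicidal, targeting the middle player,
    two random-target strategies, and a random switch between suicide and
    abstention), closed-form geometric-series expressions for the suicidal
    and abstention strategies, a seeded Monte Carlo simulator, and
    parameter-space sweeps that map the regions of marksmanship space in
    which each player has the highest probability of survival.  A
    command-line interface (exec/truel) exposes the same operations from
    the shell.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: graphics, grDevices, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
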