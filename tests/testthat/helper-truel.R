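# Shared fixtures: random valid marksmanship triples and strategy lists.

# Sorting three uniforms gives 0 <= a <= b <= c <= 1 with c > 0 a.s.
rand_marksmanship <- function() sort(stats::runif(3L))

all_strategies <- truel::truel_strategies()

# Independent truncated evaluation of sum_n y^n sum_{k<=n} x^k, used as
# the oracle for the closed-form double geometric series.  The default
# term count makes the geometric tail negligible (< 1e-13) everywhere on
# the tested grid x, y <= 0.9.
partial_double_sum <- function(x, y, terms = 2000L) {
  total <- 0
  for (n in 0:terms) total <- total + y^n * sum(x^(0:n))
  total
}
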