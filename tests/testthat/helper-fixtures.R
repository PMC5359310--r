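# Shared fixtures: built in code, deterministic.

# constant, benign forcing (all runs growable under the reference
# calibration); factors well inside (0, 1)
constant_forcing <- function(years = 48:188, T_C = 15, Q1 = 1200,
                             Cg = 350) {
  forcing_series(data.frame(year = years, T = T_C, Q1 = Q1, Cg = Cg))
}

# a tree_state shorthand
st <- function(r, h, S = 0.2) tree_state(r, h, S)

# parameters for which the closed-form sink-limited solution is exact:
# height limit effectively removed, apical meristem term negligible
analytic_params <- function(alpha2 = 0.34) {
  tree_params(h2 = 1e8, t_ratio = 1e9, alpha2 = alpha2)
}
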