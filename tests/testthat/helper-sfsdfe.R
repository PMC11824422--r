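# Shared fixtures, all built in code.

# Random coalescent tree with reproducible topology/branch lengths.
make_test_tree <- function(n_tips, seed = 42) {
  set.seed(seed)
  ape::rcoal(n_tips, tip.label = sprintf("sp%02d", seq_len(n_tips)))
}

# Equilibrium scenario with ~5,000 expected synonymous SNPs at n = 14.
default_scenario <- function(...) {
  sim_scenario(...)
}

# Noise-free folded SFS from an expected spectrum.
sfs_from_expected <- function(e, n, L = 1e6,
                              class = "synonymous", ...) {
  folded_sfs(e, n = n, L = L, class = class, ...)
}

# theta_s giving a target expected number of segregating sites under a
# demography at sample size n.
theta_for_S <- function(model, n, S) {
  S / sum(expected_neutral_sfs(model, n))
}

# Equilibrium demographic model carrying a fitted theta_s, for DFE tests.
equilibrium_demog <- function(theta_s, n = 14L) {
  m <- demographic_model(1)
  m$theta_s <- theta_s
  m$n <- n
  m
}
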