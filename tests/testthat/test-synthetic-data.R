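# Generators: determinism contracts, Poisson mean identities, and the
# within-host pileup model against exact binomial-tail oracles.

test_that("SFS count simulation is a pure function of (parameters, seed)", {
  sc <- sim_scenario(seed = 7)
  a <- simulate_sfs_counts(sc, "syn")
  b <- simulate_sfs_counts(sc, "syn")
  expect_identical(a, b)
  sc2 <- sim_scenario(seed = 8)
  expect_false(identical(simulate_sfs_counts(sc2, "syn")$counts, a$counts))
  # named substreams: the pileup stream does not perturb the SFS stream
  p <- simulate_host_pileup(sim_scenario(seed = 7, genome_length = 2000,
                                         theta_s = 50))
  expect_identical(simulate_sfs_counts(sc, "syn"), a)
  expect_identical(
    simulate_host_pileup(sim_scenario(seed = 7, genome_length = 2000,
                                      theta_s = 50)),
    p)
})

test_that("per-bin counts are Poisson draws around the model expectation", {
  # theta chosen so the expected folded singleton bin is exactly 100
  e1 <- expected_neutral_sfs(demographic_model(1), 14)[1]
  theta <- 100 / e1
  sims <- vapply(1:200, function(s) {
    simulate_sfs_counts(sim_scenario(theta_s = theta, seed = s),
                        "syn")$counts[1]
  }, 0)
  se <- sqrt(100 / 200)
  expect_lt(abs(mean(sims) - 100), 3 * se)
})

test_that("total segregating sites match the quadrature oracle (GOF)", {
  # Oracle: summed expectation from the stationary PRF quadrature, not the
  # engine used by the generator.
  theta <- 1500
  oracle_total <- theta * sum(prf_quadrature_sfs(0, 14)$expectation)
  totals <- vapply(1:500, function(s) {
    sum(simulate_sfs_counts(sim_scenario(theta_s = theta, seed = s),
                            "syn")$counts)
  }, 0)
  # Poisson dispersion goodness-of-fit against mean = oracle_total
  X <- sum((totals - oracle_total)^2 / oracle_total)
  p <- pchisq(X, df = length(totals), lower.tail = FALSE)
  expect_gt(p, 0.01)
  expect_lt(abs(mean(totals) - oracle_total),
            3 * sqrt(oracle_total / 500))
})

test_that("nonsynonymous simulation without a DFE errors", {
  sc <- sim_scenario(dfe = NULL)
  expect_error(simulate_sfs_counts(sc, "nonsyn"), "DFE")
})

test_that("pure single-strain hosts quasi-phase to the truth haplotype", {
  sc <- sim_scenario(n_hosts = 8, genome_length = 5000, theta_s = 400,
                     strain_major_fraction = 1.0, depth_mean = 100,
                     seed = 3)
  pile <- simulate_host_pileup(sc)
  truth <- attr(pile, "truth")
  for (h in rownames(truth$dominant)) {
    qp <- call_quasi_phased(pile[pile$host == h])
    called <- !is.na(qp$allele)
    expect_gt(mean(called), 0.95)  # only low-depth sites are missing
    expect_identical(qp$allele[called],
                     unname(truth$dominant[h, qp$pos0[called] + 1]))
  }
})

test_that("the missing band matches the exact binomial tail oracle", {
  f <- 0.9
  sc <- sim_scenario(n_hosts = 10, genome_length = 30000, theta_s = 3000,
                     strain_major_fraction = f, depth_mean = 50, seed = 11)
  pile <- simulate_host_pileup(sc)
  truth <- attr(pile, "truth")
  # strain-divergent sites: the dominant and secondary strain disagree, so
  # the read mixture sits at f; a site is missing when the majority count
  # k (of depth d) falls strictly inside (0.2 d, 0.8 d).
  seg <- which(truth$pop_minor_count > 0)
  pile_df <- as.data.frame(pile)
  rows <- pile_df[pile_df$pos0 %in% (seg - 1) & pile_df$depth >= 20, ]
  dom <- truth$dominant[cbind(match(rows$host, rownames(truth$dominant)), rows$pos0 + 1)]
  m <- truth$pop_minor_count[rows$pos0 + 1]
  # Exact oracle, marginalizing over the secondary strain and the emitted
  # depth: the pair is strain-divergent with probability m/H (dominant
  # carries "0") or 1 - m/H (dominant carries "1"), and a divergent pair
  # is missing when the majority read count k of depth d falls strictly
  # inside (0.2 d, 0.8 d) with k ~ Binom(d, f); concordant pairs sit at
  # mixture frequency 0 or 1 and essentially never miss.
  p_div <- ifelse(dom == "1", 1 - m / sc$n_hosts, m / sc$n_hosts)
  d <- rows$depth
  p_miss_div <- pbinom(ceiling(0.8 * d) - 1, d, f) -
    pbinom(floor(0.2 * d), d, f)
  p_hat <- p_div * p_miss_div
  obs_missing <- rows$major_freq < 0.8
  expect_lt(abs(mean(obs_missing) - mean(p_hat)),
            3 * sqrt(sum(p_hat * (1 - p_hat))) / length(p_hat))
})

test_that("a 60/40 strain mixture loses most divergent sites", {
  sc <- sim_scenario(n_hosts = 10, genome_length = 20000, theta_s = 2000,
                     strain_major_fraction = 0.6, depth_mean = 50,
                     seed = 5)
  pile <- simulate_host_pileup(sc)
  truth <- attr(pile, "truth")
  seg <- which(truth$pop_minor_count > 0)
  pile_df <- as.data.frame(pile[pile$pos0 %in% (seg - 1) & pile$depth >= 20])
  m <- truth$pop_minor_count[pile_df$pos0 + 1]
  p_div <- 2 * (m / sc$n_hosts) * (1 - m / sc$n_hosts)
  # fraction missing must exceed half the divergence rate: almost every
  # divergent site falls in the 0.5-0.8 band at f = 0.6
  expect_gt(mean(pile_df$major_freq < 0.8), 0.8 * mean(p_div))
})

test_that("depth_mean below 1 is rejected", {
  expect_error(simulate_host_pileup(sim_scenario(depth_mean = 0.5)),
               "depth_mean")
})

test_that("BM trait simulation: determinism, star-tree error, lambda = 0", {
  tr <- make_test_tree(5)
  expect_identical(simulate_bm_traits(tr, 1, 1, seed = 2),
                   simulate_bm_traits(tr, 1, 1, seed = 2))
  star <- ape::stree(5)
  star$edge.length <- rep(1, nrow(star$edge))
  expect_error(simulate_bm_traits(star, 0.5, 1, 1), "star")
  reps <- sapply(1:300, function(s) simulate_bm_traits(tr, 0, 1, seed = s))
  cc <- stats::cor(t(reps))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.25)
})
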