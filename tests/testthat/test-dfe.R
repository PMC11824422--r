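# Selected-spectrum engine, DFE mixture integration, Poisson likelihood
# and DFE fitting.

test_that("poisson_loglik arithmetic, zero cases and the MLE multiplier", {
  expect_equal(poisson_loglik(c(2, 1), c(2, 1)), 2 * log(2) - log(2) - 3,
               tolerance = 1e-10)
  e <- c(3.2, 1.5, 0.7)
  expect_equal(poisson_loglik(c(0, 0, 0), e), -sum(e))
  expect_warning(val <- poisson_loglik(c(1, 0), c(0, 2)), "-Inf")
  expect_identical(val, -Inf)
  # LL over a scalar multiplier of expected peaks at sum(x)/sum(e)
  x <- c(12.5, 6, 3, 1.25)
  e <- c(10, 5, 2, 1)
  cgrid <- seq(0.5, 2.5, by = 1e-4)
  lls <- vapply(cgrid, function(cc) poisson_loglik(x, cc * e), 0)
  expect_equal(cgrid[which.max(lls)], sum(x) / sum(e), tolerance = 1e-3)
})

test_that("the selected engine reduces to the neutral engine at gamma = 0", {
  for (model in list(demographic_model(1),
                     demographic_model(c(1, 0.2), 0.05),
                     demographic_model(c(1, 3), 0.1))) {
    neu <- expected_neutral_sfs(model, 14)
    sel <- expected_selected_sfs(model, 0, 14)
    expect_lt(max(abs(sel - neu) / neu), 1e-3)
  }
})

test_that("equilibrium selected spectra match the PRF quadrature oracle", {
  m <- demographic_model(1)
  for (g in c(-1, -5)) {
    eng <- expected_selected_sfs(m, g, 14)
    ora <- prf_quadrature_sfs(g, 14)$expectation
    expect_lt(max(abs(eng - ora) / ora), 1e-2)
  }
})

test_that("stronger purifying selection depresses every bin", {
  m <- demographic_model(1)
  gam <- c(0, -1, -2, -5, -10, -20, -50)
  E <- sapply(gam, function(g) expected_selected_sfs(m, g, 14))
  for (j in 2:length(gam)) {
    expect_true(all(E[, j] <= E[, j - 1] + 1e-10))
  }
  # proportional deficit grows with frequency
  ratio <- E[, 4] / E[, 1]
  expect_true(all(diff(ratio) < 0))
})

test_that("gamma <= 0 is enforced and numerics failures are named", {
  expect_error(expected_selected_sfs(demographic_model(1), 0.5, 14),
               "deleterious")
})

test_that("DFE mixture limits: all-neutral and point-mass", {
  m <- demographic_model(1)
  cache <- new_spectrum_cache()
  # p_neu = 1: exactly theta_ns times the neutral spectrum
  dfe1 <- dfe_model("neu_gamma", shape = 0.5, scale = 0.1, p_neu = 1,
                    N_anc_ref = 1e4)
  e <- expected_sfs_under_dfe(m, dfe1, theta_ns = 500, n = 14,
                              cache = cache)
  expect_equal(e, 500 * expected_selected_sfs(m, 0, 14, cache = cache),
               tolerance = 1e-12)
  # near-degenerate gamma at fixed mean ~ point mass at that gamma; the
  # coefficient of variation 1/sqrt(shape) must be small enough that the
  # curvature of E[X | gamma] across the spike is negligible, and the
  # integration grid fine enough to resolve it (node spacing < sd of
  # log s ~ 1/sqrt(shape))
  N <- 1e4
  s0 <- 1e-3                      # gamma = 2*N*s0 = 20
  dfe2 <- dfe_model("gamma", shape = 1e4, scale = s0 / 1e4,
                    N_anc_ref = N)
  grid <- dfe_gamma_grid(n_nodes = 300, gamma_min = 10, gamma_max = 40)
  e2 <- expected_sfs_under_dfe(m, dfe2, theta_ns = 1, n = 14,
                               gamma_grid = grid, cache = cache)
  point <- expected_selected_sfs(m, -2 * N * s0, 14, cache = cache)
  expect_lt(max(abs(e2 - point) / point), 1e-2)
})

test_that("the mixture quadrature is grid-converged", {
  m <- demographic_model(1)
  cache <- new_spectrum_cache()
  dfe <- dfe_model("gamma", shape = 0.2, scale = 1e-3 / 0.2,
                   N_anc_ref = 1e4)
  e_default <- expected_sfs_under_dfe(m, dfe, 1000, 14,
                                      cache = cache)
  e_fine <- expected_sfs_under_dfe(m, dfe, 1000, 14,
                                   gamma_grid = dfe_gamma_grid(600),
                                   cache = cache)
  expect_lt(max(abs(e_default - e_fine) / e_fine), 1e-2)
})

test_that("theta_ns scales the expected spectrum linearly", {
  m <- demographic_model(1)
  cache <- new_spectrum_cache()
  dfe <- dfe_model("gamma", shape = 0.3, scale = 0.01, N_anc_ref = 1e4)
  e1 <- expected_sfs_under_dfe(m, dfe, 100, 14, cache = cache)
  e2 <- expected_sfs_under_dfe(m, dfe, 200, 14, cache = cache)
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
})

test_that("deleterious DFEs skew the spectrum toward singletons", {
  m <- demographic_model(1)
  cache <- new_spectrum_cache()
  neu <- expected_selected_sfs(m, 0, 14, cache = cache)
  for (es in c(1e-4, 1e-3, 1e-2)) {
    dfe <- dfe_model("gamma", shape = 0.2, scale = es / 0.2,
                     N_anc_ref = 1e4)
    e <- expected_sfs_under_dfe(m, dfe, 1000, 14, cache = cache)
    expect_gte(e[1] / sum(e), neu[1] / sum(neu))
  }
})

test_that("DFE bin masses follow the gamma CDF", {
  # exponential closed form at shape 1
  m1 <- dfe_bin_masses(dfe_model("gamma", 1, 1e-2))
  expect_equal(unname(m1["neutral"]), 1 - exp(-1e-4), tolerance = 1e-10)
  expect_equal(unname(m1["lethal"]), exp(-50), tolerance = 1e-10)
  expect_equal(sum(m1), 1)
  # pure neutrality
  mn <- dfe_bin_masses(dfe_model("neu_gamma", 1, 1, p_neu = 1))
  expect_equal(unname(mn), c(1, 0, 0, 0), tolerance = 1e-15)
  # numeric-integration oracle for a generic DFE
  f <- function(lo, hi) integrate(dgamma, lo, hi, shape = 0.2,
                                  scale = 0.05, rel.tol = 1e-12)$value
  mq <- dfe_bin_masses(dfe_model("gamma", 0.2, 0.05))
  expect_equal(unname(mq[1:3]),
               c(f(0, 1e-6), f(1e-6, 1e-2), f(1e-2, 0.5)),
               tolerance = 1e-6)
})

test_that("fitting the noise-free mixture recovers the DFE within 1%", {
  m <- equilibrium_demog(1000)
  cache <- new_spectrum_cache()
  truth <- dfe_model("gamma", shape = 0.2, scale = 1e-3 / 0.2,
                     N_anc_ref = 1e4)
  e <- expected_sfs_under_dfe(demographic_model(1), truth,
                              theta_ns = 2.31 * 1000, n = 14,
                              cache = cache)
  sfs <- sfs_from_expected(e, 14, class = "nonsynonymous")
  fit <- fit_dfe(sfs, m, "gamma", N_anc = 1e4, cache = cache)
  expect_lt(abs(fit$dfe$shape - 0.2) / 0.2, 0.01)
  expect_lt(abs(fit$dfe$E_s - 1e-3) / 1e-3, 0.01)
  # neu_gamma nests gamma: its optimum cannot be worse
  fit3 <- fit_dfe(sfs, m, "neu_gamma", N_anc = 1e4, cache = cache)
  expect_gte(fit3$loglik, fit$loglik - 1e-3)
  expect_equal(fit3$k, 3L)
})

test_that("neutral-truth data drive the gamma fit to a neutral DFE", {
  m <- equilibrium_demog(1000)
  cache <- new_spectrum_cache()
  e <- 2.31 * 1000 * expected_neutral_sfs(demographic_model(1), 14)
  sfs <- sfs_from_expected(e, 14, class = "nonsynonymous")
  fit <- fit_dfe(sfs, m, "gamma", N_anc = 1e4, cache = cache)
  expect_true(dfe_bin_masses(fit$dfe)["neutral"] >= 0.95 ||
                fit$dfe$E_s < 1e-5)
})
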