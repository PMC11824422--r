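# Neutral SFS engine, demographic fitting, model selection and the
# parameter conversions.

test_that("equilibrium folded spectra match the closed form", {
  for (n in c(2, 4, 14)) {
    i <- seq_len(n - 1)
    closed <- fold_spectrum(1 / i)
    expect_equal(expected_neutral_sfs(demographic_model(1), n), closed,
                 tolerance = 1e-12)
  }
  expect_equal(expected_neutral_sfs(demographic_model(1), 2), 1.0)
  expect_equal(expected_neutral_sfs(demographic_model(1), 4),
               c(4 / 3, 1 / 2))
})

test_that("lineage-time expectations integrate Tavare's formula correctly", {
  # equilibrium: E[T_k] = 2 / (k (k-1)); validates the coefficient matrix
  Tk <- expected_lineage_times(demographic_model(c(1, 1), 0.4), 14)
  expect_equal(Tk, 2 / ((2:14) * (1:13)), tolerance = 1e-10)
})

test_that("degenerate epoch structures reduce to simpler models", {
  n <- 14
  one <- expected_neutral_sfs(demographic_model(1), n)
  for (tau in c(0.01, 0.1, 1)) {
    expect_equal(expected_neutral_sfs(demographic_model(c(1, 1), tau), n),
                 one, tolerance = 1e-10)
  }
  two <- expected_neutral_sfs(demographic_model(c(1, 0.3), 0.04), n)
  three <- expected_neutral_sfs(
    demographic_model(c(1, 0.3, 0.3), c(0.04, 0.02)), n)
  expect_equal(three, two, tolerance = 1e-10)
})

test_that("the spectrum is continuous in (nu, tau)", {
  n <- 14
  base <- expected_neutral_sfs(demographic_model(c(1, 0.2), 0.05), n)
  pert <- expected_neutral_sfs(
    demographic_model(c(1, 0.2 * (1 + 1e-6)), 0.05 * (1 + 1e-6)), n)
  expect_lt(max(abs(pert - base) / base), 1e-4)
})

test_that("old size changes converge to the new equilibrium", {
  n <- 14
  nu <- 0.3
  old <- expected_neutral_sfs(demographic_model(c(1, nu), 6), n)
  eq <- nu * expected_neutral_sfs(demographic_model(1), n)
  expect_lt(max(abs(old - eq) / eq), 1e-6)
})

test_that("multinomial likelihood is invariant to theta scaling", {
  x <- c(120, 50, 30, 22, 18, 15, 8)
  e <- expected_neutral_sfs(demographic_model(c(1, 0.5), 0.05), 14)
  expect_equal(multinomial_loglik(x, e), multinomial_loglik(x, 77.3 * e))
})

test_that("fitting a noise-free spectrum recovers the truth within 1%", {
  m <- demographic_model(c(1, 0.5), 0.05)
  theta <- theta_for_S(m, 14, 5000)
  sfs <- sfs_from_expected(theta * expected_neutral_sfs(m, 14), 14)
  fit <- fit_demography(sfs, "two")
  expect_lt(abs(fit$model$epochs[2] - 0.5) / 0.5, 0.01)
  expect_lt(abs(fit$model$change_times[1] - 0.05) / 0.05, 0.01)
  expect_lt(abs(fit$model$theta_s - theta) / theta, 0.01)
  # MLE inside its own CI, and AIC consistent with k and loglik
  ci <- fit$ci
  expect_true(ci$lower[ci$parameter == "nu"] <= 0.5 &&
                0.5 <= ci$upper[ci$parameter == "nu"])
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$loglik)
})

test_that("three-epoch fitting is exposed and nests the two-epoch optimum", {
  m <- demographic_model(c(1, 0.3), 0.05)
  theta <- theta_for_S(m, 14, 8000)
  sfs <- sfs_from_expected(theta * expected_neutral_sfs(m, 14), 14)
  f2 <- fit_demography(sfs, "two")
  f3 <- fit_demography(sfs, "three", n_starts = 25)
  expect_gte(f3$loglik, f2$loglik - 1e-3)
})

test_that("AIC model selection follows the arithmetic and tie rules", {
  mk <- function(ll, k, family) {
    structure(list(loglik = ll, k = k, aic = 2 * k - 2 * ll,
                   family = family), class = "demog_fit")
  }
  expect_identical(select_model(list(mk(-100, 0, "one"),
                                     mk(-95, 2, "two")))$family, "two")
  expect_identical(select_model(list(mk(-100, 0, "one"),
                                     mk(-99.5, 2, "two")))$family, "one")
  expect_identical(select_model(list(mk(-99, 2, "two"),
                                     mk(-97, 4, "three")))$family, "two")
})

test_that("confidence regions implement the 3-LL-unit rule", {
  # worked shape of the rule: drop of exactly 3 at nu = 0.02 and 0.66
  nu <- c(0.02, 0.1, 0.3, 0.66, 1)
  surf <- data.frame(nu = nu, ll = c(-3, -1, 0, -3, -8))
  ci <- confidence_region(surf)
  expect_equal(ci$lower, 0.02)
  expect_equal(ci$upper, 0.66)
  # flat surface: spans the grid, flagged unbounded
  flat <- data.frame(nu = seq(0.1, 10, length.out = 50), ll = rep(-2, 50))
  cf <- confidence_region(flat)
  expect_true(cf$unbounded_lower && cf$unbounded_upper)
  expect_equal(c(cf$lower, cf$upper), c(0.1, 10))
  # quadratic surface LL = -(nu - 1)^2: CI = 1 +/- sqrt(3)
  qs <- data.frame(nu = seq(-2, 4, length.out = 60001))
  qs$ll <- -(qs$nu - 1)^2
  cq <- confidence_region(qs)
  expect_equal(cq$lower, 1 - sqrt(3), tolerance = 3e-4)
  expect_equal(cq$upper, 1 + sqrt(3), tolerance = 3e-4)
})

test_that("N_Anc and calendar-time conversions follow the definitions", {
  expect_equal(ancestral_size(1632, 4.08e-10, 1e6), 1e6)
  expect_equal(ancestral_size(4 * 4.08e-10 * 5, 4.08e-10, 5), 1)
  expect_equal(ancestral_size(2 * 1632, 4.08e-10, 1e6),
               2 * ancestral_size(1632, 4.08e-10, 1e6))
  expect_error(ancestral_size(0, 4.08e-10, 1e6), "> 0")
  # one generation per day: tau * 2 N_Anc generations = that many days
  expect_equal(tau_to_years(0.05, 2e5), 0.05 * 2 * 2e5 / 365)
  expect_equal(tau_to_years(0, 1e6), 0)
  expect_equal(tau_to_years(0.1, 1e6, generations_per_day = 2),
               tau_to_years(0.1, 1e6) / 2)
})

test_that("model construction rejects invalid epoch structures", {
  expect_error(demographic_model(c(0.5, 1)), "ancestral")
  expect_error(demographic_model(c(1, -2), 0.1), "> 0")
  expect_error(demographic_model(c(1, 2, 3), c(0.01, 0.05)), "decreasing")
  expect_error(demographic_model(c(1, 2), numeric(0)), "one change time")
})
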