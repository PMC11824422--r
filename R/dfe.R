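# Distribution of fitness effects (DFE) of new nonsynonymous mutations,
# fitted by Poisson random-field maximum likelihood conditional on a
# demography inferred from synonymous sites.  Selection coefficients s are
# haploid fitness costs; the population-scaled coefficient is
# gamma = 2 * N_Anc * s.  The DFE is deleterious-only: a gamma distribution
# on |s| (shape alpha, scale beta), optionally mixed with a neutral point
# mass p_neu.

#' Construct a DFE model
#'
#' @param family `"gamma"` or `"neu_gamma"`.
#' @param shape gamma shape `alpha > 0`.
#' @param scale gamma scale `beta > 0`, on the `|s|` axis.
#' @param p_neu neutral point-mass proportion in `[0, 1]` (forced to 0 for
#'   the pure gamma family).
#' @param N_anc_ref ancestral size used to map `s` to `gamma = 2*N_Anc*s`.
#' @return an object of class `dfe_model`; `E_s = shape * scale` is the
#'   mean deleterious effect of the gamma component.
#' @export
dfe_model <- function(family = c("gamma", "neu_gamma"), shape, scale,
                      p_neu = 0, N_anc_ref = NA_real_) {
  family <- match.arg(family)
  if (family == "gamma") p_neu <- 0
  stopifnot(shape > 0, scale > 0, p_neu >= 0, p_neu <= 1)
  structure(list(family = family, shape = shape, scale = scale,
                 p_neu = p_neu, N_anc_ref = N_anc_ref,
                 E_s = shape * scale),
            class = "dfe_model")
}

#' @export
print.dfe_model <- function(x, ...) {
  cat(sprintf("DFE (%s): shape = %.4g, scale = %.4g, E[s] = %.4g",
              x$family, x$shape, x$scale, x$E_s))
  if (x$family == "neu_gamma") cat(sprintf(", p_neu = %.4g", x$p_neu))
  cat("\n")
  m <- dfe_bin_masses(x)
  print(round(m, 4))
  invisible(x)
}

#' Discretized DFE masses over the standard |s| bins
#'
#' Bins: `|s| < 1e-6` (weakly deleterious or neutral), `1e-6..1e-2`
#' (moderately deleterious), `1e-2..0.5` (highly deleterious) and
#' `|s| >= 0.5` (lethal).  Masses are gamma CDF differences with `p_neu`
#' added to the first bin; they sum to 1.
#'
#' @param dfe a [dfe_model()].
#' @return named numeric vector of four masses.
#' @export
dfe_bin_masses <- function(dfe) {
  stopifnot(inherits(dfe, "dfe_model"))
  edges <- c(0, 1e-6, 1e-2, 0.5, Inf)
  cdf <- pgamma(edges, shape = dfe$shape, scale = dfe$scale)
  m <- (1 - dfe$p_neu) * diff(cdf)
  m[1] <- m[1] + dfe$p_neu
  setNames(m, c("neutral", "moderate", "high", "lethal"))
}

# Default log-spaced |gamma| integration grid.
dfe_gamma_grid <- function(n_nodes = 60, gamma_min = 1e-4,
                           gamma_max = 2000) {
  exp(seq(log(gamma_min), log(gamma_max), length.out = n_nodes))
}

# Expected folded spectra per unit theta at each |gamma| node plus the
# neutral spectrum, under `model`.  Computed once and re-used by every
# likelihood evaluation (and by the LRT grid).
dfe_node_spectra <- function(model, n, gamma_grid = dfe_gamma_grid(),
                             cache = NULL) {
  if (is.null(cache)) cache <- new_spectrum_cache()
  E <- vapply(gamma_grid, function(g) {
    expected_selected_sfs(model, -g, n, cache = cache)
  }, numeric(n %/% 2))
  E0 <- expected_selected_sfs(model, 0, n, cache = cache)
  list(gamma = gamma_grid, E = E, E0 = E0, n = n)
}

# Mixture spectrum: trapezoid rule over the DFE on the log-|s| axis, with
# the gamma mass below the lowest node treated as neutral and the mass
# beyond the largest modeled |gamma| contributing no polymorphism
# (lethal-equivalent).
mix_dfe_spectrum <- function(nodes, shape, scale, p_neu, theta_ns, N_anc) {
  s <- nodes$gamma / (2 * N_anc)
  u <- log(s)
  du <- diff(u)
  w_trap <- c(du[1] / 2, (du[-1] + du[-length(du)]) / 2,
              du[length(du)] / 2)
  dens <- dgamma(s, shape = shape, scale = scale) * s  # density in log s
  gamma_part <- as.numeric(nodes$E %*% (dens * w_trap))
  below <- pgamma(s[1] * exp(-du[1] / 2), shape = shape, scale = scale)
  neutral_coef <- p_neu + (1 - p_neu) * below
  theta_ns * ((1 - p_neu) * gamma_part + neutral_coef * nodes$E0)
}

#' Expected nonsynonymous folded SFS under a DFE
#'
#' Integrates [expected_selected_sfs()] over the DFE on a log-spaced
#' `|gamma|` grid (trapezoid rule on the log axis, `>= 40` nodes spanning
#' `|gamma|` from `1e-4` to `2000`), adds `p_neu` times the neutral
#' spectrum, and scales by `theta_ns`.  DFE mass beyond the largest modeled
#' `|gamma|` is treated as effectively lethal (zero polymorphism); mass
#' below the smallest node is treated as neutral.
#'
#' @param model a [demographic_model()].
#' @param dfe a [dfe_model()] with `N_anc_ref` set.
#' @param theta_ns nonsynonymous population-scaled mutation rate (total).
#' @param n sample size.
#' @param gamma_grid integration nodes on `|gamma|` (log-spaced).
#' @param cache optional spectrum cache (see [expected_selected_sfs()]).
#' @return expected folded spectrum (absolute counts).
#' @export
expected_sfs_under_dfe <- function(model, dfe, theta_ns, n,
                                   gamma_grid = dfe_gamma_grid(),
                                   cache = NULL) {
  stopifnot(theta_ns > 0, inherits(dfe, "dfe_model"),
            is.finite(dfe$N_anc_ref))
  nodes <- dfe_node_spectra(model, n, gamma_grid, cache)
  mix_dfe_spectrum(nodes, dfe$shape, dfe$scale, dfe$p_neu, theta_ns,
                   dfe$N_anc_ref)
}

#' Poisson random-field log-likelihood of a folded SFS
#'
#' `sum_i [ x_i log e_i - lgamma(x_i + 1) - e_i ]`; fractional observed
#' counts are handled by the log-gamma generalized factorial.  Bins with
#' `e_i = 0` but `x_i > 0` make the likelihood `-Inf` (returned with a
#' warning rather than an error, so optimizers can step away).
#'
#' @param observed folded observed counts (vector or [folded_sfs()]).
#' @param expected expected counts, same length.
#' @return log-likelihood (scalar).
#' @export
poisson_loglik <- function(observed, expected) {
  if (inherits(observed, "folded_sfs")) observed <- observed$counts
  stopifnot(length(observed) == length(expected))
  bad <- expected <= 0 & observed > 0
  if (any(bad)) {
    warning("expected count of 0 where observed > 0; returning -Inf")
    return(-Inf)
  }
  ok <- expected > 0
  sum(observed[ok] * log(expected[ok])) - sum(lgamma(observed + 1)) -
    sum(expected)
}

#' Fit a gamma or neutral+gamma DFE to a nonsynonymous folded SFS
#'
#' Conditions on a demography fitted to the matching synonymous spectrum:
#' `theta_ns` is fixed at `theta_ratio * theta_s` and the DFE parameters
#' are found by Poisson maximum likelihood with `n_starts >= 25`
#' log-uniform multi-starts (L-BFGS-B on `log alpha` and `log E[s]`, plus a
#' logit for `p_neu` in the `neu_gamma` family).
#'
#' @param nonsyn_sfs a [folded_sfs()] of nonsynonymous sites.
#' @param demog a `demog_fit` (from [fit_demography()]) or a
#'   [demographic_model()] with `theta_s` set.
#' @param family `"gamma"` (k = 2) or `"neu_gamma"` (k = 3).
#' @param N_anc ancestral size mapping `s` to `gamma = 2*N_Anc*s`; compute
#'   it with [ancestral_size()] from the fitted `theta_s`.
#' @param theta_ratio assumed `theta_ns / theta_s` (default 2.31).
#' @param n_starts,seed multi-start controls (deterministic given `seed`).
#' @param gamma_grid,cache integration controls, see
#'   [expected_sfs_under_dfe()].
#' @return an object of class `dfe_fit` with the fitted [dfe_model()],
#'   `loglik`, `k`, `aic` and `theta_ns`.
#' @export
fit_dfe <- function(nonsyn_sfs, demog, family = c("gamma", "neu_gamma"),
                    N_anc, theta_ratio = 2.31, n_starts = 25, seed = 1,
                    gamma_grid = dfe_gamma_grid(), cache = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(nonsyn_sfs, "folded_sfs"), N_anc > 0)
  model <- if (inherits(demog, "demog_fit")) demog$model else demog
  stopifnot(inherits(model, "demographic_model"), is.finite(model$theta_s))
  theta_ns <- theta_ratio * model$theta_s
  x <- nonsyn_sfs$counts
  n <- nonsyn_sfs$n
  nodes <- dfe_node_spectra(model, n, gamma_grid, cache)

  npar <- if (family == "gamma") 2L else 3L
  lower <- c(log(1e-3), log(1e-9), -12)[seq_len(npar)]
  upper <- c(log(50), log(1), 12)[seq_len(npar)]
  objective <- function(par) {
    shape <- exp(par[1])
    es <- exp(par[2])
    p_neu <- if (npar == 3L) stats::plogis(par[3]) else 0
    e <- mix_dfe_spectrum(nodes, shape, es / shape, p_neu, theta_ns, N_anc)
    ll <- suppressWarnings(poisson_loglik(x, e))
    if (!is.finite(ll)) 1e10 else -ll
  }
  n_starts <- max(25L, as.integer(n_starts))
  start_lower <- c(log(1e-2), log(1e-7), -6)[seq_len(npar)]
  start_upper <- c(log(10), log(0.5), 6)[seq_len(npar)]
  start_mat <- with_seed(substream_seed(seed, "dfe_starts"), {
    matrix(runif(n_starts * npar, rep(start_lower, each = n_starts),
                 rep(start_upper, each = n_starts)), n_starts, npar)
  })
  results <- lapply(seq_len(n_starts), function(s) {
    r <- try(optim(start_mat[s, ], objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500)),
             silent = TRUE)
    if (inherits(r, "try-error")) NULL else r
  })
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) stop("all ", n_starts, " DFE optimization starts failed")
  vals <- vapply(results[ok], function(r) r$value, 0)
  best <- results[ok][[which.min(vals)]]
  shape <- exp(best$par[1])
  es <- exp(best$par[2])
  p_neu <- if (npar == 3L) stats::plogis(best$par[3]) else 0
  dfe <- dfe_model(family, shape = shape, scale = es / shape,
                   p_neu = p_neu, N_anc_ref = N_anc)
  ll <- -best$value
  structure(list(dfe = dfe, loglik = ll, k = npar, aic = 2 * npar - 2 * ll,
                 theta_ns = theta_ns, model = model, n = n,
                 par = best$par),
            class = "dfe_fit")
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat(sprintf("DFE fit: loglik = %.3f, k = %d, AIC = %.3f, theta_ns = %g\n",
              x$loglik, x$k, x$aic, x$theta_ns))
  print(x$dfe)
  invisible(x)
}
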