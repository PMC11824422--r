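# Maximum-likelihood fitting of piecewise-constant demographies to folded
# synonymous SFSs.  theta is profiled out of the multinomial likelihood (the
# LL depends only on bin proportions), so a k-epoch model has 2*(k-1) free
# parameters; the Poisson alternative is reserved for the DFE module.

NU_BOUNDS <- c(1e-3, 1e4)
TAU_BOUNDS <- c(1e-4, 0.15)

#' Multinomial log-likelihood of a folded SFS against a model spectrum
#'
#' `sum(x) * log`-probabilities plus the generalized multinomial
#' coefficient; fractional observed counts (from projection) enter through
#' `lgamma`.  Invariant to any positive scaling of `expected`.
#'
#' @param observed numeric vector of observed folded bin counts.
#' @param expected model spectrum (any positive scaling).
#' @return log-likelihood (scalar).
#' @export
multinomial_loglik <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  if (any(expected <= 0 & observed > 0)) return(-Inf)
  p <- expected / sum(expected)
  keep <- observed > 0
  lgamma(sum(observed) + 1) - sum(lgamma(observed + 1)) +
    sum(observed[keep] * log(p[keep]))
}

model_from_params <- function(family, par) {
  # par holds log(nu)s then log(duration)s; durations oldest-epoch first
  switch(family,
    one = demographic_model(1),
    two = demographic_model(c(1, exp(par[1])), exp(par[2])),
    three = {
      d <- exp(par[3:4])
      demographic_model(c(1, exp(par[1]), exp(par[2])),
                        change_times = c(d[1] + d[2], d[2]))
    })
}

#' Fit a piecewise-constant demographic model to a synonymous folded SFS
#'
#' Maximizes the multinomial log-likelihood of the folded spectrum over the
#' model's size ratios and epoch durations, with `theta_s` profiled
#' analytically as the ratio of observed to model total.  The search runs
#' `n_starts >= 25` local optimizations (L-BFGS-B on log-parameters) from
#' log-uniform draws over `nu` in `[1e-3, 1e4]` and epoch durations in
#' `[1e-4, 0.15]` (units of `2 * N_Anc` generations); bound hits are
#' reported, not hidden.  For the two-epoch family a log-likelihood surface
#' grid around the MLE feeds [confidence_region()] with the
#' three-log-likelihood-unit (df = 2, 95%) rule.
#'
#' @param sfs a [folded_sfs()] (synonymous).
#' @param family `"one"`, `"two"` or `"three"` epochs.
#' @param n_starts number of initial parameter guesses (`>= 25` enforced
#'   unless the family has no free parameters).
#' @param seed seed for the start draws (the fit is deterministic given it).
#' @param ci_grid points per axis of the CI surface (two-epoch family).
#' @return an object of class `demog_fit`: the fitted
#'   [demographic_model()] (with `theta_s` filled in), `loglik`, `k`,
#'   `aic`, `ci`, and per-start diagnostics.
#' @export
fit_demography <- function(sfs, family = c("two", "one", "three"),
                           n_starts = 25, seed = 1, ci_grid = 61) {
  family <- match.arg(family)
  stopifnot(inherits(sfs, "folded_sfs"))
  x <- sfs$counts
  n <- sfs$n
  npar <- switch(family, one = 0L, two = 2L, three = 4L)
  if (sum(x > 0) < npar + 1 && family != "one") {
    stop("SFS has too few informative bins for the ", family,
         "-epoch family")
  }
  # fast path: sizes/durations of the non-ancestral epochs, oldest first
  par_to_epochs <- switch(family,
    one = function(par) list(numeric(0), numeric(0)),
    two = function(par) list(exp(par[1]), exp(par[2])),
    three = function(par) list(exp(par[1:2]), exp(par[3:4])))
  objective <- function(par) {
    se <- par_to_epochs(par)
    e <- fold_spectrum(neutral_xi(se[[1]], se[[2]], n))
    ll <- multinomial_loglik(x, e)
    if (!is.finite(ll)) 1e10 else -ll
  }
  if (npar == 0L) {
    model <- demographic_model(1)
    ll <- multinomial_loglik(x, expected_neutral_sfs(model, n))
    fit_par <- numeric(0)
    starts <- data.frame()
    boundary <- logical(0)
  } else {
    n_starts <- max(25L, as.integer(n_starts))
    lower <- c(rep(log(NU_BOUNDS[1]), npar / 2),
               rep(log(TAU_BOUNDS[1]), npar / 2))
    upper <- c(rep(log(NU_BOUNDS[2]), npar / 2),
               rep(log(TAU_BOUNDS[2]), npar / 2))
    start_mat <- with_seed(substream_seed(seed, "demog_starts"), {
      matrix(runif(n_starts * npar, rep(lower, each = n_starts),
                   rep(upper, each = n_starts)), n_starts, npar)
    })
    results <- lapply(seq_len(n_starts), function(s) {
      r <- try(optim(start_mat[s, ], objective, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(factr = 1e7, maxit = 500)),
               silent = TRUE)
      if (inherits(r, "try-error")) NULL else r
    })
    ok <- !vapply(results, is.null, logical(1))
    if (!any(ok)) {
      stop("all ", n_starts, " optimization starts failed; diagnostics: ",
           paste(vapply(results[!ok], function(r) "error", ""),
                 collapse = ", "))
    }
    vals <- vapply(results[ok], function(r) r$value, 0)
    best <- results[ok][[which.min(vals)]]
    fit_par <- best$par
    model <- model_from_params(family, fit_par)
    ll <- -best$value
    boundary <- abs(fit_par - lower) < 1e-6 | abs(fit_par - upper) < 1e-6
    starts <- data.frame(start = seq_len(n_starts), ok = ok,
                         negll = ifelse(ok, vapply(results, function(r)
                           if (is.null(r)) NA_real_ else r$value, 0), NA))
  }
  e <- expected_neutral_sfs(model, n)
  theta_hat <- sum(x) / sum(e)
  model$theta_s <- theta_hat
  model$n <- n
  ci <- NULL
  if (family == "two") {
    ci <- two_epoch_ci_surface(x, n, fit_par, ll, grid_pts = ci_grid)
  }
  structure(list(model = model, family = family, loglik = ll, k = npar,
                 aic = 2 * npar - 2 * ll, ci = ci, par = fit_par,
                 boundary_hit = boundary, starts = starts),
            class = "demog_fit")
}

# Log-likelihood surface for the two-epoch family and the derived
# 3-LL-unit intervals.  The (nu, tau) likelihood often has a long ridge,
# so the surface spans the full search bounds (a local grid around the
# MLE would truncate the region whenever the MLE sits at a ridge end),
# with a finer patch around the MLE for resolution.
two_epoch_ci_surface <- function(x, n, par_hat, ll_hat, grid_pts = 61,
                                 local_pts = 31, local_half_decades = 0.5) {
  eval_grid <- function(lnu, ltau) {
    g <- expand.grid(nu = exp(lnu), tau = exp(ltau))
    g$ll <- vapply(seq_len(nrow(g)), function(i) {
      e <- fold_spectrum(neutral_xi(g$nu[i], g$tau[i], n))
      multinomial_loglik(x, e)
    }, 0)
    g
  }
  global <- eval_grid(
    seq(log(NU_BOUNDS[1]), log(NU_BOUNDS[2]), length.out = grid_pts),
    seq(log(TAU_BOUNDS[1]), log(TAU_BOUNDS[2]), length.out = grid_pts))
  h <- local_half_decades * log(10)
  local <- eval_grid(
    seq(max(par_hat[1] - h, log(NU_BOUNDS[1])),
        min(par_hat[1] + h, log(NU_BOUNDS[2])), length.out = local_pts),
    seq(max(par_hat[2] - h, log(TAU_BOUNDS[1])),
        min(par_hat[2] + h, log(TAU_BOUNDS[2])), length.out = local_pts))
  grid <- rbind(global, local,
                data.frame(nu = exp(par_hat[1]), tau = exp(par_hat[2]),
                           ll = ll_hat))
  confidence_region(grid)
}

#' Likelihood-surface confidence intervals (3-log-likelihood-unit rule)
#'
#' Given a log-likelihood surface evaluated over a parameter grid, returns
#' for each parameter the extremes of the region within `drop`
#' log-likelihood units of the maximum (df = 2 asymptotic 95% region for
#' the default `drop = 3`).  Intervals whose region touches the grid edge
#' are flagged unbounded on that side.
#'
#' @param surface data frame with one column per parameter plus an `ll`
#'   column; must contain the MLE.
#' @param drop log-likelihood drop defining the region (default 3).
#' @return data frame with `parameter`, `lower`, `upper`,
#'   `unbounded_lower`, `unbounded_upper`.
#' @export
confidence_region <- function(surface, drop = 3) {
  stopifnot(is.data.frame(surface), "ll" %in% names(surface))
  pars <- setdiff(names(surface), "ll")
  ll_max <- max(surface$ll)
  inside <- surface$ll >= ll_max - drop
  do.call(rbind, lapply(pars, function(p) {
    v <- surface[[p]][inside]
    grid_vals <- sort(unique(surface[[p]]))
    lo <- min(v)
    hi <- max(v)
    # When the extreme inside node sits exactly on the LL_max - drop
    # contour it *is* the interval end; otherwise the continuous boundary
    # lies between it and the first outside node, so report the midpoint
    # rather than quantizing the interval inward.
    on_contour <- function(val) {
      any(abs(surface$ll[surface[[p]] == val] - (ll_max - drop)) < 1e-9)
    }
    below <- grid_vals[grid_vals < lo]
    above <- grid_vals[grid_vals > hi]
    lo_ext <- if (length(below) > 0 && !on_contour(lo)) {
      (lo + max(below)) / 2
    } else {
      lo
    }
    hi_ext <- if (length(above) > 0 && !on_contour(hi)) {
      (hi + min(above)) / 2
    } else {
      hi
    }
    data.frame(parameter = p, lower = lo_ext, upper = hi_ext,
               unbounded_lower = length(below) == 0,
               unbounded_upper = length(above) == 0)
  }))
}

#' @export
print.demog_fit <- function(x, ...) {
  cat(sprintf("%s-epoch fit: loglik = %.3f, k = %d, AIC = %.3f\n",
              x$family, x$loglik, x$k, x$aic))
  print(x$model)
  if (!is.null(x$ci)) {
    cat("  95% CI (3-LL-unit rule):\n")
    print(x$ci, row.names = FALSE)
  }
  if (any(x$boundary_hit)) cat("  note: MLE hit a search bound\n")
  invisible(x)
}

#' Select among fitted demographic models by AIC
#'
#' Returns the minimum-AIC fit; AIC ties (difference `< 1e-6`) go to the
#' model with fewer parameters.
#'
#' @param fits list of `demog_fit` objects for the same SFS.
#' @return the selected `demog_fit`.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 2)
  aic <- vapply(fits, function(f) f$aic, 0)
  k <- vapply(fits, function(f) as.numeric(f$k), 0)
  best <- which(aic <= min(aic) + 1e-6)
  fits[[best[which.min(k[best])]]]
}

#' Ancestral effective population size from theta_s
#'
#' `N_Anc = theta_s / (4 * mu * L_syn)`, with `mu` the per-site
#' per-generation mutation rate and `L_syn` the number of monitored
#' synonymous sites.
#'
#' @param theta_s fitted population-scaled synonymous mutation rate (total
#'   over `L_syn`).
#' @param mu mutation rate per site per generation (default `4.08e-10`).
#' @param L_syn number of synonymous sites.
#' @return `N_Anc`.
#' @export
ancestral_size <- function(theta_s, mu = 4.08e-10, L_syn) {
  if (any(c(theta_s, mu, L_syn) <= 0)) {
    stop("theta_s, mu and L_syn must all be > 0")
  }
  theta_s / (4 * mu * L_syn)
}

#' Convert a scaled demographic time to calendar years
#'
#' `tau` is in units of `2 * N_Anc` generations, so it corresponds to
#' `tau * 2 * N_Anc` generations; at `generations_per_day` generations a
#' day this is `tau * 2 * N_Anc / (365 * generations_per_day)` years
#' (default one bacterial generation per day, a conservative choice).
#'
#' @param tau time since the size change in units of `2 * N_Anc`
#'   generations.
#' @param N_Anc ancestral effective population size.
#' @param generations_per_day generations per day (default 1).
#' @return time in years.
#' @export
tau_to_years <- function(tau, N_Anc, generations_per_day = 1) {
  stopifnot(N_Anc > 0, generations_per_day > 0, tau >= 0)
  tau * 2 * N_Anc / (365 * generations_per_day)
}
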