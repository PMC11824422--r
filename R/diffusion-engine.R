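# Expected folded SFS under genic selection and piecewise-constant
# demography.  The workhorse is a finite-volume diffusion solve (src/) on
# three increasingly fine frequency grids followed by quadratic Richardson
# extrapolation in the grid spacing, as is standard for this class of
# engine.  Two regimes bypass the time stepper:
#   * one-epoch models: the stationary density is known analytically, so
#     only the grid quadrature (still extrapolated) is needed;
#   * very strong selection (|gamma| > 150): the density is concentrated at
#     frequencies below the first grid point, but relaxes to
#     mutation-selection balance on a timescale ~ 1/(2|gamma| nu) much
#     shorter than any epoch of interest, so the engine returns the
#     stationary spectrum at the current epoch size by adaptive quadrature.

GAMMA_QUASI_STATIC <- 150

# Stationary density per unit theta at relative size nu, scaled coefficient
# gamma <= 0: phi(x) = nu * r(x) / (x(1-x)), r = expm1(a(1-x))/expm1(a),
# a = -2 gamma nu (the neutral limit is r = 1 - x).
phi_stationary <- function(x, gamma, nu = 1) {
  a <- -2 * gamma * nu
  r <- if (abs(a) < 1e-8) {
    1 - x
  } else {
    exp(-a * x) * (-expm1(-a * (1 - x))) / (-expm1(-a))
  }
  nu * r / (x * (1 - x))
}

# Stationary expected spectrum by adaptive quadrature (unfolded, per unit
# theta).  Used for the strong-selection limit and by the independent PRF
# oracle.
stationary_quadrature_sfs <- function(gamma, n, nu = 1, rel.tol = 1e-9) {
  a <- abs(2 * gamma * nu)
  # split out the boundary layer at x ~ 1/a so the adaptive rule sees it
  cuts <- if (a > 50) sort(unique(pmin(10^seq(log10(1 / a) - 1, 0, by = 1),
                                       1))) else 1
  lo <- c(0, head(cuts, -1))
  sapply(seq_len(n - 1), function(i) {
    f <- function(x) {
      phi_stationary(x, gamma, nu) *
        exp(lchoose(n, i) + i * log(x) + (n - i) * log1p(-x))
    }
    sum(vapply(seq_along(cuts), function(j) {
      integrate(f, lo[j], cuts[j], rel.tol = rel.tol,
                subdivisions = 400L)$value
    }, 0))
  })
}

# Quadratic Richardson extrapolation of per-bin values computed on grids of
# pts[1..3] points, in the mean grid spacing h = 1/(pts - 1).
extrapolate_grids <- function(fun, pts) {
  vals <- sapply(pts, fun)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  h <- 1 / (pts - 1)
  X <- cbind(1, h, h^2)
  apply(vals, 1, function(y) stats::lm.fit(X, y)$coefficients[[1]])
}

#' Expected folded SFS under genic selection
#'
#' Computes the expected folded spectrum per unit theta for a
#' population-scaled selection coefficient `gamma = 2 * N_Anc * s`
#' (deleterious or neutral, `gamma <= 0`; `s` is the haploid fitness cost)
#' under the given piecewise-constant demography.  `gamma = 0` reproduces
#' [expected_neutral_sfs()] through an entirely independent numerical path.
#'
#' @param model a [demographic_model()].
#' @param gamma scaled selection coefficient, `<= 0`.
#' @param n sample size (haplotypes).
#' @param pts three increasing frequency-grid sizes for the diffusion solve;
#'   the default satisfies `max(pts) >= 8 * n` for the sample sizes used
#'   here.
#' @param folded fold the returned spectrum (default).
#' @param cache environment used to memoize spectra across calls with the
#'   same demography (the DFE integration grid re-uses them heavily), or
#'   `NULL` to disable.
#' @return numeric vector of expected counts per unit theta.
#' @export
expected_selected_sfs <- function(model, gamma, n, pts = c(120, 160, 200),
                                  folded = TRUE, cache = NULL) {
  stopifnot(inherits(model, "demographic_model"), n >= 2)
  if (gamma > 0) stop("only deleterious or neutral gamma (<= 0) is modeled")
  n <- as.integer(n)
  key <- NULL
  if (!is.null(cache)) {
    key <- paste0("g", signif(gamma, 12), "_n", n, "_",
                  paste(signif(c(model$epochs, model$change_times), 12),
                        collapse = "_"))
    hit <- cache[[key]]
    if (!is.null(hit)) return(if (folded) fold_spectrum(hit) else hit)
  }
  sizes <- model$epochs
  if (abs(gamma) > GAMMA_QUASI_STATIC) {
    xi <- stationary_quadrature_sfs(gamma, n, nu = sizes[length(sizes)])
  } else if (length(sizes) == 1) {
    xi <- extrapolate_grids(function(p) .equilibrium_sfs_cpp(n, gamma, p),
                            pts)
  } else {
    dur <- demog_durations(model)
    xi <- extrapolate_grids(function(p) {
      .diffusion_sfs_cpp(n, gamma, sizes[-1], dur, p, 2e-4)
    }, pts)
  }
  if (any(!is.finite(xi)) || any(xi < -1e-8)) {
    stop(sprintf(paste0("diffusion engine failed to converge ",
                        "(gamma = %g, grids = %s): non-finite or negative ",
                        "expected bins"), gamma, paste(pts, collapse = "/")))
  }
  xi <- pmax(xi, 0)
  if (!is.null(cache)) cache[[key]] <- xi
  if (folded) fold_spectrum(xi) else xi
}

#' Independent stationary PRF quadrature oracle
#'
#' Expected folded SFS at mutation-selection-drift equilibrium, computed by
#' adaptive quadrature of the analytic stationary density against the exact
#' binomial sampling kernel.  This shares no code path with the grid-based
#' diffusion engine (for `|gamma| <= 150`) and serves as one of its
#' validation oracles.
#'
#' @param gamma scaled selection coefficient `2 * N_Anc * s`, `<= 0`.
#' @param n sample size.
#' @param theta scaling of the returned spectrum (default 1).
#' @return list with `expectation` (folded, length `floor(n/2)`),
#'   `mc_stderr` (zeros; the quadrature is deterministic) and `method`.
#' @export
prf_quadrature_sfs <- function(gamma, n, theta = 1) {
  stopifnot(gamma <= 0, n >= 2)
  xi <- stationary_quadrature_sfs(gamma, n)
  list(expectation = theta * fold_spectrum(xi),
       mc_stderr = numeric(n %/% 2), method = "prf_quadrature")
}

#' Create a spectrum memoization cache
#'
#' An environment passed via the `cache` arguments of
#' [expected_selected_sfs()], [expected_sfs_under_dfe()], [fit_dfe()] and
#' [lrt_dfe_pair()] so that expected spectra for a given demography and
#' selection coefficient are computed once and re-used.
#'
#' @return an empty environment.
#' @export
new_spectrum_cache <- function() new.env(parent = emptyenv())
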