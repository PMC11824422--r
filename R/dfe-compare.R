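# Likelihood-ratio tests for equality of gamma DFEs between two datasets
# (species pairs, or core vs accessory genes of one species), with
# Bonferroni-corrected chi-square critical values, plus the genus-contrast
# rank-sum / label-permutation analysis.

#' Bonferroni-corrected chi-square critical value
#'
#' Upper-tail chi-square quantile with `df` degrees of freedom at
#' probability `alpha / m`.  For `df = 2` this equals
#' `-2 * log(alpha / m)`: 5.99 for a single test, 11.77 for m = 18,
#' 18.30 for m = 471.
#'
#' @param df degrees of freedom (default 2: shared shape and scale).
#' @param alpha family-wise level (default 0.05).
#' @param m number of comparisons, `>= 1`.
#' @return the critical value.
#' @export
bonferroni_critical <- function(df = 2, alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  qchisq(alpha / m, df = df, lower.tail = FALSE)
}

#' Bundle one dataset for a DFE-equality test
#'
#' @param sfs nonsynonymous [folded_sfs()].
#' @param demog `demog_fit` or [demographic_model()] with `theta_s` set.
#' @param N_anc ancestral effective size for this dataset.
#' @param theta_ratio assumed `theta_ns / theta_s` (default 2.31).
#' @return a `dfe_dataset` list.
#' @export
dfe_dataset <- function(sfs, demog, N_anc, theta_ratio = 2.31) {
  model <- if (inherits(demog, "demog_fit")) demog$model else demog
  stopifnot(inherits(sfs, "folded_sfs"), inherits(model, "demographic_model"),
            is.finite(model$theta_s), N_anc > 0)
  structure(list(sfs = sfs, model = model, N_anc = N_anc,
                 theta_ns = theta_ratio * model$theta_s),
            class = "dfe_dataset")
}

# Per-dataset Poisson LL at shared parameters (alpha, mean).  On the s
# scale `mean` is E[s]; on the 2*N_Anc*s scale it is E[gamma], and each
# dataset's beta is back-computed from its own N_Anc.
ll_at_shared <- function(ds, nodes, shape, mean_par, scale_kind) {
  es <- if (scale_kind == "s") mean_par else mean_par / (2 * ds$N_anc)
  e <- mix_dfe_spectrum(nodes, shape, es / shape, 0, ds$theta_ns, ds$N_anc)
  suppressWarnings(poisson_loglik(ds$sfs$counts, e))
}

#' Likelihood-ratio test for equality of two gamma DFEs
#'
#' Full model: each dataset keeps its own maximum-likelihood
#' (shape, scale); constrained model: shared parameters, on either the `s`
#' scale (shared shape and scale) or the `2*N_Anc*s` scale (shared shape
#' and population-scaled scale, each dataset's `beta` back-computed from
#' its own `N_Anc`).  Expected spectra are always computed under each
#' dataset's own demography and `theta_ns`.  The constrained optimum is
#' found on a log-spaced grid over shape in `[1e-2, 10]` and the shared
#' mean in `[1e-8, 1]` (times `2*N_Anc` on the scaled axis), then refined
#' by a local search.  `2 * Lambda` is referred to a chi-square with 2 df
#' and a Bonferroni-corrected critical value for `m` comparisons.
#'
#' @param dataA,dataB [dfe_dataset()] objects.
#' @param scale `"s"` or `"two_Nanc_s"`.
#' @param m number of comparisons in the battery (Bonferroni).
#' @param alpha family-wise level.
#' @param grid_pts grid points per axis (`>= 40`).
#' @param n_starts,seed multi-start controls for the full-model fits.
#' @param gamma_grid,cacheA,cacheB spectrum-integration controls.
#' @return an object of class `dfe_lrt`.
#' @export
lrt_dfe_pair <- function(dataA, dataB, scale = c("s", "two_Nanc_s"),
                         m = 1, alpha = 0.05, grid_pts = 40,
                         n_starts = 25, seed = 1,
                         gamma_grid = dfe_gamma_grid(),
                         cacheA = NULL, cacheB = NULL) {
  scale <- match.arg(scale)
  stopifnot(inherits(dataA, "dfe_dataset"), inherits(dataB, "dfe_dataset"),
            grid_pts >= 40)
  fitA <- fit_dfe(dataA$sfs, dataA$model, "gamma", N_anc = dataA$N_anc,
                  theta_ratio = dataA$theta_ns / dataA$model$theta_s,
                  n_starts = n_starts, seed = seed, gamma_grid = gamma_grid,
                  cache = cacheA)
  fitB <- fit_dfe(dataB$sfs, dataB$model, "gamma", N_anc = dataB$N_anc,
                  theta_ratio = dataB$theta_ns / dataB$model$theta_s,
                  n_starts = n_starts, seed = seed, gamma_grid = gamma_grid,
                  cache = cacheB)
  ll_full <- fitA$loglik + fitB$loglik
  nodesA <- dfe_node_spectra(dataA$model, dataA$sfs$n, gamma_grid, cacheA)
  nodesB <- dfe_node_spectra(dataB$model, dataB$sfs$n, gamma_grid, cacheB)
  joint <- function(par) {   # par = c(log shape, log mean)
    shape <- exp(par[1])
    mean_par <- exp(par[2])
    -(ll_at_shared(dataA, nodesA, shape, mean_par, scale) +
        ll_at_shared(dataB, nodesB, shape, mean_par, scale))
  }
  mean_range <- if (scale == "s") c(1e-8, 1) else {
    c(1e-8, 1) * 2 * sqrt(dataA$N_anc * dataB$N_anc)
  }
  lsh <- seq(log(1e-2), log(10), length.out = grid_pts)
  lme <- seq(log(mean_range[1]), log(mean_range[2]), length.out = grid_pts)
  gv <- expand.grid(lsh = lsh, lme = lme)
  nll <- vapply(seq_len(nrow(gv)), function(i) joint(c(gv$lsh[i],
                                                       gv$lme[i])), 0)
  best <- which.min(nll)
  ref <- optim(c(gv$lsh[best], gv$lme[best]), joint, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  ll_con <- -ref$value
  if (ll_con > ll_full + 1e-3) {
    stop(sprintf(paste0("constrained LL (%.6f) exceeds full LL (%.6f): ",
                        "full-model optimizer failure, models must nest"),
         ll_con, ll_full))
  }
  stat <- max(2 * (ll_full - ll_con), -1e-6)
  critical <- bonferroni_critical(df = 2, alpha = alpha, m = m)
  structure(list(ll_full = ll_full, ll_constrained = ll_con, stat = stat,
                 df = 2L, alpha = alpha, m = m, critical = critical,
                 significant = stat > critical, scale = scale,
                 fitA = fitA, fitB = fitB,
                 constrained = c(shape = exp(ref$par[1]),
                                 mean = exp(ref$par[2]))),
            class = "dfe_lrt")
}

#' @export
print.dfe_lrt <- function(x, ...) {
  cat(sprintf(paste0("DFE equality LRT (%s scale): 2*Lambda = %.3f, ",
                     "critical = %.2f (df = 2, alpha = %.3g, m = %d) -> %s\n"),
              x$scale, x$stat, x$critical, x$alpha, x$m,
              if (x$significant) "different" else "not distinguishable"))
  invisible(x)
}

# Standardized Wilcoxon rank-sum statistic of `a` versus `b` (normal
# approximation with tie correction); NA when either group is empty.
rank_sum_z <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * (n1 + n2 + 1 -
                            sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sig2 <= 0) return(0)
  (W - mu) / sqrt(sig2)
}

#' Genus contrast of pairwise DFE-difference statistics
#'
#' Tests whether between-genus species pairs have larger statistics (LRT
#' `2*Lambda` values, or `|delta E[s]|`) than within-genus pairs, with a
#' two-sided Wilcoxon rank-sum test, and forms a permutation null by
#' re-assigning genus labels to *species* (holding the genus sizes fixed)
#' and recomputing the standardized rank-sum statistic.
#'
#' @param stats numeric vector of per-pair statistics.
#' @param species_a,species_b species labels of each pair.
#' @param genus_labels named character vector, species -> genus; `>= 2`
#'   genera required, and at least one within-genus pair.
#' @param n_perm number of label permutations (default `1e4`).
#' @param seed permutation seed.
#' @return list with `p_wilcoxon`, `p_permutation`, group sizes and the
#'   observed standardized statistic.
#' @export
genus_contrast <- function(stats, species_a, species_b, genus_labels,
                           n_perm = 1e4, seed = 1) {
  stopifnot(length(stats) == length(species_a),
            length(stats) == length(species_b))
  sp <- sort(unique(c(species_a, species_b)))
  if (!all(sp %in% names(genus_labels))) {
    stop("every species in the pairs needs a genus label")
  }
  gl <- genus_labels[sp]
  if (length(unique(gl)) < 2) stop("need at least 2 genera")
  classify <- function(labels) {
    unname(labels[species_a] == labels[species_b])
  }
  within <- classify(gl)
  if (!any(within)) stop("no within-genus pairs")
  obs_z <- rank_sum_z(stats[!within], stats[within])
  pw <- wilcox.test(stats[!within], stats[within], exact = FALSE)$p.value
  perm_z <- with_seed(substream_seed(seed, "genus_perm"), {
    vapply(seq_len(n_perm), function(i) {
      pl <- setNames(sample(gl), sp)
      w <- classify(pl)
      if (!any(w) || all(w)) NA_real_ else rank_sum_z(stats[!w], stats[w])
    }, 0)
  })
  perm_z <- perm_z[!is.na(perm_z)]
  p_perm <- (1 + sum(abs(perm_z) >= abs(obs_z))) / (1 + length(perm_z))
  list(p_wilcoxon = pw, p_permutation = p_perm, z_observed = obs_z,
       n_between = sum(!within), n_within = sum(within),
       n_perm_effective = length(perm_z))
}
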