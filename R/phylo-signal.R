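# Pagel's lambda for continuous DFE summaries on a species tree.
#
# The trait vector is modeled as multivariate normal with covariance
# sigma2 * C(lambda), where C is the shared-branch-length (Brownian
# motion) matrix of the tree and C(lambda) scales its off-diagonal
# entries by lambda.  lambda = 0 is star-like independence, lambda = 1
# pure Brownian motion; the search bound is set by positive-definiteness
# rather than 1, so estimates slightly above 1 are allowed.

# lambda transform of a phylogenetic covariance matrix.
lambda_vcv <- function(C, lambda) {
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}

# Largest lambda (up to `cap`) keeping the transformed matrix positive
# definite; always >= 1 since C itself is a covariance matrix.
lambda_upper_bound <- function(C, cap = 1.5, tol = 1e-8) {
  pd <- function(l) {
    ev <- eigen(lambda_vcv(C, l), symmetric = TRUE, only.values = TRUE)
    min(ev$values) > tol * mean(diag(C))
  }
  if (pd(cap)) return(cap)
  lo <- 1; hi <- cap
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (pd(mid)) lo <- mid else hi <- mid
  }
  lo
}

# Profile log-likelihood at a given lambda: GLS root state and analytic
# sigma2, then the MVN log-density.
lambda_profile_ll <- function(lambda, C, y) {
  n <- length(y)
  Cl <- lambda_vcv(C, lambda)
  ch <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  Cinv_y <- backsolve(ch, forwardsolve(t(ch), y))
  Cinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  root <- sum(Cinv_y) / sum(Cinv_1)
  r <- y - root
  Cinv_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- sum(r * Cinv_r) / n
  if (s2 <= 0) return(-Inf)
  list(ll = -0.5 * (n * log(2 * pi * s2) + logdet + n),
       sigma2 = s2, root = root)
}

#' Maximum-likelihood Pagel's lambda for a continuous trait on a tree
#'
#' Maximizes the Brownian-motion likelihood over `(lambda, sigma2, root)`
#' with `sigma2` and the root state profiled analytically; `lambda` is
#' searched on `[0, lambda_max]` where `lambda_max` keeps the transformed
#' covariance positive definite (it may exceed 1).  The p-value compares
#' `2 * (LL(lambda_hat) - LL(0))` to a plain chi-square with 1 df (no
#' boundary mixture correction, matching common phylogenetic-signal
#' implementations).
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param traits named numeric vector of tip values (`>= 4` tips).
#' @return an object of class `phylosig_result` with `lambda_hat`,
#'   `loglik_at_hat`, `loglik_at_zero`, `p_value`, `sigma2_hat`,
#'   `root_state_hat`, `lambda_max`.
#' @export
pagels_lambda <- function(tree, traits) {
  stopifnot(inherits(tree, "phylo"), !is.null(names(traits)))
  traits <- traits[!is.na(traits)]
  common <- intersect(tree$tip.label, names(traits))
  if (length(common) < 4) stop("need >= 4 tips with trait values")
  if (length(common) < length(tree$tip.label)) {
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, common))
  }
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length == 0 &
          tree$edge[, 2] <= length(tree$tip.label))) {
    warning("zero-length terminal branches perturbed by 1e-8")
    z <- tree$edge.length == 0 & tree$edge[, 2] <= length(tree$tip.label)
    tree$edge.length[z] <- 1e-8
  }
  y <- traits[tree$tip.label]
  if (stats::var(y) == 0) stop("trait variance is zero")
  C <- ape::vcv(tree)
  if (max(abs(C[upper.tri(C)])) < 1e-12 * mean(diag(C))) {
    stop("star tree: lambda is unidentifiable")
  }
  lmax <- lambda_upper_bound(C)
  f <- function(l) lambda_profile_ll(l, C, y)$ll
  op <- optimize(f, c(0, lmax), maximum = TRUE, tol = 1e-8)
  # the interior optimum can sit at an endpoint; check both
  cand <- rbind(c(op$maximum, op$objective),
                c(0, f(0)), c(lmax, f(lmax)))
  lam <- cand[which.max(cand[, 2]), 1]
  at_hat <- lambda_profile_ll(lam, C, y)
  ll0 <- lambda_profile_ll(0, C, y)$ll
  stat <- max(2 * (at_hat$ll - ll0), 0)
  structure(list(lambda_hat = lam, loglik_at_hat = at_hat$ll,
                 loglik_at_zero = ll0,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                 sigma2_hat = at_hat$sigma2, root_state_hat = at_hat$root,
                 lambda_max = lmax, n_tips = length(y)),
            class = "phylosig_result")
}

#' @export
print.phylosig_result <- function(x, ...) {
  cat(sprintf(paste0("Pagel's lambda = %.4g (max allowed %.3g), ",
                     "LL = %.3f vs %.3f at lambda = 0, p = %.3g\n"),
              x$lambda_hat, x$lambda_max, x$loglik_at_hat,
              x$loglik_at_zero, x$p_value))
  invisible(x)
}

#' Re-estimate phylogenetic signal after dropping tips
#'
#' Prunes the named tips (collapsing the resulting unifurcations and
#' summing their branch lengths, as `ape::drop.tip` does) and re-runs
#' [pagels_lambda()].
#'
#' @param tree an `ape::phylo` tree.
#' @param traits named numeric tip values.
#' @param drop character vector of tip labels to remove (may be empty).
#' @return a `phylosig_result`.
#' @export
leave_out_rerun <- function(tree, traits, drop = character(0)) {
  if (length(drop) > 0) {
    keep <- setdiff(tree$tip.label, drop)
    if (length(intersect(keep, names(traits))) < 4) {
      stop("fewer than 4 tips with traits would remain")
    }
    tree <- ape::drop.tip(tree, drop)
    traits <- traits[names(traits) %in% keep]
  }
  pagels_lambda(tree, traits)
}
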