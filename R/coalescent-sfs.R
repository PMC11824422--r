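# Closed-form expected neutral SFS under piecewise-constant demography via
# coalescent lineage-count expectations.
#
# E[xi_b] = (1/2) * sum_k k E[T_k] p_{n,k}(b) per unit theta, where T_k is
# the time during which the sample's ancestry has k lineages and p_{n,k}(b)
# is the probability that one of k ancestral lineages subtends b of the n
# sampled haplotypes.  E[T_k] is obtained by integrating Tavare's formula
# for P(A_n(t) = k) over the time-rescaled piecewise-constant history,
# which is a finite sum of exponentials and so integrates in closed form.
# Exact, smooth in the parameters, and fast enough to sit inside an
# optimizer, unlike a grid-based diffusion solve.  The n-dependent
# combinatorial matrices are memoized per sample size.

.coal_env <- new.env(parent = emptyenv())

# Coefficients a_{jk} with P(A_n(R) = k) = sum_j a_{jk} exp(-j(j-1)/2 R),
# R in coalescent-rescaled time; plus the sampling weights needed for the
# spectrum.  Memoized by n.
coal_tables <- function(n) {
  key <- as.character(n)
  hit <- .coal_env[[key]]
  if (!is.null(hit)) return(hit)
  lrf <- function(a, m) ifelse(m == 0, 0, lgamma(a + m) - lgamma(a))
  A <- matrix(0, n - 1, n - 1)  # rows j = 2..n, cols k = 2..n
  for (k in 2:n) {
    j <- k:n
    lmag <- log(2 * j - 1) + lrf(k, j - 1) +
      (lgamma(n + 1) - lgamma(n - j + 1)) -
      (lgamma(k + 1) + lgamma(j - k + 1)) - lrf(n, j)
    A[j - 1, k - 1] <- (-1)^(j - k) * exp(lmag)
  }
  cj <- (2:n) * (1:(n - 1)) / 2
  b <- seq_len(n - 1)
  k <- 2:n
  # p_{n,k}(b) = C(n-b-1, k-2) / C(n-1, k-1)
  P <- outer(b, k, function(bb, kk) {
    exp(lchoose(n - bb - 1, kk - 2) - lchoose(n - 1, kk - 1))
  })
  P[is.na(P)] <- 0
  out <- list(A = A, cj = cj, P = P, k = k)
  .coal_env[[key]] <- out
  out
}

# Expected time spent with k = 2..n lineages (vector), units of 2*N_Anc
# generations.  sizes/durations describe the non-ancestral epochs oldest
# first; the ancestral epoch has size 1.
lineage_times <- function(sizes, durations, n) {
  tb <- coal_tables(n)
  sizes_bwd <- rev(sizes)
  dur_bwd <- rev(durations)
  Tk <- numeric(n - 1)
  R0 <- 0
  e0 <- exp(-tb$cj * R0)
  for (e in seq_along(dur_bwd)) {
    lam <- sizes_bwd[e]
    R1 <- R0 + dur_bwd[e] / lam
    e1 <- exp(-tb$cj * R1)
    Tk <- Tk + lam * as.numeric(crossprod(tb$A, (e0 - e1) / tb$cj))
    R0 <- R1
    e0 <- e1
  }
  Tk <- Tk + as.numeric(crossprod(tb$A, e0 / tb$cj))  # ancestral size 1
  pmax(Tk, 0)
}

# Fast internal path: unfolded expected neutral spectrum per unit theta.
neutral_xi <- function(sizes, durations, n) {
  if (length(sizes) == 0) return(1 / seq_len(n - 1))
  tb <- coal_tables(n)
  as.numeric(0.5 * tb$P %*% (tb$k * lineage_times(sizes, durations, n)))
}

# Fold an unfolded spectrum xi_1..xi_{n-1}: bin i gets xi_i + xi_{n-i},
# except the midpoint bin at i = n/2 which is its own complement.
fold_spectrum <- function(xi) {
  n <- length(xi) + 1L
  nb <- n %/% 2L
  out <- numeric(nb)
  for (i in seq_len(nb)) {
    out[i] <- if (2L * i == n) xi[i] else xi[i] + xi[n - i]
  }
  out
}

#' Expected folded neutral SFS under a piecewise-constant demography
#'
#' Returns the expected folded spectrum per unit `theta` (the
#' population-scaled mutation rate summed over monitored sites), computed
#' from coalescent branch-length expectations.  At equilibrium this reduces
#' to the classical `theta * (1/i + 1/(n-i))` (with the midpoint bin at
#' `n/2` counted once).
#'
#' @param model a [demographic_model()].
#' @param n sample size (haplotypes), `>= 2`.
#' @param folded return the folded (default) or unfolded spectrum.
#' @return numeric vector of expected counts per unit theta
#'   (length `floor(n/2)` folded, `n - 1` unfolded).
#' @export
#' @examples
#' expected_neutral_sfs(demographic_model(1), n = 4)  # 4/3, 1/2
expected_neutral_sfs <- function(model, n, folded = TRUE) {
  stopifnot(inherits(model, "demographic_model"), n >= 2)
  n <- as.integer(n)
  xi <- neutral_xi(model$epochs[-1], demog_durations(model), n)
  if (folded) fold_spectrum(xi) else xi
}

# Kept for oracle cross-checks in the tests.
expected_lineage_times <- function(model, n) {
  lineage_times(model$epochs[-1], demog_durations(model), n)
}
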