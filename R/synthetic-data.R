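# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth, plus independent forward-simulation oracles.  All
# generators are pure functions of (parameters, seed); random streams are
# derived from the scenario's master seed with named substreams so adding
# a generator never perturbs existing ones.

#' Define a simulation scenario
#'
#' The defaults describe the stated study world: samples of 14 haplotypes
#' (one quasi-phased dominant strain per host), ~5,000 expected synonymous
#' SNPs (`theta_s = 1600` with `sum(1/i)` over 13 unfolded bins),
#' `theta_ns / theta_s = 2.31`, read depths around 50x with a 20x calling
#' floor, and hosts carrying two strains with a clearly dominant one.
#'
#' @param n_hosts hosts in the panel.
#' @param n_haplotypes_target projection target sample size (14).
#' @param genome_length monitored genome length in bp.
#' @param frac_synonymous fraction of monitored sites that are fourfold
#'   degenerate (4D), in (0, 1).
#' @param demography a [demographic_model()] (ground truth).
#' @param dfe a [dfe_model()] with `N_anc_ref` set, or `NULL` (neutral
#'   world; required for nonsynonymous simulation).
#' @param theta_s synonymous population-scaled mutation rate, total over
#'   the monitored synonymous sites (> 0).
#' @param theta_ratio `theta_ns / theta_s` (default 2.31).
#' @param depth_mean mean read depth (>= 1).
#' @param strain_major_fraction relative abundance of the dominant strain
#'   within a host, in (0.5, 1].
#' @param seed master seed; fixing it makes every generated artifact
#'   byte-identical.
#' @return an object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_hosts = 30, n_haplotypes_target = 14,
                         genome_length = 50000, frac_synonymous = 0.15,
                         demography = demographic_model(1), dfe = NULL,
                         theta_s = 1600, theta_ratio = 2.31,
                         depth_mean = 50, strain_major_fraction = 0.95,
                         seed = 1) {
  stopifnot(theta_s > 0, frac_synonymous > 0, frac_synonymous < 1,
            strain_major_fraction > 0.5, strain_major_fraction <= 1,
            inherits(demography, "demographic_model"))
  if (!is.null(dfe)) stopifnot(inherits(dfe, "dfe_model"))
  structure(list(n_hosts = as.integer(n_hosts),
                 n_haplotypes_target = as.integer(n_haplotypes_target),
                 genome_length = as.integer(genome_length),
                 frac_synonymous = frac_synonymous,
                 demography = demography, dfe = dfe, theta_s = theta_s,
                 theta_ratio = theta_ratio, depth_mean = depth_mean,
                 strain_major_fraction = strain_major_fraction,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

# Expected folded spectrum (absolute counts) for one mutation class under
# the scenario's truth.
scenario_expected_sfs <- function(scenario, class = c("syn", "nonsyn"),
                                  n = scenario$n_haplotypes_target,
                                  cache = NULL) {
  class <- match.arg(class)
  if (class == "syn") {
    scenario$theta_s * expected_neutral_sfs(scenario$demography, n)
  } else {
    if (is.null(scenario$dfe)) {
      stop("nonsynonymous simulation requires a DFE in the scenario")
    }
    expected_sfs_under_dfe(scenario$demography, scenario$dfe,
                           theta_ns = scenario$theta_ratio *
                             scenario$theta_s,
                           n = n, cache = cache)
  }
}

#' Simulate a folded SFS of independent Poisson bin counts
#'
#' Each folded bin is an independent Poisson draw whose mean is the
#' model-expected spectrum under the scenario's demography (and DFE for
#' the nonsynonymous class), scaled by the class theta — the generative
#' counterpart of the Poisson random-field likelihood used in fitting.
#'
#' @param scenario a [sim_scenario()].
#' @param class `"syn"` or `"nonsyn"`.
#' @param cache optional spectrum cache.
#' @return a [folded_sfs()]; `L` is the monitored site count of the class.
#' @export
simulate_sfs_counts <- function(scenario, class = c("syn", "nonsyn"),
                                cache = NULL) {
  class <- match.arg(class)
  e <- scenario_expected_sfs(scenario, class, cache = cache)
  L <- round(scenario$genome_length *
               if (class == "syn") scenario$frac_synonymous else
                 1 - scenario$frac_synonymous)
  counts <- with_seed(substream_seed(scenario$seed,
                                     paste0("sfs_counts_", class)), {
    rpois(length(e), e)
  })
  folded_sfs(counts, n = scenario$n_haplotypes_target, L = max(L, sum(counts)),
             class = if (class == "syn") "synonymous" else "nonsynonymous")
}

#' Simulate per-host site call tables (pileups) with known truth
#'
#' Each host carries two latent strains mixed at `strain_major_fraction`.
#' Across-host polymorphism follows the scenario's expected folded SFS at
#' `n_hosts` haplotypes (one dominant strain per host); the second strain
#' draws its allele from the same population frequency.  Per-site read
#' depths are discretized log-normal around `depth_mean` (floored at 0)
#' and the emitted major-allele frequency is the majority fraction of a
#' binomial read-sampling of the within-host mixture.  The ground-truth
#' dominant-strain haplotype is attached as attribute `"truth"`.
#'
#' @param scenario a [sim_scenario()].
#' @param species species label for the output table.
#' @param cache optional spectrum cache.
#' @return a `data.table` with columns `species, host, contig, pos0,
#'   gene_id, degeneracy, major_freq, depth, major_allele` (the observed
#'   majority allele coded "0"/"1"; frequencies alone cannot support a
#'   cross-host SFS).  Attribute `"truth"` holds the dominant-strain
#'   allele matrix and per-site metadata.
#' @export
simulate_host_pileup <- function(scenario, species = "speciesA",
                                 cache = NULL) {
  if (scenario$depth_mean < 1) stop("depth_mean must be >= 1")
  H <- scenario$n_hosts
  L <- scenario$genome_length
  with_seed(substream_seed(scenario$seed, "pileup"), {
    degeneracy <- ifelse(runif(L) < scenario$frac_synonymous, "4D", "1D")
    # expected polymorphic-site counts by minor count at n = H haplotypes
    counts <- matrix(0L, H, L)  # dominant-strain allele per host x site
    pop_minor <- integer(L)
    for (cls in c("syn", "nonsyn")) {
      if (cls == "nonsyn" && is.null(scenario$dfe)) next
      e <- scenario_expected_sfs(scenario, cls, n = H, cache = cache)
      sites_cls <- which(degeneracy == (if (cls == "syn") "4D" else "1D"))
      nseg <- rpois(length(e), e)
      if (sum(nseg) > length(sites_cls)) {  # genome too short: thin evenly
        nseg <- floor(nseg * length(sites_cls) / sum(nseg))
      }
      seg <- sites_cls[sample.int(length(sites_cls), sum(nseg))]
      at <- 0
      for (b in seq_along(nseg)) {
        if (nseg[b] == 0) next
        idx <- seg[(at + 1):(at + nseg[b])]
        at <- at + nseg[b]
        for (s in idx) {
          carriers <- sample.int(H, b)
          counts[carriers, s] <- 1L
          pop_minor[s] <- b
        }
      }
    }
    second <- matrix(rbinom(H * L, 1, rep(pop_minor / H, each = H)), H, L)
    depth <- matrix(pmax(round(stats::rlnorm(
      H * L, log(scenario$depth_mean) - 0.3^2 / 2, 0.3)), 0), H, L)
    f <- scenario$strain_major_fraction
    mix <- counts * f + second * (1 - f)        # frequency of allele "1"
    k1 <- matrix(rbinom(H * L, as.vector(depth), as.vector(mix)), H, L)
    major_allele <- ifelse(k1 * 2 >= depth, "1", "0")
    kmaj <- pmax(k1, depth - k1)
    major_freq <- ifelse(depth > 0, kmaj / depth, NA_real_)
    hosts <- sprintf("host%03d", seq_len(H))
    out <- data.table::data.table(
      species = species,
      host = rep(hosts, each = L),
      contig = "contig1",
      pos0 = rep(0:(L - 1), H),
      gene_id = rep(sprintf("gene%04d", (0:(L - 1)) %/% 300 + 1), H),
      degeneracy = rep(degeneracy, H),
      major_freq = as.vector(t(major_freq)),
      depth = as.vector(t(depth)),
      major_allele = as.vector(t(major_allele)))
    truth <- list(dominant = matrix(as.character(counts), H, L,
                                    dimnames = list(hosts, NULL)),
                  pop_minor_count = pop_minor, degeneracy = degeneracy,
                  strain_major_fraction = f)
    data.table::setattr(out, "truth", truth)
    out
  })
}

#' Forward Wright-Fisher oracle for the expected folded SFS
#'
#' Haploid Wright-Fisher simulation (fitnesses 1 and `1 + s`, `s <= 0`)
#' with `gamma = N * s` and time measured in `N` generations, matching the
#' diffusion engine's units.  At equilibrium (`demography = NULL`) each of
#' `reps` mutation events is followed independently from count 1 to
#' absorption, accumulating exact without-replacement sampling
#' probabilities (renewal-reward, so the Monte Carlo error is a clean
#' between-trajectory standard error).  With a two-epoch `demography` a
#' whole population is simulated `n_pop_reps` times through burn-in, size
#' change and sampling.
#'
#' @param N haploid population size (`<= 2000`; this is a desk-scale
#'   validation oracle, not an inference engine).
#' @param gamma scaled selection coefficient `N * s`, `<= 0`.
#' @param n sample size (haplotypes).
#' @param reps number of mutation events (`>= 1e4`) for the equilibrium
#'   oracle.
#' @param seed RNG seed.
#' @param theta scaling of the returned expectation.
#' @param demography optional [demographic_model()] (two-epoch) for the
#'   population oracle.
#' @param n_pop_reps replicate populations for the population oracle.
#' @param burn_mult burn-in length in units of `N` generations.
#' @return list with `expectation`, `mc_stderr` (per folded bin) and
#'   `method` (`"forward_wf"`).
#' @export
forward_wf_sfs <- function(N, gamma, n, reps = 1e4, seed = 1, theta = 1,
                           demography = NULL, n_pop_reps = 100,
                           burn_mult = 8) {
  stopifnot(N <= 2000, N >= 10, gamma <= 0, n >= 2, n <= N)
  if (is.null(demography)) {
    if (reps < 1e4) stop("equilibrium oracle requires reps >= 1e4")
    res <- with_seed(substream_seed(seed, "wf_traj"), {
      .wf_trajectory_sfs_cpp(as.integer(N), gamma, as.integer(n),
                             as.integer(reps))
    })
    contrib <- res$contrib
    expectation <- theta * colMeans(contrib)
    se <- theta * apply(contrib, 2, stats::sd) / sqrt(nrow(contrib))
  } else {
    stopifnot(length(demography$epochs) == 2)
    nu <- demography$epochs[2]
    tau <- demography$change_times[1]
    # time unit of the model is 2*N_Anc generations = N haploid generations
    mat <- with_seed(substream_seed(seed, "wf_pop"), {
      .wf_population_sfs_cpp(as.integer(N), gamma, nu, tau, as.integer(n),
                             as.integer(n_pop_reps), theta, burn_mult)
    })
    expectation <- colMeans(mat)
    se <- apply(mat, 2, stats::sd) / sqrt(nrow(mat))
  }
  list(expectation = expectation, mc_stderr = se, method = "forward_wf")
}

#' Simulate tip traits under lambda-transformed Brownian motion
#'
#' Multivariate-normal draw with covariance `sigma2 *
#' lambda_vcv(vcv(tree), lambda_true)`: off-diagonal shared-ancestry
#' covariances scaled by `lambda_true`, tip variances untouched.
#'
#' @param tree an `ape::phylo` tree (`>= 4` tips) with branch lengths.
#' @param lambda_true Pagel transform in `[0, 1]`.
#' @param sigma2 Brownian-motion rate.
#' @param seed RNG seed.
#' @return named numeric vector of tip trait values.
#' @export
simulate_bm_traits <- function(tree, lambda_true, sigma2 = 1, seed = 1) {
  stopifnot(inherits(tree, "phylo"), lambda_true >= 0, lambda_true <= 1,
            sigma2 > 0)
  if (length(tree$tip.label) < 4) stop("need >= 4 tips")
  C <- ape::vcv(tree)
  if (max(abs(C[upper.tri(C)])) < 1e-12 * mean(diag(C)) &&
      lambda_true > 0) {
    stop("star tree: the lambda transform has no effect (unidentifiable)")
  }
  S <- sigma2 * lambda_vcv(C, lambda_true)
  ch <- chol(S)
  with_seed(substream_seed(seed, "bm_traits"), {
    setNames(as.numeric(t(ch) %*% rnorm(nrow(C))), rownames(C))
  })
}
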