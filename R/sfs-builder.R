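# Folded SFS construction from quasi-phased haplotypes, and hypergeometric
# projection to a fixed sample size.

#' Build a folded SFS from quasi-phased haplotypes
#'
#' Restricts sites to the requested degeneracy class (4D for synonymous,
#' 1D for nonsynonymous) and, per site, counts called haplotypes `c` and
#' the minor-allele count `m` (ties at `c/2` stay at `c/2`).  Monomorphic
#' sites enter the per-site table with `m = 0` and count toward `L`.
#' Sites with more than two observed alleles violate the biallelic
#' assumption and are dropped with a warning.
#'
#' @param haplotypes a single table (or list of per-host tables) of
#'   quasi-phased calls as produced by [call_quasi_phased()]: columns
#'   `host, contig, pos0, degeneracy, allele` (`NA` = missing).
#' @param class `"synonymous"` or `"nonsynonymous"`.
#' @return list with `per_site` (data.table `contig, pos0, m, c`), and
#'   `sfs` — the raw [folded_sfs()] at `n` = number of haplotypes (the
#'   irregular, missing-data spectrum that projection repairs).
#' @export
build_folded_sfs <- function(haplotypes,
                             class = c("synonymous", "nonsynonymous")) {
  class <- match.arg(class)
  if (is.list(haplotypes) && !is.data.frame(haplotypes)) {
    haplotypes <- data.table::rbindlist(haplotypes)
  }
  hap <- data.table::as.data.table(haplotypes)
  H <- length(unique(hap$host))
  if (H < 2) stop("need >= 2 haplotypes")
  want <- if (class == "synonymous") "4D" else "1D"
  hap <- hap[hap$degeneracy == want & !is.na(hap$allele)]
  per_site <- hap[, {
    tab <- table(allele)
    if (length(tab) > 2) {
      list(m = NA_real_, c = as.numeric(sum(tab)))
    } else {
      cc <- sum(tab)
      mm <- if (length(tab) == 1) 0 else min(tab)
      list(m = as.numeric(mm), c = as.numeric(cc))
    }
  }, by = c("contig", "pos0")]
  n_multi <- sum(is.na(per_site$m))
  if (n_multi > 0) {
    warning(n_multi, " site(s) with > 2 alleles dropped (biallelic ",
            "assumption)")
    per_site <- per_site[!is.na(per_site$m)]
  }
  per_site <- per_site[per_site$c >= 2]
  counts <- numeric(H %/% 2)
  poly <- per_site[per_site$m > 0]
  if (nrow(poly) > 0) {
    tab <- table(factor(pmin(poly$m, H %/% 2), levels = seq_len(H %/% 2)))
    counts <- as.numeric(tab)
  }
  list(per_site = per_site[],
       sfs = folded_sfs(counts, n = H, L = nrow(per_site), class = class))
}

#' Project per-site minor counts to a fixed sample size
#'
#' Sites with data in fewer than `n_target` haplotypes are omitted (from
#' the counts and from `L`).  Every remaining site contributes to
#' projected bin `j` the probability that a hypergeometric draw of
#' `n_target` from its `m` minor and `c - m` major alleles yields a folded
#' minor count of `j`; the mass at `j = 0` and `j = n_target` is discarded
#' as monomorphic-in-sample.  Bin counts are fractional and are kept so —
#' rounding would bias the low bins.  For sites with `c = n_target` the
#' projection is the identity.
#'
#' @param per_site data frame `m, c` per site (monomorphic rows `m = 0`
#'   allowed; they count toward `L` only).
#' @param n_target projected sample size (default 14).
#' @param class mutation class recorded on the output.
#' @param species,gene_class labels recorded on the output.
#' @return a [folded_sfs()] with `n = n_target` and `L` = number of
#'   retained (projectable) sites.
#' @export
project_sfs <- function(per_site, n_target = 14,
                        class = c("synonymous", "nonsynonymous"),
                        species = NA_character_,
                        gene_class = NA_character_) {
  class <- match.arg(class)
  stopifnot(n_target >= 2)
  if (any(per_site$m > per_site$c)) {
    stop("minor count m exceeds called haplotypes c")
  }
  keep <- per_site$c >= n_target
  ps <- per_site[keep, , drop = FALSE]
  nb <- n_target %/% 2
  counts <- numeric(nb)
  poly <- ps[ps$m > 0, , drop = FALSE]
  if (nrow(poly) > 0) {
    j <- 0:n_target
    for (r in seq_len(nrow(poly))) {
      mass <- dhyper(j, poly$m[r], poly$c[r] - poly$m[r], n_target)
      fb <- pmin(j, n_target - j)
      for (b in seq_len(nb)) counts[b] <- counts[b] + sum(mass[fb == b])
    }
  }
  folded_sfs(counts, n = n_target, L = nrow(ps), class = class,
             species = species, gene_class = gene_class)
}

#' Single-site hypergeometric projection masses
#'
#' The folded projection kernel for one site: probabilities over folded
#' bins `0..floor(n_target/2)` that a draw of `n_target` haplotypes from
#' `m` minor and `c - m` major alleles contains `j` minor (folded) copies.
#' Bin 0 pools the monomorphic outcomes (`j = 0` and `j = n_target`).
#'
#' @param m minor-allele count at the site.
#' @param c called haplotypes at the site (`>= n_target`).
#' @param n_target projected sample size.
#' @return numeric vector of length `floor(n_target/2) + 1` (bin 0 first)
#'   summing to 1.
#' @export
projection_masses <- function(m, c, n_target = 14) {
  stopifnot(m <= c, c >= n_target)
  j <- 0:n_target
  mass <- dhyper(j, m, c - m, n_target)
  fb <- pmin(j, n_target - j)
  vapply(0:(n_target %/% 2), function(b) sum(mass[fb == b]), 0)
}
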