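# Quasi-phasing of the dominant within-host strain and the sample/site/
# gene filters applied before SFS construction: depth floors, gene copy
# number and prevalence classes, clonal-lineage exclusion, and
# low-recombination / selective-sweep masking.  Coordinates are 0-based
# half-open throughout; mask intervals use union semantics.

#' Quasi-phase the dominant lineage of one host
#'
#' A site is called as the host's major allele only if that allele's
#' frequency is at least 0.8 (inclusive) and the site depth is at least
#' `min_depth_site`; major-allele frequencies between 0.5 and 0.8 are
#' explicit missing data, as are low-depth sites.
#'
#' @param calls data frame of per-site calls for a single (species, host):
#'   columns `host, contig, pos0, gene_id, degeneracy, major_freq, depth`
#'   and `major_allele` (allele identity of the within-host majority).
#' @param min_depth_site minimum site depth in reads (default 20).
#' @return data.table with the input site columns plus `allele`
#'   (`major_allele` where called, `NA` where missing).
#' @export
call_quasi_phased <- function(calls, min_depth_site = 20) {
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) == 0) {
    return(calls[, c("allele") := character(0)])
  }
  if (length(unique(calls$host)) > 1) {
    stop("quasi-phasing operates on a single (species, host)")
  }
  called <- !is.na(calls$major_freq) & calls$major_freq >= 0.8 &
    calls$depth >= min_depth_site
  out <- calls[, c("host", "contig", "pos0", "gene_id", "degeneracy"),
               with = FALSE]
  out[, allele := ifelse(called, calls$major_allele, NA_character_)]
  out[]
}

#' Mean-depth sample filter
#'
#' Retains hosts whose mean site depth for the species is at least
#' `min_mean_depth` (the 20x minimum sample depth), applied before any
#' site-level filtering.
#'
#' @param calls per-host site-call table (column `host`, `depth`).
#' @param min_mean_depth minimum mean coverage (default 20).
#' @return character vector of retained host labels.
#' @export
filter_hosts_by_depth <- function(calls, min_mean_depth = 20) {
  calls <- data.table::as.data.table(calls)
  md <- calls[, list(mean_depth = mean(depth)), by = "host"]
  sort(md$host[md$mean_depth >= min_mean_depth])
}

#' Classify genes as core / accessory / excluded from copy numbers
#'
#' A gene with copy number above 3.0 in any host is excluded from the
#' entire dataset.  Otherwise a gene counts as present in a host when its
#' copy number is within `[0.3, 3.0]`; prevalence is the fraction of hosts
#' with the gene present.  Core: prevalence `>= 0.95`; accessory:
#' `0.30 <= prevalence <= 0.70`; anything else is excluded.
#'
#' @param copy_numbers numeric matrix, hosts x genes (dimnames used as
#'   labels), all values `>= 0`.
#' @return data frame `gene_id, prevalence, class`.
#' @export
filter_genes <- function(copy_numbers) {
  if (length(copy_numbers) == 0 || nrow(copy_numbers) == 0 ||
      ncol(copy_numbers) == 0) {
    stop("empty copy-number matrix")
  }
  if (any(copy_numbers < 0)) stop("copy numbers must be >= 0")
  genes <- colnames(copy_numbers)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(copy_numbers)))
  over <- apply(copy_numbers > 3.0, 2, any)
  present <- copy_numbers >= 0.3 & copy_numbers <= 3.0
  prevalence <- colMeans(present)
  cls <- ifelse(over, "excluded",
                ifelse(prevalence >= 0.95, "core",
                       ifelse(prevalence >= 0.30 & prevalence <= 0.70,
                              "accessory", "excluded")))
  data.frame(gene_id = genes, prevalence = prevalence, class = cls,
             row.names = NULL)
}

#' Exclude near-clonal lineages, keeping one representative per cluster
#'
#' Builds a graph with an edge between any two hosts whose genome-wide
#' divergence is below `threshold` (default `2e-4` per bp) and keeps a
#' single representative per connected component: the host with the most
#' called sites, ties broken lexicographically.  Dropping whole clusters
#' would discard the information they carry; one representative preserves
#' it while removing the clonal structure.
#'
#' @param divergences symmetric numeric matrix of pairwise divergences per
#'   bp (dimnames are host labels; the diagonal is ignored).
#' @param threshold divergence below which two hosts are considered clonal
#'   relatives (default `2e-4`).
#' @param site_counts optional named vector of called-site counts used to
#'   pick representatives.
#' @return character vector of retained hosts (sorted).
#' @export
exclude_clonal <- function(divergences, threshold = 2e-4,
                           site_counts = NULL) {
  stopifnot(is.matrix(divergences), nrow(divergences) == ncol(divergences))
  hosts <- rownames(divergences)
  if (is.null(hosts)) hosts <- paste0("host", seq_len(nrow(divergences)))
  n <- length(hosts)
  if (is.null(site_counts)) site_counts <- setNames(rep(0, n), hosts)
  adj <- divergences < threshold
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  keep <- vapply(split(seq_len(n), comp), function(idx) {
    sc <- site_counts[hosts[idx]]
    sc[is.na(sc)] <- 0
    cand <- idx[sc == max(sc)]
    cand[order(hosts[cand])][1]
  }, 0L)
  sort(hosts[keep])
}

#' Mask low-recombination windows and selective-sweep flanks
#'
#' Removes haplotype sites that fall in 1,000-bp windows whose mean
#' recombination rate is strictly below the median rate (median taken over
#' windows with defined rates), or inside a sweep interval expanded by
#' `flank` bp on each side (clipped at 0).  Masking is idempotent.
#'
#' @param haplotypes site table with columns `contig, pos0` (and anything
#'   else, preserved).
#' @param recomb_rates data frame `contig, window_start0, rate` of
#'   non-overlapping 1,000-bp tiles; `NULL` to skip.
#' @param sweeps data frame `contig, start0, end0` (0-based half-open) of
#'   sweep intervals; `NULL` or empty to skip.
#' @param window_size tile width in bp (default 1000).
#' @param flank sweep flank in bp (default 1000).
#' @return list with `haplotypes` (sites outside every mask) and `mask`
#'   (data frame `contig, start0, end0, kind`).
#' @export
apply_masks <- function(haplotypes, recomb_rates = NULL, sweeps = NULL,
                        window_size = 1000, flank = 1000) {
  hap <- data.table::as.data.table(haplotypes)
  masks <- list()
  if (!is.null(recomb_rates) && nrow(recomb_rates) > 0) {
    rr <- recomb_rates[!is.na(recomb_rates$rate), , drop = FALSE]
    med <- median(rr$rate)
    low <- rr[rr$rate < med, , drop = FALSE]
    if (nrow(low) > 0) {
      masks[[length(masks) + 1]] <- data.frame(
        contig = low$contig, start0 = low$window_start0,
        end0 = low$window_start0 + window_size, kind = "low_recombination")
    }
  }
  if (!is.null(sweeps) && nrow(sweeps) > 0) {
    if (any(sweeps$end0 <= sweeps$start0)) {
      stop("sweep intervals must have start0 < end0")
    }
    masks[[length(masks) + 1]] <- data.frame(
      contig = sweeps$contig, start0 = pmax(sweeps$start0 - flank, 0),
      end0 = sweeps$end0 + flank, kind = "sweep")
  }
  mask <- if (length(masks) > 0) do.call(rbind, masks) else
    data.frame(contig = character(0), start0 = numeric(0),
               end0 = numeric(0), kind = character(0))
  if (nrow(mask) > 0 && nrow(hap) > 0) {
    drop <- rep(FALSE, nrow(hap))
    for (i in seq_len(nrow(mask))) {
      drop <- drop | (hap$contig == mask$contig[i] &
                        hap$pos0 >= mask$start0[i] &
                        hap$pos0 < mask$end0[i])
    }
    hap <- hap[!drop]
  }
  list(haplotypes = hap[], mask = mask)
}

#' Restrict hosts to a clade and drop blacklisted genes
#'
#' Clade membership and cross-species gene identity are consumed as
#' precomputed label files, not inferred here.
#'
#' @param hosts character vector of host labels.
#' @param clade_labels named character vector host -> clade.
#' @param clade clade to keep; default the largest.
#' @return retained host labels.
#' @export
filter_hosts_by_clade <- function(hosts, clade_labels, clade = NULL) {
  cl <- clade_labels[hosts]
  if (is.null(clade)) {
    tab <- sort(table(cl), decreasing = TRUE)
    clade <- names(tab)[1]
  }
  hosts[!is.na(cl) & cl == clade]
}

#' @rdname filter_hosts_by_clade
#' @param gene_ids character vector of gene labels.
#' @param blacklist character vector of genes to exclude (e.g. >= 95%
#'   cross-species nucleotide identity).
#' @export
filter_gene_blacklist <- function(gene_ids, blacklist) {
  setdiff(gene_ids, blacklist)
}
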