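# Quasi-phasing call rules and the sample/site/gene filters.

calls_row <- function(major_freq, depth, host = "h1", pos0 = 0) {
  data.frame(species = "sp", host = host, contig = "c1", pos0 = pos0,
             gene_id = "g1", degeneracy = "4D", major_freq = major_freq,
             depth = depth, major_allele = "1")
}

test_that("quasi-phasing applies the 0.8 frequency and 20x depth rules", {
  grid <- rbind(calls_row(0.85, 25, pos0 = 0),
                calls_row(0.80, 25, pos0 = 1),   # inclusive boundary
                calls_row(0.799, 25, pos0 = 2),
                calls_row(0.95, 19, pos0 = 3),   # depth below the floor
                calls_row(0.95, 20, pos0 = 4))
  qp <- call_quasi_phased(grid)
  expect_identical(is.na(qp$allele), c(FALSE, FALSE, TRUE, TRUE, FALSE))
  # empty input -> empty haplotype, no error
  expect_identical(nrow(call_quasi_phased(grid[0, ])), 0L)
  # mixed hosts are refused
  expect_error(call_quasi_phased(rbind(calls_row(0.9, 30, host = "h1"),
                                       calls_row(0.9, 30, host = "h2"))),
               "single")
})

test_that("gene filtering classifies by copy number and prevalence", {
  H <- 100
  cn <- cbind(
    core96 = c(rep(1, 96), rep(0, 4)),          # prevalence 0.96
    acc50 = c(rep(1, 50), rep(0, 50)),          # prevalence 0.50
    exc80 = c(rep(1, 80), rep(0, 20)),          # prevalence 0.80
    high_cn = c(3.5, rep(1, H - 1)),            # CN > 3 in one host
    low_support = rep(0.2, H))                  # CN below 0.3 everywhere
  rownames(cn) <- sprintf("h%03d", 1:H)
  gc <- filter_genes(cn)
  cls <- setNames(gc$class, gc$gene_id)
  expect_identical(unname(cls[c("core96", "acc50", "exc80", "high_cn",
                                "low_support")]),
                   c("core", "accessory", "excluded", "excluded",
                     "excluded"))
  expect_equal(gc$prevalence[gc$gene_id == "acc50"], 0.5)
  expect_error(filter_genes(matrix(numeric(0), 0, 0)), "empty")
})

test_that("clonal exclusion keeps one representative per component", {
  mk <- function(d) {
    rownames(d) <- colnames(d) <- paste0("h", seq_len(nrow(d)))
    d
  }
  far <- mk(matrix(1e-3, 4, 4))
  expect_identical(exclude_clonal(far), paste0("h", 1:4))
  pair <- mk(matrix(c(0, 1e-4, 1e-4, 0), 2, 2) + diag(2) * 0)
  pair[1, 2] <- pair[2, 1] <- 1e-4
  expect_length(exclude_clonal(pair), 1)
  # triangle below threshold: brute force over components says 1 survivor
  tri <- mk(matrix(1e-4, 3, 3))
  kept <- exclude_clonal(tri, site_counts = c(h1 = 5, h2 = 9, h3 = 9))
  expect_identical(kept, "h2")  # max site count, lexicographic tie-break
  # invariant: no two retained hosts are below threshold
  set.seed(1)
  d <- matrix(runif(100, 0, 5e-4), 10, 10)
  d <- mk((d + t(d)) / 2)
  kept <- exclude_clonal(d)
  sub <- d[kept, kept, drop = FALSE]
  diag(sub) <- 1
  expect_true(all(sub >= 2e-4))
})

test_that("masking removes sweep flanks and below-median windows", {
  hap <- data.frame(contig = "c1", pos0 = c(500, 3999, 4000, 5500, 6999,
                                            7000, 9500))
  sweeps <- data.frame(contig = "c1", start0 = 5000, end0 = 6000)
  res <- apply_masks(hap, sweeps = sweeps)
  # mask is [4000, 7000): 1000 bp flanking on each side
  expect_identical(res$haplotypes$pos0, c(500, 3999, 7000, 9500))
  rr <- data.frame(contig = "c1", window_start0 = (0:4) * 1000,
                   rate = 1:5)
  res2 <- apply_masks(hap, recomb_rates = rr)
  # median 3; windows with rates 1 and 2 (strictly below) masked
  expect_identical(res2$haplotypes$pos0, c(3999, 4000, 5500, 6999, 7000,
                                           9500))
  # uniform rates and no sweeps: nothing masked
  rr_u <- data.frame(contig = "c1", window_start0 = (0:4) * 1000,
                     rate = rep(2, 5))
  expect_identical(apply_masks(hap, recomb_rates = rr_u)$haplotypes$pos0,
                   hap$pos0)
  # idempotence
  once <- apply_masks(hap, recomb_rates = rr, sweeps = sweeps)
  twice <- apply_masks(once$haplotypes, recomb_rates = rr, sweeps = sweeps)
  expect_identical(as.data.frame(twice$haplotypes),
                   as.data.frame(once$haplotypes))
})

test_that("depth, clade and blacklist helpers filter as specified", {
  calls <- data.frame(host = rep(c("a", "b"), each = 4),
                      depth = c(rep(25, 4), c(10, 15, 20, 25)))
  expect_identical(filter_hosts_by_depth(calls), "a")
  labs <- c(a = "clade1", b = "clade1", c = "clade2")
  expect_identical(filter_hosts_by_clade(c("a", "b", "c"), labs),
                   c("a", "b"))
  expect_identical(filter_gene_blacklist(c("g1", "g2", "g3"), "g2"),
                   c("g1", "g3"))
})
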