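#' Construct a folded site-frequency spectrum
#'
#' A folded SFS stores (possibly fractional) counts of polymorphic sites by
#' minor-allele count `1..floor(n/2)` in a sample of `n` haplotypes, together
#' with the number `L` of monitored sites (monomorphic sites included) and
#' the mutation class the spectrum was built from.
#'
#' Fractional counts arise from hypergeometric projection and are retained
#' unrounded; downstream likelihoods accept them through log-gamma
#' generalized factorials.
#'
#' @param counts numeric vector of length `floor(n/2)`, all `>= 0`.
#' @param n sample size (haplotypes), `>= 2`.
#' @param L number of monitored sites, `>= sum(counts)`.
#' @param class `"synonymous"` or `"nonsynonymous"`.
#' @param species optional species label.
#' @param gene_class optional gene-class label (`"core"`, `"accessory"`).
#' @return an object of class `folded_sfs`.
#' @export
folded_sfs <- function(counts, n, L,
                       class = c("synonymous", "nonsynonymous"),
                       species = NA_character_, gene_class = NA_character_) {
  class <- match.arg(class)
  n <- as.integer(n)
  if (n < 2) stop("folded SFS requires n >= 2")
  if (length(counts) != n %/% 2) {
    stop("counts must have length floor(n/2) = ", n %/% 2)
  }
  if (any(counts < 0)) stop("SFS counts must be non-negative")
  if (L < sum(counts) - 1e-8) stop("L must be >= sum(counts)")
  structure(
    list(counts = as.numeric(counts), n = n, L = as.numeric(L),
         class = class, species = species, gene_class = gene_class),
    class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat(sprintf("Folded SFS (%s%s): n = %d, L = %g, S = %g\n", x$class,
              if (!is.na(x$species)) paste0(", ", x$species) else "",
              x$n, x$L, sum(x$counts)))
  print(setNames(round(x$counts, 3), seq_along(x$counts)))
  invisible(x)
}

#' Write / read a folded SFS as TSV
#'
#' The file holds `# key=value` header lines (`n`, `L`, `class`, `species`,
#' `gene_class`) followed by a two-column `bin  count` table.  Reading back
#' is lossless.
#'
#' @param sfs a [folded_sfs()].
#' @param path output file path.
#' @return `write_sfs_tsv` returns `path` invisibly; `read_sfs_tsv` returns
#'   the [folded_sfs()].
#' @export
write_sfs_tsv <- function(sfs, path) {
  stopifnot(inherits(sfs, "folded_sfs"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# n=%d", sfs$n),
    sprintf("# L=%.17g", sfs$L),
    sprintf("# class=%s", sfs$class),
    sprintf("# species=%s", sfs$species),
    sprintf("# gene_class=%s", sfs$gene_class),
    "bin\tcount"), con)
  writeLines(sprintf("%d\t%.17g", seq_along(sfs$counts), sfs$counts), con)
  invisible(path)
}

#' @rdname write_sfs_tsv
#' @export
read_sfs_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key) {
    v <- sub(paste0("^# ", key, "="), "", grep(paste0("^# ", key, "="),
                                               hdr, value = TRUE)[1])
    v
  }
  tab <- read.table(text = lines[!grepl("^# ", lines)], header = TRUE,
                    sep = "\t")
  folded_sfs(counts = tab$count[order(tab$bin)],
             n = as.integer(get("n")), L = as.numeric(get("L")),
             class = get("class"), species = get("species"),
             gene_class = get("gene_class"))
}
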