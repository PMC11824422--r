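# Pipeline orchestration: simulate -> phase/filter -> SFS -> demography ->
# DFE (-> compare -> phylosignal) behind a single config, with plain
# TSV/JSON stage outputs so any stage can be re-run in isolation and a
# re-run with the same config and seed is byte-identical.

#' Build a pipeline configuration
#'
#' Defaults follow the stated analysis constants: projection to 14
#' haplotypes, a minimum of 14 quasi-phased genomes per species (47 for
#' accessory-gene analyses), mutation rate `4.08e-10` per site per
#' generation (an alternate `1e-10` is supported), one generation per day
#' and `theta_ns / theta_s = 2.31`.
#'
#' @param species named list; each entry is a list of [sim_scenario()]
#'   arguments (with `demography = list(epochs=, change_times=)` and
#'   optionally `dfe = list(family=, shape=, scale=, p_neu=, N_anc_ref=)`),
#'   or an already-built `sim_scenario`.
#' @param out_dir output directory (created).
#' @param input_mode `"sfs"` (simulate folded spectra directly) or
#'   `"pileup"` (simulate per-host call tables and run quasi-phasing +
#'   projection).
#' @param n_target projection sample size.
#' @param min_qp_genomes minimum quasi-phased genomes per species.
#' @param min_qp_accessory minimum QP samples for accessory analyses.
#' @param gene_class `"core"` or `"accessory"`.
#' @param mu mutation rate per site per generation.
#' @param generations_per_day generations per day for time conversion.
#' @param theta_ratio `theta_ns / theta_s`.
#' @param demog_families demographic families to fit and compare by AIC.
#' @param dfe_families DFE families to fit.
#' @param m_lrt Bonferroni `m` for the pairwise LRT battery (`NULL`: use
#'   the number of pairs actually compared).
#' @param compare run the all-pairs DFE-equality LRT battery after the
#'   per-species fits.
#' @param compare_scale `"s"` or `"two_Nanc_s"` for the battery.
#' @param tree_file optional newick species tree; when given (and at least
#'   4 species have DFE fits) Pagel's lambda is estimated for the DFE
#'   summaries (proportion neutral, `E[s]`, `N_Anc`, shape).
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(species, out_dir, input_mode = c("sfs", "pileup"),
                            n_target = 14, min_qp_genomes = 14,
                            min_qp_accessory = 47,
                            gene_class = c("core", "accessory"),
                            mu = 4.08e-10, generations_per_day = 1,
                            theta_ratio = 2.31,
                            demog_families = c("one", "two"),
                            dfe_families = "gamma", m_lrt = NULL,
                            compare = FALSE, compare_scale = "s",
                            tree_file = NULL, seed = 1) {
  structure(list(species = species, out_dir = out_dir,
                 input_mode = match.arg(input_mode),
                 n_target = as.integer(n_target),
                 min_qp_genomes = as.integer(min_qp_genomes),
                 min_qp_accessory = as.integer(min_qp_accessory),
                 gene_class = match.arg(gene_class), mu = mu,
                 generations_per_day = generations_per_day,
                 theta_ratio = theta_ratio,
                 demog_families = demog_families,
                 dfe_families = dfe_families, m_lrt = m_lrt,
                 compare = isTRUE(compare), compare_scale = compare_scale,
                 tree_file = tree_file, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file (`.yaml`/`.yml` needs the yaml package,
#'   anything else is parsed as JSON).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed for YAML configs; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame =
                          FALSE, simplifyMatrix = FALSE)
  }
  do.call(pipeline_config, raw)
}

scenario_from_config <- function(spec, default_seed) {
  if (inherits(spec, "sim_scenario")) return(spec)
  if (!is.null(spec$dfe) && length(spec$dfe) == 0) spec$dfe <- NULL
  if (!is.null(spec$demography) && !inherits(spec$demography,
                                             "demographic_model")) {
    spec$demography <- demographic_model(
      unlist(spec$demography$epochs),
      unlist(spec$demography$change_times %||% numeric(0)))
  }
  if (!is.null(spec$dfe) && !inherits(spec$dfe, "dfe_model")) {
    d <- spec$dfe
    spec$dfe <- dfe_model(d$family %||% "gamma", shape = d$shape,
                          scale = d$scale, p_neu = d$p_neu %||% 0,
                          N_anc_ref = d$N_anc_ref %||% NA_real_)
  }
  if (is.null(spec$seed)) spec$seed <- default_seed
  do.call(sim_scenario, spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_json_file <- function(x, path) {
  strip <- function(v) {
    if (is.data.frame(v)) v
    else if (is.list(v)) lapply(unclass(v), strip)
    else v
  }
  jsonlite::write_json(strip(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages per species, skipping species with fewer
#' than `min_qp_genomes` quasi-phased genomes (and, for accessory-gene
#' runs, fewer than `min_qp_accessory` QP samples), and writes plain
#' TSV/JSON artifacts plus an attrition log (no timestamps, so re-runs
#' are byte-identical) under `out_dir/<species>/`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a named list of per-species results (`"skipped"`
#'   entries carry the reason as attribute).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  resolved <- config
  resolved$species <- lapply(config$species, function(s) {
    if (inherits(s, "sim_scenario")) unclass(s) else s
  })
  write_json_file(resolved, file.path(config$out_dir, "config.json"))
  results <- list()
  for (sp in names(config$species)) {
    log_lines <- character(0)
    log_add <- function(...) {
      line <- sprintf(...)
      log_lines <<- c(log_lines, line)
      message("[", sp, "] ", line)
    }
    spd <- file.path(config$out_dir, sp)
    dir.create(spd, showWarnings = FALSE)
    scenario <- scenario_from_config(config$species[[sp]], config$seed)
    cache <- new_spectrum_cache()
    n_qp <- scenario$n_hosts
    if (config$input_mode == "pileup") {
      pileup <- simulate_host_pileup(scenario, species = sp, cache = cache)
      data.table::fwrite(pileup, file.path(spd, "pileup.tsv"), sep = "\t")
      hosts_depth <- filter_hosts_by_depth(pileup)
      log_add("hosts passing 20x mean depth: %d of %d",
              length(hosts_depth), scenario$n_hosts)
      qp <- data.table::rbindlist(lapply(hosts_depth, function(h) {
        call_quasi_phased(pileup[pileup$host == h])
      }))
      data.table::fwrite(qp, file.path(spd, "qp_haplotypes.tsv"),
                         sep = "\t", na = ".")
      n_qp <- length(hosts_depth)
    }
    min_needed <- if (config$gene_class == "accessory") {
      config$min_qp_accessory
    } else {
      config$min_qp_genomes
    }
    if (n_qp < min_needed) {
      log_add("skipped: %d QP genomes < required %d (%s analysis)",
              n_qp, min_needed, config$gene_class)
      writeLines(log_lines, file.path(spd, "log.txt"))
      results[[sp]] <- structure("skipped",
                                 reason = sprintf("%d < %d QP genomes",
                                                  n_qp, min_needed))
      next
    }
    if (config$input_mode == "pileup") {
      built_syn <- build_folded_sfs(qp, "synonymous")
      sfs_syn <- project_sfs(built_syn$per_site, config$n_target,
                             "synonymous", species = sp,
                             gene_class = config$gene_class)
      log_add("synonymous sites: %d raw, %d projectable",
              nrow(built_syn$per_site), round(sfs_syn$L))
      built_ns <- build_folded_sfs(qp, "nonsynonymous")
      sfs_ns <- project_sfs(built_ns$per_site, config$n_target,
                            "nonsynonymous", species = sp,
                            gene_class = config$gene_class)
    } else {
      sfs_syn <- simulate_sfs_counts(scenario, "syn", cache = cache)
      sfs_syn$species <- sp
      sfs_ns <- if (!is.null(scenario$dfe)) {
        s <- simulate_sfs_counts(scenario, "nonsyn", cache = cache)
        s$species <- sp
        s
      } else {
        NULL
      }
    }
    write_sfs_tsv(sfs_syn, file.path(spd, "sfs_synonymous.tsv"))
    if (!is.null(sfs_ns)) {
      write_sfs_tsv(sfs_ns, file.path(spd, "sfs_nonsynonymous.tsv"))
    }
    log_add("synonymous segregating sites: %g", sum(sfs_syn$counts))
    fits <- lapply(config$demog_families, function(f) {
      fit_demography(sfs_syn, f, seed = config$seed)
    })
    best <- if (length(fits) == 1) fits[[1]] else select_model(fits)
    N_anc <- ancestral_size(best$model$theta_s, mu = config$mu,
                            L_syn = sfs_syn$L)
    years <- if (length(best$model$change_times) > 0) {
      tau_to_years(best$model$change_times, N_anc,
                   config$generations_per_day)
    } else {
      numeric(0)
    }
    log_add("best demography: %s-epoch (AIC %.2f), theta_s = %.4g, N_Anc = %.4g",
            best$family, best$aic, best$model$theta_s, N_anc)
    demog_out <- list(
      family = best$family, epochs = best$model$epochs,
      change_times = best$model$change_times,
      theta_s = best$model$theta_s, loglik = best$loglik, k = best$k,
      aic = best$aic, N_anc = N_anc, change_times_years = years,
      ci = best$ci,
      all_aic = setNames(lapply(fits, function(f) f$aic),
                         config$demog_families))
    write_json_file(demog_out, file.path(spd, "demog_fit.json"))
    res <- list(sfs_syn = sfs_syn, sfs_ns = sfs_ns, demog = best,
                N_anc = N_anc)
    if (!is.null(sfs_ns)) {
      dfe_fits <- lapply(config$dfe_families, function(f) {
        fit_dfe(sfs_ns, best, f, N_anc = N_anc,
                theta_ratio = config$theta_ratio, seed = config$seed,
                cache = cache)
      })
      names(dfe_fits) <- config$dfe_families
      aics <- vapply(dfe_fits, function(f) f$aic, 0)
      pick <- dfe_fits[[which.min(aics + 1e-6 * seq_along(aics))]]
      log_add("DFE (%s): shape = %.4g, E[s] = %.4g",
              pick$dfe$family, pick$dfe$shape, pick$dfe$E_s)
      dfe_out <- list(
        family = pick$dfe$family, shape = pick$dfe$shape,
        scale = pick$dfe$scale, p_neu = pick$dfe$p_neu,
        E_s = pick$dfe$E_s, theta_ns = pick$theta_ns,
        loglik = pick$loglik, aic = pick$aic,
        bin_masses = as.list(dfe_bin_masses(pick$dfe)),
        all_aic = as.list(aics))
      write_json_file(dfe_out, file.path(spd, "dfe_fit.json"))
      res$dfe <- pick
    }
    writeLines(log_lines, file.path(spd, "log.txt"))
    results[[sp]] <- res
  }
  fitted <- Filter(function(r) is.list(r) && !is.null(r$dfe), results)
  if (config$compare && length(fitted) >= 2) {
    results$compare <- pipeline_compare(fitted, config)
  }
  if (!is.null(config$tree_file) && length(fitted) >= 4) {
    results$phylosignal <- pipeline_phylosignal(fitted, config)
  }
  invisible(results)
}

# All-pairs DFE-equality LRT battery over the fitted species.
pipeline_compare <- function(fitted, config) {
  sps <- names(fitted)
  pairs <- utils::combn(sps, 2)
  m <- config$m_lrt %||% ncol(pairs)
  caches <- lapply(fitted, function(x) new_spectrum_cache())
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    dsA <- dfe_dataset(fitted[[a]]$sfs_ns, fitted[[a]]$demog,
                       N_anc = fitted[[a]]$N_anc,
                       theta_ratio = config$theta_ratio)
    dsB <- dfe_dataset(fitted[[b]]$sfs_ns, fitted[[b]]$demog,
                       N_anc = fitted[[b]]$N_anc,
                       theta_ratio = config$theta_ratio)
    r <- lrt_dfe_pair(dsA, dsB, config$compare_scale, m = m,
                      seed = config$seed, cacheA = caches[[a]],
                      cacheB = caches[[b]])
    data.frame(speciesA = a, speciesB = b, scale = r$scale, stat = r$stat,
               critical = r$critical, significant = r$significant)
  })
  tab <- do.call(rbind, rows)
  write.table(tab, file.path(config$out_dir, "compare_lrt.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}

# Pagel's lambda for the four DFE summaries across the fitted species.
pipeline_phylosignal <- function(fitted, config) {
  tree <- ape::read.tree(config$tree_file)
  traits <- data.frame(
    species = names(fitted),
    prop_neutral = vapply(fitted, function(x)
      unname(dfe_bin_masses(x$dfe$dfe)["neutral"]), 0),
    E_s = vapply(fitted, function(x) x$dfe$dfe$E_s, 0),
    N_anc = vapply(fitted, function(x) x$N_anc, 0),
    shape = vapply(fitted, function(x) x$dfe$dfe$shape, 0),
    row.names = NULL)
  write.table(traits, file.path(config$out_dir, "dfe_traits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  out <- lapply(c("prop_neutral", "E_s", "N_anc", "shape"), function(tr) {
    y <- setNames(traits[[tr]], traits$species)
    res <- tryCatch(pagels_lambda(tree, y), error = function(e) NULL)
    if (is.null(res)) list(trait = tr, error = "not estimable") else
      list(trait = tr, lambda_hat = res$lambda_hat,
           p_value = res$p_value, loglik_at_hat = res$loglik_at_hat,
           loglik_at_zero = res$loglik_at_zero)
  })
  write_json_file(out, file.path(config$out_dir, "phylosignal.json"))
  out
}
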