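#' End-to-end run configuration
#'
#' Bundles the simulation (or input VCF paths), per-population QC
#' thresholds and analysis parameters of a full pipeline run.  Analysis
#' defaults are the package's standard values: a 5-Mb pair-distance cap,
#' 25-kb LD-decay bins, 50-kb consistency bins, 250-kb/25-kb haplotype
#' homozygosity windows, 0.98/0.70 strong-LD bounds and 2:1:1 combined
#' weights.
#'
#' @param sim a [sim_config()], or NULL to read panels from `vcf_paths`.
#' @param vcf_paths named character vector of phased VCFs (names are the
#'   population labels; must include B, C, D and one crossbred panel)
#'   used when `sim` is NULL.
#' @param qc_pure,qc_crossbred [qc_thresholds()] for pure lines (HWE
#'   applied) and crossbreds (HWE skipped).
#' @param max_pair_distance,decay_bin,consistency_bin,hh_window,hh_step
#'   analysis parameters in bp.
#' @param block_rules a [gabriel_rules()].
#' @param combined_weights pooling weights for the combined panel.
#' @param combined_n total size of the combined panel.
#' @param run_blocks logical; call haploblocks (the slowest stage)?
#' @param seed integer seed for the combined-panel sampling (the
#'   simulation carries its own seed).
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), vcf_paths = NULL,
                       qc_pure = qc_thresholds(apply_hwe = TRUE),
                       qc_crossbred = qc_thresholds(apply_hwe = FALSE),
                       max_pair_distance = 5e6, decay_bin = 25000,
                       consistency_bin = 50000, hh_window = 250000,
                       hh_step = 25000, block_rules = gabriel_rules(),
                       combined_weights = c(2, 1, 1), combined_n = 400,
                       run_blocks = TRUE, seed = 1L) {
  if (is.null(sim) && is.null(vcf_paths))
    stop("provide either a sim_config or input vcf_paths")
  if (!is.null(vcf_paths)) {
    if (is.null(names(vcf_paths)) ||
        !all(c("B", "C", "D") %in% names(vcf_paths)))
      stop("vcf_paths must be named and include panels B, C and D")
    missing <- vcf_paths[!file.exists(vcf_paths)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(list(sim = sim, vcf_paths = vcf_paths, qc_pure = qc_pure,
                 qc_crossbred = qc_crossbred,
                 max_pair_distance = max_pair_distance,
                 decay_bin = decay_bin, consistency_bin = consistency_bin,
                 hh_window = hh_window, hh_step = hh_step,
                 block_rules = block_rules,
                 combined_weights = combined_weights,
                 combined_n = combined_n, run_blocks = isTRUE(run_blocks),
                 seed = as.integer(seed)),
            class = "run_config")
}

.write_tsv <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full LD-characterization pipeline
#'
#' Executes simulate (or load) -> per-population QC -> LD decay by
#' chromosome category (with the r-squared < 0.2 distance) ->
#' adjacent-SNP LD summary -> combined-population construction ->
#' consistency of LD for all population pairs -> haploblocks and
#' summary -> haplotype homozygosity -> MAF spectra and F_st, writing
#' one TSV per artifact plus a machine-readable JSON manifest of the
#' parameters and completed stages into `out_dir`.  Reruns with the
#' same configuration and seed produce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if absent).
#' @param quiet suppress progress messages?
#' @return Invisibly, a list with the panels, per-stage results and the
#'   manifest.
#' @export
run_all <- function(config = run_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[crossld] ", ...)
  stages <- character(0)
  done <- function(s) stages <<- c(stages, s)

  if (!is.null(config$sim)) {
    say("simulating base population and lines")
    base <- simulate_base(config$sim)
    lines <- diverge_lines(base, config$sim)
    say("breeding three-way cross")
    cross <- make_cross(lines$B, lines$C, lines$D, config$sim)
    panels <- c(lines, list(BCD = cross))
  } else {
    say("reading input VCFs")
    panels <- lapply(names(config$vcf_paths), function(nm)
      read_phased_vcf(config$vcf_paths[[nm]], label = nm))
    names(panels) <- names(config$vcf_paths)
  }
  done("input")

  categories <- if (!is.null(config$sim))
    stats::setNames(config$sim$chrom_categories,
                    seq_along(config$sim$chrom_categories))
  else gga_categories()

  say("quality control")
  qc <- lapply(names(panels), function(nm) {
    th <- if (nm %in% c("B", "C", "D")) config$qc_pure else config$qc_crossbred
    run_qc(panels[[nm]], th)
  })
  names(qc) <- names(panels)
  for (nm in names(qc)) .write_tsv(qc[[nm]]$report, out_dir, paste0("qc_", nm))
  clean <- lapply(qc, `[[`, "panel")
  done("qc")

  say("common SNPs and orientation")
  ids <- common_snps(clean)
  clean <- orient_alleles(lapply(clean, subset_snps, snps = ids))
  names(clean) <- names(qc)
  done("common_snps")

  say("pairwise LD and decay curves")
  pairs <- lapply(clean, pairwise_ld, max_pair_distance = config$max_pair_distance)
  curves <- lapply(names(clean), function(nm) {
    cv <- decay_curve(pairs[[nm]], categories, config$decay_bin)
    cbind(population = nm, cv)
  })
  curve_tab <- do.call(rbind, curves)
  .write_tsv(curve_tab, out_dir, "ld_decay")
  d02 <- do.call(rbind, lapply(names(clean), function(nm) {
    cv <- curve_tab[curve_tab$population == nm, ]
    data.frame(population = nm, category = unique(cv$category),
               d_0.2 = vapply(unique(cv$category), function(ct)
                 d_threshold_distance(cv[cv$category == ct, ]), numeric(1)))
  }))
  .write_tsv(d02, out_dir, "d02")
  adj <- do.call(rbind, lapply(names(clean), function(nm) {
    s <- adjacent_ld_summary(clean[[nm]])
    data.frame(population = nm, n_pairs = s$n_pairs, mean_r2 = s$mean_r2,
               t(s$frac_gt))
  }))
  .write_tsv(adj, out_dir, "adjacent_ld")
  done("ld")

  say("combined panel and consistency of LD")
  comb <- predict_crossbred_ld(clean$B, clean$C, clean$D,
                               weights = config$combined_weights,
                               n_total = config$combined_n, seed = config$seed,
                               max_pair_distance = config$max_pair_distance)
  all_pops <- c(clean, list(cBCD = comb$panel))
  pairs_of <- utils::combn(names(all_pops), 2, simplify = FALSE)
  cons <- do.call(rbind, lapply(pairs_of, function(pr) {
    cb <- correlation_of_r(all_pops[[pr[1]]], all_pops[[pr[2]]], categories,
                           config$consistency_bin, config$max_pair_distance)
    cbind(pop_a = pr[1], pop_b = pr[2], cb)
  }))
  .write_tsv(cons, out_dir, "consistency")
  done("consistency")

  blocks <- NULL
  if (config$run_blocks) {
    say("haploblocks")
    blocks <- lapply(clean, gabriel_blocks, rules = config$block_rules,
                     max_pair_distance = config$max_pair_distance)
    btab <- do.call(rbind, lapply(names(blocks), function(nm)
      if (nrow(blocks[[nm]])) cbind(population = nm, blocks[[nm]])))
    if (!is.null(btab)) .write_tsv(btab, out_dir, "blocks")
    bsum <- do.call(rbind, lapply(names(blocks), function(nm)
      data.frame(population = nm,
                 block_summary(blocks[[nm]], n_snps(clean[[nm]])))))
    .write_tsv(bsum, out_dir, "block_summary")
    done("blocks")
  }

  say("haplotype homozygosity")
  hh <- do.call(rbind, lapply(names(clean), function(nm)
    cbind(population = nm,
          haplotype_homozygosity(clean[[nm]], config$hh_window, config$hh_step))))
  .write_tsv(hh, out_dir, "hh")
  done("hh")

  say("MAF spectra and F_st")
  maf <- do.call(rbind, lapply(names(clean), function(nm)
    cbind(population = nm, maf_spectrum(clean[[nm]]))))
  .write_tsv(maf, out_dir, "maf_spectrum")
  pure <- clean[c("B", "C", "D")]
  fst <- fst_table(pure)
  .write_tsv(fst, out_dir, "fst")
  fst_means <- data.frame(mode = c("average", "ratio"),
                          mean_fst = c(mean(fst$theta, na.rm = TRUE),
                                       mean_fst(pure, mode = "ratio")))
  .write_tsv(fst_means, out_dir, "fst_mean")
  done("popstats")

  manifest <- list(
    package_version = as.character(utils::packageVersion("crossld")),
    seed = config$seed,
    simulated = !is.null(config$sim),
    sim = if (!is.null(config$sim)) unclass(config$sim),
    parameters = config[c("max_pair_distance", "decay_bin", "consistency_bin",
                          "hh_window", "hh_step", "combined_weights",
                          "combined_n")],
    n_common_snps = length(ids),
    populations = names(panels),
    stages_completed = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(panels = panels, qc = qc, clean = clean, curves = curve_tab,
                 d02 = d02, adjacent = adj, consistency = cons,
                 blocks = blocks, hh = hh, fst = fst, fst_means = fst_means,
                 manifest = manifest))
}

#' Read a run configuration from YAML
#'
#' Thin convenience wrapper: reads a YAML file whose top-level keys
#' mirror the arguments of [run_config()] (and, under `sim`, of
#' [sim_config()]).
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else
    if (is.null(y$vcf_paths)) sim_config() else NULL
  args <- y[setdiff(names(y), "sim")]
  if (!is.null(args$vcf_paths)) args$vcf_paths <- unlist(args$vcf_paths)
  do.call(run_config, c(list(sim = sim), args))
}
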