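# Panel fixtures built in code.

# Panel from an explicit haplotype matrix (rows = haplotypes).
make_panel <- function(H, pos = NULL, chrom = 1L, label = "pop",
                       ids = NULL) {
  H <- as.matrix(H)
  m <- ncol(H)
  if (is.null(pos)) pos <- seq_len(m) * 10000L
  if (length(chrom) == 1L) chrom <- rep(chrom, m)
  if (is.null(ids)) ids <- paste0("s", seq_len(m))
  haplotype_panel(H, data.frame(id = ids, chrom = chrom, pos = pos,
                                allele0 = "A", allele1 = "G"),
                  label = label)
}

# Random panel with independent SNPs at random frequencies.
random_panel <- function(n_ind = 30, m = 20, seed = 1, label = "pop") {
  set.seed(seed)
  repeat {
    p <- runif(m, 0.15, 0.85)
    H <- matrix(rbinom(2 * n_ind * m, 1, rep(p, each = 2 * n_ind)), 2 * n_ind, m)
    f <- colMeans(H)
    if (all(f > 0 & f < 1)) return(make_panel(H, label = label))
  }
}

# Small simulation configuration for fast tests.
tiny_cfg <- function(seed = 1, ...) {
  args <- list(chrom_lengths_bp = c(8e6, 4e6),
               chrom_categories = c("macro", "micro"),
               n_snps_per_chrom = c(120L, 60L),
               base_pop_size = 50L, burnin_generations = 40L,
               line_sizes = c(B = 50L, C = 30L, D = 30L),
               line_wf_sizes = c(B = 40L, C = 40L, D = 40L),
               divergence_generations = 30L, n_crossbred = 80L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# One desk-scale calibrated simulation shared by the slower acceptance
# checks; built on first use and cached for the session.
.calibrated_cache <- new.env(parent = emptyenv())
calibrated_run <- function() {
  if (!is.null(.calibrated_cache$run)) return(.calibrated_cache$run)
  cfg <- sim_config(seed = 1L)
  base <- simulate_base(cfg)
  lines <- diverge_lines(base, cfg)
  cross <- make_cross(lines$B, lines$C, lines$D, cfg)
  clean <- c(lapply(lines, function(p) run_qc(p)$panel),
             list(BCD = run_qc(cross, qc_thresholds(apply_hwe = FALSE))$panel))
  ids <- common_snps(clean)
  clean <- orient_alleles(lapply(clean, subset_snps, snps = ids))
  names(clean) <- c("B", "C", "D", "BCD")
  cats <- stats::setNames(cfg$chrom_categories, seq_along(cfg$chrom_categories))
  .calibrated_cache$run <- list(cfg = cfg, clean = clean, categories = cats)
  .calibrated_cache$run
}
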