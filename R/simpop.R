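#' Simulation configuration for a three-way broiler cross
#'
#' Describes the synthetic study system: three pure lines (a male line B
#' and two female lines C and D) diverged by drift from a common base
#' population, and their terminal three-way cross B x [C x D] in which
#' line B sires are mated to CD crossbred dams.  Chromosomes belong to
#' one of three avian size categories with different recombination rates
#' per Mb.
#'
#' Sizes follow the sampling proportions of a commercial broiler
#' genotyping study at desk scale: one chromosome per category
#' (50/30/15 Mb), about one candidate SNP per 6.25 kb — drift and QC
#' attrition bring the density of SNPs common to all analysed
#' populations to roughly one per 25 kb — with pure-line panels of
#' 250/125/125 individuals and 1000 crossbreds.
#'
#' @param chrom_lengths_bp chromosome lengths in bp, one per chromosome.
#' @param chrom_categories character vector (same length) assigning each
#'   chromosome to `"macro"`, `"intermediate"` or `"micro"`.
#' @param n_snps_per_chrom integer vector: candidate SNP sites simulated
#'   per chromosome (sites fixed during base burn-in are dropped, so the
#'   realized map is somewhat sparser).
#' @param recomb_rate_cM_per_Mb named rates for the three categories;
#'   defaults 2.8 (macro), 3.9 (intermediate), 6.4 (micro).  A rate of 0
#'   is allowed (useful to isolate the effect of recombination); negative
#'   rates are rejected.
#' @param base_pop_size diploid size of the ancestral Wright-Fisher
#'   population.
#' @param burnin_generations generations of random mating in the base
#'   population before the lines split, building drift-recombination LD.
#' @param line_sizes named sizes of the genotyped pure-line panels B, C, D.
#' @param line_wf_sizes named diploid breeding-population sizes of the
#'   lines during divergence (the genotyped cohort in `line_sizes` is a
#'   final expansion generation bred from this nucleus).
#' @param divergence_generations generations of independent drift per
#'   line, set with [calibrate_divergence()] so that the realized mean
#'   F_st among the lines comfortably exceeds 0.2 (about 0.22 at the
#'   default nucleus size).
#' @param n_crossbred number of BCD offspring (and of CD dams).
#' @param seed integer seed controlling every random draw downstream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths_bp = c(50e6, 30e6, 15e6),
                       chrom_categories = c("macro", "intermediate", "micro"),
                       n_snps_per_chrom = as.integer(chrom_lengths_bp / 6250),
                       recomb_rate_cM_per_Mb = c(macro = 2.8, intermediate = 3.9,
                                                 micro = 6.4),
                       base_pop_size = 100L,
                       burnin_generations = 100L,
                       line_sizes = c(B = 250L, C = 125L, D = 125L),
                       line_wf_sizes = c(B = 100L, C = 100L, D = 100L),
                       divergence_generations = 90L,
                       n_crossbred = 1000L,
                       seed = 1L) {
  cfg <- list(chrom_lengths_bp = as.numeric(chrom_lengths_bp),
              chrom_categories = as.character(chrom_categories),
              n_snps_per_chrom = as.integer(n_snps_per_chrom),
              recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
              base_pop_size = as.integer(base_pop_size),
              burnin_generations = as.integer(burnin_generations),
              line_sizes = line_sizes,
              line_wf_sizes = line_wf_sizes,
              divergence_generations = as.integer(divergence_generations),
              n_crossbred = as.integer(n_crossbred),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  nc <- length(cfg$chrom_lengths_bp)
  if (nc < 1 || any(cfg$chrom_lengths_bp <= 0))
    stop("chromosome lengths must be strictly positive")
  if (length(cfg$chrom_categories) != nc)
    stop("every chromosome needs exactly one category")
  if (!all(cfg$chrom_categories %in% c("macro", "intermediate", "micro")))
    stop("categories must be macro/intermediate/micro")
  if (length(cfg$n_snps_per_chrom) != nc || any(cfg$n_snps_per_chrom < 1))
    stop("n_snps_per_chrom must be positive, one per chromosome")
  if (!all(cfg$chrom_categories %in% names(cfg$recomb_rate_cM_per_Mb)))
    stop("recomb_rate_cM_per_Mb must name every category in use")
  if (any(cfg$recomb_rate_cM_per_Mb < 0))
    stop("recombination rates must be non-negative")
  if (cfg$base_pop_size < 2 || cfg$burnin_generations < 0)
    stop("base population size must be >= 2 and burn-in non-negative")
  if (!all(c("B", "C", "D") %in% names(cfg$line_sizes)) ||
      !all(c("B", "C", "D") %in% names(cfg$line_wf_sizes)))
    stop("line_sizes and line_wf_sizes must name lines B, C and D")
  if (any(cfg$line_sizes < 2) || any(cfg$line_wf_sizes < 2))
    stop("line sizes must be at least 2")
  if (cfg$divergence_generations < 0)
    stop("divergence_generations must be non-negative")
  if (cfg$n_crossbred < 1) stop("n_crossbred must be positive")
  invisible(cfg)
}

## Per-chromosome geometry used by the gamete sampler: column index
## ranges, bp positions, and the expected crossover count per meiosis
## (Haldane model: Poisson with mean = cM length / 100).
.sim_geometry <- function(map, cfg) {
  chroms <- sort(unique(map$chrom))
  lapply(chroms, function(ch) {
    cols <- which(map$chrom == ch)
    cat_ch <- cfg$chrom_categories[ch]
    rate <- cfg$recomb_rate_cM_per_Mb[[cat_ch]]
    L <- cfg$chrom_lengths_bp[ch]
    list(cols = cols, pos = as.numeric(map$pos[cols]), len = L,
         lambda = L / 1e6 * rate / 100)
  })
}

## One meiotic gamete from the two haplotype rows r1, r2 of a parent.
## Returns, per chromosome, a logical mask (TRUE -> copy from r2) built
## from Poisson crossovers at uniform bp positions, with a fair coin for
## the starting strand.  Applied identically to allele and origin
## matrices so origins track the realized crossovers.
.gamete_mask <- function(geom) {
  lapply(geom, function(g) {
    k <- stats::rpois(1L, g$lambda)
    start <- stats::runif(1L) < 0.5
    if (k == 0L) {
      rep(start, length(g$cols))
    } else {
      xo <- sort(stats::runif(k, 0, g$len))
      seg <- findInterval(g$pos, xo)
      xor(start, seg %% 2L == 1L)
    }
  })
}

.apply_mask <- function(mat, r1, r2, masks, geom) {
  out <- mat[r1, ]
  h2 <- mat[r2, ]
  for (i in seq_along(geom)) {
    cols <- geom[[i]]$cols
    m <- masks[[i]]
    out[cols[m]] <- h2[cols[m]]
  }
  out
}

## One Wright-Fisher generation: n_offspring diploids, each from two
## parents drawn uniformly with replacement from the current panel.
.wf_generation <- function(H, geom, n_offspring) {
  n_par <- nrow(H) %/% 2L
  out <- matrix(0L, 2L * n_offspring, ncol(H))
  for (o in seq_len(n_offspring)) {
    sire <- sample.int(n_par, 1L)
    dam <- sample.int(n_par, 1L)
    m1 <- .gamete_mask(geom)
    m2 <- .gamete_mask(geom)
    out[2L * o - 1L, ] <- .apply_mask(H, 2L * sire - 1L, 2L * sire, m1, geom)
    out[2L * o, ] <- .apply_mask(H, 2L * dam - 1L, 2L * dam, m2, geom)
  }
  out
}

#' Simulate the ancestral base population
#'
#' Initializes candidate SNPs at linkage equilibrium with allele
#' frequencies drawn uniformly from (0.1, 0.9) — emulating the
#' medium-MAF ascertainment of commercial SNP arrays — then runs
#' Wright-Fisher random mating with Haldane crossovers for
#' `burnin_generations`, letting drift build LD that decays with
#' inter-SNP distance at the category-specific recombination rate.
#' Sites fixed during burn-in are dropped, so every SNP of the returned
#' panel segregates.
#'
#' @param cfg a [sim_config()].
#' @return A [haplotype_panel()] labelled `"base"`.
#' @export
simulate_base <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  m <- sum(cfg$n_snps_per_chrom)
  map <- data.frame(
    id = sprintf("snp%d_%d", rep(seq_along(cfg$n_snps_per_chrom),
                                 cfg$n_snps_per_chrom),
                 unlist(lapply(cfg$n_snps_per_chrom, seq_len))),
    chrom = rep(seq_along(cfg$n_snps_per_chrom), cfg$n_snps_per_chrom),
    pos = unlist(lapply(seq_along(cfg$n_snps_per_chrom), function(ch) {
      sort(sample.int(cfg$chrom_lengths_bp[ch], cfg$n_snps_per_chrom[ch]))
    })),
    allele0 = "A", allele1 = "B", stringsAsFactors = FALSE)
  geom <- .sim_geometry(map, cfg)
  n2 <- 2L * cfg$base_pop_size
  p0 <- stats::runif(m, 0.1, 0.9)
  H <- matrix(stats::rbinom(n2 * m, 1L, rep(p0, each = n2)), n2, m)
  for (g in seq_len(cfg$burnin_generations))
    H <- .wf_generation(H, geom, cfg$base_pop_size)
  freq <- colMeans(H)
  keep <- freq > 0 & freq < 1
  haplotype_panel(H[, keep, drop = FALSE], map[keep, ], label = "base")
}

#' Diverge three pure lines from a base population
#'
#' Splits the base into lines B, C and D and drifts each independently
#' (random mating at the line's nucleus size, multinomial gamete
#' sampling with recombination) for `divergence_generations`, then
#' breeds a final expansion generation of `line_sizes` genotyped
#' individuals from the nucleus.  With zero divergence generations the
#' lines are plain random subsamples of the base (F_st ~ 0).
#' Sites drifting to fixation within a line are kept; quality control
#' removes them per population downstream.
#'
#' @param base a [haplotype_panel()] from [simulate_base()].
#' @param cfg the [sim_config()] used to build `base`.
#' @param divergence_generations override of `cfg$divergence_generations`.
#' @return Named list of three [haplotype_panel()] objects `B`, `C`, `D`.
#' @export
diverge_lines <- function(base, cfg,
                          divergence_generations = cfg$divergence_generations) {
  validate_sim_config(cfg)
  stopifnot(inherits(base, "haplotype_panel"))
  t_div <- as.integer(divergence_generations)
  set.seed(cfg$seed + 1L)
  geom <- .sim_geometry(base$map, cfg)
  out <- lapply(c("B", "C", "D"), function(line) {
    n_out <- as.integer(cfg$line_sizes[[line]])
    if (t_div == 0L) {
      n_base <- n_individuals(base)
      idx <- sample.int(n_base, n_out, replace = n_out > n_base)
      p <- subset_individuals(base, idx)
      p$label <- line
      p$samples <- paste0(line, "_", seq_len(n_out))
      return(p)
    }
    H <- base$alleles
    n_wf <- as.integer(cfg$line_wf_sizes[[line]])
    for (g in seq_len(t_div)) H <- .wf_generation(H, geom, n_wf)
    H <- .wf_generation(H, geom, n_out)
    haplotype_panel(H, base$map, label = line)
  })
  names(out) <- c("B", "C", "D")
  out
}

#' Breed the three-way cross B x [C x D]
#'
#' First produces `n_offspring` CD crossbred dams (one gamete from a
#' random line-C sire, one from a random line-D dam), then mates each CD
#' dam to a random line-B sire.  Every BCD offspring therefore carries
#' one whole (recombinant but purely B-derived) paternal gamete —
#' exactly 50% B-origin alleles per individual — and one maternal gamete
#' that is a crossover mosaic of a C and a D haplotype, giving expected
#' C and D contributions of 25% each.  Per-allele line-of-origin tags
#' are recorded in the returned panel's `origin` matrix.
#'
#' @param sire_line,dam_lineC,dam_lineD pure-line [haplotype_panel()]s
#'   sharing one SNP map (lines B, C and D).
#' @param cfg the [sim_config()] (for recombination geometry and seed).
#' @param n_offspring number of BCD offspring; defaults to
#'   `cfg$n_crossbred`.
#' @return A [haplotype_panel()] labelled `"BCD"` with origin tags.
#' @export
make_cross <- function(sire_line, dam_lineC, dam_lineD, cfg,
                       n_offspring = cfg$n_crossbred) {
  validate_sim_config(cfg)
  key <- function(p) p$map[c("id", "chrom", "pos")]
  if (!identical(key(sire_line), key(dam_lineC)) ||
      !identical(key(sire_line), key(dam_lineD)))
    stop("the three pure-line panels must share an identical snp map")
  n_offspring <- as.integer(n_offspring)
  stopifnot(n_offspring >= 1)
  set.seed(cfg$seed + 2L)
  geom <- .sim_geometry(sire_line$map, cfg)
  m <- n_snps(sire_line)

  ## CD dams: haplotype 1 from line C, haplotype 2 from line D
  nC <- n_individuals(dam_lineC); nD <- n_individuals(dam_lineD)
  cd_hapC <- matrix(0L, n_offspring, m)
  cd_hapD <- matrix(0L, n_offspring, m)
  for (o in seq_len(n_offspring)) {
    cs <- sample.int(nC, 1L)
    dd <- sample.int(nD, 1L)
    cd_hapC[o, ] <- .apply_mask(dam_lineC$alleles, 2L * cs - 1L, 2L * cs,
                                .gamete_mask(geom), geom)
    cd_hapD[o, ] <- .apply_mask(dam_lineD$alleles, 2L * dd - 1L, 2L * dd,
                                .gamete_mask(geom), geom)
  }

  nB <- n_individuals(sire_line)
  H <- matrix(0L, 2L * n_offspring, m)
  orig <- matrix("B", 2L * n_offspring, m)
  for (o in seq_len(n_offspring)) {
    bs <- sample.int(nB, 1L)
    H[2L * o - 1L, ] <- .apply_mask(sire_line$alleles, 2L * bs - 1L, 2L * bs,
                                    .gamete_mask(geom), geom)
    ## maternal gamete: recombine the dam's C and D haplotypes
    masks <- .gamete_mask(geom)
    mat_hap <- cd_hapC[o, ]
    mat_orig <- rep("C", m)
    for (i in seq_along(geom)) {
      cols <- geom[[i]]$cols
      mk <- masks[[i]]
      mat_hap[cols[mk]] <- cd_hapD[o, cols[mk]]
      mat_orig[cols[mk]] <- "D"
    }
    H[2L * o, ] <- mat_hap
    orig[2L * o, ] <- mat_orig
  }
  haplotype_panel(H, sire_line$map, label = "BCD", origin = orig)
}

#' Per-line contribution fractions of a crossbred panel
#'
#' @param panel a [haplotype_panel()] with origin tags.
#' @return list with `overall` (named fractions of all allele copies by
#'   origin line) and `per_individual` (data.frame of per-individual
#'   B/C/D fractions).
#' @export
origin_fractions <- function(panel) {
  if (is.null(panel$origin)) stop("panel carries no origin tags")
  o <- panel$origin
  n <- n_individuals(panel)
  tab <- function(x) {
    c(B = mean(x == "B"), C = mean(x == "C"), D = mean(x == "D"))
  }
  per <- t(vapply(seq_len(n), function(i)
    tab(o[c(2L * i - 1L, 2L * i), ]), numeric(3)))
  list(overall = tab(o),
       per_individual = data.frame(individual = panel$samples, per))
}

#' Calibrate divergence generations to a target F_st
#'
#' Scans increasing numbers of divergence generations and reports the
#' first for which the realized mean Weir-Cockerham F_st among the three
#' lines (over SNPs with MAF >= 0.05 in every line) exceeds the target.
#' Exposed because the level of differentiation is the only constraint
#' the study system puts on the divergence process.
#'
#' @param base a [haplotype_panel()] from [simulate_base()].
#' @param cfg a [sim_config()].
#' @param target_fst target mean F_st (default 0.2).
#' @param generations candidate generation counts to scan, in order.
#' @return list with `generations` (first passing value, NA if none),
#'   `fst` (realized mean F_st at each scanned value).
#' @export
calibrate_divergence <- function(base, cfg, target_fst = 0.2,
                                 generations = seq(10L, 100L, by = 10L)) {
  fst <- numeric(0)
  for (t_div in generations) {
    lines <- diverge_lines(base, cfg, divergence_generations = t_div)
    keep <- Reduce(`&`, lapply(lines, function(p) {
      f <- colMeans(p$alleles)
      pmin(f, 1 - f) >= 0.05
    }))
    f <- mean_fst(lines, snps = base$map$id[keep])
    fst <- c(fst, f)
    if (f > target_fst)
      return(list(generations = t_div,
                  fst = stats::setNames(fst, generations[seq_along(fst)])))
  }
  list(generations = NA_integer_,
       fst = stats::setNames(fst, generations[seq_along(fst)]))
}
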