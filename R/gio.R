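## Chromosome labels arrive as "1", "chr1" or "GGA1"; everything
## internal uses the bare integer.
normalize_chrom <- function(x) {
  out <- suppressWarnings(as.integer(sub("^(chr|GGA)", "", x, ignore.case = TRUE)))
  if (anyNA(out)) stop("unparseable chromosome name(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Read a phased VCF into a haplotype panel
#'
#' Accepts diploid, biallelic SNP records with `|`-phased GT.  Under
#' `strict = TRUE` any unphased ("/"), missing or multi-allelic record
#' aborts with an error naming the offending CHROM:POS; otherwise such
#' records are skipped with a warning.
#'
#' @param path path to a VCF (v4.x, plain text or gzipped).
#' @param strict logical; see above.
#' @param label population label for the panel (default: file stem).
#' @return A [haplotype_panel()].
#' @export
read_phased_vcf <- function(path, strict = TRUE, label = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    stop("no variant records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  rec_name <- paste0(fix$CHROM, ":", fix$POS)

  biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  phased <- apply(gt, 1, function(g) all(grepl("^[01]\\|[01]$", g)))
  ok <- biallelic & phased
  if (!all(ok)) {
    bad <- rec_name[!ok][1]
    if (strict)
      stop("record ", bad, " is not a phased biallelic SNP ",
           "(unphased '/', missing, or multi-allelic GT)")
    warning(sum(!ok), " record(s) skipped (unphased/missing/multi-allelic), ",
            "first: ", bad)
  }
  fix <- fix[ok, , drop = FALSE]
  gt <- gt[ok, , drop = FALSE]
  if (nrow(fix) == 0) stop("no usable phased biallelic records in ", path)

  a1 <- substr(gt, 1, 1) != "0"
  a2 <- substr(gt, 3, 3) != "0"
  n <- ncol(gt)
  m <- nrow(gt)
  H <- matrix(0L, 2L * n, m)
  H[seq(1L, 2L * n, by = 2L), ] <- t(a1) * 1L
  H[seq(2L, 2L * n, by = 2L), ] <- t(a2) * 1L
  map <- data.frame(id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                paste0(fix$CHROM, "_", fix$POS), fix$ID),
                    chrom = normalize_chrom(fix$CHROM),
                    pos = as.integer(fix$POS),
                    allele0 = fix$REF, allele1 = fix$ALT,
                    stringsAsFactors = FALSE)
  ord <- order(map$chrom, map$pos)
  if (!identical(ord, seq_len(m)))
    stop("records out of chromosome/position order in ", path)
  if (is.null(label))
    label <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  haplotype_panel(H, map, label = label, samples = colnames(gt))
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits VCFv4.2 with `|`-phased GT, one record per SNP in map order,
#' REF/ALT taken verbatim from the map's allele labels.  Round trips
#' losslessly through [read_phased_vcf()].
#'
#' @param panel a [haplotype_panel()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=crossld_", as.character(utils::packageVersion("crossld"))),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel$samples), collapse = "\t"), con)
  n <- n_individuals(panel)
  if (n_snps(panel) > 0) {
    body <- cbind(panel$map$chrom, panel$map$pos, panel$map$id,
                  panel$map$allele0, panel$map$allele1, ".", ".", ".", "GT")
    if (n > 0) {
      H <- panel$alleles
      odd <- seq(1L, nrow(H), by = 2L)
      gt <- matrix(paste0(H[odd, , drop = FALSE], "|",
                          H[odd + 1L, , drop = FALSE]), nrow = n)
      body <- cbind(body, t(gt))
    }
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' SNPs common to several panels
#'
#' Intersects panels on SNP id, requiring agreement of chromosome and
#' position, and allele labels that are identical or swapped (the
#' orientation step resolves swaps).  This is the "common SNPs"
#' workflow used before any cross-population comparison.
#'
#' @param panels list of two or more [haplotype_panel()] objects
#'   (each typically already quality-controlled).
#' @return Character vector of common SNP ids, in the first panel's map
#'   order.
#' @export
common_snps <- function(panels) {
  stopifnot(length(panels) >= 2)
  ids <- Reduce(intersect, lapply(panels, function(p) p$map$id))
  ref <- panels[[1]]$map
  ids <- ref$id[ref$id %in% ids]
  for (p in panels[-1]) {
    mp <- p$map[match(ids, p$map$id), ]
    rp <- ref[match(ids, ref$id), ]
    bad <- mp$chrom != rp$chrom | mp$pos != rp$pos
    if (any(bad))
      stop("SNP id(s) mapped to different positions across panels: ",
           paste(utils::head(ids[bad], 5), collapse = ", "))
    same <- mp$allele0 == rp$allele0 & mp$allele1 == rp$allele1
    swap <- mp$allele0 == rp$allele1 & mp$allele1 == rp$allele0
    if (any(!(same | swap)))
      stop("irreconcilable allele labels across panels at: ",
           paste(utils::head(ids[!(same | swap)], 5), collapse = ", "))
  }
  ids
}
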