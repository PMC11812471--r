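# -- VCF input/output --------------------------------------------------------
#
# Genotypes travel as standard VCF 4.2 with GT calls (one sample column per
# individual, biallelic records at the panel positions). Reading uses
# VariantAnnotation; dosages are risk-allele counts after panel orientation,
# so a 1/1 call where the panel risk allele is REF yields dosage 0.

#' Write simulated genotypes as a VCF file
#'
#' Emits one biallelic record per panel variant (positions, alleles and ids
#' from the panel; records sorted by chromosome and position) with GT
#' genotype calls. Dosages count risk alleles: when the risk allele is the
#' panel REF allele the genotype is written with the complementary ALT
#' count, so the file round-trips through [extract_dosages()].
#'
#' @param dosages a [dosage_matrix()] aligned to `panel` (or a
#'   `simulated_cohort`, whose dosages are used).
#' @param panel the `variant_panel`.
#' @param path output path (plain text; use a `.vcf` extension).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(dosages, panel, path) {
  if (inherits(dosages, "simulated_cohort")) dosages <- dosages$dosages
  stopifnot(inherits(dosages, "dosage_matrix"), inherits(panel, "variant_panel"))
  check_alignment(dosages, panel)
  d <- dosages$dosage
  risk_is_alt <- panel$risk_allele == panel$alt
  gt_for <- function(j) {
    alt_count <- if (risk_is_alt[j]) d[, j] else 2L - d[, j]
    gt <- c("0/0", "0/1", "1/1")[alt_count + 1L]
    gt[is.na(gt)] <- "./."
    gt
  }
  gts <- vapply(seq_len(ncol(d)), gt_for, character(nrow(d)))
  if (nrow(d) == 1L) gts <- matrix(gts, nrow = 1L)
  ord <- order(panel$chrom, panel$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=amdprs",
    sprintf("##contig=<ID=%s>", unique(panel$chrom[ord])),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dosages$individual_ids), collapse = "\t"))
  body <- vapply(ord, function(j) {
    paste(c(panel$chrom[j], panel$pos[j], panel$rsid[j], panel$ref[j],
            panel$alt[j], ".", "PASS", ".", "GT", gts[, j]),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

gt_allele_count <- function(gt, allele_index) {
  # count occurrences of the given allele index (0 = REF, 1 = ALT) in
  # diploid GT strings; any call containing "." is missing
  gt <- gsub("|", "/", gt, fixed = TRUE)
  parts <- strsplit(gt, "/", fixed = TRUE)
  vapply(parts, function(p) {
    if (any(p == ".") || length(p) == 0L) return(NA_integer_)
    sum(p == as.character(allele_index))
  }, integer(1L))
}

#' Extract risk-allele dosages for a panel from a VCF file
#'
#' Matches each panel variant to a VCF record by chromosome, position and
#' allele pair, then counts risk alleles per individual from the GT call
#' (a DS dosage field, if present, is used instead and rounded to the
#' nearest integer in 0..2). Panel variants absent from the file become
#' missing-masked columns. A record at a matched position whose alleles
#' agree with neither panel allele is a hard error: it signals a genome
#' build or strand mismatch, not missing data.
#'
#' @param vcf path to a VCF file (plain or bgzipped).
#' @param panel a risk-oriented `variant_panel`.
#' @return A [dosage_matrix()] of samples by panel variants.
#' @export
extract_dosages <- function(vcf, panel) {
  stopifnot(inherits(panel, "variant_panel"))
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("extract_dosages requires the VariantAnnotation package",
         call. = FALSE)
  }
  v <- VariantAnnotation::readVcf(vcf, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(v)
  v_chrom <- as.character(GenomicRanges::seqnames(rr))
  v_pos <- GenomicRanges::start(rr)
  v_ref <- as.character(rr$REF)
  alt_list <- rr$ALT
  v_alt <- vapply(seq_along(alt_list), function(i) {
    a <- as.character(alt_list[[i]])
    if (length(a) == 0L) NA_character_ else a[1L]
  }, character(1L))
  gt <- VariantAnnotation::geno(v)$GT
  ds <- if ("DS" %in% names(VariantAnnotation::geno(v)))
    VariantAnnotation::geno(v)$DS else NULL
  samples <- colnames(gt)
  n <- length(samples)
  p <- nrow(panel)
  d <- matrix(NA_integer_, nrow = n, ncol = p)
  for (j in seq_len(p)) {
    hit <- which(v_chrom == panel$chrom[j] & v_pos == panel$pos[j])
    if (length(hit) == 0L) next
    pair_ok <- v_ref[hit] %in% c(panel$ref[j], panel$alt[j]) &
      v_alt[hit] %in% c(panel$ref[j], panel$alt[j]) &
      v_ref[hit] != v_alt[hit]
    if (!any(pair_ok)) {
      stop(sprintf(
        "allele mismatch for %s at %s:%d (VCF %s/%s vs panel %s/%s): possible build or strand mismatch",
        panel$rsid[j], panel$chrom[j], panel$pos[j],
        v_ref[hit][1L], v_alt[hit][1L], panel$ref[j], panel$alt[j]),
        call. = FALSE)
    }
    hit <- hit[pair_ok][1L]
    risk_index <- if (panel$risk_allele[j] == v_alt[hit]) 1L else 0L
    if (!is.null(ds) && !all(is.na(ds[hit, ]))) {
      alt_dose <- pmin(pmax(round(as.numeric(ds[hit, ])), 0L), 2L)
      d[, j] <- as.integer(if (risk_index == 1L) alt_dose else 2L - alt_dose)
    } else {
      d[, j] <- gt_allele_count(gt[hit, ], risk_index)
    }
  }
  dosage_matrix(d, individual_ids = samples, variant_rsids = panel$rsid)
}
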