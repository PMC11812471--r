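# -- built-in synthetic 52-variant panel -------------------------------------
#
# The real 52-variant AMD panel comes from the 2016 IAMDGC GWAS; the full
# effect-size table is not redistributable here. This synthetic stand-in
# keeps the documented structure: 52 biallelic lead variants, two
# strong-effect loci (CFH main signal, ARMS2/HTRA1), many weak-effect loci,
# a handful of protective (OR < 1) records to exercise risk orientation,
# and the five low-coverage variants that the diagnostic assay cannot
# genotype (with their published odds ratios). All other rsids, positions,
# odds ratios and frequencies are synthetic.

#' Synthetic 52-variant AMD risk panel
#'
#' Builds the package's built-in stand-in for the 52-variant AMD GWAS lead
#' panel. Two strong-effect loci (CFH, ARMS2/HTRA1) carry odds ratios of
#' 2.4 and 2.8; the remaining loci are weak (oriented OR roughly 1.1-1.4);
#' several records are stored protective (OR < 1) and are flipped at
#' construction. The five variants dropped by [amd_exclusions()] are
#' included with their published odds ratios (1.47, 0.71, 1.12, 0.9, 0.76).
#' Risk-allele frequencies are drawn once from a fixed-seed uniform(0.10,
#' 0.60) and are part of the stated preset, not a tuning knob.
#'
#' @inheritParams variant_panel
#' @return A `variant_panel` of 52 variants with a `freq` column.
#' @export
synthetic_panel_52 <- function(weight_scale = c("log_or", "or")) {
  variant_panel(synthetic_panel_52_raw(), weight_scale = match.arg(weight_scale))
}

# the unoriented source table (protective rows keep OR < 1); the TSV
# fixture under extdata/ is written from this so loading exercises the
# orientation step
synthetic_panel_52_raw <- function() {
  named <- data.frame(
    rsid = c("rs10922109", "rs3750846",
             "rs187328863", "rs114092250", "rs10781182", "rs67538026",
             "rs201459901"),
    chrom = c("1", "10", "1", "5", "9", "19", "20"),
    pos = c(196704632L, 124215565L, 196380158L, 35494448L, 76617720L,
            1031438L, 56653724L),
    ref = c("C", "T", "C", "A", "G", "G", "T"),
    alt = c("A", "C", "T", "T", "A", "C", "TA"),
    risk_allele = c("C", "C", "T", "T", "A", "C", "TA"),
    odds_ratio = c(2.40, 2.80, 1.47, 0.71, 1.12, 0.90, 0.76),
    locus = c("CFH", "ARMS2/HTRA1", "CFH", "PRLR/SPEF2", "MIR6130/RORB",
              "CNN2", "C20orf85"),
    stringsAsFactors = FALSE)
  n_weak <- 45L
  weak <- withr::with_seed(987001L, {
    or <- round(exp(stats::rnorm(n_weak, mean = log(1.20), sd = 0.10)), 3)
    or <- pmin(pmax(or, 1.05), 1.45)
    flip <- seq_len(n_weak) %% 9L == 0L   # store a few as protective
    or[flip] <- round(1 / or[flip], 3)
    freq <- round(stats::runif(n_weak, 0.10, 0.60), 3)
    alleles <- c("A", "C", "G", "T")
    ref <- alleles[1L + (seq_len(n_weak) %% 4L)]
    alt <- alleles[1L + ((seq_len(n_weak) + 1L) %% 4L)]
    data.frame(
      rsid = sprintf("rs9%07d", seq_len(n_weak)),
      chrom = as.character(rep_len(c(1:22), n_weak)),
      pos = 1000000L + 137L * seq_len(n_weak),
      ref = ref, alt = alt,
      risk_allele = ifelse(or >= 1, alt, ref),
      odds_ratio = or,
      locus = sprintf("SYNTH%02d", seq_len(n_weak)),
      freq = freq,  # frequency of the stored risk allele; flipped on orientation
      stringsAsFactors = FALSE)
  })
  named$freq <- c(0.55, 0.30, 0.12, 0.85, 0.40, 0.70, 0.80)
  rbind(named, weak)
}

#' Synthetic 47-variant diagnostic panel
#'
#' Convenience wrapper: the 52-variant synthetic panel with the five
#' low-coverage exclusions applied, i.e. the panel actually used for PRS
#' computation.
#'
#' @inheritParams variant_panel
#' @return A `variant_panel` of 47 variants.
#' @export
synthetic_panel_47 <- function(weight_scale = c("log_or", "or")) {
  apply_exclusions(synthetic_panel_52(weight_scale = weight_scale),
                   amd_exclusions())
}

#' Write a variant panel to a TSV file
#'
#' @param panel a `variant_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "variant_panel"))
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
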