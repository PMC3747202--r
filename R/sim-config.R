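#' Configuration for the synthetic locus study generator
#'
#' Bundles every tunable of the synthetic-data module into a single validated
#' object. The defaults emulate the study design the package targets: a
#' 179 kb risk locus sequenced on 4 risk and 11 non-risk haplotypes, a
#' genotype panel of 4,803 control individuals typed at 373 common markers
#' across a 357,744 bp region containing one 179 kb conserved LD block, nine
#' H3K4me1 peaks of which three co-occur with H3K27ac, and a population panel
#' of 7 risk-positive, 4 confounder-positive and 46 negative individuals.
#'
#' @param locus_length Length in bases of the haplotype-panel locus.
#' @param n_risk,n_nonrisk Number of risk / non-risk haplotype sequences.
#' @param n_planted_specific Variants planted on >= `min_risk_present` risk
#'   haplotypes and no non-risk haplotype (the recoverable truth set).
#' @param n_planted_shared Variants planted on at least one haplotype of each
#'   class (never callable as risk-specific).
#' @param n_decoy_lowcomplexity Risk-specific-patterned variants planted
#'   inside homopolymer runs (> 4 nt) or dinucleotide repeats; these must be
#'   removed by the low-complexity mask, never by the specificity rule.
#' @param n_common_negative How many planted specific variants are also
#'   carried by more than `max_negative_carriers` negative-class population
#'   individuals (removed at the population-exclusion stage).
#' @param n_enhancer_resident How many surviving specific variants fall
#'   inside true enhancer intervals.
#' @param n_motif_gain How many enhancer-resident SNPs create a planted
#'   motif match on the alternate allele.
#' @param gc_content Reference GC fraction.
#' @param genotype_region_length Length in bases of the genotype-panel
#'   region used for LD refinement.
#' @param n_individuals,n_markers Genotype-panel dimensions.
#' @param ld_block_spec Tibble with columns `start`, `end`, `dprime` (the
#'   within-block D' target in (0, 1]) declaring LD blocks on the genotype
#'   region. Default: three blocks, the middle one 179,000 bp.
#' @param maf_range Length-2 vector of target minor-allele frequencies,
#'   within (0, 0.5].
#' @param missing_rate Fraction of genotype calls set to missing.
#' @param n_h3k4me1 Total H3K4me1 peaks emitted by the peak-track generator.
#' @param n_enhancers True enhancers (H3K4me1 + H3K27ac co-occurrence).
#' @param n_pop_risk,n_pop_confounder,n_pop_negative Population-panel class
#'   sizes (risk-allele carriers, confounder-allele carriers, neither).
#' @param n_pwms Number of synthetic position weight matrices.
#' @param motif_length Length of each synthetic motif (>= 4).
#' @param seed Integer seed; every generator draw derives from it.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(locus_length = 20000, seed = 7)
#' cfg$n_risk
sim_config <- function(locus_length = 179000,
                       n_risk = 4,
                       n_nonrisk = 11,
                       n_planted_specific = 20,
                       n_planted_shared = 30,
                       n_decoy_lowcomplexity = 10,
                       n_common_negative = 5,
                       n_enhancer_resident = 3,
                       n_motif_gain = 1,
                       gc_content = 0.4,
                       genotype_region_length = 357744,
                       n_individuals = 4803,
                       n_markers = 373,
                       ld_block_spec = NULL,
                       maf_range = c(0.1, 0.5),
                       missing_rate = 0.01,
                       n_h3k4me1 = 9,
                       n_enhancers = 3,
                       n_pop_risk = 7,
                       n_pop_confounder = 4,
                       n_pop_negative = 46,
                       n_pwms = 5,
                       motif_length = 12,
                       seed = 1L) {
  counts <- list(
    n_risk = n_risk, n_nonrisk = n_nonrisk,
    n_planted_specific = n_planted_specific,
    n_planted_shared = n_planted_shared,
    n_decoy_lowcomplexity = n_decoy_lowcomplexity,
    n_common_negative = n_common_negative,
    n_enhancer_resident = n_enhancer_resident,
    n_motif_gain = n_motif_gain,
    n_individuals = n_individuals, n_markers = n_markers,
    n_h3k4me1 = n_h3k4me1, n_enhancers = n_enhancers,
    n_pop_risk = n_pop_risk, n_pop_confounder = n_pop_confounder,
    n_pop_negative = n_pop_negative, n_pwms = n_pwms
  )
  for (nm in names(counts)) stopifnot_scalar_count(counts[[nm]], nm)
  if (locus_length <= 0) abort("`locus_length` must be positive.")
  if (genotype_region_length <= 0) abort("`genotype_region_length` must be positive.")
  if (gc_content <= 0 || gc_content >= 1) abort("`gc_content` must be in (0, 1).")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair within (0, 0.5].")
  }
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1).")
  if (n_common_negative + n_enhancer_resident > n_planted_specific) {
    abort("population-common plus enhancer-resident variants exceed the planted specific count.")
  }
  if (n_enhancer_resident > 0 && n_enhancers == 0) {
    abort("cannot place enhancer-resident variants without true enhancers.")
  }
  if (n_motif_gain > n_enhancer_resident) {
    abort("`n_motif_gain` cannot exceed `n_enhancer_resident`.")
  }
  if ((n_planted_specific > 0 || n_decoy_lowcomplexity > 0) && n_risk < 3) {
    abort("risk-specific plantings require at least 3 risk haplotypes.")
  }
  if (motif_length < 4) abort("`motif_length` must be at least 4.")

  if (is.null(ld_block_spec)) {
    mid <- 179000
    if (genotype_region_length <= mid + 2000) {
      # region too small for the study-scale layout: three equal blocks
      b <- floor(genotype_region_length / 3)
      ld_block_spec <- tibble(
        start = c(1, b + 1, 2 * b + 1),
        end = c(b, 2 * b, genotype_region_length),
        dprime = 0.95
      )
    } else {
      flank <- floor((genotype_region_length - mid) / 2)
      ld_block_spec <- tibble(
        start = c(1, flank + 1, flank + mid + 1),
        end = c(flank, flank + mid, genotype_region_length),
        dprime = 0.95
      )
    }
  }
  ld_block_spec <- as_tibble(ld_block_spec)
  if (!all(c("start", "end", "dprime") %in% names(ld_block_spec))) {
    abort("`ld_block_spec` needs columns start, end, dprime.")
  }
  if (any(ld_block_spec$start > ld_block_spec$end) ||
      any(ld_block_spec$start < 1) ||
      any(ld_block_spec$end > genotype_region_length)) {
    abort("`ld_block_spec` intervals must lie within the genotype region.")
  }
  if (any(ld_block_spec$dprime <= 0) || any(ld_block_spec$dprime > 1)) {
    abort("infeasible within-block D' target: must be in (0, 1].")
  }

  structure(
    c(
      list(
        locus_length = as.integer(locus_length),
        gc_content = gc_content,
        genotype_region_length = as.integer(genotype_region_length),
        ld_block_spec = ld_block_spec,
        maf_range = maf_range,
        missing_rate = missing_rate,
        motif_length = as.integer(motif_length),
        seed = as.integer(seed)
      ),
      lapply(counts, as.integer)
    ),
    class = "sim_config"
  )
}

#' @export
#' @method print sim_config
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  locus: %d bp; haplotypes: %d risk / %d non-risk\n",
    x$locus_length, x$n_risk, x$n_nonrisk
  ))
  cat(sprintf(
    "  planted: %d specific (%d population-common, %d enhancer-resident), %d shared, %d decoys\n",
    x$n_planted_specific, x$n_common_negative, x$n_enhancer_resident,
    x$n_planted_shared, x$n_decoy_lowcomplexity
  ))
  cat(sprintf(
    "  genotypes: %d individuals x %d markers over %d bp (%d LD blocks)\n",
    x$n_individuals, x$n_markers, x$genotype_region_length,
    nrow(x$ld_block_spec)
  ))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
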