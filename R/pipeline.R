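#' Default pipeline parameters
#'
#' Every stage threshold of the variant-prioritization funnel in one list:
#' the presence/absence rule (`min_risk_present` 3, `max_nonrisk_present`
#' 0), low-complexity masking (homopolymers longer than 4 nt, dinucleotide
#' repeats of 3+ units), the population exclusion (more than 10
#' negative-class carriers), DHS score thresholds (50 / 30 / 120 with a
#' 1 kb rescue), enhancer overlap (1 bp) and the motif-scan FDR (empirical
#' q < 0.05).
#'
#' @param ... Named overrides of any default.
#' @return A named list of parameters.
#' @export
pipeline_params <- function(...) {
  defaults <- list(
    min_risk_present = 3,
    max_nonrisk_present = 0,
    min_homopolymer = 5,
    min_dinuc_units = 3,
    max_negative_carriers = 10,
    count_chromosomes = FALSE,
    dhs_min_neglog10p = 50,
    dhs_min_signal = 30,
    dhs_min_score = 120,
    dhs_rescue_distance = 1000,
    min_overlap = 1,
    require_unmethylated_cgi = FALSE,
    motif_threshold_p = 1e-4,
    n_null = 1000,
    fdr_threshold = 0.05
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown pipeline parameter(s): %s",
      paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, over)
}

#' Simulate a complete locus study with known ground truth
#'
#' Draws every input the prioritization pipeline consumes from a single
#' config and seed: the labeled haplotype panel, the control genotype panel
#' for LD refinement, the epigenetic peak tracks, the tag-SNP population
#' panel and the PWM library — all tied to one truth table.
#'
#' @param config A [sim_config()].
#' @return List with `panel`, `labels`, `truth`, `genotypes`, `tracks`,
#'   `population`, `pwms` and the plain `reference` string.
#' @export
simulate_locus_study <- function(config) {
  truth <- plan_truth(config)
  hap <- simulate_haplotype_panel(config, truth)
  tracks <- simulate_peak_tracks(config, truth)
  population <- simulate_population_panel(config, truth)
  genotypes <- simulate_genotype_panel(config)
  list(
    panel = hap$panel,
    labels = hap$labels,
    truth = truth,
    genotypes = genotypes,
    tracks = tracks[c("h3k4me1", "h3k27ac", "dhs", "cgi")],
    population = population,
    pwms = truth$pwms,
    reference = truth$reference
  )
}

#' Run the variant-prioritization funnel end to end
#'
#' Executes the staged reduction: extract variants from the aligned panel,
#' drop low-complexity sites, keep variants unique to risk haplotypes,
#' exclude variants common among negative-class population individuals,
#' intersect the survivors with active enhancers, and scan the
#' enhancer-resident candidates for allele-specific motif gains/losses.
#' Stages whose inputs are not supplied are skipped (their funnel row
#' carries the previous count).
#'
#' @param panel Aligned haplotype panel tibble (`id`, `label`, `sequence`).
#' @param labels Member label tibble; defaults to the panel's own labels.
#' @param population Optional list with `tag_genotypes`, `rules`,
#'   `genotypes` (see [simulate_population_panel()]).
#' @param tracks Optional list with `h3k4me1`, `h3k27ac` and optionally
#'   `dhs`, `cgi` peak tibbles.
#' @param pwms Optional PWM library (list of [pwm()] objects).
#' @param params Stage parameters from [pipeline_params()].
#' @param seed Seed driving the motif-scan threshold and null draws.
#' @param out_dir Optional directory; when given, all intermediate artifacts
#'   (stage VCFs, enhancer BED, report TSV/JSON, md5 checksums) are written
#'   there.
#' @return A `haplopin_result` object; see [tidy.haplopin_result()] and
#'   [glance.haplopin_result()].
#' @export
run_pipeline <- function(panel, labels = NULL, population = NULL,
                         tracks = NULL, pwms = NULL,
                         params = pipeline_params(), seed = NULL,
                         out_dir = NULL) {
  labels <- labels %||% filter(panel, .data$label != "reference")[c("id", "label")]
  reference <- gsub("-", "", panel$sequence[panel$label == "reference"],
    fixed = TRUE)

  variants <- extract_variants(panel)
  mask <- build_low_complexity_mask(reference,
    min_homopolymer = params$min_homopolymer,
    min_dinuc_units = params$min_dinuc_units)
  masked <- apply_mask(variants, mask)
  risk <- call_risk_specific(masked, labels,
    min_risk_present = params$min_risk_present,
    max_nonrisk_present = params$max_nonrisk_present)

  carrier_counts <- NULL
  if (!is.null(population)) {
    classes <- classify_individuals(population$tag_genotypes, population$rules)
    carrier_counts <- carrier_exclusion(risk, population$genotypes, classes,
      max_negative_carriers = params$max_negative_carriers,
      count_chromosomes = params$count_chromosomes)
    pop_kept <- filter(carrier_counts, .data$kept)
  } else {
    pop_kept <- risk
  }

  enhancers <- NULL
  dhs_kept <- NULL
  if (!is.null(tracks)) {
    if (!is.null(tracks$dhs) && nrow(tracks$dhs)) {
      dhs_kept <- filter_dhs(tracks$dhs,
        min_neglog10p = params$dhs_min_neglog10p,
        min_signal = params$dhs_min_signal,
        min_score = params$dhs_min_score,
        rescue_distance = params$dhs_rescue_distance)
    }
    enhancers <- call_active_enhancers(tracks$h3k4me1, tracks$h3k27ac,
      cgi = tracks$cgi, min_overlap = params$min_overlap,
      require_unmethylated_cgi = params$require_unmethylated_cgi)
    resident <- filter(intersect_variants(pop_kept, enhancers),
      .data$n_enhancers > 0)
  } else {
    resident <- pop_kept
  }

  motif_events <- NULL
  if (!is.null(pwms) && nrow(resident) > 0) {
    motif_events <- scan_variants(resident, reference, pwms,
      seed = child_seed(seed, 11))
    motif_events <- empirical_fdr(motif_events, pwms,
      n_null = params$n_null, seed = child_seed(seed, 12),
      fdr_threshold = params$fdr_threshold)
  }

  funnel <- tibble(
    stage = c("extracted", "low_complexity_pass", "risk_specific",
      "population_kept", "enhancer_resident"),
    n = c(nrow(variants), nrow(masked), nrow(risk), nrow(pop_kept),
      nrow(resident))
  )

  report <- mutate(variants[c("chrom", "pos", "ref", "alt", "type")],
    extracted = TRUE)
  key <- function(x) paste(x$pos, x$ref, x$alt)
  report$low_complexity_pass <- key(report) %in% key(masked)
  report$risk_specific <- key(report) %in% key(risk)
  report$population_kept <- report$risk_specific &
    key(report) %in% key(pop_kept)
  if (!is.null(enhancers)) {
    ann <- intersect_variants(pop_kept, enhancers)
    report$enhancers <- ann$enhancers[match(key(report), key(ann))]
    report$enhancers[!report$population_kept] <- NA_character_
    report$n_enhancers <- dplyr::coalesce(
      ann$n_enhancers[match(key(report), key(ann))], 0L)
    report$n_enhancers[!report$population_kept] <- 0L
  } else {
    report$enhancers <- NA_character_
    report$n_enhancers <- 0L
  }
  if (!is.null(motif_events)) {
    sig <- filter(motif_events, .data$significant, .data$event != "none")
    hits <- summarise(group_by(sig, .data$pos, .data$ref, .data$alt),
      motif_hits = paste0(.data$pwm, ":", .data$event, collapse = ","),
      .groups = "drop")
    report <- left_join(report, hits, by = c("pos", "ref", "alt"))
  } else {
    report$motif_hits <- NA_character_
  }

  res <- structure(
    list(
      funnel = funnel, report = report, variants = variants,
      masked = masked, risk_specific = risk,
      carrier_counts = carrier_counts, population_kept = pop_kept,
      dhs_kept = dhs_kept, enhancers = enhancers, resident = resident,
      motif_events = motif_events, mask = mask, params = params, seed = seed
    ),
    class = "haplopin_result"
  )
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_variants_vcf(res$variants, p("01_extracted.vcf"))
  write_variants_vcf(res$risk_specific, p("02_risk_specific.vcf"))
  write_variants_vcf(res$population_kept, p("03_population_kept.vcf"))
  if (!is.null(res$enhancers)) {
    enh <- mutate(res$enhancers, name = .data$enhancer_id,
      score = as.integer(.data$active), strand = ".")
    write_bed(enh, p("enhancers.bed"), extra_cols = character())
    jsonlite::write_json(res$enhancers, p("enhancers.json"),
      auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$carrier_counts)) {
    readr::write_tsv(
      select(res$carrier_counts, -dplyr::any_of("presence")),
      p("carrier_counts.tsv"), progress = FALSE)
  }
  readr::write_tsv(select(res$report, -dplyr::any_of("presence")),
    p("report.tsv"), progress = FALSE)
  jsonlite::write_json(list(funnel = res$funnel), p("funnel.json"),
    auto_unbox = TRUE, digits = NA)
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("checksums", files)]
  sums <- tools::md5sum(files)
  writeLines(paste(sums, basename(names(sums))), p("checksums.txt"))
  invisible(out_dir)
}

#' @export
#' @method print haplopin_result
print.haplopin_result <- function(x, ...) {
  cat("<haplopin_result> candidate funnel:\n")
  for (i in seq_len(nrow(x$funnel))) {
    cat(sprintf("  %-20s %d\n", x$funnel$stage[i], x$funnel$n[i]))
  }
  if (!is.null(x$motif_events)) {
    sig <- filter(x$motif_events, .data$significant, .data$event != "none")
    cat(sprintf("  significant motif events: %d\n", nrow(sig)))
  }
  invisible(x)
}

#' Tidy the pipeline result into the per-variant candidate report
#'
#' @param x A `haplopin_result`.
#' @param ... Unused.
#' @return One row per extracted variant with its stage flags (monotone:
#'   a variant failing a stage carries no later annotation), enhancer ids
#'   and significant motif hits.
#' @export
tidy.haplopin_result <- function(x, ...) {
  x$report
}

#' One-row summary of the candidate funnel
#'
#' @param x A `haplopin_result`.
#' @param ... Unused.
#' @export
glance.haplopin_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$funnel, names_from = "stage", values_from = "n")
  wide$n_active_enhancers <- if (!is.null(x$enhancers)) {
    sum(x$enhancers$active)
  } else {
    NA_integer_
  }
  wide$n_significant_motif_events <- if (!is.null(x$motif_events)) {
    sum(x$motif_events$significant & x$motif_events$event != "none")
  } else {
    NA_integer_
  }
  wide
}

#' Funnel plot of the candidate counts per stage
#'
#' @param object A `haplopin_result`.
#' @param ... Unused.
#' @export
autoplot.haplopin_result <- function(object, ...) {
  df <- mutate(object$funnel,
    stage = factor(.data$stage, levels = rev(.data$stage)))
  ggplot2::ggplot(df, ggplot2::aes(.data$n, .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), hjust = -0.2, size = 3) +
    ggplot2::labs(x = "candidate variants", y = NULL,
      title = "Variant prioritization funnel") +
    ggplot2::theme_minimal()
}
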