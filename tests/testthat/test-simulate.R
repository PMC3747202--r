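test_that("configs validate their invariants", {
  expect_error(sim_config(locus_length = 0), "positive")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(sim_config(n_risk = 2), "risk haplotypes")
  expect_error(sim_config(n_common_negative = 30), "exceed")
  bad_blocks <- tibble::tibble(start = 1, end = 10, dprime = 1.2)
  expect_error(sim_config(ld_block_spec = bad_blocks), "infeasible")
  expect_s3_class(sim_config(locus_length = 5000, n_planted_specific = 2,
    n_planted_shared = 2, n_decoy_lowcomplexity = 1, n_common_negative = 0,
    n_enhancer_resident = 1), "sim_config")
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- small_config(seed = 8)
  a <- simulate_haplotype_panel(cfg)
  b <- simulate_haplotype_panel(cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth$planted, b$truth$planted)

  fa <- withr::local_tempfile(fileext = ".fa")
  fb <- withr::local_tempfile(fileext = ".fa")
  write_panel_fasta(a$panel, fa)
  write_panel_fasta(b$panel, fb)
  expect_identical(readLines(fa), readLines(fb))

  expect_identical(simulate_genotype_panel(cfg), simulate_genotype_panel(cfg))
  ta <- simulate_peak_tracks(cfg)
  tb <- simulate_peak_tracks(cfg)
  expect_identical(ta$h3k4me1, tb$h3k4me1)
  expect_identical(ta$dhs, tb$dhs)
})

test_that("panels round-trip through FASTA with labels intact", {
  cfg <- small_config(seed = 9)
  hap <- simulate_haplotype_panel(cfg)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_panel_fasta(hap$panel, fa)
  back <- read_panel_fasta(fa)
  expect_equal(back, hap$panel)
})

test_that("member sequences equal an independent reconstruction from the truth table", {
  cfg <- small_config(seed = 10)
  hap <- simulate_haplotype_panel(cfg)
  tr <- hap$truth
  degap <- function(s) gsub("-", "", s, fixed = TRUE)
  ref <- tr$reference
  for (m in seq_len(nrow(hap$panel))) {
    row <- hap$panel[m, ]
    if (row$label == "reference") {
      expect_equal(degap(row$sequence), ref)
      next
    }
    # rebuild the expected sequence by applying this member's planted
    # variants right-to-left on the plain reference
    mine <- tr$planted[vapply(tr$planted$carriers, function(cc) row$id %in% cc,
      TRUE), ]
    mine <- mine[order(-mine$pos), ]
    expected <- ref
    for (i in seq_len(nrow(mine))) {
      v <- mine[i, ]
      stopifnot(substr(expected, v$pos, v$pos + nchar(v$ref) - 1) == v$ref)
      expected <- paste0(
        substr(expected, 1, v$pos - 1), v$alt,
        substr(expected, v$pos + nchar(v$ref), nchar(expected))
      )
    }
    expect_equal(degap(row$sequence), expected)
  }
})

test_that("planted specific variants satisfy the risk-specificity predicate in the truth", {
  for (s in c(2, 12)) {
    cfg <- small_config(seed = s)
    hap <- simulate_haplotype_panel(cfg)
    tr <- hap$truth
    for (i in which(tr$planted$role %in% c("specific", "decoy"))) {
      carriers <- tr$planted$carriers[[i]]
      expect_gte(sum(carriers %in% tr$risk_ids), 3)
      expect_equal(sum(carriers %in% tr$nonrisk_ids), 0)
    }
    for (i in which(tr$planted$role == "shared")) {
      carriers <- tr$planted$carriers[[i]]
      expect_gte(sum(carriers %in% tr$risk_ids), 1)
      expect_gte(sum(carriers %in% tr$nonrisk_ids), 1)
    }
  }
})

test_that("every decoy lies inside a masked low-complexity interval of the emitted reference", {
  cfg <- small_config(seed = 14)
  hap <- simulate_haplotype_panel(cfg)
  tr <- hap$truth
  mask <- build_low_complexity_mask(tr$reference)
  decoys <- tr$planted[tr$planted$role == "decoy", ]
  expect_equal(nrow(decoys), cfg$n_decoy_lowcomplexity)
  for (p in decoys$pos) {
    expect_true(any(mask$start <= p & mask$end >= p))
  }
  # and the declared decoy regions are genuine maximal repeats
  for (i in seq_len(nrow(tr$decoy_regions))) {
    r <- tr$decoy_regions[i, ]
    seg <- substr(tr$reference, r$start, r$end)
    if (r$kind == "homopolymer") {
      expect_gt(nchar(seg), 4)
      expect_equal(unique(strsplit(seg, "")[[1]]), r$unit)
    } else {
      expect_gte(nchar(seg) %/% 2, 3)
      expect_equal(substr(seg, 1, 2), r$unit)
    }
  }
})

test_that("nothing planted means no specific calls downstream", {
  cfg <- sim_config(
    locus_length = 15000, n_planted_specific = 0, n_planted_shared = 5,
    n_decoy_lowcomplexity = 0, n_common_negative = 0,
    n_enhancer_resident = 0, n_motif_gain = 0,
    n_individuals = 20, n_markers = 10, genotype_region_length = 15000,
    seed = 4
  )
  hap <- simulate_haplotype_panel(cfg)
  v <- extract_variants(hap$panel)
  expect_equal(sort(v$pos), sort(hap$truth$planted$pos))
  kept <- call_risk_specific(v, hap$labels)
  expect_equal(nrow(kept), 0)
})

test_that("genotype panels span the MAF range and separate within- from between-block LD", {
  cfg <- sim_config(
    locus_length = 20000, genotype_region_length = 24000,
    n_individuals = 600, n_markers = 36, missing_rate = 0.01, seed = 6
  )
  g <- simulate_genotype_panel(cfg)
  expect_equal(nrow(g), 36)
  d <- haplopin:::geno_dosages(g)
  expect_equal(ncol(d), 600)
  expect_gt(mean(is.na(d)), 0.002)
  expect_lt(mean(is.na(d)), 0.03)
  mafs <- vapply(g$marker, function(m) compute_maf(g, m), 0)
  expect_gt(max(mafs), 0.35)
  expect_lt(min(mafs), 0.2)

  ld <- ld_matrix(filter_and_thin(g, maf_min = 0.05))
  pos <- ld$markers$pos
  blocks <- cfg$ld_block_spec
  bid <- findInterval(pos, c(blocks$start, Inf))
  same <- outer(bid, bid, "==")
  ut <- upper.tri(same)
  expect_gt(mean(ld$dprime[ut & same]), mean(ld$dprime[ut & !same]) + 0.3)
  expect_lt(mean(ld$dprime[ut & !same]), 0.35)
})

test_that("population panels make planted-common variants exceed the carrier threshold", {
  cfg <- small_config(seed = 18)
  hap <- simulate_haplotype_panel(cfg)
  pop <- simulate_population_panel(cfg, hap$truth)
  expect_silent(validate_tag_rules(pop$rules))
  spec <- hap$truth$planted[hap$truth$planted$role == "specific", ]
  neg <- pop$classes$individual[pop$classes$class == "NEGATIVE"]
  dos <- as.matrix(pop$genotypes[neg])
  carriers <- rowSums(dos >= 1, na.rm = TRUE)
  expect_true(all(carriers[spec$common_negative] > 10))
  expect_true(all(carriers[!spec$common_negative] <= 10))
})

test_that("truth tables serialize to JSON and configs echo to YAML", {
  cfg <- small_config(seed = 20)
  hap <- simulate_haplotype_panel(cfg)
  tj <- withr::local_tempfile(fileext = ".json")
  write_truth_json(hap$truth, tj)
  parsed <- jsonlite::read_json(tj)
  expect_equal(length(parsed$planted), nrow(hap$truth$planted))

  cy <- withr::local_tempfile(fileext = ".yaml")
  write_config_yaml(cfg, cy)
  echo <- yaml::read_yaml(cy)
  expect_equal(echo$locus_length, cfg$locus_length)
  expect_equal(echo$seed, cfg$seed)
})

test_that("genotype VCF round-trips dosages including missing calls", {
  cfg <- sim_config(locus_length = 10000, genotype_region_length = 10000,
    n_individuals = 30, n_markers = 12, seed = 2)
  g <- simulate_genotype_panel(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(g, path)
  back <- read_genotypes_vcf(path)
  expect_equal(back$pos, g$pos)
  expect_equal(
    unname(as.matrix(back[sprintf("I%04d", 1:30)])),
    unname(haplopin:::geno_dosages(g))
  )
})
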