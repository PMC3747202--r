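test_that("an alignment of identical sequences yields no variants", {
  panel <- tibble::tibble(
    id = c("reference", "h1", "h2"),
    label = c("reference", "risk", "nonrisk"),
    sequence = rep("ACGTACGTAC", 3)
  )
  expect_equal(nrow(extract_variants(panel)), 0)
})

test_that("a toy alignment yields the hand-derived SNP and left-aligned deletion", {
  panel <- tibble::tibble(
    id = c("reference", "m1", "m2"),
    label = c("reference", "risk", "nonrisk"),
    sequence = c("ACGTACGT", "ACGAACGT", "ACG-ACGT")
  )
  v <- extract_variants(panel)
  expect_equal(nrow(v), 2)

  snp <- v[v$type == "SNP", ]
  expect_equal(snp$pos, 4)
  expect_equal(snp$ref, "T")
  expect_equal(snp$alt, "A")
  expect_equal(snp$presence[[1]][["m1"]], "present")
  expect_equal(snp$presence[[1]][["m2"]], "absent")

  del <- v[v$type == "deletion", ]
  expect_equal(del$pos, 3) # anchored on the base before the gap
  expect_equal(del$ref, "GT")
  expect_equal(del$alt, "G")
  expect_equal(del$presence[[1]][["m2"]], "present")
  expect_equal(del$presence[[1]][["m1"]], "absent")
})

test_that("insertions are anchored, merged across gap columns, and N gives no_coverage", {
  # reference has a 2-column gap; m1 carries the insertion, m2 does not,
  # m3 has an undetermined base at the SNP column
  panel <- tibble::tibble(
    id = c("reference", "m1", "m2", "m3"),
    label = c("reference", "risk", "nonrisk", "nonrisk"),
    sequence = c("ACG--TACGT", "ACGTTTACGT", "ACG--TACGT", "ACG--TACNT")
  )
  v <- extract_variants(panel)
  ins <- v[v$type == "insertion", ]
  expect_equal(ins$pos, 3)
  expect_equal(ins$ref, "G")
  expect_equal(ins$alt, "GTT")
  expect_equal(unname(ins$presence[[1]][c("m1", "m2")]),
    c("present", "absent"))

  expect_equal(nrow(v[v$type == "SNP", ]), 0)
  # the N is only reported where a variant exists; add one at that column
  panel$sequence[2] <- "ACGTTTACAT"
  v2 <- extract_variants(panel)
  snp <- v2[v2$type == "SNP", ]
  expect_equal(snp$pos, 7)
  expect_equal(snp$presence[[1]][["m3"]], "no_coverage")
})

test_that("adjacent co-segregating substitutions merge into one MNP", {
  panel <- tibble::tibble(
    id = c("reference", "m1", "m2"),
    label = c("reference", "risk", "nonrisk"),
    sequence = c("AACCGGTT", "AATTGGTT", "AACCGGTT")
  )
  v <- extract_variants(panel)
  expect_equal(nrow(v), 1)
  expect_equal(v$type, "MNP")
  expect_equal(v$ref, "CC")
  expect_equal(v$alt, "TT")
  expect_equal(v$pos, 3)

  # non-co-segregating neighbours stay separate SNPs
  panel2 <- tibble::tibble(
    id = c("reference", "m1", "m2"),
    label = c("reference", "risk", "nonrisk"),
    sequence = c("AACCGGTT", "AATCGGTT", "AACTGGTT")
  )
  v2 <- extract_variants(panel2)
  expect_equal(sort(v2$type), c("SNP", "SNP"))
})

test_that("left-normalization matches hand-worked repeat cases and is idempotent", {
  ref <- strsplit("CATTTGAC", "")[[1]]
  # deleting one T of the TTT run left-aligns to the anchor A at position 2
  norm <- normalize_variant(4, "TT", "T", ref)
  expect_equal(norm, list(pos = 2L, ref = "AT", alt = "A"))
  again <- normalize_variant(norm$pos, norm$ref, norm$alt, ref)
  expect_equal(again, norm)

  # insertion of a T inside the run shifts to the same anchor
  normi <- normalize_variant(5, "T", "TT", ref)
  expect_equal(normi, list(pos = 2L, ref = "A", alt = "AT"))
  expect_equal(normalize_variant(normi$pos, normi$ref, normi$alt, ref), normi)

  # random indels: normalizing twice equals normalizing once
  withr::with_seed(42, {
    chars <- sample(c("A", "C", "G", "T"), 500, replace = TRUE)
    for (i in 1:50) {
      pos <- sample(20:480, 1)
      len <- sample(1:6, 1)
      v <- if (runif(1) < 0.5) {
        list(pos = pos, ref = paste(chars[pos:(pos + len)], collapse = ""),
          alt = chars[pos])
      } else {
        list(pos = pos, ref = chars[pos],
          alt = paste(c(chars[pos],
            sample(c("A", "C", "G", "T"), len, replace = TRUE)), collapse = ""))
      }
      n1 <- normalize_variant(v$pos, v$ref, v$alt, chars)
      n2 <- normalize_variant(n1$pos, n1$ref, n1$alt, chars)
      expect_equal(n2, n1)
    }
  })
})

test_that("the low-complexity mask flags the documented boundary cases", {
  # positions:        123456789012345678
  mask <- build_low_complexity_mask("GGTAAAAATTACACACTT")
  hp <- mask[mask$kind == "homopolymer", ]
  expect_equal(nrow(hp), 1)
  expect_equal(c(hp$start, hp$end), c(4, 8))
  dn <- mask[mask$kind == "dinucleotide", ]
  expect_equal(nrow(dn), 1)
  expect_equal(c(dn$start, dn$end), c(11, 16))
  expect_equal(dn$unit, "AC")

  # a 4-run does not exceed 4 nucleotides; 2 dinucleotide units are no repeat
  expect_equal(nrow(build_low_complexity_mask("GGTAAAATCACACGT")), 0)
})

test_that("masking drops exactly the variants whose span touches an interval", {
  mask <- tibble::tibble(start = 10L, end = 15L, kind = "homopolymer", unit = "A")
  v <- tibble::tibble(
    chrom = "locus",
    pos = c(9L, 10L, 15L, 16L, 8L, 14L),
    ref = c("C", "C", "C", "C", "CAA", "C"),
    alt = c("T", "T", "T", "T", "C", "CTT"),
    type = c("SNP", "SNP", "SNP", "SNP", "deletion", "insertion"),
    presence = replicate(6, c(m1 = "present"), simplify = FALSE)
  )
  kept <- apply_mask(v, mask)
  # SNP at 9 and 16 survive; deletion spanning 8-10 and insertion spanning
  # 14-15 overlap the interval and are dropped
  expect_equal(kept$pos, c(9L, 16L))
})

test_that("risk-specific calling enforces the presence/absence rule", {
  members <- c(paste0("r", 1:4), paste0("n", 1:11))
  labels <- tibble::tibble(
    id = members, label = rep(c("risk", "nonrisk"), c(4, 11)))
  mk <- function(risk_in, nonrisk_in) {
    p <- setNames(rep("absent", 15), members)
    p[risk_in] <- "present"
    p[nonrisk_in] <- "present"
    p
  }
  v <- tibble::tibble(
    chrom = "locus", pos = 1:3, ref = "A", alt = "T", type = "SNP",
    presence = list(
      mk(paste0("r", 1:3), character(0)), # 3/4 risk, 0 non-risk: kept
      mk(paste0("r", 1:4), "n1"),         # present in one non-risk: dropped
      mk(paste0("r", 1:2), character(0))  # only 2 risk: dropped
    )
  )
  kept <- call_risk_specific(v, labels)
  expect_equal(kept$pos, 1L)
  expect_equal(kept$risk_present, 3L)
  expect_equal(kept$nonrisk_present, 0L)

  expect_error(
    call_risk_specific(v, labels[labels$label == "nonrisk", ]),
    "risk members"
  )
})

test_that("relabeling members changes classification but never the variant set", {
  cfg <- small_config(seed = 11)
  hap <- simulate_haplotype_panel(cfg)
  v1 <- extract_variants(hap$panel)
  flipped <- hap$panel
  flipped$label[flipped$label == "risk"] <- "tmp"
  flipped$label[flipped$label == "nonrisk"] <- "risk"
  flipped$label[flipped$label == "tmp"] <- "nonrisk"
  v2 <- extract_variants(flipped)
  expect_equal(v1[c("pos", "ref", "alt", "type")],
    v2[c("pos", "ref", "alt", "type")])
})

test_that("variant records round-trip through VCF", {
  cfg <- small_config(seed = 3)
  hap <- simulate_haplotype_panel(cfg)
  v <- extract_variants(hap$panel)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(v, path)
  back <- read_variants_vcf(path)
  expect_equal(back$pos, v$pos)
  expect_equal(back$ref, v$ref)
  expect_equal(back$alt, v$alt)
  expect_equal(back$type, v$type)
  expect_equal(back$presence, v$presence)
})
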