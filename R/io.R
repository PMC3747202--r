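# Readers and writers for the standard interchange formats: multi-FASTA
# panels (Biostrings), VCF v4.2 (text out, vcfR in), BED6 / narrowPeak
# (plain TSV), truth tables as JSON and configs as YAML.

#' Write / read an aligned haplotype panel as multi-FASTA
#'
#' Labels are carried in the FASTA description as `id label`, so a panel
#' round-trips without a side-car file; [read_panel_fasta()] also accepts an
#' explicit label tibble which then takes precedence.
#'
#' @param panel Panel tibble (`id`, `label`, `sequence`).
#' @param path Output path.
#' @param labels Optional tibble (`id`, `label`).
#' @return `read_panel_fasta()` returns a panel tibble.
#' @export
write_panel_fasta <- function(panel, path) {
  x <- Biostrings::BStringSet(setNames(panel$sequence,
    paste(panel$id, panel$label)))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' @rdname write_panel_fasta
#' @export
read_panel_fasta <- function(path, labels = NULL) {
  x <- Biostrings::readBStringSet(path)
  nm <- strsplit(names(x), "\\s+")
  panel <- tibble(
    id = vapply(nm, `[`, "", 1),
    label = vapply(nm, function(v) if (length(v) > 1) v[2] else NA_character_, ""),
    sequence = unname(as.character(x))
  )
  if (!is.null(labels)) {
    panel$label <- labels$label[match(panel$id, labels$id)]
    panel$label[panel$id == "reference"] <- "reference"
  }
  panel
}

vcf_header <- function(chrom, length, info = character(), format = character(),
                       samples = character()) {
  c(
    "##fileformat=VCFv4.2",
    "##source=haplopin",
    sprintf("##contig=<ID=%s,length=%d>", chrom, length),
    info, format,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      if (length(samples)) c("FORMAT", samples)), collapse = "\t")
  )
}

#' Write panel variant calls to VCF v4.2
#'
#' Per-member presence is encoded as a haploid genotype column per panel
#' member (`1` present, `0` absent, `.` no coverage), and the risk /
#' non-risk presence counts as INFO tags `RISK_PRESENT`, `NONRISK_PRESENT`
#' and `NOCOV` when available.
#'
#' @param variants Variant tibble with `presence` list-column.
#' @param path Output path.
#' @param contig_length Reference length for the VCF header.
#' @export
write_variants_vcf <- function(variants, path, contig_length = NA) {
  chrom <- if (nrow(variants)) variants$chrom[1] else "locus"
  members <- if (nrow(variants)) names(variants$presence[[1]]) else character()
  if (is.na(contig_length)) {
    contig_length <- max(c(1L, variants$pos + nchar(variants$ref)))
  }
  has_counts <- all(c("risk_present", "nonrisk_present") %in% names(variants))
  info_meta <- c(
    '##INFO=<ID=TYPE,Number=1,Type=String,Description="Variant type">',
    if (has_counts) c(
      '##INFO=<ID=RISK_PRESENT,Number=1,Type=Integer,Description="Risk haplotypes carrying the variant">',
      '##INFO=<ID=NONRISK_PRESENT,Number=1,Type=Integer,Description="Non-risk haplotypes carrying the variant">',
      '##INFO=<ID=NOCOV,Number=1,Type=Integer,Description="Haplotypes without coverage at the site">'
    )
  )
  fmt_meta <- '##FORMAT=<ID=GT,Number=1,Type=String,Description="Haploid presence: 1 present, 0 absent, . no coverage">'
  header <- vcf_header(chrom, contig_length, info_meta, fmt_meta, members)
  body <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    info <- paste0("TYPE=", v$type)
    if (has_counts) {
      info <- paste0(info, sprintf(";RISK_PRESENT=%d;NONRISK_PRESENT=%d;NOCOV=%d",
        v$risk_present, v$nonrisk_present, v$no_coverage))
    }
    gt <- c(present = "1", absent = "0", no_coverage = ".")[v$presence[[1]][members]]
    paste(c(v$chrom, v$pos, sprintf("var_%05d", i), v$ref, v$alt, ".",
      "PASS", info, "GT", gt), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read panel variant calls back from VCF
#'
#' Inverse of [write_variants_vcf()].
#'
#' @param path VCF path (plain text).
#' @return Variant tibble with `chrom`, `pos`, `ref`, `alt`, `type` and the
#'   `presence` list-column.
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
      alt = character(), type = character(), presence = list()))
  }
  type <- sub(".*TYPE=([^;]+).*", "\\1", fix$INFO)
  gt <- vcfR::extract.gt(v, element = "GT")
  members <- colnames(gt)
  presence <- lapply(seq_len(nrow(fix)), function(i) {
    g <- gt[i, ]
    setNames(
      ifelse(is.na(g) | g == ".", "no_coverage",
        ifelse(g == "1", "present", "absent")),
      members
    )
  })
  tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT, type = type, presence = presence
  )
}

#' Write a wide genotype tibble as a diploid VCF
#'
#' @param geno Wide genotype tibble (`marker`, `pos`, dosage columns).
#' @param path Output path.
#' @param chrom Contig name.
#' @param contig_length Contig length for the header.
#' @export
write_genotypes_vcf <- function(geno, path, chrom = "locus",
                                contig_length = max(geno$pos) + 1L) {
  d <- geno_dosages(geno)
  samples <- setdiff(names(geno), c("marker", "pos", "ref", "alt", "chrom", "block"))
  header <- vcf_header(chrom, contig_length,
    format = '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    samples = samples)
  code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(geno)), function(i) {
    gt <- ifelse(is.na(d[i, ]), "./.", code[d[i, ] + 1L])
    paste(c(chrom, geno$pos[i], geno$marker[i],
      if ("ref" %in% names(geno)) geno$ref[i] else "A",
      if ("alt" %in% names(geno)) geno$alt[i] else "G",
      ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_genotypes_vcf
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  bind_cols(
    tibble(marker = fix$ID, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT),
    as_tibble(as.data.frame(dos), .name_repair = "minimal")
  )
}

NARROWPEAK_COLS <- c("chrom", "start", "end", "name", "score", "strand",
  "signal", "neglog10p", "qvalue", "peak")

#' Write / read ENCODE narrowPeak and BED tracks
#'
#' narrowPeak columns 7 and 8 map to the signal value and `-log10 p`
#' respectively, column 5 to the integer score. `write_bed()` emits BED6
#' plus any extra columns (e.g. CGI `methylation`) appended after the
#' strand.
#'
#' @param track Peak tibble.
#' @param path File path.
#' @param extra_cols Extra column names appended after BED6 fields.
#' @return Readers return tibbles with the package's track columns.
#' @export
write_narrowpeak <- function(track, path) {
  out <- track[NARROWPEAK_COLS]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_narrowpeak
#' @export
read_narrowpeak <- function(path) {
  readr::read_tsv(path, col_names = NARROWPEAK_COLS,
    col_types = "ciicncnnni", progress = FALSE)
}

#' @rdname write_narrowpeak
#' @export
write_bed <- function(track, path, extra_cols = intersect("methylation", names(track))) {
  cols <- c("chrom", "start", "end", "name", "score", "strand", extra_cols)
  readr::write_tsv(track[cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_narrowpeak
#' @param col_names Column names for the BED file being read.
#' @export
read_bed <- function(path, col_names = c("chrom", "start", "end", "name",
                                         "score", "strand", "methylation")) {
  readr::read_tsv(path, col_names = col_names, progress = FALSE,
    col_types = readr::cols(start = "i", end = "i", .default = "c"))
}

#' Write an LD matrix and a conserved block to disk
#'
#' The pairwise `|D'|` matrix is written as a TSV with marker ids as the
#' first column and header; the block as BED (0-based half-open).
#'
#' @param ld A `haplopin_ld` object.
#' @param block One-row block tibble from [find_conserved_block()].
#' @param path Output path.
#' @param chrom Reference name for the BED record.
#' @export
write_ld_tsv <- function(ld, path) {
  m <- as.data.frame(ld$dprime)
  names(m) <- ld$markers$marker
  out <- bind_cols(tibble(marker = ld$markers$marker), as_tibble(m))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_ld_tsv
#' @export
write_block_bed <- function(block, path, chrom = "locus") {
  bed <- tibble(
    chrom = chrom,
    start = block$start - 1L, # 1-based inclusive -> 0-based half-open
    end = block$end,
    name = "ld_conserved_block",
    score = round(1000 * block$mean_dprime),
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Serialize a truth table to JSON
#'
#' @param truth A `haplopin_truth` object.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  planted <- truth$planted
  planted$carriers <- vapply(planted$carriers, paste, "", collapse = ",")
  jsonlite::write_json(
    list(
      planted = planted,
      decoy_regions = truth$decoy_regions,
      enhancers = truth$enhancers,
      motif_events = truth$motif_events
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Echo a simulation config to YAML
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @export
write_config_yaml <- function(config, path) {
  x <- unclass(config)
  x$ld_block_spec <- as.data.frame(x$ld_block_spec)
  yaml::write_yaml(x, path)
  invisible(path)
}
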