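#' Extract normalized variants from an aligned haplotype panel
#'
#' Walks the columns of a multiple sequence alignment of locus-spanning
#' haplotypes against a reference row and emits one record per distinct
#' normalized variant (SNP, MNP, insertion or deletion), with a per-member
#' presence flag. Adjacent gap columns are merged into single indel events,
#' indels are left-aligned against the reference, and alignment columns where
#' a member carries an undetermined base (`N`) yield a `no_coverage` flag for
#' that member. Runs of adjacent substitution columns that co-segregate
#' identically across all members are merged into a single MNP record.
#'
#' @param panel A tibble with columns `id`, `label`, `sequence`. Exactly one
#'   row must carry `label == "reference"`; all sequences must have equal
#'   (aligned) length. Member labels are `risk`, `nonrisk` or `excluded`.
#' @param chrom Reference/chromosome name stamped on every call.
#'
#' @return A tibble with columns `chrom`, `pos` (1-based reference position),
#'   `ref`, `alt`, `type` and a list-column `presence` holding, per variant, a
#'   named character vector over member ids with values `"present"`,
#'   `"absent"` or `"no_coverage"`.
#' @export
#' @examples
#' panel <- tibble::tibble(
#'   id = c("ref", "h1", "h2"),
#'   label = c("reference", "risk", "nonrisk"),
#'   sequence = c("ACGTACGT", "ACGAACGT", "ACG-ACGT")
#' )
#' extract_variants(panel)
extract_variants <- function(panel, chrom = "locus") {
  panel <- as_tibble(panel)
  if (!all(c("id", "label", "sequence") %in% names(panel))) {
    abort("`panel` needs columns id, label, sequence.")
  }
  is_ref <- panel$label == "reference"
  if (sum(is_ref) != 1) abort("`panel` must contain exactly one reference row.")
  seqs <- toupper(panel$sequence)
  if (length(unique(nchar(seqs))) != 1) {
    abort("aligned panel rows must all have equal length.")
  }

  refc <- seq_chars(seqs[is_ref])
  member_ids <- panel$id[!is_ref]
  if (length(member_ids) == 0) abort("`panel` has no member sequences.")
  mat <- do.call(rbind, strsplit(seqs[!is_ref], "", fixed = TRUE))
  rownames(mat) <- member_ids
  n_col <- length(refc)

  ins_col <- refc == "-"
  refpos <- cumsum(!ins_col) # anchors insertion columns to the previous base
  ref_plain <- refc[!ins_col]

  events <- list()
  add_event <- function(pos, ref, alt, type, presence) {
    events[[length(events) + 1L]] <<- list(
      pos = pos, ref = ref, alt = alt, type = type, presence = presence
    )
  }

  nocov_over <- function(cols) {
    if (length(cols) == 1) mat[, cols] == "N"
    else apply(mat[, cols, drop = FALSE] == "N", 1, any)
  }

  ## --- substitutions -------------------------------------------------------
  diff_any <- colSums(mat != matrix(refc, nrow(mat), n_col, byrow = TRUE)) > 0
  sub_cols <- which(diff_any & !ins_col)
  for (cc in sub_cols) {
    obs <- mat[, cc]
    alts <- setdiff(unique(obs), c(refc[cc], "-", "N"))
    for (a in alts) {
      presence <- ifelse(obs == "N", "no_coverage",
        ifelse(obs == a, "present", "absent")
      )
      add_event(refpos[cc], refc[cc], a, "SNP", setNames(presence, member_ids))
    }
  }

  ## --- deletions (member gap runs over reference-bearing columns) ---------
  del_keys <- list()
  for (m in seq_along(member_ids)) {
    gaps <- mat[m, ] == "-"
    if (!any(gaps)) next
    r <- rle(gaps)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      cols <- starts[k]:ends[k]
      del_cols <- cols[!ins_col[cols]]
      if (length(del_cols) == 0) next # member merely lacks an insertion
      anchor <- refpos[del_cols[1]] - 1L
      if (anchor < 1L) {
        warn("deletion at the left contig edge has no anchor base; skipped.")
        next
      }
      norm <- normalize_variant(
        anchor,
        paste(c(ref_plain[anchor], refc[del_cols]), collapse = ""),
        ref_plain[anchor],
        ref_plain
      )
      key <- paste(norm$pos, norm$ref, norm$alt, sep = "\r")
      del_keys[[key]] <- c(del_keys[[key]] %||% list(), list(list(
        member = member_ids[m], cols = cols, norm = norm
      )))
    }
  }
  for (key in names(del_keys)) {
    entries <- del_keys[[key]]
    norm <- entries[[1]]$norm
    span_cols <- sort(unique(unlist(lapply(entries, `[[`, "cols"))))
    carriers <- vapply(entries, `[[`, "", "member")
    presence <- ifelse(nocov_over(span_cols), "no_coverage", "absent")
    presence[match(carriers, member_ids)] <- "present"
    add_event(norm$pos, norm$ref, norm$alt, "deletion",
      setNames(presence, member_ids))
  }

  ## --- insertions (reference gap runs) -------------------------------------
  if (any(ins_col)) {
    r <- rle(ins_col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      cols <- starts[k]:ends[k]
      anchor <- refpos[cols[1]]
      if (anchor < 1L) {
        warn("insertion before the first reference base has no anchor; skipped.")
        next
      }
      ins_strings <- apply(mat[, cols, drop = FALSE], 1, function(s) {
        s <- s[s != "-"]
        if (any(s == "N")) NA_character_ else paste(s, collapse = "")
      })
      for (ins in setdiff(unique(ins_strings[!is.na(ins_strings)]), "")) {
        norm <- normalize_variant(
          anchor, ref_plain[anchor], paste0(ref_plain[anchor], ins), ref_plain
        )
        presence <- ifelse(is.na(ins_strings), "no_coverage",
          ifelse(ins_strings == ins, "present", "absent")
        )
        add_event(norm$pos, norm$ref, norm$alt, "insertion",
          setNames(presence, member_ids))
      }
    }
  }

  if (length(events) == 0) {
    return(tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), type = character(), presence = list()
    ))
  }

  out <- tibble(
    chrom = chrom,
    pos = vapply(events, `[[`, 0, "pos"),
    ref = vapply(events, `[[`, "", "ref"),
    alt = vapply(events, `[[`, "", "alt"),
    type = vapply(events, `[[`, "", "type"),
    presence = lapply(events, `[[`, "presence")
  )
  out <- out[!duplicated(out[c("pos", "ref", "alt")]), ]
  for (i in seq_len(nrow(out))) {
    expect <- paste(ref_plain[out$pos[i]:(out$pos[i] + nchar(out$ref[i]) - 1L)],
      collapse = "")
    if (expect != out$ref[i]) {
      abort(sprintf(
        "reference allele mismatch after normalization at column %d: %s vs %s",
        out$pos[i], out$ref[i], expect
      ))
    }
  }
  out <- merge_mnps(out[order(out$pos, out$ref, out$alt), ])
  out
}

# Merge runs of adjacent SNP columns whose presence/no-coverage pattern is
# identical across all members into single MNP records.
merge_mnps <- function(variants) {
  snp <- variants$type == "SNP"
  if (sum(snp) < 2) return(variants)
  idx <- which(snp)
  sig <- vapply(variants$presence[idx], paste, "", collapse = "|")
  runs <- list()
  current <- idx[1]
  for (j in seq_along(idx)[-1]) {
    prev <- current[length(current)]
    if (variants$pos[idx[j]] == variants$pos[prev] + 1L &&
        sig[j] == sig[match(prev, idx)] &&
        any(variants$presence[[idx[j]]] == "present")) {
      current <- c(current, idx[j])
    } else {
      runs[[length(runs) + 1L]] <- current
      current <- idx[j]
    }
  }
  runs[[length(runs) + 1L]] <- current
  merged <- lapply(runs, function(rr) {
    if (length(rr) == 1) return(variants[rr, ])
    row <- variants[rr[1], ]
    row$ref <- paste(variants$ref[rr], collapse = "")
    row$alt <- paste(variants$alt[rr], collapse = "")
    row$type <- "MNP"
    row
  })
  out <- bind_rows(bind_rows(merged), variants[!snp, ])
  out[order(out$pos, out$ref, out$alt), ]
}

#' Left-normalize a variant against a reference sequence
#'
#' Applies the standard normalization: shared trailing bases are trimmed
#' (extending left with reference context when an allele would empty), then
#' shared leading bases beyond the single anchor base are trimmed. The
#' operation is idempotent.
#'
#' @param pos 1-based reference position of the first `ref` base.
#' @param ref,alt Allele strings.
#' @param ref_chars Reference sequence as a character vector of bases.
#' @return A list with elements `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt, ref_chars) {
  r <- seq_chars(ref)
  a <- seq_chars(alt)
  repeat {
    while (length(r) > 0 && length(a) > 0 &&
           r[length(r)] == a[length(a)] &&
           (length(r) > 1 || length(a) > 1)) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    if (length(r) == 0 || length(a) == 0) {
      if (pos <= 1L) abort("cannot left-extend a variant past the contig start.")
      pos <- pos - 1L
      r <- c(ref_chars[pos], r)
      a <- c(ref_chars[pos], a)
    } else {
      break
    }
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
    alt = paste(a, collapse = ""))
}

#' Mask low-complexity regions of a reference sequence
#'
#' Flags maximal homopolymer runs longer than four bases and maximal
#' dinucleotide tandem repeats of at least `min_dinuc_units` unit copies.
#' Variants inside such regions are indistinguishable from replication
#' slippage and alignment artefacts and are excluded downstream.
#'
#' @param reference Reference sequence (single string).
#' @param min_homopolymer Minimum run length flagged (default 5, i.e. runs
#'   exceeding 4 nt).
#' @param min_dinuc_units Minimum number of tandem copies of a 2-mer.
#' @return Tibble with columns `start`, `end` (1-based inclusive), `kind`
#'   (`homopolymer` or `dinucleotide`) and `unit`.
#' @export
#' @examples
#' build_low_complexity_mask("GGTAAAAATTACACACTT")
build_low_complexity_mask <- function(reference, min_homopolymer = 5,
                                      min_dinuc_units = 3) {
  s <- seq_chars(toupper(reference))
  n <- length(s)
  if (n == 0) abort("`reference` must be non-empty.")
  out <- list()

  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hp <- which(r$lengths >= min_homopolymer & r$values %in% BASES)
  if (length(hp)) {
    out[[1]] <- tibble(
      start = starts[hp], end = ends[hp],
      kind = "homopolymer", unit = r$values[hp]
    )
  }

  if (n >= 2 * min_dinuc_units) {
    # maximal period-2 stretches: s[i] == s[i + 2]
    eq <- s[seq_len(n - 2)] == s[3:n]
    re <- rle(eq)
    e2 <- cumsum(re$lengths)
    s2 <- e2 - re$lengths + 1L
    keep <- which(re$values)
    rows <- list()
    for (k in keep) {
      st <- s2[k]
      len <- re$lengths[k] + 2L # stretch spans positions st .. st+len-1
      if (s[st] == s[st + 1L]) next # homopolymer, handled above
      units <- len %/% 2L
      if (units < min_dinuc_units) next
      rows[[length(rows) + 1L]] <- tibble(
        start = st, end = st + len - 1L,
        kind = "dinucleotide", unit = paste0(s[st], s[st + 1L])
      )
    }
    if (length(rows)) out[[length(out) + 1L]] <- bind_rows(rows)
  }

  if (length(out) == 0) {
    return(tibble(start = integer(), end = integer(),
      kind = character(), unit = character()))
  }
  arrange(bind_rows(out), .data$start)
}

# 1-based inclusive reference-affected span of each variant: the ref bases
# for substitutions and deletions; the anchor plus following base for
# insertions.
variant_span <- function(variants) {
  end <- variants$pos + nchar(variants$ref) - 1L
  end[variants$type == "insertion"] <- variants$pos[variants$type == "insertion"] + 1L
  tibble(start = variants$pos, end = as.integer(end))
}

#' Drop variants overlapping a low-complexity mask
#'
#' @param variants Variant tibble from [extract_variants()].
#' @param mask Mask tibble from [build_low_complexity_mask()].
#' @return The retained variants.
#' @export
apply_mask <- function(variants, mask) {
  if (nrow(variants) == 0 || nrow(mask) == 0) return(variants)
  sp <- variant_span(variants)
  hits <- IRanges::countOverlaps(
    IRanges::IRanges(sp$start, sp$end),
    IRanges::IRanges(mask$start, mask$end)
  )
  variants[hits == 0, ]
}

#' Call variants unique to risk haplotypes
#'
#' Applies the presence/absence rule used to define candidate susceptibility
#' variants: a variant is kept when it is present on at least
#' `min_risk_present` risk haplotypes and on at most `max_nonrisk_present`
#' non-risk haplotypes. Members labelled `excluded` never enter the counts;
#' `no_coverage` flags count as neither present nor absent and are reported
#' per variant so users can tighten the rule.
#'
#' @param variants Variant tibble with a `presence` list-column.
#' @param labels Tibble with columns `id`, `label` mapping panel members to
#'   `risk` / `nonrisk` / `excluded`.
#' @param min_risk_present Minimum risk haplotypes carrying the variant
#'   (default 3).
#' @param max_nonrisk_present Maximum non-risk haplotypes allowed to carry it
#'   (default 0, i.e. absent from all).
#' @return The retained variants with added columns `risk_present`,
#'   `nonrisk_present` and `no_coverage`.
#' @export
call_risk_specific <- function(variants, labels, min_risk_present = 3,
                               max_nonrisk_present = 0) {
  labels <- as_tibble(labels)
  risk_ids <- labels$id[labels$label == "risk"]
  nonrisk_ids <- labels$id[labels$label == "nonrisk"]
  if (length(risk_ids) < min_risk_present) {
    abort(sprintf(
      "panel has %d risk members but `min_risk_present` is %d.",
      length(risk_ids), min_risk_present
    ))
  }
  count_in <- function(p, ids, value) sum(p[ids] == value, na.rm = TRUE)
  variants <- mutate(variants,
    risk_present = vapply(.data$presence, count_in, 0L, risk_ids, "present"),
    nonrisk_present = vapply(.data$presence, count_in, 0L, nonrisk_ids, "present"),
    no_coverage = vapply(
      .data$presence, count_in, 0L, c(risk_ids, nonrisk_ids), "no_coverage"
    )
  )
  filter(variants,
    .data$risk_present >= min_risk_present,
    .data$nonrisk_present <= max_nonrisk_present)
}
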