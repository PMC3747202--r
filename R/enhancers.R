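# Enhancer calling from epigenetic peak tracks, and variant/enhancer
# intersection. All intervals are BED-convention: 0-based, half-open.

check_track <- function(track, name, scores = FALSE) {
  track <- as_tibble(track)
  need <- c("chrom", "start", "end")
  if (scores) need <- c(need, "neglog10p", "signal", "score")
  miss <- setdiff(need, names(track))
  if (length(miss)) {
    abort(sprintf("track '%s' is missing column(s): %s", name,
      paste(miss, collapse = ", ")))
  }
  if (any(track$start >= track$end)) {
    abort(sprintf("track '%s' has empty or inverted intervals.", name))
  }
  arrange(track, .data$chrom, .data$start)
}

#' Threshold-filter a DNase hypersensitivity peak track, with rescue
#'
#' Pass 1 keeps peaks satisfying all three strict score inequalities
#' (`-log10 p > min_neglog10p`, `signal > min_signal`, `score > min_score`).
#' Pass 2 rescues any failing peak lying strictly less than
#' `rescue_distance` bases (edge-to-edge; overlapping counts as 0) from a
#' pass-1 peak. With no pass-1 peaks nothing is rescued.
#'
#' @param track Peak tibble with columns `chrom`, `start`, `end`,
#'   `neglog10p`, `signal`, `score`.
#' @param min_neglog10p,min_signal,min_score Strict lower thresholds
#'   (defaults 50 / 30 / 120).
#' @param rescue_distance Rescue radius in bases (default 1000).
#' @return The retained peaks, sorted, with a `status` column
#'   (`"pass"` / `"rescued"`).
#' @export
filter_dhs <- function(track, min_neglog10p = 50, min_signal = 30,
                       min_score = 120, rescue_distance = 1000) {
  track <- check_track(track, "DHS", scores = TRUE)
  pass <- track$neglog10p > min_neglog10p &
    track$signal > min_signal &
    track$score > min_score
  if (!any(pass)) {
    return(mutate(track[0, ], status = character(0)))
  }
  rescued <- rep(FALSE, nrow(track))
  for (ch in unique(track$chrom)) {
    on_ch <- track$chrom == ch
    fail_i <- which(on_ch & !pass)
    pass_i <- which(on_ch & pass)
    if (!length(fail_i) || !length(pass_i)) next
    for (i in fail_i) {
      gaps <- interval_gap(track$start[i], track$end[i],
        track$start[pass_i], track$end[pass_i])
      rescued[i] <- min(gaps) < rescue_distance
    }
  }
  out <- mutate(track, status = ifelse(pass, "pass", "rescued"))
  arrange(filter(out, pass | rescued), .data$chrom, .data$start)
}

#' Call active enhancers from H3K4me1 / H3K27ac co-occurrence
#'
#' Every H3K4me1 peak overlapping at least one H3K27ac peak by
#' `min_overlap` bases yields an *active* enhancer whose interval is the
#' union of the H3K4me1 peak with all overlapping H3K27ac peaks;
#' non-overlapping H3K4me1 peaks are emitted as inactive elements. When a
#' CpG-island track is supplied, overlap and methylation status are
#' annotated; with `require_unmethylated_cgi = TRUE` activity additionally
#' requires an overlapping unmethylated CGI.
#'
#' @param h3k4me1,h3k27ac Peak tibbles (`chrom`, `start`, `end`, ...).
#' @param cgi Optional CGI tibble with a `methylation` column
#'   (`unmethylated` / `partial` / `methylated`).
#' @param min_overlap Minimum overlap in bases (default 1).
#' @param require_unmethylated_cgi Strict mode, see above.
#' @return Tibble of enhancer calls: `enhancer_id`, `chrom`, `start`, `end`,
#'   `active`, `n_h3k27ac`, `cgi`, `cgi_methylation`.
#' @export
call_active_enhancers <- function(h3k4me1, h3k27ac, cgi = NULL,
                                  min_overlap = 1,
                                  require_unmethylated_cgi = FALSE) {
  me1 <- check_track(h3k4me1, "H3K4me1")
  ac <- check_track(h3k27ac, "H3K27ac")
  if (length(unique(me1$chrom)) > 0 && length(unique(ac$chrom)) > 0 &&
      !any(me1$chrom %in% ac$chrom) && nrow(me1) && nrow(ac)) {
    abort("H3K4me1 and H3K27ac tracks share no reference name.")
  }
  rows <- lapply(seq_len(nrow(me1)), function(i) {
    same <- ac$chrom == me1$chrom[i]
    ov <- pmin(ac$end, me1$end[i]) - pmax(ac$start, me1$start[i])
    hit <- same & ov >= min_overlap
    if (any(hit)) {
      tibble(
        chrom = me1$chrom[i],
        start = min(me1$start[i], ac$start[hit]),
        end = max(me1$end[i], ac$end[hit]),
        active = TRUE,
        n_h3k27ac = sum(hit)
      )
    } else {
      tibble(
        chrom = me1$chrom[i], start = me1$start[i], end = me1$end[i],
        active = FALSE, n_h3k27ac = 0L
      )
    }
  })
  out <- arrange(bind_rows(rows), .data$chrom, .data$start)
  out <- mutate(out,
    enhancer_id = sprintf("enh_%02d", row_number()),
    cgi = NA_character_, cgi_methylation = NA_character_
  )
  if (!is.null(cgi)) {
    cgi <- check_track(cgi, "CGI")
    if (!"methylation" %in% names(cgi)) {
      abort("CGI track needs a `methylation` column.")
    }
    if (!"name" %in% names(cgi)) cgi$name <- sprintf("cgi_%02d", seq_len(nrow(cgi)))
    for (i in seq_len(nrow(out))) {
      hit <- which(cgi$chrom == out$chrom[i] &
        cgi$start < out$end[i] & cgi$end > out$start[i])
      if (length(hit)) {
        out$cgi[i] <- paste(cgi$name[hit], collapse = ",")
        out$cgi_methylation[i] <- paste(cgi$methylation[hit], collapse = ",")
      }
    }
    if (require_unmethylated_cgi) {
      out$active <- out$active & !is.na(out$cgi_methylation) &
        grepl("unmethylated", out$cgi_methylation)
    }
  }
  select(out, "enhancer_id", "chrom", "start", "end", "active",
    "n_h3k27ac", "cgi", "cgi_methylation")
}

#' Annotate candidate variants with the enhancers containing them
#'
#' SNPs use point containment of the 1-based variant position inside the
#' 0-based half-open enhancer interval; indels and MNPs use any-overlap of
#' their reference-affected span. Only active enhancers count.
#'
#' @param candidates Variant tibble (`chrom`, `pos`, `ref`, `alt`, `type`).
#' @param enhancers Enhancer tibble from [call_active_enhancers()].
#' @return `candidates` with added columns `enhancers` (comma-collapsed ids,
#'   `NA` when outside all active enhancers), `n_enhancers`, and an
#'   attribute-free per-enhancer count available via
#'   `dplyr::count(out, enhancers)`.
#' @export
intersect_variants <- function(candidates, enhancers) {
  candidates <- as_tibble(candidates)
  act <- filter(as_tibble(enhancers), .data$active)
  if (nrow(candidates) == 0) {
    return(mutate(candidates, enhancers = character(0), n_enhancers = integer(0)))
  }
  sp <- variant_span(candidates) # 1-based inclusive
  hits_id <- rep(NA_character_, nrow(candidates))
  hits_n <- integer(nrow(candidates))
  if (nrow(act) > 0) {
    # convert the variant span to 0-based half-open
    q <- IRanges::IRanges(sp$start - 1L, width = sp$end - sp$start + 1L)
    s <- IRanges::IRanges(act$start, width = act$end - act$start)
    ov <- IRanges::findOverlaps(q, s, minoverlap = 1L)
    same_chrom <- candidates$chrom[S4Vectors::queryHits(ov)] ==
      act$chrom[S4Vectors::subjectHits(ov)]
    ov <- ov[same_chrom]
    if (length(ov)) {
      by_q <- split(
        act$enhancer_id[S4Vectors::subjectHits(ov)],
        S4Vectors::queryHits(ov)
      )
      idx <- as.integer(names(by_q))
      hits_id[idx] <- vapply(by_q, paste, "", collapse = ",")
      hits_n[idx] <- lengths(by_q)
    }
  }
  mutate(candidates, enhancers = hits_id, n_enhancers = hits_n)
}
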