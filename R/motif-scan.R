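# Allele-specific motif scanning: score reference vs alternate contexts of a
# variant against a PWM library and call gain/loss events, with empirical
# per-event p-values from dinucleotide-shuffled nulls.

encode_seq <- function(s) match(seq_chars(toupper(s)), BASES)

# Scores of every length-L placement in an integer-encoded sequence.
# Placements containing ambiguous bases score NA.
score_placements <- function(x, logodds) {
  L <- ncol(logodds)
  n <- length(x)
  if (n < L) return(numeric(0))
  P <- n - L + 1L
  idx <- outer(seq_len(L), seq_len(P) - 1L, "+") # L x P positions
  b <- x[idx]
  v <- logodds[cbind(b, rep(seq_len(L), P))]
  colSums(matrix(v, L, P))
}

# Best score over all placements and both strands; NA placements skipped.
best_hit <- function(x, pw) {
  fw <- score_placements(x, pw$logodds)
  rv <- score_placements(rev(5L - x), pw$logodds)
  sc <- c(fw, rv)
  skipped <- sum(is.na(sc))
  sc <- sc[!is.na(sc)]
  list(
    score = if (length(sc)) max(sc) else NA_real_,
    strand = if (length(sc) && max(sc) %in% fw) "+" else "-",
    n_skipped = skipped
  )
}

#' Score the reference and alternate alleles of a variant against a PWM
#'
#' Extracts the variant's sequence context (motif length minus one bases of
#' flank on each side, so that every scored placement overlaps the variant),
#' applies the alternate allele, and scores all placements on both strands
#' for each allele. A `gain` is called when the best alternate-allele score
#' passes `score_threshold` while the best reference score does not; a
#' `loss` is the converse; otherwise `none`.
#'
#' @param variant One-row tibble (or list) with `pos`, `ref`, `alt`.
#' @param reference Reference sequence string the variant is placed on.
#' @param pw A [pwm()] object.
#' @param score_threshold Score (bits) deciding motif presence; defaults to
#'   [pwm_threshold()] at null exceedance 1e-4.
#' @param threshold_seed Seed for the default threshold computation.
#' @param null_flank Flank width (bases) of the wider window stored for the
#'   empirical null (see [empirical_fdr()]); at least the motif length minus
#'   one is always used, and the window is clamped at contig edges.
#' @return One-row tibble: `pos`, `ref`, `alt`, `pwm`, `strand`, `best_ref`,
#'   `best_alt`, `score_threshold`, `event`, `n_skipped`, plus the scan
#'   context strings (`context_ref`, `context_alt`) and the wider null
#'   windows (`context_ref_wide`, `context_alt_wide`) consumed by
#'   [empirical_fdr()].
#' @export
scan_variant <- function(variant, reference, pw, score_threshold = NULL,
                         threshold_seed = NULL, null_flank = 30) {
  L <- ncol(pw$mat)
  if (is.null(score_threshold)) {
    score_threshold <- pwm_threshold(pw, seed = threshold_seed)
  }
  pos <- variant$pos
  refa <- toupper(variant$ref)
  alta <- toupper(variant$alt)
  n <- nchar(reference)
  flank <- L - 1L
  start <- pos - flank
  end <- pos + nchar(refa) - 1L + flank
  if (start < 1L || end > n) {
    abort("variant context truncated by the contig edge.")
  }
  ref_ctx <- substr(reference, start, end)
  if (substr(ref_ctx, flank + 1L, flank + nchar(refa)) != refa) {
    abort(sprintf("reference allele mismatch at position %d.", pos))
  }
  alt_ctx <- paste0(
    substr(reference, start, pos - 1L), alta,
    substr(reference, pos + nchar(refa), end)
  )
  nf <- max(flank, as.integer(null_flank))
  wstart <- max(1L, pos - nf)
  wend <- min(n, pos + nchar(refa) - 1L + nf)
  ref_wide <- substr(reference, wstart, wend)
  alt_wide <- paste0(
    substr(reference, wstart, pos - 1L), alta,
    substr(reference, pos + nchar(refa), wend)
  )
  hr <- best_hit(encode_seq(ref_ctx), pw)
  ha <- best_hit(encode_seq(alt_ctx), pw)
  ref_pass <- !is.na(hr$score) && hr$score >= score_threshold
  alt_pass <- !is.na(ha$score) && ha$score >= score_threshold
  event <- if (alt_pass && !ref_pass) "gain"
    else if (ref_pass && !alt_pass) "loss"
    else "none"
  tibble(
    pos = pos, ref = refa, alt = alta, pwm = pw$id,
    strand = if (isTRUE(ha$score >= hr$score)) ha$strand else hr$strand,
    best_ref = hr$score, best_alt = ha$score,
    score_threshold = score_threshold, event = event,
    n_skipped = hr$n_skipped + ha$n_skipped,
    context_ref = ref_ctx, context_alt = alt_ctx,
    context_ref_wide = ref_wide, context_alt_wide = alt_wide
  )
}

#' Scan a set of variants against a PWM library
#'
#' @param variants Variant tibble with `pos`, `ref`, `alt` columns.
#' @param reference Reference sequence string.
#' @param pwms List of [pwm()] objects.
#' @param score_threshold Optional fixed threshold applied to every PWM;
#'   when `NULL`, each PWM gets its own empirical threshold (seeded).
#' @param seed Seed for threshold computation.
#' @return Tibble of one [scan_variant()] row per (variant, PWM) pair.
#' @export
scan_variants <- function(variants, reference, pwms, score_threshold = NULL,
                          seed = NULL) {
  if (nrow(variants) == 0 || length(pwms) == 0) {
    return(tibble(
      pos = integer(), ref = character(), alt = character(),
      pwm = character(), strand = character(), best_ref = numeric(),
      best_alt = numeric(), score_threshold = numeric(), event = character(),
      n_skipped = integer(), context_ref = character(),
      context_alt = character()
    ))
  }
  rows <- list()
  for (k in seq_along(pwms)) {
    thr <- score_threshold %||%
      pwm_threshold(pwms[[k]], seed = child_seed(seed, k))
    for (i in seq_len(nrow(variants))) {
      rows[[length(rows) + 1L]] <-
        scan_variant(variants[i, ], reference, pwms[[k]], thr)
    }
  }
  bind_rows(rows)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: returns a uniformly drawn sequence with exactly
#' the same dinucleotide (and hence mononucleotide) counts, first and last
#' base as the input. Used to build motif-score null distributions that
#' preserve local composition.
#'
#' @param s Sequence string.
#' @return A shuffled sequence string.
#' @export
dinuc_shuffle <- function(s) {
  x <- encode_seq(s)
  chars <- seq_chars(toupper(s))
  if (anyNA(x)) {
    # treat any non-ACGT symbol as its own vertex
    x <- match(chars, unique(chars))
    out <- unique(chars)[dinuc_shuffle_int(x)]
    return(paste(out, collapse = ""))
  }
  paste(BASES[dinuc_shuffle_int(x)], collapse = "")
}

dinuc_shuffle_int <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  last <- x[n]
  verts <- unique(x)
  succ <- lapply(verts, function(v) x[which(x[-n] == v) + 1L])
  names(succ) <- verts
  from <- verts[vapply(succ, length, 0L) > 0L & verts != last]
  if (length(from)) {
    vmap <- setNames(seq_along(verts), verts)
    for (attempt in seq_len(200L)) {
      pick <- vapply(as.character(from), function(v) {
        e <- succ[[v]]
        e[sample.int(length(e), 1L)]
      }, 0L)
      # every chosen-edge path must reach `last`
      ok <- TRUE
      for (v in from) {
        cur <- v
        steps <- 0L
        while (cur != last) {
          i <- match(as.character(cur), names(pick))
          if (is.na(i) || steps > length(verts)) {
            ok <- FALSE
            break
          }
          cur <- pick[i]
          steps <- steps + 1L
        }
        if (!ok) break
      }
      if (ok) break
    }
    if (!ok) abort("dinucleotide shuffle failed to find a valid edge ordering.")
    # permute the remaining edges; chosen last-edge goes to the end
    for (v in as.character(from)) {
      e <- succ[[v]]
      drop1 <- match(pick[v], e)
      rest <- e[-drop1]
      succ[[v]] <- c(
        if (length(rest)) rest[sample.int(length(rest))] else integer(0),
        pick[v]
      )
    }
  }
  lv <- as.character(last)
  if (!is.null(succ[[lv]]) && length(succ[[lv]]) > 1L) {
    succ[[lv]] <- succ[[lv]][sample.int(length(succ[[lv]]))]
  }
  out <- integer(n)
  out[1L] <- x[1L]
  ptr <- setNames(rep(1L, length(verts)), verts)
  for (i in 2:n) {
    v <- as.character(out[i - 1L])
    out[i] <- succ[[v]][ptr[v]]
    ptr[v] <- ptr[v] + 1L
  }
  out
}

# Best-hit null scores for n_null dinucleotide shuffles of a context,
# scored in one vectorized pass per placement/strand. Ambiguous bases are
# shuffled as their own symbol and any placement touching one scores -Inf.
null_best_scores <- function(ctx, pw, n_null) {
  x <- encode_seq(ctx)
  x[is.na(x)] <- 5L
  n <- length(x)
  L <- ncol(pw$mat)
  shuf <- matrix(0L, n, n_null)
  for (k in seq_len(n_null)) shuf[, k] <- dinuc_shuffle_int(x)
  P <- n - L + 1L
  lo <- rbind(pw$logodds, rep(NA_real_, L))
  best <- rep(-Inf, n_null)
  score_block <- function(mat_int) {
    for (o in seq_len(P)) {
      b <- mat_int[o:(o + L - 1L), , drop = FALSE]
      v <- lo[cbind(as.vector(b), rep(seq_len(L), n_null))]
      sc <- colSums(matrix(v, L, n_null))
      sc[is.na(sc)] <- -Inf
      best <<- pmax(best, sc)
    }
  }
  score_block(shuf)
  rc <- shuf[n:1, , drop = FALSE]
  rc[] <- ifelse(rc == 5L, 5L, 5L - rc)
  score_block(rc)
  best
}

#' Attach empirical p-values and BH q-values to motif events
#'
#' For each (variant, PWM) row the wide null window of the higher-scoring
#' ("gaining") allele is dinucleotide-shuffled `n_null` times and re-scanned;
#' the observed statistic is the best hit within the same window, and the
#' empirical p-value is `(1 + #{null best >= observed best}) / (1 + n_null)`.
#' Shuffling a window wider than the motif dilutes the motif's own
#' dinucleotide chain, which would otherwise make the null distribution
#' spuriously hot for genuine sites. Benjamini-Hochberg correction is
#' applied across all rows and rows with `q < fdr_threshold` are flagged
#' significant.
#'
#' @param events Tibble from [scan_variants()].
#' @param pwms The PWM library used for the scan (list of [pwm()] objects;
#'   matched to rows by motif id).
#' @param n_null Number of shuffled null contexts per event (>= 100).
#' @param seed Seed for the shuffles.
#' @param fdr_threshold Significance cutoff on the q-value (default 0.05).
#' @return `events` with added columns `p_empirical`, `q_value`,
#'   `significant`.
#' @export
empirical_fdr <- function(events, pwms, n_null = 1000, seed = NULL,
                          fdr_threshold = 0.05) {
  if (n_null < 100) abort("`n_null` must be at least 100.")
  if (nrow(events) == 0) {
    return(mutate(events, p_empirical = numeric(0), q_value = numeric(0),
      significant = logical(0)))
  }
  names(pwms) <- vapply(pwms, `[[`, "", "id")
  has_wide <- all(c("context_ref_wide", "context_alt_wide") %in% names(events))
  p <- with_seed_if(seed, vapply(seq_len(nrow(events)), function(i) {
    row <- events[i, ]
    use_alt <- isTRUE(row$best_alt >= row$best_ref)
    if (is.na(if (use_alt) row$best_alt else row$best_ref)) return(1)
    ctx <- if (has_wide) {
      if (use_alt) row$context_alt_wide else row$context_ref_wide
    } else {
      if (use_alt) row$context_alt else row$context_ref
    }
    pw <- pwms[[row$pwm]]
    if (is.null(pw)) {
      abort(sprintf("PWM '%s' missing from the supplied library.", row$pwm))
    }
    obs <- best_hit(encode_seq(ctx), pw)$score
    if (is.na(obs)) return(1)
    nb <- null_best_scores(ctx, pw, n_null)
    (1 + sum(nb >= obs)) / (1 + n_null)
  }, 0))
  q <- p.adjust(p, method = "BH")
  mutate(events, p_empirical = p, q_value = q,
    significant = q < fdr_threshold)
}
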