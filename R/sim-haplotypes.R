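# Synthetic haplotype-panel generator with a known truth table. The plan is
# drawn once (reference, decoy repeats, enhancer intervals, PWMs, planted
# variants with carrier patterns) and shared by all per-stage generators so
# that the end-to-end funnel has an exact expected outcome.

sample_reference <- function(n, gc) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(BASES, n, replace = TRUE, prob = probs)
}

# Sample a 1-based start for a span of `width` bases avoiding `occupied`
# (tibble start/end) by at least `margin`, optionally restricted to `within`
# intervals. Bounded retries; errors naming the last attempted position.
sample_free_start <- function(width, locus_length, occupied, margin = 25,
                              within = NULL, tries = 500) {
  last <- NA_integer_
  for (t in seq_len(tries)) {
    if (is.null(within)) {
      p <- sample.int(locus_length - width - margin, 1) + margin
    } else {
      row <- within[sample.int(nrow(within), 1), ]
      lo <- row$start + margin
      hi <- row$end - width - margin
      if (hi <= lo) next
      p <- sample(lo:hi, 1)
    }
    last <- p
    if (nrow(occupied) == 0 ||
        all(occupied$end < p - margin | occupied$start > p + width - 1 + margin)) {
      return(p)
    }
  }
  abort(sprintf("planting collision: no free span found near position %d.", last))
}

# Synthetic PWMs built around repeat-free consensus sequences.
simulate_pwms <- function(config) {
  with_seed_if(child_seed(config$seed, 5), {
    lapply(seq_len(config$n_pwms), function(k) {
      L <- config$motif_length
      cons <- character(L)
      cons[1] <- sample(BASES, 1)
      cons[2] <- sample(setdiff(BASES, cons[1]), 1)
      for (i in 3:L) {
        banned <- cons[i - 1]
        if (i >= 4 && cons[i - 1] == cons[i - 3]) banned <- c(banned, cons[i - 2])
        cons[i] <- sample(setdiff(BASES, banned), 1)
      }
      dom <- runif(L, 0.90, 0.98)
      # one invariant core position, as in most strong TF motifs
      dom[sample.int(L, 1)] <- 0.999
      m <- matrix((1 - rep(dom, each = 4)) / 3, 4, L, dimnames = list(BASES, NULL))
      m[cbind(match(cons, BASES), seq_len(L))] <- dom
      pwm(sprintf("motif_%02d", k), m)
    })
  })
}

# Draw the complete ground-truth plan for a simulation config.
plan_truth <- function(config) {
  pwms <- simulate_pwms(config)
  with_seed_if(child_seed(config$seed, 1), {
    L <- config$locus_length
    refc <- sample_reference(L, config$gc_content)
    occupied <- tibble(start = integer(), end = integer())
    occupy <- function(s, e) {
      occupied <<- bind_rows(occupied, tibble(start = s, end = e))
    }

    ## enhancer truth intervals (1-based inclusive), evenly spread
    enh <- tibble(start = integer(), end = integer())
    if (config$n_enhancers > 0) {
      width <- min(2000L, max(200L, L %/% (6 * max(1, config$n_enhancers))))
      centers <- round(seq(0.15, 0.85, length.out = config$n_enhancers) * L)
      enh <- tibble(
        enhancer = sprintf("true_enh_%d", seq_len(config$n_enhancers)),
        start = as.integer(centers - width %/% 2),
        end = as.integer(centers + width %/% 2 - 1L)
      )
    }

    ## decoy low-complexity regions written into the reference
    decoy_regions <- list()
    for (k in seq_len(config$n_decoy_lowcomplexity)) {
      if (k %% 2 == 1) {
        base <- sample(BASES, 1)
        len <- sample(6:8, 1)
        unit <- base
        kind <- "homopolymer"
        rep_seq <- rep(base, len)
      } else {
        two <- sample(BASES, 2)
        units <- sample(3:5, 1)
        len <- 2L * units
        unit <- paste(two, collapse = "")
        kind <- "dinucleotide"
        rep_seq <- rep(two, units)
      }
      p <- sample_free_start(len + 2L, L, bind_rows(occupied, enh), margin = 30)
      refc[p:(p + len - 1L)] <- rep_seq
      # break the pattern at the flanks so the repeat is maximal
      refc[p - 1L] <- sample(setdiff(BASES, c(rep_seq[1], rep_seq[2])), 1)
      refc[p + len] <- sample(setdiff(BASES, c(rep_seq[len], rep_seq[len - 1L])), 1)
      decoy_regions[[k]] <- tibble(
        start = p, end = p + len - 1L, kind = kind, unit = unit
      )
      occupy(p - 1L, p + len)
    }
    decoy_regions <- if (length(decoy_regions)) bind_rows(decoy_regions) else
      tibble(start = integer(), end = integer(), kind = character(), unit = character())

    ## motif-gain contexts: a degraded consensus embedded inside an
    ## enhancer. The variant column carries a mismatch at the motif's most
    ## informative position and the alternate allele restores it; further
    ## permanent mismatches are added at the least informative columns until
    ## the reference allele scores safely below the motif threshold, so only
    ## the alternate allele carries a match (a clean planted gain).
    motif_events <- list()
    motif_positions <- integer(0)
    # attempt to plant one gain event for PWM `pw`; on success updates refc
    # and the occupancy and returns the event row, otherwise NULL (e.g. for
    # PWMs whose consensus matches its own reverse complement too well to
    # ever keep the reference allele silent)
    try_plant_gain <- function(pw, thr_seed) {
      cons <- seq_chars(pwm_consensus(pw))
      ml <- length(cons)
      info <- apply(pw$logodds, 2, max) - apply(pw$logodds, 2, min)
      j_var <- order(info, decreasing = TRUE)[1]
      perm_order <- setdiff(order(info), j_var)
      thr <- pwm_threshold(pw, seed = thr_seed)
      mismatch_candidates <- function(j, relaxed = FALSE) {
        cand <- if (relaxed) {
          setdiff(BASES, cons[j])
        } else {
          setdiff(BASES, c(cons[j], cons[max(1, j - 1)], cons[min(ml, j + 1)]))
        }
        cand[order(pw$mat[cand, j])]
      }
      score_of <- function(chars) best_hit(match(chars, BASES), pw)$score

      # pick the permanent-mismatch columns by subset search: the summed
      # penalty must push the reference allele below (thr - 1.5) while the
      # alternate allele (penalty without the restored j_var column) stays
      # above (thr + 1.5); among feasible subsets, the smallest penalty
      # keeps the planted match as strong as possible
      s_cons <- sum(apply(pw$logodds, 2, max))
      p_lo <- s_cons - info[j_var] - (thr - 1.5)
      p_hi <- s_cons - (thr + 1.5)
      perm_cols <- NULL
      if (p_lo < 0) {
        perm_cols <- integer(0)
      } else {
        info_perm <- info[perm_order]
        for (ksub in seq_len(min(5L, length(perm_order)))) {
          cmb <- utils::combn(seq_along(perm_order), ksub)
          sums <- colSums(matrix(info_perm[cmb], nrow = ksub))
          feas <- which(sums > p_lo & sums <= p_hi)
          if (length(feas)) {
            pick <- feas[which.min(sums[feas])]
            perm_cols <- perm_order[cmb[, pick]]
            break
          }
        }
      }
      if (is.null(perm_cols)) return(NULL)
      base_embed <- cons
      base_embed[j_var] <- mismatch_candidates(j_var)[1]
      for (jp in perm_cols) base_embed[jp] <- mismatch_candidates(jp)[1]

      # place the context, jittering the mismatch base choices (late
      # attempts relax the neighbour-exclusion heuristic, and the location
      # itself is redrawn if needed) until (a) the exact scanner statistic —
      # best hit over both strands of the full variant context — keeps the
      # reference allele below and the alternate above threshold, and (b) no
      # low-complexity stretch covers the variant position, which the mask
      # stage would otherwise remove
      for (loc in seq_len(4L)) {
        ctx_start <- sample_free_start(ml + 2L, L, bind_rows(occupied),
          margin = 30, within = enh)
        vpos <- ctx_start + j_var - 1L
        for (attempt in seq_len(40L)) {
          embedded <- base_embed
          if (attempt > 1) {
            relax <- attempt > 20
            for (jp in c(j_var, perm_cols)) {
              embedded[jp] <- sample(mismatch_candidates(jp, relaxed = relax), 1)
            }
          }
          if (score_of(embedded) >= thr - 1.5) next
          alt_embed <- embedded
          alt_embed[j_var] <- cons[j_var]
          if (score_of(alt_embed) < thr + 1.5) next
          trial <- refc
          trial[ctx_start:(ctx_start + ml - 1L)] <- embedded
          trial[ctx_start - 1L] <- sample(setdiff(BASES,
            c(embedded[1], embedded[2])), 1)
          trial[ctx_start + ml] <- sample(setdiff(BASES,
            c(embedded[ml], embedded[ml - 1L])), 1)
          # scanner statistic on the placed context, including flanks
          ref_ctx <- trial[(vpos - ml + 1L):(vpos + ml - 1L)]
          alt_ctx <- ref_ctx
          alt_ctx[ml] <- cons[j_var]
          if (score_of(ref_ctx) >= thr - 1.5) next
          if (score_of(alt_ctx) < thr + 1.5) next
          win_lo <- max(1L, ctx_start - 10L)
          win_hi <- min(L, ctx_start + ml + 9L)
          local <- build_low_complexity_mask(
            paste(trial[win_lo:win_hi], collapse = ""))
          v_rel <- vpos - win_lo + 1L
          if (!any(local$start <= v_rel & local$end >= v_rel)) {
            refc <<- trial
            occupy(ctx_start - 1L, ctx_start + ml)
            return(tibble(
              pos = vpos, ref = embedded[j_var], alt = cons[j_var],
              pwm = pw$id, event = "gain"
            ))
          }
        }
      }
      NULL
    }

    for (k in seq_len(config$n_motif_gain)) {
      event <- NULL
      for (off in seq_along(pwms) - 1L) {
        idx <- (k - 1L + off) %% length(pwms) + 1L
        event <- try_plant_gain(pwms[[idx]], child_seed(config$seed, 50 + k))
        if (!is.null(event)) break
      }
      if (is.null(event)) {
        abort("could not plant a motif-gain context with any PWM in the library.")
      }
      motif_positions <- c(motif_positions, event$pos)
      motif_events[[k]] <- event
    }
    motif_events <- if (length(motif_events)) bind_rows(motif_events) else
      tibble(pos = integer(), ref = character(), alt = character(),
        pwm = character(), event = character())

    ## natural low-complexity intervals of the finished reference: planted
    ## non-decoy variants must stay clear of them
    mask <- build_low_complexity_mask(paste(refc, collapse = ""))
    avoid <- bind_rows(
      occupied,
      select(mask, "start", "end")
    )

    risk_ids <- sprintf("risk_%02d", seq_len(config$n_risk))
    nonrisk_ids <- sprintf("nonrisk_%02d", seq_len(config$n_nonrisk))

    draw_allele <- function(pos, force_snp = FALSE) {
      refbase <- refc[pos]
      if (force_snp || runif(1) < 0.7) {
        list(ref = refbase, alt = sample(setdiff(BASES, refbase), 1),
          type = "SNP")
      } else if (runif(1) < 0.5) {
        len <- sample(1:10, 1)
        list(ref = paste(refc[pos:(pos + len)], collapse = ""), alt = refbase,
          type = "deletion")
      } else {
        ins <- paste(sample(BASES, sample(1:10, 1), replace = TRUE),
          collapse = "")
        list(ref = refbase, alt = paste0(refbase, ins), type = "insertion")
      }
    }

    # canonical (left-aligned) by construction: re-check with the
    # normalization rule and resample the site on any shift
    plant_variant <- function(role, force_snp = FALSE, within = NULL) {
      for (t in seq_len(200)) {
        p <- sample_free_start(12L, L, avoid, margin = 15, within = within)
        al <- draw_allele(p, force_snp)
        norm <- normalize_variant(p, al$ref, al$alt, refc)
        if (norm$pos == p && norm$ref == al$ref && norm$alt == al$alt) {
          avoid <<- bind_rows(avoid,
            tibble(start = p - 1L, end = p + nchar(al$ref) + 1L))
          return(tibble(pos = p, ref = al$ref, alt = al$alt, type = al$type,
            role = role))
        }
      }
      abort(sprintf("planting collision at position %d after bounded retries.", p))
    }

    n_spec <- config$n_planted_specific
    n_resident <- config$n_enhancer_resident
    planted <- list()

    # enhancer-resident specific SNPs; the motif-gain sites are among them
    for (k in seq_len(n_resident)) {
      if (k <= nrow(motif_events)) {
        planted[[length(planted) + 1L]] <- tibble(
          pos = motif_events$pos[k], ref = motif_events$ref[k],
          alt = motif_events$alt[k], type = "SNP", role = "specific"
        )
      } else {
        planted[[length(planted) + 1L]] <-
          plant_variant("specific", force_snp = TRUE, within = enh)
      }
    }
    # remaining specific variants, planted outside enhancer intervals
    avoid <- bind_rows(avoid, select(enh, "start", "end"))
    for (k in seq_len(n_spec - n_resident)) {
      planted[[length(planted) + 1L]] <- plant_variant("specific")
    }
    for (k in seq_len(config$n_planted_shared)) {
      planted[[length(planted) + 1L]] <- plant_variant("shared")
    }
    planted <- bind_rows(planted)

    # decoys: risk-specific-patterned SNPs inside the decoy repeats
    if (nrow(decoy_regions) > 0) {
      dec <- lapply(seq_len(nrow(decoy_regions)), function(k) {
        p <- decoy_regions$start[k] +
          sample.int(decoy_regions$end[k] - decoy_regions$start[k] - 1L, 1)
        tibble(pos = p, ref = refc[p],
          alt = sample(setdiff(BASES, refc[p]), 1), type = "SNP",
          role = "decoy")
      })
      planted <- bind_rows(planted, bind_rows(dec))
    }

    ## carrier patterns
    n_all <- nrow(planted)
    planted$carriers <- vector("list", n_all)
    for (i in seq_len(n_all)) {
      planted$carriers[[i]] <- switch(planted$role[i],
        shared = c(
          sample(risk_ids, sample(seq_len(config$n_risk), 1)),
          sample(nonrisk_ids, sample(seq_len(config$n_nonrisk), 1))
        ),
        # specific and decoy: >= 3 risk carriers, no non-risk carrier
        sample(risk_ids, sample(3:config$n_risk, 1))
      )
    }

    ## which specific variants are common among population negatives and
    ## which sit in enhancers
    spec_idx <- which(planted$role == "specific")
    resident_idx <- spec_idx[seq_len(n_resident)]
    planted$in_enhancer <- seq_len(n_all) %in% resident_idx
    common_pool <- setdiff(spec_idx, resident_idx)
    common_idx <- if (config$n_common_negative > 0) {
      sort(sample(common_pool, config$n_common_negative))
    } else {
      integer(0)
    }
    planted$common_negative <- seq_len(n_all) %in% common_idx
    planted <- arrange(planted, .data$pos)

    structure(
      list(
        config = config,
        reference = paste(refc, collapse = ""),
        planted = planted,
        decoy_regions = decoy_regions,
        enhancers = enh,
        motif_events = motif_events,
        pwms = pwms,
        risk_ids = risk_ids,
        nonrisk_ids = nonrisk_ids
      ),
      class = "haplopin_truth"
    )
  })
}

#' @export
#' @method print haplopin_truth
print.haplopin_truth <- function(x, ...) {
  cat(sprintf(
    "<haplopin_truth> %d planted variants (%d specific, %d shared, %d decoys), %d enhancers, %d motif events\n",
    nrow(x$planted), sum(x$planted$role == "specific"),
    sum(x$planted$role == "shared"), sum(x$planted$role == "decoy"),
    nrow(x$enhancers), nrow(x$motif_events)
  ))
  invisible(x)
}

#' Generate a labeled haplotype sequence panel with known ground truth
#'
#' Draws a random reference locus and derives risk and non-risk haplotype
#' sequences from it: *specific* variants are planted on at least three risk
#' haplotypes and no non-risk haplotype, *shared* variants on at least one
#' of each class, and *decoy* variants (risk-specific-patterned) inside
#' homopolymer runs longer than 4 nt or dinucleotide repeats written into
#' the reference. Indels are 1-10 bp and left-aligned by construction. The
#' panel is returned as an aligned (gapped) multi-FASTA-ready tibble
#' together with the truth table.
#'
#' @param config A [sim_config()].
#' @param truth Optional precomputed truth plan (internal reuse); by default
#'   the plan is drawn from `config$seed`.
#' @return List with elements `panel` (tibble `id`, `label`, `sequence`,
#'   first row the reference), `labels` (member label tibble) and `truth`
#'   (a `haplopin_truth` object).
#' @export
simulate_haplotype_panel <- function(config, truth = NULL) {
  truth <- truth %||% plan_truth(config)
  refc <- seq_chars(truth$reference)
  L <- length(refc)
  member_ids <- c(truth$risk_ids, truth$nonrisk_ids)
  labels <- tibble(
    id = member_ids,
    label = rep(c("risk", "nonrisk"),
      c(length(truth$risk_ids), length(truth$nonrisk_ids)))
  )

  cells <- lapply(member_ids, function(m) refc)
  names(cells) <- member_ids
  width <- rep(1L, L)
  for (i in seq_len(nrow(truth$planted))) {
    v <- truth$planted[i, ]
    for (m in v$carriers[[1]]) {
      if (v$type %in% c("SNP", "MNP")) {
        idx <- v$pos:(v$pos + nchar(v$ref) - 1L)
        cells[[m]][idx] <- seq_chars(v$alt)
      } else if (v$type == "deletion") {
        idx <- (v$pos + 1L):(v$pos + nchar(v$ref) - 1L)
        cells[[m]][idx] <- ""
      } else {
        cells[[m]][v$pos] <- v$alt
        width[v$pos] <- max(width[v$pos], nchar(v$alt))
      }
    }
  }

  pad_row <- function(x) {
    x[x == ""] <- "-"
    wide <- which(width > 1L)
    if (length(wide)) {
      x[wide] <- stringr::str_pad(x[wide], width[wide], side = "right",
        pad = "-")
    }
    paste(x, collapse = "")
  }

  panel <- tibble(
    id = c("reference", member_ids),
    label = c("reference", labels$label),
    sequence = unname(c(pad_row(refc), vapply(cells, pad_row, "")))
  )
  list(panel = panel, labels = labels, truth = truth)
}
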