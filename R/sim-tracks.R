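#' Generate epigenetic peak tracks with known enhancer truth
#'
#' Emits four tracks on the simulated locus (BED convention, 0-based
#' half-open): H3K4me1, H3K27ac, DHS and CpG islands. Exactly the truth
#' enhancer intervals carry co-occurring H3K4me1 and H3K27ac peaks whose
#' union reproduces the truth interval; the remaining H3K4me1 peaks and a
#' few extra H3K27ac peaks are isolated. DHS peaks carry `-log10 p`,
#' `signal` and `score` fields that straddle the filtering thresholds: one
#' clear pass per enhancer, one near-miss within the rescue radius of a
#' pass peak, and one far-away near-miss that must be dropped. Each
#' enhancer overlaps an unmethylated CGI; one methylated and one partially
#' methylated CGI lie elsewhere.
#'
#' @param config A [sim_config()].
#' @param truth Optional precomputed truth plan (defaults to
#'   `plan_truth(config)`).
#' @param chrom Reference name stamped on the tracks.
#' @return List with tibbles `h3k4me1`, `h3k27ac`, `dhs`, `cgi` and the
#'   `truth` object.
#' @export
simulate_peak_tracks <- function(config, truth = NULL, chrom = "locus") {
  truth <- truth %||% plan_truth(config)
  enh <- truth$enhancers
  with_seed_if(child_seed(config$seed, 3), {
    L <- config$locus_length
    n_true <- nrow(enh)
    n_iso_me1 <- max(0L, config$n_h3k4me1 - n_true)
    n_iso_ac <- 2L

    # free slots for isolated peaks: evenly spaced, nudged off the enhancers
    # (margin keeps the far-fail DHS peak beyond the rescue radius)
    margin <- max(1600L, min(4000L, L %/% 50L))
    n_slots <- 2L * (n_iso_me1 + n_iso_ac + 2L)
    slots <- round(seq(0.04, 0.96, length.out = max(n_slots, 2)) * L)
    if (n_true > 0) {
      near_enh <- vapply(slots, function(s) {
        any(s > enh$start - margin & s < enh$end + margin)
      }, TRUE)
      slots <- slots[!near_enh]
    }
    if (length(slots) < n_iso_me1 + n_iso_ac) {
      abort("locus too small to place isolated peaks away from enhancers.")
    }
    slots <- sample(slots)
    spacing <- if (length(slots) > 1) min(diff(sort(slots))) else L
    iso_max <- max(60L, min(1500L, floor(spacing * 0.35)))
    iso_off <- min(100L, iso_max %/% 4L)

    peak <- function(chrom, start, end, name, score = 500, signal = NA,
                     neglog10p = NA) {
      tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
        name = name, score = score, strand = ".", signal = signal,
        neglog10p = neglog10p, qvalue = -1, peak = as.integer((end - start) %/% 2))
    }

    me1 <- list()
    ac <- list()
    dhs <- list()
    cgi <- list()

    if (n_true > 0) {
      for (i in seq_len(n_true)) {
        s0 <- enh$start[i] - 1L # truth is 1-based inclusive; tracks are BED
        e0 <- enh$end[i]
        w <- e0 - s0
        cut <- max(1L, round(w * 0.3))
        me1[[i]] <- peak(chrom, s0, e0 - cut, sprintf("me1_true_%d", i))
        ac[[i]] <- peak(chrom, s0 + cut, e0, sprintf("ac_true_%d", i))
        dhs[[length(dhs) + 1L]] <- peak(
          chrom, s0 + w %/% 3, e0 - w %/% 3, sprintf("dhs_pass_%d", i),
          score = round(runif(1, 125, 200)),
          signal = runif(1, 35, 60), neglog10p = runif(1, 55, 90)
        )
        # near-miss rescued by proximity (< 1 kb from the pass peak)
        dhs[[length(dhs) + 1L]] <- peak(
          chrom, e0 + 200L, e0 + 500L, sprintf("dhs_rescue_%d", i),
          score = round(runif(1, 125, 200)),
          signal = runif(1, 35, 60), neglog10p = runif(1, 30, 45)
        )
        cgi[[length(cgi) + 1L]] <- tibble(
          chrom = chrom, start = s0 + w %/% 4, end = e0 - w %/% 4,
          name = sprintf("cgi_enh_%d", i), score = 0L, strand = ".",
          methylation = "unmethylated"
        )
      }
    }
    for (k in seq_len(n_iso_me1)) {
      s0 <- slots[k]
      me1[[n_true + k]] <- peak(chrom, s0,
        s0 + round(runif(1, iso_max * 0.6, iso_max)), sprintf("me1_iso_%d", k))
    }
    for (k in seq_len(n_iso_ac)) {
      s0 <- slots[n_iso_me1 + k]
      ac[[n_true + k]] <- peak(chrom, s0 + iso_off,
        s0 + iso_off + round(runif(1, iso_max * 0.4, iso_max * 0.8)),
        sprintf("ac_iso_%d", k))
      if (k == 1) {
        # a methylated CGI far from any enhancer
        cgi[[length(cgi) + 1L]] <- tibble(
          chrom = chrom, start = s0 + 150L, end = s0 + 450L,
          name = "cgi_methylated", score = 0L, strand = ".",
          methylation = "methylated"
        )
      }
      if (k == 2) {
        cgi[[length(cgi) + 1L]] <- tibble(
          chrom = chrom, start = s0 + 150L, end = s0 + 450L,
          name = "cgi_partial", score = 0L, strand = ".",
          methylation = "partial"
        )
      }
    }
    # a near-miss DHS peak too far from any pass peak: must be dropped
    if (length(slots) > n_iso_me1 + n_iso_ac) {
      s0 <- slots[n_iso_me1 + n_iso_ac + 1L]
      dhs[[length(dhs) + 1L]] <- peak(
        chrom, s0, s0 + 300L, "dhs_far_fail",
        score = round(runif(1, 125, 200)),
        signal = runif(1, 35, 60), neglog10p = runif(1, 30, 45)
      )
    }

    sort_track <- function(x) {
      if (length(x) == 0) {
        return(tibble(chrom = character(), start = integer(),
          end = integer(), name = character(), score = numeric(),
          strand = character(), signal = numeric(), neglog10p = numeric(),
          qvalue = numeric(), peak = integer()))
      }
      arrange(bind_rows(x), .data$start)
    }
    list(
      h3k4me1 = sort_track(me1),
      h3k27ac = sort_track(ac),
      dhs = sort_track(dhs),
      cgi = if (length(cgi)) arrange(bind_rows(cgi), .data$start) else
        tibble(chrom = character(), start = integer(), end = integer(),
          name = character(), score = integer(), strand = character(),
          methylation = character()),
      truth = truth
    )
  })
}

#' Generate a population panel with tag-SNP classes and candidate genotypes
#'
#' Emits (i) a total tag-rule table mapping joint genotypes at two tag SNPs
#' to carrier classes, (ii) per-individual tag genotypes consistent with the
#' truth classes, and (iii) dosages of every planted specific variant in the
#' population: variants flagged `common_negative` in the truth are carried
#' by `max_negative_carriers + 2` negative-class individuals, all others by
#' at most two.
#'
#' @param config A [sim_config()].
#' @param truth Truth plan from [plan_truth()] /
#'   [simulate_haplotype_panel()].
#' @param max_negative_carriers The exclusion threshold the panel is built
#'   around (default 10).
#' @return List with `rules`, `tag_genotypes`, `classes` (truth classes),
#'   and `genotypes` (wide tibble: `marker`, `pos`, `ref`, `alt` + one
#'   dosage column per individual).
#' @export
simulate_population_panel <- function(config, truth,
                                      max_negative_carriers = 10) {
  with_seed_if(child_seed(config$seed, 4), {
    n_r <- config$n_pop_risk
    n_c <- config$n_pop_confounder
    n_n <- config$n_pop_negative
    ids <- sprintf("P%03d", seq_len(n_r + n_c + n_n))
    classes <- tibble(
      individual = ids,
      class = rep(c("RISK_POS", "CONFOUNDER_POS", "NEGATIVE"), c(n_r, n_c, n_n))
    )

    rules <- tidyr::expand_grid(g_tag1 = 0:2, g_tag2 = 0:2)
    rules$class <- ifelse(rules$g_tag2 > 0, "CONFOUNDER_POS",
      ifelse(rules$g_tag1 > 0, "RISK_POS", "NEGATIVE"))

    tag_genotypes <- tibble(
      individual = ids,
      g_tag1 = c(sample(1:2, n_r, replace = TRUE), rep(0L, n_c), rep(0L, n_n)),
      g_tag2 = c(rep(0L, n_r), sample(1:2, n_c, replace = TRUE), rep(0L, n_n))
    )

    spec <- filter(truth$planted, .data$role == "specific")
    n_common_carriers <- max_negative_carriers + 2L
    if (n_common_carriers > n_n) {
      abort("not enough negative individuals to make a variant common.")
    }
    neg_ids <- classes$individual[classes$class == "NEGATIVE"]
    risk_ids <- classes$individual[classes$class == "RISK_POS"]
    dos <- matrix(0L, nrow(spec), length(ids),
      dimnames = list(NULL, ids))
    for (i in seq_len(nrow(spec))) {
      dos[i, risk_ids] <- 1L # risk-haplotype carriers harbour the variant
      carriers <- if (spec$common_negative[i]) {
        sample(neg_ids, n_common_carriers)
      } else {
        sample(neg_ids, sample(0:2, 1))
      }
      dos[i, carriers] <- sample(1:2, length(carriers), replace = TRUE)
    }
    genotypes <- bind_cols(
      tibble(marker = sprintf("cand_%03d", seq_len(nrow(spec))),
        pos = spec$pos, ref = spec$ref, alt = spec$alt),
      as_tibble(as.data.frame(dos), .name_repair = "minimal")
    )
    list(rules = rules, tag_genotypes = tag_genotypes, classes = classes,
      genotypes = genotypes)
  })
}
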