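# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (enumeration, grids, O(n*m) scans) and never call the
# code paths they check.

small_config <- function(seed = 1, ...) {
  sim_config(
    locus_length = 30000, n_individuals = 100, n_markers = 60,
    genotype_region_length = 30000, seed = seed, ...
  )
}

# Observed-data log-likelihood of a 3x3 genotype table (rows: dosage 0..2 at
# marker A, cols: dosage 0..2 at marker B) under haplotype frequencies
# f = (AB, Ab, aB, ab). Written independently of the package's internals.
oracle_loglik <- function(tab, f) {
  pAB <- f[1]; pAb <- f[2]; paB <- f[3]; pab <- f[4]
  pr <- matrix(c(
    pab^2,       2 * paB * pab,            paB^2,
    2 * pAb * pab, 2 * pAB * pab + 2 * pAb * paB, 2 * pAB * paB,
    pAb^2,       2 * pAB * pAb,            pAB^2
  ), nrow = 3, byrow = TRUE)
  if (any(pr[tab > 0] <= 0)) return(-Inf)
  sum(tab[tab > 0] * log(pr[tab > 0]))
}

# Maximum-likelihood haplotype frequencies by (i) enumerating every phase
# assignment of the double heterozygotes and (ii) profiling the likelihood
# over D on a fine grid at the observed allele margins (the margins are
# attained at the MLE). Ties resolve toward the coupling phase, the same
# documented convention as the estimator under test.
oracle_ml_freqs <- function(tab) {
  n <- sum(tab)
  base <- c(
    2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
    2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
    2 * tab[1, 3] + tab[2, 3] + tab[1, 2],
    2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  )
  dh <- tab[2, 2]
  best_f <- NULL
  best_ll <- -Inf
  for (k in dh:0) { # coupling-heavy assignments first (tie-break)
    f <- (base + c(k, dh - k, dh - k, k)) / (2 * n)
    ll <- oracle_loglik(tab, f)
    if (ll > best_ll + 1e-12) {
      best_ll <- ll
      best_f <- f
    }
  }
  p <- (base[1] + base[2] + dh) / (2 * n)
  q <- (base[1] + base[3] + dh) / (2 * n)
  d_lo <- -min(p * q, (1 - p) * (1 - q))
  d_hi <- min(p * (1 - q), (1 - p) * q)
  if (d_hi > d_lo) {
    tv <- as.vector(t(tab)) # row-major: cell (i, j) -> pr index (i-1)*3+j
    profile_ll <- function(d) {
      fAB <- pmax(p * q + d, 0)
      fAb <- pmax(p * (1 - q) - d, 0)
      faB <- pmax((1 - p) * q - d, 0)
      fab <- pmax((1 - p) * (1 - q) + d, 0)
      pr <- list(
        fab^2, 2 * faB * fab, faB^2,
        2 * fAb * fab, 2 * fAB * fab + 2 * fAb * faB, 2 * fAB * faB,
        fAb^2, 2 * fAB * fAb, fAB^2
      )
      ll <- 0
      for (cell in which(tv > 0)) ll <- ll + tv[cell] * log(pr[[cell]])
      ll
    }
    d <- seq(d_hi, d_lo, length.out = 4001) # coupling end first
    ll <- profile_ll(d)
    m <- max(ll)
    if (is.finite(m)) {
      # candidate optima: the raw argmax plus, for flip-symmetric tables
      # whose mirrored maxima tie, the coupling-side near-tie (the
      # documented convention); each is refined locally because flat
      # likelihoods leave the coarse grid optimum ~1e-3 off
      near <- ll >= m - 1e-5
      first_near <- which(near)[1]
      # contiguous near-maximum plateau on the coupling side: refining over
      # the whole run is required because flat likelihoods spread the
      # plateau over many coarse-grid steps
      run_end <- first_near
      while (run_end < length(d) && near[run_end + 1L]) run_end <- run_end + 1L
      windows <- list(
        c(d[max(1L, first_near - 1L)], d[min(length(d), run_end + 1L)]),
        c(d[max(1L, which.max(ll) - 3L)], d[min(length(d), which.max(ll) + 3L)])
      )
      refined_d <- NA_real_
      refined_ll <- -Inf
      for (w in windows) {
        dr <- seq(max(w), min(w), length.out = 3001)
        llr <- profile_ll(dr)
        kr <- which(llr >= max(llr) - 1e-10)[1]
        better <- llr[kr] > refined_ll + 1e-9 ||
          (abs(llr[kr] - refined_ll) <= 1e-9 && dr[kr] > refined_d)
        if (better) {
          refined_ll <- llr[kr]
          refined_d <- dr[kr]
        }
      }
      if (refined_ll > best_ll + 1e-12) {
        best_ll <- refined_ll
        dd <- refined_d
        best_f <- pmax(c(p * q + dd, p * (1 - q) - dd, (1 - p) * q - dd,
          (1 - p) * (1 - q) + dd), 0)
      }
    }
  }
  list(f = best_f, loglik = best_ll)
}

# Brute-force maximization of the all-double-heterozygote likelihood over a
# hierarchically refined simplex grid (coarse pass then 0.001 refinement).
# The first coordinate (coupling haplotype AB) is scanned from high to low so
# exact likelihood ties resolve toward coupling, the convention the
# estimator documents.
oracle_grid_freqs <- function(tab, step = 0.001) {
  best <- c(0.25, 0.25, 0.25, 0.25)
  best_ll <- oracle_loglik(tab, best)
  refine <- function(center, width, step) {
    s1 <- rev(seq(max(0, center[1] - width), min(1, center[1] + width), by = step))
    s2 <- seq(max(0, center[2] - width), min(1, center[2] + width), by = step)
    s3 <- seq(max(0, center[3] - width), min(1, center[3] + width), by = step)
    for (f1 in s1) for (f2 in s2) for (f3 in s3) {
      f4 <- 1 - f1 - f2 - f3
      if (f4 < 0 || f4 > 1) next
      ll <- oracle_loglik(tab, c(f1, f2, f3, f4))
      if (ll > best_ll + 1e-12) {
        best_ll <<- ll
        best <<- c(f1, f2, f3, f4)
      }
    }
  }
  refine(c(0.5, 0.5, 0.5), 0.5, 0.02)
  refine(best, 0.03, step)
  list(f = best, loglik = best_ll)
}

# Direct evaluation of the risk-specificity predicate on one presence
# pattern (logical vectors over risk / non-risk members).
oracle_risk_specific <- function(risk_present, nonrisk_present,
                                 min_risk = 3, max_nonrisk = 0) {
  sum(risk_present) >= min_risk && sum(nonrisk_present) <= max_nonrisk
}

# Naive O(n*m) containment/overlap scan of variants against enhancer
# intervals (0-based half-open), mirroring the documented span semantics.
oracle_intersect <- function(candidates, enhancers) {
  act <- enhancers[enhancers$active, ]
  vapply(seq_len(nrow(candidates)), function(i) {
    span_start <- candidates$pos[i]
    span_end <- candidates$pos[i] + nchar(candidates$ref[i]) - 1L
    if (candidates$type[i] == "insertion") span_end <- candidates$pos[i] + 1L
    hits <- character(0)
    for (j in seq_len(nrow(act))) {
      if (act$chrom[j] != candidates$chrom[i]) next
      # overlap of 1-based [span_start, span_end] with 0-based [start, end)
      if (span_start <= act$end[j] && span_end >= act$start[j] + 1L) {
        hits <- c(hits, act$enhancer_id[j])
      }
    }
    if (length(hits)) paste(hits, collapse = ",") else NA_character_
  }, "")
}

# Dinucleotide count table of a sequence string.
dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}

random_reference <- function(n, seed) {
  withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

uniform_pwm <- function(L = 6) {
  pwm("uniform", matrix(0.25, 4, L))
}

strong_pwm <- function(cons = "TGACGTCA", id = "strong", dom = 0.94) {
  L <- nchar(cons)
  idx <- match(strsplit(cons, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix((1 - dom) / 3, 4, L)
  m[cbind(idx, seq_len(L))] <- dom
  pwm(id, m)
}
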