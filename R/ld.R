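#' Minor allele frequency of a marker
#'
#' @param geno A genotype tibble in wide form: one row per marker with
#'   metadata columns `marker`, `pos` (plus optionally `ref`, `alt`) and one
#'   integer column per individual holding the diploid alternate-allele
#'   dosage (0, 1, 2 or `NA` for missing).
#' @param marker Marker identifier.
#' @return The minor allele frequency, `min(p, 1 - p)` over non-missing
#'   alleles, in \[0, 0.5\].
#' @export
compute_maf <- function(geno, marker) {
  i <- match(marker, geno$marker)
  if (is.na(i)) abort(sprintf("marker '%s' not found.", marker))
  d <- geno_dosages(geno)[i, ]
  d <- d[!is.na(d)]
  if (length(d) == 0) abort(sprintf("marker '%s' has no non-missing calls.", marker))
  p <- sum(d) / (2 * length(d))
  min(p, 1 - p)
}

# Extract the individuals-as-columns dosage matrix from a wide genotype
# tibble (markers x individuals).
geno_dosages <- function(geno) {
  meta <- intersect(c("marker", "pos", "ref", "alt", "chrom", "block"), names(geno))
  m <- as.matrix(geno[setdiff(names(geno), meta)])
  storage.mode(m) <- "integer"
  bad <- !(m %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad, na.rm = TRUE)) abort("dosages must be 0, 1, 2 or NA.")
  m
}

#' Filter markers by MAF and thin to a random subset
#'
#' Mirrors the common locus-refinement preprocessing: markers with minor
#' allele frequency strictly greater than `maf_min` are eligible, and
#' `n_keep` of them are drawn uniformly without replacement. Position order
#' is preserved.
#'
#' @inheritParams compute_maf
#' @param maf_min MAF cutoff; markers with MAF `> maf_min` (strict) pass.
#' @param n_keep Number of markers to retain after thinning; `NULL` keeps all
#'   passing markers.
#' @param seed Seed for the random draw.
#' @return The thinned genotype tibble.
#' @export
filter_and_thin <- function(geno, maf_min = 0.1, n_keep = NULL, seed = NULL) {
  d <- geno_dosages(geno)
  nn <- rowSums(!is.na(d))
  if (any(nn == 0)) abort("all-missing marker encountered during MAF filtering.")
  p <- rowSums(d, na.rm = TRUE) / (2 * nn)
  maf <- pmin(p, 1 - p)
  pass <- which(maf > maf_min)
  if (is.null(n_keep)) n_keep <- length(pass)
  if (n_keep > length(pass)) {
    abort(sprintf(
      "`n_keep` = %d exceeds the %d markers passing MAF > %g.",
      n_keep, length(pass), maf_min
    ))
  }
  keep <- with_seed_if(seed, sort(sample(pass, n_keep)))
  geno[keep, ]
}

#' EM estimate of two-locus haplotype frequencies from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies for two biallelic markers under
#' Hardy-Weinberg equilibrium, with the phase of double heterozygotes
#' resolved by expectation-maximization. The observed-data log-likelihood is
#' non-decreasing across iterations (exposed via the `loglik` attribute).
#' To avoid the symmetric saddle point of the linkage-equilibrium start, the
#' EM is run from three deterministic initializations (near-coupling,
#' near-repulsion and linkage equilibrium) and the highest-likelihood fixed
#' point is returned; exact likelihood ties resolve to the coupling phase.
#'
#' @param a,b Integer dosage vectors (0/1/2, `NA` missing) over the same
#'   individuals. Pairwise-complete observations are used.
#' @param tol Convergence threshold on the maximum absolute frequency change
#'   per iteration.
#' @param max_iter Iteration cap.
#' @return Named numeric vector `c(AB, Ab, aB, ab)` of haplotype frequencies
#'   (uppercase = alternate allele at the first/second marker), with
#'   attributes `loglik` (per-iteration trajectory of the selected run),
#'   `iterations` and `converged`.
#' @export
em_haplotype_freqs <- function(a, b, tol = 1e-8, max_iter = 1000) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) abort("need at least 2 individuals with both markers non-missing.")
  counts <- table(factor(a[ok], 0:2), factor(b[ok], 0:2))
  em_from_counts(matrix(as.numeric(counts), 3, 3), tol = tol, max_iter = max_iter)
}

# EM on a 3x3 genotype count table: counts[i, j] = # individuals with dosage
# i-1 at the first marker and j-1 at the second.
em_from_counts <- function(counts, tol = 1e-8, max_iter = 1000) {
  n <- sum(counts)
  # unambiguous gamete contributions (AB, Ab, aB, ab) from the 8 phased cells
  base <- c(
    AB = 2 * counts[3, 3] + counts[3, 2] + counts[2, 3],
    Ab = 2 * counts[3, 1] + counts[3, 2] + counts[2, 1],
    aB = 2 * counts[1, 3] + counts[2, 3] + counts[1, 2],
    ab = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1]
  )
  dh <- counts[2, 2] # double heterozygotes: AB/ab or Ab/aB
  p <- (base[["AB"]] + base[["Ab"]] + dh) / (2 * n)
  q <- (base[["AB"]] + base[["aB"]] + dh) / (2 * n)
  le <- c(p * q, p * (1 - q), (1 - p) * q, (1 - p) * (1 - q))
  dmax_c <- min(p * (1 - q), (1 - p) * q)
  dmax_r <- min(p * q, (1 - p) * (1 - q))
  starts <- list(
    coupling = le + 0.9 * dmax_c * c(1, -1, -1, 1),
    repulsion = le - 0.9 * dmax_r * c(1, -1, -1, 1),
    le = le
  )

  run_em <- function(f) {
    f <- pmax(f, 0)
    f <- f / sum(f)
    ll <- loglik_counts(counts, f)
    trace <- ll
    iter <- 0L
    converged <- FALSE
    while (iter < max_iter) {
      iter <- iter + 1L
      denom <- f[1] * f[4] + f[2] * f[3]
      w <- if (dh > 0 && denom > 0) f[1] * f[4] / denom else 0.5
      newf <- (base + dh * c(w, 1 - w, 1 - w, w)) / (2 * n)
      delta <- max(abs(newf - f))
      f <- newf
      trace <- c(trace, loglik_counts(counts, f))
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    list(f = f, trace = trace, iter = iter, converged = converged)
  }

  fits <- lapply(starts, run_em)
  lls <- vapply(fits, function(z) tail(z$trace, 1), 0)
  best <- fits[[which.max(lls + c(1e-12, 0, 0))]] # coupling wins exact ties
  structure(
    setNames(best$f, c("AB", "Ab", "aB", "ab")),
    loglik = best$trace, iterations = best$iter, converged = best$converged
  )
}

# Observed-data log-likelihood of a 3x3 genotype count table given haplotype
# frequencies f = (AB, Ab, aB, ab).
loglik_counts <- function(counts, f) {
  pr <- matrix(0, 3, 3)
  pr[1, 1] <- f[4]^2
  pr[1, 2] <- 2 * f[3] * f[4]
  pr[1, 3] <- f[3]^2
  pr[2, 1] <- 2 * f[2] * f[4]
  pr[2, 2] <- 2 * f[1] * f[4] + 2 * f[2] * f[3]
  pr[2, 3] <- 2 * f[1] * f[3]
  pr[3, 1] <- f[2]^2
  pr[3, 2] <- 2 * f[1] * f[2]
  pr[3, 3] <- f[1]^2
  nz <- counts > 0
  if (any(pr[nz] <= 0)) return(-Inf)
  sum(counts[nz] * log(pr[nz]))
}

#' Normalized linkage disequilibrium D' from haplotype frequencies
#'
#' `D = f(AB) - p q` with `p`, `q` the alternate-allele frequencies;
#' `Dmax = min(p (1 - q), (1 - p) q)` when `D > 0` and
#' `min(p q, (1 - p)(1 - q))` when `D < 0`. Returns `|D| / Dmax`, clipped to
#' \[0, 1\]; `D = 0` returns 0. Undefined (error) when either locus is
#' monomorphic.
#'
#' @param freqs Numeric 4-vector of haplotype frequencies `(AB, Ab, aB, ab)`
#'   summing to 1.
#' @return `|D'|` in \[0, 1\].
#' @export
#' @examples
#' dprime(c(0.4, 0.1, 0.1, 0.4)) # 0.6
dprime <- function(freqs) {
  if (length(freqs) != 4 || any(freqs < -1e-9) || abs(sum(freqs) - 1) > 1e-6) {
    abort("`freqs` must be 4 non-negative frequencies summing to 1.")
  }
  p <- freqs[1] + freqs[2]
  q <- freqs[1] + freqs[3]
  eps <- 1e-12
  if (p < eps || p > 1 - eps || q < eps || q > 1 - eps) {
    abort("D' is undefined at a monomorphic locus.")
  }
  D <- freqs[1] - p * q
  if (abs(D) < eps) return(0)
  dmax <- if (D > 0) min(p * (1 - q), (1 - p) * q) else min(p * q, (1 - p) * (1 - q))
  unname(min(1, abs(D) / dmax))
}

#' Pairwise |D'| matrix for a genotype panel
#'
#' Estimates two-locus haplotype frequencies for every marker pair by EM
#' (pairwise-complete individuals) and derives `|D'|`. Markers that are
#' monomorphic among non-missing calls are rejected.
#'
#' @inheritParams compute_maf
#' @return An object of class `haplopin_ld`: a list with `markers` (tibble of
#'   `marker`, `pos`), `dprime` (symmetric matrix, unit diagonal) and `freqs`
#'   (4 x m x m array of haplotype frequencies).
#' @export
ld_matrix <- function(geno) {
  d <- geno_dosages(geno)
  m <- nrow(d)
  if (m < 2) abort("need at least two markers.")
  p <- rowSums(d, na.rm = TRUE) / (2 * rowSums(!is.na(d)))
  mono <- which(p == 0 | p == 1 | is.na(p))
  if (length(mono)) {
    abort(sprintf("monomorphic marker(s) in panel: %s",
      paste(geno$marker[mono], collapse = ", ")))
  }
  # 3x3 pair tables for all pairs at once via indicator cross-products
  ind <- lapply(0:2, function(g) {
    x <- t(d == g)
    x[is.na(x)] <- FALSE
    storage.mode(x) <- "double"
    x
  })
  tabs <- array(0, c(3, 3, m, m))
  for (i in 1:3) {
    for (j in 1:3) {
      tabs[i, j, , ] <- crossprod(ind[[i]], ind[[j]])
    }
  }
  dp <- matrix(1, m, m)
  fr <- array(NA_real_, c(4, m, m))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      f <- em_from_counts(tabs[, , i, j])
      fr[, i, j] <- fr[, j, i] <- f
      dp[i, j] <- dp[j, i] <- dprime(f)
    }
  }
  structure(
    list(
      markers = tibble(marker = geno$marker, pos = geno$pos),
      dprime = dp,
      freqs = fr
    ),
    class = "haplopin_ld"
  )
}

#' @export
#' @method print haplopin_ld
print.haplopin_ld <- function(x, ...) {
  off <- x$dprime[upper.tri(x$dprime)]
  cat(sprintf(
    "<haplopin_ld> %d markers spanning %d bp; mean off-diagonal |D'| = %.3f\n",
    nrow(x$markers), diff(range(x$markers$pos)), mean(off)
  ))
  invisible(x)
}

#' @describeIn ld_matrix Long tibble of pairwise `|D'|` values.
#' @param x A `haplopin_ld` object.
#' @param ... Unused.
#' @export
tidy.haplopin_ld <- function(x, ...) {
  m <- nrow(x$markers)
  pairs <- which(upper.tri(x$dprime), arr.ind = TRUE)
  tibble(
    marker_a = x$markers$marker[pairs[, 1]],
    marker_b = x$markers$marker[pairs[, 2]],
    pos_a = x$markers$pos[pairs[, 1]],
    pos_b = x$markers$pos[pairs[, 2]],
    dprime = x$dprime[pairs]
  )
}

#' @describeIn ld_matrix Heatmap of the pairwise `|D'|` matrix.
#' @param object A `haplopin_ld` object.
#' @export
autoplot.haplopin_ld <- function(object, ...) {
  long <- tidyr::expand_grid(
    i = seq_len(nrow(object$markers)),
    j = seq_len(nrow(object$markers))
  )
  long$dprime <- object$dprime[cbind(long$i, long$j)]
  ggplot2::ggplot(long, ggplot2::aes(.data$i, .data$j, fill = .data$dprime)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(
      low = "white", high = "firebrick", limits = c(0, 1), name = "|D'|"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "marker index", y = "marker index") +
    ggplot2::theme_minimal()
}

#' Delineate the LD-conservation block containing an anchor interval
#'
#' Starting from the markers inside the anchor interval, the window is grown
#' outward one marker at a time (right, then left, repeating) as long as the
#' fraction of within-window marker pairs with `|D'| >= dprime_threshold`
#' stays at or above `min_fraction`. The maximal such window is reported as
#' the span from its first to its last marker position.
#'
#' @param ld A `haplopin_ld` object from [ld_matrix()].
#' @param anchor Length-2 numeric: the anchor interval (1-based, inclusive)
#'   that the block must contain, e.g. the footprint of the candidate gene.
#' @param dprime_threshold Pairwise `|D'|` value counted as "conserved".
#' @param min_fraction Minimum fraction of conserved pairs in the window.
#' @return A one-row tibble: `start`, `end`, `n_markers`, `mean_dprime`,
#'   `conserved_fraction`.
#' @export
find_conserved_block <- function(ld, anchor, dprime_threshold = 0.8,
                                 min_fraction = 0.9) {
  pos <- ld$markers$pos
  inside <- which(pos >= anchor[1] & pos <= anchor[2])
  if (length(inside) == 0) abort("no marker lies inside the anchor interval.")
  lo <- min(inside)
  hi <- max(inside)
  frac <- function(idx) {
    if (length(idx) < 2) return(1)
    v <- ld$dprime[idx, idx][upper.tri(diag(length(idx)))]
    mean(v >= dprime_threshold)
  }
  repeat {
    grew <- FALSE
    if (hi < length(pos) && frac(lo:(hi + 1)) >= min_fraction) {
      hi <- hi + 1L
      grew <- TRUE
    }
    if (lo > 1 && frac((lo - 1):hi) >= min_fraction) {
      lo <- lo - 1L
      grew <- TRUE
    }
    if (!grew) break
  }
  idx <- lo:hi
  v <- if (length(idx) > 1) ld$dprime[idx, idx][upper.tri(diag(length(idx)))] else 1
  tibble(
    start = pos[lo], end = pos[hi], n_markers = length(idx),
    mean_dprime = mean(v),
    conserved_fraction = mean(v >= dprime_threshold)
  )
}
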