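#' Generate an unphased genotype panel with block-structured LD
#'
#' Markers are placed uniformly over a genotype region carved into declared
#' LD blocks. Within each block, individuals draw two haplotypes from a
#' small pool of founder haplotypes (which guarantees strong within-block
#' D' without a coalescent simulator); draws are independent across blocks,
#' so between-block D' is near zero. The within-block `dprime` target is
#' approached by introducing founder-switch (recombinant) haplotypes at rate
#' `2 * (1 - dprime)`. Target minor allele frequencies are drawn uniformly
#' from `config$maf_range` and realized as the closest achievable founder
#' combination. A `missing_rate` fraction of calls is set to `NA`.
#'
#' @param config A [sim_config()].
#' @param n_founders Founder haplotypes per block pool.
#' @return A wide genotype tibble: columns `marker`, `pos`, `block`, then one
#'   dosage column per individual.
#' @export
simulate_genotype_panel <- function(config, n_founders = 8) {
  blocks <- config$ld_block_spec
  with_seed_if(child_seed(config$seed, 2), {
    m <- config$n_markers
    n <- config$n_individuals
    pos <- sort(sample.int(config$genotype_region_length, m))
    block_of <- rep(NA_integer_, m)
    for (b in seq_len(nrow(blocks))) {
      inb <- pos >= blocks$start[b] & pos <= blocks$end[b]
      block_of[inb] <- b
    }

    dos <- matrix(0L, m, n)
    for (b in seq_len(nrow(blocks))) {
      idx <- which(block_of == b)
      mb <- length(idx)
      if (mb == 0) next
      w <- runif(n_founders, 0.5, 1.5)
      w <- w / sum(w)
      # derived alleles are carried by clades of a random founder genealogy
      # (laminar subsets, as under infinite sites): this keeps every marker
      # pair free of four-gamete violations, so within-block |D'| is 1 by
      # construction before recombination
      clusters <- as.list(seq_len(n_founders))
      clades <- as.list(seq_len(n_founders))
      while (length(clusters) > 2) {
        pick <- sample.int(length(clusters), 2)
        merged <- c(clusters[[pick[1]]], clusters[[pick[2]]])
        clusters <- c(clusters[-pick], list(merged))
        clades[[length(clades) + 1L]] <- merged
      }
      clade_freq <- vapply(clades, function(s) sum(w[s]), 0)
      hap <- matrix(0L, n_founders, mb)
      for (j in seq_len(mb)) {
        target <- runif(1, config$maf_range[1], config$maf_range[2])
        # the allele label may be flipped to hit the target MAF; |D'| is
        # invariant under relabeling
        d_direct <- abs(clade_freq - target)
        d_flip <- abs(1 - clade_freq - target)
        k <- which.min(pmin(d_direct, d_flip))
        carrier <- clades[[k]]
        if (d_flip[k] < d_direct[k]) carrier <- setdiff(seq_len(n_founders), carrier)
        hap[carrier, j] <- 1L
      }
      r <- min(0.9, 2 * (1 - blocks$dprime[b]))
      draw_haplotypes <- function(n_hap) {
        f <- sample.int(n_founders, n_hap, replace = TRUE, prob = w)
        al <- hap[f, , drop = FALSE]
        if (r > 0 && mb > 1) {
          rec <- which(runif(n_hap) < r)
          for (h in rec) {
            f2 <- sample.int(n_founders, 1, prob = w)
            s <- sample.int(mb - 1L, 1)
            al[h, (s + 1L):mb] <- hap[f2, (s + 1L):mb]
          }
        }
        al
      }
      dos[idx, ] <- t(draw_haplotypes(n) + draw_haplotypes(n))
    }
    # markers falling outside every declared block segregate independently
    out_idx <- which(is.na(block_of))
    for (j in out_idx) {
      p <- runif(1, config$maf_range[1], config$maf_range[2])
      dos[j, ] <- rbinom(n, 2, p)
    }

    if (config$missing_rate > 0) {
      miss <- runif(length(dos)) < config$missing_rate
      dos[miss] <- NA_integer_
    }

    out <- tibble(
      marker = sprintf("m%04d", seq_len(m)),
      pos = pos,
      block = block_of
    )
    geno <- as_tibble(as.data.frame(dos), .name_repair = "minimal")
    names(geno) <- sprintf("I%04d", seq_len(n))
    dplyr::bind_cols(out, geno)
  })
}
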