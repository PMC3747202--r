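dhs_track <- function(...) {
  rows <- list(...)
  tibble::tibble(
    chrom = "locus",
    start = vapply(rows, `[[`, 0, 1),
    end = vapply(rows, `[[`, 0, 2),
    name = sprintf("p%d", seq_along(rows)),
    neglog10p = vapply(rows, `[[`, 0, 3),
    signal = vapply(rows, `[[`, 0, 4),
    score = vapply(rows, `[[`, 0, 5)
  )
}

test_that("DHS filtering applies strict thresholds with proximity rescue", {
  # pass peak, boundary-pass peak, near-miss within 1 kb, near-miss beyond
  trk <- dhs_track(
    c(1000, 1500, 60, 40, 130),   # clear pass
    c(2400, 2600, 51, 31, 121),   # all three strictly above: pass
    c(3100, 3200, 49, 31, 121),   # fails p; 500 bp from pass peak: rescued
    c(9000, 9100, 49, 40, 130),   # fails p; far from any pass: dropped
    c(5000, 5100, 50, 40, 130)    # -log10 p exactly 50 is NOT > 50
  )
  out <- filter_dhs(trk)
  expect_setequal(out$name, c("p1", "p2", "p3"))
  expect_equal(out$status[out$name == "p2"], "pass")
  expect_equal(out$status[out$name == "p3"], "rescued")

  # rescue radius is strict: exactly 1000 bp away is not rescued
  trk2 <- dhs_track(
    c(1000, 1500, 60, 40, 130),
    c(2500, 2600, 49, 40, 130)
  )
  expect_equal(filter_dhs(trk2)$name, "p1")
  trk2$start[2] <- 2499
  expect_setequal(filter_dhs(trk2)$name, c("p1", "p2"))

  # without any pass-1 peak nothing is rescued
  trk3 <- dhs_track(c(1000, 1500, 49, 40, 130), c(1600, 1700, 48, 40, 130))
  expect_equal(nrow(filter_dhs(trk3)), 0)

  expect_error(filter_dhs(trk[, setdiff(names(trk), "signal")]), "missing")
})

test_that("relaxing any DHS threshold never removes a kept peak", {
  withr::with_seed(19, {
    trk <- dhs_track()
    rows <- lapply(1:30, function(i) {
      s <- sample(0:50000, 1)
      c(s, s + 200, runif(1, 30, 70), runif(1, 20, 40), runif(1, 100, 140))
    })
    trk <- do.call(dhs_track, rows)
  })
  base <- filter_dhs(trk)
  relaxed <- list(
    filter_dhs(trk, min_neglog10p = 40),
    filter_dhs(trk, min_signal = 25),
    filter_dhs(trk, min_score = 110),
    filter_dhs(trk, rescue_distance = 2000)
  )
  for (r in relaxed) expect_true(all(base$name %in% r$name))
})

peaks <- function(..., chrom = "locus") {
  rows <- list(...)
  tibble::tibble(
    chrom = chrom,
    start = vapply(rows, `[`, 0, 1),
    end = vapply(rows, `[`, 0, 2),
    name = sprintf("pk%d", seq_along(rows))
  )
}

test_that("enhancer calls are the union of co-occurring marks", {
  enh <- call_active_enhancers(peaks(c(100, 200)), peaks(c(150, 250)))
  expect_equal(nrow(enh), 1)
  expect_true(enh$active)
  expect_equal(c(enh$start, enh$end), c(100, 250))

  # disjoint tracks yield no active calls but keep the H3K4me1 element
  enh2 <- call_active_enhancers(peaks(c(100, 200)), peaks(c(300, 400)))
  expect_false(any(enh2$active))

  # an overlap smaller than min_overlap does not activate
  enh3 <- call_active_enhancers(peaks(c(100, 200)), peaks(c(190, 300)),
    min_overlap = 20)
  expect_false(any(enh3$active))

  expect_error(
    call_active_enhancers(peaks(c(1, 2), chrom = "a"),
      peaks(c(1, 2), chrom = "b")),
    "reference"
  )
})

test_that("enhancer calling is invariant to input track ordering", {
  withr::with_seed(29, {
    me1 <- do.call(peaks, lapply(1:8, function(i) {
      s <- i * 2000
      c(s, s + 800)
    }))
    ac <- do.call(peaks, lapply(1:5, function(i) {
      s <- i * 3100
      c(s, s + 700)
    }))
    out1 <- call_active_enhancers(me1, ac)
    out2 <- call_active_enhancers(me1[sample(nrow(me1)), ], ac[sample(nrow(ac)), ])
  })
  expect_equal(out1[c("chrom", "start", "end", "active")],
    out2[c("chrom", "start", "end", "active")])
})

test_that("CGI annotation and the strict unmethylated mode behave as documented", {
  me1 <- peaks(c(100, 200), c(1000, 1100))
  ac <- peaks(c(150, 250), c(1050, 1150))
  cgi <- tibble::tibble(
    chrom = "locus", start = c(120, 1020), end = c(180, 1080),
    name = c("cgi_a", "cgi_b"), methylation = c("unmethylated", "methylated")
  )
  out <- call_active_enhancers(me1, ac, cgi = cgi)
  expect_equal(sum(out$active), 2)
  expect_equal(out$cgi_methylation, c("unmethylated", "methylated"))
  strict <- call_active_enhancers(me1, ac, cgi = cgi,
    require_unmethylated_cgi = TRUE)
  expect_equal(strict$active, c(TRUE, FALSE))
})

test_that("synthetic tracks with 3 co-marked regions among 9 H3K4me1 peaks give 3 active calls at truth", {
  cfg <- small_config(seed = 33)
  trk <- simulate_peak_tracks(cfg)
  enh <- call_active_enhancers(trk$h3k4me1, trk$h3k27ac, cgi = trk$cgi)
  expect_equal(nrow(enh), 9)
  act <- enh[enh$active, ]
  expect_equal(nrow(act), 3)
  truth <- trk$truth$enhancers
  expect_equal(act$start, truth$start - 1L) # truth is 1-based inclusive
  expect_equal(act$end, truth$end)
  expect_true(all(grepl("unmethylated", act$cgi_methylation)))

  # no true enhancers, only isolated single-mark peaks: zero active calls
  cfg0 <- small_config(seed = 34, n_enhancers = 0, n_enhancer_resident = 0,
    n_motif_gain = 0)
  trk0 <- simulate_peak_tracks(cfg0)
  enh0 <- call_active_enhancers(trk0$h3k4me1, trk0$h3k27ac)
  expect_equal(nrow(enh0), 9)
  expect_equal(sum(enh0$active), 0)
})

test_that("variant containment uses half-open boundary semantics", {
  enh <- tibble::tibble(
    enhancer_id = "e1", chrom = "locus", start = 100L, end = 250L,
    active = TRUE
  )
  v <- tibble::tibble(
    chrom = "locus",
    pos = c(150L, 101L, 250L, 251L, 100L),
    ref = "A", alt = "T", type = "SNP"
  )
  out <- intersect_variants(v, enh)
  # 1-based 150 and 101 and 250 sit inside [100, 250); 251 does not; 1-based
  # 100 maps to 0-based 99, one base before the interval
  expect_equal(out$n_enhancers, c(1L, 1L, 1L, 0L, 0L))

  # an indel overlapping by its span is annotated even if anchored outside
  d <- tibble::tibble(chrom = "locus", pos = 95L, ref = "AACCTTGGAA",
    alt = "A", type = "deletion")
  expect_equal(intersect_variants(d, enh)$n_enhancers, 1L)
})

test_that("indexed intersection equals a naive scan on random instances", {
  withr::with_seed(41, {
    enh <- tibble::tibble(
      enhancer_id = sprintf("e%02d", 1:50),
      chrom = "locus",
      start = sort(sample.int(100000, 50)) * 1L
    )
    enh$end <- enh$start + sample(50:500, 50, replace = TRUE)
    enh$active <- runif(50) < 0.8
    v <- tibble::tibble(
      chrom = "locus",
      pos = sample.int(101000, 1000),
      ref = ifelse(runif(1000) < 0.7, "A", "ACGT"),
      alt = "T",
      type = ifelse(runif(1000) < 0.7, "SNP", "deletion")
    )
    v$type[v$ref == "A" & v$type == "deletion"] <- "insertion"
    v$alt[v$type == "insertion"] <- "TACG"
  })
  fast <- intersect_variants(v, enh)
  slow <- oracle_intersect(v, enh)
  expect_equal(fast$enhancers, slow)
})

test_that("peak tracks round-trip through narrowPeak and BED", {
  cfg <- small_config(seed = 35)
  trk <- simulate_peak_tracks(cfg)
  np <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(trk$dhs, np)
  back <- read_narrowpeak(np)
  expect_equal(back$start, trk$dhs$start)
  expect_equal(back$signal, trk$dhs$signal, tolerance = 1e-9)
  expect_equal(back$neglog10p, trk$dhs$neglog10p, tolerance = 1e-9)

  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(dplyr::mutate(trk$cgi, score = 0, strand = "."), bed)
  cgi <- read_bed(bed)
  expect_equal(cgi$methylation, trk$cgi$methylation)
})
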