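#' Construct a position weight matrix
#'
#' @param id Motif identifier.
#' @param mat A 4 x L numeric matrix (rows A, C, G, T) of per-position base
#'   probabilities or counts; columns are normalized to probabilities after
#'   adding `pseudocount * background`.
#' @param background Named base frequencies used both for pseudocount
#'   regularization and log-odds scoring (default uniform).
#' @param pseudocount Pseudocount added per column (in units of total column
#'   mass; default 0, appropriate when `mat` already holds probabilities;
#'   use e.g. 0.1 for raw counts).
#' @return A `pwm` object.
#' @export
pwm <- function(id, mat, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                pseudocount = 0) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) abort("`mat` must have 4 rows (A, C, G, T).")
  rownames(mat) <- BASES
  if (ncol(mat) < 4) abort("motif length must be at least 4.")
  if (any(mat < 0)) abort("`mat` entries must be non-negative.")
  background <- background[BASES] / sum(background[BASES])
  prob <- sweep(
    mat + pseudocount * background,
    2, colSums(mat) + pseudocount, "/"
  )
  if (any(abs(colSums(prob) - 1) > 1e-9)) {
    abort("PWM columns failed to normalize to 1.")
  }
  structure(
    list(id = id, mat = prob, background = background,
      logodds = log2(prob / background)),
    class = "pwm"
  )
}

#' @export
#' @method print pwm
print.pwm <- function(x, ...) {
  cat(sprintf(
    "<pwm> %s, length %d, consensus %s\n",
    x$id, ncol(x$mat), pwm_consensus(x)
  ))
  invisible(x)
}

#' Consensus sequence (most probable base per column) of a PWM
#' @param x A `pwm` object.
#' @export
pwm_consensus <- function(x) {
  paste(BASES[apply(x$mat, 2, which.max)], collapse = "")
}

# Reverse-complemented PWM (reversed columns, complemented rows).
pwm_revcomp <- function(x) {
  m <- x$mat[4:1, rev(seq_len(ncol(x$mat))), drop = FALSE]
  rownames(m) <- BASES
  bg <- setNames(x$background[4:1], BASES)
  pwm(paste0(x$id, "_rc"), m, background = bg)
}

#' Log-odds score of a sequence window against a PWM
#'
#' Sum over motif positions of `log2(p_motif(base) / p_background(base))`,
#' in bits. Windows containing ambiguous bases score `NA` (the placement is
#' skipped and reported by callers).
#'
#' @param window Base string of exactly the motif length.
#' @param x A `pwm` object.
#' @return Score in bits, or `NA` for ambiguous windows.
#' @export
pwm_logodds <- function(window, x) {
  L <- ncol(x$mat)
  chars <- seq_chars(toupper(window))
  if (length(chars) != L) abort("`window` length must equal the motif length.")
  idx <- match(chars, BASES)
  if (anyNA(idx)) return(NA_real_)
  sum(x$logodds[cbind(idx, seq_len(L))])
}

#' Empirical score threshold for a PWM
#'
#' Samples `n` windows i.i.d. from the background composition, scores them,
#' and returns the smallest score `t` such that the fraction of null windows
#' with score `>= t` is at most `p` (the conventional motif-scan operating
#' point, default `p = 1e-4`).
#'
#' @param x A `pwm` object.
#' @param p Target null exceedance probability.
#' @param n Number of background windows sampled.
#' @param seed Seed for the draw.
#' @return Score threshold in bits.
#' @export
pwm_threshold <- function(x, p = 1e-4, n = 1e5, seed = NULL) {
  L <- ncol(x$mat)
  with_seed_if(seed, {
    draws <- matrix(
      sample.int(4, n * L, replace = TRUE, prob = x$background), L, n
    )
    scores <- colSums(matrix(
      x$logodds[cbind(as.vector(draws), rep(seq_len(L), n))], L, n
    ))
    sorted <- sort(scores, decreasing = TRUE)
    k <- max(1L, floor(p * n))
    # smallest score still exceeded by at most p of the null mass
    sorted[k] + 1e-9
  })
}

#' Read / write PWM libraries in JASPAR text format
#'
#' The JASPAR 2016+ matrix format: a `>ID name` header line followed by four
#' rows `A [ n n ... ]` etc.
#'
#' @param path File path.
#' @param pwms A list of `pwm` objects.
#' @param digits Significant digits written.
#' @return `read_jaspar()` returns a named list of `pwm` objects.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  out <- list()
  for (h in heads) {
    id <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]][1]
    rows <- lines[(h + 1):(h + 4)]
    vals <- lapply(rows, function(r) {
      nums <- gsub("^[ACGT]\\s*\\[?|\\]\\s*$", "", r)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    bases <- toupper(substr(trimws(rows), 1, 1))
    m <- do.call(rbind, vals)[match(BASES, bases), , drop = FALSE]
    out[[id]] <- pwm(id, m)
  }
  out
}

#' @rdname read_jaspar
#' @export
write_jaspar <- function(pwms, path, digits = 6) {
  lines <- unlist(lapply(pwms, function(x) {
    c(
      paste0(">", x$id, " ", x$id),
      vapply(seq_len(4), function(i) {
        sprintf("%s  [ %s ]", BASES[i],
          paste(signif(x$mat[i, ], digits), collapse = " "))
      }, "")
    )
  }))
  writeLines(lines, path)
  invisible(path)
}
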