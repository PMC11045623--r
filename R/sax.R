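# Symbolic aggregate approximation at point resolution: one letter per raw
# data point, so letters can be edited at specific retention-time indices
# (peak bounds, enforced split points).

sax_breakpoints <- function(alphabet_size) {
  qnorm(seq_len(alphabet_size - 1L) / alphabet_size)
}

new_sax <- function(letters_idx, alphabet_size) {
  structure(list(letters = letters[letters_idx],
                 idx = as.integer(letters_idx),
                 alphabet_size = as.integer(alphabet_size),
                 breakpoints = sax_breakpoints(alphabet_size),
                 source_len = length(letters_idx)),
            class = "ats_sax")
}

#' @export
print.ats_sax <- function(x, ...) {
  cat(sprintf("<ats_sax> a=%d, %d letters: %s\n", x$alphabet_size,
              x$source_len, paste(x$letters, collapse = "")))
  invisible(x)
}

#' @export
format.ats_sax <- function(x, ...) paste(x$letters, collapse = "")

#' SAX-encode an intensity trace
#'
#' Z-normalises the intensities (zero mean, unit variance) and maps each
#' value to the letter of its standard-normal bin, one letter per point. A
#' constant trace has no variance to normalise and maps every point to the
#' middle letter.
#'
#' @param intensities Numeric vector (>= 2 points).
#' @param alphabet_size Alphabet size in `[2, 20]`.
#' @return An `ats_sax` object.
#' @export
encode_sax <- function(intensities, alphabet_size = 7) {
  stopifnot(length(intensities) >= 2,
            alphabet_size >= 2, alphabet_size <= 20)
  s <- sd(intensities)
  if (!is.finite(s) || s == 0) {
    mid <- as.integer(ceiling((alphabet_size + 1) / 2))
    return(new_sax(rep(mid, length(intensities)), alphabet_size))
  }
  z <- (intensities - mean(intensities)) / s
  bins <- findInterval(z, sax_breakpoints(alphabet_size)) + 1L
  new_sax(bins, alphabet_size)
}

# MINDIST cell lookup: letters one bin apart (or equal) contribute zero;
# otherwise the gap between the nearer breakpoints.
mindist_cell <- function(r, c, breakpoints) {
  if (abs(r - c) <= 1) return(0)
  breakpoints[max(r, c) - 1L] - breakpoints[min(r, c)]
}

#' SAX lower-bound distance between two sequences
#'
#' The standard MINDIST lower bound on the Euclidean distance of the
#' z-normalised source signals, evaluated letter-by-letter with the
#' breakpoint lookup table. Sequences of unequal length are compared after
#' linearly index-resampling the shorter onto the longer.
#'
#' @param seq_a,seq_b `ats_sax` objects with equal alphabet size.
#' @return Nonnegative distance; 0 for identical sequences.
#' @export
mindist <- function(seq_a, seq_b) {
  stopifnot(inherits(seq_a, "ats_sax"), inherits(seq_b, "ats_sax"))
  if (seq_a$alphabet_size != seq_b$alphabet_size) {
    stop("MINDIST requires equal alphabet sizes", call. = FALSE)
  }
  a <- seq_a$idx
  b <- seq_b$idx
  n <- max(length(a), length(b))
  resample <- function(v) {
    if (length(v) == n) return(v)
    v[round(seq(1, length(v), length.out = n))]
  }
  a <- resample(a)
  b <- resample(b)
  bp <- seq_a$breakpoints
  cells <- vapply(seq_len(n), function(i) mindist_cell(a[i], b[i], bp),
                  numeric(1))
  sqrt(sum(cells^2))
}

#' Fraction of a trace covered by zigzag interference
#'
#' Zigzag is the alternating-spike pattern of noise: contiguous runs where
#' the intensity alternates between "high" (above baseline + 3 * noise) and
#' "low" (at most baseline + noise) from point to point. Runs of at least
#' `params$zigzag_min_run` points are flagged; the returned value is
#' flagged points over total points.
#'
#' @param eic An `ats_eic`.
#' @param baseline,noise Baseline and noise levels in counts.
#' @param params [ats_params()].
#' @return Fraction in `[0, 1]`.
#' @export
zigzag_fraction <- function(eic, baseline, noise, params = ats_params()) {
  y <- eic$intensity
  n <- length(y)
  if (n < params$zigzag_min_run) return(0)
  lab <- ifelse(y > baseline + 3 * noise, "H",
                ifelse(y <= baseline + noise, "L", "M"))
  flagged <- logical(n)
  run_start <- 1L
  for (i in 2:(n + 1)) {
    alternating <- i <= n && lab[i] != "M" && lab[i - 1] != "M" &&
      lab[i] != lab[i - 1]
    if (!alternating) {
      if (i - run_start >= params$zigzag_min_run &&
          all(lab[run_start:(i - 1)] != "M")) {
        flagged[run_start:(i - 1)] <- TRUE
      }
      run_start <- i
    }
  }
  sum(flagged) / n
}

#' Force letters to the lowest symbol at given positions
#'
#' Peak starts, ends, and enforced split points are written into the SAX
#' sequence as the lowest letter `"a"` so shape comparison sees separated
#' segments.
#'
#' @param seq An `ats_sax`.
#' @param indices Positions (1-based) to zero out; may be empty.
#' @return The edited `ats_sax`.
#' @export
zero_out_bounds <- function(seq, indices) {
  stopifnot(inherits(seq, "ats_sax"))
  if (!length(indices)) return(seq)
  indices <- as.integer(indices)
  if (any(indices < 1 | indices > seq$source_len)) {
    stop("zero-out index outside the sequence", call. = FALSE)
  }
  seq$idx[indices] <- 1L
  seq$letters <- letters[seq$idx]
  seq
}
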