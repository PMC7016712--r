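# Direct-repeat discovery between two genome windows.
#
# Direct repeats flanking a deleted segment are the substrate of
# illegitimate-recombination deletions in mtDNA; a near-exact repeat with an
# internal mismatch decomposes into exact subrepeats on either side of the
# mismatch, which determines the breakpoint-ambiguity structure of the
# deletion.

#' Find maximal direct repeats between two windows
#'
#' Scans every alignment register (diagonal) between the two windows and
#' reports all maximal repeat pairs of length >= `min_len` containing at most
#' `max_mismatch` internal mismatches. Maximal means the pair cannot be
#' extended in either direction without exceeding the mismatch budget or a
#' window boundary, and both ends are exact matches. Each pair carries its
#' decomposition into exact subrepeats (the match segments between
#' mismatches).
#'
#' @param genome An [annotated_genome()].
#' @param window_a,window_b Two disjoint intervals `c(start, end)`, 1-based
#'   inclusive. On circular genomes an end may exceed the genome length to
#'   reach across the origin.
#' @param min_len Minimum repeat length (>= 5).
#' @param max_mismatch Maximum internal mismatches per repeat (default 1).
#' @return List of `repeat_pair` objects sorted by length descending, each
#'   with `left_interval`, `right_interval`, `length`, `mismatch_positions`
#'   (1-based offsets within the repeat) and `exact_subrepeats`
#'   (data frame `offset`, `length`).
#' @export
find_direct_repeats <- function(genome, window_a, window_b, min_len = 5L,
                                max_mismatch = 1L) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (!is_count(min_len, 5L)) stopf("min_len must be an integer >= 5")
  window_a <- as.integer(window_a); window_b <- as.integer(window_b)
  if (length(window_a) != 2L || length(window_b) != 2L ||
      window_a[1] > window_a[2] || window_b[1] > window_b[2]) {
    stopf("windows must be c(start, end) with start <= end")
  }
  if (window_a[1] <= window_b[2] && window_b[1] <= window_a[2]) {
    stopf("windows overlap")
  }
  doubled <- paste0(genome$sequence,
                    if (genome$circular) genome$sequence else "")
  if (max(window_a[2], window_b[2]) > nchar(doubled)) {
    stopf("window exceeds genome bounds")
  }
  a <- seq_to_chars(substr(doubled, window_a[1], window_a[2]))
  b <- seq_to_chars(substr(doubled, window_b[1], window_b[2]))
  n <- length(a); m <- length(b)

  hits <- list()
  for (d in seq.int(-(n - 1L), m - 1L)) {
    ia <- max(1L, 1L - d); ib <- ia + d
    len_d <- min(n - ia, m - ib) + 1L
    if (len_d < min_len) next
    match <- a[seq.int(ia, ia + len_d - 1L)] == b[seq.int(ib, ib + len_d - 1L)]
    mm <- which(!match)
    bounds <- c(0L, mm, len_d + 1L)
    k <- as.integer(max_mismatch)
    for (i in seq_len(length(bounds) - 1L)) {
      j <- min(i + k + 1L, length(bounds))
      lo <- bounds[i] + 1L
      hi <- bounds[j] - 1L
      if (hi < lo) next
      while (lo <= hi && !match[lo]) lo <- lo + 1L
      while (hi >= lo && !match[hi]) hi <- hi - 1L
      if (hi - lo + 1L < min_len) next
      mm_in <- mm[mm > lo & mm < hi]
      if (length(mm_in) > k) next
      key <- paste(d, lo, hi, sep = ":")
      if (!is.null(hits[[key]])) next
      offs <- mm_in - lo + 1L
      seg_bounds <- c(0L, offs, hi - lo + 2L)
      subs <- data.frame(offset = head(seg_bounds, -1L) + 1L,
                         length = diff(seg_bounds) - 1L)
      subs <- subs[subs$length > 0L, , drop = FALSE]
      rownames(subs) <- NULL
      hits[[key]] <- structure(list(
        left_interval = c(window_a[1] + ia + lo - 2L,
                          window_a[1] + ia + hi - 2L),
        right_interval = c(window_b[1] + ib + lo - 2L,
                           window_b[1] + ib + hi - 2L),
        length = hi - lo + 1L,
        mismatch_positions = offs,
        exact_subrepeats = subs), class = "repeat_pair")
    }
  }
  hits <- unname(hits)
  # drop pairs nested inside a longer pair on the same register
  if (length(hits) > 1L) {
    keep <- rep(TRUE, length(hits))
    for (i in seq_along(hits)) {
      for (j in seq_along(hits)) {
        if (i == j || !keep[i]) next
        hi <- hits[[i]]; hj <- hits[[j]]
        if (hj$length > hi$length &&
            hi$left_interval[1] >= hj$left_interval[1] &&
            hi$left_interval[2] <= hj$left_interval[2] &&
            hi$right_interval[1] - hi$left_interval[1] ==
              hj$right_interval[1] - hj$left_interval[1]) {
          keep[i] <- FALSE
        }
      }
    }
    hits <- hits[keep]
  }
  hits[order(vapply(hits, function(h) h$length, integer(1)),
             decreasing = TRUE)]
}

#' @export
print.repeat_pair <- function(x, ...) {
  cat(sprintf("<repeat_pair> %d bp at %d..%d / %d..%d, %d mismatch(es)\n",
              x$length, x$left_interval[1], x$left_interval[2],
              x$right_interval[1], x$right_interval[2],
              length(x$mismatch_positions)))
  invisible(x)
}
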