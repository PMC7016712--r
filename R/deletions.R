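# Direct-repeat-mediated large-deletion calling from split reads.
#
# Split alignments are clustered by their canonical (left-aligned) deletion
# placement. Because the breakpoints fall inside a direct repeat, their
# exact position is inherently ambiguous within the flanking exact-repeat
# extent; the call reports the canonical start, the ambiguity interval, and
# a frequency computed per breakpoint as split support over split support
# plus reads spanning that breakpoint without the deletion, reported as a
# range over the two breakpoints.

#' Call large deletions from split alignments
#'
#' @param alignments List of `alignment` objects (after [realign_indels()]
#'   if used).
#' @param genome The reference [annotated_genome()].
#' @param min_support Minimum split-read support per cluster (default 4).
#' @param min_len Minimum deletion length treated as "large" (default 50).
#' @param repeat_window Half-width of the windows searched for the flanking
#'   direct repeat (default 45).
#' @param span_margin Bases a read must extend past a breakpoint on both
#'   sides to count as a reference-spanning molecule (default 10; junction
#'   reads with shorter overhangs are not informative either way).
#' @return List of `deletion_call` objects: `canonical_start` (1-based first
#'   deleted base, left-aligned), `length`, `ambiguity_interval`,
#'   `support`, `coverage_range`, `frequency_range`, `repeat_pair` (or
#'   `NULL`).
#' @export
call_large_deletions <- function(alignments, genome, min_support = 4L,
                                 min_len = LARGE_DELETION_MIN,
                                 repeat_window = 45L, span_margin = 10L) {
  stopifnot(inherits(genome, "annotated_genome"))
  chars <- seq_to_chars(genome$sequence)
  L <- genome$length
  splits <- Filter(function(al) al$status == "mapped" &&
                     al$gap_type == "del" && al$gap_len >= min_len,
                   alignments)
  if (!length(splits)) return(list())
  canon <- vapply(splits, function(al) {
    p0 <- wrap_pos(al$segments$ref_end[1] + 1L, L)
    left_align_deletion(chars, p0, al$gap_len)
  }, integer(1))
  lens <- vapply(splits, function(al) al$gap_len, integer(1))
  key <- paste(canon, lens, sep = ":")
  out <- list()
  for (kk in unique(key)) {
    idx <- which(key == kk)
    support <- length(idx)
    if (support < min_support) next
    start <- canon[idx[1]]; len <- lens[idx[1]]
    # right-shift extent of the equivalent placements = ambiguity interval
    shift <- 0L
    while (start + shift <= L &&
           chars[wrap_pos(start + shift, L)] ==
             chars[wrap_pos(start + len + shift, L)]) {
      shift <- shift + 1L
    }
    bp <- c(start, start + len - 1L)  # first and last deleted base
    # at the left breakpoint a reference molecule is only distinguishable
    # from a deletion molecule once it extends beyond the shared repeat
    # (the ambiguity zone); at the right breakpoint left-alignment makes
    # the zone extent zero
    right_ext <- c(shift, 0L)
    span_counts <- vapply(seq_along(bp), function(i)
      count_spanning(alignments, bp[i], L, span_margin, right_ext[i]),
      integer(1))
    freqs <- support / (support + span_counts)
    rp <- flanking_repeat(genome, start, len, repeat_window)
    out[[length(out) + 1L]] <- structure(list(
      canonical_start = start, length = len,
      ambiguity_interval = c(start, start + shift),
      support = support,
      coverage_range = range(support + span_counts),
      frequency_range = range(round(freqs, 3L)),
      repeat_pair = rp), class = "deletion_call")
  }
  out[order(vapply(out, function(d) -d$support, numeric(1)))]
}

# Reads spanning position b with `margin` anchor bases on each side (the
# right anchor extended by `right_ext` ambiguity bases) on a single
# segment, i.e. molecules without the deletion at that breakpoint.
count_spanning <- function(alignments, b, L, margin = 10L, right_ext = 0L) {
  n <- 0L
  for (al in alignments) {
    if (al$status != "mapped") next
    # molecules carrying a large deletion never count as reference-spanning
    if (al$gap_type == "del" && al$gap_len >= LARGE_DELETION_MIN) next
    seg <- al$segments
    for (si in seq_len(length(seg$ref_start))) {
      lo <- seg$ref_start[si]; hi <- seg$ref_end[si]
      if ((lo <= b - margin && hi >= b + right_ext + margin) ||
          (lo <= b - margin + L && hi >= b + right_ext + margin + L)) {
        n <- n + 1L
        break
      }
    }
  }
  n
}

flanking_repeat <- function(genome, start, len, w) {
  win_a <- c(max(1L, start - w), start + w)
  win_b <- c(start + len - w, start + len + w)
  if (win_a[2] >= win_b[1]) return(NULL)
  rp <- tryCatch(
    find_direct_repeats(genome, win_a, win_b, min_len = 5L,
                        max_mismatch = 1L),
    error = function(e) list())
  if (length(rp)) rp[[1]] else NULL
}

#' @export
print.deletion_call <- function(x, ...) {
  cat(sprintf("<deletion_call> -N(%d) at %d (ambiguity %d..%d), support %d, frequency %.3f-%.3f\n",
              x$length, x$canonical_start, x$ambiguity_interval[1],
              x$ambiguity_interval[2], x$support, x$frequency_range[1],
              x$frequency_range[2]))
  invisible(x)
}
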