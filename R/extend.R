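# Iterative reference extension into low-complexity flanks.
#
# Reads are mapped to the current reference allowing overhang past its ends;
# overhanging bases vote into a majority-rule consensus which extends the
# reference, and the procedure repeats. After the final iteration, extended
# positions whose coverage falls below mean - low_cov_sd * SD of the
# whole-reference coverage are trimmed back.

#' Extend a truncated reference using read overhangs
#'
#' @param reads Data frame with `id`, `seq` (merged reads).
#' @param genome The truncated reference ([annotated_genome()]); treated as
#'   linear for the purpose of extension.
#' @param iterations Number of map-consensus-extend rounds (default 10).
#' @param low_cov_sd Trim extended positions with coverage below
#'   mean - `low_cov_sd` * SD (default 2).
#' @param k Seed k-mer size for the internal mapping (default 12).
#' @param max_mismatch_rate Maximum mismatch rate on the overlapping part of
#'   a read for it to contribute (default 0.05).
#' @param min_anchor Minimum bases of a read that must overlap the current
#'   reference (default 30).
#' @param min_ext_cov Minimum overhang coverage to accept an extended
#'   position (default 2).
#' @return An [annotated_genome()] with the extended sequence; feature
#'   coordinates are shifted by the left extension. If no reads map, the
#'   input genome is returned with a warning.
#' @export
extend_reference <- function(reads, genome, iterations = 10L, low_cov_sd = 2,
                             k = 12L, max_mismatch_rate = 0.05,
                             min_anchor = 30L, min_ext_cov = 2L) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (!is_count(iterations, 1L)) stopf("iterations must be an integer >= 1")
  ref <- seq_to_chars(genome$sequence)
  left_total <- 0L
  pad <- max(nchar(reads$seq)) + 10L
  any_mapped <- FALSE
  votes <- NULL

  for (it in seq_len(iterations)) {
    res <- overhang_votes(reads, ref, k, max_mismatch_rate, min_anchor, pad)
    votes <- res$votes
    if (res$n_mapped == 0L) break
    any_mapped <- TRUE
    cov <- colSums(votes)
    L <- length(ref)
    # majority-rule consensus: an extended position needs both coverage and
    # clear agreement (mis-merged low-complexity reads vote discordantly)
    accept <- function(pos) {
      cov[pos] >= min_ext_cov && max(votes[, pos]) / cov[pos] >= 0.7
    }
    left_ext <- character()
    pos <- pad
    while (pos >= 1L && accept(pos)) {
      left_ext <- c(BASES[which.max(votes[, pos])], left_ext)
      pos <- pos - 1L
    }
    right_ext <- character()
    pos <- pad + L + 1L
    while (pos <= ncol(votes) && accept(pos)) {
      right_ext <- c(right_ext, BASES[which.max(votes[, pos])])
      pos <- pos + 1L
    }
    if (!length(left_ext) && !length(right_ext)) break
    ref <- c(left_ext, ref, right_ext)
    left_total <- left_total + length(left_ext)
  }

  if (!any_mapped) {
    warning("no reads mapped; returning the input reference")
    return(genome)
  }

  # final coverage over the whole (extended) reference, then trim
  # low-coverage extended positions from the outer ends
  res <- overhang_votes(reads, ref, k, max_mismatch_rate, min_anchor, pad)
  L <- length(ref)
  cov <- colSums(res$votes)[seq.int(pad + 1L, pad + L)]
  thr <- mean(cov) - low_cov_sd * stats::sd(cov)
  orig_start <- left_total + 1L
  orig_end <- L - (L - left_total - genome$length)
  lo <- 1L
  while (lo < orig_start && cov[lo] < thr) lo <- lo + 1L
  hi <- L
  while (hi > orig_end && cov[hi] < thr) hi <- hi - 1L
  ref <- ref[seq.int(lo, hi)]
  left_total <- left_total - (lo - 1L)

  feats <- genome$features
  if (nrow(feats)) {
    feats$start <- feats$start + left_total
    feats$end <- feats$end + left_total
    feats$reading_frame_start <- feats$reading_frame_start + left_total
    feats$coding_end <- feats$coding_end + left_total
  }
  annotated_genome(genome$name, chars_to_seq(ref), circular = genome$circular,
                   features = feats)
}

# Map reads (both orientations) to a linear reference by best seed diagonal
# and tally per-position base votes including overhanging bases.
overhang_votes <- function(reads, ref, k, max_mismatch_rate, min_anchor, pad) {
  L <- length(ref)
  ref_str <- chars_to_seq(ref)
  starts <- seq_len(max(0L, L - k + 1L))
  kmers <- substring(ref_str, starts, starts + k - 1L)
  env <- list2env(split(starts, kmers), hash = TRUE)
  votes <- matrix(0L, nrow = 4L, ncol = L + 2L * pad,
                  dimnames = list(BASES, NULL))
  n_mapped <- 0L
  for (i in seq_len(nrow(reads))) {
    best <- NULL
    for (strand in c("+", "-")) {
      oriented <- if (strand == "+") reads$seq[i] else
        revcomp_fast(reads$seq[i])
      chars <- seq_to_chars(oriented)
      len <- length(chars)
      if (len < k) next
      offs <- unique(as.integer(round(seq(1L, len - k + 1L,
                                          length.out = 8L))))
      dvotes <- new.env(hash = TRUE)
      for (q in offs) {
        hits <- env[[substr(oriented, q, q + k - 1L)]]
        if (is.null(hits) || length(hits) > 40L) next
        for (p in hits) {
          key <- as.character(p - q)
          dvotes[[key]] <- (if (is.null(dvotes[[key]])) 0L
                            else dvotes[[key]]) + 1L
        }
      }
      keys <- ls(dvotes)
      if (!length(keys)) next
      vc <- vapply(keys, function(kk) dvotes[[kk]], integer(1))
      for (d in utils::head(as.integer(keys)[order(vc, decreasing = TRUE)], 3L)) {
        ov_lo <- max(1L, d + 1L); ov_hi <- min(L, d + len)
        if (ov_hi - ov_lo + 1L < min_anchor) next
        ridx <- seq.int(ov_lo - d, ov_hi - d)
        mm <- sum(chars[ridx] != ref[seq.int(ov_lo, ov_hi)])
        if (mm / length(ridx) > max_mismatch_rate) next
        cand <- list(d = d, chars = chars, len = len, mm = mm,
                     anchor = length(ridx), n_pass = 1L)
        if (is.null(best)) {
          best <- cand
        } else {
          best$n_pass <- best$n_pass + 1L
          if (cand$mm / cand$anchor < best$mm / best$anchor) {
            cand$n_pass <- best$n_pass
            best <- cand
          }
        }
      }
    }
    # reads anchoring acceptably on more than one placement (low-complexity
    # sequence) are ambiguous and must not steer the consensus
    if (is.null(best) || best$n_pass > 1L) next
    n_mapped <- n_mapped + 1L
    cols <- pad + best$d + seq_len(best$len)
    keep <- cols >= 1L & cols <= ncol(votes)
    idx <- cbind(match(best$chars[keep], BASES), cols[keep])
    ok <- !is.na(idx[, 1L])
    votes[idx[ok, , drop = FALSE]] <- votes[idx[ok, , drop = FALSE]] + 1L
  }
  list(votes = votes, n_mapped = n_mapped)
}
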