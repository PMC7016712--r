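# Seed-and-extend mapping of merged reads to a small circular reference.
#
# Seeds are exact k-mers; candidate placements are diagonals (ref position
# minus read offset) voted by seed hits. A read is scored on its best
# diagonals by direct comparison (+1 match, -1 mismatch); a single long
# deletion (up to maxindel) or short insertion is modeled as two collinear
# segments with the split point chosen to maximize matches, at a flat gap
# penalty independent of gap length (one biological event). Ties between
# distinct best placements are discarded as ambiguous; best identity below
# minratio is unmapped.

GAP_OPEN_PENALTY <- 4L   # flat, in match units
MAX_INSERTION <- 50L     # largest read-relative insertion modeled
LARGE_DELETION_MIN <- 50L  # gaps at least this long are "large" deletions

#' Build an exact k-mer seed index over a reference
#'
#' For circular references the sequence is doubled so k-mers spanning the
#' origin are indexed; positions are reported on the primary copy
#' (1..length), one entry per circular start.
#'
#' @param genome An [annotated_genome()].
#' @param k K-mer size, 4-15 (default 8).
#' @return A `seed_index` (environment-backed k-mer -> positions map plus
#'   the reference character vectors used for extension).
#' @export
index_reference <- function(genome, k = 8L) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (!is_count(k, 4L) || k > 15L) stopf("k must be an integer in [4, 15]")
  if (genome$length < k) stopf("genome shorter than k")
  L <- genome$length
  doubled_str <- if (genome$circular) paste0(genome$sequence, genome$sequence)
                 else genome$sequence
  starts <- if (genome$circular) seq_len(L) else seq_len(L - k + 1L)
  kmers <- substring(doubled_str, starts, starts + k - 1L)
  env <- list2env(split(starts, kmers), hash = TRUE)
  structure(list(env = env, k = as.integer(k), L = L,
                 circular = genome$circular,
                 ref_chars = seq_to_chars(genome$sequence),
                 doubled_chars = seq_to_chars(doubled_str),
                 name = genome$name),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> %s: %d bp (%s), k = %d, %d distinct k-mer(s)\n",
              x$name, x$L, if (x$circular) "circular" else "linear", x$k,
              length(x$env)))
  invisible(x)
}

#' Map one read against a seed index
#'
#' @param seq Read sequence (merged single-end read).
#' @param index A [index_reference()] result.
#' @param minratio Minimum identity (matches / aligned read length) to
#'   report a placement (default 0.8).
#' @param maxindel Largest reference deletion bridged by a split alignment
#'   (default 2000).
#' @param id Read identifier carried into the alignment.
#' @param n_seeds Number of seed k-mers sampled along the read.
#' @param max_seed_hits Seeds hitting more reference positions than this are
#'   skipped as repetitive.
#' @return An `alignment` object with `status` one of `"mapped"`,
#'   `"unmapped"`, `"ambiguous"`. Mapped alignments carry `segments`
#'   (`ref_start`, `ref_end`, `read_start`, `read_end`; reference
#'   coordinates may exceed the reference length when a read wraps the
#'   circular origin), `gap_type` (`"none"`, `"del"`, `"ins"`), `gap_len`,
#'   `strand`, `matches`, `identity`, `score` and the oriented sequence.
#' @export
map_read <- function(seq, index, minratio = 0.8, maxindel = 2000L,
                     id = "read", n_seeds = 12L, max_seed_hits = 40L) {
  stopifnot(inherits(index, "seed_index"))
  k <- index$k
  if (nchar(seq) < k) stopf("read shorter than k")
  best <- NULL; second_score <- -Inf
  for (strand in c("+", "-")) {
    # a near-perfect placement on the first strand cannot be beaten on the
    # other strand (barring pathological palindromes)
    if (strand == "-" && !is.null(best) && best$identity >= 0.95) break
    oriented <- if (strand == "+") seq else revcomp_fast(seq)
    cand <- candidate_placements(oriented, index, maxindel, n_seeds,
                                 max_seed_hits)
    for (pl in cand) {
      pl$strand <- strand
      pl$seq <- oriented
      if (is.null(best) || pl$score > best$score) {
        if (!is.null(best) && !same_placement(best, pl)) {
          second_score <- best$score
        }
        best <- pl
      } else if (!same_placement(best, pl) && pl$score > second_score) {
        second_score <- pl$score
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(id = id, status = "unmapped"), class = "alignment"))
  }
  if (second_score == best$score) {
    return(structure(list(id = id, status = "ambiguous"), class = "alignment"))
  }
  if (best$identity < minratio) {
    return(structure(list(id = id, status = "unmapped"), class = "alignment"))
  }
  structure(c(list(id = id, status = "mapped"), best), class = "alignment")
}

# Two placements are the "same" when they put the bulk of the read at the
# same locus (possibly with a different gap representation); ambiguity is
# about genuinely different locations, e.g. two copies of a perfect repeat.
# The locus is the diagonal of the longest segment.
major_diagonal <- function(seg) {
  i <- which.max(seg$read_end - seg$read_start)
  seg$ref_start[i] - seg$read_start[i]
}

same_placement <- function(a, b) {
  identical(a$strand, b$strand) &&
    abs(major_diagonal(a$segments) - major_diagonal(b$segments)) <= 30L
}

# segments are plain lists of parallel vectors (cheap to build on the
# mapper's hot path); n_segments() gives the segment count
segments_list <- function(ref_start, ref_end, read_start, read_end) {
  list(ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
       read_start = as.integer(read_start), read_end = as.integer(read_end))
}

#' Number of segments in an alignment
#' @param al An `alignment` object.
#' @return Integer segment count (0 for unmapped).
#' @export
n_segments <- function(al) {
  if (al$status != "mapped") return(0L)
  length(al$segments$ref_start)
}

# Enumerate scored placements (single- and two-segment) for an oriented read.
candidate_placements <- function(oriented, index, maxindel, n_seeds,
                                 max_seed_hits) {
  k <- index$k
  L <- index$L
  dbl <- index$doubled_chars
  chars <- seq_to_chars(oriented)
  len <- length(chars)
  max_start <- len - k + 1L
  offs <- unique(as.integer(round(seq(1L, max_start,
                                      length.out = min(n_seeds, max_start)))))
  dvec <- integer(0)
  for (q in offs) {
    kmer <- substr(oriented, q, q + k - 1L)
    hits <- index$env[[kmer]]
    if (is.null(hits) || length(hits) > max_seed_hits) next
    d <- hits - q
    if (index$circular) d <- d %% L
    dvec <- c(dvec, d)
  }
  if (!length(dvec)) return(list())
  vcount <- table(dvec)
  diags <- as.integer(names(vcount))[order(vcount, decreasing = TRUE)]
  diags <- utils::head(diags, 8L)

  # cache per-diagonal match vectors
  usable <- logical(length(diags))
  mvecs <- vector("list", length(diags))
  for (i in seq_along(diags)) {
    d <- diags[i]
    if (d < 0L || d + len > length(dbl)) next
    mvecs[[i]] <- chars == dbl[seq.int(d + 1L, d + len)]
    usable[i] <- TRUE
  }
  diags <- diags[usable]; mvecs <- mvecs[usable]
  if (!length(diags)) return(list())

  out <- list()
  best_single <- 0
  for (i in seq_along(diags)) {
    m <- sum(mvecs[[i]])
    best_single <- max(best_single, m / len)
    out[[length(out) + 1L]] <- list(
      segments = segments_list(diags[i] + 1L, diags[i] + len, 1L, len),
      gap_type = "none", gap_len = 0L, matches = m,
      identity = m / len, score = 2L * m - len)
  }
  # two-segment placements across ordered diagonal pairs; skipped when a
  # near-perfect single placement exists (no indel can improve on it).
  # Diagonals one step off each candidate are added as partners: a +/-1 bp
  # slippage indel close to a read end leaves its short segment without a
  # seed, so its diagonal never gets a vote of its own.
  if (best_single < 0.99) {
    aug <- unique(c(diags, diags + 1L, diags - 1L))
    aug <- aug[aug >= 0L & aug + len <= length(dbl)]
    new_d <- setdiff(aug, diags)
    for (d in new_d) {
      diags <- c(diags, d)
      mvecs[[length(mvecs) + 1L]] <- chars == dbl[seq.int(d + 1L, d + len)]
    }
  }
  if (length(diags) > 1L && best_single < 0.99) {
    cums <- lapply(mvecs, cumsum)
    for (i in seq_along(diags)) for (j in seq_along(diags)) {
      if (i == j) next
      da <- diags[i]; db <- diags[j]
      gap <- db - da
      if (gap > 0L && gap <= maxindel) {
        cumA <- cums[[i]]; cumB <- cums[[j]]
        s_range <- seq_len(len - 1L)
        tot <- cumA[s_range] + cumB[len] - cumB[s_range]
        s <- which.max(tot)
        matches <- tot[s]
        score <- 2L * matches - len - GAP_OPEN_PENALTY
        out[[length(out) + 1L]] <- list(
          segments = segments_list(c(da + 1L, db + s + 1L),
                                   c(da + s, db + len),
                                   c(1L, s + 1L), c(s, len)),
          gap_type = "del", gap_len = gap, matches = matches,
          identity = matches / len, score = score)
      } else if (gap < 0L && -gap <= MAX_INSERTION) {
        ins <- -gap
        if (len - ins - 1L < 1L) next
        cumA <- cums[[i]]; cumB <- cums[[j]]
        s_range <- seq_len(len - ins - 1L)
        tot <- cumA[s_range] + cumB[len] - cumB[s_range + ins]
        s <- which.max(tot)
        matches <- tot[s]
        aligned <- len - ins
        score <- 2L * matches - aligned - GAP_OPEN_PENALTY
        out[[length(out) + 1L]] <- list(
          segments = segments_list(c(da + 1L, da + s + 1L),
                                   c(da + s, da + aligned),
                                   c(1L, s + ins + 1L), c(s, len)),
          gap_type = "ins", gap_len = ins, matches = matches,
          identity = matches / aligned, score = score,
          ins_seq = substr(oriented, s + 1L, s + ins),
          ins_after_read = s)
      }
    }
  }
  out
}

#' @export
print.alignment <- function(x, ...) {
  if (x$status != "mapped") {
    cat(sprintf("<alignment> %s: %s\n", x$id, x$status))
  } else {
    cat(sprintf("<alignment> %s: %s strand %s, %d segment(s), identity %.3f\n",
                x$id, paste(x$segments$ref_start, collapse = "/"),
                x$strand, n_segments(x), x$identity))
  }
  invisible(x)
}

#' Map a set of reads
#'
#' @param reads Data frame with `id` and `seq` columns.
#' @param index A [index_reference()] result.
#' @inheritParams map_read
#' @return List of `alignment` objects (one per read, in input order).
#' @export
map_reads <- function(reads, index, minratio = 0.8, maxindel = 2000L) {
  lapply(seq_len(nrow(reads)), function(i) {
    map_read(reads$seq[i], index, minratio = minratio, maxindel = maxindel,
             id = reads$id[i])
  })
}

#' Realign reads around a candidate deletion
#'
#' Reads whose single-segment alignment overlaps the candidate deletion are
#' rescored against the deletion haplotype (same scoring as the mapper);
#' reads scoring strictly better with the deletion are converted to split
#' alignments.
#'
#' @param alignments List of `alignment` objects.
#' @param deletion List with `start` (1-based first deleted base) and
#'   `length`.
#' @param index The [index_reference()] the alignments came from.
#' @return The alignment list with converted records.
#' @export
realign_indels <- function(alignments, deletion, index) {
  stopifnot(inherits(index, "seed_index"))
  del_start <- as.integer(deletion$start)
  del_len <- as.integer(deletion$length)
  dbl <- index$doubled_chars
  for (i in seq_along(alignments)) {
    al <- alignments[[i]]
    if (al$status != "mapped" || al$gap_type != "none") next
    rs <- al$segments$ref_start[1]; re <- al$segments$ref_end[1]
    if (re < del_start || rs > del_start + del_len) next
    chars <- seq_to_chars(al$seq)
    len <- length(chars)
    d <- rs - 1L
    # the read's current diagonal may be either side of the junction
    for (da in c(d, d - del_len)) {
      db <- da + del_len
      if (da < 0L || db + len > length(dbl)) next
      mA <- chars == dbl[seq.int(da + 1L, da + len)]
      mB <- chars == dbl[seq.int(db + 1L, db + len)]
      cumA <- cumsum(mA); cumB <- cumsum(mB)
      s_range <- seq_len(len - 1L)
      tot <- cumA[s_range] + cumB[len] - cumB[s_range]
      s <- which.max(tot)
      matches <- tot[s]
      score <- 2L * matches - len - GAP_OPEN_PENALTY
      if (score > al$score) {
        al$segments <- segments_list(c(da + 1L, db + s + 1L),
                                     c(da + s, db + len),
                                     c(1L, s + 1L), c(s, len))
        al$gap_type <- "del"; al$gap_len <- del_len
        al$matches <- matches; al$identity <- matches / len; al$score <- score
        alignments[[i]] <- al
      }
    }
  }
  alignments
}
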