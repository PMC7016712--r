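# Read preprocessing: adapter trimming, overlap merging of pairs, exact
# duplicate removal. The pipeline order is trim -> merge -> dedupe; pairs
# that cannot be merged are discarded by default, and duplicate identity is
# by sequence only, so that every surviving read can be treated as an
# independent source molecule.

#' Merge parameters
#'
#' @param min_overlap Minimum overlap between mates (bp, >= 10).
#' @param max_mismatch_rate Maximum mismatch fraction tolerated in the
#'   overlap (in [0, 0.2]).
#' @param adapter Optional adapter sequence trimmed before merging.
#' @return A `merge_params` list.
#' @export
merge_params <- function(min_overlap = 20L, max_mismatch_rate = 0.1,
                         adapter = NULL) {
  if (!is_count(min_overlap, 10L)) stopf("min_overlap must be an integer >= 10")
  stopifnot(max_mismatch_rate >= 0, max_mismatch_rate <= 0.2)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_mismatch_rate = max_mismatch_rate, adapter = adapter),
            class = "merge_params")
}

#' Trim adapter read-through from a read's 3' end
#'
#' Removes the longest read suffix that matches a prefix of the adapter with
#' at most one mismatch per 10 bases (exact match required below 10 bases).
#' Suffix matches shorter than `min_match` bases are ignored so random
#' sequence is never clipped. Never lengthens a read.
#'
#' @param seq Read sequence.
#' @param qual Base qualities (same length); trimmed in step.
#' @param adapter Adapter sequence (>= 5 bases).
#' @param min_match Shortest suffix match considered (default 5).
#' @return List with `seq` and `qual` trimmed.
#' @export
trim_adapter <- function(seq, qual = NULL, adapter, min_match = 5L) {
  if (nchar(adapter) < 5L) stopf("adapter must be at least 5 bases")
  n <- nchar(seq)
  a <- seq_to_chars(adapter)
  r <- seq_to_chars(seq)
  if (is.null(qual)) qual <- strrep("I", n)
  best <- 0L
  s_max <- min(n, length(a))
  if (s_max >= min_match) {
    for (s in seq.int(s_max, min_match)) {
      mm <- sum(r[seq.int(n - s + 1L, n)] != a[seq_len(s)])
      if (mm <= s %/% 10L) { best <- s; break }
    }
  }
  if (best > 0L) {
    seq <- substr(seq, 1L, n - best)
    qual <- substr(qual, 1L, n - best)
  }
  list(seq = seq, qual = qual)
}

#' Merge one read pair by overlap
#'
#' The second mate is reverse-complemented, the best overlap of at least
#' `min_overlap` bases with mismatch rate at most `max_mismatch_rate` is
#' located, and a merged read is assembled taking the higher-quality base at
#' overlap disagreements. Returns unmerged when no overlap qualifies.
#'
#' @param seq1,qual1 Forward read and qualities.
#' @param seq2,qual2 Reverse read and qualities (as sequenced).
#' @param params A [merge_params()].
#' @return List with `merged` (logical) and, when merged, `seq` and `qual`.
#' @export
merge_pairs <- function(seq1, qual1, seq2, qual2, params = merge_params()) {
  a <- seq_to_chars(seq1)
  b <- seq_to_chars(revcomp_fast(seq2))
  qa <- utf8ToInt(qual1)
  qb <- rev(utf8ToInt(qual2))
  la <- length(a); lb <- length(b)
  best_o <- 0L; best_rate <- Inf
  for (o in seq.int(min(la, lb), params$min_overlap)) {
    ia <- seq.int(la - o + 1L, la)
    mm <- sum(a[ia] != b[seq_len(o)])
    rate <- mm / o
    if (rate <= params$max_mismatch_rate && rate < best_rate) {
      best_o <- o; best_rate <- rate
      if (rate <= 0.02) break  # a near-perfect long overlap cannot be beaten
    }
  }
  if (best_o == 0L) return(list(merged = FALSE))
  o <- best_o
  ia <- seq.int(la - o + 1L, la)
  ib <- seq_len(o)
  cons <- a[ia]
  take_b <- a[ia] != b[ib] & qb[ib] > qa[ia]
  cons[take_b] <- b[ib][take_b]
  cons_q <- pmax(qa[ia], qb[ib])
  list(merged = TRUE,
       seq = paste0(substr(seq1, 1L, la - o), chars_to_seq(cons),
                    chars_to_seq(b[seq.int(o + 1L, length.out = lb - o)])),
       qual = intToUtf8(c(qa[seq_len(la - o)], cons_q,
                          qb[seq.int(o + 1L, length.out = lb - o)])))
}

#' Remove exact duplicate reads
#'
#' Keeps the first occurrence of each exact sequence string; containment is
#' not deduplicated, only exact equality.
#'
#' @param reads Character vector of sequences, or a data frame with a `seq`
#'   column.
#' @return Same shape as the input, with duplicates removed.
#' @export
dedupe_exact <- function(reads) {
  if (is.character(reads)) return(reads[!duplicated(reads)])
  if (is.data.frame(reads) && "seq" %in% names(reads)) {
    out <- reads[!duplicated(reads$seq), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  stopf("reads must be a character vector or a data frame with a 'seq' column")
}

#' Preprocess a paired-end library: trim, merge, dedupe
#'
#' @param pairs Data frame with columns `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2` (as from [simulate_reads()] or paired [read_fastq()] files).
#' @param params A [merge_params()].
#' @param keep_unmerged Keep pairs that fail to merge (as separate reads)?
#'   Off by default: unmerged pairs are discarded.
#' @return Data frame of merged reads (`id`, `seq`, `qual`), deduplicated.
#' @export
preprocess_reads <- function(pairs, params = merge_params(),
                             keep_unmerged = FALSE) {
  n <- nrow(pairs)
  seq1 <- pairs$seq1; qual1 <- pairs$qual1
  seq2 <- pairs$seq2; qual2 <- pairs$qual2
  if (!is.null(params$adapter)) {
    for (i in seq_len(n)) {
      t1 <- trim_adapter(seq1[i], qual1[i], params$adapter)
      t2 <- trim_adapter(seq2[i], qual2[i], params$adapter)
      seq1[i] <- t1$seq; qual1[i] <- t1$qual
      seq2[i] <- t2$seq; qual2[i] <- t2$qual
    }
  }
  out_seq <- character(n); out_qual <- character(n); ok <- logical(n)
  for (i in seq_len(n)) {
    m <- merge_pairs(seq1[i], qual1[i], seq2[i], qual2[i], params)
    if (m$merged) {
      ok[i] <- TRUE; out_seq[i] <- m$seq; out_qual[i] <- m$qual
    }
  }
  merged <- data.frame(id = pairs$id[ok], seq = out_seq[ok],
                       qual = out_qual[ok], stringsAsFactors = FALSE)
  if (keep_unmerged && any(!ok)) {
    un <- data.frame(id = c(paste0(pairs$id[!ok], "/1"),
                            paste0(pairs$id[!ok], "/2")),
                     seq = c(seq1[!ok], vapply(seq2[!ok], revcomp_fast, "")),
                     qual = c(qual1[!ok],
                              vapply(qual2[!ok], function(q)
                                intToUtf8(rev(utf8ToInt(q))), "")),
                     stringsAsFactors = FALSE)
    merged <- rbind(merged, un)
  }
  dedupe_exact(merged)
}
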