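# Per-site, per-strand pileup over a reference.
#
# Base counts are tallied per strand; insertion and deletion events from
# split alignments are left-aligned (shifted to their leftmost equivalent
# reference placement) before aggregation so that all placements of a
# homopolymer slippage event collapse onto one canonical record.

#' Build a pileup from alignments
#'
#' Only `status == "mapped"` alignments contribute; reads discarded as
#' ambiguous are never counted. Deletion gaps of [call_large_deletions()]
#' scale (>= 50 bp) contribute no base counts across the gap and are kept
#' for split-read deletion calling rather than the small-indel table.
#'
#' @param alignments List of `alignment` objects ([map_reads()] or
#'   [read_sam()]).
#' @param genome The reference [annotated_genome()] (names must agree with
#'   the alignments' reference).
#' @return A `pileup`: list with `counts_plus`, `counts_minus` (4 x L base
#'   count matrices), `ins` and `del` (aggregated left-aligned indel event
#'   tables with per-strand support), `coverage` (total base coverage per
#'   position), `ref_chars` and `genome`.
#' @export
build_pileup <- function(alignments, genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  L <- genome$length
  ref_chars <- seq_to_chars(genome$sequence)
  # encoded base-position codes per strand, tabulated at the end
  codes_plus <- vector("list", length(alignments))
  codes_minus <- vector("list", length(alignments))
  ins_rows <- list(); del_rows <- list()
  for (ai in seq_along(alignments)) {
    al <- alignments[[ai]]
    if (al$status != "mapped") next
    chars <- seq_to_chars(al$seq)
    seg <- al$segments
    pos_all <- integer(0); base_all <- integer(0)
    for (si in seq_len(length(seg$ref_start))) {
      rpos <- seq.int(seg$ref_start[si], seg$ref_end[si])
      if (!length(rpos)) next
      b <- match(chars[seq.int(seg$read_start[si], seg$read_end[si])], BASES)
      keep <- !is.na(b)
      pos_all <- c(pos_all, wrap_pos(rpos[keep], L))
      base_all <- c(base_all, b[keep])
    }
    code <- (pos_all - 1L) * 4L + base_all
    if (al$strand == "+") codes_plus[[ai]] <- code else
      codes_minus[[ai]] <- code
    if (al$gap_type == "del" && al$gap_len < LARGE_DELETION_MIN) {
      p0 <- wrap_pos(seg$ref_end[1] + 1L, L)  # first deleted base
      norm <- left_align_deletion(ref_chars, p0, al$gap_len)
      del_rows[[length(del_rows) + 1L]] <-
        data.frame(pos = norm, len = al$gap_len, strand = al$strand,
                   stringsAsFactors = FALSE)
    } else if (al$gap_type == "ins") {
      anchor <- wrap_pos(seg$ref_end[1], L)  # base preceding the insertion
      norm <- left_align_insertion(ref_chars, anchor, al$ins_seq)
      if (norm$anchor == 0L) norm$anchor <- L
      ins_rows[[length(ins_rows) + 1L]] <-
        data.frame(pos = norm$anchor, seq = norm$seq, strand = al$strand,
                   stringsAsFactors = FALSE)
    }
  }
  tab_plus <- tabulate(c(unlist(codes_plus), integer(0)), nbins = 4L * L)
  tab_minus <- tabulate(c(unlist(codes_minus), integer(0)), nbins = 4L * L)
  counts_plus <- matrix(tab_plus, nrow = 4L, dimnames = list(BASES, NULL))
  counts_minus <- matrix(tab_minus, nrow = 4L, dimnames = list(BASES, NULL))
  structure(list(
    counts_plus = counts_plus, counts_minus = counts_minus,
    ins = aggregate_indels(ins_rows, c("pos", "seq")),
    del = aggregate_indels(del_rows, c("pos", "len")),
    coverage = colSums(counts_plus) + colSums(counts_minus),
    ref_chars = ref_chars, genome_name = genome$name, length = L),
    class = "pileup")
}

aggregate_indels <- function(rows, keys) {
  if (!length(rows)) {
    out <- data.frame(pos = integer(), plus = integer(), minus = integer())
    out[[setdiff(keys, "pos")]] <- if ("len" %in% keys) integer() else
      character()
    return(out[, c(keys, "plus", "minus")])
  }
  df <- do.call(rbind, rows)
  key <- do.call(paste, c(df[keys], sep = "\r"))
  agg <- tapply(df$strand, key, function(s)
    c(plus = sum(s == "+"), minus = sum(s == "-")))
  first <- df[!duplicated(key), keys, drop = FALSE]
  first <- first[match(names(agg), unique(key)), , drop = FALSE]
  out <- cbind(first,
               plus = vapply(agg, `[[`, integer(1), "plus"),
               minus = vapply(agg, `[[`, integer(1), "minus"))
  rownames(out) <- NULL
  out[order(out$pos), , drop = FALSE]
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %s: %d bp, mean coverage %.1f, %d ins / %d del event type(s)\n",
              x$genome_name, x$length, mean(x$coverage), nrow(x$ins),
              nrow(x$del)))
  invisible(x)
}

# Shift a deletion of `len` bases starting at ref position p to its leftmost
# equivalent placement.
left_align_deletion <- function(ref_chars, p, len) {
  while (p > 1L && ref_chars[p - 1L] == ref_chars[p + len - 1L]) p <- p - 1L
  p
}

# Shift an insertion (inserted after `anchor`) to its leftmost equivalent
# placement, rotating the inserted sequence.
left_align_insertion <- function(ref_chars, anchor, ins_seq) {
  ins <- seq_to_chars(ins_seq)
  while (anchor >= 1L && ref_chars[anchor] == ins[length(ins)]) {
    ins <- c(ins[length(ins)], ins[-length(ins)])
    anchor <- anchor - 1L
  }
  list(anchor = anchor, seq = chars_to_seq(ins))
}

#' Majority-rule reference from a progenitor pileup
#'
#' The most frequent base at each position becomes the working reference
#' used for variant calling in the progenitor and all MA lines. Positions
#' with zero coverage, or with an exact tie, fall back to the FASTA base and
#' are flagged.
#'
#' @param pileup A [build_pileup()] result for the progenitor library.
#' @return List with `ref_chars` (majority reference) and `flagged`
#'   (positions that fell back to the FASTA base).
#' @export
progenitor_reference <- function(pileup) {
  stopifnot(inherits(pileup, "pileup"))
  tot <- pileup$counts_plus + pileup$counts_minus
  flagged <- integer()
  ref <- pileup$ref_chars
  for (p in seq_len(pileup$length)) {
    col <- tot[, p]
    if (sum(col) == 0L) { flagged <- c(flagged, p); next }
    mx <- max(col)
    winners <- BASES[col == mx]
    if (length(winners) > 1L) { flagged <- c(flagged, p); next }
    ref[p] <- winners
  }
  list(ref_chars = ref, flagged = flagged)
}
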