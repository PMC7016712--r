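# Minimal SAM 1.x writer/reader for the mapper's alignments.
#
# Split reads are encoded with a D CIGAR operation for the inter-segment
# deletion gap and I for insertions. Reads wrapping the circular origin are
# written at their wrapped start position; their CIGAR span may extend past
# the reference length (the circular convention used throughout the
# package).

#' Write alignments to SAM
#'
#' @param alignments List of `alignment` objects (from [map_reads()]).
#' @param genome The reference [annotated_genome()].
#' @param path Output path.
#' @param include_unmapped Write unmapped/ambiguous reads with FLAG 4?
#' @return Invisibly, `path`.
#' @export
write_sam <- function(alignments, genome, path, include_unmapped = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", genome$name, genome$length),
               sprintf("@PG\tID:mthet\tPN:mthet")), con)
  recs <- character()
  pos_key <- integer()
  for (al in alignments) {
    if (al$status != "mapped") {
      if (include_unmapped) {
        recs <- c(recs, sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*", al$id))
        pos_key <- c(pos_key, NA_integer_)
      }
      next
    }
    cigar <- alignment_cigar(al)
    pos <- wrap_pos(al$segments$ref_start[1], genome$length)
    flag <- if (al$strand == "-") 16L else 0L
    recs <- c(recs, sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                            al$id, flag, genome$name, pos, cigar, al$seq))
    pos_key <- c(pos_key, pos)
  }
  writeLines(recs[order(pos_key, na.last = TRUE)], con)
  invisible(path)
}

alignment_cigar <- function(al) {
  seg <- al$segments
  if (al$gap_type == "none") {
    sprintf("%dM", seg$read_end[1] - seg$read_start[1] + 1L)
  } else if (al$gap_type == "del") {
    sprintf("%dM%dD%dM", seg$read_end[1], al$gap_len,
            seg$read_end[2] - seg$read_start[2] + 1L)
  } else {
    sprintf("%dM%dI%dM", seg$read_end[1], al$gap_len,
            seg$read_end[2] - seg$read_start[2] + 1L)
  }
}

#' Read a SAM file produced by [write_sam()]
#'
#' Supports CIGAR strings of the forms aM, aM gD bM and aM gI bM.
#'
#' @param path SAM path.
#' @return List of `alignment` objects.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  lapply(lines, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) {
      return(structure(list(id = f[1], status = "unmapped"),
                       class = "alignment"))
    }
    pos <- as.integer(f[4])
    cig <- parse_cigar(f[6])
    seq <- f[10]
    len <- nchar(seq)
    if (nrow(cig) == 1L) {
      segments <- segments_list(pos, pos + cig$len[1] - 1L, 1L, cig$len[1])
      gap_type <- "none"; gap_len <- 0L
    } else {
      a <- cig$len[1]; g <- cig$len[2]; b <- cig$len[3]
      if (cig$op[2] == "D") {
        segments <- segments_list(c(pos, pos + a + g),
                                  c(pos + a - 1L, pos + a + g + b - 1L),
                                  c(1L, a + 1L), c(a, a + b))
        gap_type <- "del"; gap_len <- g
      } else {
        segments <- segments_list(c(pos, pos + a),
                                  c(pos + a - 1L, pos + a + b - 1L),
                                  c(1L, a + g + 1L), c(a, a + g + b))
        gap_type <- "ins"; gap_len <- g
      }
    }
    structure(list(id = f[1], status = "mapped",
                   segments = segments, gap_type = gap_type,
                   gap_len = gap_len,
                   ins_seq = if (gap_type == "ins")
                     substr(seq, cig$len[1] + 1L, cig$len[1] + gap_len)
                   else NULL,
                   ins_after_read = if (gap_type == "ins") cig$len[1] else NULL,
                   strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
                   seq = seq, matches = NA_integer_, identity = NA_real_,
                   score = NA_integer_),
              class = "alignment")
  })
}

parse_cigar <- function(cigar) {
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  data.frame(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^[0-9]+", "", toks), stringsAsFactors = FALSE)
}
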