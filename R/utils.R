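# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param seq Character scalar over the alphabet ACGTN.
#' @return Character scalar, the reverse complement.
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Fast scalar reverse complement for hot paths (no DNAString construction).
revcomp_fast <- function(s) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
}

# Character-vector variants used on hot paths (mapper, merger); avoids
# repeated DNAString construction.
revcomp_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}

seq_to_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

chars_to_seq <- function(chars) paste(chars, collapse = "")

#' Wrap 1-based positions onto a circular genome
#' @keywords internal
wrap_pos <- function(pos, len) ((pos - 1L) %% len) + 1L

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

validate_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stopf("%s must be a non-empty character scalar", what)
  }
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stopf("%s contains non-ACGTN characters", what)
  seq
}
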