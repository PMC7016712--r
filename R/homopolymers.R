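# A/T homopolymer census.
#
# Mononucleotide A/T runs of >= 8 bp are replication-slippage hotspots in
# nematode mtDNA; the census feeds the homopolymer-indel mutation-rate
# denominator n. The AT-rich control region is excluded because it is not
# considered for variant calling.

#' Census maximal A/T homopolymer runs
#'
#' Finds every maximal A-run and T-run in the genome (a run is maximal when
#' flanked by a different base or, for linear genomes, a sequence boundary;
#' for circular genomes a run may span the origin and is counted once).
#' `n_sites` totals the bases of runs with length >= `min_run`, never
#' counting bases that fall inside the excluded feature: a run straddling the
#' exclusion boundary contributes only its outside bases.
#'
#' @param genome An [annotated_genome()].
#' @param min_run Minimum run length for a run to qualify (>= 2; default 8).
#' @param exclude Feature role whose span is excluded (default `"AT-rich"`;
#'   `NULL` to exclude nothing).
#' @return An object of class `homopolymer_census`: a list with `runs`
#'   (data frame: `base`, `start`, `end`, `length`, `wrap`), `min_run`,
#'   `excluded_region` (feature row or `NULL`) and `n_sites`.
#' @export
census_homopolymers <- function(genome, min_run = 8L, exclude = "AT-rich") {
  stopifnot(inherits(genome, "annotated_genome"))
  if (!is_count(min_run, min = 2L)) stopf("min_run must be an integer >= 2")
  if (genome$length == 0L) stopf("empty sequence")
  chars <- seq_to_chars(genome$sequence)
  L <- genome$length
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(base = r$values, start = starts, end = ends,
                     length = r$lengths, wrap = FALSE,
                     stringsAsFactors = FALSE)
  # merge the origin-spanning run on circular genomes
  if (genome$circular && nrow(runs) > 1L &&
      runs$base[1] == runs$base[nrow(runs)]) {
    n <- nrow(runs)
    merged <- data.frame(base = runs$base[1], start = runs$start[n],
                         end = runs$end[1],
                         length = runs$length[1] + runs$length[n],
                         wrap = TRUE, stringsAsFactors = FALSE)
    runs <- rbind(merged, runs[-c(1L, n), ])
  }
  runs <- runs[runs$base %in% c("A", "T"), , drop = FALSE]
  rownames(runs) <- NULL

  excluded_feature <- if (is.null(exclude)) NULL else
    feature_by_role(genome, exclude)
  excl_pos <- feature_positions(excluded_feature, L)

  qual <- runs[runs$length >= min_run, , drop = FALSE]
  n_sites <- 0L
  if (nrow(qual)) {
    for (i in seq_len(nrow(qual))) {
      pos <- if (qual$wrap[i]) {
        c(seq.int(qual$start[i], L), seq.int(1L, qual$end[i]))
      } else seq.int(qual$start[i], qual$end[i])
      n_sites <- n_sites + sum(!(pos %in% excl_pos))
    }
  }
  structure(list(runs = runs, min_run = as.integer(min_run),
                 excluded_region = excluded_feature,
                 n_sites = as.integer(n_sites)),
            class = "homopolymer_census")
}

#' @export
print.homopolymer_census <- function(x, ...) {
  cat(sprintf("<homopolymer_census> %d A/T run(s), %d qualifying (>= %d bp), n_sites = %d\n",
              nrow(x$runs), sum(x$runs$length >= x$min_run), x$min_run,
              x$n_sites))
  invisible(x)
}

#' Homopolymer run length containing a position
#'
#' Returns the length of the maximal mononucleotide run of `base` covering
#' `pos`, or 0 when the base at `pos` differs from `base`.
#' @keywords internal
run_length_at <- function(chars, pos, base, circular = TRUE) {
  L <- length(chars)
  if (chars[pos] != base) return(0L)
  left <- pos
  right <- pos
  steps <- 0L
  while (steps < L) {
    nxt <- if (left == 1L) (if (circular) L else NA_integer_) else left - 1L
    if (is.na(nxt) || chars[nxt] != base || nxt == right) break
    left <- nxt; steps <- steps + 1L
  }
  steps <- 0L
  while (steps < L) {
    nxt <- if (right == L) (if (circular) 1L else NA_integer_) else right + 1L
    if (is.na(nxt) || chars[nxt] != base || nxt == left) break
    right <- nxt; steps <- steps + 1L
  }
  if (left <= right) right - left + 1L else (L - left + 1L) + right
}
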