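# Shared fixtures and oracles, built in code.

# memoized default study-condition genome
.genome_cache <- new.env(parent = emptyenv())
default_genome <- function(seed = 42L) {
  key <- paste0("g", seed)
  if (is.null(.genome_cache[[key]])) {
    .genome_cache[[key]] <- build_synthetic_genome(genome_spec(), seed = seed)
  }
  .genome_cache[[key]]
}

# small genome without repeat/AT-rich pathologies, for mapper properties
plain_genome_spec <- function(length = 4000L, at_rich = TRUE) {
  genome_spec(
    length = length,
    genes = data.frame(label = character(), start = integer(),
                       end = integer(), coding_end = integer()),
    other_features = if (at_rich) {
      data.frame(label = "AT-rich", role = "AT-rich",
                 start = length - 199L, end = length)
    } else {
      data.frame(label = character(), role = character(),
                 start = integer(), end = integer())
    },
    homopolymers = data.frame(base = character(), start = integer(),
                              length = integer()),
    motifs = data.frame(start = integer(), seq = character()),
    repeat_spec = NULL)
}

empty_state <- function() {
  lineage_state(data.frame(type = character(), position = integer(),
                           ref = character(), alt = character(),
                           length = integer(), frequency = numeric()))
}

# Ground-truth alignments for simulations without indel/deletion variants:
# each merged read is placed at its fragment's true origin.
truth_alignments <- function(merged, pairs, refs) {
  if (inherits(refs, "annotated_genome")) refs <- list(refs)
  names(refs) <- vapply(refs, function(g) g$name, character(1))
  src_of <- function(id) sub("_[0-9]+(:dup[0-9]+)?$", "", id)
  lapply(seq_len(nrow(merged)), function(i) {
    id <- merged$id[i]
    row <- pairs[match(sub(":dup[0-9]+$", "", id), pairs$id), ]
    seq <- merged$seq[i]
    if (row$orientation == "-") seq <- mthet:::revcomp_fast(seq)
    len <- nchar(seq)
    structure(list(
      id = id, status = "mapped",
      segments = mthet:::segments_list(row$start, row$start + len - 1L,
                                       1L, len),
      gap_type = "none", gap_len = 0L, strand = row$orientation,
      seq = seq, matches = len, identity = 1, score = len),
      class = "alignment")
  })
}

# brute-force homopolymer census oracle: O(L) scan comparing each base to
# its predecessor (linear sequences)
census_oracle <- function(seq, min_run) {
  chars <- strsplit(seq, "")[[1]]
  n_sites <- 0L
  run_base <- ""
  run_len <- 0L
  flush <- function(base, len) {
    if (base %in% c("A", "T") && len >= min_run) len else 0L
  }
  for (ch in chars) {
    if (ch == run_base) {
      run_len <- run_len + 1L
    } else {
      n_sites <- n_sites + flush(run_base, run_len)
      run_base <- ch
      run_len <- 1L
    }
  }
  n_sites + flush(run_base, run_len)
}

# construct a pileup with prescribed base counts at chosen sites
make_test_pileup <- function(genome, ref_counts, alt_counts, positions,
                             alt_base = "T") {
  L <- genome$length
  ref_chars <- strsplit(genome$sequence, "")[[1]]
  cp <- matrix(0L, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  cm <- cp
  for (i in seq_along(positions)) {
    p <- positions[i]
    rb <- ref_chars[p]
    cp[rb, p] <- ref_counts[i] %/% 2L
    cm[rb, p] <- ref_counts[i] - ref_counts[i] %/% 2L
    cp[alt_base, p] <- cp[alt_base, p] + alt_counts[i] %/% 2L
    cm[alt_base, p] <- cm[alt_base, p] + alt_counts[i] - alt_counts[i] %/% 2L
  }
  structure(list(
    counts_plus = cp, counts_minus = cm,
    ins = data.frame(pos = integer(), seq = character(),
                     plus = integer(), minus = integer()),
    del = data.frame(pos = integer(), len = integer(),
                     plus = integer(), minus = integer()),
    coverage = colSums(cp) + colSums(cm),
    ref_chars = ref_chars, genome_name = genome$name, length = L),
    class = "pileup")
}

empty_calls_df <- function() {
  data.frame(position = integer(), type = character(), alt = character(),
             length = integer(), frequency = numeric(),
             hp_run_length = integer())
}
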