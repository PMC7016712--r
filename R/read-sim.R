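# Paired-end read simulation with planted ground truth.
#
# Fragments are drawn uniformly from the circular mtgenome (and linear
# nuclear loci); each fragment independently carries each variant with
# probability equal to its truth frequency (molecular linkage between
# variants is not modeled). Fragment lengths are kept between read_length+10
# and 2*read_length-30 so every clean pair has a mergeable overlap, matching
# a library dominated by merged 250 bp pairs.

#' Read-simulation parameters
#'
#' @param read_length Read length in bp (default 250, paired-end).
#' @param fragment_mean,fragment_sd Fragment length distribution (bp).
#' @param error_rate Per-base i.i.d. substitution error probability
#'   (in [0, 0.05]).
#' @param mt_coverage Target mean mtDNA coverage (default 300, inside the
#'   200-360x range of the emulated libraries).
#' @param nuclear_coverage Target mean nuclear-locus coverage (default 5.5).
#' @param duplicate_fraction Fraction of emitted pairs duplicated as exact
#'   PCR copies.
#' @param adapter Adapter sequence (reads never run into it at these
#'   fragment lengths; kept for the preprocessing contract).
#' @return A `read_sim_params` list.
#' @export
read_sim_params <- function(read_length = 250L, fragment_mean = 320L,
                            fragment_sd = 40L, error_rate = 0.002,
                            mt_coverage = 300, nuclear_coverage = 5.5,
                            duplicate_fraction = 0.1,
                            adapter = "AGATCGGAAGAGCACACGTCT") {
  stopifnot(read_length >= 50L, fragment_mean >= read_length,
            error_rate >= 0, error_rate <= 0.05,
            mt_coverage > 0, nuclear_coverage > 0,
            duplicate_fraction >= 0, duplicate_fraction < 1)
  structure(list(read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 error_rate = error_rate, mt_coverage = mt_coverage,
                 nuclear_coverage = nuclear_coverage,
                 duplicate_fraction = duplicate_fraction, adapter = adapter),
            class = "read_sim_params")
}

#' Simulate paired-end reads from a lineage state
#'
#' @param genome Mitochondrial [annotated_genome()] (circular).
#' @param nuclear_refs List of linear [annotated_genome()] loci (or `NULL`).
#' @param state A `lineage_state` carrying truth variants and frequencies.
#' @param params A [read_sim_params()].
#' @param seed Integer seed; all randomness flows from it.
#' @param dir Optional directory: writes `<prefix>_R1.fastq`,
#'   `<prefix>_R2.fastq` and `<prefix>_truth.tsv` there.
#' @param prefix File prefix when `dir` is given.
#' @return Invisibly when writing, else a list with `pairs` (data frame:
#'   `id`, `seq1`, `qual1`, `seq2`, `qual2`, `source`, `haplotype`,
#'   `start`, `fragment_length`, `duplicate`), `truth` (variant table with
#'   frequencies) and `params`.
#' @export
simulate_reads <- function(genome, nuclear_refs, state, params, seed = 1L,
                           dir = NULL, prefix = "sim") {
  stopifnot(inherits(genome, "annotated_genome"),
            inherits(params, "read_sim_params"))
  if (!inherits(state, "lineage_state")) stopf("state must be a lineage_state")
  rl <- params$read_length
  min_frag <- rl + 10L
  max_frag <- 2L * rl - 30L
  if (params$fragment_mean < min_frag || params$fragment_mean > max_frag) {
    stopf("fragment_mean must lie in [%d, %d] for read length %d",
          min_frag, max_frag, rl)
  }

  with_seed(seed, {
    vars <- state$variants
    vars <- vars[vars$frequency > 0, , drop = FALSE]
    large <- vars[vars$type == "large_deletion", , drop = FALSE]
    point <- vars[vars$type != "large_deletion", , drop = FALSE]

    haps <- build_haplotypes(genome, large)

    n_frag <- round(params$mt_coverage * genome$length / params$fragment_mean)
    pairs <- simulate_fragment_pairs(haps, point, n_frag, params,
                                     source = "mt",
                                     circular = genome$circular)

    for (nr in nuclear_refs) {
      n_f <- max(1L, round(params$nuclear_coverage * nr$length /
                             params$fragment_mean))
      hap_n <- list(list(name = "ref", seq = nr$seq, chars = NULL,
                         prob = 1, shift_from = Inf, del_len = 0L,
                         length = nr$length))
      pairs <- rbind(pairs,
                     simulate_fragment_pairs(hap_n, point[0, ], n_f, params,
                                             source = nr$name,
                                             circular = FALSE))
    }

    # exact PCR duplicates of already-emitted pairs
    n_dup <- round(params$duplicate_fraction * nrow(pairs))
    if (n_dup > 0L) {
      idx <- sample.int(nrow(pairs), n_dup, replace = TRUE)
      dups <- pairs[idx, ]
      dups$id <- sprintf("%s:dup%d", dups$id, seq_len(n_dup))
      dups$duplicate <- TRUE
      pairs <- rbind(pairs, dups)
    }
    rownames(pairs) <- NULL

    out <- list(pairs = pairs, truth = state$variants, params = params,
                genome_name = genome$name)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_fastq(data.frame(id = pairs$id, seq = pairs$seq1,
                             qual = pairs$qual1),
                  file.path(dir, paste0(prefix, "_R1.fastq")))
      write_fastq(data.frame(id = pairs$id, seq = pairs$seq2,
                             qual = pairs$qual2),
                  file.path(dir, paste0(prefix, "_R2.fastq")))
      utils::write.table(state$variants,
                         file.path(dir, paste0(prefix, "_truth.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
  })
}

# Haplotype set: reference plus one sequence per large deletion (mutually
# exclusive molecules). Point-variant coordinates on a deletion haplotype
# shift by -del_len beyond the deleted segment; variants inside it drop out.
build_haplotypes <- function(genome, large) {
  haps <- list(list(name = "ref", seq = genome$sequence, prob = NA,
                    shift_from = Inf, del_len = 0L, del_start = NA_integer_,
                    length = genome$length))
  if (nrow(large)) {
    if (sum(large$frequency) > 1) stopf("large-deletion frequencies exceed 1")
    for (i in seq_len(nrow(large))) {
      d <- large[i, ]
      del_seq <- paste0(substr(genome$sequence, 1L, d$position - 1L),
                        substr(genome$sequence, d$position + d$length,
                               genome$length))
      haps[[length(haps) + 1L]] <-
        list(name = d$id, seq = del_seq, prob = d$frequency,
             shift_from = d$position, del_len = d$length,
             del_start = d$position, length = nchar(del_seq))
    }
    haps[[1]]$prob <- 1 - sum(large$frequency)
  } else {
    haps[[1]]$prob <- 1
  }
  haps
}

simulate_fragment_pairs <- function(haps, point, n_frag, params, source,
                                    circular) {
  rl <- params$read_length
  if (n_frag < 1L) n_frag <- 1L
  hap_idx <- sample.int(length(haps), n_frag, replace = TRUE,
                        prob = vapply(haps, function(h) h$prob, numeric(1)))
  lens <- pmin(pmax(round(stats::rnorm(n_frag, params$fragment_mean,
                                       params$fragment_sd)),
                    rl + 10L), 2L * rl - 30L)
  qual_char <- if (params$error_rate > 0) {
    rawToChar(as.raw(33L + min(40L, round(-10 * log10(params$error_rate)))))
  } else "I"

  seq1 <- character(n_frag); seq2 <- character(n_frag)
  starts <- integer(n_frag)
  orient <- character(n_frag)
  for (i in seq_len(n_frag)) {
    h <- haps[[hap_idx[i]]]
    len <- lens[i]
    start <- if (circular) sample.int(h$length, 1L) else
      sample.int(max(1L, h$length - len + 1L), 1L)
    if (!circular) len <- min(len, h$length - start + 1L)
    frag <- if (circular && start + len - 1L > h$length) {
      paste0(substr(h$seq, start, h$length),
             substr(h$seq, 1L, start + len - 1L - h$length))
    } else substr(h$seq, start, start + len - 1L)

    # apply point variants carried by this molecule
    if (nrow(point)) {
      frag <- apply_point_variants(frag, start, len, point, h, circular)
    }
    # adapters ligate to either fragment end: sequence half the fragments
    # in reverse orientation so merged reads carry both strands
    orient[i] <- if (stats::runif(1L) < 0.5) "-" else "+"
    if (orient[i] == "-") frag <- revcomp_fast(frag)
    flen <- nchar(frag)
    r1 <- substr(frag, 1L, min(rl, flen))
    r2 <- revcomp_fast(substr(frag, max(1L, flen - rl + 1L), flen))
    seq1[i] <- r1; seq2[i] <- r2; starts[i] <- start
  }

  # i.i.d. substitution errors
  if (params$error_rate > 0) {
    seq1 <- add_errors(seq1, params$error_rate)
    seq2 <- add_errors(seq2, params$error_rate)
  }
  data.frame(id = sprintf("%s_%06d", source, seq_len(n_frag)),
             seq1 = seq1, qual1 = strrep(qual_char, nchar(seq1)),
             seq2 = seq2, qual2 = strrep(qual_char, nchar(seq2)),
             source = source,
             haplotype = vapply(haps, function(h) h$name,
                                character(1))[hap_idx],
             start = starts, fragment_length = lens, orientation = orient,
             duplicate = FALSE, stringsAsFactors = FALSE)
}

apply_point_variants <- function(frag, start, len, point, hap, circular) {
  L <- hap$length
  chars <- NULL
  for (j in seq_len(nrow(point))) {
    v <- point[j, ]
    # haplotype coordinate of the variant
    vpos <- v$position
    if (is.finite(hap$shift_from)) {
      if (vpos >= hap$del_start && vpos < hap$del_start + hap$del_len) next
      if (vpos >= hap$del_start + hap$del_len) vpos <- vpos - hap$del_len
    }
    off <- vpos - start + 1L
    if (circular && off < 1L) off <- off + L
    if (off < 1L || off > nchar(frag)) next
    if (stats::runif(1L) > v$frequency) next
    frag <- apply_edit(frag, off, v)
  }
  frag
}

apply_edit <- function(frag, off, v) {
  if (v$type == "SNP") {
    substr(frag, off, off) <- v$alt
    frag
  } else if (v$type == "insertion") {
    paste0(substr(frag, 1L, off), v$alt, substr(frag, off + 1L, nchar(frag)))
  } else if (v$type == "deletion") {
    paste0(substr(frag, 1L, off - 1L),
           substr(frag, off + v$length, nchar(frag)))
  } else frag
}

add_errors <- function(seqs, rate) {
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    chars <- seq_to_chars(seqs[i])
    for (p in pos) chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
    seqs[i] <- chars_to_seq(chars)
  }
  seqs
}

#' Write reads to FASTQ
#' @param reads Data frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("@%s\n%s\n+\n%s", reads$id, reads$seq, reads$qual), con)
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ path.
#' @return Data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stopf("malformed FASTQ: %s", path)
  ids <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  ids <- sub("\\s.*$", "", ids)
  data.frame(id = ids, seq = lines[seq(2L, length(lines), by = 4L)],
             qual = lines[seq(4L, length(lines), by = 4L)],
             stringsAsFactors = FALSE)
}
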