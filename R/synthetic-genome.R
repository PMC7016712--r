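# Synthetic annotated-genome construction.
#
# The builder emits a ~14.4 kb circular mitochondrial genome whose
# architecture mirrors the nematode mtgenomes the pipeline targets: an
# AT-rich low-complexity control region, protein-coding genes translated
# with the invertebrate mitochondrial code, planted A/T homopolymer runs of
# 5-13 bp, and a pseudogene sharing a near-exact 36 bp direct repeat (one
# internal mismatch at offset 6) with a downstream gene, so that the
# repeat-mediated ~870 bp deletion geometry is reproducible.

#' Specification of a synthetic mitochondrial genome
#'
#' The defaults describe the study conditions emulated by the package: a
#' 14,420 bp circular genome, overall 75% AT, a 270 bp AT-rich region at 95%
#' AT, a pseudogene carrying the left copy of a 36 bp direct repeat whose
#' right copy sits 870 bp downstream inside the nd5-like gene (single C/T
#' mismatch at repeat offset 6, splitting it into 5 bp + 30 bp exact
#' subrepeats), and eight planted A/T homopolymer runs between 5 and 13 bp.
#'
#' @param length Genome length in bp.
#' @param at_fraction Background A+T fraction.
#' @param genes,other_features,homopolymers,motifs,repeat_spec Optional
#'   overrides for the planted architecture (same shapes as the defaults);
#'   pass `NULL` for `repeat_spec` to omit the repeat pair.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(length = 14420L, at_fraction = 0.75, genes = NULL,
                        other_features = NULL, homopolymers = NULL,
                        motifs = NULL, repeat_spec = "default") {
  stopifnot(length >= 100L, at_fraction > 0, at_fraction <= 1)
  default_genes <- data.frame(
    label = c("nduo-6", "nduo-1", "atp-6", "nduo-3", "ctc-3", "nduo-4", "nduo-5"),
    start = c(541L, 2101L, 3203L, 5001L, 6401L, 7901L, 12574L),
    end = c(1020L, 2940L, 3580L, 5420L, 7000L, 8260L, 14148L),
    coding_end = c(1020L, 2940L, 3562L, 5420L, 7000L, 8260L, 14148L),
    stringsAsFactors = FALSE)
  default_other <- data.frame(
    label = c("tRNA-Val", "tRNA-Ser", "l-rRNA", "psi-nd5", "AT-rich"),
    role = c("tRNA", "tRNA", "rRNA", "pseudogene", "AT-rich"),
    start = c(380L, 3700L, 10901L, 12230L, 14151L),
    end = c(440L, 3760L, 11900L, 12560L, 14420L),
    stringsAsFactors = FALSE)
  default_hp <- data.frame(
    base = c("T", "A", "A", "T", "T", "A", "T", "T"),
    start = c(570L, 3565L, 5500L, 8305L, 9400L, 10200L, 12200L, 6515L),
    length = c(8L, 10L, 12L, 9L, 13L, 8L, 5L, 7L),
    stringsAsFactors = FALSE)
  # serine codon planted so that a C>T at the following position is a
  # second-codon-position S>L substitution
  default_motifs <- data.frame(start = 3413L, seq = "TCA",
                               stringsAsFactors = FALSE)
  default_repeat <- list(left_start = 12473L, right_start = 13343L,
                         length = 36L, mismatch_offset = 6L,
                         left_base = "C", right_base = "T")
  structure(list(
    name = "mt_synth",
    length = as.integer(length),
    at_fraction = at_fraction,
    at_rich_fraction = 0.95,
    genes = if (is.null(genes)) default_genes else genes,
    other_features = if (is.null(other_features)) default_other else other_features,
    homopolymers = if (is.null(homopolymers)) default_hp else homopolymers,
    motifs = if (is.null(motifs)) default_motifs else motifs,
    repeat_spec = if (identical(repeat_spec, "default")) default_repeat
                  else repeat_spec),
    class = "genome_spec")
}

#' Build a synthetic annotated genome
#'
#' Deterministic for a fixed seed. Planted homopolymer runs are maximal
#' (flanked by C/G), accidental A/T runs reaching the census threshold (8 bp)
#' outside the AT-rich region are broken, and the planted direct-repeat pair
#' is recoverable by [find_direct_repeats()].
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed governing all randomness.
#' @return An [annotated_genome()] with attributes `planted_homopolymers`,
#'   `planted_repeat` and `spec` recording the ground truth.
#' @export
build_synthetic_genome <- function(spec = genome_spec(), seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(seed, {
    L <- spec$length
    p_at <- spec$at_fraction / 2
    p_cg <- (1 - spec$at_fraction) / 2
    probs <- c(A = p_at, C = p_cg, G = p_cg, T = p_at)
    chars <- sample(BASES, L, replace = TRUE, prob = probs[BASES])

    gene_feats <- if (nrow(spec$genes))
      data.frame(label = spec$genes$label, role = "gene",
                 start = spec$genes$start, end = spec$genes$end,
                 strand = "+", wrap = FALSE,
                 reading_frame_start = spec$genes$start,
                 coding_end = spec$genes$coding_end,
                 stringsAsFactors = FALSE) else empty_features()
    other_feats <- if (nrow(spec$other_features))
      data.frame(label = spec$other_features$label,
                 role = spec$other_features$role,
                 start = spec$other_features$start,
                 end = spec$other_features$end,
                 strand = "+", wrap = FALSE,
                 reading_frame_start = NA_integer_,
                 coding_end = NA_integer_, stringsAsFactors = FALSE)
      else empty_features()
    feats <- rbind(gene_feats, other_feats)
    if (any(feats$end > L)) stopf("spec features exceed genome length %d", L)
    check_disjoint_features(feats)

    # AT-rich region: resample at its own composition
    atr <- feats[feats$role == "AT-rich", ]
    atr_idx <- integer()
    if (nrow(atr)) {
      atr_idx <- seq.int(atr$start[1], atr$end[1])
      p_at2 <- spec$at_rich_fraction / 2
      p_cg2 <- (1 - spec$at_rich_fraction) / 2
      chars[atr_idx] <- sample(BASES, length(atr_idx), replace = TRUE,
                               prob = c(p_at2, p_cg2, p_cg2, p_at2))
    }

    # gene bodies: random sense codons ending in TAA
    code <- mito_genetic_code()
    sense <- names(code)[code != "*"]
    codon_w <- vapply(strsplit(sense, ""), function(cs)
      prod(probs[cs]), numeric(1))
    for (i in seq_len(nrow(spec$genes))) {
      g <- spec$genes[i, ]
      span <- g$coding_end - g$start + 1L
      if (span %% 3L != 0L) stopf("gene %s coding span not a codon multiple",
                                  g$label)
      n_codon <- span %/% 3L
      body <- sample(sense, n_codon - 1L, replace = TRUE, prob = codon_w)
      chars[seq.int(g$start, g$coding_end)] <-
        seq_to_chars(paste0(paste(body, collapse = ""), "TAA"))
    }

    for (i in seq_len(nrow(spec$motifs))) {
      m <- spec$motifs[i, ]
      chars[seq.int(m$start, m$start + nchar(m$seq) - 1L)] <- seq_to_chars(m$seq)
    }

    # direct-repeat pair with single internal mismatch
    rs <- spec$repeat_spec
    if (!is.null(rs)) {
      rep_core <- sample(BASES, rs$length, replace = TRUE, prob = probs[BASES])
      left <- rep_core; left[rs$mismatch_offset] <- rs$left_base
      right <- rep_core; right[rs$mismatch_offset] <- rs$right_base
      chars[seq.int(rs$left_start, rs$left_start + rs$length - 1L)] <- left
      chars[seq.int(rs$right_start, rs$right_start + rs$length - 1L)] <- right
      # the repeat must not extend by chance: force the flanking bases of
      # the two copies to disagree
      for (delta in c(-1L, rs$length)) {
        pl <- rs$left_start + delta; pr <- rs$right_start + delta
        if (pl >= 1L && pr <= L && chars[pl] == chars[pr]) {
          chars[pr] <- setdiff(BASES, chars[pl])[1]
        }
      }
    }

    # planted homopolymers, flanked by C/G so the runs are maximal
    protected <- logical(L)
    protected[atr_idx] <- TRUE
    for (i in seq_len(nrow(spec$homopolymers))) {
      h <- spec$homopolymers[i, ]
      idx <- seq.int(h$start, h$start + h$length - 1L)
      chars[idx] <- h$base
      flank <- if (h$base == "A") "C" else "G"
      if (h$start > 1L) chars[h$start - 1L] <- flank
      if (h$start + h$length <= L) chars[h$start + h$length] <- flank
      protected[idx] <- TRUE
    }
    if (!is.null(rs)) {
      protected[seq.int(rs$left_start, rs$left_start + rs$length - 1L)] <- TRUE
      protected[seq.int(rs$right_start, rs$right_start + rs$length - 1L)] <- TRUE
    }

    # break accidental A/T runs that would reach the census threshold
    repeat {
      r <- rle(chars)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      bad <- which(r$values %in% c("A", "T") & r$lengths >= 8L)
      broke <- FALSE
      for (b in bad) {
        idx <- seq.int(starts[b], ends[b])
        if (any(protected[idx])) next
        chars[idx[ceiling(length(idx) / 2)]] <- "C"
        broke <- TRUE
      }
      if (!broke) break
    }

    genome <- annotated_genome(spec$name, chars_to_seq(chars),
                               circular = TRUE, features = feats)
    attr(genome, "planted_homopolymers") <- spec$homopolymers
    attr(genome, "planted_repeat") <- rs
    attr(genome, "spec") <- spec
    genome
  })
}

check_disjoint_features <- function(feats) {
  # pseudogene/repeat nesting aside, planned features must not overlap
  n <- nrow(feats)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (feats$start[i] <= feats$end[j] && feats$start[j] <= feats$end[i]) {
      stopf("features '%s' and '%s' overlap", feats$label[i], feats$label[j])
    }
  }
  invisible(TRUE)
}

#' Synthetic single-copy nuclear reference loci
#'
#' Three independent linear references standing in for the single-copy
#' nuclear genes used as the copy-number normalizer (ama-1, efl-2, ego-1).
#'
#' @param lengths Integer vector of locus lengths.
#' @param labels Locus names.
#' @param seed Integer seed.
#' @return List of linear [annotated_genome()] objects.
#' @export
synthetic_nuclear_refs <- function(lengths = c(2000L, 1500L, 2400L),
                                   labels = c("ama-1", "efl-2", "ego-1"),
                                   seed = 1L) {
  stopifnot(length(lengths) == length(labels))
  with_seed(seed + 7L, {
    lapply(seq_along(labels), function(i) {
      annotated_genome(labels[i],
                       chars_to_seq(sample(BASES, lengths[i], replace = TRUE,
                                           prob = c(.3, .2, .2, .3))),
                       circular = FALSE)
    })
  })
}
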