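# Protein-effect annotation of variant calls.
#
# Genes are translated with genetic code table 5 (invertebrate
# mitochondrial), the code used by nematode mtDNA. A gene annotation may
# extend past its stop codon (e.g. a 3' homopolymer inside the annotated
# interval); variants located after the stop codon have no protein effect.

MITO_CODE_ID <- "SGC4"  # NCBI translation table 5

mito_genetic_code <- function() Biostrings::getGeneticCode(MITO_CODE_ID)

#' Annotate the protein-level effect of a variant call
#'
#' @param call A list or one-row data frame with at least `position`
#'   (1-based), `type` (`"SNP"`, `"insertion"`, `"deletion"`,
#'   `"large_deletion"`), `ref`, `alt` and, for deletions, `length`.
#' @param genome An [annotated_genome()] whose gene features carry
#'   `reading_frame_start`.
#' @return An object of class `protein_effect`: list with `effects`
#'   (character vector drawn from `none`, `silent`, `substitution`,
#'   `frameshift`, `truncation`, `alternative_start`, `non_coding`),
#'   `aa_from`, `aa_to` (single letters, substitutions only), `feature`
#'   (label or `NA`) and `feature_role`.
#' @export
annotate_effect <- function(call, genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  call <- as.list(call)
  pos <- as.integer(call$position)
  if (is.na(pos) || pos < 1L || pos > genome$length) {
    stopf("call position %s outside genome [1, %d]", call$position,
          genome$length)
  }
  type <- call$type
  del_len <- if (!is.null(call$length)) as.integer(call$length) else
    if (!is.null(call$ref)) nchar(call$ref) - nchar(call$alt) else 1L

  if (identical(type, "large_deletion")) {
    return(annotate_large_deletion(pos, del_len, genome))
  }

  feat <- containing_feature(genome, pos)
  if (is.null(feat)) {
    return(protein_effect("non_coding", feature = NA_character_,
                          feature_role = "intergenic"))
  }
  if (feat$role != "gene") {
    return(protein_effect("non_coding", feature = feat$label,
                          feature_role = feat$role))
  }

  cds <- gene_coding_info(genome, feat)
  # position after the stop codon (or before the reading frame): no effect
  if (pos > cds$stop_end || pos < cds$frame_start) {
    return(protein_effect("none", feature = feat$label,
                          feature_role = "gene"))
  }

  if (identical(type, "SNP")) {
    codon_idx <- (pos - cds$frame_start) %/% 3L
    codon_start <- cds$frame_start + 3L * codon_idx
    codon <- substr(genome$sequence, codon_start, codon_start + 2L)
    offset <- pos - codon_start + 1L
    alt_codon <- codon
    substr(alt_codon, offset, offset) <- toupper(call$alt)
    code <- mito_genetic_code()
    aa_from <- unname(code[codon])
    aa_to <- unname(code[alt_codon])
    if (is.na(aa_to)) stopf("invalid alt base '%s'", call$alt)
    eff <- if (aa_from == aa_to) "silent"
           else if (aa_to == "*") "truncation"
           else "substitution"
    return(protein_effect(eff, aa_from = aa_from, aa_to = aa_to,
                          feature = feat$label, feature_role = "gene"))
  }

  # small indel inside the coding region
  indel_len <- if (identical(type, "insertion")) nchar(call$alt) - nchar(call$ref)
               else abs(del_len)
  if (indel_len %% 3L != 0L) {
    return(protein_effect("frameshift", feature = feat$label,
                          feature_role = "gene"))
  }
  protein_effect("none", feature = feat$label, feature_role = "gene")
}

annotate_large_deletion <- function(pos, del_len, genome) {
  del_start <- pos
  del_end <- pos + del_len - 1L
  effects <- character()
  labels <- character()
  for (i in seq_len(nrow(genome$features))) {
    f <- genome$features[i, ]
    if (f$role != "gene") next
    if (f$start >= del_start && f$start <= del_end && f$end > del_end) {
      # the gene's start (and original start codon) is removed: translation
      # can only resume from an internal alternative start, truncating the
      # protein
      effects <- c(effects, "alternative_start", "truncation")
      labels <- c(labels, f$label)
    } else if (f$start >= del_start && f$end <= del_end) {
      effects <- c(effects, "truncation")
      labels <- c(labels, f$label)
    } else if (f$end >= del_start && f$end <= del_end && f$start < del_start) {
      effects <- c(effects, "truncation")
      labels <- c(labels, f$label)
    }
  }
  if (!length(effects)) effects <- "non_coding"
  protein_effect(unique(effects),
                 feature = if (length(labels)) paste(unique(labels), collapse = "..")
                           else NA_character_,
                 feature_role = if (length(labels)) "gene" else "intergenic")
}

protein_effect <- function(effects, aa_from = NA_character_,
                           aa_to = NA_character_, feature = NA_character_,
                           feature_role = NA_character_) {
  structure(list(effects = effects, aa_from = aa_from, aa_to = aa_to,
                 feature = feature, feature_role = feature_role),
            class = "protein_effect")
}

#' @export
#' @method format protein_effect
format.protein_effect <- function(x, ...) {
  if (identical(x$effects, "substitution")) {
    sprintf("%s -> %s Sub", x$aa_from, x$aa_to)
  } else if (identical(x$effects, "non_coding")) {
    sprintf("non-coding (%s)", x$feature_role)
  } else {
    paste(vapply(x$effects, function(e) switch(e,
      none = "None", silent = "Silent", frameshift = "Frame Shift",
      truncation = "Truncation", alternative_start = "Alternative Start Codon",
      e), character(1)), collapse = ", ")
  }
}

#' @export
print.protein_effect <- function(x, ...) {
  cat(sprintf("<protein_effect> %s [%s]\n", format(x),
              if (is.na(x$feature)) "-" else x$feature))
  invisible(x)
}

containing_feature <- function(genome, pos) {
  feats <- genome$features
  if (!nrow(feats)) return(NULL)
  hit <- which(mapply(function(s, e, w) {
    if (isTRUE(w)) pos >= s || pos <= e else pos >= s && pos <= e
  }, feats$start, feats$end, feats$wrap))
  if (!length(hit)) return(NULL)
  prio <- match(feats$role[hit],
                c("gene", "tRNA", "rRNA", "pseudogene", "AT-rich", "intergenic"))
  feats[hit[which.min(prio)], ]
}

# Coding geometry of a gene: reading-frame start and the last base of its
# stop codon (capped at the annotated/declared coding end if no stop found).
gene_coding_info <- function(genome, feat) {
  frame_start <- if (!is.na(feat$reading_frame_start)) feat$reading_frame_start
                 else feat$start
  coding_cap <- if (!is.na(feat$coding_end)) feat$coding_end else feat$end
  code <- mito_genetic_code()
  pos <- frame_start
  stop_end <- coding_cap
  while (pos + 2L <= coding_cap) {
    codon <- substr(genome$sequence, pos, pos + 2L)
    aa <- code[codon]
    if (!is.na(aa) && aa == "*") { stop_end <- pos + 2L; break }
    pos <- pos + 3L
  }
  list(frame_start = frame_start, stop_end = stop_end)
}
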