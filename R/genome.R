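# Annotated circular mitochondrial genome container and IO.
#
# Coordinates are 1-based inclusive everywhere user-visible. Features may
# wrap the circular origin via the `wrap` flag, in which case start > end
# and the feature covers start..length plus 1..end.

FEATURE_ROLES <- c("gene", "tRNA", "rRNA", "pseudogene", "AT-rich", "intergenic")

#' Construct an annotated genome
#'
#' An `annotated_genome` bundles a single DNA sequence (uppercase ACGT),
#' a circularity flag and a feature table. It is the reference container used
#' by the homopolymer census, repeat search, mapper and caller.
#'
#' @param name Sequence name (used as the reference name in SAM/VCF output).
#' @param sequence DNA string, alphabet ACGT (lowercase accepted, normalized).
#' @param circular Logical; `TRUE` for mitochondrial genomes.
#' @param features Data frame with columns `label`, `role`, `start`, `end`,
#'   `strand`, and optionally `wrap` (logical, origin-spanning) and
#'   `reading_frame_start` / `coding_end` for genes.
#' @return An object of class `annotated_genome` with elements `name`,
#'   `sequence`, `length`, `circular`, `features`.
#' @export
annotated_genome <- function(name, sequence, circular = TRUE,
                             features = empty_features()) {
  sequence <- validate_dna(sequence, "genome sequence")
  features <- validate_features(features, nchar(sequence))
  structure(
    list(name = as.character(name), sequence = sequence,
         length = nchar(sequence), circular = isTRUE(circular),
         features = features),
    class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d bp, %s, %d feature(s)\n",
              x$name, x$length, if (x$circular) "circular" else "linear",
              nrow(x$features)))
  invisible(x)
}

empty_features <- function() {
  data.frame(label = character(), role = character(),
             start = integer(), end = integer(), strand = character(),
             wrap = logical(), reading_frame_start = integer(),
             coding_end = integer(), stringsAsFactors = FALSE)
}

validate_features <- function(features, genome_len) {
  if (is.null(features)) return(empty_features())
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  required <- c("label", "role", "start", "end", "strand")
  missing <- setdiff(required, names(features))
  if (length(missing)) stopf("feature table lacks column(s): %s",
                             paste(missing, collapse = ", "))
  if (!"wrap" %in% names(features)) features$wrap <- FALSE
  features$wrap[is.na(features$wrap)] <- FALSE
  if (!"reading_frame_start" %in% names(features)) {
    features$reading_frame_start <- ifelse(features$role == "gene",
                                           features$start, NA_integer_)
  }
  if (!"coding_end" %in% names(features)) {
    features$coding_end <- ifelse(features$role == "gene",
                                  features$end, NA_integer_)
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    if (!f$role %in% FEATURE_ROLES) {
      stopf("feature '%s' has unknown role '%s'", f$label, f$role)
    }
    if (is.na(f$start) || is.na(f$end) || f$start < 1L ||
        f$start > genome_len || f$end < 1L || f$end > genome_len) {
      stopf("feature '%s' lies outside [1, %d]", f$label, genome_len)
    }
    if (!f$wrap && f$start > f$end) {
      stopf("feature '%s' has start > end without wrap flag", f$label)
    }
    if (!f$strand %in% c("+", "-")) {
      stopf("feature '%s' has invalid strand '%s'", f$label, f$strand)
    }
  }
  if (sum(features$role == "AT-rich") > 1L) {
    stopf("at most one AT-rich feature is allowed")
  }
  features
}

#' Load a genome from FASTA plus a feature table
#'
#' @param fasta_path Path to a single-record FASTA file.
#' @param features_path Optional path to a tab-separated feature table with
#'   header columns `label`, `role`, `start`, `end`, `strand` (and optional
#'   `wrap`, `reading_frame_start`, `coding_end`).
#' @param circular Logical circularity flag (default `TRUE`).
#' @return An [annotated_genome()].
#' @export
load_genome <- function(fasta_path, features_path = NULL, circular = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) {
    stopf("expected exactly one FASTA record in '%s', found %d",
          fasta_path, length(seqs))
  }
  features <- if (is.null(features_path)) empty_features() else
    utils::read.delim(features_path, stringsAsFactors = FALSE)
  annotated_genome(name = sub("\\s.*$", "", names(seqs)[1]),
                   sequence = as.character(seqs[[1]]),
                   circular = circular, features = features)
}

#' Write a genome to FASTA (and optionally its feature table)
#'
#' @param genome An [annotated_genome()].
#' @param fasta_path Output FASTA path.
#' @param features_path Optional output TSV path for the feature table.
#' @return Invisibly, `fasta_path`.
#' @export
write_genome <- function(genome, fasta_path, features_path = NULL) {
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$name
  Biostrings::writeXStringSet(set, fasta_path, width = 70L)
  if (!is.null(features_path)) {
    utils::write.table(genome$features, features_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Extract the single feature with a given role, or NULL
#' @keywords internal
feature_by_role <- function(genome, role) {
  idx <- which(genome$features$role == role)
  if (!length(idx)) return(NULL)
  genome$features[idx[1], ]
}

#' Positions covered by a feature, unwrapping circular features
#' @keywords internal
feature_positions <- function(feature, genome_len) {
  if (is.null(feature)) return(integer())
  if (isTRUE(feature$wrap)) {
    c(seq.int(feature$start, genome_len), seq.int(1L, feature$end))
  } else {
    seq.int(feature$start, feature$end)
  }
}
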