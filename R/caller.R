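# Heteroplasmy calling from a pileup.
#
# A variant is reported when it clears: minimum coverage, minimum raw
# supporting reads, an upper-tail exact-binomial p-value against the
# sequencing-error null, and a strand-bias screen (an exact binomial test of
# the support's strand split against the site's strand composition, applied
# only when the support exceeds the bias trigger). A permissive mode drops
# the coverage/support/p gates to screen for variants segregating at
# extremely low frequency.

#' Calling thresholds
#'
#' Defaults follow the discovery settings the pipeline emulates: coverage
#' >= 100, >= 4 raw supporting reads, p < 1e-6, and a strand-bias p value
#' > 1e-5 required only when one strand carries more than 65% of the
#' support.
#'
#' @param min_coverage Minimum site coverage.
#' @param min_support Minimum raw supporting reads.
#' @param max_p Maximum binomial p-value.
#' @param strand_bias_trigger Strand fraction above which the bias test is
#'   applied (in (0.5, 1]).
#' @param strand_bias_min_p Minimum strand-bias p-value to keep a call.
#' @param error_rate Per-base error probability of the binomial null.
#' @return A `call_thresholds` list.
#' @export
call_thresholds <- function(min_coverage = 100L, min_support = 4L,
                            max_p = 1e-6, strand_bias_trigger = 0.65,
                            strand_bias_min_p = 1e-5, error_rate = 0.002) {
  stopifnot(min_coverage > 0, min_support > 0, max_p > 0,
            strand_bias_trigger > 0.5, strand_bias_trigger <= 1,
            strand_bias_min_p > 0, error_rate > 0, error_rate < 1)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_support = as.integer(min_support), max_p = max_p,
                 strand_bias_trigger = strand_bias_trigger,
                 strand_bias_min_p = strand_bias_min_p,
                 error_rate = error_rate),
            class = "call_thresholds")
}

empty_calls <- function() {
  data.frame(position = integer(), type = character(), ref = character(),
             alt = character(), length = integer(), coverage = integer(),
             support = integer(), frequency = numeric(), p_value = numeric(),
             support_plus = integer(), support_minus = integer(),
             strand_bias_pass = logical(), hp_run_length = integer(),
             change = character(), feature = character(), effect = character(),
             de_novo = logical(), stringsAsFactors = FALSE)
}

#' Call site-level variants (SNPs and small indels) from a pileup
#'
#' Frequencies are support/coverage, reported to three decimals. For base
#' substitutions, coverage is the total base coverage at the site; for
#' deletion events the deletion-carrying reads are added to the denominator
#' (they leave no base count at the deleted position).
#'
#' @param pileup A [build_pileup()] result.
#' @param thresholds A [call_thresholds()].
#' @param reference Optional majority reference character vector (from
#'   [progenitor_reference()]); defaults to the pileup's FASTA reference.
#' @param permissive Drop the coverage, support and p-value gates (the
#'   strand-bias screen is retained); used to screen progenitor libraries
#'   for variants at any frequency.
#' @param genome Optional [annotated_genome()] used to annotate feature
#'   context and protein effects.
#' @return Data frame of variant calls (one row per position/alt).
#' @export
call_site_variants <- function(pileup, thresholds = call_thresholds(),
                               reference = NULL, permissive = FALSE,
                               genome = NULL) {
  stopifnot(inherits(pileup, "pileup"), inherits(thresholds, "call_thresholds"))
  ref <- if (is.null(reference)) pileup$ref_chars else reference
  L <- pileup$length
  tot <- pileup$counts_plus + pileup$counts_minus
  cov <- pileup$coverage
  calls <- list()

  ref_idx <- match(ref, BASES)
  # candidate SNP sites: any non-reference base observed
  alt_mask <- tot > 0L
  alt_mask[cbind(ref_idx, seq_len(L))] <- FALSE
  cand <- which(alt_mask, arr.ind = TRUE)
  for (r in seq_len(nrow(cand))) {
    b <- cand[r, 1L]; p <- cand[r, 2L]
    support <- tot[b, p]
    coverage <- cov[p]
    row <- make_call(
      position = p, type = "SNP", ref = ref[p], alt = BASES[b], length = 1L,
      coverage = coverage, support = support,
      support_plus = pileup$counts_plus[b, p],
      support_minus = pileup$counts_minus[b, p],
      cov_plus = sum(pileup$counts_plus[, p]),
      cov_minus = sum(pileup$counts_minus[, p]),
      thresholds = thresholds, permissive = permissive)
    if (!is.null(row)) calls[[length(calls) + 1L]] <- row
  }

  for (r in seq_len(nrow(pileup$ins))) {
    e <- pileup$ins[r, ]
    support <- e$plus + e$minus
    coverage <- cov[e$pos]
    row <- make_call(
      position = e$pos, type = "insertion", ref = ref[e$pos],
      alt = paste0(ref[e$pos], e$seq), length = nchar(e$seq),
      coverage = coverage, support = support,
      support_plus = e$plus, support_minus = e$minus,
      cov_plus = sum(pileup$counts_plus[, e$pos]),
      cov_minus = sum(pileup$counts_minus[, e$pos]),
      thresholds = thresholds, permissive = permissive)
    if (!is.null(row)) calls[[length(calls) + 1L]] <- row
  }
  for (r in seq_len(nrow(pileup$del))) {
    e <- pileup$del[r, ]
    support <- e$plus + e$minus
    coverage <- cov[e$pos] + support
    anchor <- wrap_pos(e$pos - 1L, L)
    row <- make_call(
      position = anchor, type = "deletion", ref = ref[anchor], alt = "-",
      length = e$len, coverage = coverage, support = support,
      support_plus = e$plus, support_minus = e$minus,
      cov_plus = sum(pileup$counts_plus[, e$pos]) + e$plus,
      cov_minus = sum(pileup$counts_minus[, e$pos]) + e$minus,
      thresholds = thresholds, permissive = permissive)
    if (!is.null(row)) calls[[length(calls) + 1L]] <- row
  }
  out <- if (length(calls)) do.call(rbind, calls) else empty_calls()
  if (nrow(out)) {
    out <- annotate_calls(out, pileup, genome)
    out <- out[order(out$position, out$type), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

make_call <- function(position, type, ref, alt, length, coverage, support,
                      support_plus, support_minus, cov_plus, cov_minus,
                      thresholds, permissive) {
  if (support == 0L || coverage == 0L) return(NULL)
  p_value <- stats::pbinom(support - 1L, coverage, thresholds$error_rate,
                           lower.tail = FALSE)
  sb <- strand_bias_test(support_plus, support_minus, cov_plus, cov_minus,
                         thresholds)
  if (!permissive) {
    if (coverage < thresholds$min_coverage) return(NULL)
    if (support < thresholds$min_support) return(NULL)
    if (p_value >= thresholds$max_p) return(NULL)
    if (!sb) return(NULL)
  }
  data.frame(position = position, type = type, ref = ref, alt = alt,
             length = as.integer(length), coverage = as.integer(coverage),
             support = as.integer(support),
             frequency = round(support / coverage, 3L), p_value = p_value,
             support_plus = as.integer(support_plus),
             support_minus = as.integer(support_minus),
             strand_bias_pass = sb, hp_run_length = NA_integer_,
             change = NA_character_, feature = NA_character_,
             effect = NA_character_, de_novo = NA,
             stringsAsFactors = FALSE)
}

#' Strand-bias filter
#'
#' Passes when the supporting reads' strand split does not exceed the
#' trigger fraction, or when an exact two-sided binomial test of the split
#' against the site's strand coverage proportions has p above the minimum.
#'
#' @param call One-row data frame (or list) with `support_plus`,
#'   `support_minus`, `cov_plus`, `cov_minus`.
#' @param thresholds A [call_thresholds()].
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
strand_bias_filter <- function(call, thresholds = call_thresholds()) {
  call <- as.list(call)
  strand_bias_test(call$support_plus, call$support_minus,
                   call$cov_plus, call$cov_minus, thresholds)
}

strand_bias_test <- function(sp, sm, cp, cm, thresholds) {
  n <- sp + sm
  if (n == 0L) return(TRUE)
  frac <- max(sp, sm) / n
  if (frac <= thresholds$strand_bias_trigger) return(TRUE)
  expected <- if (cp + cm > 0L) cp / (cp + cm) else 0.5
  pv <- stats::binom.test(sp, n, p = expected)$p.value
  pv > thresholds$strand_bias_min_p
}

# Attach homopolymer run length, the "(B)n -> (B)n+/-1" change string, and
# feature/effect context.
annotate_calls <- function(calls, pileup, genome) {
  chars <- pileup$ref_chars
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    if (cl$type == "SNP") {
      calls$change[i] <- sprintf("%s -> %s", cl$ref, cl$alt)
      calls$hp_run_length[i] <- 0L
    } else {
      base <- if (cl$type == "insertion") substr(cl$alt, 2L, 2L) else
        chars[cl$position + (cl$type == "deletion")]
      # run length measured just right of the anchor for insertions, at the
      # first deleted base for deletions
      probe <- if (cl$type == "insertion") cl$position + 1L else
        cl$position + 1L
      probe <- wrap_pos(probe, pileup$length)
      n_run <- run_length_at(chars, probe, base)
      calls$hp_run_length[i] <- n_run
      if (cl$length == 1L && n_run >= 2L) {
        delta <- if (cl$type == "insertion") 1L else -1L
        calls$change[i] <- sprintf("(%s)%d -> (%s)%d", base, n_run, base,
                                   n_run + delta)
      } else {
        calls$change[i] <- sprintf("%s%d%s",
                                   if (cl$type == "insertion") "+" else "-",
                                   cl$length,
                                   if (cl$type == "insertion")
                                     substr(cl$alt, 2L, nchar(cl$alt)) else "")
      }
    }
    if (!is.null(genome)) {
      eff <- annotate_effect(list(position = cl$position, type = cl$type,
                                  ref = cl$ref, alt = cl$alt,
                                  length = cl$length), genome)
      calls$feature[i] <- eff$feature
      calls$effect[i] <- format(eff)
    }
  }
  calls
}

#' Left-align (normalize) an indel call
#'
#' Shifts an insertion or deletion to its leftmost equivalent reference
#' placement and records the containing homopolymer run length plus the
#' canonical change representation. Calls produced by [call_site_variants()]
#' are already canonical; this operation is exposed for externally supplied
#' calls.
#'
#' @param call One-row call data frame (columns as in [call_site_variants()]).
#' @param genome The reference [annotated_genome()].
#' @return The normalized call row.
#' @export
left_align_indel <- function(call, genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  chars <- seq_to_chars(genome$sequence)
  if (call$type == "deletion") {
    p0 <- call$position + 1L  # first deleted base, anchor convention
    p <- left_align_deletion(chars, p0, call$length)
    call$position <- p - 1L
    call$ref <- chars[max(p - 1L, 1L)]
  } else if (call$type == "insertion") {
    ins_seq <- substr(call$alt, 2L, nchar(call$alt))
    norm <- left_align_insertion(chars, call$position, ins_seq)
    call$position <- norm$anchor
    call$ref <- chars[max(norm$anchor, 1L)]
    call$alt <- paste0(call$ref, norm$seq)
  }
  # refresh run-length/change annotation
  probe <- wrap_pos(call$position + 1L, genome$length)
  base <- if (call$type == "insertion") substr(call$alt, 2L, 2L) else
    chars[probe]
  n_run <- run_length_at(chars, probe, base)
  call$hp_run_length <- n_run
  if (call$length == 1L && n_run >= 2L) {
    delta <- if (call$type == "insertion") 1L else -1L
    call$change <- sprintf("(%s)%d -> (%s)%d", base, n_run, base,
                           n_run + delta)
  }
  call
}

#' Flag de novo variants against a permissive progenitor screen
#'
#' A variant is de novo when the progenitor screen (run in permissive mode,
#' i.e. "at any frequency") contains zero supporting reads for it.
#'
#' @param ma_calls Calls from an MA line.
#' @param progenitor_calls Permissive-mode calls from the progenitor.
#' @return `ma_calls` with `de_novo` filled.
#' @export
mark_de_novo <- function(ma_calls, progenitor_calls) {
  if (!nrow(ma_calls)) return(ma_calls)
  key <- function(df) paste(df$position, df$type, df$alt, df$length,
                            sep = "\r")
  prog_keys <- if (nrow(progenitor_calls)) key(progenitor_calls) else
    character()
  ma_calls$de_novo <- !(key(ma_calls) %in% prog_keys)
  ma_calls
}
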