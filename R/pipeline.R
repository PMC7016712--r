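# Workflow orchestration: simulate -> preprocess -> map -> call -> rates ->
# copy number, with a run manifest, packaged worked-example tables, and a
# report bundle on disk.

#' Validate a run manifest
#'
#' @param lines Data frame with columns `isolate`, `line`, `role`
#'   (`"progenitor"` or `"MA"`) and `generations` (0 for progenitors, >= 1
#'   for MA lines).
#' @return The validated manifest (class `run_manifest`).
#' @export
run_manifest <- function(lines) {
  lines <- as.data.frame(lines, stringsAsFactors = FALSE)
  required <- c("isolate", "line", "role", "generations")
  missing <- setdiff(required, names(lines))
  if (length(missing)) stopf("manifest lacks column(s): %s",
                             paste(missing, collapse = ", "))
  if (!all(lines$role %in% c("progenitor", "MA"))) {
    stopf("role must be 'progenitor' or 'MA'")
  }
  for (iso in unique(lines$isolate)) {
    n_prog <- sum(lines$role == "progenitor" & lines$isolate == iso)
    if (n_prog != 1L) {
      stopf("isolate '%s' must have exactly one progenitor (found %d)",
            iso, n_prog)
    }
  }
  ma <- lines[lines$role == "MA", ]
  if (any(ma$generations < 1L)) stopf("MA lines need generations >= 1")
  structure(lines, class = c("run_manifest", "data.frame"))
}

#' Run the full synthetic-data pipeline for one isolate
#'
#' For every manifest line: simulates the lineage and its paired-end
#' library, preprocesses (trim/merge/dedupe), maps merged reads to the
#' mtgenome (nuclear reads to their loci), builds pileups, then calls
#' variants against the progenitor majority reference, screens the
#' progenitor permissively to flag de novo variants, calls large deletions
#' from split reads, estimates mutation rates, and compares normalized
#' copy number. Writes a TSV/VCF report bundle plus a JSON run log.
#'
#' @param manifest A [run_manifest()] (single isolate).
#' @param genome Mitochondrial reference ([annotated_genome()]).
#' @param nuclear_refs List of nuclear loci ([synthetic_nuclear_refs()]).
#' @param config List with optional entries `thresholds`
#'   ([call_thresholds()]), `merge` ([merge_params()]), `read_params`
#'   ([read_sim_params()]), `plan` (list of [lineage_plan()] arguments
#'   shared by all lines, e.g. initial heteroplasmies and de novo rates)
#'   and `k` (seed size).
#' @param out_dir Output directory (created).
#' @param seed Base seed; line i uses seed + i.
#' @return Invisibly, a list with per-line calls, deletion calls, rates,
#'   copy-number report and file paths.
#' @export
run_pipeline <- function(manifest, genome, nuclear_refs, config = list(),
                         out_dir = tempfile("mthet_run"), seed = 1L) {
  manifest <- run_manifest(manifest)
  if (length(unique(manifest$isolate)) != 1L) {
    stopf("run_pipeline handles one isolate at a time")
  }
  thresholds <- config$thresholds %||% call_thresholds()
  mparams <- config$merge %||% merge_params()
  rparams <- config$read_params %||% read_sim_params()
  plan_args <- config$plan %||% list()
  k <- config$k %||% 8L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  index <- index_reference(genome, k = k)
  nuc_index <- lapply(nuclear_refs, index_reference, k = max(k, 12L))
  names(nuc_index) <- vapply(nuclear_refs, function(g) g$name, character(1))

  per_line <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    line_seed <- seed + i
    plan <- do.call(lineage_plan,
                    c(list(generations = row$generations), plan_args))
    state <- simulate_ma_lineage(genome, plan, seed = line_seed)
    sim <- simulate_reads(genome, nuclear_refs, state, rparams,
                          seed = line_seed)
    reads <- preprocess_reads(sim$pairs, mparams)
    is_mt <- startsWith(reads$id, "mt_")
    aln <- map_reads(reads[is_mt, , drop = FALSE], index)
    # realign around the dominant candidate deletion, if any
    cand <- dominant_deletion(aln)
    if (!is.null(cand)) aln <- realign_indels(aln, cand, index)
    pu <- build_pileup(aln, genome)
    nuc_cov <- lapply(names(nuc_index), function(nm) {
      sel <- startsWith(reads$id, paste0(nm, "_"))
      nal <- map_reads(reads[sel, , drop = FALSE], nuc_index[[nm]])
      ref <- nuclear_refs[[which(names(nuc_index) == nm)]]
      build_pileup(nal, ref)$coverage
    })
    per_line[[row$line]] <- list(row = row, state = state, pileup = pu,
                                 alignments = aln, nuclear_coverage = nuc_cov)
  }

  prog_id <- manifest$line[manifest$role == "progenitor"]
  prog <- per_line[[prog_id]]
  ref <- progenitor_reference(prog$pileup)
  prog_permissive <- call_site_variants(prog$pileup, thresholds,
                                        reference = ref$ref_chars,
                                        permissive = TRUE, genome = genome)

  calls <- list(); deletions <- list(); norm_cov <- list()
  for (nm in names(per_line)) {
    pl <- per_line[[nm]]
    cl <- call_site_variants(pl$pileup, thresholds,
                             reference = ref$ref_chars, genome = genome)
    if (pl$row$role == "MA") cl <- mark_de_novo(cl, prog_permissive)
    calls[[nm]] <- cl
    deletions[[nm]] <- call_large_deletions(pl$alignments, genome,
                                            min_support = thresholds$min_support)
    norm_cov[[nm]] <- normalize_coverage(pl$pileup$coverage,
                                         pl$nuclear_coverage, genome,
                                         sample_id = nm)
  }

  ma_ids <- manifest$line[manifest$role == "MA"]
  rates <- estimate_rates(calls[[prog_id]], calls[ma_ids],
                          manifest$generations[match(ma_ids, manifest$line)],
                          genome)
  cn <- if (length(ma_ids) >= 1L)
    compare_to_progenitor(norm_cov[ma_ids], norm_cov[[prog_id]]) else NULL

  paths <- write_report_bundle(manifest, calls, deletions, rates, cn,
                               norm_cov, genome, thresholds, rparams,
                               seed, out_dir)
  invisible(list(calls = calls, deletions = deletions, rates = rates,
                 copy_number = cn, normalized_coverage = norm_cov,
                 progenitor_permissive = prog_permissive,
                 reference = ref, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Most-supported large-deletion candidate among split alignments.
dominant_deletion <- function(alignments) {
  splits <- Filter(function(al) al$status == "mapped" &&
                     al$gap_type == "del" && al$gap_len >= LARGE_DELETION_MIN,
                   alignments)
  if (length(splits) < 2L) return(NULL)
  key <- vapply(splits, function(al)
    paste(al$segments$ref_end[1] + 1L, al$gap_len, sep = ":"), character(1))
  top <- names(sort(table(key), decreasing = TRUE))[1]
  parts <- as.integer(strsplit(top, ":", fixed = TRUE)[[1]])
  list(start = parts[1], length = parts[2])
}

write_report_bundle <- function(manifest, calls, deletions, rates, cn,
                                norm_cov, genome, thresholds, rparams,
                                seed, out_dir) {
  variants <- do.call(rbind, lapply(names(calls), function(nm) {
    cl <- calls[[nm]]
    if (!nrow(cl)) return(NULL)
    cbind(isolate = manifest$isolate[1], line = nm, cl)
  }))
  variants_path <- file.path(out_dir, "variants.tsv")
  utils::write.table(variants %||% empty_calls(), variants_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  del_df <- do.call(rbind, lapply(names(deletions), function(nm) {
    dl <- deletions[[nm]]
    if (!length(dl)) return(NULL)
    do.call(rbind, lapply(dl, function(d) data.frame(
      line = nm, position = d$canonical_start,
      change = sprintf("-N(%d)", d$length),
      coverage_range = paste(d$coverage_range, collapse = "-"),
      frequency_range = paste(sprintf("%.3f", d$frequency_range),
                              collapse = "-"),
      support = d$support,
      repeat_length = if (!is.null(d$repeat_pair)) d$repeat_pair$length
                      else NA_integer_,
      stringsAsFactors = FALSE)))
  }))
  deletions_path <- file.path(out_dir, "deletions.tsv")
  if (is.null(del_df)) {
    del_df <- data.frame(line = character(), position = integer(),
                         change = character(), coverage_range = character(),
                         frequency_range = character(), support = integer(),
                         repeat_length = integer())
  }
  utils::write.table(del_df, deletions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rates_path <- file.path(out_dir, "rates.tsv")
  utils::write.table(rates, rates_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cn_path <- file.path(out_dir, "copy_number.tsv")
  cn_df <- do.call(rbind, lapply(norm_cov, function(x) data.frame(
    line = x$sample_id, normalized_mean = x$mean, normalized_sd = x$sd,
    normalizer = x$normalizer, stringsAsFactors = FALSE)))
  if (!is.null(cn)) {
    cn_df <- merge(cn_df, cn$contrasts, by.x = "line", by.y = "sample_id",
                   all.x = TRUE)
  }
  utils::write.table(cn_df, cn_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  counts <- summarize_variants(build_summary_input(manifest, calls,
                                                   deletions))
  counts_path <- file.path(out_dir, "variant_counts.tsv")
  utils::write.table(counts$per_line, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  vcf_path <- file.path(out_dir, "variants.vcf")
  write_vcf(variants %||% empty_calls(), genome, vcf_path)
  log_path <- file.path(out_dir, "run_log.json")
  log <- list(seed = seed, thresholds = unclass(thresholds),
              read_params = unclass(rparams),
              manifest = as.data.frame(manifest), genome = genome$name,
              genome_length = genome$length)
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  list(variants = variants_path, deletions = deletions_path,
       rates = rates_path, copy_number = cn_path, counts = counts_path,
       vcf = vcf_path, log = log_path)
}

build_summary_input <- function(manifest, calls, deletions) {
  rows <- list()
  for (nm in names(calls)) {
    cl <- calls[[nm]]
    if (nrow(cl)) {
      rows[[length(rows) + 1L]] <- data.frame(
        isolate = manifest$isolate[1], line = nm, change = cl$change,
        stringsAsFactors = FALSE)
    }
    for (d in deletions[[nm]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        isolate = manifest$isolate[1], line = nm,
        change = sprintf("-N(%d)", d$length), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(isolate = character(), line = character(),
                      change = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Summarize variant records per line
#'
#' Classifies each record from its change representation:
#' `"(B)n -> (B)n+/-1"` homopolymer indels (insertion when the run grows),
#' `"X -> Y"` SNPs, and `"-N(len)"` large deletions.
#'
#' @param records Data frame with columns `line` and `change` (an `isolate`
#'   column is carried through if present).
#' @return List with `per_line` (counts per line: `snps`,
#'   `hp_insertions`, `hp_deletions`, `large_deletions`, `records`) and
#'   `total` (the same counts summed across lines).
#' @export
summarize_variants <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  classify <- function(ch) {
    if (grepl("^-N\\(", ch)) return("large_deletion")
    if (grepl("^\\(", ch)) {
      nums <- as.integer(regmatches(ch, gregexpr("[0-9]+", ch))[[1]])
      return(if (nums[2] > nums[1]) "hp_insertion" else "hp_deletion")
    }
    if (grepl("^[+-]", ch)) {
      return(if (startsWith(ch, "+")) "hp_insertion" else "hp_deletion")
    }
    "snp"
  }
  cls <- vapply(records$change, classify, character(1), USE.NAMES = FALSE)
  lines <- unique(records$line)
  per_line <- do.call(rbind, lapply(lines, function(ln) {
    sel <- records$line == ln
    data.frame(line = ln,
               snps = sum(cls[sel] == "snp"),
               hp_insertions = sum(cls[sel] == "hp_insertion"),
               hp_deletions = sum(cls[sel] == "hp_deletion"),
               large_deletions = sum(cls[sel] == "large_deletion"),
               records = sum(sel), stringsAsFactors = FALSE)
  }))
  if (is.null(per_line)) {
    per_line <- data.frame(line = character(), snps = integer(),
                           hp_insertions = integer(), hp_deletions = integer(),
                           large_deletions = integer(), records = integer())
  }
  total <- c(snps = sum(per_line$snps),
             hp_insertions = sum(per_line$hp_insertions),
             hp_deletions = sum(per_line$hp_deletions),
             large_deletions = sum(per_line$large_deletions),
             records = sum(per_line$records))
  list(per_line = per_line, total = total)
}

#' Load the packaged worked-example study tables
#'
#' Transcriptions of the published summary tables from the two-isolate
#' C. briggsae MA sequencing study the pipeline emulates: per-line
#' sequencing/coverage aggregates, the identified homopolymer indels and
#' SNPs, and the large-deletion events.
#'
#' @return List of data frames: `lines`, `variants`, `deletions`.
#' @export
load_study_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "mthet",
                                  mustWork = TRUE)
  list(lines = utils::read.delim(path("ma_lines.tsv"),
                                 stringsAsFactors = FALSE),
       variants = utils::read.delim(path("ma_variants.tsv"),
                                    stringsAsFactors = FALSE),
       deletions = utils::read.delim(path("ma_deletions.tsv"),
                                     stringsAsFactors = FALSE))
}

#' Write calls to a minimal VCF 4.2
#'
#' @param calls Call data frame (optionally with `line` column, emitted as
#'   the SAMPLE-less INFO-only records).
#' @param genome Reference [annotated_genome()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(calls, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", genome$name, genome$length),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant frequency\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Coverage\">",
    "##INFO=<ID=SB,Number=2,Type=Integer,Description=\"Strand split of support\">",
    "##INFO=<ID=HPRUN,Number=1,Type=Integer,Description=\"Homopolymer run length\">",
    "##INFO=<ID=DENOVO,Number=0,Type=Flag,Description=\"Absent from progenitor at any frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  chars <- seq_to_chars(genome$sequence)
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    if (cl$type == "SNP") {
      pos <- cl$position; ref <- cl$ref; alt <- cl$alt
    } else if (cl$type == "insertion") {
      pos <- cl$position; ref <- chars[pos]; alt <- cl$alt
    } else {
      pos <- cl$position
      ref <- chars_to_seq(chars[seq.int(pos, pos + cl$length)])
      alt <- chars[pos]
    }
    info <- sprintf("AF=%.3f;DP=%d;SB=%d,%d;HPRUN=%d%s",
                    cl$frequency, cl$coverage, cl$support_plus,
                    cl$support_minus,
                    if (is.na(cl$hp_run_length)) 0L else cl$hp_run_length,
                    if (isTRUE(cl$de_novo)) ";DENOVO" else "")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                       genome$name, pos, ref, alt, info), con)
  }
  invisible(path)
}
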