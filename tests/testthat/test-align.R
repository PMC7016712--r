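test_that("the seed index covers every circular k-mer start", {
  g <- annotated_genome("c20", "ACGTACGTTGCAACGGTTCA", circular = TRUE)
  idx <- index_reference(g, k = 8)
  n_pos <- sum(vapply(ls(idx$env), function(k) length(idx$env[[k]]),
                      integer(1)))
  expect_equal(n_pos, 20L)

  # degenerate poly-A genome: one distinct k-mer holding every position
  gp <- annotated_genome("pa", strrep("A", 20), circular = TRUE)
  idxp <- index_reference(gp, k = 8)
  expect_equal(length(ls(idxp$env)), 1L)
  expect_equal(length(idxp$env[["AAAAAAAA"]]), 20L)

  expect_error(index_reference(g, k = 2), "k must be")
  expect_error(index_reference(annotated_genome("s", "ACGT"), k = 8),
               "shorter")
})

test_that("exact reads map to their true origin; revcomp flips the strand", {
  g <- build_synthetic_genome(plain_genome_spec(4000), seed = 17)
  idx <- index_reference(g, k = 8)
  set.seed(17)
  for (i in 1:20) {
    start <- sample(3500, 1)
    read <- substr(g$sequence, start, start + 279)
    al <- map_read(read, idx)
    expect_equal(al$status, "mapped")
    expect_equal(al$strand, "+")
    expect_equal(al$segments$ref_start[1], start)
    expect_equal(al$matches, 280L)
    expect_equal(al$identity, 1)

    rc <- map_read(mthet:::revcomp_fast(read), idx)
    expect_equal(rc$status, "mapped")
    expect_equal(rc$strand, "-")
    expect_equal(rc$segments$ref_start[1], start)
  }
})

test_that("reads matching a perfect duplicated block are tossed as ambiguous", {
  set.seed(31)
  chars <- sample(c("A", "C", "G", "T"), 4000, replace = TRUE)
  chars[2001:2400] <- chars[501:900]  # perfect 400 bp duplication
  g <- annotated_genome("dup", paste(chars, collapse = ""), circular = TRUE)
  idx <- index_reference(g, k = 8)
  read <- substr(g$sequence, 551, 850)  # fully inside the repeat copy
  al <- map_read(read, idx)
  expect_equal(al$status, "ambiguous")
})

test_that("reads across the planted deletion produce a split alignment", {
  g <- default_genome()
  idx <- index_reference(g, k = 8)
  # haplotype junction: ...12478 | 13349... (deletion 12479..13348)
  hap <- paste0(substr(g$sequence, 1, 12478),
                substr(g$sequence, 13349, g$length))
  read <- substr(hap, 12478 - 150, 12478 + 149)  # 150 bases each side
  al <- map_read(read, idx)
  expect_equal(al$status, "mapped")
  expect_equal(al$gap_type, "del")
  expect_equal(al$gap_len, 870L)
  expect_equal(length(al$segments$ref_start), 2L)
  gap <- al$segments$ref_start[2] - al$segments$ref_end[1] - 1L
  expect_equal(gap, 870L)

  # the gap never exceeds maxindel: with a smaller cap the read cannot be
  # represented as a split and falls below minratio
  al2 <- map_read(read, idx, maxindel = 500)
  expect_true(al2$status != "mapped" || al2$gap_len <= 500)

  # an insertion read maps with an I gap
  with_ins <- paste0(substr(g$sequence, 5901, 6050), "CGATT",
                     substr(g$sequence, 6051, 6200))
  ali <- map_read(with_ins, idx)
  expect_equal(ali$status, "mapped")
  expect_equal(ali$gap_type, "ins")
  expect_equal(ali$gap_len, 5L)
  # the placement may be an equivalent shift; canonical forms must agree
  ref_chars <- strsplit(g$sequence, "")[[1]]
  got <- mthet:::left_align_insertion(ref_chars,
                                      ali$segments$ref_end[1], ali$ins_seq)
  want <- mthet:::left_align_insertion(ref_chars, 6050L, "CGATT")
  expect_equal(got, want)
})

test_that("nearly all error-free reads from a repeat-free genome map uniquely", {
  g <- build_synthetic_genome(plain_genome_spec(4000, at_rich = FALSE),
                              seed = 19)
  params <- read_sim_params(mt_coverage = 40, error_rate = 0,
                            duplicate_fraction = 0)
  sim <- simulate_reads(g, list(), empty_state(), params, seed = 4)
  reads <- preprocess_reads(sim$pairs, merge_params())
  idx <- index_reference(g, k = 8)
  aln <- map_reads(reads, idx)
  status <- vapply(aln, function(a) a$status, character(1))
  expect_gte(mean(status == "mapped"), 0.999)
  single <- vapply(aln[status == "mapped"], function(a)
    length(a$segments$ref_start) == 1L, logical(1))
  expect_gte(mean(single), 0.999)
  # and at the true origin
  mapped <- aln[status == "mapped"]
  starts <- vapply(mapped, function(a)
    mthet:::wrap_pos(a$segments$ref_start[1], g$length), integer(1))
  ids <- vapply(mapped, function(a) a$id, character(1))
  expect_gte(mean(starts == sim$pairs$start[match(ids, sim$pairs$id)]),
             0.999)
})

test_that("realignment converts breakpoint-overhang reads to split alignments", {
  # a deletion in non-repetitive context: the junction overhang is
  # informative even when very short
  g <- build_synthetic_genome(plain_genome_spec(4000, at_rich = FALSE),
                              seed = 29)
  idx <- index_reference(g, k = 8)
  del_start <- 2001L; del_len <- 300L
  hap <- paste0(substr(g$sequence, 1, del_start - 1L),
                substr(g$sequence, del_start + del_len, g$length))
  # read ending only 6 bases past the junction: single-segment at first
  read <- substr(hap, del_start - 294L, del_start + 5L)
  al <- map_read(read, idx, id = "edge")
  expect_equal(al$status, "mapped")
  expect_equal(al$gap_type, "none")
  re <- realign_indels(list(al), list(start = del_start, length = del_len),
                       idx)
  expect_equal(re[[1]]$gap_type, "del")
  expect_equal(re[[1]]$gap_len, del_len)

  # and symmetrically for a short left anchor
  read2 <- substr(hap, del_start - 6L, del_start + 293L)
  al2 <- map_read(read2, idx, id = "edge2")
  re2 <- realign_indels(list(al2), list(start = del_start, length = del_len),
                        idx)
  expect_equal(re2[[1]]$gap_type, "del")

  # a read fully inside the non-deleted allele is unchanged
  far <- map_read(substr(g$sequence, 3001, 3300), idx, id = "far")
  re3 <- realign_indels(list(far), list(start = del_start, length = del_len),
                        idx)
  expect_identical(re3[[1]]$segments, far$segments)
  expect_equal(re3[[1]]$gap_type, "none")

  # no reads near the breakpoint: no-op
  expect_identical(realign_indels(list(), list(start = del_start,
                                               length = del_len), idx),
                   list())
})

test_that("reference extension recovers a truncated flank and trims junk", {
  spec <- plain_genome_spec(3000)
  full <- build_synthetic_genome(spec, seed = 5)
  full_lin <- annotated_genome("full", full$sequence, circular = FALSE)
  trunc <- annotated_genome("trunc", substr(full$sequence, 403, 3000),
                            circular = FALSE)
  params <- read_sim_params(mt_coverage = 60, error_rate = 0,
                            duplicate_fraction = 0)
  sim <- simulate_reads(full_lin, list(), empty_state(), params, seed = 3)
  reads <- preprocess_reads(sim$pairs, merge_params())

  ext <- extend_reference(reads, trunc, iterations = 10)
  gain <- ext$length - trunc$length
  expect_gte(gain, 150L)
  expect_lte(gain, 402L)
  expect_equal(ext$sequence, substr(full$sequence, 403 - gain, 3000))

  # with the low-coverage trim effectively disabled, more flank survives
  ext_loose <- extend_reference(reads, trunc, iterations = 10,
                                low_cov_sd = 50)
  expect_gt(ext_loose$length, ext$length)

  # full-length reference is a fixed point
  ext2 <- extend_reference(reads, full_lin, iterations = 1)
  expect_identical(ext2$sequence, full_lin$sequence)

  # no mappable reads: input returned with a warning
  junk <- data.frame(id = "x", seq = strrep("ACGT", 60),
                     qual = strrep("I", 240))
  expect_warning(out <- extend_reference(junk, trunc, iterations = 1),
                 "no reads mapped")
  expect_identical(out$sequence, trunc$sequence)
})

test_that("SAM round-trip preserves placements, CIGARs and pileups", {
  g <- build_synthetic_genome(plain_genome_spec(3000), seed = 23)
  idx <- index_reference(g, k = 8)
  reads <- data.frame(
    id = c("plain", "rc"),
    seq = c(substr(g$sequence, 101, 400),
            mthet:::revcomp_fast(substr(g$sequence, 901, 1200))))
  aln <- map_reads(reads, idx)
  hap <- paste0(substr(g$sequence, 1, 1800), substr(g$sequence, 2001, 3000))
  aln[[3]] <- map_read(substr(hap, 1651, 1950), idx, id = "split")
  path <- tempfile(fileext = ".sam")
  write_sam(aln, g, path)
  back <- read_sam(path)
  expect_equal(length(back), 3L)
  ord <- match(c("plain", "rc", "split"),
               vapply(back, function(a) a$id, character(1)))
  back <- back[ord]
  for (i in 1:3) {
    expect_equal(back[[i]]$segments, aln[[i]]$segments)
    expect_equal(back[[i]]$strand, aln[[i]]$strand)
    expect_equal(back[[i]]$gap_type, aln[[i]]$gap_type)
  }
  pu1 <- build_pileup(aln, g)
  pu2 <- build_pileup(back, g)
  expect_identical(pu1$counts_plus, pu2$counts_plus)
  expect_identical(pu1$del, pu2$del)
})
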