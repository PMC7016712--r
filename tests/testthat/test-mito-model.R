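test_that("load_genome round-trips FASTA + feature table and validates bounds", {
  fa <- tempfile(fileext = ".fasta")
  ft <- tempfile(fileext = ".tsv")
  writeLines(c(">tiny", "ACGTACGTACGTACGTACGT"), fa)
  write.table(data.frame(label = "g1", role = "gene", start = 1, end = 9,
                         strand = "+"),
              ft, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- load_genome(fa, ft, circular = FALSE)
  expect_equal(g$length, 20L)
  expect_equal(nrow(g$features), 1L)
  expect_equal(g$name, "tiny")

  # lowercase input is normalized
  writeLines(c(">tiny", "acgtacgtacgtacgtacgt"), fa)
  expect_equal(load_genome(fa)$sequence, "ACGTACGTACGTACGTACGT")

  # out-of-bounds feature names the offender
  write.table(data.frame(label = "bad", role = "gene", start = 1, end = 25,
                         strand = "+"),
              ft, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_genome(fa, ft), "bad")

  # multi-record FASTA refused
  writeLines(c(">a", "ACGT", ">b", "ACGT"), fa)
  expect_error(load_genome(fa), "one FASTA record")
})

test_that("homopolymer census handles thresholds, exclusion and wrap", {
  g <- annotated_genome("t", "CCAAAAAAAATTG", circular = FALSE)
  cen <- census_homopolymers(g, min_run = 8, exclude = NULL)
  qual <- cen$runs[cen$runs$length >= 8, ]
  expect_equal(nrow(qual), 1L)
  expect_equal(qual$base, "A")
  expect_equal(cen$n_sites, 8L)
  expect_equal(census_homopolymers(g, min_run = 9, exclude = NULL)$n_sites, 0L)
  expect_error(census_homopolymers(g, min_run = 1))

  # circular genomes merge the origin-spanning run, counted once
  gc <- annotated_genome("c", "AAACGGAA", circular = TRUE)
  cen <- census_homopolymers(gc, min_run = 5, exclude = NULL)
  wrap_run <- cen$runs[cen$runs$wrap, ]
  expect_equal(nrow(wrap_run), 1L)
  expect_equal(wrap_run$length, 5L)
  expect_equal(cen$n_sites, 5L)

  # bases inside the excluded feature never count, partial overlap kept
  g2 <- annotated_genome("e", "CCTTTTTTTTTTGG",
                         circular = FALSE,
                         features = data.frame(label = "ar", role = "AT-rich",
                                               start = 8, end = 14,
                                               strand = "+"))
  cen2 <- census_homopolymers(g2, min_run = 8)
  # run T 3..12 (10 bp), bases 8..12 excluded -> 5 outside
  expect_equal(cen2$n_sites, 5L)
})

test_that("census matches the brute-force scan oracle on random sequences", {
  set.seed(101)
  for (i in 1:1000) {
    len <- sample(50:400, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                        prob = c(.4, .1, .1, .4)), collapse = "")
    g <- annotated_genome("r", seq, circular = FALSE)
    min_run <- sample(3:9, 1)
    expect_identical(census_homopolymers(g, min_run, exclude = NULL)$n_sites,
                     census_oracle(seq, min_run))
  }
})

test_that("qualifying site count is non-increasing in the run threshold", {
  g <- default_genome()
  sites <- vapply(2:13, function(k)
    census_homopolymers(g, k, exclude = NULL)$n_sites, integer(1))
  expect_true(all(diff(sites) <= 0))
})

test_that("find_direct_repeats recovers planted repeats and decompositions", {
  set.seed(7)
  chars <- sample(c("A", "C", "G", "T"), 2000, replace = TRUE)
  motif <- sample(c("A", "C", "G", "T"), 36, replace = TRUE)
  chars[200:235] <- motif
  chars[1070:1105] <- motif
  chars[c(199, 236)] <- "A"; chars[c(1069, 1106)] <- "C"
  g <- annotated_genome("r", paste(chars, collapse = ""), circular = FALSE)
  hits <- find_direct_repeats(g, c(150, 300), c(1000, 1200),
                              min_len = 20, max_mismatch = 0)
  expect_equal(length(hits), 1L)
  expect_equal(hits[[1]]$length, 36L)
  expect_equal(hits[[1]]$left_interval, c(200L, 235L))
  expect_equal(hits[[1]]$right_interval, c(1070L, 1105L))
  expect_equal(length(hits[[1]]$mismatch_positions), 0L)

  # one mismatch at offset 6 -> exact subrepeats of 5 and 30
  chars[200 + 5] <- setdiff(c("A", "C", "G", "T"), chars[1070 + 5])[1]
  g2 <- annotated_genome("r2", paste(chars, collapse = ""), circular = FALSE)
  hits2 <- find_direct_repeats(g2, c(150, 300), c(1000, 1200),
                               min_len = 20, max_mismatch = 1)
  expect_equal(hits2[[1]]$length, 36L)
  expect_equal(hits2[[1]]$mismatch_positions, 6L)
  expect_equal(hits2[[1]]$exact_subrepeats$length, c(5L, 30L))

  # windows sharing nothing -> empty
  expect_length(find_direct_repeats(g, c(400, 470), c(1400, 1470),
                                    min_len = 20, max_mismatch = 0), 0)
  expect_error(find_direct_repeats(g, c(100, 300), c(250, 400)),
               "overlap")
})

test_that("repeat search is symmetric in its two windows", {
  g <- default_genome()
  a <- find_direct_repeats(g, c(12400, 12560), c(13300, 13420),
                           min_len = 10, max_mismatch = 1)
  b <- find_direct_repeats(g, c(13300, 13420), c(12400, 12560),
                           min_len = 10, max_mismatch = 1)
  expect_equal(length(a), length(b))
  expect_equal(a[[1]]$left_interval, b[[1]]$right_interval)
  expect_equal(a[[1]]$right_interval, b[[1]]$left_interval)
  expect_equal(a[[1]]$length, b[[1]]$length)
})

test_that("protein effects follow the invertebrate mitochondrial code", {
  g <- default_genome()
  # second codon position C>T in the planted TCA codon: serine -> leucine
  eff <- annotate_effect(list(position = 3414, type = "SNP",
                              ref = "C", alt = "T"), g)
  expect_equal(eff$effects, "substitution")
  expect_equal(eff$aa_from, "S")
  expect_equal(eff$aa_to, "L")
  expect_equal(format(eff), "S -> L Sub")

  # insertion in the homopolymer after the atp-6 stop codon: no effect
  eff2 <- annotate_effect(list(position = 3566, type = "insertion",
                               ref = "A", alt = "AA", length = 1), g)
  expect_equal(eff2$effects, "none")

  # +1 insertion inside a gene body: frameshift
  eff3 <- annotate_effect(list(position = 700, type = "insertion",
                               ref = "T", alt = "TT", length = 1), g)
  expect_equal(eff3$effects, "frameshift")

  # length-3 indels inside genes are never frameshifts
  for (pos in c(700, 2200, 5100)) {
    e <- annotate_effect(list(position = pos, type = "deletion",
                              ref = "N", alt = "-", length = 3), g)
    expect_false("frameshift" %in% e$effects)
  }

  # large deletion removing a gene's start
  eff4 <- annotate_effect(list(position = 12479, type = "large_deletion",
                               length = 870), g)
  expect_setequal(eff4$effects, c("alternative_start", "truncation"))

  # non-coding contexts and bounds
  expect_equal(annotate_effect(list(position = 400, type = "SNP", ref = "A",
                                    alt = "G"), g)$feature_role, "tRNA")
  expect_error(annotate_effect(list(position = 99999, type = "SNP",
                                    ref = "A", alt = "G"), g), "outside")
})
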