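test_that("genome construction is deterministic and plants recoverable truth", {
  g1 <- build_synthetic_genome(genome_spec(), seed = 11)
  g2 <- build_synthetic_genome(genome_spec(), seed = 11)
  expect_identical(g1$sequence, g2$sequence)
  expect_false(identical(g1$sequence,
                         build_synthetic_genome(genome_spec(), seed = 12)$sequence))

  # FASTA writing is byte-identical for identical genomes
  f1 <- tempfile(); f2 <- tempfile()
  write_genome(g1, f1); write_genome(g2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # a spec with one planted (A)10 run yields exactly one qualifying run
  spec <- plain_genome_spec(3000)
  spec$homopolymers <- data.frame(base = "A", start = 1200L, length = 10L)
  g <- build_synthetic_genome(spec, seed = 3)
  cen <- census_homopolymers(g, min_run = 8)
  qual <- cen$runs[cen$runs$length >= 8, ]
  in_atr <- qual$start >= 2801
  expect_equal(nrow(qual[!in_atr, ]), 1L)
  expect_equal(qual$start[!in_atr], 1200L)
  expect_equal(cen$n_sites, 10L)

  # the planted mismatch repeat decomposes into 5 + 30 exact subrepeats
  gd <- default_genome()
  rp <- find_direct_repeats(gd, c(12400, 12560), c(13300, 13420),
                            min_len = 10, max_mismatch = 1)[[1]]
  expect_equal(rp$length, 36L)
  expect_equal(rp$exact_subrepeats$length, c(5L, 30L))
  expect_equal(rp$left_interval[1], 12473L)
  expect_equal(rp$right_interval[1], 13343L)
})

test_that("lineage simulation obeys the null model and the drift variance law", {
  g <- build_synthetic_genome(plain_genome_spec(2000), seed = 5)
  # zero rates, zero initial frequency: no variants ever
  plan0 <- lineage_plan(generations = 30, n_eff = 50)
  st <- simulate_ma_lineage(g, plan0, seed = 1)
  expect_equal(nrow(st$variants), 0L)

  # neutral drift from p0 = 0.4: mean preserved, replicate variance matches
  # the Wright-Fisher recursion p(1-p)(1-(1-1/N)^t)
  plan <- lineage_plan(generations = 50, n_eff = 100,
                       initial = data.frame(type = "SNP", position = 500,
                                            ref = "A", alt = "G",
                                            frequency = 0.4))
  f <- vapply(1:2000, function(s)
    simulate_ma_lineage(g, plan, seed = s)$variants$frequency[1], numeric(1))
  v_theory <- 0.4 * 0.6 * (1 - (1 - 1 / 100)^50)
  se_mean <- sqrt(v_theory / 2000)
  expect_lt(abs(mean(f) - 0.4), 3 * se_mean)
  # variance of a sample variance ~ 2 v^2 / n under near-normality
  expect_lt(abs(var(f) - v_theory), 4 * v_theory * sqrt(2 / 2000))
})

test_that("transmission bias raises the chance of reaching high frequency", {
  g <- build_synthetic_genome(plain_genome_spec(2000), seed = 5)
  run_frac <- function(b, seeds) {
    plan <- lineage_plan(generations = 50, n_eff = 50,
                         initial = data.frame(type = "large_deletion",
                                              position = 300, ref = "N",
                                              alt = "-", length = 100,
                                              frequency = 1 / 50, b = b))
    mean(vapply(seeds, function(s)
      simulate_ma_lineage(g, plan, seed = s)$variants$frequency[1] > 0.5,
      logical(1)))
  }
  seeds <- 1:400
  expect_gt(run_frac(5, seeds), run_frac(1, seeds))
})

test_that("all three heteroplasmy fates occur under a small bottleneck", {
  g <- build_synthetic_genome(plain_genome_spec(2000), seed = 5)
  plan <- lineage_plan(generations = 50, n_eff = 20,
                       initial = data.frame(type = "SNP", position = 500,
                                            ref = "A", alt = "G",
                                            frequency = 0.4))
  fates <- vapply(1:200, function(s)
    simulate_ma_lineage(g, plan, seed = s)$variants$fate, character(1))
  expect_setequal(unique(fates),
                  c("fixed_variant", "fixed_reference", "heteroplasmic"))
})

test_that("noiseless reads are exact substrings of the circularized genome", {
  g <- build_synthetic_genome(plain_genome_spec(3000), seed = 9)
  params <- read_sim_params(mt_coverage = 30, error_rate = 0,
                            duplicate_fraction = 0)
  sim <- simulate_reads(g, list(), empty_state(), params, seed = 2)
  reads <- preprocess_reads(sim$pairs, merge_params())
  doubled <- paste0(g$sequence, g$sequence)
  doubled_rc <- mthet:::revcomp_fast(doubled)
  ok <- vapply(reads$seq, function(s)
    grepl(s, doubled, fixed = TRUE) || grepl(s, doubled_rc, fixed = TRUE),
    logical(1))
  expect_true(all(ok))
})

test_that("identical seeds give byte-identical FASTQ", {
  g <- build_synthetic_genome(plain_genome_spec(2000), seed = 9)
  params <- read_sim_params(mt_coverage = 15, error_rate = 0.002,
                            duplicate_fraction = 0.1)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_reads(g, list(), empty_state(), params, seed = 4, dir = d1)
  simulate_reads(g, list(), empty_state(), params, seed = 4, dir = d2)
  expect_identical(readLines(file.path(d1, "sim_R1.fastq")),
                   readLines(file.path(d2, "sim_R1.fastq")))
  expect_identical(readLines(file.path(d1, "sim_R2.fastq")),
                   readLines(file.path(d2, "sim_R2.fastq")))
})

test_that("realized coverage and planted variant fractions match targets", {
  g <- default_genome()
  params <- read_sim_params(mt_coverage = 60, error_rate = 0,
                            duplicate_fraction = 0)
  # coverage within 10% of target on a >= 5 kb genome
  sim <- simulate_reads(g, list(), empty_state(), params, seed = 5)
  reads <- preprocess_reads(sim$pairs, merge_params())
  aln <- truth_alignments(reads, sim$pairs, g)
  pu <- build_pileup(aln, g)
  expect_lt(abs(mean(pu$coverage) - 60) / 60, 0.10)

  # truth frequency 0.30 at 300x: pileup fraction within 3 binomial SE
  g4 <- build_synthetic_genome(plain_genome_spec(3000), seed = 9)
  st <- lineage_state(data.frame(type = "SNP", position = 1500,
                                 ref = substr(g4$sequence, 1500, 1500),
                                 alt = setdiff(c("A", "C", "G", "T"),
                                               substr(g4$sequence, 1500, 1500))[1],
                                 length = 1, frequency = 0.30))
  params300 <- read_sim_params(mt_coverage = 300, error_rate = 0,
                               duplicate_fraction = 0)
  sim2 <- simulate_reads(g4, list(), st, params300, seed = 6)
  reads2 <- preprocess_reads(sim2$pairs, merge_params())
  idx <- index_reference(g4, k = 8)
  aln2 <- map_reads(reads2, idx)
  pu2 <- build_pileup(aln2, g4)
  alt <- st$variants$alt[1]
  frac <- (pu2$counts_plus[alt, 1500] + pu2$counts_minus[alt, 1500]) /
    pu2$coverage[1500]
  expect_lt(abs(frac - 0.30), 3 * sqrt(0.3 * 0.7 / 300))
})

test_that("planted coverage ratio is recovered as normalized copy number", {
  g <- build_synthetic_genome(plain_genome_spec(3000), seed = 9)
  nuc <- synthetic_nuclear_refs(lengths = c(1200L, 1000L, 1500L), seed = 2)
  params <- read_sim_params(mt_coverage = 120, nuclear_coverage = 3,
                            error_rate = 0, duplicate_fraction = 0)
  sim <- simulate_reads(g, nuc, empty_state(), params, seed = 8)
  reads <- preprocess_reads(sim$pairs, merge_params())
  mt_pu <- build_pileup(
    truth_alignments(reads[startsWith(reads$id, "mt_"), ], sim$pairs, g), g)
  nuc_cov <- lapply(nuc, function(nr) {
    sel <- startsWith(reads$id, paste0(nr$name, "_"))
    build_pileup(truth_alignments(reads[sel, ], sim$pairs, nr), nr)$coverage
  })
  norm <- normalize_coverage(mt_pu$coverage, nuc_cov, g, "sim")
  expect_lt(abs(norm$mean - 40) / 40, 0.10)
})
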