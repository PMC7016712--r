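test_that("pileups count single reads and mismatches correctly", {
  g <- build_synthetic_genome(plain_genome_spec(3000), seed = 23)
  idx <- index_reference(g, k = 8)
  read <- substr(g$sequence, 501, 800)
  al <- map_read(read, idx, id = "r1")
  pu <- build_pileup(list(al), g)
  expect_true(all(pu$coverage[501:800] == 1L))
  expect_true(all(pu$coverage[c(1:500, 801:3000)] == 0L))

  # one mismatch: alt count 1 at that site
  read2 <- read
  orig <- substr(read2, 150, 150)
  alt <- setdiff(c("A", "C", "G", "T"), orig)[1]
  substr(read2, 150, 150) <- alt
  al2 <- map_read(read2, idx, id = "r2")
  pu2 <- build_pileup(list(al2), g)
  expect_equal(unname(pu2$counts_plus[alt, 650] +
                        pu2$counts_minus[alt, 650]), 1L)
})

test_that("the progenitor majority reference follows the stated tie rules", {
  g <- annotated_genome("t", "ACGTACGTAC", circular = FALSE)
  cp <- matrix(0L, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
  cm <- cp
  # site 2 (FASTA C): 60% C / 40% T -> majority C
  cp["C", 2] <- 30L; cm["C", 2] <- 30L; cp["T", 2] <- 20L; cm["T", 2] <- 20L
  # site 3 (FASTA G): unanimous T -> T replaces the FASTA base
  cp["T", 3] <- 50L
  # site 4 (FASTA T): exact 50/50 A/T tie -> FASTA base, flagged
  cp["A", 4] <- 25L; cm["T", 4] <- 25L
  pu <- structure(list(counts_plus = cp, counts_minus = cm,
                       ins = data.frame(), del = data.frame(),
                       coverage = colSums(cp) + colSums(cm),
                       ref_chars = strsplit(g$sequence, "")[[1]],
                       genome_name = "t", length = 10L), class = "pileup")
  ref <- progenitor_reference(pu)
  expect_equal(ref$ref_chars[2], "C")
  expect_equal(ref$ref_chars[3], "T")
  expect_equal(ref$ref_chars[4], "T")
  expect_true(4L %in% ref$flagged)
  # zero-coverage sites fall back to FASTA and are flagged
  expect_true(1L %in% ref$flagged)
})

test_that("calling applies the coverage/support/p gates and reports freq = support/coverage", {
  g <- build_synthetic_genome(plain_genome_spec(2000), seed = 3)
  pos <- which(strsplit(g$sequence, "")[[1]] == "C")[20:24]
  # merged-consensus libraries: per-base error near 1e-4 (about Q40)
  th <- call_thresholds(error_rate = 1e-4)

  cases <- data.frame(cov = c(402L, 196L, 260L, 287L),
                      sup = c(6L, 54L, 260L, 116L),
                      freq = c(0.015, 0.276, 1.000, 0.404))
  pu <- make_test_pileup(g, ref_counts = cases$cov - cases$sup,
                         alt_counts = cases$sup, positions = pos[1:4])
  calls <- call_site_variants(pu, th)
  calls <- calls[match(pos[1:4], calls$position), ]
  expect_equal(calls$frequency, cases$freq)
  expect_equal(calls$support, cases$sup)
  expect_equal(calls$coverage, cases$cov)
  expect_true(all(calls$p_value < th$max_p))
  # the printed-frequency invariant
  expect_equal(round(calls$support / calls$coverage, 3), calls$frequency)

  # coverage gate: 50/99 is silent despite huge support
  pu2 <- make_test_pileup(g, 49L, 50L, pos[5])
  expect_equal(nrow(call_site_variants(pu2, th)), 0L)
  # support gate: 3/300
  pu3 <- make_test_pileup(g, 297L, 3L, pos[5])
  expect_equal(nrow(call_site_variants(pu3, th)), 0L)
  # permissive mode emits every observation
  expect_equal(call_site_variants(pu3, th, permissive = TRUE)$support, 3L)
  expect_equal(call_site_variants(pu2, th, permissive = TRUE)$frequency,
               round(50 / 99, 3))
})

test_that("the strand-bias screen follows the trigger-then-test rule", {
  th <- call_thresholds()
  # balanced split passes outright
  expect_true(strand_bias_filter(list(support_plus = 20, support_minus = 20,
                                      cov_plus = 150, cov_minus = 150), th))
  # 60/40 is below the 65% trigger: passes without testing
  expect_true(strand_bias_filter(list(support_plus = 24, support_minus = 16,
                                      cov_plus = 150, cov_minus = 150), th))
  # 40/0 support on balanced coverage: p = 2 * 0.5^40 << 1e-5, fails
  expect_false(strand_bias_filter(list(support_plus = 40, support_minus = 0,
                                       cov_plus = 150, cov_minus = 150), th))
  # heavily skewed support is tolerated when the site's coverage is skewed
  # the same way
  expect_true(strand_bias_filter(list(support_plus = 40, support_minus = 2,
                                      cov_plus = 280, cov_minus = 15), th))
})

test_that("indel calls left-align to one canonical record per run", {
  g <- default_genome()
  idx <- index_reference(g, k = 8)
  # the planted (A)10 run spans 3565..3574: insert an extra A at each
  # possible placement; all must collapse to the same canonical record
  alns <- list()
  for (off in 0:9) {
    p <- 3565 + off
    read <- paste0(substr(g$sequence, p - 150, p - 1), "A",
                   substr(g$sequence, p, p + 148))
    alns[[length(alns) + 1L]] <- map_read(read, idx,
                                          id = sprintf("ins%d", off))
  }
  pu <- build_pileup(alns, g)
  expect_equal(nrow(pu$ins), 1L)
  expect_equal(pu$ins$pos, 3564L)  # anchor just before the run
  expect_equal(pu$ins$plus + pu$ins$minus, 10L)
  calls <- call_site_variants(pu, call_thresholds(), permissive = TRUE,
                              genome = g)
  ins <- calls[calls$type == "insertion", ]
  expect_equal(ins$change, "(A)10 -> (A)11")
  expect_equal(ins$hp_run_length, 10L)

  # left_align_indel leaves a non-repetitive indel unchanged
  chars <- strsplit(g$sequence, "")[[1]]
  p <- 6100
  while (chars[p] == chars[p - 1] || chars[p + 1] == chars[p]) p <- p + 1
  call <- data.frame(position = p, type = "deletion", ref = chars[p],
                     alt = "-", length = 1L, hp_run_length = NA_integer_,
                     change = NA_character_)
  out <- left_align_indel(call, g)
  expect_equal(out$position, p)
})

test_that("large deletions cluster by canonical placement with truthful geometry", {
  g <- default_genome()
  idx <- index_reference(g, k = 8)
  # reads spanning the MA12-like junction (deletion 12479..13348) and the
  # MA3-like junction shifted -6 (deletion 12473..13342)
  hap_a <- paste0(substr(g$sequence, 1, 12478),
                  substr(g$sequence, 13349, g$length))
  hap_b <- paste0(substr(g$sequence, 1, 12472),
                  substr(g$sequence, 13343, g$length))
  alns <- list()
  for (i in 0:5) {
    ra <- substr(hap_a, 12478 - 170 - 7 * i, 12478 + 129 - 7 * i)
    rb <- substr(hap_b, 12472 - 170 - 7 * i, 12472 + 129 - 7 * i)
    alns[[length(alns) + 1L]] <- map_read(ra, idx, id = sprintf("a%d", i))
    alns[[length(alns) + 1L]] <- map_read(rb, idx, id = sprintf("b%d", i))
  }
  # reference reads spanning both junction regions
  for (i in 0:5) {
    r1 <- substr(g$sequence, 12330 + 10 * i, 12629 + 10 * i)
    r2 <- substr(g$sequence, 13200 + 10 * i, 13499 + 10 * i)
    alns[[length(alns) + 1L]] <- map_read(r1, idx, id = sprintf("s%d", i))
    alns[[length(alns) + 1L]] <- map_read(r2, idx, id = sprintf("t%d", i))
  }
  dels <- call_large_deletions(alns, g, min_support = 4)
  expect_equal(length(dels), 2L)
  starts <- sort(vapply(dels, function(d) d$canonical_start, integer(1)))
  expect_equal(starts, c(12473L, 12479L))
  expect_equal(diff(starts), 6L)
  for (d in dels) {
    expect_equal(d$length, 870L)
    expect_equal(d$support, 6L)
    expect_false(is.null(d$repeat_pair))
    expect_equal(d$repeat_pair$length, 36L)
    expect_true(all(d$frequency_range >= 0 & d$frequency_range <= 1))
  }
  # deletion length equals the distance between the repeat-copy starts
  rp <- dels[[1]]$repeat_pair
  expect_equal(rp$right_interval[1] - rp$left_interval[1], 870L)

  # no split reads: empty list
  expect_length(call_large_deletions(alns[13:24], g), 0L)
})

test_that("de novo flags require zero progenitor support at any frequency", {
  ma <- data.frame(position = c(100L, 200L, 300L),
                   type = c("SNP", "SNP", "insertion"),
                   alt = c("T", "A", "CT"), length = c(1L, 1L, 1L),
                   frequency = c(0.1, 0.278, 0.05))
  prog <- data.frame(position = c(100L, 999L),
                     type = c("SNP", "SNP"),
                     alt = c("T", "G"), length = c(1L, 1L),
                     frequency = c(0.004, 0.5), support = c(2L, 50L))
  out <- mark_de_novo(ma, prog)
  # 2 progenitor reads (below thresholds) still vetoes de novo
  expect_equal(out$de_novo, c(FALSE, TRUE, TRUE))
  # progenitor-only variants never enter the MA output
  expect_false(999L %in% out$position)
})
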