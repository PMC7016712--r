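# Heteroplasmy dynamics across single-individual bottleneck generations.
#
# Each MA generation is modeled as one Wright-Fisher bottleneck over N_eff
# effective mtDNA copies: a variant at frequency p is transmitted as
# Binomial(N_eff, p*b / (p*b + (1-p))) / N_eff, where b is its transmission
# bias (b = 1: neutral drift; b > 1: selfish propagation). De novo variants
# arise as Poisson events on the N_eff transmitted copies and enter at
# frequency 1/N_eff.

#' Plan for a simulated mutation-accumulation lineage
#'
#' @param generations Number of single-individual bottleneck generations
#'   (0-50 in the emulated design).
#' @param n_eff Effective mtDNA copy number per bottleneck (default 100; the
#'   real germline bottleneck size is unknown, so this is a free parameter).
#' @param initial Data frame of initial heteroplasmies (columns `id`, `type`,
#'   `position`, `ref`, `alt`, `length`, `frequency`, `b`), or `NULL`.
#' @param snp_rate De novo base-substitution rate per site per generation.
#' @param hp_indel_rate De novo homopolymer slippage rate per qualifying
#'   homopolymer site per generation.
#' @param deletion_rate De novo repeat-deletion formation rate per mtDNA copy
#'   per generation.
#' @param deletion_b Transmission bias applied to de novo large deletions
#'   (b = 1 is neutral; the selfish-element regime uses b > 1).
#' @param hp_min_run Minimum run length at which slippage operates.
#' @return A `lineage_plan` list.
#' @export
lineage_plan <- function(generations = 50L, n_eff = 100L, initial = NULL,
                         snp_rate = 0, hp_indel_rate = 0, deletion_rate = 0,
                         deletion_b = 1, hp_min_run = 8L) {
  if (!is_count(generations, 0L) || generations > 1000L) {
    stopf("generations must be an integer >= 0")
  }
  if (!is_count(n_eff, 1L)) stopf("n_eff must be an integer >= 1")
  stopifnot(snp_rate >= 0, hp_indel_rate >= 0, deletion_rate >= 0,
            deletion_b > 0)
  initial <- normalize_variants(initial)
  if (any(initial$frequency < 0 | initial$frequency > 1)) {
    stopf("initial frequencies must lie in [0, 1]")
  }
  structure(list(generations = as.integer(generations),
                 n_eff = as.integer(n_eff), initial = initial,
                 snp_rate = snp_rate, hp_indel_rate = hp_indel_rate,
                 deletion_rate = deletion_rate, deletion_b = deletion_b,
                 hp_min_run = as.integer(hp_min_run)),
            class = "lineage_plan")
}

empty_variants <- function() {
  data.frame(id = character(), type = character(), position = integer(),
             ref = character(), alt = character(), length = integer(),
             frequency = numeric(), b = numeric(), origin_generation = integer(),
             stringsAsFactors = FALSE)
}

normalize_variants <- function(v) {
  if (is.null(v) || !nrow(as.data.frame(v))) return(empty_variants())
  v <- as.data.frame(v, stringsAsFactors = FALSE)
  if (!"id" %in% names(v)) v$id <- sprintf("v%03d", seq_len(nrow(v)))
  if (!"length" %in% names(v)) v$length <- 1L
  if (!"b" %in% names(v)) v$b <- 1
  if (!"origin_generation" %in% names(v)) v$origin_generation <- 0L
  v$position <- as.integer(v$position)
  v$length <- as.integer(v$length)
  v[, names(empty_variants())]
}

#' Simulate an MA lineage
#'
#' Runs `plan$generations` bottlenecks over the genome, tracking every
#' initial and de novo variant to its final frequency and fate.
#'
#' @param genome An [annotated_genome()] (supplies eligible SNP sites, the
#'   homopolymer census for slippage targets and the planted repeat for
#'   de novo deletions).
#' @param plan A [lineage_plan()].
#' @param seed Integer seed.
#' @return A `lineage_state`: list with `variants` (the plan's variant
#'   columns plus `frequency` = final frequency, `origin_generation`,
#'   `fate` in `fixed_variant`, `fixed_reference`, `heteroplasmic`, `lost`)
#'   and `generations`.
#' @export
simulate_ma_lineage <- function(genome, plan, seed = 1L) {
  stopifnot(inherits(genome, "annotated_genome"), inherits(plan, "lineage_plan"))
  with_seed(seed, {
    vars <- plan$initial
    initial_freq <- vars$frequency
    N <- plan$n_eff
    atr <- feature_by_role(genome, "AT-rich")
    n_snp_sites <- genome$length - length(feature_positions(atr, genome$length))
    census <- census_homopolymers(genome, min_run = plan$hp_min_run)
    hp_runs <- census$runs[census$runs$length >= plan$hp_min_run, , drop = FALSE]
    n_hp_sites <- census$n_sites
    chars <- seq_to_chars(genome$sequence)
    rs <- attr(genome, "planted_repeat")

    for (g in seq_len(plan$generations)) {
      # de novo events on the N transmitted copies
      n_new_snp <- stats::rpois(1L, plan$snp_rate * n_snp_sites * N)
      n_new_hp <- stats::rpois(1L, plan$hp_indel_rate * n_hp_sites * N)
      n_new_del <- if (is.null(rs)) 0L else
        stats::rpois(1L, plan$deletion_rate * N)
      if (n_new_snp > 0L) {
        for (i in seq_len(n_new_snp)) {
          pos <- sample_snp_site(genome, atr)
          ref <- chars[pos]
          alt <- sample(setdiff(BASES, ref), 1L)
          vars <- rbind(vars, data.frame(
            id = sprintf("dn_snp_g%d_%d", g, i), type = "SNP", position = pos,
            ref = ref, alt = alt, length = 1L, frequency = 1 / N, b = 1,
            origin_generation = g, stringsAsFactors = FALSE))
          initial_freq <- c(initial_freq, 0)
        }
      }
      if (n_new_hp > 0L && nrow(hp_runs)) {
        for (i in seq_len(n_new_hp)) {
          run <- hp_runs[sample.int(nrow(hp_runs), 1L), ]
          type <- sample(c("insertion", "deletion"), 1L)
          vars <- rbind(vars, data.frame(
            id = sprintf("dn_hp_g%d_%d", g, i), type = type,
            position = run$start, ref = run$base, alt = run$base,
            length = 1L, frequency = 1 / N, b = 1,
            origin_generation = g, stringsAsFactors = FALSE))
          initial_freq <- c(initial_freq, 0)
        }
      }
      if (n_new_del > 0L) {
        for (i in seq_len(n_new_del)) {
          vars <- rbind(vars, data.frame(
            id = sprintf("dn_del_g%d", g), type = "large_deletion",
            position = rs$left_start + rs$mismatch_offset,
            ref = "N", alt = "-",
            length = rs$right_start - rs$left_start,
            frequency = 1 / N, b = plan$deletion_b,
            origin_generation = g, stringsAsFactors = FALSE))
          initial_freq <- c(initial_freq, 0)
        }
      }
      if (nrow(vars)) {
        p <- vars$frequency
        w <- p * vars$b / (p * vars$b + (1 - p))
        w[p >= 1] <- 1
        vars$frequency <- stats::rbinom(nrow(vars), N, w) / N
      }
    }

    vars$fate <- ifelse(vars$frequency >= 1, "fixed_variant",
                 ifelse(vars$frequency > 0, "heteroplasmic",
                 ifelse(initial_freq > 0, "fixed_reference", "lost")))
    structure(list(variants = vars, generations = plan$generations,
                   n_eff = N), class = "lineage_state")
  })
}

sample_snp_site <- function(genome, atr) {
  excl <- feature_positions(atr, genome$length)
  repeat {
    pos <- sample.int(genome$length, 1L)
    if (!(pos %in% excl)) return(pos)
  }
}

#' Construct a lineage state directly from a variant table
#'
#' Convenience for planting known truth frequencies (e.g. a repeat-mediated
#' deletion at 0.85) without simulating drift.
#' @param variants Data frame with at least `type`, `position`, `frequency`
#'   (plus `ref`, `alt`, `length` as applicable).
#' @param generations Generation count to record.
#' @return A `lineage_state`.
#' @export
lineage_state <- function(variants, generations = 0L) {
  vars <- normalize_variants(variants)
  vars$fate <- ifelse(vars$frequency >= 1, "fixed_variant",
               ifelse(vars$frequency > 0, "heteroplasmic", "lost"))
  structure(list(variants = vars, generations = as.integer(generations),
                 n_eff = NA_integer_), class = "lineage_state")
}

#' @export
print.lineage_state <- function(x, ...) {
  cat(sprintf("<lineage_state> %d generation(s), %d variant(s): %s\n",
              x$generations, nrow(x$variants),
              paste(sprintf("%s@%0.3f", x$variants$type, x$variants$frequency),
                    collapse = ", ")))
  invisible(x)
}
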