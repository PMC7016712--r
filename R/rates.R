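# Mutation-rate estimation for MA experiments.
#
# The per-site per-generation rate for a variant class is
#
#   mu = m / (L * n * T)                               (rate)
#   SE = sqrt(mu / (L * n * T))                        (standard error)
#
# where m is the summed mutation measure (over MA lines, the sum of
# |variant frequency in the line - variant frequency in the progenitor|
# across the union of variant sites, absent = 0), L the number of MA lines,
# n the number of scanned nucleotide sites for the class, and T the average
# number of MA generations per line.

#' Average generations per MA line
#'
#' @param generations Positive numeric vector of per-line generation counts.
#' @return Arithmetic mean.
#' @export
average_generations <- function(generations) {
  if (!length(generations)) stopf("no generation counts supplied")
  if (any(generations <= 0)) stopf("generation counts must be positive")
  mean(generations)
}

#' Summed frequency-difference mutation measure m
#'
#' For every MA line and every (site, alternate allele) present in the line
#' or the progenitor for the chosen variant class, accumulates
#' |freq_MA - freq_progenitor| with absent treated as frequency 0. For the
#' homopolymer-indel class, only calls whose homopolymer run length is at
#' least `min_run` are counted (slippage below that threshold is reported
#' by the caller but excluded from rate estimation).
#'
#' @param progenitor_calls Call data frame for the progenitor (may be the
#'   permissive screen).
#' @param ma_calls_list Named list of call data frames, one per MA line.
#' @param class `"base_substitution"` or `"homopolymer_indel"`.
#' @param census Optional [census_homopolymers()] whose `min_run` applies.
#' @param min_run Run-length threshold when `census` is not given.
#' @return The scalar m.
#' @export
estimate_m <- function(progenitor_calls, ma_calls_list,
                       class = c("base_substitution", "homopolymer_indel"),
                       census = NULL, min_run = 8L) {
  class <- match.arg(class)
  if (!is.null(census)) min_run <- census$min_run
  sel <- function(df) {
    if (!nrow(df)) return(df)
    if (class == "base_substitution") df[df$type == "SNP", , drop = FALSE]
    else df[df$type %in% c("insertion", "deletion") &
              !is.na(df$hp_run_length) & df$hp_run_length >= min_run, ,
            drop = FALSE]
  }
  key <- function(df) paste(df$position, df$type, df$alt, df$length,
                            sep = "\r")
  prog <- sel(progenitor_calls)
  prog_freq <- stats::setNames(prog$frequency, key(prog))
  m <- 0
  for (ma in ma_calls_list) {
    ma <- sel(ma)
    ma_freq <- stats::setNames(ma$frequency, key(ma))
    union_keys <- union(names(prog_freq), names(ma_freq))
    for (kk in union_keys) {
      f_ma <- if (kk %in% names(ma_freq)) ma_freq[[kk]] else 0
      f_pr <- if (kk %in% names(prog_freq)) prog_freq[[kk]] else 0
      m <- m + abs(f_ma - f_pr)
    }
  }
  m
}

#' Mutation rate and standard error from (m, L, n, T)
#'
#' @param m Summed mutation measure (>= 0).
#' @param L Number of MA lines (>= 1).
#' @param n Number of scanned nucleotide sites (>= 1).
#' @param T_gen Average generations per line (> 0).
#' @param class Variant class label carried in the result.
#' @return A `rate_estimate`: list with `mu`, `se`, `class` and the inputs.
#' @export
mutation_rate <- function(m, L, n, T_gen, class = "base_substitution") {
  stopifnot(m >= 0, L >= 1, n >= 1, T_gen > 0)
  denom <- L * n * T_gen
  mu <- m / denom
  structure(list(mu = mu, se = sqrt(mu / denom), class = class,
                 m = m, L = L, n = n, T_gen = T_gen),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %s: mu = %.3e (SE = %.3e) site^-1 generation^-1 [m = %.3f, L = %d, n = %d, T = %.1f]\n",
              x$class, x$mu, x$se, x$m, x$L, x$n, x$T_gen))
  invisible(x)
}

#' Combined rate report
#'
#' @param snp_estimate,hp_estimate `rate_estimate` objects for the base
#'   substitution and homopolymer-indel classes.
#' @param path Optional TSV output path.
#' @return Data frame with one row per class (class, m, L, n, T, mu, se).
#' @export
rate_report <- function(snp_estimate, hp_estimate, path = NULL) {
  row <- function(x) data.frame(class = x$class, m = x$m, L = x$L, n = x$n,
                                T_gen = x$T_gen, mu = x$mu, se = x$se,
                                stringsAsFactors = FALSE)
  out <- rbind(row(snp_estimate), row(hp_estimate))
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' End-to-end rate estimation from calls
#'
#' Convenience wrapper: computes m for both classes, n from the genome
#' (total length minus the AT-rich region for substitutions; the
#' homopolymer census for indels) and applies the closed forms.
#'
#' @param progenitor_calls Progenitor call table.
#' @param ma_calls_list Named list of MA-line call tables.
#' @param generations Per-line generation counts (same order/length as the
#'   list).
#' @param genome The reference [annotated_genome()].
#' @param min_run Homopolymer census threshold (default 8).
#' @return Data frame as from [rate_report()].
#' @export
estimate_rates <- function(progenitor_calls, ma_calls_list, generations,
                           genome, min_run = 8L) {
  stopifnot(length(generations) == length(ma_calls_list))
  T_gen <- average_generations(generations)
  L <- length(ma_calls_list)
  census <- census_homopolymers(genome, min_run = min_run)
  atr <- feature_by_role(genome, "AT-rich")
  n_snp <- genome$length - length(feature_positions(atr, genome$length))
  m_snp <- estimate_m(progenitor_calls, ma_calls_list, "base_substitution")
  m_hp <- estimate_m(progenitor_calls, ma_calls_list, "homopolymer_indel",
                     census = census)
  n_hp <- max(census$n_sites, 1L)
  rate_report(
    mutation_rate(m_snp, L, n_snp, T_gen, "base_substitution"),
    mutation_rate(m_hp, L, n_hp, T_gen, "homopolymer_indel"))
}
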