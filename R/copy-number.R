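# Nuclear-normalized mtDNA copy-number analysis.
#
# Per-position mtgenome coverage (AT-rich region excluded) is divided by
# the mean of the average coverages of three single-copy nuclear loci; the
# resulting per-position values are compared across samples with
# nonparametric tests (Kruskal-Wallis + Dunn's post hoc against the
# progenitor; two-sample Kolmogorov-Smirnov between isolates), after a
# D'Agostino-Pearson normality check.

#' Normalize mtDNA coverage to nuclear loci
#'
#' @param mt_coverage Numeric vector of per-position raw mtDNA coverage
#'   (length = genome length), e.g. `pileup$coverage`.
#' @param nuclear_coverages List of per-position coverage vectors, one per
#'   nuclear locus (three loci in the emulated design).
#' @param genome The mitochondrial [annotated_genome()] (supplies the
#'   AT-rich region to exclude).
#' @param sample_id Sample label.
#' @return A `normalized_coverage`: list with `sample_id`, `values`
#'   (named per-position normalized coverage, AT-rich positions dropped),
#'   `normalizer`, `mean`, `sd`.
#' @export
normalize_coverage <- function(mt_coverage, nuclear_coverages, genome,
                               sample_id = "sample") {
  stopifnot(inherits(genome, "annotated_genome"))
  if (length(mt_coverage) != genome$length) {
    stopf("mt_coverage length (%d) does not match genome length (%d)",
          length(mt_coverage), genome$length)
  }
  loc_means <- vapply(nuclear_coverages, mean, numeric(1))
  if (any(!is.finite(loc_means)) || any(loc_means <= 0)) {
    stopf("every nuclear locus must have positive coverage")
  }
  normalizer <- mean(loc_means)
  atr <- feature_by_role(genome, "AT-rich")
  drop <- feature_positions(atr, genome$length)
  keep <- setdiff(seq_len(genome$length), drop)
  values <- mt_coverage[keep] / normalizer
  names(values) <- keep
  structure(list(sample_id = sample_id, values = values,
                 normalizer = normalizer, mean = mean(values),
                 sd = stats::sd(values)),
            class = "normalized_coverage")
}

#' @export
print.normalized_coverage <- function(x, ...) {
  cat(sprintf("<normalized_coverage> %s: %d position(s), mean %.2f (SD %.3f), normalizer %.2f\n",
              x$sample_id, length(x$values), x$mean, x$sd, x$normalizer))
  invisible(x)
}

#' Compare MA-line coverage distributions to the progenitor
#'
#' Kruskal-Wallis over all groups, then Dunn's multiple-comparisons test
#' for each MA-vs-progenitor contrast with Bonferroni adjustment over those
#' contrasts, plus each line's mean difference from the progenitor.
#'
#' @param ma List of `normalized_coverage` objects (MA lines).
#' @param progenitor A `normalized_coverage` for the progenitor.
#' @return List with `kruskal` (`statistic`, `p_value`, `df`) and
#'   `contrasts` (data frame: `sample_id`, `z`, `p_unadjusted`,
#'   `p_adjusted`, `mean_difference` = progenitor mean - line mean).
#' @export
compare_to_progenitor <- function(ma, progenitor) {
  groups <- c(list(progenitor), ma)
  sizes <- vapply(groups, function(g) length(g$values), integer(1))
  if (any(sizes < 2L)) stopf("every group needs at least 2 values")
  values <- unlist(lapply(groups, function(g) g$values), use.names = FALSE)
  labels <- factor(rep(seq_along(groups), sizes))
  kw <- stats::kruskal.test(values, labels)
  dunn <- dunn_contrasts(values, labels, control = 1L)
  contrasts <- data.frame(
    sample_id = vapply(ma, function(g) g$sample_id, character(1)),
    z = dunn$z, p_unadjusted = dunn$p,
    p_adjusted = pmin(1, dunn$p * length(ma)),
    mean_difference = progenitor$mean -
      vapply(ma, function(g) g$mean, numeric(1)),
    stringsAsFactors = FALSE)
  list(kruskal = list(statistic = unname(kw$statistic),
                      p_value = kw$p.value,
                      df = unname(kw$parameter)),
       contrasts = contrasts)
}

# Dunn's z statistics of every non-control group against the control,
# with the usual tie correction on the pooled rank variance.
dunn_contrasts <- function(values, labels, control = 1L) {
  N <- length(values)
  rk <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(rk, labels, mean)
  n <- tabulate(labels)
  idx <- setdiff(seq_along(n), control)
  z <- vapply(idx, function(i) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[control]))
    (mean_rank[[i]] - mean_rank[[control]]) / se
  }, numeric(1))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param a,b `normalized_coverage` objects (or numeric vectors).
#' @return List with `D` and `p_value`.
#' @export
compare_distributions <- function(a, b) {
  va <- if (inherits(a, "normalized_coverage")) a$values else a
  vb <- if (inherits(b, "normalized_coverage")) b$values else b
  if (!length(va) || !length(vb)) stopf("both samples must be non-empty")
  ks <- suppressWarnings(stats::ks.test(va, vb))
  list(D = unname(ks$statistic), p_value = ks$p.value)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness z and the Anscombe-Glynn kurtosis z
#' into K^2 = z1^2 + z2^2, referred to a chi-squared distribution with 2
#' degrees of freedom.
#'
#' @param values Numeric vector, n >= 20.
#' @return List with `k2`, `p_value`, `z_skewness`, `z_kurtosis`, `n`.
#' @export
normality_check <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 20L) stopf("normality_check requires at least 20 values")
  if (stats::sd(values) == 0) stopf("degenerate (constant) sample")
  x <- values - mean(values)
  m2 <- mean(x^2); m3 <- mean(x^3); m4 <- mean(x^4)

  # skewness (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis (Anscombe & Glynn 1983)
  g2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(k2 = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skewness = z1, z_kurtosis = z2, n = n)
}
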