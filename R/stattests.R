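# Self-contained statistical tests used by the crossing and screening
# analyses, returning uniform one-row result tibbles.

test_result <- function(statistic, p, df = NA_real_, n = NA_integer_, method) {
  tibble::tibble(statistic = statistic, p = max(p, .Machine$double.xmin),
                 df = df, n = n, method = method)
}

#' Chi-squared test of a 2x2 table
#'
#' Pearson chi-squared with Yates continuity correction by default (the
#' correction is capped so `|O - E| - 0.5` never goes negative), 1 degree
#' of freedom. Any zero margin is an error.
#'
#' @param table A 2x2 non-negative integer matrix (or something coercible).
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return A one-row result tibble.
#' @export
chisq_2x2 <- function(table, correct = TRUE) {
  m <- matrix(as.numeric(as.matrix(table)), 2, 2)
  if (any(m < 0) || any(m != round(m))) {
    stop("table must contain non-negative integers", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero margin in 2x2 table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  test_result(unname(ct$statistic), ct$p.value, df = 1, n = sum(m),
              method = if (correct) "chi-squared (Yates)" else "chi-squared")
}

#' Exact two-sided binomial test
#'
#' Exact binomial test with the minimum-likelihood two-sided convention
#' (outcomes no more probable than the observed one are summed).
#'
#' @param k Successes.
#' @param n Trials.
#' @param p0 Null probability (default 0.5).
#' @return A one-row result tibble (`statistic` is the observed proportion).
#' @export
binom_two_sided <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n)
  bt <- stats::binom.test(k, n, p = p0)
  test_result(k / n, bt$p.value, n = n, method = "exact binomial, two-sided")
}

#' Sample size for detecting a binomial proportion shift
#'
#' Normal-approximation sample size for a two-sided test of `p0` against
#' `p1`:
#' `n = ((z_{1-a/2} sqrt(p0 q0) + z_{1-b} sqrt(p1 q1)) / |p1 - p0|)^2`,
#' rounded up.
#'
#' @param p0,p1 Null and alternative proportions.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @return Required sample size (integer).
#' @export
binom_sample_size <- function(p0, p1, alpha = 0.05, power = 0.8) {
  stopifnot(p0 > 0, p0 < 1, p1 > 0, p1 < 1, p0 != p1)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n <- ((za * sqrt(p0 * (1 - p0)) + zb * sqrt(p1 * (1 - p1))) / abs(p1 - p0))^2
  ceiling(n)
}

#' Wilcoxon signed-rank test on paired values
#'
#' Two-sided signed-rank test on `x - y` (or on `x` alone): zero
#' differences are dropped (signed-rank convention), ties are mid-ranked,
#' the exact distribution is used below 25 non-zero differences when there
#' are no ties, and the normal approximation otherwise. All-zero
#' differences give p = 1 with `all_zero = TRUE`.
#'
#' @param x Numeric vector (differences, or first member of each pair).
#' @param y Optional second member of each pair.
#' @return A one-row result tibble with an extra `all_zero` column.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (!length(nz)) {
    out <- test_result(NA_real_, 1, n = length(d), method = "Wilcoxon signed-rank")
    out$all_zero <- TRUE
    return(out)
  }
  exact <- length(nz) < 25 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(stats::wilcox.test(nz, exact = exact, correct = TRUE))
  out <- test_result(unname(wt$statistic), wt$p.value, n = length(nz),
                     method = paste0("Wilcoxon signed-rank",
                                     if (exact) " (exact)" else " (normal approx.)"))
  out$all_zero <- FALSE
  out
}

#' Coverage-based symbiont infection call
#'
#' A sample is called infected when its mean read depth over the symbiont
#' scaffolds reaches `threshold` times its genome-wide mean depth.
#'
#' @param scaffold_depths Named numeric vector of per-scaffold mean depths.
#' @param symbiont_scaffolds Names of the symbiont scaffolds (non-empty).
#' @param genome_mean Genome-wide mean depth.
#' @param threshold Fraction of the genome-wide mean (default 0.1).
#' @return `"infected"` or `"uninfected"`.
#' @export
infection_call <- function(scaffold_depths, symbiont_scaffolds, genome_mean,
                           threshold = 0.1) {
  if (!length(symbiont_scaffolds)) {
    stop("symbiont scaffold set is empty", call. = FALSE)
  }
  d <- scaffold_depths[symbiont_scaffolds]
  if (anyNA(d)) stop("unknown symbiont scaffold(s)", call. = FALSE)
  if (any(d < 0) || genome_mean < 0) stop("depths must be >= 0", call. = FALSE)
  if (mean(d) >= threshold * genome_mean) "infected" else "uninfected"
}
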