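# Sliding-window diversity and differentiation.
#
# All per-site statistics are computed from allele counts among called
# alleles: pi as expected heterozygosity under sampling without replacement,
# dXY as the cross-population mismatch probability, and FST as the Hudson
# estimator 1 - pi_within / dXY taken as a ratio of window sums. Invariant
# positions of an `all_callable` matrix contribute zero to every numerator
# and one callable site to every denominator.

# Per-site allele counts for one sample set. Returns a list of matrices
# (sites x alleles) `cnt` and the vector `n` of called alleles per site.
allele_counts <- function(gm, samples) {
  ci <- match(samples, gm$samples)
  if (anyNA(ci)) stop("unknown sample(s): ",
                      paste(samples[is.na(ci)], collapse = ", "), call. = FALSE)
  a1 <- gm$gt1[, ci, drop = FALSE]; a2 <- gm$gt2[, ci, drop = FALSE]
  max_a <- max(0L, a1, a2, na.rm = TRUE)
  cnt <- matrix(0L, nrow = n_sites(gm), ncol = max_a + 1L)
  for (a in 0:max_a) {
    cnt[, a + 1L] <- rowSums(a1 == a, na.rm = TRUE) + rowSums(a2 == a, na.rm = TRUE)
  }
  list(cnt = cnt, n = rowSums(cnt))
}

site_pi <- function(ac) {
  n <- ac$n
  num <- rowSums(ac$cnt * (ac$cnt - 1L))
  out <- ifelse(n >= 2, 1 - num / (n * (n - 1)), NA_real_)
  out
}

site_dxy <- function(ac1, ac2) {
  n1 <- ac1$n; n2 <- ac2$n
  A <- max(ncol(ac1$cnt), ncol(ac2$cnt))
  pad <- function(m) if (ncol(m) < A) cbind(m, matrix(0L, nrow(m), A - ncol(m))) else m
  same <- rowSums(pad(ac1$cnt) * pad(ac2$cnt))
  ifelse(n1 >= 1 & n2 >= 1, 1 - same / (n1 * n2), NA_real_)
}

window_sum <- function(values, pos, usable, win) {
  # cumulative sums over sorted positions; win = c(start, end)
  lo <- findInterval(win[1] - 0.5, pos)
  hi <- findInterval(win[2] - 0.5, pos)
  if (hi <= lo) return(c(sum = 0, n_use = 0L, n_var = 0L))
  idx <- (lo + 1):hi
  u <- usable[idx]
  c(sum = sum(values[idx][u], na.rm = TRUE), n_use = sum(u), n_var = length(idx))
}

win_denominator <- function(gm, win, n_use, n_var) {
  unname(if (gm$all_callable) (win[2] - win[1]) - (n_var - n_use) else n_use)
}

#' Window diversity and differentiation
#'
#' For one window, per-population nucleotide diversity (pi), and for every
#' population pair the absolute divergence dXY and Hudson's FST
#' (1 - pi_within / dXY, as a ratio of window sums). Missing calls are
#' excluded per site; a site enters a statistic only when enough alleles are
#' called in each population involved (two for pi and FST, one for dXY).
#'
#' @param gm A [genotype_matrix()].
#' @param populations Named list of character vectors of sample ids.
#' @param window A window as `c(start, end)` on `chrom`, or a one-row tibble
#'   from [iter_windows()].
#' @param chrom Chromosome (defaulted from a tibble `window`).
#' @return A tibble with columns `stat` (`pi`, `dxy`, `fst`), `pop`, `value`,
#'   `n_sites`.
#' @export
window_diversity <- function(gm, populations, window, chrom = NULL) {
  if (is.data.frame(window)) {
    chrom <- window$chrom[1]; window <- c(window$start[1], window$end[1])
  }
  stopifnot(!is.null(chrom), length(populations) >= 1,
            !is.null(names(populations)))
  si <- site_index(gm, chrom)
  sub <- subset_genotypes(gm, sites = si)
  pos <- sub$pos
  acs <- lapply(populations, function(s) allele_counts(sub, s))
  pis <- lapply(acs, site_pi)
  out <- list()
  for (pn in names(populations)) {
    u <- !is.na(pis[[pn]])
    ws <- window_sum(pis[[pn]], pos, u, window)
    denom <- win_denominator(gm, window, ws["n_use"], ws["n_var"])
    out[[length(out) + 1]] <- tibble::tibble(
      stat = "pi", pop = pn,
      value = if (denom > 0) ws[["sum"]] / denom else NA_real_,
      n_sites = as.integer(denom))
  }
  pns <- names(populations)
  if (length(pns) >= 2) {
    for (i in seq_len(length(pns) - 1)) for (j in (i + 1):length(pns)) {
      dxy <- site_dxy(acs[[i]], acs[[j]])
      u_d <- !is.na(dxy)
      ws_d <- window_sum(dxy, pos, u_d, window)
      denom_d <- win_denominator(gm, window, ws_d["n_use"], ws_d["n_var"])
      pw <- (pis[[i]] + pis[[j]]) / 2
      u_f <- !is.na(pw) & !is.na(dxy)
      ws_w <- window_sum(pw, pos, u_f, window)
      ws_b <- window_sum(dxy, pos, u_f, window)
      pair <- paste(pns[i], pns[j], sep = ":")
      out[[length(out) + 1]] <- tibble::tibble(
        stat = "dxy", pop = pair,
        value = if (denom_d > 0) ws_d[["sum"]] / denom_d else NA_real_,
        n_sites = as.integer(denom_d))
      out[[length(out) + 1]] <- tibble::tibble(
        stat = "fst", pop = pair,
        value = if (ws_b[["sum"]] > 0) 1 - ws_w[["sum"]] / ws_b[["sum"]] else NA_real_,
        n_sites = as.integer(win_denominator(gm, window, ws_w["n_use"], ws_w["n_var"])))
    }
  }
  dplyr::bind_rows(out)
}

#' Heterozygous-site density of one sample in a window
#'
#' Heterozygous calls per genotyped site. For an `all_callable` matrix the
#' denominator is the window length minus this sample's missing variant
#' calls; otherwise the sample's non-missing variant calls in the window.
#' Haploid-coded sites are a contract violation.
#'
#' @inheritParams window_diversity
#' @param sample One sample id.
#' @return A single numeric density, or `NA` when nothing is genotyped.
#' @export
het_density <- function(gm, sample, window, chrom = NULL) {
  if (is.data.frame(window)) {
    chrom <- window$chrom[1]; window <- c(window$start[1], window$end[1])
  }
  ci <- match(sample, gm$samples)
  if (is.na(ci)) stop("unknown sample: ", sample, call. = FALSE)
  si <- site_index(gm, chrom, window[1], window[2])
  if (any(gm$haploid[si])) {
    stop("het_density is undefined for haploid-coded sites", call. = FALSE)
  }
  a1 <- gm$gt1[si, ci]; a2 <- gm$gt2[si, ci]
  called <- !is.na(a1) & !is.na(a2)
  het <- sum(called & a1 != a2)
  denom <- if (gm$all_callable) (window[2] - window[1]) - sum(!called)
           else sum(called)
  if (denom <= 0) return(NA_real_)
  het / denom
}

#' Sliding-window genome scan
#'
#' Applies [window_diversity()] or [het_density()] over sliding windows
#' (default 100 kb, step 20 kb) across the chromosomes of a layout. Windows
#' with fewer than `min_sites` genotyped sites are emitted with a null value
#' and `low_sites = TRUE` rather than dropped.
#'
#' @param gm A [genotype_matrix()].
#' @param meta Sample table with columns `sample` and `population` (for
#'   `statistic = "het"`, per-sample rows are emitted instead).
#' @param layout A [genome_layout()]; defaults to the one attached to `gm`.
#' @param statistic One of `"pi"`, `"dxy"`, `"fst"`, `"het"`.
#' @param populations Character vector of population labels to use (default:
#'   all in `meta`); unknown labels are an error.
#' @param size,step Window size and step in bp.
#' @param min_sites Minimum genotyped sites per window (default 20,000).
#' @param chromosomes Chromosomes to scan (default: all in the layout).
#' @param region Optional `c(start, end)` restriction applied on every
#'   scanned chromosome.
#' @return A tibble: `chrom`, `start`, `end`, `n_sites`, `stat`, `pop`,
#'   `value`, `low_sites`.
#' @export
genome_scan <- function(gm, meta, layout = gm$layout, statistic = "fst",
                        populations = NULL, size = 1e5, step = 2e4,
                        min_sites = 2e4, chromosomes = NULL, region = NULL) {
  stopifnot(statistic %in% c("pi", "dxy", "fst", "het"))
  if (is.null(layout)) stop("a genome layout is required", call. = FALSE)
  if (is.null(chromosomes)) chromosomes <- intersect(layout$chrom, unique(gm$chrom))
  if (statistic == "het") {
    groups <- stats::setNames(as.list(meta$sample), meta$sample)
  } else {
    if (is.null(populations)) populations <- unique(meta$population)
    unknown <- setdiff(populations, meta$population)
    if (length(unknown)) stop("unknown population label(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    groups <- lapply(stats::setNames(populations, populations),
                     function(pp) meta$sample[meta$population == pp])
  }
  res <- list()
  for (ch in chromosomes) {
    wins <- iter_windows(layout, ch, size, step)
    if (!is.null(region)) {
      wins <- wins[wins$start >= region[1] & wins$end <= region[2], ]
    }
    for (w in seq_len(nrow(wins))) {
      win <- c(wins$start[w], wins$end[w])
      if (statistic == "het") {
        rows <- dplyr::bind_rows(lapply(names(groups), function(s) {
          v <- het_density(gm, s, win, chrom = ch)
          ci <- match(s, gm$samples)
          si <- site_index(gm, ch, win[1], win[2])
          called <- sum(!is.na(gm$gt1[si, ci]) & !is.na(gm$gt2[si, ci]))
          ns <- if (gm$all_callable) (win[2] - win[1]) - (length(si) - called)
                else called
          tibble::tibble(stat = "het", pop = s, value = v,
                         n_sites = as.integer(ns))
        }))
      } else {
        rows <- window_diversity(gm, groups, win, chrom = ch)
        rows <- rows[rows$stat == statistic, ]
      }
      rows$chrom <- ch; rows$start <- win[1]; rows$end <- win[2]
      res[[length(res) + 1]] <- rows
    }
  }
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) return(out)
  out$low_sites <- out$n_sites < min_sites
  out$value[out$low_sites] <- NA_real_
  dplyr::select(out, "chrom", "start", "end", "n_sites", "stat", "pop",
                "value", "low_sites")
}

#' Diversity at 4-fold degenerate positions
#'
#' Per-site pi restricted to positions classified `fourfold` by
#' [classify_degeneracy()]. For an `all_callable` matrix the denominator is
#' the number of classified 4-fold positions; otherwise the number of
#' genotyped 4-fold variant sites.
#'
#' @param gm A [genotype_matrix()].
#' @param degeneracy A degeneracy map from [classify_degeneracy()].
#' @param samples Sample ids (default: all).
#' @return A single per-site diversity.
#' @export
fourfold_pi <- function(gm, degeneracy, samples = gm$samples) {
  ff <- degeneracy[degeneracy$class == "fourfold", ]
  if (!nrow(ff)) return(NA_real_)
  key <- paste(gm$chrom, gm$pos)
  idx <- which(key %in% paste(ff$chrom, ff$pos))
  num <- 0; n_use <- 0
  if (length(idx)) {
    sub <- subset_genotypes(gm, sites = idx)
    ac <- allele_counts(sub, samples)
    pv <- site_pi(ac)
    num <- sum(pv, na.rm = TRUE); n_use <- sum(!is.na(pv))
  }
  denom <- if (gm$all_callable) nrow(ff) - (length(idx) - n_use) else n_use
  if (denom <= 0) return(NA_real_)
  num / denom
}

#' Copy-number call from normalised read depth
#'
#' Classifies a region's per-window depths (normalised by the sample's
#' genome-wide mean) as two copies (anchor 1), one copy (anchor 0.5) or zero
#' copies (anchor 0): the median is assigned to the nearest anchor if within
#' `band` of it, otherwise `no_call`.
#'
#' @param depths Numeric vector of normalised window depths.
#' @param band Half-width of the call band around each anchor (default 0.2).
#' @return One of `"two_copies"`, `"one_copy"`, `"zero_copies"`, `"no_call"`,
#'   or `NA` for an empty region.
#' @export
depth_genotype <- function(depths, band = 0.2) {
  depths <- depths[!is.na(depths)]
  if (!length(depths)) return(NA_character_)
  med <- stats::median(depths)
  anchors <- c(two_copies = 1, one_copy = 0.5, zero_copies = 0)
  d <- abs(med - anchors)
  if (min(d) < band) names(anchors)[which.min(d)] else "no_call"
}
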