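# Per-window haplotype cluster assignment ("chromosome painting") of the
# supergene against three reference allele groups, with the 80%-distance
# rule, plus the per-individual supergene genotype call.

#' A phased haplotype alignment
#'
#' Haplotypes over a shared set of variant sites on one chromosome: an
#' allele-code matrix (sites x haplotypes, `NA` = missing) with 0-based
#' positions. This is the substrate of distance computation, painting and
#' tree building.
#'
#' @param chrom Chromosome name.
#' @param pos 0-based positions (strictly increasing).
#' @param H Integer matrix of allele codes, sites x haplotypes.
#' @param labels Haplotype labels (default column names).
#' @return An object of class `hap_set`.
#' @export
hap_set <- function(chrom, pos, H, labels = colnames(H)) {
  H <- as.matrix(H)
  stopifnot(length(pos) == nrow(H), !is.unsorted(pos, strictly = TRUE))
  if (is.null(labels)) labels <- paste0("hap", seq_len(ncol(H)))
  colnames(H) <- labels
  structure(list(chrom = chrom, pos = as.numeric(pos), H = H, labels = labels),
            class = "hap_set")
}

#' @exportS3Method base::print
print.hap_set <- function(x, ...) {
  cat("<hap_set>", length(x$pos), "sites x", ncol(x$H), "haplotypes on",
      x$chrom, "\n")
  invisible(x)
}

#' True phased haplotypes of cohort samples
#'
#' Builds a [hap_set()] from a simulated cohort's ground-truth phase, over
#' the cohort's variant sites on one chromosome. Columns are labelled
#' `<sample>|1` (maternal) and `<sample>|2` (paternal). Real-data use
#' requires externally phased input instead.
#'
#' @param cohort A `neow_cohort`.
#' @param chrom Chromosome (default `"chr15"`).
#' @param samples Sample ids (default all).
#' @return A [hap_set()].
#' @export
cohort_haplotypes <- function(cohort, chrom = "chr15", samples = NULL) {
  if (is.null(samples)) samples <- cohort$samples$sample
  gm <- cohort$gm
  si <- which(gm$chrom == chrom)
  pos <- gm$pos[si]
  cols <- list()
  for (s in samples) {
    h <- cohort$truth$haps[[s]]
    sets <- switch(chrom, chr15 = h$chr15, auto1 = h$auto,
                   mito = list(mat = h$mito))
    for (k in seq_along(sets)) {
      cols[[paste0(s, "|", k)]] <- as.integer(pos %in% sets[[k]])
    }
  }
  hap_set(chrom, pos, do.call(cbind, cols))
}

#' Pairwise haplotype distance in a window
#'
#' Proportion of mismatching alleles among pairwise-complete sites inside
#' the window; `NA` when fewer than `min_sites` complete sites remain.
#'
#' @param hapA,hapB Allele-code vectors aligned on the same site set
#'   (`NA` = missing).
#' @param pos Optional positions (required with `window`).
#' @param window Optional `c(start, end)` restriction.
#' @param min_sites Minimum pairwise-complete sites (default 100).
#' @return A proportion in `[0, 1]`, or `NA`.
#' @export
hap_distance <- function(hapA, hapB, pos = NULL, window = NULL, min_sites = 100) {
  stopifnot(length(hapA) == length(hapB))
  keep <- !is.na(hapA) & !is.na(hapB)
  if (!is.null(window)) {
    stopifnot(!is.null(pos))
    keep <- keep & pos >= window[1] & pos < window[2]
  }
  n <- sum(keep)
  if (n < min_sites) return(NA_real_)
  sum(hapA[keep] != hapB[keep]) / n
}

group_mean_distance <- function(hap, ref_H, min_sites) {
  d <- vapply(seq_len(ncol(ref_H)), function(j) {
    keep <- !is.na(hap) & !is.na(ref_H[, j])
    n <- sum(keep)
    if (n < min_sites) return(NA_real_)
    sum(hap[keep] != ref_H[keep, j]) / n
  }, numeric(1))
  if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
}

#' Assign one haplotype to a reference cluster
#'
#' The haplotype is assigned to the reference group to which its average
#' genetic distance is smallest, provided that distance is strictly less
#' than `ratio` (default 0.8) times the average distance to the other two
#' groups; otherwise it is left unassigned. "Average distance to the other
#' two groups" is by default the mean of the two group-mean distances
#' (`other = "mean_of_means"`); `other = "pooled"` averages over all their
#' haplotypes instead.
#'
#' @param hap Allele-code vector.
#' @param references Named list of three reference allele-code matrices
#'   aligned on the same sites as `hap`.
#' @param ratio Assignment threshold (default 0.8).
#' @param min_sites Minimum pairwise-complete sites per distance.
#' @param other How the non-focal groups are averaged (see above).
#' @return A list: `cluster` (group name or `NA`), `distances` (named).
#' @export
assign_cluster <- function(hap, references, ratio = 0.8, min_sites = 100,
                           other = c("mean_of_means", "pooled")) {
  other <- match.arg(other)
  stopifnot(length(references) == 3, !is.null(names(references)))
  d <- vapply(references, function(R) group_mean_distance(hap, R, min_sites),
              numeric(1))
  if (anyNA(d)) return(list(cluster = NA_character_, distances = d))
  best <- which.min(d)
  d_other <- if (other == "mean_of_means") mean(d[-best]) else {
    pooled <- do.call(cbind, references[-best])
    group_mean_distance(hap, pooled, min_sites)
  }
  # strict inequality, guarded against floating-point ties at the boundary
  strictly_below <- !is.na(d_other) && d_other > 0 &&
    d[best] / d_other < ratio - 1e-9
  cl <- if (strictly_below) names(d)[best] else NA_character_
  list(cluster = cl, distances = d)
}

#' Paint a sample's chromosome against three reference groups
#'
#' Analyses each window (default 20 kb) separately: both haplotypes of the
#' sample are assigned by [assign_cluster()] against the three reference
#' groups, yielding a painted chromosome; the supergene genotype is then
#' called per haplotype as the majority cluster over windows inside the
#' supergene interval, and a haplotype whose assigned windows show more than
#' one cluster is flagged mosaic (putative recombinant). Windows with no
#' usable data give the missing state.
#'
#' @param haps A two-column matrix (or [hap_set()] restricted to one sample)
#'   of the sample's phased haplotypes.
#' @param references Named list of three [hap_set()] objects (or matrices
#'   aligned to `haps`).
#' @param pos Positions, defaulted from a `hap_set`.
#' @param chrom Chromosome name.
#' @param layout A [genome_layout()] used to enumerate windows.
#' @param window Window size (default 20 kb; step equals size).
#' @param sg_interval `c(start, end)` of the supergene used for the genotype
#'   call (default: all windows).
#' @param ratio,min_sites Passed to [assign_cluster()].
#' @param sample Sample label carried into the output.
#' @return A list of class `painted_chromosome`: `painting` (tibble: sample,
#'   hap, chrom, start, end, cluster, plus per-group distances) and
#'   `genotype` (tibble: hap, call, n_windows, mosaic).
#' @export
paint_chromosome <- function(haps, references, pos = NULL, chrom = NULL,
                             layout = NULL, window = 2e4, sg_interval = NULL,
                             ratio = 0.8, min_sites = 100, sample = "sample") {
  if (inherits(haps, "hap_set")) {
    pos <- haps$pos; chrom <- haps$chrom; haps <- haps$H
  }
  stopifnot(ncol(haps) == 2, !is.null(pos), !is.null(chrom))
  refs <- lapply(references, function(r) {
    if (inherits(r, "hap_set")) {
      idx <- match(pos, r$pos)
      r$H[idx, , drop = FALSE]
    } else r
  })
  if (is.null(layout)) {
    layout <- genome_layout(tibble::tibble(
      chrom = chrom, length = max(pos) + 1))
  }
  wins <- iter_windows(layout, chrom, size = window, step = window)
  rows <- list()
  for (w in seq_len(nrow(wins))) {
    in_w <- pos >= wins$start[w] & pos < wins$end[w]
    for (hp in 1:2) {
      hv <- haps[, hp]; hv[!in_w] <- NA
      a <- assign_cluster(hv, refs, ratio = ratio, min_sites = min_sites)
      state <- if (all(is.na(a$distances))) "missing"
               else if (is.na(a$cluster)) "unassigned" else a$cluster
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample = sample, hap = hp, chrom = chrom,
        start = wins$start[w], end = wins$end[w], cluster = state,
        !!!stats::setNames(as.list(a$distances),
                           paste0("d_", names(refs))))
    }
  }
  painting <- dplyr::bind_rows(rows)
  sg <- painting
  if (!is.null(sg_interval)) {
    sg <- sg[sg$start >= sg_interval[1] & sg$end <= sg_interval[2], ]
  }
  genotype <- dplyr::bind_rows(lapply(1:2, function(hp) {
    cl <- sg$cluster[sg$hap == hp & !sg$cluster %in% c("missing", "unassigned")]
    if (!length(cl)) {
      return(tibble::tibble(hap = hp, call = NA_character_,
                            n_windows = 0L, mosaic = NA))
    }
    tab <- sort(table(cl), decreasing = TRUE)
    tibble::tibble(hap = hp, call = names(tab)[1],
                   n_windows = length(cl),
                   mosaic = length(tab) > 1)
  }))
  structure(list(painting = painting, genotype = genotype),
            class = "painted_chromosome")
}

#' @exportS3Method base::print
print.painted_chromosome <- function(x, ...) {
  g <- x$genotype
  cat("<painted_chromosome>", nrow(x$painting) / 2, "windows; genotype",
      paste(g$call, collapse = "/"),
      if (any(g$mosaic %in% TRUE)) "(mosaic)", "\n")
  invisible(x)
}
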