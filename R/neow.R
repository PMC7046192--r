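# The neo-W discovery chain: the female-specific mutation scan, diagnostic
# heterozygous sites, fragment-based haploid reconstruction, haploid
# diversity, the divergence (heterozygosity) comparison, and moment-based
# root dating.

#' Scan for high-frequency female-specific alleles
#'
#' Counts, per sliding window, alleles whose frequency among called female
#' alleles exceeds `freq_threshold` while being absent from all called male
#' alleles (missing calls are excluded from both denominators; sites with no
#' called male alleles cannot assert absence and are skipped). A cohort
#' without males is an error since the contrast is undefined.
#'
#' @param gm A [genotype_matrix()].
#' @param meta Sample table with `sample` and `sex`.
#' @param layout A [genome_layout()]; defaults to the one attached to `gm`.
#' @param freq_threshold Minimum female allele frequency (default 0.2).
#' @param size,step Window size and step (defaults 100 kb / 20 kb).
#' @param chromosomes Chromosomes to scan.
#' @return A tibble: `chrom`, `start`, `end`, `count`.
#' @export
female_specific_scan <- function(gm, meta, layout = gm$layout,
                                 freq_threshold = 0.2, size = 1e5, step = 2e4,
                                 chromosomes = NULL) {
  females <- meta$sample[meta$sex == "female"]
  males <- meta$sample[meta$sex == "male"]
  if (!length(males)) {
    stop("no males in cohort: the female-specific contrast is undefined",
         call. = FALSE)
  }
  if (is.null(layout)) stop("a genome layout is required", call. = FALSE)
  if (is.null(chromosomes)) chromosomes <- intersect(layout$chrom, unique(gm$chrom))
  acf <- allele_counts(gm, females)
  acm <- allele_counts(gm, males)
  # a site qualifies if any non-reference allele passes the two-sided rule
  qual <- rep(FALSE, n_sites(gm))
  for (a in seq_len(max(1L, ncol(acf$cnt) - 1L))) {
    fa <- if (a + 1 <= ncol(acf$cnt)) acf$cnt[, a + 1] else 0L
    ma <- if (a + 1 <= ncol(acm$cnt)) acm$cnt[, a + 1] else 0L
    qual <- qual | (acf$n > 0 & acm$n > 0 &
                      fa / pmax(acf$n, 1) > freq_threshold & ma == 0L)
  }
  res <- list()
  for (ch in chromosomes) {
    wins <- iter_windows(layout, ch, size, step)
    on_ch <- gm$chrom == ch
    qpos <- gm$pos[on_ch & qual]
    res[[ch]] <- dplyr::mutate(wins, count = vapply(seq_len(nrow(wins)),
      function(w) sum(qpos >= wins$start[w] & qpos < wins$end[w]), numeric(1)))
  }
  dplyr::bind_rows(res)
}

#' Find diagnostic neo-W sites
#'
#' A diagnostic site carries an allele present in exactly one copy in every
#' carrier (all heterozygous for it) and absent from every non-carrier and
#' outgroup. By default every non-carrier must be genotyped and homozygous
#' for another allele; `max_missing_noncarriers` relaxes how many
#' non-carriers may be missing. Carriers are expected to be female; a
#' carrier missing at more than half the sites triggers a warning but is
#' still processed.
#'
#' @param gm A [genotype_matrix()].
#' @param carriers,non_carriers Disjoint character vectors of sample ids.
#' @param outgroups Additional sample ids the allele must be absent from.
#' @param meta Optional sample table used to check carrier sex.
#' @param chrom Restrict to one chromosome (default `"chr15"`).
#' @param max_missing_noncarriers Missing non-carrier calls tolerated per
#'   site (default 0).
#' @return A tibble of class `diagnostic_sites`: `chrom`, `pos`, `ref`,
#'   `alt`, `allele` (the neo-W allele index), with the carrier set as an
#'   attribute.
#' @export
find_diagnostic_sites <- function(gm, carriers, non_carriers,
                                  outgroups = character(0), meta = NULL,
                                  chrom = "chr15",
                                  max_missing_noncarriers = 0) {
  if (length(intersect(carriers, non_carriers))) {
    stop("carriers and non-carriers must be disjoint", call. = FALSE)
  }
  if (!is.null(meta)) {
    sex <- meta$sex[match(carriers, meta$sample)]
    if (any(sex != "female", na.rm = TRUE)) {
      stop("all carriers must be female", call. = FALSE)
    }
  }
  si <- if (is.null(chrom)) seq_len(n_sites(gm)) else which(gm$chrom == chrom)
  sub <- subset_genotypes(gm, sites = si)
  ci <- match(carriers, sub$samples)
  ni <- match(c(non_carriers, outgroups), sub$samples)
  if (anyNA(c(ci, ni))) stop("unknown sample id among carriers/non-carriers",
                             call. = FALSE)
  c1 <- sub$gt1[, ci, drop = FALSE]; c2 <- sub$gt2[, ci, drop = FALSE]
  miss_frac <- colMeans(is.na(c1))
  if (any(miss_frac > 0.5)) {
    warning("carrier(s) with >50% missing genotypes: ",
            paste(carriers[miss_frac > 0.5], collapse = ", "))
  }
  n1 <- sub$gt1[, ni, drop = FALSE]; n2 <- sub$gt2[, ni, drop = FALSE]
  max_a <- max(1L, c1, c2, n1, n2, na.rm = TRUE)
  hit_allele <- rep(NA_integer_, nrow(c1))
  for (a in seq_len(max_a)) {
    carrier_ok <- rowSums(is.na(c1) | is.na(c2)) == 0 &
      rowSums((c1 == a) + (c2 == a) == 1L) == length(ci) &
      rowSums(c1 == a & c2 == a) == 0
    nc_missing <- rowSums(is.na(n1) | is.na(n2))
    nc_has <- rowSums(n1 == a, na.rm = TRUE) + rowSums(n2 == a, na.rm = TRUE)
    nc_ok <- nc_has == 0 & nc_missing <= max_missing_noncarriers
    hit <- carrier_ok & nc_ok & is.na(hit_allele)
    hit_allele[hit] <- a
  }
  keep <- !is.na(hit_allele)
  out <- tibble::tibble(chrom = sub$chrom[keep], pos = sub$pos[keep],
                        ref = sub$ref[keep], alt = sub$alt[keep],
                        allele = hit_allele[keep])
  attr(out, "carriers") <- carriers
  class(out) <- c("diagnostic_sites", class(out))
  out
}

fragment_overlap_count <- function(starts, ends, sorted_pos) {
  findInterval(ends - 0.5, sorted_pos) - findInterval(starts - 0.5, sorted_pos)
}

coverage_intervals <- function(starts, ends, min_depth) {
  if (!length(starts)) return(matrix(numeric(0), ncol = 2))
  ev <- c(starts, ends)
  dl <- c(rep(1L, length(starts)), rep(-1L, length(ends)))
  o <- order(ev, -dl)
  ev <- ev[o]; depth <- cumsum(dl[o])
  on <- depth >= min_depth
  open <- which(on & !c(FALSE, on[-length(on)]))
  close <- which(!on & c(FALSE, on[-length(on)]))
  if (length(close) < length(open)) close <- c(close, length(ev))
  iv <- cbind(ev[open], ev[close])
  iv[iv[, 1] < iv[, 2], , drop = FALSE]
}

#' Reconstruct the haploid neo-W from diagnostic sites and fragments
#'
#' For each carrier, phased fragments that overlap a diagnostic site and
#' carry its neo-W allele are attributed to the neo-W; every variant site
#' covered by at least `min_support` attributed fragments receives the
#' haploid call those fragments carry, and all other positions stay
#' missing. The per-carrier genomic mask where attributed-fragment depth
#' reaches `min_support` is retained so that haploid diversity can be
#' expressed per covered base pair.
#'
#' @param gm A [genotype_matrix()] (supplies the variant-site universe).
#' @param diagnostics A [find_diagnostic_sites()] result.
#' @param fragments A `fragment_set` from the simulated cohort.
#' @param min_support Minimum attributed fragments per call (default 3,
#'   the haploid minimum-depth rule).
#' @return An object of class `neow_haplotypes`: `chrom`, `pos`, `H`
#'   (sites x carriers haploid allele calls, `NA` = missing), `support`,
#'   `masks` (per-carrier interval matrices), `no_fragment_carriers`.
#' @export
reconstruct_neow <- function(gm, diagnostics, fragments, min_support = 3) {
  carriers <- attr(diagnostics, "carriers")
  chrom <- fragments$chrom
  si <- which(gm$chrom == chrom)
  pos <- gm$pos[si]
  dpos <- sort(diagnostics$pos[diagnostics$chrom == chrom])
  H <- matrix(NA_integer_, nrow = length(pos), ncol = length(carriers),
              dimnames = list(NULL, carriers))
  supp <- matrix(0L, nrow = length(pos), ncol = length(carriers))
  masks <- stats::setNames(vector("list", length(carriers)), carriers)
  empty <- character(0)
  fr_all <- fragments$fragments
  for (k in seq_along(carriers)) {
    s <- carriers[k]
    fr <- fr_all[fr_all$sample == s, ]
    hsets <- fragments$haps[[s]]
    attributed <- logical(nrow(fr))
    if (nrow(fr)) {
      n_diag <- fragment_overlap_count(fr$start, fr$end, dpos)
      cand <- which(n_diag > 0)
      for (i in cand) {
        hs <- hsets[[fr$hap[i]]]
        dcov <- dpos[dpos >= fr$start[i] & dpos < fr$end[i]]
        # carries the neo-W (derived) allele at a covered diagnostic site
        attributed[i] <- any(dcov %in% hs)
      }
    }
    fa <- fr[attributed, ]
    if (!nrow(fa)) {
      masks[[s]] <- matrix(numeric(0), ncol = 2)
      empty <- c(empty, s)
      next
    }
    masks[[s]] <- coverage_intervals(fa$start, fa$end, min_support)
    # per-site support and calls
    for (i in seq_len(nrow(fa))) {
      in_fr <- which(pos >= fa$start[i] & pos < fa$end[i])
      if (!length(in_fr)) next
      supp[in_fr, k] <- supp[in_fr, k] + 1L
      hs <- hsets[[fa$hap[i]]]
      H[in_fr, k] <- as.integer(pos[in_fr] %in% hs)
    }
    H[supp[, k] < min_support, k] <- NA_integer_
  }
  if (length(empty)) {
    warning("carrier(s) with no attributed fragments: ",
            paste(empty, collapse = ", "))
  }
  structure(list(chrom = chrom, pos = pos, H = H, support = supp,
                 masks = masks, no_fragment_carriers = empty,
                 min_support = min_support),
            class = "neow_haplotypes")
}

#' @exportS3Method base::print
print.neow_haplotypes <- function(x, ...) {
  called <- colSums(!is.na(x$H))
  cat("<neow_haplotypes>", ncol(x$H), "carriers;",
      round(mean(called)), "called sites per carrier (median support ",
      stats::median(x$support[x$support > 0]), ")\n")
  invisible(x)
}

#' Export reconstructed neo-W haplotypes as FASTA
#'
#' One sequence per carrier over the variant-site alignment, `N` where the
#' haploid call is missing.
#'
#' @param recon A [reconstruct_neow()] result.
#' @param gm The genotype matrix the reconstruction was built from.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_neow_fasta <- function(recon, gm, path) {
  si <- which(gm$chrom == recon$chrom)
  ref <- gm$ref[si]; alt <- gm$alt[si]
  seqs <- vapply(seq_len(ncol(recon$H)), function(k) {
    b <- ifelse(is.na(recon$H[, k]), "N", ifelse(recon$H[, k] == 0, ref, alt))
    paste(b, collapse = "")
  }, character(1))
  names(seqs) <- colnames(recon$H)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

mask_len <- function(iv) if (nrow(iv)) sum(iv[, 2] - iv[, 1]) else 0

#' Haploid nucleotide diversity
#'
#' Mean pairwise mismatch proportion over pairwise-complete sites, averaged
#' over haplotype pairs. For a [reconstruct_neow()] result, the denominator
#' of each pair is the overlap of the two carriers' supported genomic masks
#' in base pairs, so the value is a per-bp diversity directly comparable
#' with window pi; for a plain matrix, the denominator is the count of
#' pairwise-complete sites.
#'
#' @param x A `neow_haplotypes` object or a sites-x-haplotypes allele
#'   matrix with `NA` for missing.
#' @return Mean pairwise diversity, or `NA` when no pair shares data.
#' @export
haploid_pi <- function(x) UseMethod("haploid_pi")

#' @export
haploid_pi.default <- function(x) {
  H <- as.matrix(x)
  if (ncol(H) < 2) stop("need at least two haplotypes", call. = FALSE)
  ds <- c()
  for (i in seq_len(ncol(H) - 1)) for (j in (i + 1):ncol(H)) {
    keep <- !is.na(H[, i]) & !is.na(H[, j])
    if (!sum(keep)) { ds <- c(ds, NA_real_); next }
    ds <- c(ds, sum(H[keep, i] != H[keep, j]) / sum(keep))
  }
  if (all(is.na(ds))) return(NA_real_)
  mean(ds, na.rm = TRUE)
}

#' @export
haploid_pi.neow_haplotypes <- function(x) {
  carriers <- colnames(x$H)
  if (length(carriers) < 2) stop("need at least two haplotypes", call. = FALSE)
  ds <- c()
  for (i in seq_len(length(carriers) - 1)) for (j in (i + 1):length(carriers)) {
    ov <- intersect_intervals(x$masks[[i]], x$masks[[j]])
    bp <- mask_len(ov)
    if (bp <= 0) { ds <- c(ds, NA_real_); next }
    keep <- !is.na(x$H[, i]) & !is.na(x$H[, j]) & in_intervals(x$pos, ov)
    ds <- c(ds, sum(x$H[keep, i] != x$H[keep, j]) / bp)
  }
  if (all(is.na(ds))) return(NA_real_)
  mean(ds, na.rm = TRUE)
}

#' Neo-W vs wild-type divergence test
#'
#' Compares per-window mean heterozygosity density between females carrying
#' the neo-W and wild-type individuals over the colinear region, in
#' non-overlapping windows (default 100 kb), and tests the paired per-window
#' differences with the two-sided Wilcoxon signed-rank test. A window is
#' used only when at least `min_sites` sites are genotyped in at least two
#' individuals of each group. Fewer than six usable windows yields a null
#' p-value with a warning.
#'
#' @param gm A [genotype_matrix()].
#' @param neow_females,wildtype Character vectors of sample ids.
#' @param layout A [genome_layout()]; defaults to the attached one.
#' @param chrom Chromosome (default `"chr15"`).
#' @param region `c(start, end)` of the colinear region (default from 11 Mb
#'   to the chromosome end, the convention for the real chromosome; pass the
#'   simulated colinear interval explicitly for simulator output).
#' @param size Window size (windows do not overlap).
#' @param min_sites Minimum qualifying sites per window (default 20,000).
#' @return A list of class `divergence_test`: `windows` (tibble with both
#'   group means and their difference), `p`, `n_windows`, `statistic`.
#' @export
divergence_test <- function(gm, neow_females, wildtype, layout = gm$layout,
                            chrom = "chr15", region = c(11e6, Inf),
                            size = 1e5, min_sites = 2e4) {
  if (is.null(layout)) stop("a genome layout is required", call. = FALSE)
  len <- chrom_length(layout, chrom)
  region[2] <- min(region[2], len)
  wins <- iter_windows(layout, chrom, size = size, step = size)
  wins <- wins[wins$start >= region[1] & wins$end <= region[2], ]
  groups <- list(neow = neow_females, wt = wildtype)
  rows <- list()
  for (w in seq_len(nrow(wins))) {
    win <- c(wins$start[w], wins$end[w])
    si <- site_index(gm, chrom, win[1], win[2])
    ok_site <- rep(TRUE, length(si))
    for (g in groups) {
      ci <- match(g, gm$samples)
      called <- rowSums(!is.na(gm$gt1[si, ci, drop = FALSE]) &
                          !is.na(gm$gt2[si, ci, drop = FALSE]))
      ok_site <- ok_site & called >= 2
    }
    ns <- if (gm$all_callable) (win[2] - win[1]) - sum(!ok_site) else sum(ok_site)
    if (ns < min_sites) next
    mh <- vapply(groups, function(g)
      mean(vapply(g, function(s) het_density(gm, s, win, chrom = chrom),
                  numeric(1)), na.rm = TRUE), numeric(1))
    rows[[length(rows) + 1]] <- tibble::tibble(
      chrom = chrom, start = win[1], end = win[2], n_sites = ns,
      het_neow = mh[["neow"]], het_wt = mh[["wt"]],
      diff = mh[["neow"]] - mh[["wt"]])
  }
  windows <- dplyr::bind_rows(rows)
  if (nrow(windows) < 6) {
    warning("fewer than 6 usable windows; p-value not computed")
    return(structure(list(windows = windows, p = NA_real_,
                          n_windows = nrow(windows), statistic = NA_real_),
                     class = "divergence_test"))
  }
  wt <- wilcoxon_signed_rank(windows$het_neow, windows$het_wt)
  structure(list(windows = windows, p = wt$p, n_windows = nrow(windows),
                 statistic = wt$statistic),
            class = "divergence_test")
}

#' @exportS3Method base::print
print.divergence_test <- function(x, ...) {
  cat("<divergence_test>", x$n_windows, "windows; Wilcoxon signed-rank p =",
      signif(x$p, 3), "\n")
  invisible(x)
}

#' Moment-based root age from haploid diversity
#'
#' Under a star-genealogy approximation, pairwise diversity accumulates at
#' `2 * mu` per generation, so `T = pi / (2 * mu)` estimates the time to the
#' common ancestor. The estimator deliberately replaces Bayesian genealogy
#' dating: it will not reproduce a posterior mean/SD and is validated by
#' simulation recovery instead.
#'
#' @param pi Haploid per-bp diversity (e.g. [haploid_pi()]).
#' @param mu Per-bp per-generation mutation rate.
#' @param generations_per_year Generations per year (default 12).
#' @return A tibble: `pi`, `mu`, `generations`, `years`.
#' @export
root_age <- function(pi, mu, generations_per_year = 12) {
  stopifnot(mu > 0)
  gens <- if (is.na(pi)) NA_real_ else pi / (2 * mu)
  tibble::tibble(pi = pi, mu = mu, generations = gens,
                 years = gens / generations_per_year)
}

#' @rdname root_age
#' @param years,generations Quantities to convert.
#' @export
years_to_generations <- function(years, generations_per_year = 12) {
  years * generations_per_year
}

#' @rdname root_age
#' @export
generations_to_years <- function(generations, generations_per_year = 12) {
  generations / generations_per_year
}

#' Mitochondrial haplotype clades
#'
#' Groups samples into mitochondrial clades from the haploid mitochondrial
#' genotypes: pairwise mismatch distances, single-linkage clustering, and a
#' cut at `h_frac` of the mean pairwise distance — matrilines are separated
#' by standing divergence that is far larger than the few mutations accrued
#' within a matriline.
#'
#' @param gm A [genotype_matrix()] containing the `mito` chromosome.
#' @param samples Sample ids (default all).
#' @param chrom Mitochondrial chromosome name (default `"mito"`).
#' @param h_frac Cut height as a fraction of the mean distance (default 0.1).
#' @return A tibble: `sample`, `clade` (integer labels).
#' @export
mito_clades <- function(gm, samples = gm$samples, chrom = "mito", h_frac = 0.1) {
  si <- which(gm$chrom == chrom)
  if (!length(si)) stop("no sites on chromosome '", chrom, "'", call. = FALSE)
  ci <- match(samples, gm$samples)
  H <- gm$gt1[si, ci, drop = FALSE]
  n <- length(samples)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    keep <- !is.na(H[, i]) & !is.na(H[, j])
    D[i, j] <- D[j, i] <- if (sum(keep)) sum(H[keep, i] != H[keep, j]) else NA
  }
  if (all(D[upper.tri(D)] == 0, na.rm = TRUE)) {
    return(tibble::tibble(sample = samples, clade = 1L))
  }
  hc <- stats::hclust(stats::as.dist(D), method = "single")
  cl <- stats::cutree(hc, h = h_frac * mean(D[upper.tri(D)], na.rm = TRUE))
  tibble::tibble(sample = samples, clade = as.integer(cl))
}
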