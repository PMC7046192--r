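#' The genotype-matrix container
#'
#' Sites-by-samples diploid (or haploid, for the mitochondrion) genotype
#' calls with per-call read depth and phred-scaled genotype quality. Allele
#' calls are stored as two integer matrices of allele indices (0 = reference)
#' with `NA` for a missing call; haploid sites have `NA` in the second track
#' and are marked in the `haploid` site flag. Positions are 0-based.
#'
#' `all_callable = TRUE` marks matrices whose every position is considered
#' genotyped in every sample apart from the listed variant records (the
#' simulator's output, where the reference is known everywhere). For such
#' matrices per-site statistics are normalised per base pair of window;
#' matrices loaded from a VCF of variant records only are normalised per
#' genotyped variant site.
#'
#' @param chrom,pos,ref,alt Per-site chromosome, 0-based position, reference
#'   and alternate allele strings (comma-separated when multi-allelic).
#' @param gt1,gt2 Integer matrices (sites x samples) of allele indices.
#' @param dp,gq Integer matrices of per-call depth and quality (`NA` where the
#'   tag was absent).
#' @param samples Character vector of sample ids (column order).
#' @param haploid Logical per-site flag; haploid sites carry one allele.
#' @param layout Optional [genome_layout()] attached for window arithmetic.
#' @param all_callable See description.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, gt1, gt2, dp = NULL, gq = NULL,
                            samples = colnames(gt1), haploid = NULL,
                            layout = NULL, all_callable = FALSE) {
  n <- length(pos)
  gt1 <- as.matrix(gt1); gt2 <- as.matrix(gt2)
  stopifnot(length(chrom) == n, nrow(gt1) == n, nrow(gt2) == n,
            ncol(gt1) == ncol(gt2), !is.null(samples))
  if (is.null(haploid)) haploid <- rep(FALSE, n)
  ord <- order(factor(chrom, levels = unique(chrom)), pos)
  if (is.unsorted(ord)) {
    gt1 <- gt1[ord, , drop = FALSE]; gt2 <- gt2[ord, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[ord, , drop = FALSE]
    if (!is.null(gq)) gq <- gq[ord, , drop = FALSE]
    chrom <- chrom[ord]; pos <- pos[ord]; ref <- ref[ord]; alt <- alt[ord]
    haploid <- haploid[ord]
  }
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (anyDuplicated(p) > 0) stop("duplicate position on ", ch, call. = FALSE)
  }
  structure(list(chrom = as.character(chrom), pos = as.numeric(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 gt1 = gt1, gt2 = gt2, dp = dp, gq = gq,
                 samples = as.character(samples), haploid = haploid,
                 layout = layout, all_callable = isTRUE(all_callable)),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", n_sites(x), " sites x ", n_samples(x), " samples (",
      paste(unique(x$chrom), collapse = ", "), ")",
      if (x$all_callable) " [all positions callable]", "\n", sep = "")
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm A `genotype_matrix`.
#' @export
n_sites <- function(gm) length(gm$pos)

#' @rdname genotype_matrix
#' @export
n_samples <- function(gm) length(gm$samples)

#' Subset a genotype matrix by sites and/or samples
#'
#' @param gm A [genotype_matrix()].
#' @param sites Logical or integer site index.
#' @param samples Character sample ids, or logical/integer column index.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, sites = NULL, samples = NULL) {
  si <- if (is.null(sites)) seq_along(gm$pos) else seq_along(gm$pos)[sites]
  if (is.null(samples)) {
    ci <- seq_along(gm$samples)
  } else if (is.character(samples)) {
    ci <- match(samples, gm$samples)
    if (anyNA(ci)) stop("unknown sample(s): ",
                        paste(samples[is.na(ci)], collapse = ", "), call. = FALSE)
  } else ci <- seq_along(gm$samples)[samples]
  genotype_matrix(gm$chrom[si], gm$pos[si], gm$ref[si], gm$alt[si],
                  gm$gt1[si, ci, drop = FALSE], gm$gt2[si, ci, drop = FALSE],
                  dp = if (!is.null(gm$dp)) gm$dp[si, ci, drop = FALSE],
                  gq = if (!is.null(gm$gq)) gm$gq[si, ci, drop = FALSE],
                  samples = gm$samples[ci], haploid = gm$haploid[si],
                  layout = gm$layout, all_callable = gm$all_callable)
}

#' Tidy view of genotype calls
#'
#' Long-format tibble of calls, one row per site x sample, with allele
#' indices, depth and quality. Intended for small matrices and plotting.
#'
#' @param gm A [genotype_matrix()].
#' @return A tibble with columns `chrom`, `pos`, `sample`, `a1`, `a2`, `dp`, `gq`.
#' @export
tidy_genotypes <- function(gm) {
  ns <- n_sites(gm); np <- n_samples(gm)
  tibble::tibble(
    chrom = rep(gm$chrom, np), pos = rep(gm$pos, np),
    sample = rep(gm$samples, each = ns),
    a1 = as.vector(gm$gt1), a2 = as.vector(gm$gt2),
    dp = if (!is.null(gm$dp)) as.vector(gm$dp) else NA_integer_,
    gq = if (!is.null(gm$gq)) as.vector(gm$gq) else NA_integer_)
}

site_index <- function(gm, chrom, start = 0, end = Inf) {
  which(gm$chrom == chrom & gm$pos >= start & gm$pos < end)
}
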