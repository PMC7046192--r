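# Genotype-phenotype association: the quantitative Wald test on 0/0.5/1
# phenotype scores with the standard SNP filters and greedy thinning.

#' SNP filters for association analysis
#'
#' Retains biallelic SNPs genotyped in at least `min_n` individuals, with a
#' minor allele count of at least `min_mac`, heterozygous in no more than
#' `max_het_frac` of the non-missing individuals, and thinned to a minimum
#' spacing of `thin_bp`: scanning left to right, the first passing SNP is
#' kept and any subsequent passing SNP closer than `thin_bp` to the last
#' kept one is dropped.
#'
#' @param gm A [genotype_matrix()].
#' @param min_n Minimum individuals with a complete diploid call (default 40).
#' @param min_mac Minimum minor allele count (default 2).
#' @param max_het_frac Maximum heterozygote fraction among non-missing calls
#'   (default 0.75).
#' @param thin_bp Minimum distance between retained SNPs (default 100).
#' @return A logical site mask.
#' @export
filter_snps <- function(gm, min_n = 40, min_mac = 2, max_het_frac = 0.75,
                        thin_bp = 100) {
  a1 <- gm$gt1; a2 <- gm$gt2
  biallelic <- !grepl(",", gm$alt, fixed = TRUE) & !gm$haploid
  called <- !is.na(a1) & !is.na(a2)
  n_ind <- rowSums(called)
  alt_cnt <- rowSums(a1 == 1L, na.rm = TRUE) + rowSums(a2 == 1L, na.rm = TRUE)
  n_all <- 2L * n_ind
  mac <- pmin(alt_cnt, n_all - alt_cnt)
  het <- rowSums(called & a1 != a2)
  het_frac <- ifelse(n_ind > 0, het / n_ind, 0)
  pass <- biallelic & n_ind >= min_n & mac >= min_mac & het_frac <= max_het_frac
  # greedy left-to-right thinning within chromosomes
  for (ch in unique(gm$chrom)) {
    idx <- which(pass & gm$chrom == ch)
    if (length(idx) < 2) next
    last_kept <- gm$pos[idx[1]]
    for (i in idx[-1]) {
      if (gm$pos[i] - last_kept < thin_bp) pass[i] <- FALSE
      else last_kept <- gm$pos[i]
    }
  }
  pass
}

#' Wald association of one SNP with a quantitative phenotype
#'
#' Ordinary least-squares regression of the phenotype score (0, 0.5 or 1)
#' on allele dosage (0, 1 or 2), reporting the slope, its standard error,
#' the Wald statistic `(beta/SE)^2` and its two-sided p-value on the t
#' reference with `n - 2` degrees of freedom. Pairs with a missing dosage
#' or phenotype are excluded. Degenerate fits return a null row with a
#' reason code; a noiseless perfect fit reports the smallest representable
#' p-value.
#'
#' @param dosages Numeric vector of allele dosages (NA allowed).
#' @param phenotypes Numeric vector of phenotype scores (NA allowed).
#' @return A one-row tibble: `n`, `beta`, `se`, `stat`, `p`, `reason`.
#' @export
wald_assoc <- function(dosages, phenotypes) {
  stopifnot(length(dosages) == length(phenotypes))
  ok <- !is.na(dosages) & !is.na(phenotypes)
  x <- dosages[ok]; y <- phenotypes[ok]; n <- length(x)
  null_row <- function(reason) tibble::tibble(
    n = n, beta = NA_real_, se = NA_real_, stat = NA_real_, p = NA_real_,
    reason = reason)
  if (n < 3) return(null_row("too few complete pairs"))
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(null_row("no variance"))
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta <- sxy / sxx
  sse <- syy - beta^2 * sxx
  df <- n - 2
  if (df <= 0) return(null_row("no residual degrees of freedom"))
  if (sse <= .Machine$double.eps * max(1, syy)) {
    return(tibble::tibble(n = n, beta = beta, se = 0, stat = Inf,
                          p = .Machine$double.xmin, reason = NA_character_))
  }
  se <- sqrt(sse / df / sxx)
  t <- beta / se
  tibble::tibble(n = n, beta = beta, se = se, stat = t^2,
                 p = max(2 * stats::pt(-abs(t), df), .Machine$double.xmin),
                 reason = NA_character_)
}

#' Genome-wide Wald association scan
#'
#' Applies [filter_snps()] and then [wald_assoc()] at every retained SNP,
#' with the phenotype taken from a score column of the sample table.
#'
#' @param gm A [genotype_matrix()].
#' @param meta Sample table with a `sample` column and the score column.
#' @param pheno Name of the phenotype score column (default `"score_B"`).
#' @param ... Passed to [filter_snps()].
#' @return A tibble with one row per tested SNP: `chrom`, `pos`, `ref`,
#'   `alt`, `n`, `beta`, `se`, `stat`, `p`.
#' @export
assoc_scan <- function(gm, meta, pheno = "score_B", ...) {
  stopifnot(pheno %in% names(meta))
  ci <- match(meta$sample, gm$samples)
  if (anyNA(ci)) stop("samples in meta missing from genotypes", call. = FALSE)
  mask <- filter_snps(gm, ...)
  idx <- which(mask)
  y <- meta[[pheno]]
  a1 <- gm$gt1[idx, ci, drop = FALSE]; a2 <- gm$gt2[idx, ci, drop = FALSE]
  dose <- a1 + a2
  # vectorised per-site OLS with pairwise-complete exclusion
  ym <- matrix(y, nrow = length(idx), ncol = length(y), byrow = TRUE)
  m <- !is.na(dose) & !is.na(ym)
  x0 <- ifelse(m, dose, 0); y0 <- ifelse(m, ym, 0)
  n <- rowSums(m)
  sx <- rowSums(x0); sy <- rowSums(y0)
  sxx <- rowSums(x0^2) - sx^2 / pmax(n, 1)
  syy <- rowSums(y0^2) - sy^2 / pmax(n, 1)
  sxy <- rowSums(x0 * y0) - sx * sy / pmax(n, 1)
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  sse <- pmax(syy - beta^2 * sxx, 0)
  df <- n - 2
  se <- ifelse(!is.na(beta) & df > 0, sqrt(sse / pmax(df, 1) / sxx), NA_real_)
  perfect <- !is.na(se) & se <= sqrt(.Machine$double.eps)
  tstat <- ifelse(perfect, Inf, beta / se)
  p <- ifelse(perfect, .Machine$double.xmin,
              pmax(2 * stats::pt(-abs(tstat), pmax(df, 1)), .Machine$double.xmin))
  bad <- n < 3 | is.na(beta) | df <= 0
  tibble::tibble(chrom = gm$chrom[idx], pos = gm$pos[idx],
                 ref = gm$ref[idx], alt = gm$alt[idx],
                 n = as.integer(n),
                 beta = ifelse(bad, NA_real_, beta),
                 se = ifelse(bad, NA_real_, se),
                 stat = ifelse(bad, NA_real_, tstat^2),
                 p = ifelse(bad, NA_real_, p))
}

#' Top association hits with nearest-gene annotation
#'
#' Retains SNPs whose Wald statistic reaches the empirical `quantile`
#' (nearest-rank convention, `>=`, ties all kept) and annotates each with
#' the nearest gene by midpoint distance; equidistant genes are all
#' reported.
#'
#' @param results An [assoc_scan()] tibble.
#' @param quantile Empirical quantile of the statistic (default 0.9999).
#' @param genes Optional gene tibble (`gene`, `chrom`, `start`, `end`); when
#'   absent, hits are returned unannotated.
#' @return A tibble of hits, possibly with `nearest_gene` and `distance`.
#' @export
top_hits <- function(results, quantile = 0.9999, genes = NULL) {
  res <- results[!is.na(results$stat), ]
  if (!nrow(res)) return(res)
  thr <- stats::quantile(res$stat, quantile, type = 1, names = FALSE)
  hits <- res[res$stat >= thr, ]
  if (is.null(genes) || !nrow(hits)) return(hits)
  gmid <- (genes$start + genes$end) / 2
  ann <- lapply(seq_len(nrow(hits)), function(i) {
    g <- genes[genes$chrom == hits$chrom[i], ]
    if (!nrow(g)) {
      return(cbind(hits[i, ], tibble::tibble(nearest_gene = NA_character_,
                                             distance = NA_real_)))
    }
    d <- abs((g$start + g$end) / 2 - hits$pos[i])
    nearest <- which(d == min(d))
    cbind(hits[rep(i, length(nearest)), ],
          tibble::tibble(nearest_gene = g$gene[nearest], distance = d[nearest]))
  })
  tibble::as_tibble(dplyr::bind_rows(ann))
}

#' Load gene models from a GFF3 file
#'
#' Reads gene/CDS features and returns a tibble in the package's 0-based
#' half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble: `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
load_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(seq_along(gr))
  tibble::tibble(gene = ids,
                 chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1,
                 end = as.numeric(GenomicRanges::end(gr)),
                 strand = as.character(GenomicRanges::strand(gr)))
}
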