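# Genetic-load machinery: conservative 0-fold/4-fold site classification,
# frequency-stratified Pn/Ps within a cohort, and gene-level bootstrap
# comparison between genomic regions.

to_base_codes <- function(x) {
  if (is.integer(x) || is.numeric(x)) return(as.integer(x))
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet")) {
    x <- as.character(x)
  }
  if (is.character(x) && length(x) == 1) x <- strsplit(x, "")[[1]]
  match(toupper(x), BASES)
}

#' Classify coding positions as 0-fold or 4-fold degenerate
#'
#' Strict classification: the third position of a codon whose family is
#' fully degenerate is `fourfold`; a position where every nucleotide change
#' alters the amino acid is `zerofold`; everything else is excluded. A
#' position is classified only if the other two positions of its codon are
#' invariant across the entire dataset (no variant record there in `gm`).
#' Genes whose length is not a multiple of 3, or whose reference frame
#' contains an internal stop, are skipped with a warning.
#'
#' @param gm A [genotype_matrix()] (supplies the polymorphism universe).
#' @param genes Gene tibble (`gene`, `chrom`, `start`, `end`, `strand`);
#'   only `+`-strand genes are supported.
#' @param refs Named list (by chromosome) of reference sequences: character
#'   strings, `Biostrings::DNAStringSet` elements, or integer base codes.
#' @return A tibble (the degeneracy map): `chrom`, `pos`, `class`
#'   (`zerofold`/`fourfold`), `gene`, `codon_pos`.
#' @export
classify_degeneracy <- function(gm, genes, refs) {
  deg_tab <- codon_degeneracy_table()
  code <- Biostrings::GENETIC_CODE
  var_key <- paste(gm$chrom, gm$pos)
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    len <- g$end - g$start
    if (len %% 3 != 0) {
      warning("gene ", g$gene, ": length not divisible by 3; skipped")
      next
    }
    if (!identical(g$strand, "+")) {
      warning("gene ", g$gene, ": only + strand supported; skipped")
      next
    }
    codes <- to_base_codes(refs[[g$chrom]])
    cds <- codes[(g$start + 1):g$end]
    codons <- matrix(BASES[cds], ncol = 3, byrow = TRUE)
    cstr <- paste0(codons[, 1], codons[, 2], codons[, 3])
    if (any(code[cstr] == "*")) {
      warning("gene ", g$gene, ": internal stop codon in reference; skipped")
      next
    }
    cls <- deg_tab[cstr, , drop = FALSE]
    posm <- matrix(g$start + seq_len(len) - 1, ncol = 3, byrow = TRUE)
    poly <- matrix(paste(g$chrom, posm) %in% var_key, ncol = 3)
    for (cp in 1:3) {
      others_invariant <- !poly[, -cp, drop = FALSE][, 1] &
        !poly[, -cp, drop = FALSE][, 2]
      keep <- cls[, cp] %in% c("zerofold", "fourfold") & others_invariant
      if (!any(keep)) next
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = g$chrom, pos = posm[keep, cp], class = unname(cls[keep, cp]),
        gene = g$gene, codon_pos = cp)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res)) res <- dplyr::arrange(res, .data$chrom, .data$pos)
  res
}

#' Frequency-stratified Pn/Ps
#'
#' Counts non-synonymous (0-fold) and synonymous (4-fold) polymorphisms
#' among sites genotyped in every cohort member (complete-case rule),
#' stratified by folded minor-allele count (classes 1 to N for N diploid
#' samples), and normalises by the total classified sites of each kind:
#' `Pn/Ps = (Pn/Ln) / (Ps/Ls)`. A region restricts to chromosomes and can
#' exclude an interval (e.g. chr15 without the supergene).
#'
#' @param gm A [genotype_matrix()].
#' @param degeneracy A [classify_degeneracy()] map.
#' @param cohort Character vector of sample ids (e.g. the neo-W females).
#' @param chroms Chromosomes included in the region.
#' @param exclude Optional `c(start, end)` excluded on those chromosomes.
#' @return A list of class `pnps_counts`: `by_class` (tibble: `freq_class`,
#'   `Pn`, `Ps`, `ratio`), `Ln`, `Ls`, `overall` (one-row tibble), and
#'   `per_gene` (tibble used by [bootstrap_compare()]).
#' @export
stratified_pnps <- function(gm, degeneracy, cohort, chroms, exclude = NULL) {
  deg <- degeneracy[degeneracy$chrom %in% chroms, ]
  if (!is.null(exclude)) {
    deg <- deg[!(deg$pos >= exclude[1] & deg$pos < exclude[2]), ]
  }
  ci <- match(cohort, gm$samples)
  if (anyNA(ci)) stop("unknown cohort sample(s)", call. = FALSE)
  n_cls <- length(cohort)          # folded classes 1..N for 2N alleles
  key <- paste(gm$chrom, gm$pos)
  dkey <- paste(deg$chrom, deg$pos)
  site_of <- match(dkey, key)      # NA = invariant classified site
  is_var <- !is.na(site_of)
  mac <- rep(NA_integer_, nrow(deg))
  complete <- rep(TRUE, nrow(deg))
  if (any(is_var)) {
    idx <- site_of[is_var]
    a1 <- gm$gt1[idx, ci, drop = FALSE]; a2 <- gm$gt2[idx, ci, drop = FALSE]
    comp <- rowSums(is.na(a1) | is.na(a2)) == 0
    alt <- rowSums(a1 == 1L, na.rm = TRUE) + rowSums(a2 == 1L, na.rm = TRUE)
    m <- pmin(alt, 2L * length(ci) - alt)
    complete[is_var] <- comp
    mac[is_var] <- ifelse(comp, m, NA_integer_)
  }
  if (!gm$all_callable) {
    # without an all-callable reference, invariant classified sites cannot be
    # verified complete; they are assumed genotyped (documented assumption)
  }
  deg$mac <- mac
  deg$complete <- complete
  used <- deg[deg$complete, ]
  Ln <- sum(used$class == "zerofold"); Ls <- sum(used$class == "fourfold")
  polym <- used[!is.na(used$mac) & used$mac >= 1L, ]
  by_class <- dplyr::bind_rows(lapply(seq_len(n_cls), function(k) {
    tibble::tibble(freq_class = k,
                   Pn = sum(polym$class == "zerofold" & polym$mac == k),
                   Ps = sum(polym$class == "fourfold" & polym$mac == k))
  }))
  ratio_of <- function(Pn, Ps) {
    if (Ls == 0 || Ln == 0 || Ps == 0) return(NA_real_)
    (Pn / Ln) / (Ps / Ls)
  }
  by_class$ratio <- mapply(ratio_of, by_class$Pn, by_class$Ps)
  per_gene <- polym |>
    dplyr::count(.data$gene, .data$class, .data$mac, name = "n") |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  for (col in c("zerofold", "fourfold")) {
    if (!col %in% names(per_gene)) per_gene[[col]] <- 0L
  }
  gene_sites <- used |>
    dplyr::count(.data$gene, .data$class, name = "n") |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  for (col in c("zerofold", "fourfold")) {
    if (!col %in% names(gene_sites)) gene_sites[[col]] <- 0L
  }
  names(gene_sites) <- c("gene", "Ln", "Ls")[match(names(gene_sites),
                                                   c("gene", "zerofold", "fourfold"))]
  overall <- tibble::tibble(
    Pn = sum(by_class$Pn), Ps = sum(by_class$Ps), Ln = Ln, Ls = Ls,
    ratio = ratio_of(sum(by_class$Pn), sum(by_class$Ps)))
  structure(list(by_class = by_class, Ln = Ln, Ls = Ls, overall = overall,
                 per_gene = per_gene, gene_sites = gene_sites,
                 n_cohort = length(cohort), chroms = chroms),
            class = "pnps_counts")
}

#' @exportS3Method base::print
print.pnps_counts <- function(x, ...) {
  cat("<pnps_counts>", paste(x$chroms, collapse = "+"), "| Ln =", x$Ln,
      "Ls =", x$Ls, "| overall Pn/Ps =", signif(x$overall$ratio, 3), "\n")
  invisible(x)
}

pnps_point <- function(counts, classes, boot_genes = NULL) {
  pg <- counts$per_gene; gs <- counts$gene_sites
  if (!is.null(boot_genes)) {
    pg <- pg[match(boot_genes, pg$gene), ]
    pg <- pg[!is.na(pg$gene), ]
    gs <- gs[match(boot_genes, gs$gene), ]
    gs <- gs[!is.na(gs$gene), ]
  }
  if (!is.null(classes)) pg <- pg[pg$mac %in% classes, ]
  Pn <- sum(pg$zerofold); Ps <- sum(pg$fourfold)
  Ln <- sum(gs$Ln); Ls <- sum(gs$Ls)
  if (Ln == 0 || Ls == 0 || Ps == 0) return(NA_real_)
  (Pn / Ln) / (Ps / Ls)
}

#' Bootstrap comparison of Pn/Ps between two regions
#'
#' Resamples genes with replacement within each region, recomputes the
#' Pn/Ps difference (optionally restricted to chosen frequency classes per
#' side), and reports a one-sided p-value as one minus the fraction of
#' replicates reproducing the observed direction, together with a 95%
#' percentile interval of the difference. When every replicate reproduces
#' the direction, the p-value is reported as the bound `1 / n_boot` with
#' `p_is_bound = TRUE` rather than zero.
#'
#' @param counts_a,counts_b Two [stratified_pnps()] results.
#' @param classes_a,classes_b Frequency classes summed on each side
#'   (default: all).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional seed.
#' @return A one-row tibble: `diff_obs`, `n_boot`, `n_reproduce`, `p`,
#'   `p_is_bound`, `ci_lo`, `ci_hi`.
#' @export
bootstrap_compare <- function(counts_a, counts_b, classes_a = NULL,
                              classes_b = NULL, n_boot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes_a <- counts_a$gene_sites$gene
  genes_b <- counts_b$gene_sites$gene
  if (length(genes_a) < 2 || length(genes_b) < 2) {
    stop("need at least two genes per region", call. = FALSE)
  }
  obs <- pnps_point(counts_a, classes_a) - pnps_point(counts_b, classes_b)
  if (is.na(obs)) stop("point estimate undefined (no synonymous polymorphism?)",
                       call. = FALSE)
  # with a zero observed difference the direction is arbitrary
  dir <- if (obs == 0) 1 else sign(obs)
  diffs <- vapply(seq_len(n_boot), function(b) {
    ra <- sample(genes_a, replace = TRUE)
    rb <- sample(genes_b, replace = TRUE)
    pnps_point(counts_a, classes_a, ra) - pnps_point(counts_b, classes_b, rb)
  }, numeric(1))
  ok <- !is.na(diffs)
  if (!any(ok)) {
    stop("all bootstrap replicates undefined (no synonymous polymorphism in resamples)",
         call. = FALSE)
  }
  if (mean(ok) < 0.5) {
    warning("more than half of the bootstrap replicates were undefined")
  }
  reproduce <- sum(sign(diffs[ok]) == dir)
  p_raw <- 1 - reproduce / sum(ok)
  bound <- p_raw == 0
  tibble::tibble(diff_obs = obs, n_boot = sum(ok), n_reproduce = reproduce,
                 p = if (bound) 1 / sum(ok) else p_raw, p_is_bound = bound,
                 ci_lo = stats::quantile(diffs[ok], 0.025, names = FALSE),
                 ci_hi = stats::quantile(diffs[ok], 0.975, names = FALSE))
}

#' The bootstrap-direction p-value convention
#'
#' Converts "k of n replicates reproduce the observed direction" into the
#' reported one-sided p-value, `1 - k/n`, bounded below by `1/n`.
#'
#' @param n_reproduce,n_boot Replicate counts.
#' @return The p-value (a bound flagged via `attr(, "is_bound")`).
#' @export
bootstrap_p <- function(n_reproduce, n_boot) {
  stopifnot(n_reproduce >= 0, n_reproduce <= n_boot)
  p <- 1 - n_reproduce / n_boot
  if (p == 0) structure(1 / n_boot, is_bound = TRUE)
  else structure(p, is_bound = FALSE)
}
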