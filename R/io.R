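#' Genotype-call filter policy
#'
#' The depth/quality rule applied when loading a VCF, matching the asymmetric
#' convention of requiring depth for every call but quality only for calls
#' that assert a non-reference allele: calls below `min_dp` become missing;
#' heterozygous or alternate-homozygous calls below `min_gq` become missing;
#' reference-homozygous calls are kept regardless of quality.
#'
#' @param min_dp Minimum per-call read depth (default 8).
#' @param min_gq Minimum genotype quality for heterozygous/alternate calls
#'   (default 20).
#' @param missing_tag_passes How a call lacking a DP or GQ tag is treated:
#'   `TRUE` (default) treats the absent tag as passing, `FALSE` as failing.
#' @return A list of class `filter_policy`.
#' @export
filter_policy <- function(min_dp = 8, min_gq = 20, missing_tag_passes = TRUE) {
  stopifnot(min_dp >= 0, min_gq >= 0)
  structure(list(min_dp = min_dp, min_gq = min_gq,
                 missing_tag_passes = isTRUE(missing_tag_passes)),
            class = "filter_policy")
}

#' @rdname filter_policy
#' @export
permissive_policy <- function() filter_policy(min_dp = 0, min_gq = 0)

parse_allele_tracks <- function(gt) {
  g <- gsub("|", "/", gt, fixed = TRUE)
  has2 <- grepl("/", g, fixed = TRUE)
  a1 <- sub("/.*$", "", g)
  a2 <- ifelse(has2, sub("^[^/]*/", "", g), NA_character_)
  a1[a1 %in% c(".", "")] <- NA
  a2[!is.na(a2) & a2 == "."] <- NA
  list(a1 = suppressWarnings(matrix(as.integer(a1), nrow = nrow(gt),
                                    dimnames = dimnames(gt))),
       a2 = suppressWarnings(matrix(as.integer(a2), nrow = nrow(gt),
                                    dimnames = dimnames(gt))),
       haploid_call = matrix(!has2 & !is.na(a1), nrow = nrow(gt)))
}

#' Load a genotype matrix from a VCF
#'
#' Reads a (plain or gzipped) VCF with FORMAT fields GT, DP and GQ and applies
#' a [filter_policy()]: the depth rule hits every call, the quality rule only
#' heterozygous and alternate-homozygous calls, and reference-homozygous
#' calls survive any quality. Positions are converted to the package's
#' 0-based convention. Multi-allelic records are retained with their allele
#' indices; downstream biallelic-only operations filter explicitly.
#'
#' @param path Path to a `.vcf` or `.vcf.gz` file.
#' @param policy A [filter_policy()]; default `filter_policy()`.
#' @param samples Optional character vector restricting (and ordering) the
#'   sample columns; unknown ids raise an error.
#' @param layout Optional [genome_layout()] attached to the result.
#' @return A [genotype_matrix()].
#' @export
load_genotypes <- function(path, policy = filter_policy(), samples = NULL,
                           layout = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (nrow(vcf@gt) == 0 && nrow(vcf@fix) == 0) stop("empty VCF: ", path, call. = FALSE)
  fix <- vcf@fix
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(gt_raw))
    if (length(miss)) stop("unknown sample(s) in filter: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    gt_raw <- gt_raw[, samples, drop = FALSE]
    dp <- dp[, samples, drop = FALSE]; gq <- gq[, samples, drop = FALSE]
  }
  tr <- parse_allele_tracks(gt_raw)
  a1 <- tr$a1; a2 <- tr$a2
  called <- !is.na(a1)
  # depth rule: applies to all calls
  fail_dp <- called & (if (policy$missing_tag_passes) !is.na(dp) & dp < policy$min_dp
                       else (is.na(dp) | dp < policy$min_dp))
  # quality rule: only het / alt-homozygous calls
  nonref <- called & ((!is.na(a2) & (a1 != a2 | a1 > 0)) | (is.na(a2) & a1 > 0))
  fail_gq <- nonref & (if (policy$missing_tag_passes) !is.na(gq) & gq < policy$min_gq
                       else (is.na(gq) | gq < policy$min_gq))
  drop <- fail_dp | fail_gq
  a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  # haploid records: every called genotype at the site has a single allele
  haploid <- vapply(seq_len(nrow(a1)), function(i) {
    hc <- tr$haploid_call[i, ]; any(hc) && all(is.na(a2[i, ]))
  }, logical(1))
  genotype_matrix(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]) - 1,
                  ref = fix[, "REF"], alt = fix[, "ALT"],
                  gt1 = a1, gt2 = a2,
                  dp = matrix(as.integer(dp), nrow = nrow(a1)),
                  gq = matrix(as.integer(gq), nrow = nrow(a1)),
                  samples = colnames(gt_raw), haploid = haploid,
                  layout = layout, all_callable = FALSE)
}

#' Write a genotype matrix as a VCF
#'
#' Plain-text VCF 4.2 with FORMAT `GT:DP:GQ`. Haploid sites are written with
#' single-allele genotypes. Positions are converted back to 1-based.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  ns <- n_sites(gm)
  gts <- matrix("", nrow = ns, ncol = n_samples(gm))
  a1 <- gm$gt1; a2 <- gm$gt2
  dp <- if (is.null(gm$dp)) matrix(NA_integer_, ns, n_samples(gm)) else gm$dp
  gq <- if (is.null(gm$gq)) matrix(NA_integer_, ns, n_samples(gm)) else gm$gq
  dp_s <- ifelse(is.na(dp), ".", as.character(dp))
  gq_s <- ifelse(is.na(gq), ".", as.character(gq))
  hap <- matrix(gm$haploid, nrow = ns, ncol = n_samples(gm))
  gt_s <- ifelse(hap,
                 ifelse(is.na(a1), ".", as.character(a1)),
                 ifelse(is.na(a1) | is.na(a2), "./.",
                        paste0(a1, "/", a2)))
  body <- paste(gm$chrom, format(gm$pos + 1, scientific = FALSE, trim = TRUE),
                ".", gm$ref, gm$alt, ".", "PASS", ".", "GT:DP:GQ",
                sep = "\t")
  cell <- matrix(paste(gt_s, dp_s, gq_s, sep = ":"), nrow = ns)
  lines <- paste(body, apply(cell, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=neowsweep",
           if (!is.null(gm$layout))
             sprintf("##contig=<ID=%s,length=%d>", gm$layout$chrom,
                     as.integer(gm$layout$length)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

normalise_sex <- function(x) {
  out <- tolower(as.character(x))
  out[out %in% c("f", "female")] <- "female"
  out[out %in% c("m", "male")] <- "male"
  out[is.na(out) | out %in% c("", "u", "unknown", "na")] <- "unknown"
  bad <- setdiff(unique(out), c("female", "male", "unknown"))
  if (length(bad)) stop("invalid sex value(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out
}

check_scores <- function(x, col) {
  bad <- !is.na(x) & !(x %in% c(0, 0.5, 1))
  if (any(bad)) stop("phenotype score outside {0, 0.5, 1} in column ", col,
                     ": ", paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  as.numeric(x)
}

#' Load a sample metadata table
#'
#' Tab-separated table with a header. Required column: `sample`. Recognised
#' columns: `sex` (F/M/female/male/unknown), `population`, phenotype scores
#' `score_A`, `score_B`, `score_C` (each 0, 0.5 or 1, or empty), `infected`
#' (logical), `neow_carrier` (logical), `matriline`. Lines starting `#` are
#' comments. Duplicate sample ids and out-of-domain scores are errors.
#'
#' @param path Path to the TSV.
#' @return A tibble, one row per sample.
#' @export
load_samples <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  validate_samples(tab)
}

#' @rdname load_samples
#' @param table A data frame to validate/normalise in place of a file.
#' @export
validate_samples <- function(table) {
  tab <- tibble::as_tibble(table)
  if (!"sample" %in% names(tab)) stop("sample table needs a 'sample' column",
                                      call. = FALSE)
  tab$sample <- as.character(tab$sample)
  dup <- tab$sample[duplicated(tab$sample)]
  if (length(dup)) stop("duplicate sample id(s): ",
                        paste(unique(dup), collapse = ", "), call. = FALSE)
  if ("sex" %in% names(tab)) tab$sex <- normalise_sex(tab$sex)
  else tab$sex <- "unknown"
  if (!"population" %in% names(tab)) tab$population <- NA_character_
  for (col in c("score_A", "score_B", "score_C")) {
    if (col %in% names(tab)) tab[[col]] <- check_scores(tab[[col]], col)
    else tab[[col]] <- NA_real_
  }
  for (col in c("infected", "neow_carrier")) {
    if (col %in% names(tab)) tab[[col]] <- as.logical(tab[[col]])
    else tab[[col]] <- NA
  }
  if (!"matriline" %in% names(tab)) tab$matriline <- NA_character_
  else tab$matriline <- as.character(tab$matriline)
  tab
}

#' @rdname load_samples
#' @param samples A validated sample tibble.
#' @export
write_samples <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

#' Load a genome layout table
#'
#' Tab-separated, columns `chrom` and `length` (and optionally `scaffold`,
#' `start`, `end` for scaffold spans, one row per span with the chromosome
#' row repeated).
#'
#' @param path Path to the TSV.
#' @return A [genome_layout()].
#' @export
load_layout <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (all(c("scaffold", "start", "end") %in% names(tab))) {
    chroms <- dplyr::distinct(tab[, c("chrom", "length")])
    genome_layout(chroms, scaffolds = tab[, c("chrom", "scaffold", "start", "end")])
  } else {
    genome_layout(tab[, c("chrom", "length")])
  }
}
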