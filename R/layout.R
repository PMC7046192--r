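#' Genome layout: pseudo-chromosome sizes and scaffold spans
#'
#' A genome layout records the pseudo-chromosomes all window arithmetic runs
#' on: one row per chromosome with its length in base pairs, optionally
#' annotated with the ordered scaffold spans that were concatenated to build
#' it. Coordinates are 0-based and half-open throughout the package; VCF
#' 1-based positions are converted at the file boundary.
#'
#' @param chromosomes A data frame with columns `chrom` (character) and
#'   `length` (base pairs).
#' @param scaffolds Optional data frame with columns `chrom`, `scaffold`,
#'   `start`, `end` giving non-overlapping, ordered scaffold spans in
#'   pseudo-chromosome coordinates. The end of the last span of a chromosome
#'   must equal its length.
#'
#' @return A tibble of class `genome_layout` with columns `chrom` and
#'   `length`, carrying the scaffold table as an attribute.
#' @export
genome_layout <- function(chromosomes, scaffolds = NULL) {
  chromosomes <- tibble::as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$chrom) > 0) {
    stop("duplicate chromosome names in layout", call. = FALSE)
  }
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (!is.null(scaffolds)) {
    scaffolds <- tibble::as_tibble(scaffolds)
    stopifnot(all(c("chrom", "scaffold", "start", "end") %in% names(scaffolds)))
    for (ch in unique(scaffolds$chrom)) {
      sp <- scaffolds[scaffolds$chrom == ch, ]
      if (is.unsorted(sp$start) || any(sp$start >= sp$end)) {
        stop("scaffold spans on ", ch, " must be ordered with start < end", call. = FALSE)
      }
      if (any(sp$start[-1] < sp$end[-nrow(sp)])) {
        stop("scaffold spans on ", ch, " overlap", call. = FALSE)
      }
      len <- chromosomes$length[match(ch, chromosomes$chrom)]
      if (is.na(len) || sp$end[nrow(sp)] != len) {
        stop("last scaffold span on ", ch, " must end at the chromosome length", call. = FALSE)
      }
    }
  }
  structure(chromosomes, scaffolds = scaffolds,
            class = c("genome_layout", class(chromosomes)))
}

#' @exportS3Method base::print
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", nrow(x), " chromosome(s), ",
      format(sum(x$length), big.mark = ","), " bp\n", sep = "")
  NextMethod()
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (is.na(i)) stop("chromosome '", chrom, "' not in layout", call. = FALSE)
  layout$length[i]
}

#' Sliding windows over a chromosome
#'
#' Enumerates fixed-width sliding windows starting at 0, `step`, 2`step`, ...
#' Only windows lying wholly inside the chromosome are emitted; a trailing
#' short window is never produced, so every window has exactly `size` bp.
#'
#' @param layout A [genome_layout()].
#' @param chrom Chromosome name.
#' @param size Window size in bp (default 100 kb).
#' @param step Step between window starts in bp (default 20 kb); must satisfy
#'   `size >= step > 0`.
#'
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open).
#'   Zero rows when `size` exceeds the chromosome length.
#' @export
#' @examples
#' lay <- genome_layout(data.frame(chrom = "chr1", length = 1e6))
#' nrow(iter_windows(lay, "chr1"))  # 46
iter_windows <- function(layout, chrom, size = 1e5, step = 2e4) {
  stopifnot(size >= step, step > 0)
  len <- chrom_length(layout, chrom)
  if (size > len) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  starts <- seq(0, len - size, by = step)
  tibble::tibble(chrom = chrom, start = starts, end = starts + size)
}
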