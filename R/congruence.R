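# Genealogical congruence plumbing and the Procrustes (PACo-style)
# permutation test of host-symbiont co-diversification.

#' Pairwise mismatch distance matrix
#'
#' Missing-aware pairwise mismatch proportions between haplotypes or
#' sequences. Sites missing in more than `max_missing` of the taxa are
#' dropped first (the automated stand-in for manual exclusion of
#' inconsistently covered regions); a pair left with no complete site is an
#' error naming the pair.
#'
#' @param x A [hap_set()], a sites-x-taxa matrix (`NA` = missing), or a
#'   named list of mutation-position sets (compared as presence/absence over
#'   their union).
#' @param min_sites Minimum pairwise-complete sites per pair (default 1).
#' @param max_missing Maximum fraction of taxa missing at a retained site
#'   (default 0.2).
#' @return A symmetric numeric matrix with zero diagonal and taxon labels.
#' @export
distance_matrix <- function(x, min_sites = 1, max_missing = 0.2) {
  if (inherits(x, "hap_set")) x <- x$H
  if (is.list(x) && !is.matrix(x)) {
    all_pos <- sort(unique(unlist(x)))
    H <- vapply(x, function(s) as.integer(all_pos %in% s),
                integer(length(all_pos)))
    if (length(all_pos) == 0) H <- matrix(0L, nrow = 0, ncol = length(x),
                                          dimnames = list(NULL, names(x)))
    x <- H
  }
  H <- as.matrix(x)
  n <- ncol(H)
  if (n < 3) stop("need at least three taxa", call. = FALSE)
  labels <- colnames(H)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  keep <- rowMeans(is.na(H)) <= max_missing
  H <- H[keep, , drop = FALSE]
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(H[, i]) & !is.na(H[, j])
    m <- sum(ok)
    if (m < min_sites) {
      stop("no usable sites between '", labels[i], "' and '", labels[j], "'",
           call. = FALSE)
    }
    D[i, j] <- D[j, i] <- sum(H[ok, i] != H[ok, j]) / m
  }
  D
}

#' Neighbor-joining tree as newick text
#'
#' Standard neighbor joining (via ape) on a distance matrix; taxa are
#' processed in label order so ties resolve deterministically.
#'
#' @param D A symmetric distance matrix with labels.
#' @return A newick string (the `phylo` object is attached as an attribute).
#' @export
nj_tree <- function(D) {
  if (any(!is.finite(D))) stop("non-finite distance", call. = FALSE)
  tr <- ape::nj(stats::as.dist(D))
  structure(ape::write.tree(tr), phylo = tr)
}

#' Principal-coordinate embedding of a distance matrix
#'
#' Gower double-centred principal coordinates. When the matrix is not
#' Euclidean-embeddable (any eigenvalue below `-1e-8`), the Cailliez
#' correction is applied before embedding.
#'
#' @param D A symmetric distance matrix.
#' @return A coordinate matrix (taxa x axes) with the eigenvalues as an
#'   attribute; a zero matrix embeds to zero coordinates.
#' @export
pcoa_embed <- function(D) {
  D <- as.matrix(D)
  if (all(D == 0)) {
    return(structure(matrix(0, nrow(D), 1,
                            dimnames = list(rownames(D), "Axis.1")),
                     eig = 0, corrected = FALSE))
  }
  pc <- ape::pcoa(D)
  corrected <- FALSE
  if (min(pc$values$Eigenvalues) < -1e-8) {
    pc <- ape::pcoa(D, correction = "cailliez")
    corrected <- TRUE
  }
  vec <- if (!is.null(pc$vectors.cor)) pc$vectors.cor else pc$vectors
  structure(vec, eig = pc$values$Eigenvalues, corrected = corrected)
}

# all n! permutations of 1..n, one per row (used to enumerate the exact
# permutation null for small n)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(rep(k, nrow(sub)), matrix(rest[sub], nrow(sub)))
  }))
}

procrustes_m2 <- function(X, Y) {
  # normalised residual of the least-squares superimposition of Y onto X
  # (translation, rotation/reflection, scaling); both configurations are
  # centred and scaled to unit trace, so m2 is in [0, 1] and invariant to
  # rigid motions and global rescaling of either side.
  X <- scale(X, center = TRUE, scale = FALSE)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  trX <- sum(X^2); trY <- sum(Y^2)
  if (trX == 0 || trY == 0) return(0)
  X <- X / sqrt(trX); Y <- Y / sqrt(trY)
  1 - sum(svd(crossprod(Y, X))$d)^2
}

#' Procrustes permutation test of congruence (PACo-style)
#'
#' Embeds the host and parasite distance matrices by [pcoa_embed()],
#' superimposes the parasite configuration onto the host configuration by
#' least-squares Procrustes (translation, scaling, rotation), and takes the
#' normalised residual sum of squares m2 as the congruence statistic. The
#' null distribution is generated by permuting which parasite is paired
#' with which host; the p-value uses the add-one convention
#' `(1 + #[m2_perm <= m2_obs]) / (1 + n_perm)`, so perfect congruence
#' reports the smallest achievable value rather than zero.
#'
#' @param host_D,parasite_D Distance matrices with taxon labels.
#' @param pairing Two-column data frame (`host`, `parasite`) or named
#'   character vector (`names` = host taxa) giving the one-to-one pairing;
#'   default pairs identical labels.
#' @param n_perm Number of permutations (default 100,000).
#' @param seed Optional seed.
#' @return A list of class `paco_test`: `m2`, `p`, `n_perm`, `n_as_low`,
#'   `seed`.
#' @export
paco_test <- function(host_D, parasite_D, pairing = NULL, n_perm = 1e5,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hl <- rownames(host_D); pl <- rownames(parasite_D)
  if (is.null(pairing)) {
    pairing <- data.frame(host = hl, parasite = hl)
  } else if (!is.data.frame(pairing)) {
    pairing <- data.frame(host = names(pairing), parasite = unname(pairing))
  }
  if (anyDuplicated(pairing$host) || anyDuplicated(pairing$parasite) ||
      nrow(pairing) != nrow(host_D) ||
      !setequal(pairing$host, hl) || !all(pairing$parasite %in% pl)) {
    stop("pairing must be a bijection between host and parasite taxa",
         call. = FALSE)
  }
  hi <- match(pairing$host, hl); pi <- match(pairing$parasite, pl)
  X <- pcoa_embed(host_D)[hi, , drop = FALSE]
  Y <- pcoa_embed(parasite_D)[pi, , drop = FALSE]
  m2_obs <- procrustes_m2(X, Y)
  n <- nrow(X)
  as_low <- 0L
  for (b in seq_len(n_perm)) {
    m2_b <- procrustes_m2(X, Y[sample.int(n), , drop = FALSE])
    if (m2_b <= m2_obs) as_low <- as_low + 1L
  }
  structure(list(m2 = m2_obs, p = (1 + as_low) / (1 + n_perm),
                 n_perm = n_perm, n_as_low = as_low, seed = seed),
            class = "paco_test")
}

#' @exportS3Method base::print
print.paco_test <- function(x, ...) {
  cat("<paco_test> m2 =", signif(x$m2, 4), "| p =", signif(x$p, 3),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}
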