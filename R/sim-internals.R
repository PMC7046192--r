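# Internal machinery of the forward simulator.
#
# Haplotypes are lazy genealogy nodes: a founder carries an explicit mutation
# set; a transmission that adds mutations wraps its parent in a delta node;
# male meiosis wraps two parents in a recombination node with breakpoints.
# Nothing is copied per generation — a haplotype's mutation set is resolved
# only when an individual is sampled into a cohort. This is what makes
# default-scale runs (10*N burn-in generations) tractable.
#
# Node kinds: 0 founder (mut), 1 delta (par, add), 2 recombination
# (par = left of segment [0,b1), par2, br, add). All nodes carry the eager
# fields sg (supergene allele code, 0 = none) and fused (neo-W flag), so
# trajectories and phenotypes never require resolution.

new_founder <- function(mut, sg = 0L, fused = FALSE) {
  list(k = 0L, par = NULL, par2 = NULL, br = NULL, add = NULL,
       mut = mut, sg = sg, fused = fused)
}

new_delta <- function(par, add, fused = par$fused) {
  if (length(add) == 0L && identical(fused, par$fused)) return(par)
  list(k = 1L, par = par, par2 = NULL, br = NULL, add = add,
       mut = NULL, sg = par$sg, fused = fused)
}

new_recomb <- function(left, right, br, add, sg) {
  list(k = 2L, par = left, par2 = right, br = br, add = add,
       mut = NULL, sg = sg, fused = FALSE)
}

# points inside a set of disjoint sorted half-open intervals (2-col matrix)
in_intervals <- function(p, iv) {
  if (is.null(iv)) return(rep(TRUE, length(p)))
  if (nrow(iv) == 0L || length(p) == 0L) return(rep(FALSE, length(p)))
  idx <- findInterval(p, as.vector(t(iv)))
  idx %% 2L == 1L
}

intersect_intervals <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.null(a)) return(b)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1]); hi <- pmin(a[i, 2], b[, 2])
    keep <- lo < hi
    if (any(keep)) out <- rbind(out, cbind(lo[keep], hi[keep]))
  }
  out[order(out[, 1]), , drop = FALSE]
}

segments_from_breaks <- function(br, L) {
  bounds <- c(0, br, L)
  n <- length(bounds) - 1L
  iv <- cbind(bounds[-length(bounds)], bounds[-1])
  odd <- seq_len(n) %% 2L == 1L
  list(left = iv[odd, , drop = FALSE], right = iv[!odd, , drop = FALSE])
}

# Resolve a haplotype node to its sorted mutation-position set.
resolve_hap <- function(h, L) {
  acc <- list(); na <- 0L
  stack <- list(list(h = h, iv = NULL))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr$h; iv <- fr$iv
    repeat {
      if (node$k == 1L) {
        a <- node$add
        if (length(a)) {
          if (!is.null(iv)) a <- a[in_intervals(a, iv)]
          if (length(a)) { na <- na + 1L; acc[[na]] <- a }
        }
        node <- node$par
      } else if (node$k == 0L) {
        m <- node$mut
        if (length(m)) {
          if (!is.null(iv)) m <- m[in_intervals(m, iv)]
          if (length(m)) { na <- na + 1L; acc[[na]] <- m }
        }
        break
      } else {
        a <- node$add
        if (length(a)) {
          if (!is.null(iv)) a <- a[in_intervals(a, iv)]
          if (length(a)) { na <- na + 1L; acc[[na]] <- a }
        }
        segs <- segments_from_breaks(node$br, L)
        ivl <- intersect_intervals(segs$left, iv)
        ivr <- intersect_intervals(segs$right, iv)
        if (nrow(ivr)) stack[[length(stack) + 1L]] <- list(h = node$par2, iv = ivr)
        if (nrow(ivl)) { node <- node$par; iv <- ivl } else break
      }
    }
  }
  if (na == 0L) return(numeric(0))
  sort(unique(unlist(acc[seq_len(na)], use.names = FALSE)))
}

# ---- standing-variation registries -----------------------------------------

# Frequencies under a neutral 1/f spectrum truncated to [lo, hi].
rsfs <- function(n, lo = 0.01, hi = 0.99) lo * (hi / lo)^stats::runif(n)

sfs_het_mean <- function(lo = 0.01, hi = 0.99) {
  lg <- log(hi / lo)
  ef <- (hi - lo) / lg
  ef2 <- (hi^2 - lo^2) / (2 * lg)
  2 * (ef - ef2)
}

# Registry of standing segregating sites for one chromosome region.
# Zero-fold coding positions get a rare-conditioned spectrum (purifying
# selection footprint): the site is kept with probability del_keep and its
# frequency is drawn from the 1/f spectrum truncated above at del_max_freq.
make_registry <- function(len, pi_target, exclude = NULL, zerofold = NULL,
                          del_keep = 0.25, del_max_freq = 0.05) {
  if (pi_target <= 0) {
    return(list(pos = numeric(0), freq = numeric(0), len = len))
  }
  region_len <- len - if (is.null(exclude)) 0 else sum(exclude[, 2] - exclude[, 1])
  s_target <- ceiling(pi_target * region_len / sfs_het_mean())
  s_draw <- min(ceiling(s_target * 1.3) + 100, region_len)
  pos <- sample.int(len, s_draw) - 1
  if (!is.null(exclude)) pos <- pos[!in_intervals(pos, exclude)]
  pos <- sort(pos)
  is_del <- if (is.null(zerofold)) rep(FALSE, length(pos)) else pos %in% zerofold
  keep <- !is_del | stats::runif(length(pos)) < del_keep
  pos <- pos[keep]; is_del <- is_del[keep]
  if (length(pos) > s_target) {
    sel <- sort(sample.int(length(pos), s_target))
    pos <- pos[sel]; is_del <- is_del[sel]
  }
  freq <- numeric(length(pos))
  freq[!is_del] <- rsfs(sum(!is_del))
  if (any(is_del)) freq[is_del] <- rsfs(sum(is_del), hi = del_max_freq)
  list(pos = pos, freq = freq, len = len)
}

registry_draw <- function(reg) {
  if (length(reg$pos) == 0L) return(numeric(0))
  reg$pos[stats::runif(length(reg$pos)) < reg$freq]
}

# New-mutation positions, rejecting collisions with the standing registry
# (residual collisions between independent new mutations are ~1e-3 and
# are tolerated as recurrent hits). Membership is a binary search on the
# sorted registry: this runs once per transmitted haplotype.
in_sorted <- function(pos, sorted) {
  if (!length(sorted) || !length(pos)) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos, sorted)
  idx > 0 & sorted[pmax(idx, 1L)] == pos
}

draw_new_positions <- function(k, L, standing_pos) {
  if (k == 0L) return(numeric(0))
  pos <- floor(stats::runif(k) * L)
  for (i in 1:4) {
    bad <- in_sorted(pos, standing_pos)
    if (!any(bad)) break
    pos[bad] <- floor(stats::runif(sum(bad)) * L)
  }
  pos
}

# ---- reference sequence, genes and codon degeneracy ------------------------

BASES <- c("A", "C", "G", "T")

codon_degeneracy_table <- function() {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  deg <- matrix(NA_character_, nrow = length(codons), ncol = 3,
                dimnames = list(codons, NULL))
  for (cd in codons) {
    if (code[[cd]] == "*") next
    for (p in 1:3) {
      muts <- vapply(BASES, function(b) {
        x <- strsplit(cd, "")[[1]]; x[p] <- b
        code[[paste(x, collapse = "")]]
      }, character(1))
      n_same <- sum(muts == code[[cd]])
      deg[cd, p] <- if (n_same == 4) "fourfold" else if (n_same == 1) "zerofold" else "other"
    }
  }
  deg
}

# Random stop-free coding sequence of n_codons, as integer base codes 1..4.
random_cds <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  ok <- names(code)[code != "*"]
  cds <- sample(ok, n_codons, replace = TRUE)
  match(unlist(strsplit(cds, "")), BASES)
}

# Build a reference genome: random background, stop-free genes tiled over the
# given regions. Returns per-chromosome integer base vectors, a gene tibble
# (0-based half-open, + strand) and per-chromosome 0-fold/4-fold position
# vectors derived from the reference alone.
make_genome <- function(layout, gene_regions, gene_len = 900, gene_spacing = 3e4) {
  stopifnot(gene_len %% 3 == 0)
  deg_tab <- codon_degeneracy_table()
  refs <- lapply(stats::setNames(layout$length, layout$chrom), function(L)
    sample.int(4L, L, replace = TRUE))
  genes <- list(); zf <- list(); ff <- list()
  gid <- 0L
  for (ch in names(gene_regions)) {
    L <- chrom_length(layout, ch)
    reg <- gene_regions[[ch]]
    starts <- seq(reg[1], reg[2] - gene_len, by = gene_spacing)
    zf[[ch]] <- numeric(0); ff[[ch]] <- numeric(0)
    for (s in starts) {
      gid <- gid + 1L
      cds <- random_cds(gene_len / 3)
      refs[[ch]][(s + 1):(s + gene_len)] <- cds
      genes[[gid]] <- tibble::tibble(
        gene = sprintf("gene%03d", gid), chrom = ch,
        start = s, end = s + gene_len, strand = "+")
      codons <- matrix(BASES[cds], ncol = 3, byrow = TRUE)
      cstr <- paste0(codons[, 1], codons[, 2], codons[, 3])
      cls <- deg_tab[cstr, , drop = FALSE]
      posm <- matrix(s + seq_len(gene_len) - 1, ncol = 3, byrow = TRUE)
      zf[[ch]] <- c(zf[[ch]], posm[cls == "zerofold"])
      ff[[ch]] <- c(ff[[ch]], posm[cls == "fourfold"])
    }
    zf[[ch]] <- sort(zf[[ch]]); ff[[ch]] <- sort(ff[[ch]])
  }
  list(refs = refs, genes = dplyr::bind_rows(genes),
       zerofold = zf, fourfold = ff)
}
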