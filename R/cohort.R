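#' Cohort sampling design
#'
#' Describes which individuals to draw into a resequencing-style cohort: one
#' row per (population, group, sex) cell. Groups are `contact_infected`
#' (infected females from the focal deme), `contact_uninfected` (uninfected
#' focal females), `contact_male` (focal males), and `source` (individuals
#' synthesised from the source population's standing variation, fixed for the
#' population's supergene allele). The default mirrors a 42-individual,
#' multi-population design: 15 infected neo-W females from the contact zone
#' plus three 9-individual allopatric subspecies samples. With complete male
#' killing and perfect transmission the deme's females fix for infection, so
#' uninfected individuals and males come from the allopatric populations;
#' request `contact_uninfected`/`contact_males` explicitly for runs sampled
#' before fixation or with leakier parameters.
#'
#' @param contact_infected,contact_uninfected,contact_males Contact-zone cell
#'   sizes.
#' @param source_n Named integer vector: allopatric samples per subspecies
#'   population (names must be supergene allele names).
#' @param source_females Number of females within each source cell (the rest
#'   are males).
#' @return A tibble with columns `population`, `group`, `sex`, `n`,
#'   `sg_allele`.
#' @export
cohort_design <- function(contact_infected = 15, contact_uninfected = 0,
                          contact_males = 0,
                          source_n = c(dorippus = 9, orientis = 9, chrysippus = 9),
                          source_females = 4) {
  rows <- list(
    tibble::tibble(population = "contact_zone", group = "contact_infected",
                   sex = "female", n = contact_infected, sg_allele = NA_character_),
    tibble::tibble(population = "contact_zone", group = "contact_uninfected",
                   sex = "female", n = contact_uninfected, sg_allele = NA_character_),
    tibble::tibble(population = "contact_zone", group = "contact_male",
                   sex = "male", n = contact_males, sg_allele = NA_character_))
  for (al in names(source_n)) {
    stopifnot(al %in% SG_ALLELES)
    nf <- min(source_females, source_n[[al]])
    rows[[length(rows) + 1]] <- tibble::tibble(
      population = al, group = "source",
      sex = c("female", "male"), n = c(nf, source_n[[al]] - nf),
      sg_allele = al)
  }
  dplyr::filter(dplyr::bind_rows(rows), .data$n > 0)
}

resolve_individual <- function(ind, p) {
  list(chr15 = list(mat = resolve_hap(ind$chr15$mat, p$chr15_len),
                    pat = resolve_hap(ind$chr15$pat, p$chr15_len)),
       auto = list(mat = resolve_hap(ind$auto$mat, p$auto_len),
                   pat = resolve_hap(ind$auto$pat, p$auto_len)),
       mito = resolve_hap(ind$mito, p$mito_len),
       symb = if (ind$infected) resolve_hap(ind$symb, p$symb_len))
}

score_from_sg <- function(a_mat, a_pat, penetrance) {
  dose <- (a_mat == 2L) + (a_pat == 2L)
  if (dose == 2L) return(1)
  if (dose == 0L) return(0)
  if (stats::runif(1) < penetrance) 0.5 else 1
}

presence_matrix <- function(sets, all_pos) {
  m <- matrix(0L, nrow = length(all_pos), ncol = length(sets))
  for (j in seq_along(sets)) {
    idx <- match(sets[[j]], all_pos)
    m[idx[!is.na(idx)], j] <- 1L
  }
  m
}

site_alleles <- function(ref_codes, pos) {
  code <- ref_codes[pos + 1]
  list(ref = BASES[code], alt = BASES[code %% 4L + 1L])
}

#' Sample a cohort from a completed simulation
#'
#' Draws the designed individuals, resolves their true haplotypes, and emits
#' a diploid [genotype_matrix()] (phase is recorded only in the truth and the
#' fragments), a sample metadata table with phenotype scores, a phased
#' fragment set over chromosome 15, and the ground-truth record against which
#' inference is validated. Sites fixed or absent across the whole cohort are
#' dropped; the matrix is flagged `all_callable` since every position of the
#' simulated reference is genotypable.
#'
#' @param sim A `neow_sim` from [run_simulation()].
#' @param design A [cohort_design()].
#' @return A list of class `neow_cohort`: `gm`, `samples`, `fragments`,
#'   `truth`, `genes`, `refs`, `layout`, `params`.
#' @export
sample_cohort <- function(sim, design = cohort_design()) {
  st <- sim$state; p <- sim$params
  if (sim$extinct) stop("cannot sample an extinct population", call. = FALSE)
  fem <- st$females
  inf <- vapply(fem, function(i) i$infected, logical(1))
  pools <- list(contact_infected = fem[inf],
                contact_uninfected = fem[!inf],
                contact_male = st$males)
  used <- c(contact_infected = 0L, contact_uninfected = 0L, contact_male = 0L)
  for (g in names(pools)) {
    pools[[g]] <- sample(pools[[g]])  # shuffle once, then take in order
  }
  inds <- list(); meta <- list()
  for (r in seq_len(nrow(design))) {
    row <- design[r, ]
    for (k in seq_len(row$n)) {
      if (row$group == "source") {
        ind <- synth_source_individual(st, match(row$sg_allele, SG_ALLELES), row$sex)
      } else {
        used[[row$group]] <- used[[row$group]] + 1L
        if (used[[row$group]] > length(pools[[row$group]])) {
          stop("design requests more '", row$group,
               "' individuals than alive (", length(pools[[row$group]]),
               " available)", call. = FALSE)
        }
        ind <- pools[[row$group]][[used[[row$group]]]]
      }
      inds[[length(inds) + 1]] <- ind
      meta[[length(meta) + 1]] <- tibble::tibble(
        population = row$population, group = row$group, sex = row$sex)
    }
  }
  meta <- dplyr::bind_rows(meta)
  n <- nrow(meta)
  meta$sample <- sprintf("%s_%02d", toupper(substr(meta$population, 1, 2)), seq_len(n))

  truth_haps <- lapply(inds, resolve_individual, p = p)
  names(truth_haps) <- meta$sample
  fused <- vapply(inds, function(i) isTRUE(i$chr15$mat$fused), logical(1))
  infected <- vapply(inds, function(i) i$infected, logical(1))
  sg_mat <- vapply(inds, function(i) i$chr15$mat$sg, integer(1))
  sg_pat <- vapply(inds, function(i) i$chr15$pat$sg, integer(1))
  matriline <- vapply(inds, function(i)
    if (is.na(i$matriline)) NA_character_ else paste0("M", i$matriline),
    character(1))

  scores <- vapply(seq_len(n), function(i)
    score_from_sg(sg_mat[i], sg_pat[i], p$transiens_penetrance), numeric(1))

  samples <- tibble::tibble(
    sample = meta$sample, sex = meta$sex, population = meta$population,
    score_A = NA_real_, score_B = scores, score_C = scores,
    infected = infected, neow_carrier = fused, matriline = matriline)

  lay <- st$layout
  chrom_spec <- list(
    chr15 = list(get = function(h) h$chr15, ref = st$genome$refs$chr15, dip = TRUE),
    auto1 = list(get = function(h) h$auto, ref = st$genome$refs$auto1, dip = TRUE),
    mito = list(get = function(h) list(mat = h$mito), ref = st$genome$refs$mito,
                dip = FALSE))
  parts <- lapply(names(chrom_spec), function(ch) {
    cs <- chrom_spec[[ch]]
    mats <- lapply(truth_haps, function(h) cs$get(h)$mat)
    pats <- if (cs$dip) lapply(truth_haps, function(h) cs$get(h)$pat)
    all_pos <- sort(unique(c(unlist(mats), unlist(pats))))
    g1 <- presence_matrix(mats, all_pos)
    g2 <- if (cs$dip) presence_matrix(pats, all_pos)
          else matrix(NA_integer_, length(all_pos), n)
    tot <- rowSums(g1) + if (cs$dip) rowSums(g2) else 0
    seg <- tot > 0 & tot < (if (cs$dip) 2L * n else n)
    al <- site_alleles(cs$ref, all_pos[seg])
    list(chrom = rep(ch, sum(seg)), pos = all_pos[seg],
         ref = al$ref, alt = al$alt,
         g1 = g1[seg, , drop = FALSE], g2 = g2[seg, , drop = FALSE],
         haploid = rep(!cs$dip, sum(seg)))
  })
  ns_tot <- sum(vapply(parts, function(x) length(x$pos), integer(1)))
  dp <- matrix(stats::rpois(ns_tot * n, p$depth_mean), ncol = n)
  gq <- matrix(pmin(99L, 25L + stats::rpois(ns_tot * n, 45)), ncol = n)
  gm <- genotype_matrix(
    chrom = unlist(lapply(parts, `[[`, "chrom")),
    pos = unlist(lapply(parts, `[[`, "pos")),
    ref = unlist(lapply(parts, `[[`, "ref")),
    alt = unlist(lapply(parts, `[[`, "alt")),
    gt1 = do.call(rbind, lapply(parts, `[[`, "g1")),
    gt2 = do.call(rbind, lapply(parts, `[[`, "g2")),
    dp = dp, gq = gq, samples = meta$sample,
    haploid = unlist(lapply(parts, `[[`, "haploid")),
    layout = lay, all_callable = TRUE)

  frags <- make_fragments(truth_haps, meta$sample, p)

  truth <- list(
    table = tibble::tibble(sample = meta$sample, fused = fused,
                           infected = infected, matriline = matriline,
                           sg_mat = SG_ALLELES[sg_mat], sg_pat = SG_ALLELES[sg_pat]),
    haps = truth_haps,
    symb = stats::setNames(lapply(truth_haps, `[[`, "symb"), meta$sample),
    fusion_gen = sim$fusion_gen,
    sampling_gen = st$gen,
    foundress_matriline = if (is.na(sim$foundress_matriline)) NA_character_
                          else paste0("M", sim$foundress_matriline))
  structure(list(gm = gm, samples = samples, fragments = frags, truth = truth,
                 genes = st$genome$genes, refs = st$genome$refs, layout = lay,
                 params = p),
            class = "neow_cohort")
}

#' @exportS3Method base::print
print.neow_cohort <- function(x, ...) {
  cat("<neow_cohort>", nrow(x$samples), "samples;", n_sites(x$gm),
      "variant sites;", sum(x$truth$table$fused), "neo-W carriers\n")
  invisible(x)
}

# Phased fragments over chr15: the desk-scale stand-in for read pairs.
# Intervals only; alleles are looked up lazily against the true haplotype
# of origin (fragments are error-free by design).
make_fragments <- function(truth_haps, samples, p) {
  L <- p$chr15_len
  per_hap <- round(p$frag_coverage * L / p$frag_mean_len)
  rows <- list()
  for (s in samples) {
    for (hap in 1:2) {
      if (per_hap == 0) next
      start <- floor(stats::runif(per_hap) * L)
      len <- stats::rgeom(per_hap, 1 / p$frag_mean_len) + 1
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample = s, hap = hap, start = start,
        end = pmin(start + len, L))
    }
  }
  fr <- if (length(rows)) dplyr::bind_rows(rows)
        else tibble::tibble(sample = character(), hap = integer(),
                            start = numeric(), end = numeric())
  structure(list(fragments = fr, chrom = "chr15",
                 haps = lapply(truth_haps, function(h)
                   list(h$chr15$mat, h$chr15$pat)),
                 coverage = p$frag_coverage, mean_len = p$frag_mean_len),
            class = "fragment_set")
}

#' @exportS3Method base::print
print.fragment_set <- function(x, ...) {
  cat("<fragment_set>", nrow(x$fragments), "fragments on", x$chrom,
      "| per-haplotype coverage", x$coverage, "\n")
  invisible(x)
}

ref_as_string <- function(codes) paste(BASES[codes], collapse = "")

#' Export a cohort to standard file formats
#'
#' Writes, into `dir`: the genotypes as a plain VCF (`cohort.vcf`), the
#' sample table, truth table and trajectory as TSV, the phased fragments as
#' TSV, per-chromosome true-haplotype alignments over variant sites as FASTA
#' (two sequences per sample per autosome, one mitochondrial), the gene
#' models as GFF3 with their coding sequences as FASTA, and the genome
#' layout. All outputs are re-loadable with the package's readers.
#'
#' @param cohort A `neow_cohort`.
#' @param dir Output directory (created if needed).
#' @param trajectory Optional trajectory tibble from the `neow_sim`.
#' @return Named character vector of file paths, invisibly.
#' @export
export_sim <- function(cohort, dir, trajectory = NULL) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    stop("cannot write to directory: ", dir, call. = FALSE)
  }
  gm <- cohort$gm
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"),
             fragments = file.path(dir, "fragments.tsv"),
             layout = file.path(dir, "layout.tsv"),
             genes = file.path(dir, "genes.gff3"),
             cds = file.path(dir, "cds.fasta"))
  write_genotypes(gm, paths["vcf"])
  write_samples(cohort$samples, paths["samples"])
  readr::write_tsv(cohort$truth$table, paths["truth"], progress = FALSE)
  readr::write_tsv(cohort$fragments$fragments, paths["fragments"], progress = FALSE)
  readr::write_tsv(tibble::tibble(chrom = cohort$layout$chrom,
                                  length = cohort$layout$length),
                   paths["layout"], progress = FALSE)
  if (!is.null(trajectory) && nrow(trajectory)) {
    paths["trajectory"] <- file.path(dir, "trajectory.tsv")
    readr::write_tsv(trajectory, paths["trajectory"], progress = FALSE)
  }
  # true haplotypes over variant sites, one FASTA per chromosome
  for (ch in unique(gm$chrom)) {
    si <- which(gm$chrom == ch)
    pos <- gm$pos[si]; ref <- gm$ref[si]; alt <- gm$alt[si]
    seqs <- character(0)
    for (s in names(cohort$truth$haps)) {
      h <- cohort$truth$haps[[s]]
      hsets <- switch(ch, chr15 = h$chr15, auto1 = h$auto,
                      mito = list(mito = h$mito))
      for (nm in names(hsets)) {
        b <- ifelse(pos %in% hsets[[nm]], alt, ref)
        seqs[paste0(s, "__", nm)] <- paste(b, collapse = "")
      }
    }
    fp <- file.path(dir, paste0("haplotypes_", ch, ".fasta"))
    paths[paste0("fasta_", ch)] <- fp
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fp)
  }
  g <- cohort$genes
  gr <- GenomicRanges::GRanges(g$chrom,
                               IRanges::IRanges(start = g$start + 1, end = g$end),
                               strand = g$strand, type = "CDS", ID = g$gene,
                               phase = 0L)
  rtracklayer::export(gr, paths[["genes"]], format = "gff3")
  cds <- vapply(seq_len(nrow(g)), function(i) {
    codes <- cohort$refs[[g$chrom[i]]][(g$start[i] + 1):g$end[i]]
    ref_as_string(codes)
  }, character(1))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(cds, g$gene)), paths[["cds"]])
  invisible(paths)
}
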