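test_that("the female-specific scan applies both sides of the frequency rule", {
  # 4 females + 2 males; site 1: allele at 25% in females, absent in males;
  # site 2: same but one male copy; site 3: female frequency 12.5% (too low)
  calls <- rbind(c("0/1", "0/1", "0/0", "0/0", "0/0", "0/0"),
                 c("0/1", "0/1", "0/0", "0/0", "0/1", "0/0"),
                 c("0/1", "0/0", "0/0", "0/0", "0/0", "0/0"))
  lay <- genome_layout(data.frame(chrom = "chr1", length = 1e5))
  gm <- toy_gm(calls, pos = c(10, 20, 30), layout = lay)
  meta <- tibble::tibble(sample = paste0("S", 1:6),
                         sex = rep(c("female", "male"), c(4, 2)))
  sc <- female_specific_scan(gm, meta, size = 1e5, step = 1e5)
  expect_equal(sc$count, 1)
  meta_f <- meta; meta_f$sex <- "female"
  expect_error(female_specific_scan(gm, meta_f), "no males")
})

test_that("female-specific counts concentrate on the fused chromosome", {
  # a male-rich cohort, as in the real study design: with many male alleles
  # the "absent in males" filter clears the autosomal floor
  reps <- replicate_set()
  scan_design <- cohort_design(contact_infected = 10,
                               source_n = c(dorippus = 9, orientis = 9,
                                            chrysippus = 9),
                               source_females = 2)
  ratios <- vapply(seq_along(reps), function(i) {
    set.seed(4000 + i)
    ch <- sample_cohort(reps[[i]]$sim, scan_design)
    sc <- female_specific_scan(ch$gm, ch$samples, size = 5e4, step = 5e4)
    c15 <- sum(sc$count[sc$chrom == "chr15"])
    aut <- sum(sc$count[sc$chrom == "auto1"])
    c15 / max(aut, 1)
  }, numeric(1))
  expect_gt(stats::median(ratios), 10)
})

test_that("diagnostic sites demand heterozygous carriers and absent elsewhere", {
  # carriers C1, C2; non-carriers N1, N2; outgroup O1; 5 sites, only site 2
  # qualifies (all carriers het, allele absent elsewhere)
  calls <- rbind(
    c("0/1", "0/0", "0/0", "0/0", "0/0"),   # not het in all carriers
    c("0/1", "0/1", "0/0", "0/0", "0/0"),   # qualifies
    c("0/1", "1/1", "0/0", "0/0", "0/0"),   # one carrier homozygous -> out
    c("0/1", "0/1", "0/1", "0/0", "0/0"),   # present in a non-carrier
    c("0/1", "0/1", "0/0", "0/0", "0/1"))   # present in the outgroup
  gm <- toy_gm(calls, chrom = "chr15", samples = c("C1", "C2", "N1", "N2", "O1"))
  d <- find_diagnostic_sites(gm, c("C1", "C2"), c("N1", "N2"),
                             outgroups = "O1")
  expect_equal(d$pos, 1)
  expect_equal(d$allele, 1L)
  # by default a missing non-carrier call disqualifies the site; the
  # tolerance flag re-admits it
  calls2 <- rbind(c("0/1", "0/1", "./.", "0/0", "0/0"))
  gm2 <- toy_gm(calls2, chrom = "chr15",
                samples = c("C1", "C2", "N1", "N2", "O1"))
  expect_equal(nrow(find_diagnostic_sites(gm2, c("C1", "C2"), c("N1", "N2"))), 0)
  expect_equal(nrow(find_diagnostic_sites(gm2, c("C1", "C2"), c("N1", "N2"),
                                          max_missing_noncarriers = 1)), 1)
  expect_error(find_diagnostic_sites(gm, c("C1", "N1"), c("N1", "N2")),
               "disjoint")
})

test_that("every diagnostic site satisfies its predicate on simulated data", {
  ch <- smoke_cohort()
  gm <- ch$gm
  carriers <- carriers_of(ch)
  others <- setdiff(ch$samples$sample, carriers)
  d <- find_diagnostic_sites(gm, carriers, others, meta = ch$samples)
  expect_gt(nrow(d), 10)
  ci <- match(carriers, gm$samples); oi <- match(others, gm$samples)
  for (k in sample(seq_len(nrow(d)), min(20, nrow(d)))) {
    i <- which(gm$chrom == "chr15" & gm$pos == d$pos[k])
    expect_true(all(gm$gt1[i, ci] + gm$gt2[i, ci] == 1))
    expect_true(all(gm$gt1[i, oi] + gm$gt2[i, oi] == 0))
  }
})

toy_fragment_set <- function(fragments, haps, chrom = "chr15") {
  structure(list(fragments = fragments, chrom = chrom, haps = haps,
                 coverage = NA, mean_len = NA), class = "fragment_set")
}

test_that("reconstruction calls linked alleles at support >= 3 and not below", {
  # one carrier; diagnostic site at 100 (derived on hap 1); linked derived
  # allele at 140 on the same haplotype; variant site at 500 uncovered
  gm <- toy_gm(rbind("0/1", "0/1", "0/1"), chrom = "chr15",
               pos = c(100, 140, 500), samples = "C1")
  diags <- tibble::tibble(chrom = "chr15", pos = 100, ref = "A", alt = "T",
                          allele = 1L)
  attr(diags, "carriers") <- "C1"
  class(diags) <- c("diagnostic_sites", class(diags))
  haps <- list(C1 = list(c(100, 140), c(500)))  # hap1 = neo-W side
  fr3 <- tibble::tibble(sample = "C1", hap = 1L,
                        start = c(60, 80, 95), end = c(160, 180, 200))
  rec <- reconstruct_neow(gm, diags, toy_fragment_set(fr3, haps))
  expect_equal(unname(rec$H[rec$pos == 140, 1]), 1L)  # linked SNP rescued
  expect_equal(unname(rec$H[rec$pos == 100, 1]), 1L)
  expect_true(is.na(rec$H[rec$pos == 500, 1]))        # uncovered
  # with only two overlapping fragments the call stays missing
  rec2 <- reconstruct_neow(gm, diags, toy_fragment_set(fr3[1:2, ], haps))
  expect_true(all(is.na(rec2$H)))
  # fragments from the autosomal haplotype are never attributed
  fr_wrong <- tibble::tibble(sample = "C1", hap = 2L,
                             start = c(60, 80, 95), end = c(160, 180, 200))
  expect_warning(rec3 <- reconstruct_neow(gm, diags,
                                          toy_fragment_set(fr_wrong, haps)),
                 "no attributed fragments")
  expect_true(all(is.na(rec3$H)))
})

test_that("reconstructed calls never contradict the diploid genotypes", {
  ch <- smoke_cohort()
  gm <- ch$gm
  carriers <- carriers_of(ch)
  d <- find_diagnostic_sites(gm, carriers, setdiff(ch$samples$sample, carriers))
  rec <- reconstruct_neow(gm, d, ch$fragments)
  si <- which(gm$chrom == "chr15")
  for (s in carriers) {
    j <- match(s, gm$samples)
    called <- which(!is.na(rec$H[, s]))
    a <- rec$H[called, s]
    g1 <- gm$gt1[si[called], j]; g2 <- gm$gt2[si[called], j]
    # the haploid allele must be one of the two diploid alleles
    expect_true(all(a == g1 | a == g2))
  }
})

test_that("haploid diversity handles identical, toy and masked inputs", {
  H <- cbind(rep(0L, 100), rep(0L, 100))
  expect_equal(haploid_pi(H), 0)
  H2 <- cbind(rep(0L, 1e5), c(rep(1L, 7), rep(0L, 1e5 - 7)))
  expect_equal(haploid_pi(H2), 7e-5)
  expect_error(haploid_pi(H[, 1, drop = FALSE]), "at least two")
  # all-missing overlap -> NA
  H3 <- cbind(c(1L, NA), c(NA, 0L), c(NA, 0L))
  expect_true(is.na(haploid_pi(H3[, 1:2])))
})

test_that("the divergence test pairs windows and returns p = 1 for identical groups", {
  ch <- smoke_cohort()
  meta <- ch$samples
  dori <- meta$sample[meta$population == "dorippus"]
  colinear <- c(ch$params$sg_end, ch$params$chr15_len)
  # identical groups: all differences zero -> p = 1 by the zero-drop policy
  dt0 <- divergence_test(ch$gm, dori, dori, chrom = "chr15",
                         region = colinear, size = 1e4, min_sites = 2e3)
  expect_equal(dt0$p, 1)
  # carriers immediately post-sweep: no significant divergence yet
  carriers <- carriers_of(ch)
  dt <- divergence_test(ch$gm, carriers, dori, chrom = "chr15",
                        region = colinear, size = 1e4, min_sites = 2e3)
  expect_equal(dt$n_windows, 8)
  expect_true(is.finite(dt$p))
  # too few windows -> null p with warning
  expect_warning(
    dtw <- divergence_test(ch$gm, carriers, dori, chrom = "chr15",
                           region = c(colinear[1], colinear[1] + 4e4),
                           size = 2e4, min_sites = 5e3),
    "fewer than 6")
  expect_true(is.na(dtw$p))
})

test_that("root-age conversions and the moment estimator behave", {
  expect_equal(years_to_generations(2200, 12), 26400)
  expect_equal(generations_to_years(26400, 12), 2200)
  expect_equal(root_age(0, 2.9e-9)$generations, 0)
  expect_equal(root_age(7e-5, 2.9e-9)$generations, 7e-5 / (2 * 2.9e-9))
  expect_true(is.na(root_age(NA_real_, 1e-6)$generations))
  expect_error(root_age(1e-4, 0))
})

test_that("the moment estimator is unbiased on star genealogies", {
  # star tree: k haplotypes each accumulating Poisson(mu*L*T) private
  # mutations; pi-hat / (2 mu) should recover T on average
  set.seed(31)
  mu <- 1e-6; L <- 1e5; T <- 400; k <- 10
  est <- vapply(1:200, function(r) {
    counts <- rpois(k, mu * L * T)
    # expected pairwise difference = counts_i + counts_j over L sites
    pi_hat <- mean(utils::combn(counts, 2, sum)) / L
    pi_hat / (2 * mu)
  }, numeric(1))
  expect_gt(mean(est) / T, 0.9)
  expect_lt(mean(est) / T, 1.1)
})

test_that("mitochondrial clades separate matrilines", {
  ch <- smoke_cohort()
  cl <- mito_clades(ch$gm)
  tt <- ch$truth$table
  inf <- tt$sample[tt$infected]
  expect_equal(length(unique(cl$clade[match(inf, cl$sample)])), 1)
  # the infected clade is not shared with unrelated allopatric samples
  out <- tt$sample[!tt$infected]
  inf_clade <- cl$clade[match(inf, cl$sample)][1]
  expect_lt(mean(cl$clade[match(out, cl$sample)] == inf_clade), 0.2)
})

test_that("neo-W FASTA export writes N for missing calls", {
  ch <- smoke_cohort()
  carriers <- carriers_of(ch)
  d <- find_diagnostic_sites(ch$gm, carriers,
                             setdiff(ch$samples$sample, carriers))
  rec <- reconstruct_neow(ch$gm, d, ch$fragments)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_neow_fasta(rec, ch$gm, path)
  fa <- Biostrings::readDNAStringSet(path)
  expect_equal(length(fa), length(carriers))
  expect_equal(unique(Biostrings::width(fa)), sum(ch$gm$chrom == "chr15"))
  counts <- Biostrings::alphabetFrequency(fa)[1, ]
  expect_gt(counts[["N"]], 0)
})
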