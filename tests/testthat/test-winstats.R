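test_that("window pi, dXY and FST match the brute-force pair-enumeration oracle", {
  set.seed(101)
  for (rep in 1:15) {
    gm <- random_toy_gm(n_sites = 40, n_samples = 8, miss = 0.15)
    pops <- list(P1 = paste0("S", 1:4), P2 = paste0("S", 5:8))
    wd <- window_diversity(gm, pops, c(0, 40), chrom = "chr1")
    # oracle values
    pi1 <- oracle_window_pi(subset_genotypes(gm), pops$P1)
    dxy_site <- vapply(seq_len(40), function(i)
      oracle_site_dxy(site_alleles_of(gm, i, pops$P1),
                      site_alleles_of(gm, i, pops$P2)), numeric(1))
    pw_site <- vapply(seq_len(40), function(i) {
      a <- oracle_site_pi(site_alleles_of(gm, i, pops$P1))
      b <- oracle_site_pi(site_alleles_of(gm, i, pops$P2))
      (a + b) / 2
    }, numeric(1))
    use <- !is.na(pw_site) & !is.na(dxy_site)
    expect_equal(wd$value[wd$stat == "pi" & wd$pop == "P1"], pi1,
                 tolerance = 1e-12)
    expect_equal(wd$value[wd$stat == "dxy"],
                 mean(dxy_site, na.rm = TRUE), tolerance = 1e-12)
    expect_equal(wd$value[wd$stat == "fst"],
                 1 - sum(pw_site[use]) / sum(dxy_site[use]), tolerance = 1e-12)
  }
})

test_that("fixed differences give dXY = k/L and FST = 1", {
  # 100 sites, populations fixed for different alleles at 3 of them
  calls <- matrix("0/0", 100, 4)
  calls[1:3, 3:4] <- "1/1"
  gm <- toy_gm(calls)
  pops <- list(A = c("S1", "S2"), B = c("S3", "S4"))
  wd <- window_diversity(gm, pops, c(0, 100), chrom = "chr1")
  expect_equal(wd$value[wd$stat == "dxy"], 0.03)
  expect_equal(wd$value[wd$stat == "fst"], 1)
  expect_equal(wd$value[wd$stat == "pi" & wd$pop == "A"], 0)
})

test_that("two identical haplotype pairs give pi = 0; dxy(P,P) matches its oracle", {
  calls <- cbind(rep("0/1", 10), rep("0/1", 10))
  gm <- toy_gm(calls)
  wd <- window_diversity(gm, list(P = c("S1", "S2")), c(0, 10), chrom = "chr1")
  expect_gt(wd$value[wd$stat == "pi"], 0)  # het pairs do segregate
  gm0 <- toy_gm(cbind(rep("0/0", 10), rep("0/0", 10)))
  wd0 <- window_diversity(gm0, list(P = c("S1", "S2")), c(0, 10), chrom = "chr1")
  expect_equal(wd0$value[wd0$stat == "pi"], 0)
  # between-population formula applied to two copies of one population
  set.seed(7)
  gm2 <- random_toy_gm(30, 4, miss = 0)
  both <- list(X = paste0("S", 1:4), Y = paste0("S", 1:4))
  wd2 <- window_diversity(gm2, both, c(0, 30), chrom = "chr1")
  oracle <- mean(vapply(1:30, function(i) {
    a <- site_alleles_of(gm2, i, both$X)
    oracle_site_dxy(a, a)
  }, numeric(1)))
  expect_equal(wd2$value[wd2$stat == "dxy"], oracle, tolerance = 1e-12)
  # and it approaches within-population pi (they differ by the 1/(n-1) term)
  pi_val <- wd2$value[wd2$stat == "pi" & wd2$pop == "X"]
  expect_lt(abs(wd2$value[wd2$stat == "dxy"] - pi_val), pi_val / 7 + 1e-12)
})

test_that("Hudson FST is centred on zero for samples from one population", {
  set.seed(42)
  fst <- vapply(1:100, function(r) {
    f <- runif(300, 0.05, 0.95)
    calls <- vapply(seq_len(12), function(j)
      paste(rbinom(300, 1, f), rbinom(300, 1, f), sep = "/"), character(300))
    gm <- toy_gm(calls)
    pops <- list(A = paste0("S", 1:6), B = paste0("S", 7:12))
    wd <- window_diversity(gm, pops, c(0, 300), chrom = "chr1")
    wd$value[wd$stat == "fst"]
  }, numeric(1))
  expect_lt(abs(mean(fst)), 0.02)
})

test_that("pi is invariant to sample order and allele relabelling", {
  set.seed(8)
  gm <- random_toy_gm(30, 6, miss = 0.1)
  pop <- paste0("S", 1:6)
  v1 <- window_diversity(gm, list(P = pop), c(0, 30), chrom = "chr1")
  v2 <- window_diversity(gm, list(P = rev(pop)), c(0, 30), chrom = "chr1")
  expect_equal(v1$value[1], v2$value[1])
  # swap allele labels 0 <-> 1
  gm_sw <- gm
  gm_sw$gt1 <- 1L - gm$gt1; gm_sw$gt2 <- 1L - gm$gt2
  v3 <- window_diversity(gm_sw, list(P = pop), c(0, 30), chrom = "chr1")
  expect_equal(v1$value[1], v3$value[1])
})

test_that("heterozygosity density counts hets per genotyped site", {
  calls <- cbind(c(rep("0/1", 5), rep("0/0", 3), rep("./.", 2)))
  lay <- genome_layout(data.frame(chrom = "chr1", length = 1e5))
  gm <- toy_gm(calls, pos = seq(0, 9000, by = 1000), all_callable = TRUE,
               layout = lay)
  # all-callable: denominator is window length minus this sample's missing
  expect_equal(het_density(gm, "S1", c(0, 1e5), chrom = "chr1"),
               5 / (1e5 - 2))
  gm2 <- toy_gm(calls, pos = seq(0, 9000, by = 1000))
  expect_equal(het_density(gm2, "S1", c(0, 1e5), chrom = "chr1"), 5 / 8)
  # haploid-coded sites are a contract violation
  gmh <- toy_gm(cbind(c("1", "0")))
  expect_error(het_density(gmh, "S1", c(0, 2), chrom = "chr1"), "haploid")
  # identity with the two-haplotype pi on simulated truth
  ch <- smoke_cohort()
  s <- ch$samples$sample[1]
  h <- ch$truth$haps[[s]]$chr15
  win <- c(120000, 200000)
  m1 <- h$mat[h$mat >= win[1] & h$mat < win[2]]
  m2 <- h$pat[h$pat >= win[1] & h$pat < win[2]]
  mism <- length(setdiff(m1, m2)) + length(setdiff(m2, m1))
  expect_equal(het_density(ch$gm, s, win, chrom = "chr15"),
               mism / (win[2] - win[1]))
})

test_that("genome_scan enumerates windows, flags low-site windows, honours regions", {
  lay <- genome_layout(data.frame(chrom = "chr1", length = 1e6))
  set.seed(3)
  gm <- random_toy_gm(60, 4)
  gm$chrom <- rep("chr1", 60)
  gm$pos <- sort(sample(0:999999, 60))
  gm$layout <- lay
  meta <- tibble::tibble(sample = paste0("S", 1:4),
                         population = rep(c("A", "B"), each = 2))
  sc <- genome_scan(gm, meta, layout = lay, statistic = "pi", min_sites = 0)
  expect_equal(nrow(sc), 46 * 2)  # 46 windows x 2 populations
  sc2 <- genome_scan(gm, meta, layout = lay, statistic = "pi", min_sites = 2e4)
  expect_true(all(sc2$low_sites))
  expect_true(all(is.na(sc2$value)))
  sc3 <- genome_scan(gm, meta, layout = lay, statistic = "pi", min_sites = 0,
                     region = c(5e5, 1e6))
  expect_true(all(sc3$start >= 5e5))
  expect_error(genome_scan(gm, meta, layout = lay, statistic = "fst",
                           populations = c("A", "Z")), "unknown population")
})

test_that("a window with 19,999 genotyped sites is null-flagged at the 20,000 rule", {
  lay <- genome_layout(data.frame(chrom = "chr1", length = 1e5))
  gm <- toy_gm(matrix("0/1", 2, 4), pos = c(10, 20), layout = lay)
  meta <- tibble::tibble(sample = paste0("S", 1:4), population = "A")
  # not all-callable: only 2 genotyped variant sites < 20,000
  sc <- genome_scan(gm, meta, layout = lay, statistic = "pi")
  expect_true(all(sc$low_sites))
  # all-callable 100-kb window minus one fully-missing site: 99,999 sites
  calls <- matrix("0/1", 2, 4); calls[2, ] <- "./."
  gm2 <- toy_gm(calls, pos = c(10, 20), layout = lay, all_callable = TRUE)
  sc2 <- genome_scan(gm2, meta, layout = lay, statistic = "pi",
                     min_sites = 1e5)
  expect_equal(sc2$n_sites, 1e5 - 1L)
  expect_true(sc2$low_sites)
})

test_that("4-fold diversity matches hand enumeration on a toy gene", {
  # gene of glycine codons GGA: all third positions are 4-fold
  gene <- tibble::tibble(gene = "g1", chrom = "chr1", start = 0, end = 9,
                         strand = "+")
  refs <- list(chr1 = "GGAGGAGGA")
  # polymorphism at the two third positions 2 and 5
  calls <- rbind(c("0/1", "0/1", "0/0"), c("1/1", "0/0", "0/1"))
  gm <- toy_gm(calls, pos = c(2, 5))
  deg <- classify_degeneracy(gm, gene, refs)
  expect_equal(deg$pos[deg$class == "fourfold"], c(2, 5, 8))
  # hand enumeration: site 2 alleles (0,1,0,1,0,0): pi = 1 - (C(4,2)+C(2,2))/C(6,2);
  # site 5 alleles (1,1,0,0,0,1): pi = 1 - (C(3,2)+C(3,2))/C(6,2)
  pi2 <- 1 - (choose(4, 2) + choose(2, 2)) / choose(6, 2)
  pi5 <- 1 - (choose(3, 2) + choose(3, 2)) / choose(6, 2)
  expect_equal(fourfold_pi(gm, deg), (pi2 + pi5) / 2)
  # no polymorphism -> 0 (all-callable denominates over classified sites)
  gm0 <- toy_gm(matrix("0/0", 2, 3), pos = c(2, 5), all_callable = TRUE)
  deg0 <- classify_degeneracy(gm0, gene, refs)
  expect_equal(fourfold_pi(gm0, deg0), 0)
})

test_that("depth genotyping uses anchors 1, 0.5, 0 with a no-call band", {
  expect_equal(depth_genotype(c(0.97, 0.99, 1.01)), "two_copies")
  expect_equal(depth_genotype(rep(0.5, 5)), "one_copy")
  expect_equal(depth_genotype(c(0.01, 0.05)), "zero_copies")
  expect_equal(depth_genotype(0.3), "no_call")   # inside the gap
  expect_equal(depth_genotype(numeric(0)), NA_character_)
})

test_that("chr15 differentiation exceeds the control autosome after the sweep", {
  reps <- replicate_set()
  fst_gap <- vapply(reps, function(r) {
    ch <- r$cohort
    meta <- ch$samples
    pops <- list(contact = meta$sample[meta$population == "contact_zone"],
                 dorippus = meta$sample[meta$population == "dorippus"])
    colinear <- c(ch$params$sg_end, ch$params$chr15_len)
    f15 <- window_diversity(ch$gm, pops, colinear, chrom = "chr15")
    fau <- window_diversity(ch$gm, pops, c(0, ch$params$auto_len),
                            chrom = "auto1")
    f15$value[f15$stat == "fst"] - fau$value[fau$stat == "fst"]
  }, numeric(1))
  expect_gt(mean(fst_gap), 0)
  expect_gt(mean(fst_gap > 0), 0.8)
})
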