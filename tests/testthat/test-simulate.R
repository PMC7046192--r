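tiny_params <- function(...) {
  base <- list(n_females = 10, n_males = 10, chr15_len = 2e4, auto_len = 2e4,
               mito_len = 5e3, mu = 1e-6, burn_in = 20, t_fusion = 20,
               n_gen_post = 20, sg_start = 5e3, sg_end = 1.2e4,
               gene_spacing = 4e3, pool_size = 20, frag_coverage = 0)
  do.call(sim_params, utils::modifyList(base, list(...)))
}

test_that("parameter validation catches invalid inputs", {
  expect_error(sim_params(mk_penetrance = 1.5), "probabilities")
  expect_error(sim_params(n_females = 0), "positive")
  expect_error(sim_params(mu = -1), "mutation rates")
  expect_error(sim_params(chr15_len = 0), "lengths must be positive")
  expect_error(sim_params(sg_start = 2e6), "supergene interval")
  expect_error(sim_params(sg_freqs = c(a = 1, b = 0, c = 0.5)), "summing to 1")
})

test_that("identical seeds give identical trajectories and cohorts", {
  s1 <- run_simulation(tiny_params(seed = 11))
  s2 <- run_simulation(tiny_params(seed = 11))
  expect_equal(s1$trajectory, s2$trajectory)
  c1 <- sample_cohort(s1, cohort_design(contact_infected = 4,
                                        source_n = c(dorippus = 3),
                                        source_females = 1))
  # RNG state differs after the two runs; reseed for the sampling step
  set.seed(99); c1 <- sample_cohort(s1, cohort_design(contact_infected = 4,
                                                      source_n = c(dorippus = 3),
                                                      source_females = 1))
  set.seed(99); c2 <- sample_cohort(s2, cohort_design(contact_infected = 4,
                                                      source_n = c(dorippus = 3),
                                                      source_females = 1))
  expect_equal(c1$gm$pos, c2$gm$pos)
  expect_equal(c1$gm$gt1, c2$gm$gt1)
})

test_that("zero mutation rate and empty source give no segregating sites", {
  p <- tiny_params(mu = 0, mu_mito = 0, mu_symb = 0, source_pi = 0,
                   sg_within_pi = 0, sg_div = 0, mito_pi = 0, seed = 3)
  sim <- run_simulation(p, condition_on_survival = FALSE)
  ch <- sample_cohort(sim, cohort_design(contact_infected = 0,
                                         contact_uninfected = 4,
                                         contact_males = 2,
                                         source_n = c(dorippus = 0)))
  expect_equal(n_sites(ch$gm), 0)
})

test_that("forward burn-in from a monomorphic start matches Watterson's expectation", {
  # mu * L = 0.1 per transmitted haplotype; diploid Ne = 4*Nf*Nm/(Nf+Nm)
  n_rep <- 12
  S <- vapply(seq_len(n_rep), function(i) {
    p <- sim_params(n_females = 10, n_males = 10, chr15_len = 1e4,
                    auto_len = 1e4, mito_len = 1e3, mu = 1e-5, mu_mito = 0,
                    xover_male = 0, migration = 0, burn_in = 200, t_fusion = 200,
                    n_gen_post = 0, sg_start = 2e3, sg_end = 5e3,
                    source_pi = 0, sg_within_pi = 0, sg_div = 0, mito_pi = 0,
                    gene_spacing = 4e3, pool_size = 5, frag_coverage = 0,
                    seed = 500 + i)
    sim <- run_simulation(p, condition_on_survival = FALSE)
    ch <- sample_cohort(sim, cohort_design(contact_infected = 0,
                                           contact_uninfected = 8,
                                           contact_males = 0,
                                           source_n = c(dorippus = 0)))
    sum(ch$gm$chrom == "auto1")
  }, numeric(1))
  ne <- 4 * 10 * 10 / 20
  theta <- 4 * ne * 0.1               # per-chromosome theta = 4 Ne mu L
  a_n <- sum(1 / seq_len(16 - 1))     # 8 diploids = 16 alleles
  expected <- theta * a_n
  se <- stats::sd(S) / sqrt(n_rep)
  expect_lt(abs(mean(S) - expected), 3 * se + 0.15 * expected)
})

test_that("complete male-killing with perfect transmission leaves no infected males", {
  sim <- smoke_sim()   # mk_penetrance = 1, transmission = 1
  males <- sim$state$males
  if (length(males)) {
    expect_false(any(vapply(males, function(i) i$infected, logical(1))))
  }
  # and no male ever carries a fused haplotype
  fused_m <- vapply(males, function(i)
    isTRUE(i$chr15$mat$fused) || isTRUE(i$chr15$pat$fused), logical(1))
  expect_false(any(fused_m))
})

test_that("infected individuals form a single matriline that carries the fusion", {
  sim <- smoke_sim()
  fem <- sim$state$females
  inf <- vapply(fem, function(i) i$infected, logical(1))
  mats <- vapply(fem, function(i) i$matriline, integer(1))
  expect_true(any(inf))
  expect_equal(unique(mats[inf]), sim$foundress_matriline)
  fused <- vapply(fem, function(i) isTRUE(i$chr15$mat$fused), logical(1))
  expect_true(all(fused[inf]))   # tau = 1: infected => fused matriline
})

test_that("sampled genotypes re-derive exactly from the true haplotypes", {
  ch <- smoke_cohort()
  gm <- ch$gm
  for (s in sample(ch$samples$sample, 5)) {
    j <- match(s, gm$samples)
    h <- ch$truth$haps[[s]]
    for (chn in c("chr15", "auto1")) {
      si <- which(gm$chrom == chn)
      sets <- if (chn == "chr15") h$chr15 else h$auto
      expect_equal(unname(gm$gt1[si, j]), as.integer(gm$pos[si] %in% sets$mat))
      expect_equal(unname(gm$gt2[si, j]), as.integer(gm$pos[si] %in% sets$pat))
    }
    si <- which(gm$chrom == "mito")
    expect_equal(unname(gm$gt1[si, j]), as.integer(gm$pos[si] %in% h$mito))
    expect_true(all(is.na(gm$gt2[si, j])))
  }
})

test_that("the trajectory records every post-fusion generation", {
  sim <- smoke_sim()
  expect_equal(nrow(sim$trajectory), sim$params$n_gen_post)
  expect_true(all(diff(sim$trajectory$gen) == 1))
  expect_true(all(sim$trajectory$fused_freq >= 0 &
                    sim$trajectory$fused_freq <= 1))
})

test_that("an all-infected deme without immigration signals extinction", {
  p <- tiny_params(migration = 0, seed = 5)
  st <- init_population(p)
  st$females <- lapply(st$females, function(f) {
    f$infected <- TRUE
    f$symb <- neowsweep:::new_founder(numeric(0))
    f
  })
  st2 <- advance_generation(st)   # no mother can produce a surviving son
  expect_true(st2$extinct)
})

test_that("neutral, closed runs leave the fused-haplotype frequency unbiased", {
  # s = 0, k_mk = 0, m = 0: the fusion drifts; mean change over replicates ~ 0
  n_rep <- 120
  delta <- vapply(seq_len(n_rep), function(i) {
    p <- sim_params(n_females = 12, n_males = 12, chr15_len = 1e4,
                    auto_len = 1e4, mito_len = 1e3, mu = 0, mu_mito = 0,
                    xover_male = 0, migration = 0, mk_penetrance = 0, brood_advantage = 0,
                    burn_in = 0, t_fusion = 0, n_gen_post = 8,
                    sg_start = 2e3, sg_end = 5e3, source_pi = 0,
                    sg_within_pi = 0, sg_div = 0, mito_pi = 0,
                    gene_spacing = 4e3, pool_size = 5, frag_coverage = 0,
                    seed = 9000 + i)
    sim <- run_simulation(p, condition_on_survival = FALSE)
    tr <- sim$trajectory
    tr$fused_freq[nrow(tr)] - tr$fused_freq[1]
  }, numeric(1))
  se <- stats::sd(delta) / sqrt(n_rep)
  expect_lt(abs(mean(delta)), 3 * se + 1e-9)
})

test_that("requesting more individuals than alive errors; zero coverage empties fragments", {
  sim <- smoke_sim()
  expect_error(sample_cohort(sim, cohort_design(contact_infected = 500)),
               "more .* individuals than alive")
  p0 <- tiny_params(frag_coverage = 0, seed = 21)
  ch <- sample_cohort(run_simulation(p0),
                      cohort_design(contact_infected = 3,
                                    source_n = c(dorippus = 3),
                                    source_females = 1))
  expect_equal(nrow(ch$fragments$fragments), 0)
  expect_gt(n_sites(ch$gm), 0)
})

test_that("export writes reloadable files with matching sample order", {
  ch <- smoke_cohort()
  dir <- withr::local_tempdir()
  paths <- export_sim(ch, dir)
  gm2 <- load_genotypes(paths[["vcf"]], permissive_policy())
  expect_equal(gm2$samples, ch$samples$sample)
  expect_equal(unname(gm2$gt1), unname(ch$gm$gt1))
  expect_equal(unname(gm2$gt2), unname(ch$gm$gt2))
  tab <- load_samples(paths[["samples"]])
  expect_equal(tab$sample, ch$samples$sample)
  # truth FASTA: 2 sequences per sample per autosome, 1 mitochondrial
  fa <- Biostrings::readDNAStringSet(paths[["fasta_chr15"]])
  expect_equal(length(fa), 2 * nrow(ch$samples))
  fm <- Biostrings::readDNAStringSet(paths[["fasta_mito"]])
  expect_equal(length(fm), nrow(ch$samples))
  genes <- load_genes(paths[["genes"]])
  expect_equal(sort(genes$gene), sort(ch$genes$gene))
  expect_error(export_sim(ch, file.path(tempfile(), "no", "such", "deep")),
               NA)  # creates directories recursively
})
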