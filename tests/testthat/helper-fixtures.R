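# Shared fixtures and independent oracles. Simulated cohorts are expensive,
# so they are built once per test run and memoised in this environment.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# ---- toy genotype matrices --------------------------------------------------

# Build a genotype_matrix from a character matrix of "a/b" calls ("." or
# "./." = missing, "a" = haploid), default positions 0,1,2,...
toy_gm <- function(calls, chrom = "chr1", pos = NULL, samples = NULL,
                   all_callable = FALSE, layout = NULL) {
  calls <- as.matrix(calls)
  ns <- nrow(calls)
  if (is.null(pos)) pos <- seq_len(ns) - 1
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(calls)))
  a1 <- matrix(NA_integer_, ns, ncol(calls))
  a2 <- matrix(NA_integer_, ns, ncol(calls))
  haploid <- rep(FALSE, ns)
  for (i in seq_len(ns)) for (j in seq_len(ncol(calls))) {
    g <- calls[i, j]
    if (g %in% c(".", "./.", NA)) next
    parts <- strsplit(g, "/", fixed = TRUE)[[1]]
    a1[i, j] <- as.integer(parts[1])
    if (length(parts) == 2) a2[i, j] <- as.integer(parts[2])
    else haploid[i] <- TRUE
  }
  genotype_matrix(chrom = rep(chrom, ns), pos = pos,
                  ref = rep("A", ns), alt = rep("T", ns),
                  gt1 = a1, gt2 = a2, samples = samples, haploid = haploid,
                  layout = layout, all_callable = all_callable)
}

# Random toy matrix: biallelic sites, diploid calls with missingness.
random_toy_gm <- function(n_sites = 50, n_samples = 6, miss = 0.1,
                          all_callable = FALSE) {
  draw <- function() {
    f <- runif(1, 0.1, 0.9)
    a <- rbinom(2, 1, f)
    paste(a[1], a[2], sep = "/")
  }
  calls <- matrix("", n_sites, n_samples)
  for (i in seq_len(n_sites)) for (j in seq_len(n_samples)) {
    calls[i, j] <- if (runif(1) < miss) "./." else draw()
  }
  toy_gm(calls, all_callable = all_callable)
}

# ---- brute-force oracles ----------------------------------------------------

# Enumerate all unordered pairs of called alleles at one site.
oracle_site_pi <- function(alleles) {
  a <- alleles[!is.na(alleles)]
  n <- length(a)
  if (n < 2) return(NA_real_)
  diff <- 0; tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if (a[i] != a[j]) diff <- diff + 1
  }
  diff / tot
}

oracle_site_dxy <- function(alleles1, alleles2) {
  a <- alleles1[!is.na(alleles1)]; b <- alleles2[!is.na(alleles2)]
  if (!length(a) || !length(b)) return(NA_real_)
  diff <- 0; tot <- 0
  for (x in a) for (y in b) {
    tot <- tot + 1
    if (x != y) diff <- diff + 1
  }
  diff / tot
}

site_alleles_of <- function(gm, site, samples) {
  ci <- match(samples, gm$samples)
  c(gm$gt1[site, ci], gm$gt2[site, ci])
}

# Window oracle over variant sites (per genotyped variant site, i.e. for
# all_callable = FALSE matrices).
oracle_window_pi <- function(gm, samples) {
  vals <- vapply(seq_len(n_sites(gm)), function(i)
    oracle_site_pi(site_alleles_of(gm, i, samples)), numeric(1))
  mean(vals, na.rm = TRUE)
}

# ---- simulated fixtures -----------------------------------------------------

smoke_params <- function(seed = 42) {
  sim_params(n_females = 30, n_males = 30, chr15_len = 2e5, auto_len = 2e5,
             mu = 1e-6, burn_in = 100, t_fusion = 100, n_gen_post = 100,
             sg_start = 5e4, sg_end = 1.2e5, gene_spacing = 5e3,
             pool_size = 60, frag_coverage = 10, seed = seed)
}

smoke_design <- function() {
  cohort_design(contact_infected = 10,
                source_n = c(dorippus = 6, orientis = 5, chrysippus = 5),
                source_females = 2)
}

smoke_sim <- function() memo("smoke_sim", function() run_simulation(smoke_params()))

smoke_cohort <- function() memo("smoke_cohort", function()
  sample_cohort(smoke_sim(), smoke_design()))

# Replicate set for property checks: smaller demes, sampled near the end of
# the sweep (the deme is a finite matrilineal population, so sampling long
# after fixation would let the neo-W lineages coalesce again and blur the
# fusion-age signal).
replicate_params <- function(seed) {
  sim_params(n_females = 24, n_males = 24, chr15_len = 1.5e5, auto_len = 1.5e5,
             mu = 1e-6, burn_in = 80, t_fusion = 80, n_gen_post = 75,
             sg_start = 4e4, sg_end = 9e4, gene_spacing = 4e3,
             pool_size = 50, frag_coverage = 10, seed = seed)
}

replicate_design <- function() {
  cohort_design(contact_infected = 10,
                source_n = c(dorippus = 6, orientis = 5, chrysippus = 5),
                source_females = 1)
}

# One replicate; a run whose sweep left fewer carriers than the design needs
# is replaced (the design, like the real study, samples a swept zone).
one_replicate <- function(seed) {
  for (k in 0:4) {
    sim <- run_simulation(replicate_params(seed + 1000 * k))
    ch <- tryCatch(sample_cohort(sim, replicate_design()),
                   error = function(e) NULL)
    if (!is.null(ch)) return(list(sim = sim, cohort = ch))
  }
  stop("no usable replicate for seed ", seed)
}

replicate_set <- function(n = 10) {
  memo(paste0("replicates_", n), function()
    lapply(seq_len(n), function(i) one_replicate(100 + i)))
}

# Dedicated replicates for root-age recovery. The moment estimator reads the
# mean pairwise coalescence time of the sampled neo-W copies, which tracks
# the fusion age only while the matrilineal deme is large relative to the
# sweep duration (as in the empirical system); these runs use a larger deme
# and sample close to fixation so post-sweep matrilineal drift has not yet
# erased the signal.
rootage_params <- function(seed) {
  sim_params(n_females = 150, n_males = 150, chr15_len = 1.5e5, auto_len = 3e4,
             mito_len = 5e3, mu = 1e-6, burn_in = 40, t_fusion = 40,
             n_gen_post = 125, sg_start = 4e4, sg_end = 9e4,
             gene_spacing = 4e3, pool_size = 60, frag_coverage = 10,
             seed = seed)
}

rootage_design <- function() {
  cohort_design(contact_infected = 12, source_n = c(dorippus = 6),
                source_females = 2)
}

rootage_set <- function(n = 5) {
  memo(paste0("rootage_", n), function() lapply(seq_len(n), function(i) {
    for (k in 0:4) {
      sim <- run_simulation(rootage_params(300 + i + 1000 * k))
      ch <- tryCatch(sample_cohort(sim, rootage_design()),
                     error = function(e) NULL)
      if (!is.null(ch)) return(ch)
    }
    stop("no usable root-age replicate for seed ", 300 + i)
  }))
}

carriers_of <- function(ch) ch$samples$sample[ch$samples$neow_carrier %in% TRUE]

painting_refs <- function(ch) {
  meta <- ch$samples
  als <- c("chrysippus", "dorippus", "orientis")
  lapply(stats::setNames(als, als), function(a)
    cohort_haplotypes(ch, "chr15", meta$sample[meta$population == a]))
}
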