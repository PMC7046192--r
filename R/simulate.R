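SG_ALLELES <- c("chrysippus", "dorippus", "orientis")

#' Parameters of the forward neo-W/male-killer simulator
#'
#' The generator emulates a contact-zone deme of a ZW butterfly embedded in a
#' very large, nearly panmictic source population: achiasmatic female meiosis
#' (whole chromosomes transmitted intact by mothers), a W-autosome fusion
#' introduced in a single infected foundress, a maternally co-transmitted
#' male-killing symbiont and mitochondrion, heavy male immigration from a
#' source pool fixed for the dorippus supergene allele, recombining male
#' meiosis, and infinite-sites mutation. Standing variation is seeded from a
#' neutral 1/f frequency spectrum representing the source population's
#' mutation-drift equilibrium; the focal deme is additionally burned in
#' forward for `burn_in` generations before the fusion event.
#'
#' @param n_females,n_males Focal deme sizes per generation.
#' @param chr15_len,auto_len,mito_len,symb_len Chromosome lengths (bp) for the
#'   fused chromosome, a control autosome, the mitochondrion, and the symbiont
#'   genome.
#' @param mu,mu_mito,mu_symb Per-base per-generation mutation rates.
#' @param xover_male Expected crossovers per chromosome per male meiosis
#'   (female meiosis has none).
#' @param migration Probability that an offspring's father is an immigrant
#'   from the source pool.
#' @param mk_penetrance Probability that an infected son dies (male killing).
#' @param transmission Mother-to-offspring symbiont transmission fidelity.
#' @param brood_advantage Fitness advantage `s` of daughters of infected
#'   broods: infected mothers receive weight `1 + s` when daughters are drawn.
#' @param burn_in Neutral forward generations before the fusion; default
#'   `10 * (n_females + n_males)`.
#' @param t_fusion Generation (counted from the start of the run, after
#'   seeding) at which the single fused, infected foundress appears; default
#'   equals `burn_in`.
#' @param n_gen_post Generations simulated after the fusion event.
#' @param sg_start,sg_end Supergene interval on chr15 (0-based, half-open);
#'   male crossovers are suppressed inside it.
#' @param sg_freqs Initial supergene allele frequencies in the focal deme
#'   (named: chrysippus, dorippus, orientis).
#' @param transiens_penetrance Probability that a heterozygote carrying
#'   dorippus expresses the intermediate (transiens) phenotype and is scored
#'   0.5 rather than 1.
#' @param foundress_allele Supergene allele carried by the foundress's fused
#'   haplotype (default `"chrysippus"`: the neo-W carries the recessive
#'   colour-pattern allele, so infected females are heterozygous against the
#'   dorippus haplotypes their immigrant fathers supply).
#' @param source_pi Standing per-bp nucleotide diversity of the source
#'   population outside the supergene.
#' @param sg_within_pi,sg_div Within-allele diversity and per-bp density of
#'   allele-private fixed differences inside the supergene (the three alleles
#'   are old, diverged, low-diversity clades).
#' @param mito_pi Standing mitochondrial diversity.
#' @param del_keep,del_max_freq Purifying-selection footprint at 0-fold coding
#'   positions: fraction of candidate standing sites kept, and the upper
#'   frequency bound of their spectrum.
#' @param gene_len,gene_spacing Coding-gene length (multiple of 3) and spacing
#'   used to tile the colinear part of chr15 and the control autosome.
#' @param pool_size Number of males in the immigrant source pool.
#' @param frag_mean_len,frag_coverage Phased-fragment generator: geometric
#'   mean fragment length (bp) and expected per-site fragment depth per
#'   haplotype.
#' @param depth_mean Mean simulated per-call read depth.
#' @param seed Optional integer seed; when set, `run_simulation()` is fully
#'   reproducible.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_females = 100, n_males = 100,
                       chr15_len = 1e6, auto_len = 1e6, mito_len = 15000,
                       symb_len = 1e6,
                       mu = 5e-7, mu_mito = 5e-7, mu_symb = 5e-7,
                       xover_male = 1.0, migration = 0.8,
                       mk_penetrance = 1.0, transmission = 1.0,
                       brood_advantage = 0.1,
                       burn_in = 10 * (n_females + n_males),
                       t_fusion = burn_in, n_gen_post = 150,
                       sg_start = 250e3, sg_end = 600e3,
                       sg_freqs = c(chrysippus = 0.3, dorippus = 0.5, orientis = 0.2),
                       transiens_penetrance = 0.5,
                       foundress_allele = "chrysippus",
                       source_pi = 0.0228, sg_within_pi = 0.004, sg_div = 0.005,
                       mito_pi = 0.01, del_keep = 0.25, del_max_freq = 0.05,
                       gene_len = 900, gene_spacing = 3e4, pool_size = 200,
                       frag_mean_len = 500, frag_coverage = 10,
                       depth_mean = 20, seed = NULL) {
  p <- as.list(environment())
  probs <- c(migration, mk_penetrance, transmission, transiens_penetrance)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (n_females <= 0 || n_males <= 0) stop("population sizes must be positive", call. = FALSE)
  if (any(c(mu, mu_mito, mu_symb) < 0)) stop("mutation rates must be >= 0", call. = FALSE)
  if (any(c(chr15_len, auto_len, mito_len, symb_len) <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  if (!(sg_start >= 0 && sg_start < sg_end && sg_end <= chr15_len)) {
    stop("supergene interval must lie inside chr15", call. = FALSE)
  }
  if (abs(sum(sg_freqs) - 1) > 1e-8 || length(sg_freqs) != 3) {
    stop("sg_freqs must be three frequencies summing to 1", call. = FALSE)
  }
  if (t_fusion < burn_in) stop("t_fusion must be >= burn_in", call. = FALSE)
  if (!foundress_allele %in% SG_ALLELES) {
    stop("foundress_allele must be one of ", paste(SG_ALLELES, collapse = ", "),
         call. = FALSE)
  }
  structure(p, class = "sim_params")
}

#' @exportS3Method base::print
print.sim_params <- function(x, ...) {
  cat("<sim_params> deme", x$n_females, "F +", x$n_males, "M; chr15",
      x$chr15_len, "bp; mu", x$mu, "; burn-in", x$burn_in,
      "gens; post-fusion", x$n_gen_post, "gens\n")
  invisible(x)
}

sim_layout <- function(p) {
  genome_layout(tibble::tibble(
    chrom = c("chr15", "auto1", "mito"),
    length = c(p$chr15_len, p$auto_len, p$mito_len)))
}

new_individual <- function(sex, chr15_mat, chr15_pat, auto_mat, auto_pat,
                           mito, infected, symb, matriline) {
  list(sex = sex, chr15 = list(mat = chr15_mat, pat = chr15_pat),
       auto = list(mat = auto_mat, pat = auto_pat), mito = mito,
       infected = infected, symb = symb, matriline = matriline)
}

founder_chr15 <- function(st, allele) {
  mut <- c(registry_draw(st$reg$chr15), st$reg$sg_fixed[[allele]],
           registry_draw(st$reg$sg_poly[[allele]]))
  new_founder(sort(mut), sg = allele)
}

founder_auto <- function(st) new_founder(registry_draw(st$reg$auto))
founder_mito <- function(st) new_founder(registry_draw(st$reg$mito))

synth_source_individual <- function(st, allele, sex) {
  new_individual(sex,
                 founder_chr15(st, allele), founder_chr15(st, allele),
                 founder_auto(st), founder_auto(st),
                 founder_mito(st), infected = FALSE, symb = NULL,
                 matriline = NA_integer_)
}

#' Initialise the focal deme and immigrant pool, then burn in
#'
#' Seeds the focal deme and the immigrant pool from the source population's
#' standing variation (neutral 1/f spectrum; the supergene as three diverged
#' low-diversity allele clades; 0-fold coding positions rare-conditioned) and
#' runs `burn_in` neutral forward generations. With `source_pi = 0` the run
#' starts monomorphic and diversity accumulates purely by forward mutation,
#' which is the configuration checked against Watterson's expectation.
#'
#' @param params A [sim_params()].
#' @return A population state (list), with elements `females`, `males`,
#'   `pool`, `reg`, `genome`, `params`, `gen`, `extinct`.
#' @export
init_population <- function(params) {
  p <- params
  lay <- sim_layout(p)
  regions <- list(chr15 = c(p$sg_end, p$chr15_len - p$gene_len),
                  auto1 = c(0, p$auto_len - p$gene_len))
  genome <- make_genome(lay, regions, p$gene_len, p$gene_spacing)
  sg_iv <- matrix(c(p$sg_start, p$sg_end), ncol = 2)
  reg <- list(
    chr15 = make_registry(p$chr15_len, p$source_pi, exclude = sg_iv,
                          zerofold = genome$zerofold$chr15,
                          del_keep = p$del_keep, del_max_freq = p$del_max_freq),
    auto = make_registry(p$auto_len, p$source_pi,
                         zerofold = genome$zerofold$auto1,
                         del_keep = p$del_keep, del_max_freq = p$del_max_freq),
    mito = make_registry(p$mito_len, p$mito_pi))
  # supergene: per-allele private fixed differences + within-allele polymorphism
  sg_len <- p$sg_end - p$sg_start
  n_fix <- round(p$sg_div * sg_len)
  n_poly_target <- ceiling(p$sg_within_pi * sg_len / sfs_het_mean())
  total <- 3 * (n_fix + n_poly_target)
  all_sg <- p$sg_start + sample.int(sg_len, min(total, sg_len)) - 1
  idx <- 0
  sg_fixed <- list(); sg_poly <- list()
  for (a in 1:3) {
    sg_fixed[[a]] <- sort(all_sg[idx + seq_len(n_fix)]); idx <- idx + n_fix
    pp <- sort(all_sg[idx + seq_len(n_poly_target)]); idx <- idx + n_poly_target
    sg_poly[[a]] <- list(pos = pp, freq = rsfs(length(pp)), len = sg_len)
  }
  reg$sg_fixed <- sg_fixed; reg$sg_poly <- sg_poly
  st <- list(reg = reg, genome = genome, layout = lay, params = p,
             gen = 0L, extinct = FALSE, next_matriline = 0L)
  draw_allele <- function(n) sample.int(3L, n, replace = TRUE, prob = p$sg_freqs)
  st$females <- lapply(seq_len(p$n_females), function(i) {
    st$next_matriline <<- st$next_matriline + 1L
    new_individual("female", founder_chr15(st, draw_allele(1)),
                   founder_chr15(st, draw_allele(1)),
                   founder_auto(st), founder_auto(st), founder_mito(st),
                   FALSE, NULL, st$next_matriline)
  })
  st$males <- lapply(seq_len(p$n_males), function(i) {
    st$next_matriline <<- st$next_matriline + 1L
    new_individual("male", founder_chr15(st, draw_allele(1)),
                   founder_chr15(st, draw_allele(1)),
                   founder_auto(st), founder_auto(st), founder_mito(st),
                   FALSE, NULL, st$next_matriline)
  })
  st$pool <- lapply(seq_len(p$pool_size), function(i)
    synth_source_individual(st, 2L, "male"))
  for (g in seq_len(p$burn_in)) {
    st <- advance_generation(st)
    if (st$extinct) break
  }
  st
}

transmit_female <- function(mom_hap, n_new, L, standing) {
  new_delta(mom_hap, draw_new_positions(n_new, L, standing))
}

transmit_male <- function(dad, chrom, n_cx, n_new, L, standing, sg_iv, sg_mid) {
  haps <- dad[[chrom]]
  adds <- draw_new_positions(n_new, L, standing)
  if (n_cx == 0L) {
    h <- if (stats::runif(1) < 0.5) haps$mat else haps$pat
    return(new_delta(h, adds))
  }
  br <- stats::runif(n_cx) * L
  if (!is.null(sg_iv)) {
    for (i in 1:10) {
      bad <- br >= sg_iv[1] & br < sg_iv[2]
      if (!any(bad)) break
      br[bad] <- stats::runif(sum(bad)) * L
    }
    br[br >= sg_iv[1] & br < sg_iv[2]] <- sg_iv[2]
  }
  br <- sort(unique(br))
  if (stats::runif(1) < 0.5) { left <- haps$mat; right <- haps$pat }
  else { left <- haps$pat; right <- haps$mat }
  sg <- if (is.null(sg_mid)) 0L else {
    if (sum(br <= sg_mid) %% 2 == 0) left$sg else right$sg
  }
  new_recomb(left, right, br, adds, sg)
}

#' Advance the population by one generation
#'
#' One non-overlapping generation: mothers of daughters are drawn with weight
#' `1 + s` for infected broods; each offspring's father is an immigrant with
#' probability `migration`, else a resident male; daughters receive the
#' mother's W-side chromosome 15 (the fused haplotype, when she carries one)
#' and sons the Z-side copy, each intact; fathers transmit with male
#' crossovers (suppressed inside the supergene); mitochondrion and symbiont
#' travel maternally, the symbiont with fidelity `transmission`; infected
#' sons die with probability `mk_penetrance`; every transmitted haplotype
#' gains Poisson(mu * L) new mutations at uniform positions.
#'
#' If no surviving male (or no mother able to produce one) exists and
#' immigration is zero, the state returns with `extinct = TRUE` rather than
#' erroring.
#'
#' @param state A population state from [init_population()].
#' @return The next-generation state.
#' @export
advance_generation <- function(state) {
  st <- state; p <- st$params
  if (st$extinct) return(st)
  fem <- st$females
  if (length(fem) == 0L) { st$extinct <- TRUE; return(st) }
  mal <- st$males
  if (length(mal) == 0L && p$migration == 0) { st$extinct <- TRUE; return(st) }
  inf <- vapply(fem, function(i) i$infected, logical(1))
  w_d <- ifelse(inf, 1 + p$brood_advantage, 1)
  mom_d <- sample.int(length(fem), p$n_females, replace = TRUE, prob = w_d)
  inf_d <- inf[mom_d] & stats::runif(p$n_females) < p$transmission

  # sons: drawn uniformly, infected sons die with probability mk_penetrance.
  # When no mother can produce a surviving son the deme simply has no
  # resident males this generation; that is extinction only if immigrant
  # fathers are also unavailable.
  son_surv <- ifelse(inf, 1 - p$transmission * p$mk_penetrance, 1)
  n_sons <- if (all(son_surv <= 1e-12)) 0L else p$n_males
  if (n_sons == 0L && p$migration == 0) { st$extinct <- TRUE; return(st) }
  mom_s <- integer(0); inf_s <- logical(0)
  while (length(mom_s) < n_sons) {
    cand <- sample.int(length(fem), 2L * p$n_males, replace = TRUE)
    ci <- inf[cand] & stats::runif(length(cand)) < p$transmission
    dies <- ci & stats::runif(length(cand)) < p$mk_penetrance
    mom_s <- c(mom_s, cand[!dies]); inf_s <- c(inf_s, ci[!dies])
  }
  mom_s <- mom_s[seq_len(n_sons)]; inf_s <- inf_s[seq_len(n_sons)]

  n_off <- p$n_females + n_sons
  moms <- c(mom_d, mom_s)
  infs <- c(inf_d, inf_s)
  sexes <- rep(c("female", "male"), c(p$n_females, n_sons))
  use_pool <- stats::runif(n_off) < p$migration | length(mal) == 0L
  dad_pool <- sample.int(length(st$pool), n_off, replace = TRUE)
  dad_res <- if (length(mal)) sample.int(length(mal), n_off, replace = TRUE) else rep(1L, n_off)

  mu15 <- p$mu * p$chr15_len; muA <- p$mu * p$auto_len; muM <- p$mu_mito * p$mito_len
  nm_m15 <- stats::rpois(n_off, mu15); nm_p15 <- stats::rpois(n_off, mu15)
  nm_mA <- stats::rpois(n_off, muA); nm_pA <- stats::rpois(n_off, muA)
  nm_mt <- stats::rpois(n_off, muM)
  ncx15 <- stats::rpois(n_off, p$xover_male); ncxA <- stats::rpois(n_off, p$xover_male)
  sg_iv <- c(p$sg_start, p$sg_end); sg_mid <- (p$sg_start + p$sg_end) / 2
  st15 <- st$reg$chr15$pos; stA <- st$reg$auto$pos; stM <- st$reg$mito$pos

  offspring <- vector("list", n_off)
  for (i in seq_len(n_off)) {
    mom <- fem[[moms[i]]]
    dad <- if (use_pool[i]) st$pool[[dad_pool[i]]] else mal[[dad_res[i]]]
    fused_mat <- isTRUE(mom$chr15$mat$fused)
    if (sexes[i] == "female") {
      from_mom <- if (fused_mat || stats::runif(1) < 0.5) mom$chr15$mat else mom$chr15$pat
    } else {
      from_mom <- if (fused_mat) mom$chr15$pat
                  else if (stats::runif(1) < 0.5) mom$chr15$mat else mom$chr15$pat
      if (isTRUE(from_mom$fused)) stop("internal: male received a fused haplotype")
    }
    c15m <- transmit_female(from_mom, nm_m15[i], p$chr15_len, st15)
    c15p <- transmit_male(dad, "chr15", ncx15[i], nm_p15[i], p$chr15_len,
                          st15, sg_iv, sg_mid)
    autm <- transmit_female(
      if (stats::runif(1) < 0.5) mom$auto$mat else mom$auto$pat,
      nm_mA[i], p$auto_len, stA)
    autp <- transmit_male(dad, "auto", ncxA[i], nm_pA[i], p$auto_len,
                          stA, NULL, NULL)
    mito <- new_delta(mom$mito, draw_new_positions(nm_mt[i], p$mito_len, stM))
    symb <- if (infs[i]) {
      new_delta(mom$symb, draw_new_positions(
        stats::rpois(1, p$mu_symb * p$symb_len), p$symb_len, numeric(0)))
    } else NULL
    offspring[[i]] <- new_individual(sexes[i], c15m, c15p, autm, autp, mito,
                                     infs[i], symb, mom$matriline)
  }
  st$females <- offspring[seq_len(p$n_females)]
  st$males <- offspring[p$n_females + seq_len(n_sons)]
  st$gen <- st$gen + 1L
  st
}

state_summary <- function(st) {
  fem <- st$females
  fused <- vapply(fem, function(i) isTRUE(i$chr15$mat$fused), logical(1))
  infected <- c(vapply(fem, function(i) i$infected, logical(1)),
                vapply(st$males, function(i) i$infected, logical(1)))
  sg <- unlist(lapply(c(fem, st$males), function(i)
    c(i$chr15$mat$sg, i$chr15$pat$sg)))
  tibble::tibble(gen = st$gen,
                 fused_freq = mean(fused),
                 infected_freq = mean(infected),
                 freq_chrysippus = mean(sg == 1L),
                 freq_dorippus = mean(sg == 2L),
                 freq_orientis = mean(sg == 3L))
}

#' Run the full simulation: burn-in, fusion event, spread
#'
#' Initialises and burns in the deme, introduces a single infected female
#' whose maternal chromosome 15 becomes fused to the W at `t_fusion`, runs
#' `n_gen_post` further generations, and records the per-generation
#' trajectory of fusion, infection and supergene allele frequencies.
#'
#' @param params A [sim_params()].
#' @param condition_on_survival Retry the post-fusion phase (from the saved
#'   fusion-time state, with a new random foundress) until the fused lineage
#'   survives to the end of the run (default `TRUE`: the generator models the
#'   observed, successful invasion; a single new copy is usually lost by
#'   drift). Set `FALSE` for unconditioned dynamics, e.g. neutrality checks.
#' @param max_attempts Maximum establishment retries (default 200).
#' @return A list of class `neow_sim`: `state` (final), `params`,
#'   `trajectory` (tibble), `fusion_gen`, `foundress_matriline`, `extinct`,
#'   `attempts`.
#' @export
run_simulation <- function(params, condition_on_survival = TRUE,
                           max_attempts = 200) {
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  st0 <- init_population(p)
  for (g in seq_len(p$t_fusion - p$burn_in)) {
    st0 <- advance_generation(st0)
    if (st0$extinct) break
  }
  attempts <- 0L
  repeat {
    attempts <- attempts + 1L
    st <- st0
    foundress_matriline <- NA_integer_
    if (!st$extinct) {
      i <- sample.int(length(st$females), 1)
      f <- st$females[[i]]
      # the fused haplotype carries the foundress allele on a fresh
      # source-population background (she is an immigrant-descended female)
      fh <- founder_chr15(st, match(p$foundress_allele, SG_ALLELES))
      fh$fused <- TRUE
      f$chr15$mat <- fh
      f$infected <- TRUE
      f$symb <- new_founder(numeric(0))
      st$females[[i]] <- f
      foundress_matriline <- f$matriline
    }
    traj <- vector("list", p$n_gen_post)
    lost <- FALSE
    for (g in seq_len(p$n_gen_post)) {
      if (st$extinct) break
      st <- advance_generation(st)
      traj[[g]] <- state_summary(st)
      if (condition_on_survival && traj[[g]]$fused_freq == 0) {
        lost <- TRUE  # lineage lost; abandon this attempt early
        break
      }
    }
    traj <- dplyr::bind_rows(traj)
    established <- !st$extinct && !lost && nrow(traj) > 0 &&
      traj$fused_freq[nrow(traj)] > 0
    if (!condition_on_survival || established || attempts >= max_attempts ||
        st$extinct) {
      break
    }
  }
  if (condition_on_survival && !established && !st$extinct) {
    warning("fused lineage not established after ", attempts, " attempts")
  }
  structure(list(state = st, params = p, trajectory = traj,
                 fusion_gen = p$t_fusion,
                 foundress_matriline = foundress_matriline,
                 extinct = st$extinct, attempts = attempts),
            class = "neow_sim")
}

#' @exportS3Method base::print
print.neow_sim <- function(x, ...) {
  cat("<neow_sim> generation", x$state$gen,
      if (x$extinct) "(EXTINCT)" else "", "\n")
  if (nrow(x$trajectory)) {
    last <- x$trajectory[nrow(x$trajectory), ]
    cat("  fused haplotype frequency among females:",
        round(last$fused_freq, 3), "\n",
        " infected fraction:", round(last$infected_freq, 3), "\n")
  }
  invisible(x)
}
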