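# Orchestration: one configuration, seeded end-to-end runs of
# simulate -> scans -> association -> painting -> neo-W chain -> Pn/Ps ->
# congruence, with every output table carrying a commented header that
# echoes the package version, the seed and the full parameter set.

#' Assemble a run configuration
#'
#' @param seed Integer seed used for every stochastic stage.
#' @param sim Named list of [sim_params()] overrides.
#' @param design Named list of [cohort_design()] overrides.
#' @param stages Stages to run, in dependency order; any of `"simulate"`,
#'   `"scan"`, `"assoc"`, `"paint"`, `"neow"`, `"pnps"`, `"paco"`,
#'   `"export"`.
#' @param out_dir Output directory (`NULL` = no files written).
#' @param scan_stats Statistics for the scan stage.
#' @param n_perm Permutations for the congruence test.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, sim = list(), design = list(),
                       stages = c("simulate", "scan", "assoc", "paint",
                                  "neow", "pnps", "paco"),
                       out_dir = NULL, scan_stats = c("pi", "fst"),
                       n_perm = 999) {
  structure(list(seed = seed, sim = sim, design = design, stages = stages,
                 out_dir = out_dir, scan_stats = scan_stats, n_perm = n_perm),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()].
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

header_lines <- function(config, params) {
  c(paste0("# neowsweep ", as.character(utils::packageVersion("neowsweep"))),
    paste0("# seed: ", config$seed),
    paste0("# params: ", paste(names(params), unlist(lapply(params, function(x)
      paste(format(x, trim = TRUE), collapse = ","))),
      sep = "=", collapse = " ")))
}

write_stage_tsv <- function(df, path, config, params = list()) {
  writeLines(header_lines(config, params), path)
  suppressWarnings(readr::write_tsv(df, path, append = TRUE, col_names = TRUE,
                                    progress = FALSE))
  invisible(path)
}

#' Run the configured pipeline end to end
#'
#' Executes the requested stages in dependency order on one seed. Every
#' analysis stage consumes the simulated cohort, so requesting an analysis
#' stage without `"simulate"` fails loudly naming the missing dependency.
#'
#' @param config A [run_config()] or path to a YAML file.
#' @return A list of class `neow_pipeline` with one element per stage run.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- load_config(config)
  stages <- config$stages
  needs_cohort <- setdiff(stages, c("simulate"))
  if (length(needs_cohort) && !"simulate" %in% stages) {
    stop("stage(s) ", paste(needs_cohort, collapse = ", "),
         " require the 'simulate' stage", call. = FALSE)
  }
  out <- list(config = config)
  dir <- config$out_dir
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)

  p <- do.call(sim_params, c(config$sim, list(seed = config$seed)))
  sim <- run_simulation(p)
  if (sim$extinct) stop("population went extinct during the run", call. = FALSE)
  design <- do.call(cohort_design, config$design)
  cohort <- sample_cohort(sim, design)
  out$simulate <- list(sim = sim, cohort = cohort)
  if (!is.null(dir)) export_sim(cohort, file.path(dir, "sim"), sim$trajectory)

  gm <- cohort$gm; meta <- cohort$samples
  sg_iv <- c(p$sg_start, p$sg_end)
  colinear <- c(p$sg_end, p$chr15_len)
  carriers <- meta$sample[meta$neow_carrier %in% TRUE]
  wildtype <- setdiff(meta$sample[meta$population == "contact_zone"], carriers)
  if (length(wildtype) < 2) {
    # after a completed sweep no uninfected contact individuals remain; the
    # allopatric dorippus sample stands in as the wild-type comparison
    wildtype <- meta$sample[meta$population == "dorippus"]
  }

  if ("scan" %in% stages) {
    scans <- dplyr::bind_rows(lapply(config$scan_stats, function(st)
      genome_scan(gm, meta, statistic = st,
                  chromosomes = c("chr15", "auto1"))))
    out$scan <- scans
    if (!is.null(dir)) {
      write_stage_tsv(scans, file.path(dir, "scan.tsv"), config,
                      list(size = 1e5, step = 2e4, min_sites = 2e4))
    }
  }
  if ("assoc" %in% stages) {
    res <- assoc_scan(gm, meta, pheno = "score_B",
                      min_n = ceiling(0.95 * nrow(meta)))
    hits <- top_hits(res, genes = cohort$genes)
    out$assoc <- list(results = res, hits = hits)
    if (!is.null(dir)) {
      write_stage_tsv(res, file.path(dir, "assoc.tsv"), config,
                      list(pheno = "score_B"))
    }
  }
  if ("paint" %in% stages) {
    refs <- lapply(stats::setNames(SG_ALLELES, SG_ALLELES), function(al)
      cohort_haplotypes(cohort, "chr15",
                        meta$sample[meta$population == al]))
    focal <- meta$sample[meta$population == "contact_zone"]
    paintings <- lapply(focal, function(s) {
      hs <- cohort_haplotypes(cohort, "chr15", s)
      paint_chromosome(hs, refs, layout = cohort$layout,
                       sg_interval = sg_iv, sample = s)
    })
    out$paint <- dplyr::bind_rows(lapply(paintings, `[[`, "painting"))
    if (!is.null(dir)) {
      write_stage_tsv(out$paint, file.path(dir, "painting.tsv"), config,
                      list(window = 2e4, ratio = 0.8))
    }
  }
  if ("neow" %in% stages) {
    fss <- female_specific_scan(gm, meta)
    diag <- find_diagnostic_sites(gm, carriers,
                                  setdiff(meta$sample, carriers), meta = meta)
    recon <- reconstruct_neow(gm, diag, cohort$fragments)
    hpi <- haploid_pi(recon)
    age <- root_age(hpi, p$mu)
    col_len <- colinear[2] - colinear[1]
    dsize <- min(1e5, max(1e4, 1e4 * (col_len %/% 8e4)))
    dt <- divergence_test(gm, carriers, wildtype, chrom = "chr15",
                          region = colinear, size = dsize,
                          min_sites = 0.2 * dsize)
    out$neow <- list(scan = fss, diagnostics = diag, reconstruction = recon,
                     haploid_pi = hpi, root_age = age, divergence = dt)
    if (!is.null(dir)) {
      write_stage_tsv(fss, file.path(dir, "female_specific.tsv"), config,
                      list(freq_threshold = 0.2))
      write_stage_tsv(dt$windows, file.path(dir, "divergence.tsv"), config,
                      list(p = dt$p))
    }
  }
  if ("pnps" %in% stages) {
    deg <- classify_degeneracy(gm, cohort$genes, cohort$refs)
    chr15 <- stratified_pnps(gm, deg, carriers, "chr15", exclude = sg_iv)
    autos <- stratified_pnps(gm, deg, carriers, "auto1")
    cmp <- bootstrap_compare(chr15, autos, seed = config$seed)
    out$pnps <- list(chr15 = chr15, autosomes = autos, compare = cmp)
    if (!is.null(dir)) {
      write_stage_tsv(chr15$by_class, file.path(dir, "pnps_chr15.tsv"),
                      config, list(cohort = length(carriers)))
    }
  }
  if ("paco" %in% stages) {
    if (length(carriers) >= 3) {
      host <- distance_matrix(
        lapply(stats::setNames(carriers, carriers), function(s)
          cohort$truth$haps[[s]]$chr15$mat))
      para <- distance_matrix(cohort$truth$symb[carriers])
      out$paco <- paco_test(host, para, n_perm = config$n_perm,
                            seed = config$seed)
    }
  }
  structure(out, class = "neow_pipeline")
}

#' @exportS3Method base::print
print.neow_pipeline <- function(x, ...) {
  cat("<neow_pipeline> stages:",
      paste(setdiff(names(x), "config"), collapse = ", "), "\n")
  invisible(x)
}
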