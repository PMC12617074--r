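## End-to-end orchestration: a structured (YAML) run configuration drives
## the stages simulate -> harmonize -> qc -> split -> summarize -> popgen ->
## model -> adjust.  Every output CSV is stamped with the resolved-config
## hash and the run seed, and reruns with the same configuration are
## byte-identical.

#' Default run configuration
#'
#' All tunables of a full run: scaling constants (mu 4e-8 per generation
#' per site, generation time 5 years), epoch boundaries, QC quantiles
#' (0.975 replicate filter, 0.95 edge filter), MAF threshold 0.02, window
#' sizes (10 kb pi, 50 kb dxy), permutation counts and the scenario of the
#' synthetic cohort.
#'
#' @param seed master seed; every stochastic step derives its own seed from
#'   it.
#' @return nested list of class "RunConfig".
#' @export
defaultRunConfig <- function(seed = 1) {
  structure(list(
    seed = seed,
    scaling = list(mu = 4e-8, gen_time = 5),
    scenario = list(
      species_per_host = list(generalist = 3, SD = 3),
      pops_per_species = 2, n_bootstraps = 10, base_ne = 1e5,
      gamma = list(generalist = 0, SD = 0.5),
      noise_sd = 0.2, ar_coef = 0.6, n_segments = 20, max_age = 1e6,
      contam_frac = 0),
    ## the covariate curve is a fixed reference dataset (one chronology
    ## realization), not resampled per run
    sea = list(max_age = 1e6, step = 1000, seed = 42),
    epochs = list(
      list(name = "fluctuation_old", t_start = 150000, t_end = 350000),
      list(name = "fluctuation_recent", t_start = 15000, t_end = 120000),
      list(name = "rise", t_start = 0, t_end = 15000)),
    qc = list(replicate_q = 0.975, edge_q = 0.95, by_population = FALSE,
              outlier_epochs = c("fluctuation_old", "fluctuation_recent"),
              exclusions = list()),
    split = list(threshold = 0.5, n_segments = 40),
    genotypes = list(pops_per_species = 3, n_diploids = 10, n_sites = 2000,
                     fst = 0.1, chrom_length = 1e6, maf = 0.02,
                     pi_window = 10000, dxy_window = 50000),
    model = list(backend = "lmm", formula_mode = "randomSlope",
                 fanova_B = 199)),
    class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override \code{\link{defaultRunConfig}}.
#'
#' @param path YAML file.
#' @return a "RunConfig" list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig(seed = if (!is.null(user$seed)) user$seed else 1)
  merge2 <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]) &&
                        !is.null(names(upd[[nm]])))
        merge2(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  structure(merge2(unclass(cfg), user), class = "RunConfig")
}

.config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(unclass(cfg)), tf)
  unname(tools::md5sum(tf))
}

.write_stamped <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", .config_hash(cfg),
                     as.integer(cfg$seed)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.read_stamped <- function(path) {
  if (!file.exists(path))
    stop("missing dependency: '", path,
         "' (run the upstream stage first)", call. = FALSE)
  utils::read.csv(path, comment.char = "#")
}

.msg <- function(log, ...) {
  line <- sprintf(...)
  message(line)
  if (!is.null(log)) cat(line, "\n", file = log, append = TRUE)
}

.traj_path <- function(dir, sp, pop, rep)
  file.path(dir, "smc", sprintf("%s__%s__%s.final.txt", sp, pop, rep))

## rebuild trajectory list from the simulate stage's files
.load_trajectories <- function(outdir, constants) {
  metaPath <- file.path(outdir, "trajectory_meta.csv")
  meta <- .read_stamped(metaPath)
  trajs <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    p <- .traj_path(outdir, meta$species[i], meta$population[i],
                    meta$replicate[i])
    trajs[[i]] <- scaleToReal(readSMC(p), constants,
                              species = meta$species[i],
                              population = meta$population[i],
                              replicate = meta$replicate[i])
  }
  list(trajs = trajs, meta = meta,
       hosts = stats::setNames(meta$host_category,
                               meta$species)[!duplicated(meta$species)])
}

.ensemble_from_csv <- function(path) {
  df <- .read_stamped(path)
  ids <- unique(df[, c("species", "population", "replicate",
                       "host_category")])
  tm <- sort(unique(df$time))
  ne <- matrix(NA_real_, length(tm), nrow(ids))
  for (j in seq_len(nrow(ids))) {
    sub <- df[df$species == ids$species[j] &
              df$population == ids$population[j] &
              df$replicate == ids$replicate[j], ]
    ne[match(sub$time, tm), j] <- sub$Ne
  }
  TrajectoryEnsemble(ne, tm, ids)
}

.ensemble_to_csv <- function(ensemble, path, cfg, sea = NULL) {
  ne <- neValues(ensemble)
  info <- trajInfo(ensemble)
  tm <- gridTimes(ensemble)
  idx <- which(!is.na(ne), arr.ind = TRUE)
  df <- data.frame(species = info$species[idx[, 2]],
                   population = info$population[idx[, 2]],
                   replicate = info$replicate[idx[, 2]],
                   host_category = info$host_category[idx[, 2]],
                   time = tm[idx[, 1]], Ne = ne[idx])
  if (!is.null(sea)) df$sea_level <- sea[idx[, 1]]
  df <- df[order(df$species, df$population, df$replicate, df$time), ]
  .write_stamped(df, path, cfg)
}

.cfg_epochs <- function(cfg)
  stats::setNames(lapply(cfg$epochs, function(e)
    epoch(e$name, e$t_start, e$t_end)),
    vapply(cfg$epochs, `[[`, "", "name"))

#' Run one pipeline stage
#'
#' Stages: \code{simulate} (write all synthetic inputs), \code{harmonize}
#' (common-grid ensemble), \code{qc} (replicate and edge filters),
#' \code{split} (pairwise split times), \code{summarize} (epoch harmonic
#' means + rank tests), \code{popgen} (pi/FST/dxy and the pairwise table),
#' \code{model} (mixed model + functional ANOVA), \code{adjust}
#' (covariate-adjusted FST/dxy), or \code{all}.  Stages are idempotent;
#' missing upstream outputs raise an error naming the absent file.
#'
#' @param stage stage name.
#' @param cfg a "RunConfig" (see \code{\link{defaultRunConfig}}).
#' @param outdir output directory.
#' @return invisible list of artifact paths written by the stage.
#' @export
runStage <- function(stage, cfg = defaultRunConfig(), outdir = "nescape_run") {
  stages <- c("simulate", "harmonize", "qc", "split", "summarize",
              "popgen", "model", "adjust")
  if (identical(stage, "all")) {
    out <- lapply(stages, runStage, cfg = cfg, outdir = outdir)
    return(invisible(unlist(out)))
  }
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; use one of: ",
         paste(c(stages, "all"), collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(outdir, "run.log")
  constants <- scalingConstants(cfg$scaling$mu, cfg$scaling$gen_time)
  writeLines(yaml::as.yaml(unclass(cfg)),
             file.path(outdir, "resolved_config.yaml"))
  paths <- switch(stage,
    simulate = .stage_simulate(cfg, outdir, constants, log),
    harmonize = .stage_harmonize(cfg, outdir, constants, log),
    qc = .stage_qc(cfg, outdir, log),
    split = .stage_split(cfg, outdir, log),
    summarize = .stage_summarize(cfg, outdir, constants, log),
    popgen = .stage_popgen(cfg, outdir, log),
    model = .stage_model(cfg, outdir, log),
    adjust = .stage_adjust(cfg, outdir, log))
  invisible(paths)
}

#' Run the whole pipeline
#'
#' Convenience wrapper for \code{runStage("all", ...)}.
#'
#' @inheritParams runStage
#' @return invisible vector of artifact paths.
#' @export
runPipeline <- function(cfg = defaultRunConfig(), outdir = "nescape_run")
  runStage("all", cfg = cfg, outdir = outdir)

.stage_simulate <- function(cfg, outdir, constants, log) {
  sc <- cfg$scenario
  scen <- scenarioConfig(
    nSpeciesPerHost = unlist(sc$species_per_host),
    popsPerSpecies = sc$pops_per_species, nBootstraps = sc$n_bootstraps,
    baseNe = sc$base_ne, gamma = unlist(sc$gamma), noiseSd = sc$noise_sd,
    arCoef = sc$ar_coef, nSegments = sc$n_segments, maxAge = sc$max_age,
    contamFrac = sc$contam_frac, seed = cfg$seed)
  seaSeed <- if (!is.null(cfg$sea$seed)) cfg$sea$seed else cfg$seed
  sea <- simSeaLevel(cfg$sea$max_age, cfg$sea$step, seed = seaSeed)
  writeSeaLevel(sea, file.path(outdir, "sea_level.csv"))
  sim <- simTrajectories(scen, sea, constants)
  dir.create(file.path(outdir, "smc"), showWarnings = FALSE)
  for (i in seq_along(sim$scaled))
    writeSMC(sim$scaled[[i]],
             .traj_path(outdir, sim$meta$species[i], sim$meta$population[i],
                        sim$meta$replicate[i]))
  .write_stamped(sim$meta, file.path(outdir, "trajectory_meta.csv"), cfg)
  ## cross-coalescence series + genotypes, one set per species
  dir.create(file.path(outdir, "crosscoal"), showWarnings = FALSE)
  dir.create(file.path(outdir, "vcf"), showWarnings = FALSE)
  gcfg <- cfg$genotypes
  species <- unique(sim$meta$species)
  truth <- list(); samples <- list()
  for (si in seq_along(species)) {
    sp <- species[si]
    spSeed <- cfg$seed * 1000L + si
    pops <- sprintf("%s_gpop%d", sp, seq_len(gcfg$pops_per_species))
    gen <- simGenotypes(nPops = gcfg$pops_per_species,
                        nDiploids = gcfg$n_diploids,
                        nSites = gcfg$n_sites, fst = gcfg$fst,
                        chromLength = gcfg$chrom_length, seed = spSeed)
    ## relabel generic pops with species-qualified names
    gmeta <- gen$meta
    gmeta$population <- pops[match(gmeta$population,
                                   sprintf("pop%d", seq_along(pops)))]
    gmeta$species <- sp
    gmeta$host_category <- sim$hosts[[sp]]
    gmeta$sample <- sprintf("%s_%s", sp, gmeta$sample)
    G <- GenotypeMatrix(genotypes(gen$G),
                        chrom = as.character(
                          GenomicRanges::seqnames(rowRanges(gen$G))),
                        pos = GenomicRanges::start(rowRanges(gen$G)),
                        samples = gmeta$sample,
                        population = gmeta$population)
    writeVCF(G, file.path(outdir, "vcf", paste0(sp, ".vcf")))
    samples[[sp]] <- gmeta
    np <- length(pops)
    k <- 0
    for (i in seq_len(np - 1)) for (j in (i + 1):np) {
      k <- k + 1
      ts <- .with_seed(spSeed + k,
                       10^stats::runif(1, log10(3e4), log10(5e5)))
      ccs <- simCrossCoal(ts, N = cfg$scenario$base_ne,
                          shape = "logistic",
                          constants = constants,
                          nSegments = cfg$split$n_segments,
                          maxAge = cfg$scenario$max_age)
      writeCrossCoal(ccs, file.path(outdir, "crosscoal",
                                    sprintf("%s__%s__%s.tsv", sp, pops[i],
                                            pops[j])))
      truth[[length(truth) + 1L]] <- data.frame(
        species = sp, pop1 = pops[i], pop2 = pops[j], true_split_years = ts)
    }
  }
  .write_stamped(do.call(rbind, samples),
                 file.path(outdir, "samples.csv"), cfg)
  .write_stamped(do.call(rbind, truth),
                 file.path(outdir, "sim_truth_splits.csv"), cfg)
  .msg(log, "[simulate] %d trajectories, %d species, seed %d",
       length(sim$trajectories), length(species), cfg$seed)
  file.path(outdir, c("sea_level.csv", "trajectory_meta.csv",
                      "samples.csv", "sim_truth_splits.csv"))
}

.stage_harmonize <- function(cfg, outdir, constants, log) {
  td <- .load_trajectories(outdir, constants)
  ens <- buildEnsemble(td$trajs, td$hosts, maxTime = cfg$scenario$max_age)
  sea <- readSeaLevel(file.path(outdir, "sea_level.csv"))
  aligned <- alignCovariate(sea, gridTimes(ens))
  p <- file.path(outdir, "ensemble.csv")
  .ensemble_to_csv(ens, p, cfg, sea = aligned)
  .msg(log, "[harmonize] grid 100 points, %d trajectories, %.1f%% coverage",
       ncol(ens), 100 * mean(!is.na(neValues(ens))))
  p
}

.stage_qc <- function(cfg, outdir, log) {
  ens <- .ensemble_from_csv(file.path(outdir, "ensemble.csv"))
  ex <- cfg$qc$exclusions
  if (length(ex))
    ens <- excludeReplicates(ens, do.call(rbind, lapply(ex, as.data.frame)))
  eps <- .cfg_epochs(cfg)
  removed <- list()
  for (en in cfg$qc$outlier_epochs) {
    fo <- flagOutlierReplicates(ens, eps[[en]], q = cfg$qc$replicate_q,
                                byPopulation = isTRUE(cfg$qc$by_population))
    ens <- fo$ensemble
    if (nrow(fo$report)) {
      fo$report$epoch <- en
      removed[[en]] <- fo$report
    }
  }
  tr <- trimExtremeValues(ens, q = cfg$qc$edge_q)
  ens <- tr$ensemble
  rem <- if (length(removed)) do.call(rbind, removed) else
    data.frame(species = character(), population = character(),
               replicate = character(), trigger = numeric(),
               threshold = numeric(), epoch = character())
  .write_stamped(rem, file.path(outdir, "qc_removed_replicates.csv"), cfg)
  .write_stamped(tr$report, file.path(outdir, "qc_masked_points.csv"), cfg)
  sea <- readSeaLevel(file.path(outdir, "sea_level.csv"))
  p <- file.path(outdir, "ensemble_qc.csv")
  .ensemble_to_csv(ens, p, cfg, sea = alignCovariate(sea, gridTimes(ens)))
  .msg(log, "[qc] removed %d replicates, masked %d values",
       nrow(rem), nrow(tr$report))
  p
}

.stage_split <- function(cfg, outdir, log) {
  files <- list.files(file.path(outdir, "crosscoal"), full.names = TRUE)
  if (!length(files))
    stop("missing dependency: '", file.path(outdir, "crosscoal"),
         "' is empty (run the simulate stage first)")
  rows <- lapply(files, function(f) {
    parts <- strsplit(sub("\\.tsv$", "", basename(f)), "__")[[1]]
    est <- estimateSplit(rccr(readCrossCoal(f)),
                         threshold = cfg$split$threshold)
    data.frame(species = parts[1], pop1 = parts[2], pop2 = parts[3],
               split_years = est$split_years, flag = est$flag)
  })
  df <- do.call(rbind, rows)
  p <- file.path(outdir, "split_times.csv")
  .write_stamped(df, p, cfg)
  .msg(log, "[split] %d pairs, %d resolved", nrow(df),
       sum(df$flag == "ok"))
  p
}

.stage_summarize <- function(cfg, outdir, constants, log) {
  ens <- .ensemble_from_csv(file.path(outdir, "ensemble_qc.csv"))
  eps <- .cfg_epochs(cfg)
  info <- trajInfo(ens)
  ## harmonic means from the original (unmasked-segment) trajectories of
  ## the replicates that survived QC
  td <- .load_trajectories(outdir, constants)
  keep <- paste(td$meta$species, td$meta$population, td$meta$replicate) %in%
    paste(info$species, info$population, info$replicate)
  hm <- epochHarmonicMeans(td$trajs[keep], eps, hosts = td$hosts)
  .write_stamped(hm, file.path(outdir, "harmonic_means.csv"), cfg)
  ## population-level values (mean over replicates) for the rank tests
  agg <- stats::aggregate(harmonic_Ne ~ species + population + epoch +
                            host_category, data = hm, FUN = mean)
  tests <- epochRankTests(agg)
  .write_stamped(tests, file.path(outdir, "epoch_rank_tests.csv"), cfg)
  .msg(log, "[summarize] %d harmonic means, %d tests", nrow(hm),
       nrow(tests))
  file.path(outdir, c("harmonic_means.csv", "epoch_rank_tests.csv"))
}

.stage_popgen <- function(cfg, outdir, log) {
  samples <- .read_stamped(file.path(outdir, "samples.csv"))
  gcfg <- cfg$genotypes
  pr <- list(); piw <- list()
  for (sp in unique(samples$species)) {
    vp <- file.path(outdir, "vcf", paste0(sp, ".vcf"))
    if (!file.exists(vp))
      stop("missing dependency: '", vp, "' (run the simulate stage first)")
    sm <- samples[samples$species == sp, ]
    G <- readGenotypeVCF(vp, stats::setNames(sm$population, sm$sample))
    G <- mafFilter(G, gcfg$maf)
    pr[[sp]] <- pairwiseStats(G, sm, windowSize = gcfg$dxy_window)
    for (pop in unique(sm$population)) {
      pi <- populationPi(G, pop)
      w <- windowAverage(pi$chrom, pi$pos, pi$pi, gcfg$pi_window,
                         chromLength = c(chr1 = gcfg$chrom_length))
      w$species <- sp; w$population <- pop
      piw[[paste(sp, pop)]] <- w
    }
  }
  pairw <- do.call(rbind, pr); rownames(pairw) <- NULL
  .write_stamped(pairw, file.path(outdir, "pairwise_stats.csv"), cfg)
  .write_stamped(do.call(rbind, piw), file.path(outdir, "pi_windows.csv"),
                 cfg)
  .msg(log, "[popgen] %d population pairs, %d pi windows", nrow(pairw),
       nrow(do.call(rbind, piw)))
  file.path(outdir, c("pairwise_stats.csv", "pi_windows.csv"))
}

.stage_model <- function(cfg, outdir, log) {
  ens <- .ensemble_from_csv(file.path(outdir, "ensemble_qc.csv"))
  sea <- readSeaLevel(file.path(outdir, "sea_level.csv"))
  tab <- buildModelTable(ens, alignCovariate(sea, gridTimes(ens)))
  fit <- fitNeGLMM(tab, backend = cfg$model$backend,
                   formulaMode = cfg$model$formula_mode)
  co <- fit$coefficients
  co$backend <- fit$backend; co$converged <- fit$converged
  .write_stamped(co, file.path(outdir, "model_coefficients.csv"), cfg)
  fan <- functionalAnova(ens, B = cfg$model$fanova_B, seed = cfg$seed)
  .write_stamped(data.frame(statistic = fan$statistic,
                            p_value = fan$p_value, B = fan$B,
                            seed = fan$seed),
                 file.path(outdir, "fanova.csv"), cfg)
  .msg(log, "[model] backend %s (converged: %s); FANOVA F=%.2f p=%.4g",
       fit$backend, fit$converged, fan$statistic, fan$p_value)
  file.path(outdir, c("model_coefficients.csv", "fanova.csv"))
}

.stage_adjust <- function(cfg, outdir, log) {
  pairw <- .read_stamped(file.path(outdir, "pairwise_stats.csv"))
  splits <- .read_stamped(file.path(outdir, "split_times.csv"))
  tab <- merge(pairw, splits[, c("species", "pop1", "pop2", "split_years")],
               by = c("species", "pop1", "pop2"))
  names(tab)[names(tab) == "split_years"] <- "split_time_years"
  out <- list()
  for (v in c("fst", "dxy")) {
    adj <- adjustPairwise(tab, value = v)
    a <- adj$table
    a$statistic <- v
    out[[v]] <- a[, c("statistic", "species", "pop1", "pop2", v,
                      "distance_km", "split_time_years", "host_category",
                      "adjusted")]
    names(out[[v]])[5] <- "observed"
  }
  df <- do.call(rbind, out); rownames(df) <- NULL
  p <- file.path(outdir, "adjusted_stats.csv")
  .write_stamped(df, p, cfg)
  .msg(log, "[adjust] %d pair rows adjusted for distance and split time",
       nrow(df))
  p
}
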