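## Synthetic inputs with known parameters: a sea-level curve, piecewise Ne
## trajectories whose log-Ne responds linearly to standardized sea level
## with host-category-specific coefficients, cross-coalescence series with a
## known split time, and Balding-Nichols genotypes with a known FST.  Every
## generator is a pure function of (configuration, seed).

## evaluate expr under a local RNG seeded with `seed`, restoring global state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Simulate a glacial-cycle sea-level curve
#'
#' Stand-in for the late Quaternary eustatic curve: ~100 ky and ~41 ky
#' orbital sinusoids phased so that lowstands fall at the known glacial
#' maxima (most recently ~20 kya), plus seeded smooth low-frequency
#' undulation and a small phase jitter.  The curve is anchored near
#' present-day level at age 0 and clamped to [-140, +10] m, so every
#' realization carries the defining feature the epoch comparisons rely on:
#' a deep lowstand around the last glacial maximum followed by the
#' post-glacial rise.  Deterministic per seed.
#'
#' @param maxAge oldest age in years BP.
#' @param step sampling step in years.
#' @param seed integer seed.
#' @return data.frame with columns \code{age}, \code{level}
#'   (\code{maxAge/step + 1} rows).
#' @export
simSeaLevel <- function(maxAge = 1e6, step = 1000, seed = 1) {
  stopifnot(maxAge >= step, step > 0)
  .with_seed(seed, {
    age <- seq(0, maxAge, by = step)
    jit <- stats::runif(1, -3000, 3000)     # chronology jitter, years
    lgm <- 20000 + jit                       # last glacial maximum
    raw <- -55 * cos(2 * pi * (age - lgm) / 1e5) -
           25 * cos(2 * pi * (age - lgm) / 41000)
    ## smooth seeded undulation, periods 150-900 ky; its combined sd (~5 m)
    ## reflects the spread among eustatic reconstructions and stays well
    ## below the glacial-interglacial signal
    for (k in 1:6) {
      raw <- raw + stats::rnorm(1, 0, 2) *
        cos(2 * pi * age / stats::runif(1, 1.5e5, 9e5) +
            stats::runif(1, 0, 2 * pi))
    }
    lvl <- raw - raw[1] + stats::runif(1, -3, 3)
    data.frame(age = age, level = pmin(10, pmax(-140, lvl)))
  })
}

#' Scenario configuration for trajectory simulation
#'
#' @param nSpeciesPerHost named integer vector: species count per host
#'   category.
#' @param popsPerSpecies populations per species.
#' @param nBootstraps bootstrap replicates per population (besides "main");
#'   default 50.
#' @param baseNe baseline effective size in individuals; a scalar, or a
#'   named vector with one entry per host category.
#' @param gamma named numeric vector: per-host-category response of log-Ne
#'   to standardized sea level.
#' @param noiseSd replicate-level lognormal noise sd (on log Ne).
#' @param arCoef AR(1) correlation of the noise across adjacent segments,
#'   in [0, 1).
#' @param nSegments piecewise-constant segments per trajectory, log-spaced
#'   over [100, maxAge]; default 20.
#' @param maxAge oldest segment boundary in years BP.
#' @param contamFrac fraction of bootstrap replicates with uniformly
#'   inflated Ne (exercises the outlier filter); default 0.
#' @param contamFactor Ne multiplier for contaminated replicates.
#' @param seed integer seed.
#' @return validated list of class "ScenarioConfig".
#' @export
scenarioConfig <- function(nSpeciesPerHost = c(generalist = 3, RM = 1,
                                               EQ = 1, SD = 1),
                           popsPerSpecies = 2, nBootstraps = 50,
                           baseNe = 1e5,
                           gamma = c(generalist = 0, RM = 0.5,
                                     EQ = 0.5, SD = 0.5),
                           noiseSd = 0.2, arCoef = 0.6, nSegments = 20,
                           maxAge = 1e6, contamFrac = 0, contamFactor = 10,
                           seed = 1) {
  stopifnot(all(nSpeciesPerHost >= 1), popsPerSpecies >= 1, nBootstraps >= 0,
            all(baseNe > 0),
            is.null(names(baseNe)) ||
              all(names(nSpeciesPerHost) %in% names(baseNe)),
            noiseSd >= 0, arCoef >= 0, arCoef < 1,
            nSegments >= 2, maxAge > 100, contamFrac >= 0, contamFrac <= 1,
            contamFactor > 0,
            all(names(nSpeciesPerHost) %in% names(gamma)))
  structure(list(nSpeciesPerHost = nSpeciesPerHost,
                 popsPerSpecies = popsPerSpecies, nBootstraps = nBootstraps,
                 baseNe = baseNe, gamma = gamma, noiseSd = noiseSd,
                 arCoef = arCoef, nSegments = nSegments, maxAge = maxAge,
                 contamFrac = contamFrac, contamFactor = contamFactor,
                 seed = seed),
            class = "ScenarioConfig")
}

#' Simulate Ne trajectories responding to sea level
#'
#' For each population, segment boundaries are log-spaced over
#' [100, maxAge]; per segment,
#' \code{log Ne = log(baseNe) + gamma[host] * z(sea at midpoint) + e},
#' where \code{z} standardizes the sea level over the segment midpoints and
#' \code{e} is an AR(1) Gaussian process across segments with marginal sd
#' \code{noiseSd}, drawn independently per replicate ("main" plus
#' \code{nBootstraps} bootstraps; bootstraps share the main run's segment
#' boundaries).  Each trajectory is also emitted in SMC scaled units via the
#' exact inverse of \code{\link{scaleToReal}} so the full pipeline can run
#' from files.
#'
#' @param cfg a \code{\link{scenarioConfig}}.
#' @param sea sea-level data.frame (\code{age}, \code{level}) spanning
#'   [0, maxAge].
#' @param constants \code{\link{scalingConstants}} used for the scaled-unit
#'   export.
#' @return list with \code{trajectories} (list of
#'   \linkS4class{NeTrajectory}), \code{scaled} (matching list of
#'   \linkS4class{ScaledRateSeries}), \code{meta} (data.frame species,
#'   population, replicate, host_category), \code{hosts} (named species ->
#'   host map) and \code{config}.
#' @export
simTrajectories <- function(cfg, sea, constants = scalingConstants()) {
  stopifnot(inherits(cfg, "ScenarioConfig"))
  bounds <- 10^seq(log10(100), log10(cfg$maxAge), length.out = cfg$nSegments + 1)
  tmid <- (bounds[-1] + bounds[-length(bounds)]) / 2
  z <- standardize(stats::approx(sea$age, sea$level, xout = tmid,
                                 rule = 2)$y)
  .with_seed(cfg$seed, {
    trajs <- list(); meta <- list(); hosts <- character()
    spIdx <- 0
    for (host in names(cfg$nSpeciesPerHost)) {
      for (s in seq_len(cfg$nSpeciesPerHost[[host]])) {
        spIdx <- spIdx + 1
        sp <- sprintf("sp%02d_%s", spIdx, host)
        hosts[sp] <- host
        for (p in seq_len(cfg$popsPerSpecies)) {
          pop <- sprintf("%s_pop%d", sp, p)
          reps <- c("main", if (cfg$nBootstraps > 0)
            sprintf("boot%02d", seq_len(cfg$nBootstraps)))
          contam <- stats::runif(length(reps)) < cfg$contamFrac
          contam[1] <- FALSE            # never contaminate the main run
          for (k in seq_along(reps)) {
            e <- numeric(cfg$nSegments)
            innov_sd <- cfg$noiseSd * sqrt(1 - cfg$arCoef^2)
            e[1] <- stats::rnorm(1, 0, cfg$noiseSd)
            for (i in seq_len(cfg$nSegments - 1))
              e[i + 1] <- cfg$arCoef * e[i] + stats::rnorm(1, 0, innov_sd)
            base <- if (is.null(names(cfg$baseNe))) cfg$baseNe
                    else cfg$baseNe[[host]]
            ne <- exp(log(base) + cfg$gamma[[host]] * z + e)
            if (contam[k]) ne <- ne * cfg$contamFactor
            trajs[[length(trajs) + 1L]] <- NeTrajectory(
              species = sp, population = pop, replicate = reps[k],
              segments = data.frame(t_left = bounds[-length(bounds)],
                                    t_right = bounds[-1], Ne = ne))
            meta[[length(meta) + 1L]] <- data.frame(
              species = sp, population = pop, replicate = reps[k],
              host_category = host, contaminated = contam[k])
          }
        }
      }
    }
    list(trajectories = trajs,
         scaled = lapply(trajs, realToScaled, constants = constants),
         meta = do.call(rbind, meta), hosts = hosts, config = cfg)
  })
}

#' Simulate a cross-coalescence series with known split time
#'
#' Within-population rates are constant at \code{1/(2*mu*N)} (scaled
#' units); the cross rate rises from 0 (recent) to the within rate
#' (ancient) either as a step at \code{tSplit} or as a logistic centred on
#' it, so the relative cross-coalescence rate equals 0.5 exactly at
#' \code{tSplit} for the logistic shape.  Times are years BP.
#'
#' @param tSplit split time in years BP; must lie inside the series' span.
#' @param N within-population effective size in individuals.
#' @param shape \code{"logistic"} (default) or \code{"step"}.
#' @param logisticScale logistic width in years.
#' @param constants \code{\link{scalingConstants}}.
#' @param nSegments number of time segments.
#' @param minAge,maxAge series span in years BP (log-spaced boundaries).
#' @return A \linkS4class{CrossCoalSeries}.
#' @export
simCrossCoal <- function(tSplit, N = 1e4, shape = c("logistic", "step"),
                         logisticScale = 5000,
                         constants = scalingConstants(), nSegments = 40,
                         minAge = 100, maxAge = 1e6) {
  shape <- match.arg(shape)
  if (tSplit <= minAge || tSplit >= maxAge)
    stop("tSplit must lie inside the series' time span")
  bounds <- 10^seq(log10(minAge), log10(maxAge), length.out = nSegments + 1)
  tmid <- (bounds[-1] + bounds[-length(bounds)]) / 2
  within <- 1 / (2 * constants$mu * N)
  s <- switch(shape,
              step = as.numeric(tmid >= tSplit),
              logistic = 1 / (1 + exp(-(tmid - tSplit) / logisticScale)))
  CrossCoalSeries(data.frame(
    t_left = bounds[-length(bounds)], t_right = bounds[-1],
    lambda_00 = within, lambda_01 = within * s, lambda_11 = within))
}

#' Simulate Balding-Nichols genotypes with known FST
#'
#' Per site, an ancestral frequency \code{p ~ U(0.05, 0.95)}; each
#' population's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) with
#' \code{F = fst}; diploid genotypes are Binomial(2, population frequency).
#' Positions are a sorted uniform draw over the chromosome.  Deterministic
#' per seed.
#'
#' @param nPops number of populations.
#' @param nDiploids diploid individuals per population.
#' @param nSites number of biallelic sites.
#' @param fst Wright's F between 0 and 1 (exclusive).
#' @param chromLength chromosome length in bp.
#' @param seed integer seed.
#' @param vcfPath optional path; when given, a minimal VCF 4.2 is written.
#' @param metaPath optional path for the sample metadata CSV.
#' @return list with \code{G} (a \linkS4class{GenotypeMatrix}), \code{meta}
#'   (sample metadata data.frame) and \code{popFreq} (sites x pops matrix of
#'   realized population allele frequencies).
#' @export
simGenotypes <- function(nPops = 2, nDiploids = 25, nSites = 5000,
                         fst = 0.1, chromLength = 1e6, seed = 1,
                         vcfPath = NULL, metaPath = NULL) {
  stopifnot(fst > 0, fst < 1, nSites >= 1, nPops >= 1, nDiploids >= 1,
            chromLength >= nSites)
  .with_seed(seed, {
    pos <- sort(sample.int(chromLength, nSites))
    p <- stats::runif(nSites, 0.05, 0.95)
    a <- p * (1 - fst) / fst
    b <- (1 - p) * (1 - fst) / fst
    popFreq <- vapply(seq_len(nPops),
                      function(k) stats::rbeta(nSites, a, b),
                      numeric(nSites))
    gt <- matrix(NA_integer_, nSites, nPops * nDiploids)
    pops <- character(nPops * nDiploids)
    for (k in seq_len(nPops)) {
      cols <- (k - 1) * nDiploids + seq_len(nDiploids)
      gt[, cols] <- stats::rbinom(nSites * nDiploids, 2, popFreq[, k])
      pops[cols] <- sprintf("pop%d", k)
    }
    samples <- sprintf("%s_ind%02d", pops,
                       rep(seq_len(nDiploids), times = nPops))
    colnames(gt) <- samples
    G <- GenotypeMatrix(gt, chrom = "chr1", pos = pos, samples = samples,
                        population = pops)
    lat <- stats::runif(nPops, -25, 25)
    lon <- stats::runif(nPops, 90, 170)
    meta <- data.frame(sample = samples, species = "simsp",
                       population = pops,
                       latitude = rep(lat, each = nDiploids),
                       longitude = rep(lon, each = nDiploids),
                       host_category = "generalist")
    if (!is.null(vcfPath)) writeVCF(G, vcfPath)
    if (!is.null(metaPath)) utils::write.csv(meta, metaPath,
                                             row.names = FALSE)
    list(G = G, meta = meta, popFreq = popFreq)
  })
}

#' Write a minimal VCF 4.2 for a genotype matrix
#'
#' Biallelic SNPs (REF A, ALT T), GT-only FORMAT, unphased genotypes,
#' missing as "./.".
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVCF <- function(G, path) {
  stopifnot(is(G, "GenotypeMatrix"))
  gt <- genotypes(G)
  chrom <- as.character(GenomicRanges::seqnames(rowRanges(G)))
  pos <- GenomicRanges::start(rowRanges(G))
  code <- c("0/0", "0/1", "1/1")
  gs <- matrix("./.", nrow(gt), ncol(gt))
  ok <- !is.na(gt)
  gs[ok] <- code[gt[ok] + 1L]
  body <- paste(chrom, pos, ".", "A", "T", ".", "PASS", ".", "GT",
                apply(gs, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", unique(chrom)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}
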