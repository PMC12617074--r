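# Shared fixtures, built in code.

# two-segment series with lambda chosen so Ne = 1000 under mu = 4e-8
fix_series <- function() {
  ScaledRateSeries(data.frame(
    time_index = 0:1,
    left_time_boundary = c(0, 4e-6),
    right_time_boundary = c(4e-6, 8e-6),
    lambda = c(12500, 12500)))
}

# the worked harmonic-mean trajectory: Ne 100 on [0,100), 300 on [100,400)
fix_traj_h <- function() {
  NeTrajectory("sp", "pop", data.frame(
    t_left = c(0, 100), t_right = c(100, 400), Ne = c(100, 300)))
}

# small ensemble built directly from a value matrix
fix_ensemble <- function(ne, time = NULL, species = NULL, pop = NULL,
                         rep = NULL, host = NULL) {
  n <- ncol(ne)
  if (is.null(time)) time <- seq_len(nrow(ne))
  info <- data.frame(
    species = if (is.null(species)) rep("sp1", n) else species,
    population = if (is.null(pop)) rep("p1", n) else pop,
    replicate = if (is.null(rep)) paste0("r", seq_len(n)) else rep,
    host_category = if (is.null(host)) rep("generalist", n) else host)
  TrajectoryEnsemble(ne, time, info)
}

# the shared sea-level curve used by simulation-heavy tests
fix_sea <- function() simSeaLevel(maxAge = 1e6, step = 1000, seed = 42)

# small planted-effect cohort: two host groups, gamma gG vs gS
fix_cohort <- function(seed, gG = 0, gS = 0.5, nSpecies = 3, pops = 1,
                       boots = 10, noiseSd = 0.2, sea = fix_sea(), ...) {
  cfg <- scenarioConfig(
    nSpeciesPerHost = c(generalist = nSpecies, SD = nSpecies),
    gamma = c(generalist = gG, SD = gS), popsPerSpecies = pops,
    nBootstraps = boots, noiseSd = noiseSd, seed = seed, ...)
  simTrajectories(cfg, sea)
}

# synthetic pairwise table with a planted distance slope
fix_pairs <- function(seed, slope = 0.05, noise = 0.01) {
  set.seed(seed)
  rows <- list()
  for (sp in 1:6) for (i in 1:2) for (j in (i + 1):3) {
    rows[[length(rows) + 1]] <- data.frame(
      species = paste0("s", sp),
      pop1 = sprintf("s%d_p%d", sp, i), pop2 = sprintf("s%d_p%d", sp, j),
      distance_km = runif(1, 100, 5000),
      split_time_years = runif(1, 1e4, 5e5),
      host_category = ifelse(sp <= 3, "generalist", "SD"))
  }
  tab <- do.call(rbind, rows)
  dz <- as.vector(scale(tab$distance_km))
  tab$fst <- 0.1 + slope * dz + rnorm(nrow(tab), 0, noise)
  tab
}
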