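test_that("replicate filter matches the pooled-quantile fixture exactly", {
  # 10 replicates x 5 in-epoch points: 49 values of 1000, one of 1e6
  ne <- matrix(1000, nrow = 5, ncol = 10)
  ne[3, 7] <- 1e6
  ens <- fix_ensemble(ne, time = seq(100, 500, by = 100))
  fo <- flagOutlierReplicates(ens, epoch("e", 100, 500), q = 0.975)
  expect_equal(nrow(fo$report), 1)
  expect_equal(fo$report$replicate, "r7")
  expect_equal(fo$report$threshold, 1000)   # h = 49 * 0.975 between two 1000s
  expect_equal(fo$report$trigger, 1e6)
  expect_equal(ncol(fo$ensemble), 9)
})

test_that("replicate filter uses strict exceedance and respects q = 1", {
  ne <- matrix(500, nrow = 4, ncol = 6)
  ens <- fix_ensemble(ne, time = 1:4)
  fo <- flagOutlierReplicates(ens, epoch("e", 1, 4))
  expect_equal(nrow(fo$report), 0)          # all equal: threshold == values
  ne[1, 2] <- 1e9
  ens2 <- fix_ensemble(ne, time = 1:4)
  fo2 <- flagOutlierReplicates(ens2, epoch("e", 1, 4), q = 1)
  expect_equal(nrow(fo2$report), 0)         # the maximum is never exceeded
})

test_that("edge-value filter matches the order-statistic fixture", {
  v <- c(1e4, 1e4, 1.2e4, 5e6, 8e6)
  expect_equal(quantileThreshold(v, 0.95), 7.4e6)  # 5e6 + 0.8 * 3e6
  ne <- cbind(v, v)                          # >= 2 columns for an ensemble
  ens <- fix_ensemble(ne, time = 1:5)
  tr <- trimExtremeValues(ens, q = 0.95)
  expect_equal(nrow(tr$report), 2)           # the 8e6 in each column
  expect_true(all(tr$report$Ne == 8e6))
  expect_equal(tr$report$threshold, rep(7.4e6, 2))
  expect_equal(sum(is.na(neValues(tr$ensemble))), 2)
})

test_that("edge-value filter masks nothing on constant trajectories and is
           bounded on monotone ones", {
  ens <- fix_ensemble(matrix(3, 10, 2), time = 1:10)
  expect_equal(nrow(trimExtremeValues(ens)$report), 0)
  # monotone decreasing: at most ceiling(0.05 * n) points masked
  set.seed(31)
  v <- sort(exp(rnorm(40, 10, 1)), decreasing = TRUE)
  ens2 <- fix_ensemble(cbind(v, rev(v)), time = 1:40)
  tr <- trimExtremeValues(ens2, q = 0.95)
  perCol <- table(factor(tr$report$replicate, levels = c("r1", "r2")))
  expect_true(all(perCol <= ceiling(0.05 * 40)))
})

test_that("filters are invariant to replicate enumeration order and
           monotone in q", {
  sim <- fix_cohort(6, nSpecies = 1, boots = 8, noiseSd = 0.3)
  ens <- buildEnsemble(sim$trajectories, sim$hosts)
  ep <- epoch("f", 150000, 350000)
  set.seed(17)
  perm <- sample(ncol(ens))
  fo1 <- flagOutlierReplicates(ens, ep)
  fo2 <- flagOutlierReplicates(ens[, perm], ep)
  key <- function(r) sort(paste(r$population, r$replicate))
  expect_equal(key(fo1$report), key(fo2$report))
  removals <- vapply(c(0.8, 0.9, 0.95, 0.975, 1),
                     function(q) nrow(flagOutlierReplicates(ens, ep,
                                                            q = q)$report),
                     0)
  expect_true(all(diff(removals) <= 0))
})

test_that("pooled-quantile removals respect the exceedance budget and a
           spiked replicate is always caught", {
  ep <- epoch("f", 150000, 350000)
  for (seed in 1:10) {
    sim <- fix_cohort(seed, nSpecies = 1, pops = 2, boots = 10,
                      noiseSd = 0.1)
    # inflate one bootstrap of the first population tenfold
    idx <- which(sim$meta$population == sim$meta$population[1] &
                 sim$meta$replicate == "boot03")
    sg <- neSegments(sim$trajectories[[idx]])
    sg$Ne <- sg$Ne * 10
    sim$trajectories[[idx]] <- NeTrajectory(
      sim$meta$species[idx], sim$meta$population[idx], sg, "boot03")
    ens <- buildEnsemble(sim$trajectories, sim$hosts)
    fo <- flagOutlierReplicates(ens, ep)
    hit <- fo$report$replicate == "boot03" &
      fo$report$population == sim$meta$population[idx]
    expect_true(any(hit))
    # every removed replicate needs >= 1 exceedance; exceedances are capped
    tm <- gridTimes(ens)
    npool <- sum(tm >= ep$t_start & tm <= ep$t_end) * ncol(ens)
    expect_lte(nrow(fo$report), floor(0.025 * npool) + 1)
  }
})

test_that("curated exclusions drop whole populations or single replicates", {
  sim <- fix_cohort(2, nSpecies = 1, pops = 2, boots = 3)
  ens <- buildEnsemble(sim$trajectories, sim$hosts)
  sp <- sim$meta$species[1]
  p1 <- unique(sim$meta$population)[1]
  ex <- data.frame(species = sp, population = p1, replicate = "*")
  e2 <- excludeReplicates(ens, ex)
  expect_false(p1 %in% trajInfo(e2)$population)
  ex2 <- data.frame(species = sp,
                    population = unique(sim$meta$population)[2],
                    replicate = "boot01")
  expect_equal(ncol(excludeReplicates(ens, ex2)), ncol(ens) - 1)
})
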