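test_that("midpoints are segment centres and infinite segments are dropped", {
  tr <- NeTrajectory("s", "p", data.frame(
    t_left = c(0, 100, 400), t_right = c(100, 400, Inf),
    Ne = c(100, 300, 900)))
  m <- midpointTimes(tr)
  expect_equal(m$t_mid, c(50, 250))
  expect_equal(m$Ne, c(100, 300))
  allinf <- NeTrajectory("s", "p",
                         data.frame(t_left = 0, t_right = Inf, Ne = 10))
  expect_error(midpointTimes(allinf), "finite")
})

test_that("common grid follows the 100-point log-spacing rule", {
  g <- buildCommonGrid(9.6e5)       # rounds up to 1e6
  expect_length(g, 100)
  expect_equal(g[1], 1)
  expect_equal(g[100], 1e6)
  expect_equal(g[34], 100)          # exponent 6 * 33/99 = 2
  expect_equal(sd(diff(log(g))), 0, tolerance = 1e-12)  # constant ratio
  # round-half-up with a floor of one million
  expect_equal(max(buildCommonGrid(1.5e6)), 2e6)
  expect_equal(max(buildCommonGrid(1.49e6)), 1e6)
  expect_equal(max(buildCommonGrid(2)), 1e6)
  # idempotent: rebuilding from the grid maximum returns the same grid
  expect_equal(buildCommonGrid(g[100]), g)
})

test_that("interpolation is exact on affine Ne(t) and NA outside coverage", {
  g <- buildCommonGrid(1e6)
  mid <- data.frame(t_mid = c(100, 300), Ne = c(100, 300))
  v <- interpolateToGrid(mid, c(50, 200, 350))
  expect_equal(v, c(NA, 200, NA))
  # affine function reproduced exactly at every covered grid point
  mid2 <- data.frame(t_mid = c(10, 1e5), Ne = 500 + 0.01 * c(10, 1e5))
  v2 <- interpolateToGrid(mid2, g)
  cov <- g >= 10 & g <= 1e5
  expect_equal(v2[cov], 500 + 0.01 * g[cov])
  expect_true(all(is.na(v2[!cov])))
  # constant trajectories interpolate to the constant
  v3 <- interpolateToGrid(data.frame(t_mid = c(10, 100, 1000), Ne = 7), g)
  expect_true(all(v3[!is.na(v3)] == 7))
  expect_error(interpolateToGrid(data.frame(t_mid = 1, Ne = 2), g), ">= 2")
})

test_that("weighted harmonic mean matches the worked examples", {
  tr <- fix_traj_h()
  expect_equal(weightedHarmonicNe(tr, epoch("a", 0, 400)), 200)
  expect_equal(weightedHarmonicNe(tr, epoch("b", 50, 200)), 180)
  # constant Ne: harmonic mean is the constant
  cst <- NeTrajectory("s", "p", data.frame(
    t_left = c(0, 10), t_right = c(10, 50), Ne = 42))
  expect_equal(weightedHarmonicNe(cst, epoch("c", 0, 50)), 42)
  # masked segments contribute no weight
  msk <- NeTrajectory("s", "p", data.frame(
    t_left = c(0, 100), t_right = c(100, 400), Ne = c(100, NA)))
  expect_equal(weightedHarmonicNe(msk, epoch("d", 0, 400)), 100)
  expect_error(weightedHarmonicNe(tr, epoch("e", 500, 600)), "overlap")
})

test_that("harmonic mean <= arithmetic mean, equality only when constant", {
  set.seed(7)
  for (i in 1:25) {
    k <- sample(3:8, 1)
    bounds <- cumsum(c(0, sample(50:500, k)))
    ne <- exp(runif(k, log(1e2), log(1e5)))
    tr <- NeTrajectory("s", "p", data.frame(
      t_left = bounds[-(k + 1)], t_right = bounds[-1], Ne = ne))
    ep <- epoch("e", 0, max(bounds))
    H <- weightedHarmonicNe(tr, ep)
    w <- diff(bounds)
    A <- sum(w * ne) / sum(w)
    expect_lt(H, A)
  }
})

test_that("harmonic mean agrees with a 1-year Riemann discretization", {
  set.seed(11)
  for (i in 1:30) {
    k <- sample(3:10, 1)
    bounds <- cumsum(c(0, sample(100:2000, k)))
    ne <- exp(runif(k, log(1e2), log(1e6)))
    tr <- NeTrajectory("s", "p", data.frame(
      t_left = bounds[-(k + 1)], t_right = bounds[-1], Ne = ne))
    e0 <- sample(0:(max(bounds) %/% 2), 1)
    e1 <- sample((e0 + 100):max(bounds), 1)
    ep <- epoch("e", e0, e1)
    H <- weightedHarmonicNe(tr, ep)
    yrs <- e0:(e1 - 1) + 0.5                      # 1-year step midpoints
    ney <- ne[findInterval(yrs, bounds, rightmost.closed = TRUE)]
    brute <- length(yrs) / sum(1 / ney)
    expect_equal(H, brute, tolerance = 1e-3)
  }
})

test_that("grid harmonic mean cross-checks the segment-based one", {
  sim <- fix_cohort(5, boots = 2)
  ens <- buildEnsemble(sim$trajectories, sim$hosts)
  ep <- epoch("f", 150000, 350000)
  gh <- gridHarmonicNe(ens, ep)
  sh <- vapply(sim$trajectories, weightedHarmonicNe, 0, ep = ep)
  expect_equal(unname(gh), sh, tolerance = 0.05)
})

test_that("covariate alignment interpolates and refuses extrapolation", {
  sea <- data.frame(age = c(0, 1000), level = c(0, -100))
  expect_equal(alignCovariate(sea, 500), -50)
  expect_true(is.na(alignCovariate(sea, 2000)))
  expect_equal(alignCovariate(data.frame(age = c(0, 10, 20), level = -3),
                              c(0, 5, 20)), rep(-3, 3))
})

test_that("standardize yields mean-0 sd-1 and propagates NA", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize(c(4, NA, 8, 1, 0))
  expect_true(is.na(z[2]))
  expect_equal(mean(z, na.rm = TRUE), 0)
  expect_equal(sd(z, na.rm = TRUE), 1)
  expect_error(standardize(5), ">= 2")
  expect_error(standardize(c(2, 2, 2)), "zero spread")
})

test_that("ensembles hold trajectories with NA outside coverage", {
  sim <- fix_cohort(3, boots = 1)
  ens <- buildEnsemble(sim$trajectories, sim$hosts)
  expect_s4_class(ens, "TrajectoryEnsemble")
  expect_equal(ncol(ens), length(sim$trajectories))
  g <- gridTimes(ens)
  expect_length(g, 100)
  m1 <- midpointTimes(sim$trajectories[[1]])
  v <- neValues(ens)[, 1]
  expect_true(all(is.na(v[g < min(m1$t_mid) | g > max(m1$t_mid)])))
  expect_true(all(!is.na(v[g >= min(m1$t_mid) & g <= max(m1$t_mid)])))
})
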