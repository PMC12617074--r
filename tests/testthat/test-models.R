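test_that("model table keeps covered grid points and standardizes over them", {
  ne <- matrix(1000, nrow = 10, ncol = 4)
  ne[1:3, 2] <- NA
  ens <- fix_ensemble(ne, time = 1:10,
                      species = rep(c("s1", "s2"), each = 2),
                      pop = rep(c("p1", "p2"), each = 2),
                      rep = rep(c("r1", "r2"), 2),
                      host = rep(c("generalist", "SD"), each = 2))
  sea <- seq(-100, -10, length.out = 10)
  tab <- buildModelTable(ens, sea)
  expect_equal(nrow(tab), 37)                 # 40 cells minus 3 NA
  expect_equal(mean(tab$sea_z), 0, tolerance = 1e-12)
  expect_equal(sd(tab$time_z), 1, tolerance = 1e-12)
  expect_error(buildModelTable(ens, rep(NA_real_, 10)), "empty")
})

test_that("planted sea-level x host interaction is recovered with the
           correct sign by both backends", {
  skip_if_not_installed("glmmTMB")
  sim <- fix_cohort(1, gG = 0, gS = 0.5, boots = 6)
  ens <- buildEnsemble(sim$trajectories, sim$hosts)
  sea <- fix_sea()
  tab <- buildModelTable(ens, alignCovariate(sea, gridTimes(ens)))
  f1 <- fitNeGLMM(tab, backend = "lmm")
  co1 <- f1$coefficients[f1$coefficients$term == "sea_z:host_categorySD", ]
  expect_gt(co1$estimate, 0)
  expect_lt(co1$p, 0.05)
  expect_match(f1$backend, "lmm")            # the report names the backend
  f2 <- fitNeGLMM(tab, backend = "glmm", formulaMode = "literal")
  co2 <- f2$coefficients[f2$coefficients$term == "sea_z:host_categorySD", ]
  expect_match(f2$backend, "Gamma")
  expect_gt(co2$estimate, 0)                 # backends agree on the sign
})

test_that("degenerate responses are flagged, never silently reported", {
  set.seed(2)
  tab <- data.frame(Ne = 1000, sea_z = rnorm(160), time_z = rnorm(160),
                    host_category = rep(c("a", "b"), each = 80),
                    species = rep(c("s1", "s2"), each = 80),
                    population = "p1", replicate = rep(1:4, each = 40))
  f <- fitNeGLMM(tab)
  expect_false(f$converged)
  tab1 <- tab; tab1$host_category <- "a"
  expect_error(fitNeGLMM(tab1), "host categories")
})

test_that("functional ANOVA is seed-reproducible and validates its contract", {
  sim <- fix_cohort(3, gG = 0, gS = 0.5, nSpecies = 2, pops = 2, boots = 1)
  ens <- buildEnsemble(sim$trajectories, sim$hosts)
  a1 <- functionalAnova(ens, B = 99, seed = 7)
  a2 <- functionalAnova(ens, B = 99, seed = 7)
  expect_identical(a1$p_value, a2$p_value)
  expect_identical(a1$statistic, a2$statistic)
  expect_true(all(a1$pointwise$F >= 0, na.rm = TRUE))
  expect_gte(a1$p_value, 1 / 100)
  one <- ens[, trajInfo(ens)$host_category == "SD"]
  expect_error(functionalAnova(one), ">= 2 host groups")
  two <- ens[, c(which(trajInfo(ens)$host_category == "generalist"),
                 which(trajInfo(ens)$host_category == "SD")[1])]
  expect_error(functionalAnova(two), ">= 2 trajectories")
})

test_that("pointwise F is computed only where every group has coverage", {
  ne <- matrix(rnorm(40, 10), nrow = 10, ncol = 4)
  ne[1:4, 3:4] <- NA                   # group SD uncovered on rows 1-4
  ens <- fix_ensemble(exp(ne), time = 1:10,
                      species = c("s1", "s2", "s3", "s4"),
                      host = rep(c("generalist", "SD"), each = 2))
  a <- functionalAnova(ens, B = 19, seed = 1)
  expect_true(all(is.na(a$pointwise$F[1:4])))
  expect_true(all(!is.na(a$pointwise$F[5:10])))
})

test_that("epoch rank tests match exact fixtures and flag sparse cells", {
  hm <- data.frame(
    epoch = rep(c("fluct", "rise"), each = 6),
    harmonic_Ne = c(1, 2, 3, 10, 20, 30, 2, 3, 4, 11, 21, 31),
    host_category = rep(rep(c("g", "s"), each = 3), 2))
  out <- epochRankTests(hm)
  kw <- out[out$test == "kruskal_wallis", ]
  expect_true(all(kw$flag == "ok"))
  # one-sided exact rank-sum: groups (10,20,30) vs (1,2,3) has p = 1/20
  w <- wilcox.test(c(10, 20, 30), c(1, 2, 3), alternative = "greater")
  expect_equal(w$p.value, 0.05)
  # constant values: KW statistic 0
  hm2 <- data.frame(epoch = "e", harmonic_Ne = 5,
                    host_category = rep(c("g", "s"), each = 3))
  kw2 <- epochRankTests(hm2)
  expect_equal(kw2$statistic[kw2$test == "kruskal_wallis"], 0)
  # single-value group rows are flagged, not dropped
  hm3 <- rbind(hm, data.frame(epoch = "fluct", harmonic_Ne = 9,
                              host_category = "lone"))
  out3 <- epochRankTests(hm3)
  expect_true("insufficient_data" %in%
                out3$flag[out3$group == "lone" | out3$test == "wilcoxon"])
})

test_that("null calibration: same-distribution groups rarely reject", {
  set.seed(12)
  rej <- 0
  for (i in 1:60) {
    hm <- data.frame(epoch = "e", harmonic_Ne = rlnorm(12, 10, 0.5),
                     host_category = rep(c("g", "s"), each = 6))
    p <- epochRankTests(hm)$p[1]
    rej <- rej + (p < 0.05)
  }
  expect_lte(rej / 60, 0.12)
})

test_that("pairwise adjustment removes the planted fixed effects only", {
  tab <- fix_pairs(1)
  adj <- adjustPairwise(tab, "fst")
  # the planted distance slope is gone from the adjusted values
  sl <- coef(lm(adjusted ~ distance_z, data = adj$table))[2]
  expect_lt(abs(sl), 0.01)
  # zero fitted betas => adjusted == observed
  a0 <- adj$table
  b <- adj$fit$coefficients
  manual <- tab$fst -
    b$estimate[b$term == "distance_z"] * a0$distance_z -
    b$estimate[b$term == "splittime_z"] * a0$splittime_z
  expect_equal(a0$adjusted, manual)
  # permuting row order leaves adjusted values unchanged
  set.seed(4)
  perm <- sample(nrow(tab))
  adj2 <- adjustPairwise(tab[perm, ], "fst")
  expect_equal(adj2$table$adjusted, adj$table$adjusted[perm],
               tolerance = 1e-8)
})

test_that("pairwise adjustment validates its design matrix and inputs", {
  tab <- fix_pairs(2)
  tab$split_time_years <- tab$distance_km          # perfectly collinear
  expect_error(adjustPairwise(tab, "fst"), "collinear")
  small <- fix_pairs(3)[1:6, ]
  expect_error(adjustPairwise(small, "fst"), ">= 10 pairs")
})
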