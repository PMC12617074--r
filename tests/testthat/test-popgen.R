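# scalar reference implementation of the Weir-Cockerham (1984) per-site
# components for two populations, written independently of wcFst()
ref_wc_site <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n <- c(length(g1), length(g2))
  p <- c(sum(g1) / (2 * n[1]), sum(g2) / (2 * n[2]))
  h <- c(mean(g1 == 1), mean(g2 == 1))
  r <- 2
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = hbar / 2)
}

mk_G <- function(gt, pops, pos = NULL) {
  gt <- as.matrix(gt)
  if (is.null(pos)) pos <- seq_len(nrow(gt)) * 10L
  GenotypeMatrix(gt, "chr1", pos, paste0("i", seq_len(ncol(gt))), pops)
}

test_that("sitePi equals exhaustive pairwise-difference enumeration, n <= 8", {
  for (n in 2:8) for (a in 0:n) {
    hap <- c(rep(1, a), rep(0, n - a))
    pairs <- combn(n, 2)
    brute <- mean(hap[pairs[1, ]] != hap[pairs[2, ]])
    expect_equal(sitePi(a, n - a), brute)
  }
  expect_equal(sitePi(2, 2), 2 / 3)
  expect_equal(sitePi(1, 1), 1)
  expect_equal(sitePi(0, 6), 0)
  expect_true(is.na(sitePi(1, 0)))
})

test_that("MAF filter applies the >= 0.02 boundary and is idempotent", {
  # 50 diploids = 100 chromosomes; 1 alt copy -> MAF 0.01, 2 -> 0.02
  gt <- matrix(0L, nrow = 3, ncol = 50)
  gt[1, 1] <- 1L                    # MAF 0.01: removed
  gt[2, 1] <- 1L; gt[2, 2] <- 1L    # MAF 0.02: kept
  # row 3 monomorphic: removed
  G <- mk_G(gt, rep(c("A", "B"), each = 25))
  f <- mafFilter(G, 0.02)
  expect_equal(nrow(f), 1)
  expect_equal(GenomicRanges::start(SummarizedExperiment::rowRanges(f)), 20)
  f2 <- mafFilter(f, 0.02)
  expect_identical(genotypes(f2), genotypes(f))
})

test_that("window averaging tiles half-open windows from zero", {
  w <- windowAverage("chr1", c(5000, 9999), c(0.2, 0.4), 10000)
  expect_equal(nrow(w), 1)
  expect_equal(w$value, 0.3)
  expect_equal(w$n_sites, 2)
  expect_equal(c(w$start, w$end), c(0, 10000))
  # a site at exactly position 10001 (0-based 10000) opens the second window
  w2 <- windowAverage("chr1", c(5000, 10001), c(0.2, 0.4), 10000)
  expect_equal(w2$value, c(0.2, 0.4))
  # empty windows are NA with 0 sites under the variant-sites denominator
  w3 <- windowAverage("chr1", 25000, 0.5, 10000,
                      chromLength = c(chr1 = 40000))
  expect_equal(w3$n_sites, c(0, 0, 1, 0))
  expect_true(all(is.na(w3$value[c(1, 2, 4)])))
  # length denominator divides by window size instead
  w4 <- windowAverage("chr1", c(5000, 9999), c(0.2, 0.4), 10000,
                      denominator = "length")
  expect_equal(w4$value, 0.6 / 10000)
})

test_that("Weir-Cockerham theta is 1 at fixation and ~0 without
           differentiation", {
  gt <- rbind(c(rep(2L, 10), rep(0L, 10)))
  G <- mk_G(gt, rep(c("A", "B"), each = 10))
  expect_equal(wcFst(G, "A", "B")$theta, 1)
  # identical allele frequencies and heterozygosity in both populations
  block <- c(rep(0L, 15), rep(1L, 20), rep(2L, 15))
  G2 <- mk_G(rbind(c(block, block)), rep(c("A", "B"), each = 50))
  expect_lt(abs(wcFst(G2, "A", "B")$theta), 0.05)
  # pooled-then-split identical populations: theta within 0.01 of 0
  set.seed(3)
  p <- runif(2500, 0.1, 0.9)
  gt3 <- matrix(rbinom(2500 * 40, 2, rep(p, 40)), nrow = 2500)
  G3 <- mk_G(gt3, rep(c("A", "B"), each = 20),
             pos = sort(sample.int(1e6, 2500)))
  expect_lt(abs(wcFst(G3, "A", "B")$theta), 0.01)
})

test_that("wcFst components match an independent scalar reference", {
  set.seed(8)
  gt <- matrix(rbinom(30 * 24, 2, 0.4), nrow = 30)
  gt[sample(length(gt), 40)] <- NA          # scattered missingness
  pops <- rep(c("A", "B"), c(10, 14))       # unequal sizes
  G <- mk_G(gt, pops)
  res <- wcFst(G, "A", "B")
  for (i in seq_len(nrow(gt))) {
    ref <- ref_wc_site(gt[i, pops == "A"], gt[i, pops == "B"])
    if (!is.na(res$per_site$a[i])) {
      expect_equal(res$per_site$a[i], unname(ref["a"]), tolerance = 1e-12)
      expect_equal(res$per_site$b[i], unname(ref["b"]), tolerance = 1e-12)
      expect_equal(res$per_site$c[i], unname(ref["c"]), tolerance = 1e-12)
    }
  }
})

test_that("dxy matches fixtures, is symmetric and bounded", {
  gt <- rbind(c(rep(2L, 4), rep(0L, 4)),     # pA=1, pB=0 -> d=1
              c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),  # 0.5 vs 0.5 -> 0.5
              rep(0L, 8))                    # 0 vs 0 -> 0
  G <- mk_G(gt, rep(c("A", "B"), each = 4))
  d <- dxyWindows(G, "A", "B", windowSize = 1000)
  expect_equal(d$per_site$dxy, c(1, 0.5, 0))
  d2 <- dxyWindows(G, "B", "A", windowSize = 1000)
  expect_equal(d2$per_site$dxy, d$per_site$dxy)
  set.seed(9)
  r <- simGenotypes(nSites = 300, seed = 9)
  dr <- dxyWindows(r$G, "pop1", "pop2")$per_site$dxy
  expect_true(all(dr >= 0 & dr <= 1))
})

test_that("Balding-Nichols genotypes recover the target FST", {
  th <- vapply(1:6, function(s) {
    r <- simGenotypes(nPops = 2, nDiploids = 25, nSites = 2000, fst = 0.1,
                      seed = s)
    wcFst(r$G, "pop1", "pop2")$theta
  }, 0)
  expect_gt(mean(th), 0.08)
  expect_lt(mean(th), 0.12)
})

test_that("great-circle distance matches the closed form and is a metric", {
  expect_equal(greatCircleKm(0, 0, 0, 90), pi * 6371 / 2, tolerance = 1e-6)
  expect_equal(greatCircleKm(12, 44, 12, 44), 0)
  expect_equal(greatCircleKm(-10, 100, 20, 150),
               greatCircleKm(20, 150, -10, 100))
  expect_error(greatCircleKm(95, 0, 0, 0), "range")
})

test_that("VCF writer/reader round-trip genotypes, positions and samples", {
  r <- simGenotypes(nPops = 2, nDiploids = 6, nSites = 80, seed = 5)
  p <- withr::local_tempfile(fileext = ".vcf")
  writeVCF(r$G, p)
  G2 <- readGenotypeVCF(p, setNames(r$meta$population, r$meta$sample))
  expect_identical(unname(genotypes(G2)), unname(genotypes(r$G)))
  expect_equal(GenomicRanges::start(SummarizedExperiment::rowRanges(G2)),
               GenomicRanges::start(SummarizedExperiment::rowRanges(r$G)))
  expect_equal(popAssignment(G2), popAssignment(r$G))
})

test_that("pairwise summary combines fst, dxy and centroid distances", {
  r <- simGenotypes(nPops = 3, nDiploids = 8, nSites = 400, seed = 7)
  ps <- pairwiseStats(r$G, r$meta)
  expect_equal(nrow(ps), 3)
  expect_true(all(ps$distance_km >= 0))
  expect_true(all(is.finite(ps$fst)))
  expect_true(all(ps$dxy > 0 & ps$dxy < 1))
})
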