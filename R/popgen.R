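## Windowed population-genetic statistics from diploid biallelic genotypes:
## per-site nucleotide diversity pi, Weir-Cockerham (1984) FST and absolute
## divergence dxy, with the MAF filter applied upstream of all of them.
## Window coordinates are 0-based half-open [k*w, (k+1)*w); VCF positions
## (1-based) are converted on read.

#' Read biallelic SNP genotypes from a VCF
#'
#' Parses the GT field of a VCF 4.x file (via \pkg{vcfR}), keeps biallelic
#' SNPs only, and attaches population assignments.
#'
#' @param path VCF path (plain or bgzipped).
#' @param popMap named character vector sample -> population, or a
#'   data.frame with columns \code{sample} and \code{population}.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readGenotypeVCF <- function(path, popMap) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  keep <- vcfR::is.biallelic(v)
  v <- v[keep, ]
  gtc <- vcfR::extract.gt(v, element = "GT")
  alt <- matrix(NA_integer_, nrow(gtc), ncol(gtc), dimnames = dimnames(gtc))
  clean <- gsub("|", "/", gtc, fixed = TRUE)
  alt[clean == "0/0"] <- 0L
  alt[clean %in% c("0/1", "1/0")] <- 1L
  alt[clean == "1/1"] <- 2L
  if (is.data.frame(popMap))
    popMap <- stats::setNames(as.character(popMap$population),
                              popMap$sample)
  samples <- colnames(alt)
  miss <- setdiff(samples, names(popMap))
  if (length(miss))
    stop("samples without population assignment: ",
         paste(miss, collapse = ", "))
  fix <- vcfR::getFIX(v)
  GenotypeMatrix(alt, chrom = fix[, "CHROM"],
                 pos = as.integer(fix[, "POS"]),
                 samples = samples, population = popMap[samples])
}

## alt-allele count, chromosome count and heterozygote count per site for a
## set of columns
.site_counts <- function(gt, cols) {
  sub <- gt[, cols, drop = FALSE]
  nonmiss <- rowSums(!is.na(sub))
  list(alt = rowSums(sub, na.rm = TRUE), n_chrom = 2L * nonmiss,
       n_ind = nonmiss, het = rowSums(sub == 1L, na.rm = TRUE))
}

#' Minor-allele-frequency filter
#'
#' Keeps a site iff \code{min(p, 1-p) >= threshold}, with the allele
#' frequency computed from non-missing chromosomes across all individuals.
#' Monomorphic sites (MAF 0) are always removed.  Idempotent.
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param threshold minimum MAF, default 0.02.
#' @return the filtered \linkS4class{GenotypeMatrix}.
#' @export
mafFilter <- function(G, threshold = 0.02) {
  stopifnot(is(G, "GenotypeMatrix"))
  cnt <- .site_counts(genotypes(G), seq_len(ncol(G)))
  p <- ifelse(cnt$n_chrom > 0, cnt$alt / cnt$n_chrom, NA)
  maf <- pmin(p, 1 - p)
  G[!is.na(maf) & maf >= threshold & maf > 0, ]
}

#' Per-site nucleotide diversity
#'
#' For a biallelic site with \code{a} copies of one allele and \code{b} of
#' the other among \code{n = a + b} observed chromosomes,
#' \code{pi = a * b / choose(n, 2)}: the proportion of differing pairs.
#'
#' @param a,b allele counts (vectors allowed).
#' @return per-site pi; NA where fewer than 2 chromosomes were observed.
#' @export
sitePi <- function(a, b) {
  n <- a + b
  ifelse(n >= 2, a * b / choose(n, 2), NA_real_)
}

#' Per-site pi within one population
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param pop population label.
#' @return data.frame with chrom, pos (1-based), pi, n_chrom.
#' @export
populationPi <- function(G, pop) {
  cols <- which(popAssignment(G) == pop)
  if (length(cols) == 0) stop("unknown population: ", pop)
  cnt <- .site_counts(genotypes(G), cols)
  data.frame(chrom = as.character(GenomicRanges::seqnames(rowRanges(G))),
             pos = GenomicRanges::start(rowRanges(G)),
             pi = sitePi(cnt$alt, cnt$n_chrom - cnt$alt),
             n_chrom = cnt$n_chrom)
}

#' Average per-site values over non-overlapping windows
#'
#' Windows tile each chromosome from coordinate 0 in half-open intervals
#' \code{[k*w, (k+1)*w)} on the 0-based scale; a site at 1-based position P
#' occupies 0-based coordinate P-1.  The default window value is the mean
#' over variant sites in the window (matching the averaging of per-site
#' outputs); \code{denominator = "length"} divides the per-site sum by the
#' window length instead.
#'
#' @param chrom,pos,values per-site chromosome, 1-based position, value.
#' @param windowSize window width in bp.
#' @param chromLength optional named vector of chromosome lengths, used to
#'   emit trailing empty windows; otherwise windows run to the last site.
#' @param denominator \code{"sites"} (default) or \code{"length"}.
#' @return data.frame: chrom, start, end (0-based half-open), value,
#'   n_sites.  Empty windows have NA value (sites denominator) or 0.
#' @export
windowAverage <- function(chrom, pos, values, windowSize,
                          chromLength = NULL,
                          denominator = c("sites", "length")) {
  denominator <- match.arg(denominator)
  if (length(chrom) == 1) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos), length(pos) == length(values))
  out <- list()
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    p0 <- pos[sel] - 1L                      # 0-based
    v <- values[sel]
    known <- !is.null(chromLength) && cc %in% names(chromLength)
    maxc <- if (known) chromLength[[cc]] else max(p0) + 1
    nwin <- ceiling(maxc / windowSize)
    win <- floor(p0 / windowSize) + 1L
    ns <- tabulate(win[!is.na(v)], nbins = nwin)
    sums <- rep(0, nwin)
    agg <- tapply(v[!is.na(v)], win[!is.na(v)], sum)
    sums[as.integer(names(agg))] <- agg
    val <- switch(denominator,
                  sites = ifelse(ns > 0, sums / ns, NA_real_),
                  length = sums / windowSize)
    ends <- seq_len(nwin) * windowSize
    if (known) ends <- pmin(ends, ceiling(maxc))  # clip only the last window
    out[[cc]] <- data.frame(chrom = cc,
                            start = (seq_len(nwin) - 1L) * windowSize,
                            end = ends, value = val, n_sites = ns)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Weir-Cockerham FST between two populations
#'
#' Per site, the 1984 variance components for two populations with unequal
#' sample sizes and observed heterozygosity: \code{a} (among populations),
#' \code{b} (among individuals within populations), \code{c} (within
#' individuals).  The genome-wide estimate is the ratio of sums
#' \code{theta = sum(a) / sum(a + b + c)} over used sites; per-site ratios
#' (which can be negative) are also returned.
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param popA,popB population labels.
#' @param minInd minimum non-missing diploids per population per site
#'   (default 2); sites below this, or monomorphic across both populations,
#'   are skipped.
#' @return list with \code{theta} (genome-wide), \code{per_site}
#'   (data.frame chrom, pos, a, b, c, theta) and \code{n_sites} used.
#' @export
wcFst <- function(G, popA, popB, minInd = 2L) {
  stopifnot(is(G, "GenotypeMatrix"))
  gt <- genotypes(G)
  pa <- which(popAssignment(G) == popA)
  pb <- which(popAssignment(G) == popB)
  if (!length(pa) || !length(pb)) stop("unknown population label")
  ca <- .site_counts(gt, pa); cb <- .site_counts(gt, pb)
  n1 <- ca$n_ind; n2 <- cb$n_ind
  use <- n1 >= minInd & n2 >= minInd
  p1 <- ca$alt / (2 * n1); p2 <- cb$alt / (2 * n2)
  h1 <- ca$het / n1; h2 <- cb$het / n2
  poly <- (ca$alt + cb$alt) > 0 & (ca$alt + cb$alt) < (2 * (n1 + n2))
  use <- use & poly
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!use] <- NA; b[!use] <- NA; cc[!use] <- NA
  tot <- a + b + cc
  per_site <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rowRanges(G))),
    pos = GenomicRanges::start(rowRanges(G)),
    a = a, b = b, c = cc,
    theta = ifelse(!is.na(tot) & tot != 0, a / tot, NA_real_))
  theta <- sum(a[use]) / sum(tot[use])
  list(theta = theta, per_site = per_site, n_sites = sum(use))
}

#' Per-site and windowed absolute divergence dxy
#'
#' Per site \code{d = pA*(1-pB) + pB*(1-pA)} from the two populations'
#' allele frequencies; window values are means over variant sites in
#' non-overlapping windows (default 50 kb).
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param popA,popB population labels.
#' @param windowSize window width in bp, default 50000.
#' @param chromLength,denominator passed to \code{\link{windowAverage}}.
#' @return list with \code{per_site} (chrom, pos, dxy) and \code{windows}
#'   (\code{\link{windowAverage}} output).
#' @export
dxyWindows <- function(G, popA, popB, windowSize = 50000,
                       chromLength = NULL, denominator = "sites") {
  gt <- genotypes(G)
  ca <- .site_counts(gt, which(popAssignment(G) == popA))
  cb <- .site_counts(gt, which(popAssignment(G) == popB))
  pA <- ifelse(ca$n_chrom > 0, ca$alt / ca$n_chrom, NA)
  pB <- ifelse(cb$n_chrom > 0, cb$alt / cb$n_chrom, NA)
  d <- pA * (1 - pB) + pB * (1 - pA)
  chrom <- as.character(GenomicRanges::seqnames(rowRanges(G)))
  pos <- GenomicRanges::start(rowRanges(G))
  list(per_site = data.frame(chrom = chrom, pos = pos, dxy = d),
       windows = windowAverage(chrom, pos, d, windowSize,
                               chromLength = chromLength,
                               denominator = denominator))
}

#' Great-circle distance between two coordinates
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance in km.
#' @export
greatCircleKm <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of range (lat in [-90,90], lon in [-180,180])")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Pairwise population summary table
#'
#' For every within-species population pair: genome-wide Weir-Cockerham
#' theta, mean windowed dxy, and great-circle distance between population
#' centroids.  Feeds the covariate-adjustment model once split times and
#' host categories are joined on.
#'
#' @param G a \linkS4class{GenotypeMatrix} (already MAF-filtered).
#' @param meta data.frame with columns sample, species, population,
#'   latitude, longitude, host_category.
#' @param windowSize dxy window in bp.
#' @return data.frame: species, pop1, pop2, fst, dxy, distance_km,
#'   host_category.
#' @export
pairwiseStats <- function(G, meta, windowSize = 50000) {
  meta <- as.data.frame(meta)
  pops <- unique(meta[, c("species", "population", "host_category")])
  cent <- stats::aggregate(cbind(latitude, longitude) ~ species + population,
                           data = meta, FUN = mean)
  rows <- list()
  for (sp in unique(pops$species)) {
    pp <- pops$population[pops$species == sp]
    if (length(pp) < 2) next
    for (i in seq_len(length(pp) - 1)) for (j in (i + 1):length(pp)) {
      p1 <- pp[i]; p2 <- pp[j]
      fst <- wcFst(G, p1, p2)$theta
      dx <- dxyWindows(G, p1, p2, windowSize = windowSize)$windows
      c1 <- cent[cent$species == sp & cent$population == p1, ]
      c2 <- cent[cent$species == sp & cent$population == p2, ]
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, pop1 = p1, pop2 = p2, fst = fst,
        dxy = mean(dx$value, na.rm = TRUE),
        distance_km = greatCircleKm(c1$latitude, c1$longitude,
                                    c2$latitude, c2$longitude),
        host_category = pops$host_category[pops$species == sp][1])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
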