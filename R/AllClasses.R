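#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#'   rowRanges
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

## Central containers.  Tabular coalescent-rate series are thin S4 wrappers
## around validated data.frames; gridded ensembles and genotypes reuse the
## SummarizedExperiment infrastructure (assay matrix + row/col annotation).

#' Scaled coalescence-rate series
#'
#' One SMC-style final output: per time segment, dimensionless left/right
#' time boundaries (units of generations times mutation rate) and the scaled
#' coalescence rate lambda.  Ne in individuals is \code{1/(2*mu*lambda)}.
#'
#' @slot table data.frame with columns \code{time_index},
#'   \code{left_time_boundary}, \code{right_time_boundary}, \code{lambda}.
#' @export
setClass("ScaledRateSeries", representation(table = "data.frame"))

setValidity("ScaledRateSeries", function(object) {
  tb <- object@table
  need <- c("time_index", "left_time_boundary", "right_time_boundary", "lambda")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(tb) == 0) return("empty series")
  if (!identical(as.integer(tb$time_index), seq_len(nrow(tb)) - 1L))
    return("time_index must increase by 1 from 0")
  bad <- which(!(tb$left_time_boundary < tb$right_time_boundary))
  if (length(bad))
    return(sprintf("row %d: left boundary not < right boundary", bad[1]))
  if (nrow(tb) > 1) {
    gap <- which(abs(tb$right_time_boundary[-nrow(tb)] -
                     tb$left_time_boundary[-1]) >
                 1e-12 * pmax(1, abs(tb$left_time_boundary[-1])))
    if (length(gap))
      return(sprintf("row %d: segments not contiguous", gap[1] + 1L))
  }
  bad <- which(!(tb$lambda > 0) | !is.finite(tb$lambda))
  if (length(bad))
    return(sprintf("row %d: lambda must be finite and > 0", bad[1]))
  TRUE
})

#' Piecewise-constant Ne trajectory in real units
#'
#' Segments carry years before present (present = 0; last right boundary may
#' be \code{Inf}) and effective population size in individuals, possibly
#' \code{NA} after quality masking.
#'
#' @slot species,population,replicate character labels; replicate is
#'   \code{"main"} or a bootstrap id.
#' @slot segments data.frame with columns \code{t_left}, \code{t_right},
#'   \code{Ne}.
#' @export
setClass("NeTrajectory",
  representation(species = "character", population = "character",
                 replicate = "character", segments = "data.frame"))

setValidity("NeTrajectory", function(object) {
  sg <- object@segments
  need <- c("t_left", "t_right", "Ne")
  if (!all(need %in% names(sg)))
    return("segments need columns t_left, t_right, Ne")
  if (nrow(sg) == 0) return("trajectory has no segments")
  if (any(!(sg$t_left < sg$t_right)))
    return("each segment needs t_left < t_right")
  if (nrow(sg) > 1 &&
      any(abs(sg$t_right[-nrow(sg)] - sg$t_left[-1]) >
          1e-9 * pmax(1, abs(sg$t_left[-1]))))
    return("segments must be contiguous in time")
  if (any(!is.na(sg$Ne) & sg$Ne <= 0))
    return("Ne must be positive where present")
  TRUE
})

#' Within- and cross-population coalescence rates for one population pair
#'
#' @slot table data.frame with columns \code{t_left}, \code{t_right},
#'   \code{lambda_00}, \code{lambda_01}, \code{lambda_11} (within pop 0,
#'   across, within pop 1).  Times may be scaled or real; rates are
#'   nonnegative and not all zero in a row.
#' @export
setClass("CrossCoalSeries", representation(table = "data.frame"))

setValidity("CrossCoalSeries", function(object) {
  tb <- object@table
  need <- c("t_left", "t_right", "lambda_00", "lambda_01", "lambda_11")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(tb) == 0) return("empty series")
  if (any(!(tb$t_left < tb$t_right)))
    return("each row needs t_left < t_right")
  if (nrow(tb) > 1 &&
      any(abs(tb$t_right[-nrow(tb)] - tb$t_left[-1]) >
          1e-9 * pmax(1, abs(tb$t_left[-1]))))
    return("rows must be contiguous in time")
  lam <- as.matrix(tb[, c("lambda_00", "lambda_01", "lambda_11")])
  bad <- which(apply(lam < 0 | !is.finite(lam), 1, any))
  if (length(bad))
    return(sprintf("row %d: rates must be finite and >= 0", bad[1]))
  bad <- which(rowSums(lam) == 0)
  if (length(bad))
    return(sprintf("row %d: all three rates are zero", bad[1]))
  TRUE
})

#' Trajectory ensemble on a common time grid
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"Ne"} holds
#' one column per (species, population, replicate) trajectory and one row per
#' grid time; \code{NA} marks grid points outside a trajectory's coverage or
#' masked by QC.  \code{rowData} carries \code{time} (years BP) and, once
#' aligned, \code{sea_level}; \code{colData} carries \code{species},
#' \code{population}, \code{replicate}, \code{host_category}.
#'
#' @export
setClass("TrajectoryEnsemble", contains = "SummarizedExperiment")

setValidity("TrajectoryEnsemble", function(object) {
  if (!"Ne" %in% SummarizedExperiment::assayNames(object))
    return("assay 'Ne' required")
  if (!"time" %in% names(rowData(object)))
    return("rowData must contain 'time'")
  tm <- rowData(object)$time
  if (any(diff(tm) <= 0)) return("grid times must be strictly increasing")
  need <- c("species", "population", "replicate", "host_category")
  miss <- setdiff(need, names(colData(object)))
  if (length(miss))
    return(paste("colData missing:", paste(miss, collapse = ", ")))
  ne <- assay(object, "Ne")
  if (any(!is.na(ne) & ne <= 0)) return("Ne must be positive where present")
  TRUE
})

#' Sites-by-individuals diploid genotype matrix
#'
#' A \linkS4class{RangedSummarizedExperiment} with assay \code{"GT"} of
#' alternate-allele counts in {0, 1, 2} (NA = missing), biallelic SNPs as
#' width-1 ranges, and a \code{population} column in \code{colData}.
#'
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  if (!"GT" %in% SummarizedExperiment::assayNames(object))
    return("assay 'GT' required")
  gt <- assay(object, "GT")
  if (!all(gt %in% c(0L, 1L, 2L, NA)))
    return("genotypes must be 0, 1, 2 or NA")
  if (!"population" %in% names(colData(object)))
    return("colData must contain 'population'")
  pos <- GenomicRanges::start(rowRanges(object))
  chr <- as.character(GenomicRanges::seqnames(rowRanges(object)))
  for (cc in unique(chr)) {
    if (any(diff(pos[chr == cc]) <= 0))
      return(sprintf("positions not strictly increasing on %s", cc))
  }
  TRUE
})
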