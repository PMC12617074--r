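#' Construct a ScaledRateSeries
#'
#' @param table data.frame with columns \code{time_index},
#'   \code{left_time_boundary}, \code{right_time_boundary}, \code{lambda}.
#' @return A \linkS4class{ScaledRateSeries}.
#' @export
ScaledRateSeries <- function(table) {
  table <- as.data.frame(table)
  if ("time_index" %in% names(table))
    table$time_index <- as.integer(table$time_index)
  new("ScaledRateSeries", table = table)
}

#' Construct an NeTrajectory
#'
#' @param species,population,replicate labels; replicate defaults to "main".
#' @param segments data.frame with columns \code{t_left}, \code{t_right}
#'   (years BP, last may be \code{Inf}) and \code{Ne} (individuals, NA
#'   allowed).
#' @return An \linkS4class{NeTrajectory}.
#' @export
NeTrajectory <- function(species, population, segments, replicate = "main") {
  new("NeTrajectory", species = as.character(species),
      population = as.character(population),
      replicate = as.character(replicate),
      segments = as.data.frame(segments))
}

#' Construct a CrossCoalSeries
#'
#' @param table data.frame with columns \code{t_left}, \code{t_right},
#'   \code{lambda_00}, \code{lambda_01}, \code{lambda_11}.
#' @return A \linkS4class{CrossCoalSeries}.
#' @export
CrossCoalSeries <- function(table) {
  new("CrossCoalSeries", table = as.data.frame(table))
}

#' Construct a TrajectoryEnsemble
#'
#' @param ne numeric matrix, grid times x trajectories (NA outside coverage).
#' @param time numeric vector of grid times in years BP, one per row.
#' @param info data.frame with one row per trajectory: \code{species},
#'   \code{population}, \code{replicate}, \code{host_category}.
#' @return A \linkS4class{TrajectoryEnsemble}.
#' @export
TrajectoryEnsemble <- function(ne, time, info) {
  ne <- as.matrix(ne)
  colnames(ne) <- paste(info$species, info$population, info$replicate,
                        sep = ".")
  se <- SummarizedExperiment(
    assays = list(Ne = ne),
    rowData = DataFrame(time = as.numeric(time)),
    colData = DataFrame(info, row.names = colnames(ne)))
  new("TrajectoryEnsemble", se)
}

#' Construct a GenotypeMatrix
#'
#' @param gt integer matrix of alternate-allele counts (sites x individuals),
#'   values 0/1/2/NA.
#' @param chrom chromosome label(s), recycled over sites.
#' @param pos 1-based positions, strictly increasing within chromosome.
#' @param samples sample names, one per column.
#' @param population population assignment, one per column.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(gt, chrom, pos, samples, population) {
  gt <- matrix(as.integer(gt), nrow = NROW(gt), ncol = NCOL(gt))
  rownames(gt) <- NULL
  colnames(gt) <- samples
  rr <- GRanges(chrom, IRanges(start = as.integer(pos), width = 1L))
  se <- SummarizedExperiment(
    assays = list(GT = gt), rowRanges = rr,
    colData = DataFrame(sample = samples, population = as.character(population),
                        row.names = samples))
  new("GenotypeMatrix", se)
}

## ---- accessors -----------------------------------------------------------

#' Underlying rate table of a series
#' @param x a ScaledRateSeries or CrossCoalSeries.
#' @return The validated data.frame.
#' @export
rateTable <- function(x) x@table

#' Segment table of a trajectory
#' @param x an NeTrajectory.
#' @return data.frame with t_left, t_right, Ne.
#' @export
neSegments <- function(x) x@segments

#' Species / population / replicate labels of a trajectory
#' @param x an NeTrajectory.
#' @return named character vector.
#' @export
trajectoryId <- function(x)
  c(species = x@species, population = x@population, replicate = x@replicate)

#' Grid times of an ensemble (years BP)
#' @param x a TrajectoryEnsemble.
#' @return numeric vector.
#' @export
gridTimes <- function(x) rowData(x)$time

#' Ne matrix of an ensemble (grid times x trajectories)
#' @param x a TrajectoryEnsemble.
#' @return numeric matrix with NA outside coverage.
#' @export
neValues <- function(x) assay(x, "Ne")

#' Per-trajectory annotation of an ensemble
#' @param x a TrajectoryEnsemble.
#' @return data.frame with species, population, replicate, host_category.
#' @export
trajInfo <- function(x) as.data.frame(colData(x))

#' Genotype matrix (alternate-allele counts)
#' @param x a GenotypeMatrix.
#' @return integer matrix, sites x individuals.
#' @export
genotypes <- function(x) assay(x, "GT")

#' Population assignment of individuals
#' @param x a GenotypeMatrix.
#' @return character vector, one entry per column.
#' @export
popAssignment <- function(x) colData(x)$population

## ---- show ----------------------------------------------------------------

setMethod("show", "ScaledRateSeries", function(object) {
  tb <- object@table
  cat("ScaledRateSeries with", nrow(tb), "segments;",
      sprintf("scaled time [%g, %g], lambda [%g, %g]\n",
              min(tb$left_time_boundary), max(tb$right_time_boundary),
              min(tb$lambda), max(tb$lambda)))
})

setMethod("show", "NeTrajectory", function(object) {
  sg <- object@segments
  cat(sprintf("NeTrajectory %s/%s/%s: %d segments, %g-%g years BP, Ne [%g, %g]%s\n",
              object@species, object@population, object@replicate, nrow(sg),
              min(sg$t_left), max(sg$t_right),
              suppressWarnings(min(sg$Ne, na.rm = TRUE)),
              suppressWarnings(max(sg$Ne, na.rm = TRUE)),
              if (anyNA(sg$Ne)) sprintf(" (%d masked)", sum(is.na(sg$Ne)))
              else ""))
})

setMethod("show", "CrossCoalSeries", function(object) {
  cat("CrossCoalSeries with", nrow(object@table), "segments\n")
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat(sprintf("TrajectoryEnsemble: %d grid points x %d trajectories (%d species, %s)\n",
              nrow(object), ncol(object),
              length(unique(colData(object)$species)),
              paste(unique(colData(object)$host_category), collapse = "/")))
  cat(sprintf("  grid %g-%g years BP; %.1f%% of cells covered\n",
              min(rowData(object)$time), max(rowData(object)$time),
              100 * mean(!is.na(assay(object, "Ne")))))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d biallelic sites x %d diploids in %d population(s)\n",
              nrow(object), ncol(object),
              length(unique(colData(object)$population))))
})
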