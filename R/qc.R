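## Quantile-based reliability filters for bootstrap replicates.
##
## Two rules: (1) whole-replicate removal when any in-epoch Ne exceeds the
## 97.5% percentile of all in-epoch Ne values pooled over the species'
## bootstraps (anomalously high bootstrap Ne typically reflects sampled
## hybrids or migrants); (2) value-wise masking of a replicate's own Ne
## values above its 95% quantile (edge segments with little coalescent
## information).  Quantiles use linear interpolation between order
## statistics, h = (n-1)*q (base R type 7), so thresholds are reproducible.

#' Quantile threshold (order-statistic interpolation)
#'
#' @param values numeric vector (NA dropped).
#' @param q probability.
#' @return the h = (n-1)*q interpolated quantile.
#' @export
quantileThreshold <- function(values, q) {
  stats::quantile(values, probs = q, na.rm = TRUE, names = FALSE, type = 7)
}

#' Remove bootstrap replicates with anomalously high Ne
#'
#' Per species (or per population with \code{byPopulation = TRUE}) and
#' epoch, the threshold is the \code{q}-quantile of ALL in-epoch Ne values
#' pooled across that group's trajectories; any trajectory with at least one
#' in-epoch value strictly above the threshold is removed entirely.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param ep an \code{\link{epoch}} defining the evaluation window.
#' @param q quantile, default 0.975.
#' @param byPopulation pool values per population instead of per species.
#' @return list with \code{ensemble} (filtered) and \code{report}
#'   (data.frame of removed replicates: species, population, replicate,
#'   trigger value, threshold).
#' @export
flagOutlierReplicates <- function(ensemble, ep, q = 0.975,
                                  byPopulation = FALSE) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"), inherits(ep, "Epoch"))
  tm <- gridTimes(ensemble)
  inEp <- tm >= ep$t_start & tm <= ep$t_end
  if (!any(inEp)) stop("epoch covers no grid points")
  ne <- neValues(ensemble)[inEp, , drop = FALSE]
  info <- trajInfo(ensemble)
  grp <- if (byPopulation) paste(info$species, info$population)
         else info$species
  drop <- logical(ncol(ne))
  thr <- rep(NA_real_, ncol(ne))
  for (g in unique(grp)) {
    cols <- which(grp == g)
    if (length(cols) < 2)
      stop("need >= 2 replicates for group '", g, "'")
    pool <- ne[, cols, drop = FALSE]
    if (all(is.na(pool))) stop("no in-epoch Ne values for group '", g, "'")
    th <- quantileThreshold(as.vector(pool), q)
    thr[cols] <- th
    drop[cols] <- apply(pool, 2, function(v) any(!is.na(v) & v > th))
  }
  report <- data.frame(
    species = info$species[drop], population = info$population[drop],
    replicate = info$replicate[drop],
    trigger = apply(ne[, drop, drop = FALSE], 2,
                    function(v) suppressWarnings(max(v, na.rm = TRUE))),
    threshold = thr[drop], row.names = NULL)
  list(ensemble = ensemble[, !drop], report = report)
}

#' Mask a replicate's extreme Ne values
#'
#' For each trajectory, the threshold is the \code{q}-quantile of its own
#' non-missing Ne values over all time points; values strictly above it are
#' set to NA.  The default masks wherever the threshold is exceeded; with
#' \code{edgesOnly = TRUE} only leading/trailing runs of above-threshold
#' values are masked.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param q quantile, default 0.95.
#' @param edgesOnly restrict masking to the trajectory edges.
#' @return list with \code{ensemble} (masked) and \code{report} (data.frame
#'   of masked points: species, population, replicate, time, Ne, threshold).
#' @export
trimExtremeValues <- function(ensemble, q = 0.95, edgesOnly = FALSE) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  ne <- neValues(ensemble)
  info <- trajInfo(ensemble)
  tm <- gridTimes(ensemble)
  rows <- list()
  for (j in seq_len(ncol(ne))) {
    v <- ne[, j]
    if (sum(!is.na(v)) < 3) next
    th <- quantileThreshold(v, q)
    over <- !is.na(v) & v > th
    if (edgesOnly && any(over)) {
      cov <- which(!is.na(v))
      keepmask <- logical(length(v))
      lead <- cov[cumall(over[cov])]
      trail <- rev(cov)[cumall(over[rev(cov)])]
      keepmask[c(lead, trail)] <- TRUE
      over <- over & keepmask
    }
    if (any(over)) {
      rows[[length(rows) + 1L]] <- data.frame(
        species = info$species[j], population = info$population[j],
        replicate = info$replicate[j], time = tm[over], Ne = v[over],
        threshold = th)
      ne[over, j] <- NA
    }
  }
  se <- ensemble
  SummarizedExperiment::assay(se, "Ne") <- ne
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), population = character(),
               replicate = character(), time = numeric(), Ne = numeric(),
               threshold = numeric())
  rownames(report) <- NULL
  list(ensemble = se, report = report)
}

## TRUE for the initial run of TRUE values
cumall <- function(x) cumprod(as.integer(x)) > 0

#' Drop listed replicates (curated exclusions)
#'
#' Dataset-specific curation: removes the trajectories named in an
#' exclusion table rather than by any statistical rule.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param exclusions data.frame with columns \code{species},
#'   \code{population}, \code{replicate}; \code{replicate = "*"} removes
#'   the whole population.
#' @return the filtered ensemble.
#' @export
excludeReplicates <- function(ensemble, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0) return(ensemble)
  info <- trajInfo(ensemble)
  drop <- logical(nrow(info))
  for (i in seq_len(nrow(exclusions))) {
    ex <- exclusions[i, ]
    hit <- info$species == ex$species & info$population == ex$population &
      (ex$replicate == "*" | info$replicate == ex$replicate)
    drop <- drop | hit
  }
  ensemble[, !drop]
}

#' Write a QC report as CSV files
#'
#' @param report list as returned by the QC filters; elements that are
#'   data.frames are written as \code{<name>.csv}.
#' @param dir output directory (created if needed).
#' @return paths written, invisibly.
#' @export
writeQCReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(report)) {
    if (is.data.frame(report[[nm]])) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(report[[nm]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
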