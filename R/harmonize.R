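## Common-grid harmonization, covariate alignment and epoch summaries.
##
## All times are years before present (present = 0).  The shared grid is the
## 100-point logarithmic grid between 1 year and the maximum reconstructed
## time rounded to the nearest million years; trajectory values are linearly
## interpolated between segment-midpoint estimates and left NA outside each
## trajectory's coverage.

#' Define a climatic epoch
#'
#' @param name label.
#' @param t_start,t_end epoch bounds in years BP, \code{t_start < t_end}.
#' @return list with class "Epoch".
#' @export
epoch <- function(name, t_start, t_end) {
  stopifnot(is.numeric(t_start), is.numeric(t_end), t_start < t_end,
            t_start >= 0)
  structure(list(name = as.character(name), t_start = t_start, t_end = t_end),
            class = "Epoch")
}

#' Default epoch set
#'
#' Two windows of pronounced sea-level fluctuation (350-150 kya and
#' 120-15 kya) and the post-glacial rise (15-0 kya).  Boundaries are
#' configurable because they delimit qualitative phases of the global
#' sea-level curve rather than sharp events.
#'
#' @return named list of \code{\link{epoch}} objects.
#' @export
defaultEpochs <- function() {
  list(fluctuation_old = epoch("fluctuation_old", 150000, 350000),
       fluctuation_recent = epoch("fluctuation_recent", 15000, 120000),
       rise = epoch("rise", 0, 15000))
}

#' Segment midpoint times of a trajectory
#'
#' The midpoint \code{(t_left + t_right)/2} of each finite segment; segments
#' with an infinite right boundary carry no midpoint and are dropped.
#'
#' @param traj an \linkS4class{NeTrajectory}.
#' @return data.frame with columns \code{t_mid}, \code{Ne}.
#' @export
midpointTimes <- function(traj) {
  stopifnot(is(traj, "NeTrajectory"))
  sg <- neSegments(traj)
  sg <- sg[is.finite(sg$t_right), , drop = FALSE]
  if (nrow(sg) == 0)
    stop("trajectory has no finite segments; cannot form midpoints")
  data.frame(t_mid = (sg$t_left + sg$t_right) / 2, Ne = sg$Ne)
}

#' Build the common logarithmic time grid
#'
#' 100 logarithmically spaced points between 1 and \code{maxTime} rounded to
#' the nearest million years (round-half-up, floor of 1e6):
#' \code{grid[i] = 10^(log10(M) * (i-1)/99)}.
#'
#' @param maxTime maximum reconstructed time in years, > 1.
#' @return numeric vector of length 100.
#' @export
buildCommonGrid <- function(maxTime) {
  stopifnot(is.numeric(maxTime), length(maxTime) == 1, maxTime > 1)
  M <- max(1e6, floor(maxTime / 1e6 + 0.5) * 1e6)
  10^(log10(M) * (0:99) / 99)
}

#' Interpolate midpoint estimates onto a grid
#'
#' Linear interpolation in raw time and raw Ne between bracketing midpoints;
#' grid points before the first or after the last (non-missing) midpoint are
#' NA.  Set \code{logTime = TRUE} to interpolate linearly in log10(time)
#' instead (sensitivity analysis; not the default convention).
#'
#' @param mid data.frame from \code{\link{midpointTimes}}.
#' @param grid numeric vector of grid times.
#' @param logTime interpolate on a log10 time axis.
#' @return numeric vector along \code{grid}, NA outside coverage.
#' @export
interpolateToGrid <- function(mid, grid, logTime = FALSE) {
  mid <- mid[!is.na(mid$Ne), , drop = FALSE]
  if (nrow(mid) < 2)
    stop("need >= 2 non-missing midpoints to interpolate")
  x <- mid$t_mid; xout <- grid
  if (logTime) { x <- log10(x); xout <- log10(xout) }
  stats::approx(x, mid$Ne, xout = xout, method = "linear", rule = 1,
                ties = "ordered")$y
}

#' Assemble trajectories into an ensemble on the common grid
#'
#' Builds the shared 100-point grid from the largest finite midpoint time
#' across trajectories (unless \code{maxTime} is given), interpolates every
#' trajectory onto it, and attaches host-category labels.
#'
#' @param trajs list of \linkS4class{NeTrajectory} objects.
#' @param hosts named character vector mapping species to host category
#'   (one of generalist, RM, EQ, SD or any labelling scheme).
#' @param maxTime optional override for the grid's maximum time.
#' @param logTime passed to \code{\link{interpolateToGrid}}.
#' @return A \linkS4class{TrajectoryEnsemble}.
#' @export
buildEnsemble <- function(trajs, hosts, maxTime = NULL, logTime = FALSE) {
  stopifnot(length(trajs) >= 1, all(vapply(trajs, is, TRUE, "NeTrajectory")))
  mids <- lapply(trajs, midpointTimes)
  if (is.null(maxTime))
    maxTime <- max(vapply(mids, function(m) max(m$t_mid), 0))
  grid <- buildCommonGrid(maxTime)
  ne <- vapply(mids, interpolateToGrid, numeric(length(grid)),
               grid = grid, logTime = logTime)
  info <- do.call(rbind, lapply(trajs, function(tr) {
    id <- trajectoryId(tr)
    data.frame(species = id[["species"]], population = id[["population"]],
               replicate = id[["replicate"]],
               host_category = unname(hosts[id[["species"]]]))
  }))
  if (anyNA(info$host_category))
    stop("species without a host-category label: ",
         paste(unique(info$species[is.na(info$host_category)]), collapse = ", "))
  TrajectoryEnsemble(ne, grid, info)
}

#' Weighted harmonic mean Ne over an epoch
#'
#' \code{H = sum(w) / sum(w / Ne)} with weights \code{w} equal to the
#' duration of overlap between each trajectory segment and the epoch;
#' segments with missing Ne contribute no weight.  Harmonic because genetic
#' drift compounds through 1/Ne.
#'
#' @param traj an \linkS4class{NeTrajectory}.
#' @param ep an \code{\link{epoch}}.
#' @return harmonic-mean Ne (individuals).
#' @export
weightedHarmonicNe <- function(traj, ep) {
  stopifnot(is(traj, "NeTrajectory"), inherits(ep, "Epoch"))
  sg <- neSegments(traj)
  w <- pmax(0, pmin(sg$t_right, ep$t_end) - pmax(sg$t_left, ep$t_start))
  keep <- w > 0 & !is.na(sg$Ne)
  if (!any(keep))
    stop(sprintf("trajectory has no usable overlap with epoch '%s'", ep$name))
  sum(w[keep]) / sum(w[keep] / sg$Ne[keep])
}

#' Epoch-wise harmonic means for a set of trajectories
#'
#' @param trajs list of \linkS4class{NeTrajectory} objects.
#' @param epochs list of \code{\link{epoch}} objects
#'   (default \code{\link{defaultEpochs}}).
#' @param hosts optional named species -> host-category map, added as a
#'   column when given.
#' @return data.frame with one row per trajectory x epoch (NA harmonic mean
#'   where a trajectory has no usable overlap).
#' @export
epochHarmonicMeans <- function(trajs, epochs = defaultEpochs(), hosts = NULL) {
  rows <- lapply(trajs, function(tr) {
    id <- trajectoryId(tr)
    do.call(rbind, lapply(epochs, function(ep) {
      H <- tryCatch(weightedHarmonicNe(tr, ep), error = function(e) NA_real_)
      data.frame(species = id[["species"]], population = id[["population"]],
                 replicate = id[["replicate"]], epoch = ep$name,
                 harmonic_Ne = H)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(hosts)) out$host_category <- unname(hosts[out$species])
  out
}

#' Grid-based harmonic mean (cross-check variant)
#'
#' Riemann approximation of the epoch harmonic mean from an interpolated
#' ensemble column, weighting each in-epoch grid value by the length of its
#' surrounding half-interval.  Used to cross-check the segment-based
#' \code{\link{weightedHarmonicNe}}; the segment version is authoritative
#' because segment durations are the defined weights.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param ep an \code{\link{epoch}}.
#' @return numeric vector, one harmonic mean per trajectory (NA when the
#'   trajectory has no non-missing in-epoch values).
#' @export
gridHarmonicNe <- function(ensemble, ep) {
  tm <- gridTimes(ensemble)
  edges <- c(tm[1], (tm[-1] + tm[-length(tm)]) / 2, tm[length(tm)])
  w <- pmax(0, pmin(edges[-1], ep$t_end) - pmax(edges[-length(edges)], ep$t_start))
  ne <- neValues(ensemble)
  apply(ne, 2, function(v) {
    keep <- w > 0 & !is.na(v)
    if (!any(keep)) return(NA_real_)
    sum(w[keep]) / sum(w[keep] / v[keep])
  })
}

#' Read a sea-level series
#'
#' CSV with columns \code{age_years} (years BP, strictly increasing) and
#' \code{level_m} (metres relative to present).
#'
#' @param path CSV path.
#' @return data.frame with columns \code{age}, \code{level}.
#' @export
readSeaLevel <- function(path) {
  df <- utils::read.csv(path)
  need <- c("age_years", "level_m")
  if (!all(need %in% names(df)))
    stop("sea-level CSV needs columns age_years, level_m")
  out <- data.frame(age = as.numeric(df$age_years),
                    level = as.numeric(df$level_m))
  if (any(diff(out$age) <= 0)) stop("ages must be strictly increasing")
  out
}

#' Write a sea-level series
#'
#' @param sea data.frame with columns \code{age}, \code{level}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSeaLevel <- function(sea, path) {
  utils::write.csv(data.frame(age_years = sea$age, level_m = sea$level),
                   path, row.names = FALSE)
  invisible(path)
}

#' Align a sea-level series with a time grid
#'
#' Linear interpolation of level at each grid time; grid times outside the
#' series' age span are NA (no extrapolation).
#'
#' @param sea data.frame with columns \code{age}, \code{level}.
#' @param grid numeric grid times (years BP).
#' @return numeric vector along \code{grid}.
#' @export
alignCovariate <- function(sea, grid) {
  stats::approx(sea$age, sea$level, xout = grid, method = "linear",
                rule = 1, ties = "ordered")$y
}

#' Standardize to z-scores
#'
#' \code{(x - mean) / sd} over non-missing values; NA propagates.  Applied
#' to covariates over exactly the rows entering a model, after filtering.
#'
#' @param x numeric vector.
#' @return numeric vector of z-scores.
#' @export
standardize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need >= 2 non-missing values to standardize")
  s <- stats::sd(x[ok])
  if (s == 0) stop("cannot standardize values with zero spread")
  (x - mean(x[ok])) / s
}
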