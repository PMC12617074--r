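## Reading/writing SMC-style final output and unit conversion.
##
## Scaled units: times are in units of (generations * mu); the scaled
## coalescence rate lambda maps to Ne = 1/(2 * mu * lambda).  Real times are
## years BEFORE PRESENT (present = 0), matching the orientation of sea-level
## series.

#' Scaling constants for SMC output
#'
#' @param mu mutation rate per generation per site.  Default 4e-8.
#' @param genTime generation time in years.  Default 5.
#' @return validated list with elements \code{mu}, \code{genTime}.
#' @export
scalingConstants <- function(mu = 4e-8, genTime = 5) {
  stopifnot(is.numeric(mu), length(mu) == 1, is.finite(mu), mu > 0,
            is.numeric(genTime), length(genTime) == 1, is.finite(genTime),
            genTime > 0)
  list(mu = mu, genTime = genTime)
}

.read_tsv_header <- function(path, need) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!grepl("^\\s*$", ln)]        # trailing/blank lines ignored
  if (length(ln) < 2)
    stop("format error in '", path, "': need a header line and >= 1 data row")
  hdr <- strsplit(ln[1], "\t", fixed = TRUE)[[1]]
  miss <- setdiff(need, hdr)
  if (length(miss))
    stop("format error in '", path, "': missing column(s) ",
         paste(miss, collapse = ", "))
  body <- strsplit(ln[-1], "\t", fixed = TRUE)
  nf <- lengths(body)
  if (any(nf != length(hdr)))
    stop("format error in '", path, "': row ", which(nf != length(hdr))[1],
         " has ", nf[nf != length(hdr)][1], " fields, expected ", length(hdr))
  m <- do.call(rbind, body)
  colnames(m) <- hdr
  as.data.frame(m, stringsAsFactors = FALSE)[, need, drop = FALSE]
}

.num_or_inf <- function(x) {
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  out[x == "" | tolower(x) == "inf"] <- Inf
  out
}

#' Read an SMC-style final output table
#'
#' Tab-separated file with header columns \code{time_index},
#' \code{left_time_boundary}, \code{right_time_boundary}, \code{lambda};
#' column order is taken from the header.  A blank or "inf" right boundary in
#' the last row is read as \code{Inf}.
#'
#' @param path file path.
#' @return A \linkS4class{ScaledRateSeries}.
#' @export
readSMC <- function(path) {
  need <- c("time_index", "left_time_boundary", "right_time_boundary", "lambda")
  df <- .read_tsv_header(path, need)
  tb <- data.frame(
    time_index = as.integer(df$time_index),
    left_time_boundary = .num_or_inf(df$left_time_boundary),
    right_time_boundary = .num_or_inf(df$right_time_boundary),
    lambda = as.numeric(df$lambda))
  tryCatch(ScaledRateSeries(tb),
           error = function(e) stop("format error in '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
}

#' Write an SMC-style final output table
#'
#' @param series a \linkS4class{ScaledRateSeries}.
#' @param path output path.  Infinite right boundaries are written as "inf".
#' @return \code{path}, invisibly.
#' @export
writeSMC <- function(series, path) {
  stopifnot(is(series, "ScaledRateSeries"))
  tb <- rateTable(series)
  fmt <- function(x) ifelse(is.infinite(x), "inf", format(x, digits = 17))
  ln <- c(paste(c("time_index", "left_time_boundary", "right_time_boundary",
                  "lambda"), collapse = "\t"),
          paste(tb$time_index, fmt(tb$left_time_boundary),
                fmt(tb$right_time_boundary), fmt(tb$lambda), sep = "\t"))
  writeLines(ln, path)
  invisible(path)
}

#' Read a combined cross-coalescence table
#'
#' Tab-separated file with time boundaries and the three rates
#' \code{lambda_00} (within population 0), \code{lambda_01} (across) and
#' \code{lambda_11} (within population 1).
#'
#' @param path file path.
#' @return A \linkS4class{CrossCoalSeries}.
#' @export
readCrossCoal <- function(path) {
  need <- c("t_left", "t_right", "lambda_00", "lambda_01", "lambda_11")
  df <- .read_tsv_header(path, need)
  tb <- data.frame(t_left = .num_or_inf(df$t_left),
                   t_right = .num_or_inf(df$t_right),
                   lambda_00 = as.numeric(df$lambda_00),
                   lambda_01 = as.numeric(df$lambda_01),
                   lambda_11 = as.numeric(df$lambda_11))
  tryCatch(CrossCoalSeries(tb),
           error = function(e) stop("format error in '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
}

#' Write a combined cross-coalescence table
#'
#' @param series a \linkS4class{CrossCoalSeries}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCrossCoal <- function(series, path) {
  stopifnot(is(series, "CrossCoalSeries"))
  tb <- rateTable(series)
  fmt <- function(x) ifelse(is.infinite(x), "inf", format(x, digits = 17))
  ln <- c(paste(c("t_left", "t_right", "lambda_00", "lambda_01", "lambda_11"),
                collapse = "\t"),
          do.call(paste, c(lapply(tb, fmt), sep = "\t")))
  writeLines(ln, path)
  invisible(path)
}

#' Convert a scaled series to a real-unit Ne trajectory
#'
#' Times become years BP via \code{t = scaled_time / mu * genTime}; the
#' coalescence rate becomes \code{Ne = 1 / (2 * mu * lambda)} individuals.
#' An infinite right boundary is preserved.
#'
#' @param series a \linkS4class{ScaledRateSeries}.
#' @param constants output of \code{\link{scalingConstants}}.
#' @param species,population,replicate labels for the resulting trajectory.
#' @return An \linkS4class{NeTrajectory}.
#' @export
scaleToReal <- function(series, constants = scalingConstants(),
                        species = "sp", population = "pop",
                        replicate = "main") {
  stopifnot(is(series, "ScaledRateSeries"))
  tb <- rateTable(series)
  NeTrajectory(
    species = species, population = population, replicate = replicate,
    segments = data.frame(
      t_left = tb$left_time_boundary / constants$mu * constants$genTime,
      t_right = tb$right_time_boundary / constants$mu * constants$genTime,
      Ne = 1 / (2 * constants$mu * tb$lambda)))
}

#' Convert a real-unit trajectory back to scaled units
#'
#' Exact inverse of \code{\link{scaleToReal}} for the same constants.
#'
#' @param traj an \linkS4class{NeTrajectory} with no missing Ne.
#' @param constants output of \code{\link{scalingConstants}}.
#' @return A \linkS4class{ScaledRateSeries}.
#' @export
realToScaled <- function(traj, constants = scalingConstants()) {
  stopifnot(is(traj, "NeTrajectory"))
  sg <- neSegments(traj)
  if (anyNA(sg$Ne))
    stop("cannot convert a trajectory with masked Ne back to scaled units")
  ScaledRateSeries(data.frame(
    time_index = seq_len(nrow(sg)) - 1L,
    left_time_boundary = sg$t_left * constants$mu / constants$genTime,
    right_time_boundary = sg$t_right * constants$mu / constants$genTime,
    lambda = 1 / (2 * constants$mu * sg$Ne)))
}
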