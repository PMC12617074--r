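## Comparative models: mixed-effects regression of Ne on sea level x host
## category x time, a permutation functional ANOVA over whole trajectories,
## epoch-wise rank tests, and the fixed-effect-removal adjustment of
## pairwise FST/dxy.

.fitResult <- function(coefficients, backend, converged, n, note = "") {
  structure(list(coefficients = coefficients, backend = backend,
                 converged = converged, n = n, note = note),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult [%s], n = %d, converged: %s\n", x$backend, x$n,
              x$converged))
  if (nzchar(x$note)) cat(" ", x$note, "\n")
  if (nrow(x$coefficients)) print(x$coefficients, digits = 4)
  invisible(x)
}

#' Build the trajectory model table
#'
#' One row per (species, population, replicate, grid point) with
#' non-missing Ne and sea level; covariates are standardized over exactly
#' the included rows (i.e., after all filtering).
#'
#' @param ensemble a QC-filtered \linkS4class{TrajectoryEnsemble}.
#' @param seaLevel sea level aligned on the ensemble grid
#'   (\code{\link{alignCovariate}}).
#' @return data.frame with columns Ne, sea_z, time_z, host_category,
#'   species, population, replicate, time.
#' @export
buildModelTable <- function(ensemble, seaLevel) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"),
            length(seaLevel) == nrow(ensemble))
  ne <- neValues(ensemble)
  info <- trajInfo(ensemble)
  tm <- gridTimes(ensemble)
  rows <- which(!is.na(ne) & !is.na(seaLevel[row(ne)]), arr.ind = TRUE)
  if (nrow(rows) == 0) stop("model table is empty")
  tab <- data.frame(
    Ne = ne[rows],
    time = tm[rows[, 1]],
    sea_level = seaLevel[rows[, 1]],
    host_category = info$host_category[rows[, 2]],
    species = info$species[rows[, 2]],
    population = info$population[rows[, 2]],
    replicate = info$replicate[rows[, 2]])
  tab$sea_z <- standardize(tab$sea_level)
  tab$time_z <- standardize(tab$time)
  tab
}

#' Mixed-model regression of Ne on sea level x host category x time
#'
#' Fixed effects are the full three-way interaction of standardized sea
#' level, host category and standardized time (optionally plus population);
#' random effects follow the nested species/population/replicate structure.
#' Backends: \code{"lmm"} (default) fits a linear mixed model on log(Ne)
#' via \pkg{lmerTest} -- the log-link correspondence of a Gamma/log model
#' with multiplicative noise -- and \code{"glmm"} fits the Gamma GLMM with
#' log link via \pkg{glmmTMB}.  The default random-effect structure adds a
#' replicate-level random slope for sea level to the nested intercepts:
#' replicate-level noise induces replicate-to-replicate variation in the
#' apparent sea-level response, and gridded trajectories carry strong
#' within-replicate autocorrelation, so intercept-only models understate
#' the uncertainty of the sea-level contrasts.  \code{formulaMode =
#' "literal"} reproduces the plain nested-intercept formula.
#'
#' @param table output of \code{\link{buildModelTable}}.
#' @param backend \code{"lmm"} or \code{"glmm"}.
#' @param formulaMode \code{"randomSlope"} (default) or \code{"literal"}.
#' @param popFixed also include population as a fixed effect.
#' @return A \code{FitResult}; \code{converged} is FALSE (with empty or
#'   flagged coefficients) when the fit degenerates -- never a silent
#'   fallback.
#' @export
fitNeGLMM <- function(table, backend = c("lmm", "glmm"),
                      formulaMode = c("randomSlope", "literal"),
                      popFixed = FALSE) {
  backend <- match.arg(backend)
  formulaMode <- match.arg(formulaMode)
  stopifnot(all(c("Ne", "sea_z", "time_z", "host_category", "species",
                  "population", "replicate") %in% names(table)))
  if (length(unique(table$host_category)) < 2)
    stop("need >= 2 host categories")
  if (!is.factor(table$host_category))   # appearance order, locale-proof
    table$host_category <- factor(table$host_category,
                                  levels = unique(table$host_category))
  table$repid <- interaction(table$species, table$population,
                             table$replicate, drop = TRUE)
  table$popid <- interaction(table$species, table$population, drop = TRUE)
  fx <- "sea_z * host_category * time_z"
  if (popFixed) fx <- paste(fx, "+ population")
  rnd <- switch(formulaMode,
    randomSlope = "(1 + sea_z | repid) + (1 | popid) + (1 | species)",
    literal = "(1 | species) + (1 | popid) + (1 | repid)")
  conv <- TRUE
  note <- character(1)
  if (backend == "lmm") {
    f <- stats::as.formula(paste("log(Ne) ~", fx, "+", rnd))
    fit <- withCallingHandlers(
      tryCatch(lmerTest::lmer(f, data = table),
               error = function(e) { note <<- conditionMessage(e); NULL }),
      warning = function(w) {
        if (!grepl("singular", conditionMessage(w))) conv <<- FALSE
        note <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage"))
    if (is.null(fit))
      return(.fitResult(data.frame(term = character(), estimate = numeric(),
                                   se = numeric(), statistic = numeric(),
                                   p = numeric()),
                        "lmm/lmerTest log(Ne)", FALSE, nrow(table), note))
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                        se = sm[, "Std. Error"], statistic = sm[, "t value"],
                        p = sm[, "Pr(>|t|)"], row.names = NULL)
    bname <- sprintf("lmm/lmerTest log(Ne), %s", formulaMode)
  } else {
    if (!requireNamespace("glmmTMB", quietly = TRUE))
      stop("backend 'glmm' requires the glmmTMB package")
    f <- stats::as.formula(paste("Ne ~", fx, "+", rnd))
    fit <- tryCatch(
      suppressWarnings(glmmTMB::glmmTMB(
        f, data = table, family = stats::Gamma(link = "log"))),
      error = function(e) { note <<- conditionMessage(e); NULL })
    if (is.null(fit) || !isTRUE(fit$fit$convergence == 0)) {
      conv <- FALSE
      if (is.null(fit))
        return(.fitResult(data.frame(term = character(),
                                     estimate = numeric(), se = numeric(),
                                     statistic = numeric(), p = numeric()),
                          "glmm/glmmTMB Gamma(log)", FALSE, nrow(table),
                          note))
    }
    sm <- summary(fit)$coefficients$cond
    coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                        se = sm[, "Std. Error"], statistic = sm[, "z value"],
                        p = sm[, "Pr(>|z|)"], row.names = NULL)
    bname <- sprintf("glmm/glmmTMB Gamma(log), %s", formulaMode)
  }
  if (!is.null(fit) && backend == "lmm") {
    ## boundary (singular) fits are valid boundary estimates; real optimizer
    ## failures and degenerate responses are not
    msgs <- fit@optinfo$conv$lme4$messages
    msgs <- msgs[!grepl("singular", msgs)]
    if (length(msgs)) { conv <- FALSE; note <- paste(msgs, collapse = "; ") }
    if (stats::sigma(fit) < 1e-8) {
      conv <- FALSE; note <- "zero residual variance (degenerate response)"
    }
  }
  .fitResult(coefs, bname, conv, nrow(table), note)
}

## pointwise one-way F across groups for an Ne matrix (rows = grid points)
## NULL entries where fewer than minPerGroup trajectories of any group cover
## the point.
.pointwise_F <- function(y, glab, minPerGroup = 2) {
  groups <- unique(glab)
  K <- length(groups)
  obs <- !is.na(y)
  nk <- sapply(groups, function(g)
    rowSums(obs[, glab == g, drop = FALSE]))        # points x K
  sk <- sapply(groups, function(g)
    rowSums(y[, glab == g, drop = FALSE], na.rm = TRUE))
  mk <- sk / nk
  N <- rowSums(nk)
  m <- rowSums(sk) / N
  ssb <- rowSums(nk * (mk - m)^2)
  sst <- rowSums(y^2, na.rm = TRUE) - N * m^2
  ssw <- sst - ssb
  valid <- apply(nk >= minPerGroup, 1, all) & (N - K) > 0 & ssw > 0
  Fv <- rep(NA_real_, nrow(y))
  Fv[valid] <- (ssb[valid] / (K - 1)) / (ssw[valid] / (N[valid] - K))
  Fv
}

#' Permutation functional ANOVA of Ne trajectories
#'
#' Treats each trajectory as a functional observation on the common grid
#' (on the log scale, matching the multiplicative response).  The pointwise
#' one-way F statistic across host groups is computed at every grid point
#' where each group has at least two covering trajectories; the global
#' statistic is the mean pointwise F.  Significance comes from permuting
#' host labels at the species level (all trajectories of a species move
#' together, respecting their non-independence), with
#' \code{p = (1 + #permuted >= observed) / (B + 1)}.  Deterministic per
#' seed.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param B number of permutations, default 999.
#' @param seed integer seed.
#' @param logNe compare log10(Ne) trajectories (default TRUE).
#' @return list of class "FanovaResult": \code{pointwise} (data.frame
#'   time, F), \code{statistic}, \code{p_value}, \code{B}, \code{seed}.
#' @export
functionalAnova <- function(ensemble, B = 999, seed = 1, logNe = TRUE) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  info <- trajInfo(ensemble)
  glab <- info$host_category
  if (length(unique(glab)) < 2) stop("need >= 2 host groups")
  if (any(table(glab) < 2))
    stop("every host group needs >= 2 trajectories")
  y <- neValues(ensemble)
  if (logNe) y <- log10(y)
  Fobs <- .pointwise_F(y, glab)
  if (all(is.na(Fobs)))
    stop("no grid point is covered by >= 2 trajectories in every group")
  stat <- mean(Fobs, na.rm = TRUE)
  spLab <- vapply(split(glab, info$species), `[`, "", 1)  # species -> host
  sps <- names(spLab)
  perm <- .with_seed(seed, replicate(B, {
    lab <- sample(unname(spLab))
    names(lab) <- sps
    mean(.pointwise_F(y, unname(lab[info$species])), na.rm = TRUE)
  }))
  p <- (1 + sum(perm >= stat, na.rm = TRUE)) / (B + 1)
  structure(list(pointwise = data.frame(time = gridTimes(ensemble),
                                        F = Fobs),
                 statistic = stat, p_value = p, B = B, seed = seed),
            class = "FanovaResult")
}

#' @export
print.FanovaResult <- function(x, ...) {
  cat(sprintf("Permutation functional ANOVA: mean pointwise F = %.3f, p = %.4g (B = %d)\n",
              x$statistic, x$p_value, x$B))
  invisible(x)
}

#' Epoch-wise rank tests of harmonic-mean Ne
#'
#' Within each epoch, a Kruskal-Wallis test across host groups; within each
#' group, Wilcoxon rank-sum tests between every pair of epochs.  Ties are
#' handled by midranks; rows with insufficient data are flagged rather than
#' dropped.
#'
#' @param hm data.frame with columns \code{epoch}, a value column and a
#'   group column (e.g. output of \code{\link{epochHarmonicMeans}} with
#'   hosts attached).
#' @param value,group column names for the tested value and the grouping.
#' @param alternative passed to \code{\link[stats]{wilcox.test}} for the
#'   epoch contrasts, interpreted as epoch1 vs epoch2 in the listed order.
#' @return data.frame: test, epoch, group, statistic, df, p, n, flag.
#' @export
epochRankTests <- function(hm, value = "harmonic_Ne",
                           group = "host_category",
                           alternative = "two.sided") {
  stopifnot(all(c("epoch", value, group) %in% names(hm)))
  hm <- hm[!is.na(hm[[value]]), , drop = FALSE]
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)
  for (ep in unique(hm$epoch)) {
    sub <- hm[hm$epoch == ep, ]
    counts <- table(sub[[group]])
    if (length(counts) >= 2 && all(counts >= 2)) {
      if (stats::var(sub[[value]]) == 0) {
        ## all values tied across groups: no rank variation at all
        add(test = "kruskal_wallis", epoch = ep, group = "all",
            statistic = 0, df = length(counts) - 1, p = 1,
            n = nrow(sub), flag = "ok")
        next
      }
      kw <- stats::kruskal.test(sub[[value]], factor(sub[[group]]))
      add(test = "kruskal_wallis", epoch = ep, group = "all",
          statistic = unname(kw$statistic), df = unname(kw$parameter),
          p = kw$p.value, n = nrow(sub), flag = "ok")
    } else {
      add(test = "kruskal_wallis", epoch = ep, group = "all",
          statistic = NA_real_, df = NA_real_, p = NA_real_,
          n = nrow(sub), flag = "insufficient_data")
    }
  }
  eps <- unique(hm$epoch)
  for (g in unique(hm[[group]])) {
    sub <- hm[hm[[group]] == g, ]
    if (length(eps) < 2) next
    for (i in seq_len(length(eps) - 1)) for (j in (i + 1):length(eps)) {
      x <- sub[[value]][sub$epoch == eps[i]]
      y <- sub[[value]][sub$epoch == eps[j]]
      lab <- paste(eps[i], "vs", eps[j])
      if (length(x) >= 2 && length(y) >= 2) {
        wt <- suppressWarnings(stats::wilcox.test(x, y,
                                                  alternative = alternative))
        add(test = "wilcoxon", epoch = lab, group = g,
            statistic = unname(wt$statistic), df = NA_real_, p = wt$p.value,
            n = length(x) + length(y), flag = "ok")
      } else {
        add(test = "wilcoxon", epoch = lab, group = g,
            statistic = NA_real_, df = NA_real_, p = NA_real_,
            n = length(x) + length(y), flag = "insufficient_data")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Adjust pairwise statistics for distance and divergence time
#'
#' Fits \code{value ~ distance_z + splittime_z + host_category} with
#' crossed random intercepts for the two populations of each pair and a
#' random intercept for species, then removes the fitted contributions of
#' the distance and split-time fixed effects:
#' \code{adjusted = observed - b_dist * distance_z - b_split * splittime_z}.
#' Host and random effects are retained, so species- and population-level
#' structure survives the adjustment.
#'
#' @param table data.frame with columns pop1, pop2, species, value,
#'   distance_km, split_time_years, host_category.
#' @param value name of the statistic column (e.g. "fst" or "dxy").
#' @return list with \code{table} (input plus \code{distance_z},
#'   \code{splittime_z} and \code{adjusted}) and \code{fit} (a
#'   \code{FitResult}).
#' @export
adjustPairwise <- function(table, value = "fst") {
  need <- c("pop1", "pop2", "species", value, "distance_km",
            "split_time_years", "host_category")
  stopifnot(all(need %in% names(table)))
  if (nrow(table) < 10 || length(unique(table$species)) < 2)
    stop("need >= 10 pairs spanning >= 2 species")
  if (any(table$pop1 == table$pop2)) stop("pop1 must differ from pop2")
  tab <- table
  tab$distance_z <- standardize(tab$distance_km)
  tab$splittime_z <- standardize(tab$split_time_years)
  tab$.y <- tab[[value]]
  mm <- stats::model.matrix(~ distance_z + splittime_z + host_category,
                            data = tab)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  conv <- TRUE; note <- ""
  fit <- withCallingHandlers(
    lmerTest::lmer(.y ~ distance_z + splittime_z + host_category +
                     (1 | pop1) + (1 | pop2) + (1 | species), data = tab),
    warning = function(w) {
      if (!grepl("singular", conditionMessage(w))) conv <<- FALSE
      note <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], statistic = sm[, "t value"],
                      p = sm[, "Pr(>|t|)"], row.names = NULL)
  bd <- coefs$estimate[coefs$term == "distance_z"]
  bs <- coefs$estimate[coefs$term == "splittime_z"]
  tab$adjusted <- tab$.y - bd * tab$distance_z - bs * tab$splittime_z
  tab$.y <- NULL
  list(table = tab,
       fit = .fitResult(coefs, "lmm/lmerTest identity link", conv,
                        nrow(tab), note))
}
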