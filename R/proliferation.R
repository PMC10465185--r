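## Dye-dilution deconvolution and precursor-cohort proliferation indices.
##
## The mixture is deliberately rigid: component means are pinned at
## mu0 - g*log10(2) (perfect fluorescence halving per division) and all peaks
## share one SD. Only the weights, the common shift mu0 and sigma are free,
## which keeps sparse high generations identifiable.

peakLogDensity <- function(x, mu0, sigma, weights) {
  gmax <- length(weights) - 1L
  means <- mu0 - (0:gmax) * LOG10_2
  ld <- vapply(seq_along(means),
               function(k) stats::dnorm(x, means[k], sigma, log = TRUE) +
                 log(weights[k]),
               numeric(length(x)))
  if (!is.matrix(ld)) ld <- matrix(ld, nrow = length(x))
  ld
}

emPass <- function(x, mu0, sigma, weights, maxIter, tol) {
  n <- length(x)
  gmax <- length(weights) - 1L
  g <- 0:gmax
  llPrev <- -Inf
  llTrace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  sumx <- sum(x); sumx2 <- sum(x^2)
  repeat {
    iter <- iter + 1L
    ld <- peakLogDensity(x, mu0, sigma, pmax(weights, 1e-300))
    lse <- rowLogSumExp(ld)
    ll <- sum(lse)
    llTrace <- c(llTrace, ll)
    resp <- exp(ld - lse)
    nk <- colSums(resp)
    cx <- colSums(resp * x)
    weights <- nk / n
    mu0 <- (sumx + LOG10_2 * sum(g * nk)) / n
    means <- mu0 - g * LOG10_2
    sigma <- sqrt(max((sumx2 - 2 * sum(cx * means) + sum(nk * means^2)) / n,
                      1e-12))
    if (is.finite(llPrev) && abs(ll - llPrev) < tol) { converged <- TRUE; break }
    if (iter >= maxIter) break
    llPrev <- ll
  }
  list(mu0 = mu0, sigma = sigma, weights = weights, logLik = llTrace[length(llTrace)],
       llTrace = llTrace, nIter = iter, converged = converged)
}

## Shift the whole label set by k generations (mu0 up/down by k peak spacings)
## and renormalize; used to escape label-shifted local optima of EM.
shiftFit <- function(fit, k, gmax) {
  w <- rep(1e-8, gmax + 1L)
  for (g in 0:gmax) {
    gNew <- g + k
    if (gNew >= 0L && gNew <= gmax) w[gNew + 1L] <- w[gNew + 1L] + fit$weights[g + 1L]
  }
  list(mu0 = fit$mu0 + k * LOG10_2, sigma = fit$sigma, weights = w / sum(w))
}

#' Fit a constrained dye-peak mixture
#'
#' Maximum-likelihood fit of the dye-dilution mixture (see
#' [PeakModel-class]) by expectation-maximization: component means are fixed
#' at `mu0 - g * log10(2)` with `mu0`, the shared `sigma` and the weights
#' free. Convergence is declared when successive log-likelihoods differ by
#' less than `tol` (default 1e-8) or after `maxIter` (default 500)
#' iterations; non-convergence sets a flag and raises a warning, not an
#' error. When `mu0Init` is not supplied, `mu0` starts at the mode of the
#' upper-quartile intensities (the brightest peak is the undivided one);
#' after convergence the fit is additionally screened against whole-label
#' shifts of +-1, 2 generations and refitted from the best shift, which
#' protects against a mis-anchored generation 0 when the undivided peak is
#' small.
#'
#' @param x numeric vector of log10 dye intensities (at least 50).
#' @param gMax maximum modelled generation (cells beyond pool into it).
#' @param mu0Init optional starting value for the undivided-peak position.
#' @param maxIter,tol EM iteration cap and log-likelihood tolerance.
#' @return a [PeakModel]. The attribute `"llTrace"` carries the
#'   log-likelihood trace of the final EM pass.
#' @examples
#' x <- simulateDye(sample(0:1, 500, TRUE), mu0 = 4.5, sigma = 0.05, seed = 1)
#' fitPeaks(x, gMax = 1)
#' @export
fitPeaks <- function(x, gMax = 6L, mu0Init = NULL, maxIter = 500L, tol = 1e-8) {
  if (length(x) < 50L) stopInput("fitPeaks requires at least 50 observations")
  if (gMax < 1L) stopInput("gMax must be at least 1")
  gMax <- as.integer(gMax)
  if (is.null(mu0Init)) {
    # the brightest substantial density peak anchors generation 0
    d <- stats::density(x, n = 1024)
    i <- 2:(length(d$y) - 1L)
    pk <- i[d$y[i] > d$y[i - 1L] & d$y[i] >= d$y[i + 1L] &
              d$y[i] > 0.04 * max(d$y)]
    mu0Init <- if (length(pk)) max(d$x[pk]) else d$x[which.max(d$y)]
    # refine against the upper-quartile mode when both agree on the peak
    top <- x[x >= stats::quantile(x, 0.75)]
    if (length(top) >= 10) {
      dt <- stats::density(top, n = 512)
      cand <- dt$x[which.max(dt$y)]
      if (abs(cand - mu0Init) < LOG10_2 / 2) mu0Init <- cand
    }
  }
  near <- x[abs(x - mu0Init) < LOG10_2 / 2]
  sigma0 <- if (length(near) >= 20) max(stats::sd(near), 1e-3)
            else max(min(stats::sd(x) / 2, 0.15), 1e-3)
  fit <- emPass(x, mu0Init, sigma0, rep(1 / (gMax + 1), gMax + 1L), maxIter, tol)
  # escape label-shifted optima: re-anchor generation 0 and keep the best fit
  repeat {
    cand <- lapply(setdiff(-2:2, 0L), function(k) {
      s <- shiftFit(fit, k, gMax)
      emPass(x, s$mu0, s$sigma, s$weights, maxIter = 40L, tol = tol)
    })
    lls <- vapply(cand, `[[`, numeric(1), "logLik")
    if (max(lls) > fit$logLik + 1e-6) {
      best <- cand[[which.max(lls)]]
      fit <- emPass(x, best$mu0, best$sigma, best$weights, maxIter, tol)
    } else break
  }
  if (!fit$converged)
    warning("fitPeaks: EM did not reach tolerance within ", maxIter, " iterations")
  # mu0 is unidentifiable under whole-grid shifts when edge components are
  # empty; anchor the brightest populated component as generation 0
  lead <- which(fit$weights >= 1e-4)
  if (length(lead) && lead[1] > 1L) {
    k <- lead[1] - 1L
    fit$mu0 <- fit$mu0 - k * LOG10_2
    fit$weights <- c(fit$weights[-seq_len(k)], rep(0, k))
  }
  out <- new("PeakModel", mu0 = fit$mu0, sigma = fit$sigma,
             weights = fit$weights / sum(fit$weights), gMax = gMax,
             logLik = fit$logLik, nIter = fit$nIter, converged = fit$converged)
  attr(out, "llTrace") <- fit$llTrace
  out
}

#' Assign each cell to a division generation
#'
#' Each cell receives the generation with maximal posterior responsibility
#' under a fitted [PeakModel]; exact ties are broken toward the lower
#' generation. Accepts a numeric vector of log10 intensities or an
#' [EventTable], in which case every row must carry a dye intensity.
#'
#' @param x intensities or an `EventTable`.
#' @param model a fitted [PeakModel].
#' @return integer vector of generations (0-based).
#' @export
setGeneric("assignGenerations", function(x, model) standardGeneric("assignGenerations"))

#' @rdname assignGenerations
#' @export
setMethod("assignGenerations", "numeric", function(x, model) {
  ld <- peakLogDensity(x, model@mu0, model@sigma, pmax(model@weights, 1e-300))
  mx <- do.call(pmax, as.data.frame(ld))
  gen <- rep(NA_integer_, length(x))
  for (k in rev(seq_len(ncol(ld)))) {
    hit <- ld[, k] >= mx - 1e-9 * pmax(abs(mx), 1)
    gen[hit] <- k - 1L
  }
  gen
})

#' @rdname assignGenerations
#' @export
setMethod("assignGenerations", "EventTable", function(x, model) {
  bad <- which(is.na(x$dye_log_intensity))
  if (length(bad))
    stopInput("rows without dye intensity cannot be assigned a generation: rows ",
              paste(utils::head(bad, 10), collapse = ", "),
              if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10) else "")
  assignGenerations(as.numeric(x$dye_log_intensity), model)
})

#' Deconvolve a whole panel into division generations
#'
#' Fits one [PeakModel] per donor x target subset x day (pooling the
#' co-culture and background conditions, whose proliferation structure is
#' shared) and assigns every dyed cell a generation. NK rows get `NA`.
#'
#' @param events an [EventTable].
#' @param gMax maximum modelled generation.
#' @return list with `generations` (integer vector aligned to `events` rows)
#'   and `models` (named list of [PeakModel]s, `"<donor>.<subset>"`).
#' @export
deconvolveGenerations <- function(events, gMax = 6L) {
  gen <- rep(NA_integer_, nrow(events))
  models <- list()
  isT <- events$subset %in% TARGET_SUBSETS
  key <- paste(events$donor_id, events$subset, sep = ".")
  for (k in unique(key[isT])) {
    idx <- which(isT & key == k)
    model <- fitPeaks(as.numeric(events$dye_log_intensity[idx]), gMax = gMax)
    gen[idx] <- assignGenerations(as.numeric(events$dye_log_intensity[idx]), model)
    models[[k]] <- model
  }
  list(generations = gen, models = models)
}

#' Build a generation profile from counts or per-cell assignments
#'
#' @param counts numeric vector of cell counts per generation (`counts[g+1]`
#'   is generation `g`).
#' @return a [GenerationProfile].
#' @export
generationProfile <- function(counts) {
  if (length(counts) < 1L) stopInput("counts must be non-empty")
  new("GenerationProfile", counts = as.numeric(counts))
}

#' @rdname generationProfile
#' @param generations integer vector of per-cell generation assignments.
#' @param gMax highest generation slot of the profile (defaults to the
#'   maximum observed).
#' @export
tabulateGenerations <- function(generations, gMax = max(generations)) {
  if (any(is.na(generations))) generations <- generations[!is.na(generations)]
  if (!length(generations)) stopInput("no generation assignments supplied")
  counts <- vapply(0:gMax, function(g) sum(generations == g), numeric(1))
  generationProfile(counts)
}

profileTotal <- function(profile) {
  total <- sum(profile@counts)
  if (total <= 0) stopInput("empty generation profile")
  total
}

precursorCounts <- function(profile) {
  g <- seq_along(profile@counts) - 1L
  profile@counts / 2^g
}

#' Proportion of cells that have divided at least once
#'
#' Computed over acquired cells (not back-calculated precursors):
#' `sum(n_g, g >= 1) / sum(n_g)`.
#'
#' @param profile a [GenerationProfile].
#' @return fraction in \[0, 1\].
#' @examples
#' percentDivided(generationProfile(c(6, 40, 54)))  # 0.94
#' @export
percentDivided <- function(profile) {
  total <- profileTotal(profile)
  sum(profile@counts[-1]) / total
}

#' Division index
#'
#' Average number of divisions per cell of the original (precursor)
#' population: with precursor counts `P_g = n_g / 2^g`,
#' `DI = sum(g * P_g) / sum(P_g)`. Undivided precursors count with weight
#' zero, so `DI <= PI` always.
#'
#' @param profile a [GenerationProfile].
#' @return non-negative number.
#' @examples
#' divisionIndex(generationProfile(c(50, 0, 100)))  # 0.6667
#' @export
divisionIndex <- function(profile) {
  profileTotal(profile)
  P <- precursorCounts(profile)
  g <- seq_along(P) - 1L
  sum(g * P) / sum(P)
}

#' Proliferation index
#'
#' Average number of divisions among the precursors that divided at least
#' once: `PI = sum(g * P_g, g >= 1) / sum(P_g, g >= 1)`. Undefined when no
#' cell has divided (raises an undefined-result error, distinct from the
#' input error used for empty profiles).
#'
#' @param profile a [GenerationProfile].
#' @return number >= 1.
#' @examples
#' proliferationIndex(generationProfile(c(0, 40, 40)))  # 1.3333
#' @export
proliferationIndex <- function(profile) {
  profileTotal(profile)
  P <- precursorCounts(profile)
  g <- seq_along(P) - 1L
  div <- g >= 1 & P > 0
  if (!any(div)) stopUndefined("proliferation index undefined: no divided cells")
  sum(g[div] * P[div]) / sum(P[div])
}

#' Compute all proliferation statistics for one population
#'
#' @param profile a [GenerationProfile].
#' @return list with `percent_divided`, `division_index` and
#'   `proliferation_index` (`NA` when undefined).
#' @export
proliferationStats <- function(profile) {
  pi <- tryCatch(proliferationIndex(profile),
                 nkassay_undefined_result = function(e) NA_real_)
  list(percent_divided = percentDivided(profile),
       division_index = divisionIndex(profile),
       proliferation_index = pi)
}

#' Paired comparison of proliferation indices
#'
#' Two-tailed paired t-test of two equally long vectors of per-donor index
#' values (`t = mean(d) / (sd(d)/sqrt(n))` with `d = a - b`, `df = n - 1`).
#'
#' @param a,b paired index values (length >= 2).
#' @return list with `statistic`, `df` and `p.value`.
#' @examples
#' compareIndices(c(1.5, 1.8, 2.0, 1.9), c(1.4, 1.6, 1.7, 1.7))
#' @export
compareIndices <- function(a, b) {
  if (length(a) != length(b)) stopInput("a and b must have equal length")
  if (length(a) < 2L) stopInput("need at least two pairs")
  d <- a - b
  if (stats::var(d) == 0)
    stopDegenerate("zero variance of paired differences; t statistic undefined")
  ht <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}
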