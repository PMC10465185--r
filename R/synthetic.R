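#' Construct a synthetic-cohort configuration
#'
#' Builds a [SimConfig] describing a paired-donor NK killing assay cohort. The
#' defaults are the calibration values of the assay the package models: 14
#' donors harvested at day 2.5 (n = 10) or day 3.5 (n = 4); spontaneous-death
#' group means of 7.0%/16.2% (Tconv, day 2.5/3.5) and 8.6%/9.7% (Treg);
#' stratified specific-killing means of 25.6%/17.7% (CD56br on Tconv,
#' high/low proliferation) and 22.0%/15.0% (CD56br on Treg); 22.5% (Tconv)
#' and 20.7% (Treg) for CD56dim in both strata; and per-subset, per-day
#' division-generation distributions matching the observed proliferation
#' dynamics (94%/71% of Tconv/Treg divided at day 2.5; 97%/87% at day 3.5).
#'
#' Death probabilities are assembled additively on the proportion scale
#' (background + specific-killing mean for the cell's proliferation stratum,
#' clamped to \[0, 1\]) and then shifted on the logit scale by a donor-level
#' offset (SD `donorSdLogit`, shared by all wells of a donor — this is what
#' the donor-pair regression term absorbs) plus a well-level offset (SD
#' `wellSdLogit`, independent per culture well — biological replicate noise).
#'
#' @param nDonors number of donors.
#' @param dayAssignment assay day (2.5 or 3.5) per donor.
#' @param cellsPerPopulation acquired T-cell events per well.
#' @param nkEventsPerPopulation acquired NK events per co-culture well.
#' @param dyeMu0,dyeSigma undivided-peak position and per-peak SD, log10 scale.
#' @param generationDist per subset x day probability vectors over
#'   generations 0..gMax (all four vectors must have equal length).
#' @param backgroundDeath per subset x day x stratum spontaneous-death
#'   proportions.
#' @param killMeans per effector x target x stratum specific-killing means.
#' @param donorSdLogit,wellSdLogit logit-scale SDs of the donor- and
#'   well-level random offsets.
#' @param nkDeathRate death proportion of acquired NK events.
#' @param seed integer RNG seed.
#' @return a validated [SimConfig].
#' @examples
#' cfg <- simConfig(seed = 1, cellsPerPopulation = 500)
#' cfg
#' @export
simConfig <- function(nDonors = 14L,
                      dayAssignment = c(rep(2.5, 10), rep(3.5, 4)),
                      cellsPerPopulation = 20000L,
                      nkEventsPerPopulation = 5000L,
                      dyeMu0 = 4.5,
                      dyeSigma = 0.08,
                      generationDist = defaultGenerationDist(),
                      backgroundDeath = defaultBackgroundDeath(),
                      killMeans = defaultKillMeans(),
                      donorSdLogit = 0.15,
                      wellSdLogit = 0.10,
                      nkDeathRate = 0.05,
                      seed = 1L) {
  cfg <- try(new("SimConfig",
    nDonors = as.integer(nDonors),
    dayAssignment = as.numeric(dayAssignment),
    cellsPerPopulation = as.integer(cellsPerPopulation),
    nkEventsPerPopulation = as.integer(nkEventsPerPopulation),
    dyeMu0 = dyeMu0, dyeSigma = dyeSigma,
    generationDist = generationDist,
    backgroundDeath = backgroundDeath,
    killMeans = killMeans,
    donorSdLogit = donorSdLogit, wellSdLogit = wellSdLogit,
    nkDeathRate = nkDeathRate,
    seed = as.integer(seed)), silent = TRUE)
  if (inherits(cfg, "try-error"))
    stopConfig("invalid SimConfig: ", attr(cfg, "condition")$message)
  cfg
}

#' @rdname simConfig
#' @export
defaultGenerationDist <- function() {
  list(
    Tconv = list(
      "2.5" = c(0.060, 0.200, 0.320, 0.270, 0.139, 0.0051, 0.0059),
      "3.5" = c(0.030, 0.080, 0.200, 0.270, 0.2548, 0.100, 0.0652)
    ),
    Treg = list(
      "2.5" = c(0.290, 0.260, 0.240, 0.150, 0.056, 0.0019, 0.0021),
      "3.5" = c(0.130, 0.070, 0.140, 0.200, 0.2019, 0.150, 0.1081)
    )
  )
}

#' @rdname simConfig
#' @export
defaultBackgroundDeath <- function() {
  list(
    Tconv = list("2.5" = list(high = 0.070, low = 0.070),
                 "3.5" = list(high = 0.162, low = 0.162)),
    Treg = list("2.5" = list(high = 0.086, low = 0.086),
                "3.5" = list(high = 0.097, low = 0.097))
  )
}

#' @rdname simConfig
#' @export
defaultKillMeans <- function() {
  list(
    CD56br = list(Tconv = list(high = 0.256, low = 0.177),
                  Treg = list(high = 0.220, low = 0.150)),
    CD56dim = list(Tconv = list(high = 0.225, low = 0.225),
                   Treg = list(high = 0.207, low = 0.207))
  )
}

#' Simulate log10 dye intensities for given division generations
#'
#' The proliferation dye halves its fluorescence with every division, so a
#' cell in generation `g` is drawn from
#' `Normal(mu0 - g * log10(2), sigma)` on the log10 scale.
#'
#' @param generations non-negative integer vector of division counts.
#' @param mu0 log10 intensity of the undivided peak.
#' @param sigma within-generation SD (log10 scale), > 0.
#' @param seed optional RNG seed.
#' @return numeric vector of log10 intensities.
#' @examples
#' simulateDye(c(0, 1, 3), mu0 = 4.5, sigma = 0.05, seed = 1)
#' @export
simulateDye <- function(generations, mu0, sigma, seed = NULL) {
  if (any(generations < 0) || any(generations != floor(generations)))
    stopInput("generations must be non-negative integers")
  if (sigma <= 0) stopInput("sigma must be > 0")
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(length(generations), mu0 - generations * LOG10_2, sigma)
}

dayKey <- function(day) format(day, nsmall = 1)

#' Simulate an event-level assay panel
#'
#' Generates acquired-cell events for every donor x target subset x condition
#' (`cocult_br`, `cocult_dim`, `alone`) of the cohort described by `config`,
#' plus undyed NK-cell events in the co-culture wells. Per-cell division
#' generations are drawn from the configured generation distributions, dye
#' intensities from the halving model, and death flags from the additive
#' death model (see [simConfig()]); the specific-killing component applied to
#' a co-cultured cell is the one for its proliferation stratum, determined
#' from its true generation and the assay day by the same rule used in the
#' analysis ([stratifyGeneration()]). Output is byte-identical across calls
#' with the same configuration (per-donor RNG substreams are derived
#' deterministically from `config@seed`).
#'
#' @param config a [SimConfig].
#' @return an [EventTable] with ground-truth column `true_generation`.
#' @examples
#' panel <- simulatePanel(simConfig(nDonors = 2, dayAssignment = c(2.5, 2.5),
#'                                  cellsPerPopulation = 200,
#'                                  nkEventsPerPopulation = 50, seed = 7))
#' table(panel$subset, panel$condition)
#' @export
simulatePanel <- function(config) {
  v <- validObject(config, test = TRUE)
  if (!isTRUE(v)) stopConfig("invalid SimConfig: ", paste(v, collapse = "; "))
  gmax <- length(config@generationDist[[1]][[1]]) - 1L
  n <- config@cellsPerPopulation
  nNK <- config@nkEventsPerPopulation
  pieces <- vector("list", config@nDonors)

  for (i in seq_len(config@nDonors)) {
    set.seed((config@seed + 7919L * i) %% .Machine$integer.max)
    donor <- sprintf("D%02d", i)
    day <- config@dayAssignment[i]
    dk <- dayKey(day)
    uDonor <- stats::rnorm(1, 0, config@donorSdLogit)
    dparts <- list()

    for (subset in TARGET_SUBSETS) {
      gd <- config@generationDist[[subset]][[dk]]
      bg <- config@backgroundDeath[[subset]][[dk]]
      for (cond in CONDITIONS) {
        uWell <- stats::rnorm(1, 0, config@wellSdLogit)
        g <- sample(0:gmax, n, replace = TRUE, prob = gd)
        stratum <- stratifyGeneration(g, day)
        p0 <- c(bg$low, bg$high)[(stratum == "high") + 1L]
        if (cond != "alone") {
          eff <- if (cond == "cocult_br") "CD56br" else "CD56dim"
          km <- config@killMeans[[eff]][[subset]]
          p0 <- p0 + c(km$low, km$high)[(stratum == "high") + 1L]
        }
        p <- shiftLogit(clamp01(p0), uDonor + uWell)
        dparts[[length(dparts) + 1L]] <- data.frame(
          donor_id = donor, subset = subset, condition = cond, day = day,
          dye_log_intensity = stats::rnorm(n, config@dyeMu0 - g * LOG10_2,
                                           config@dyeSigma),
          dead = stats::runif(n) < p,
          true_generation = g
        )
      }
    }
    for (cond in c("cocult_br", "cocult_dim")) {
      uWell <- stats::rnorm(1, 0, config@wellSdLogit)
      pNK <- shiftLogit(config@nkDeathRate, uDonor + uWell)
      dparts[[length(dparts) + 1L]] <- data.frame(
        donor_id = donor,
        subset = if (cond == "cocult_br") "NK_br" else "NK_dim",
        condition = cond, day = day,
        dye_log_intensity = NA_real_,
        dead = stats::runif(nNK) < pNK,
        true_generation = NA_integer_
      )
    }
    pieces[[i]] <- do.call(rbind, dparts)
  }
  df <- do.call(rbind, pieces)
  rownames(df) <- NULL
  new("EventTable", DataFrame(df))
}
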