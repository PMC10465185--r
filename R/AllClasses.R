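#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

TARGET_SUBSETS <- c("Tconv", "Treg")
NK_SUBSETS <- c("NK_br", "NK_dim")
CONDITIONS <- c("cocult_br", "cocult_dim", "alone")
EFFECTORS <- c("CD56br", "CD56dim")
STRATA <- c("all", "high", "low")
ASSAY_DAYS <- c(2.5, 3.5)

EVENT_COLUMNS <- c("donor_id", "subset", "condition", "day",
                   "dye_log_intensity", "dead")

KILLING_COLUMNS <- c("donor_id", "effector", "target", "stratum", "day",
                     "dead_fraction", "background_fraction", "specific_killing")

#' SimConfig: parameterization of a synthetic assay cohort
#'
#' Full description of a simulated paired-donor NK killing assay: cohort
#' layout, dye-dilution physics, per-generation population structure,
#' spontaneous (background) death, specific-killing effects and the
#' donor/well-level variability, plus the RNG seed. Construct with
#' [simConfig()], whose defaults are the calibration values of the assay the
#' package models.
#'
#' @slot nDonors number of donors in the cohort.
#' @slot dayAssignment numeric vector (length `nDonors`) of assay days
#'   (2.5 or 3.5) at which each donor's cultures are harvested.
#' @slot cellsPerPopulation acquired T-cell events per donor x subset x
#'   condition well.
#' @slot nkEventsPerPopulation acquired NK-cell events per co-culture well.
#' @slot dyeMu0 log10 fluorescence of the undivided (generation 0) dye peak.
#' @slot dyeSigma within-generation SD of log10 fluorescence.
#' @slot generationDist list: `generationDist[[subset]][[day]]` is a
#'   probability vector over generations `0..gMax`.
#' @slot backgroundDeath list: `backgroundDeath[[subset]][[day]][[stratum]]`,
#'   spontaneous death proportion (stratum is `"high"` or `"low"`).
#' @slot killMeans list: `killMeans[[effector]][[target]][[stratum]]`,
#'   specific-killing group mean added to background in co-culture.
#' @slot donorSdLogit SD of the donor-level logit-scale random offset shared
#'   by all of a donor's wells.
#' @slot wellSdLogit SD of the well-level logit-scale random offset drawn
#'   independently per donor x subset x condition culture.
#' @slot nkDeathRate death proportion for acquired NK events.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
  representation(
    nDonors = "integer",
    dayAssignment = "numeric",
    cellsPerPopulation = "integer",
    nkEventsPerPopulation = "integer",
    dyeMu0 = "numeric",
    dyeSigma = "numeric",
    generationDist = "list",
    backgroundDeath = "list",
    killMeans = "list",
    donorSdLogit = "numeric",
    wellSdLogit = "numeric",
    nkDeathRate = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@nDonors) != 1L || object@nDonors < 1L)
    msg <- c(msg, "nDonors must be a single positive integer")
  if (length(object@dayAssignment) != object@nDonors)
    msg <- c(msg, "day_assignment length must equal n_donors")
  if (!all(object@dayAssignment %in% ASSAY_DAYS))
    msg <- c(msg, "dayAssignment entries must be 2.5 or 3.5")
  if (object@cellsPerPopulation < 1L)
    msg <- c(msg, "cellsPerPopulation must be positive")
  if (object@dyeSigma <= 0)
    msg <- c(msg, "dyeSigma must be > 0")
  for (ss in names(object@generationDist)) {
    for (dd in names(object@generationDist[[ss]])) {
      p <- object@generationDist[[ss]][[dd]]
      if (any(p < 0))
        msg <- c(msg, sprintf("generationDist[%s][%s] has negative entries", ss, dd))
      if (abs(sum(p) - 1) > 1e-9)
        msg <- c(msg, sprintf("generationDist[%s][%s] does not sum to 1", ss, dd))
    }
  }
  flatBg <- unlist(object@backgroundDeath)
  if (!is.numeric(flatBg) || any(flatBg < 0 | flatBg > 1))
    msg <- c(msg, "backgroundDeath values must lie in [0, 1]")
  flatKm <- unlist(object@killMeans)
  if (!is.numeric(flatKm) || any(flatKm < 0 | flatKm > 1))
    msg <- c(msg, "killMeans values must lie in [0, 1]")
  if (object@donorSdLogit < 0) msg <- c(msg, "donorSdLogit must be >= 0")
  if (object@wellSdLogit < 0) msg <- c(msg, "wellSdLogit must be >= 0")
  if (object@nkDeathRate < 0 || object@nkDeathRate > 1)
    msg <- c(msg, "nkDeathRate must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' EventTable: one row per acquired cell
#'
#' A [S4Vectors::DataFrame] subclass holding event-level (per-cell) assay
#' data. Required columns: `donor_id`, `subset` (`Tconv`, `Treg`, `NK_br`,
#' `NK_dim`), `condition` (`cocult_br`, `cocult_dim`, `alone`), `day`,
#' `dye_log_intensity` (log10 fluorescence; `NA` for NK rows, which are not
#' dye-stained), `dead` (viability-dye positive). Synthetic tables carry the
#' ground-truth `true_generation` column. Extra columns are preserved.
#'
#' @export
setClass("EventTable", contains = "DFrame")

setValidity("EventTable", function(object) {
  msg <- character()
  missing <- setdiff(EVENT_COLUMNS, colnames(object))
  if (length(missing))
    return(sprintf("missing mandatory column(s): %s", paste(missing, collapse = ", ")))
  if (!all(object$subset %in% c(TARGET_SUBSETS, NK_SUBSETS)))
    msg <- c(msg, "subset must be one of Tconv, Treg, NK_br, NK_dim")
  if (!all(object$condition %in% CONDITIONS))
    msg <- c(msg, "condition must be one of cocult_br, cocult_dim, alone")
  if (!is.logical(object$dead))
    msg <- c(msg, "dead must be logical")
  isT <- object$subset %in% TARGET_SUBSETS
  if (any(isT & is.na(object$dye_log_intensity)))
    msg <- c(msg, "dye_log_intensity must be present for T-cell rows")
  if (any(!isT & !is.na(object$dye_log_intensity)))
    msg <- c(msg, "dye_log_intensity must be absent for NK rows")
  if (length(msg)) msg else TRUE
})

#' PeakModel: constrained Gaussian mixture over dye-dilution peaks
#'
#' Mixture with component means fixed at `mu0 - g * log10(2)` for generations
#' `g = 0..gMax`, a shared standard deviation and free weights. Fitted by
#' [fitPeaks()].
#'
#' @slot mu0 log10 intensity of the undivided (generation 0) peak.
#' @slot sigma shared per-peak SD (log10 scale).
#' @slot weights mixture weights over generations `0..gMax` (sum to 1).
#' @slot gMax maximum modelled generation.
#' @slot logLik final log-likelihood.
#' @slot nIter EM iterations used.
#' @slot converged whether EM reached the tolerance within the iteration cap.
#' @export
setClass("PeakModel",
  representation(mu0 = "numeric", sigma = "numeric", weights = "numeric",
                 gMax = "integer", logLik = "numeric", nIter = "integer",
                 converged = "logical")
)

setValidity("PeakModel", function(object) {
  msg <- character()
  if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
  if (length(object@weights) != object@gMax + 1L)
    msg <- c(msg, "weights must have gMax + 1 entries")
  if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "weights must be a probability vector (sum 1)")
  if (length(msg)) msg else TRUE
})

#' GenerationProfile: cell counts per division generation
#'
#' Counts `n_g` of acquired cells per generation `g = 0..gMax` for one
#' population. Precursor (founder) counts `P_g = n_g / 2^g` are derived on
#' demand by the index functions, not stored.
#'
#' @slot counts non-negative numeric vector, `counts[g + 1]` is `n_g`.
#' @export
setClass("GenerationProfile", representation(counts = "numeric"))

setValidity("GenerationProfile", function(object) {
  if (length(object@counts) < 1L) return("counts must be non-empty")
  if (any(object@counts < 0) || any(!is.finite(object@counts)))
    return("counts must be finite and non-negative")
  TRUE
})

#' KillingTable: specific-killing records
#'
#' A [S4Vectors::DataFrame] subclass with one row per donor x effector x
#' target x stratum observation: `donor_id`, `effector` (`CD56br`,
#' `CD56dim`), `target` (`Tconv`, `Treg`), `stratum` (`all`, `high`, `low`),
#' `day`, `dead_fraction`, `background_fraction` and `specific_killing`
#' (`dead_fraction - background_fraction`; may be negative). Built by
#' [buildKillingTable()].
#'
#' @export
setClass("KillingTable", contains = "DFrame")

setValidity("KillingTable", function(object) {
  missing <- setdiff(KILLING_COLUMNS, colnames(object))
  if (length(missing))
    return(sprintf("missing mandatory column(s): %s", paste(missing, collapse = ", ")))
  msg <- character()
  if (!isProportion(object$dead_fraction))
    msg <- c(msg, "dead_fraction must lie in [0, 1]")
  if (!isProportion(object$background_fraction))
    msg <- c(msg, "background_fraction must lie in [0, 1]")
  if (any(abs(object$specific_killing -
              (object$dead_fraction - object$background_fraction)) > 1e-12))
    msg <- c(msg, "specific_killing must equal dead_fraction - background_fraction")
  if (!all(object$stratum %in% STRATA))
    msg <- c(msg, "stratum must be one of all, high, low")
  if (length(msg)) msg else TRUE
})

#' RegressionData: response and design for the Beta regression
#'
#' Holds the proportion response (strictly inside (0,1); see
#' [prepareResponse()]), the group factor carrying the contrast of interest,
#' the donor/sample-pair factor (a single-level factor means no pair effects)
#' and the ordered contrast (numerator level, denominator level).
#'
#' @slot y numeric response in (0, 1).
#' @slot group factor; first level is the reference.
#' @slot pair factor; first level is the reference.
#' @slot contrast character of length 2 (numerator, denominator) or 0.
#' @export
setClass("RegressionData",
  representation(y = "numeric", group = "factor", pair = "factor",
                 contrast = "character")
)

setValidity("RegressionData", function(object) {
  msg <- character()
  n <- length(object@y)
  if (n < 1L) msg <- c(msg, "empty response")
  if (any(object@y <= 0 | object@y >= 1))
    msg <- c(msg, "y must lie strictly inside (0, 1); apply prepareResponse() first")
  if (length(object@group) != n || length(object@pair) != n)
    msg <- c(msg, "group and pair must match the length of y")
  if (length(object@contrast) && !all(object@contrast %in% levels(object@group)))
    msg <- c(msg, "contrast levels must be levels of group")
  if (length(object@contrast) && length(object@contrast) != 2L)
    msg <- c(msg, "contrast must have exactly two levels (numerator, denominator)")
  if (length(msg)) msg else TRUE
})

#' PosteriorDraws: MCMC draws from the Beta regression posterior
#'
#' @slot draws matrix of kept draws (rows) by parameter (columns: `alpha`,
#'   `beta_<level>`, `gamma_<level>`, `logphi`).
#' @slot chain integer chain index per row.
#' @slot nChains,nWarmup,nKept sampler configuration.
#' @slot data the [RegressionData] the model was fitted to.
#' @slot rhat split-R-hat per parameter.
#' @slot accept acceptance rate per chain.
#' @slot kernel sampling kernel used per chain (`"laplace-imh"` or
#'   `"adaptive-rwm"`).
#' @slot converged TRUE when all split-R-hat are at most 1.01.
#' @export
setClass("PosteriorDraws",
  representation(draws = "matrix", chain = "integer", nChains = "integer",
                 nWarmup = "integer", nKept = "integer", data = "RegressionData",
                 rhat = "numeric", accept = "numeric", kernel = "character",
                 converged = "logical")
)

setValidity("PosteriorDraws", function(object) {
  if (nrow(object@draws) != length(object@chain))
    return("chain index must match number of draws")
  if (nrow(object@draws) != object@nChains * object@nKept)
    return("draws must contain nChains * nKept rows")
  TRUE
})

#' PosteriorSummary: median, credible interval, FSR and effect draws
#'
#' @slot label what the summarized effect is.
#' @slot median posterior median.
#' @slot ciLow,ciHigh equal-tailed 95% credible bounds (type-7 quantiles).
#' @slot fsr false sign rate: posterior mass on the side of zero (for a
#'   difference) or of the median's sign opposite to the median.
#' @slot draws the effect draws the summary was computed from.
#' @export
setClass("PosteriorSummary",
  representation(label = "character", median = "numeric", ciLow = "numeric",
                 ciHigh = "numeric", fsr = "numeric", draws = "numeric")
)

setValidity("PosteriorSummary", function(object) {
  if (length(object@median) != 1L) return("median must be scalar")
  if (object@ciLow > object@median || object@median > object@ciHigh)
    return("ciLow <= median <= ciHigh must hold")
  if (!is.na(object@fsr) && (object@fsr < 0 || object@fsr > 0.5))
    return("fsr must lie in [0, 0.5]")
  TRUE
})
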