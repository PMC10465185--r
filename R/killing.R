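## Specific-killing statistics under the assay's gating rules: all acquired
## cells are analysed (no scatter pre-gating, dead cells never excluded), T
## cells are told apart from NK cells by dye staining, and the background
## subtracted from a stratum is the matched stratum of the same donor's
## no-NK control.

#' Gate the target (T-cell) events
#'
#' Returns exactly the dye-stained CD4 T-cell rows of an event table. No
#' viability-based exclusion is applied: dead cells stay in, since removing
#' them would bias the killing estimate.
#'
#' @param events an [EventTable].
#' @return the T-cell subset of `events` (still an `EventTable`).
#' @export
gateTargets <- function(events) {
  keep <- events$subset %in% TARGET_SUBSETS
  if (!any(keep)) stopInput("no target (T-cell) rows in the event table")
  events[keep, , drop = FALSE]
}

#' Fraction of dead cells among gated targets
#'
#' @param targets an [EventTable] subset (or any table with a logical `dead`
#'   column) containing at least one row.
#' @return proportion of rows flagged dead.
#' @export
deathFraction <- function(targets) {
  if (nrow(targets) < 1L) stopInput("deathFraction needs at least one target row")
  mean(targets$dead)
}

#' Background-subtracted specific killing
#'
#' `specific_killing = dead_fraction - background_fraction`. Negative values
#' are truthful (co-culture death below the spontaneous background) and are
#' returned as-is with a logical `negative` attribute.
#'
#' @param deadFraction,backgroundFraction proportions in \[0, 1\]
#'   (vectorized).
#' @return numeric; attribute `"negative"` flags values below zero.
#' @examples
#' specificKilling(0.25, 0.084)   # 0.166
#' @export
specificKilling <- function(deadFraction, backgroundFraction) {
  if (!isProportion(deadFraction) || !isProportion(backgroundFraction))
    stopInput("dead and background fractions must lie in [0, 1]")
  out <- deadFraction - backgroundFraction
  attr(out, "negative") <- out < 0
  out
}

stratumThreshold <- function(day) {
  if (!all(day %in% ASSAY_DAYS)) stopInput("unknown assay day: ",
                                           paste(setdiff(day, ASSAY_DAYS), collapse = ", "))
  ifelse(day == 2.5, 2L, 3L)
}

#' Classify cells into proliferation strata
#'
#' A cell is "highly proliferative" when it has undergone at least 2
#' divisions at day 2.5, or at least 3 at day 3.5 (the later harvest uses a
#' higher threshold because proliferation has progressed further).
#'
#' @param generation integer vector of division counts (>= 0).
#' @param day assay day, 2.5 or 3.5 (scalar or vector).
#' @return character vector, `"high"` or `"low"`.
#' @examples
#' stratifyGeneration(c(0, 2, 3), day = 2.5)  # low high high
#' stratifyGeneration(c(0, 2, 3), day = 3.5)  # low low  high
#' @export
stratifyGeneration <- function(generation, day) {
  if (any(generation < 0, na.rm = TRUE)) stopInput("generation must be >= 0")
  thr <- stratumThreshold(day)
  ifelse(generation >= thr, "high", "low")
}

#' Build the per-donor specific-killing table
#'
#' For every donor x effector x target with co-culture data, computes the
#' dead-cell fraction overall (`all`) and within the `high` and `low`
#' proliferation strata, subtracts the same donor and target's no-NK
#' background from the *matching* stratum, and returns one
#' [KillingTable] row per stratum. A co-culture without its `alone` control
#' is an error naming the donor and target.
#'
#' @param events an [EventTable].
#' @param generations integer vector of division generations aligned to the
#'   rows of `events` (NA allowed on NK rows), e.g. from
#'   [deconvolveGenerations()] or the `true_generation` column.
#' @return a [KillingTable].
#' @export
buildKillingTable <- function(events, generations) {
  if (length(generations) != nrow(events))
    stopInput("generations must align with the rows of events")
  targets <- gateTargets(events)
  gens <- generations[events$subset %in% TARGET_SUBSETS]
  if (any(is.na(gens)))
    stopInput("all target rows need a generation assignment")
  stratum <- stratifyGeneration(gens, as.numeric(targets$day))

  rows <- list()
  for (donor in unique(targets$donor_id)) {
    for (target in TARGET_SUBSETS) {
      sel <- targets$donor_id == donor & targets$subset == target
      if (!any(sel)) next
      conds <- unique(targets$condition[sel])
      cocs <- intersect(c("cocult_br", "cocult_dim"), conds)
      if (!length(cocs)) next
      if (!"alone" %in% conds)
        stopInput("missing `alone` background control for donor ", donor,
                  ", target ", target)
      alone <- sel & targets$condition == "alone"
      day <- as.numeric(targets$day[which(sel)[1]])
      for (cond in cocs) {
        eff <- if (cond == "cocult_br") "CD56br" else "CD56dim"
        coc <- sel & targets$condition == cond
        for (str in STRATA) {
          inStr <- if (str == "all") rep(TRUE, nrow(targets)) else stratum == str
          nCoc <- sum(coc & inStr)
          nBg <- sum(alone & inStr)
          if (nCoc == 0L || nBg == 0L) next
          dead <- mean(targets$dead[coc & inStr])
          bg <- mean(targets$dead[alone & inStr])
          rows[[length(rows) + 1L]] <- data.frame(
            donor_id = donor, effector = eff, target = target, stratum = str,
            day = day, dead_fraction = dead, background_fraction = bg,
            specific_killing = dead - bg)
        }
      }
    }
  }
  if (!length(rows)) stopInput("no killing records could be built")
  df <- do.call(rbind, rows)
  df <- df[order(df$donor_id, df$effector, df$target,
                 match(df$stratum, STRATA)), , drop = FALSE]
  rownames(df) <- NULL
  new("KillingTable", DataFrame(df))
}
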