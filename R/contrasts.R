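## Builders that turn killing tables / event tables into RegressionData for
## the three contrasts the assay reports.

#' Regression data for the high- vs low-proliferation contrast
#'
#' One observation per donor and stratum: the specific killing of `target`
#' cells by `effector` NK cells in the `high` and `low` proliferation strata,
#' with the donor as sample-pair factor. The contrast is `high : low`.
#'
#' @param kt a [KillingTable].
#' @param effector `"CD56br"` or `"CD56dim"`.
#' @param target `"Tconv"` or `"Treg"`.
#' @param epsilon boundary clamp passed to [prepareResponse()].
#' @return a [RegressionData].
#' @export
contrastStratum <- function(kt, effector, target, epsilon = 0.005) {
  sel <- kt$effector == effector & kt$target == target &
    kt$stratum %in% c("high", "low")
  if (!any(sel)) stopInput("no stratified records for ", effector, " x ", target)
  y <- prepareResponse(kt$specific_killing[sel], epsilon)
  rd <- regressionData(
    y = y,
    group = factor(kt$stratum[sel], levels = c("low", "high")),
    pair = kt$donor_id[sel],
    contrast = c("high", "low"))
  attr(rd, "nClamped") <- attr(y, "nClamped")
  rd
}

#' Regression data for the Tconv vs Treg contrast
#'
#' One observation per donor and target subset: the overall (`all` stratum)
#' specific killing by `effector` NK cells, donor as pair factor. The
#' contrast is `Tconv : Treg`.
#'
#' @inheritParams contrastStratum
#' @return a [RegressionData].
#' @export
contrastTarget <- function(kt, effector, epsilon = 0.005) {
  sel <- kt$effector == effector & kt$stratum == "all"
  if (!any(sel)) stopInput("no records for effector ", effector)
  y <- prepareResponse(kt$specific_killing[sel], epsilon)
  rd <- regressionData(
    y = y,
    group = factor(kt$target[sel], levels = c("Treg", "Tconv")),
    pair = kt$donor_id[sel],
    contrast = c("Tconv", "Treg"))
  attr(rd, "nClamped") <- attr(y, "nClamped")
  rd
}

#' Regression data for the spontaneous-death day contrast
#'
#' One observation per donor: the dead-cell fraction of `target` cells
#' cultured alone (no NK cells), with the assay day (2.5 vs 3.5) as the group
#' and no pair effects (each donor contributes a single observation). The
#' contrast is `3.5 : 2.5`.
#'
#' @param events an [EventTable] containing `alone` condition rows.
#' @inheritParams contrastStratum
#' @return a [RegressionData].
#' @export
contrastSpontaneousDay <- function(events, target, epsilon = 0.005) {
  sel <- events$subset == target & events$condition == "alone"
  if (!any(sel)) stopInput("no `alone` background rows for ", target)
  ev <- events[sel, , drop = FALSE]
  donors <- unique(ev$donor_id)
  y <- vapply(donors, function(d) mean(ev$dead[ev$donor_id == d]), numeric(1))
  day <- vapply(donors, function(d) as.numeric(ev$day[ev$donor_id == d][1]),
                numeric(1))
  yy <- prepareResponse(y, epsilon)
  rd <- regressionData(
    y = yy,
    group = factor(dayKey(day), levels = c("2.5", "3.5")),
    pair = NULL,
    contrast = c("3.5", "2.5"))
  attr(rd, "nClamped") <- attr(yy, "nClamped")
  rd
}
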